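sig <- synthetic_signature_genes("hrd")

test_that("clustering recovers a planted two-group structure at effect size 3", {
  x <- simulate_expression(30, 30, sig, effect_size = 3, seed = 21)
  cl <- cluster_two_way(x$mat, sig)
  labels <- derive_labels(cl$sample_cluster, x$mat, sig)
  expect_gte(mean(labels == x$labels), 0.95)
})

test_that("a duplicated sample lands in the same cluster", {
  x <- simulate_expression(5, 5, sig, effect_size = 3, seed = 22)
  mat <- cbind(x$mat, DUP = x$mat[, 1])
  cl <- cluster_two_way(mat, sig)
  expect_equal(unname(cl$sample_cluster["DUP"]),
               unname(cl$sample_cluster[colnames(x$mat)[1]]))
})

test_that("cluster guards: sample count and missing signature genes", {
  x <- simulate_expression(3, 3, sig, 1, seed = 23)
  expect_error(cluster_two_way(x$mat[, 1, drop = FALSE], sig),
               "at least 2 samples")
  expect_error(cluster_two_way(x$mat, c(sig, "ABSENT1")), "ABSENT1")
  bad <- x$mat; bad[1, 1] <- NA
  expect_error(cluster_two_way(bad, sig), "missing")
})

test_that("the lower-centroid cluster is labelled DEFICIENT; ties go NORMAL", {
  x <- simulate_expression(10, 10, sig, effect_size = 2, seed = 24)
  cl <- cluster_two_way(x$mat, sig)
  labels <- derive_labels(cl$sample_cluster, x$mat, sig)
  sub <- x$mat[sig, ]
  cent <- vapply(1:2, function(k)
    mean(sub[, cl$sample_cluster == k, drop = FALSE]), 0)
  expect_equal(unique(labels[cl$sample_cluster == which.min(cent)]),
               "DEFICIENT")
  # exact tie: constant matrix
  const <- matrix(5, nrow = length(sig), ncol = 4,
                  dimnames = list(sig, paste0("S", 1:4)))
  clusters <- stats::setNames(c(1L, 1L, 2L, 2L), colnames(const))
  expect_warning(tie <- derive_labels(clusters, const, sig), "equal")
  expect_true(all(tie == "NORMAL"))
})

test_that("KNN guards and nearest-neighbour identity", {
  x <- simulate_expression(10, 10, sig, 3, seed = 25)
  cl <- cluster_two_way(x$mat, sig)
  labels <- derive_labels(cl$sample_cluster, x$mat, sig)
  expect_error(train_knn(x$mat, labels, sig, k = 4), "odd")
  expect_error(train_knn(x$mat, labels, sig, k = 21), "n - 1")
  one_class <- stats::setNames(rep("NORMAL", 20), names(labels))
  expect_error(train_knn(x$mat, one_class, sig), "single class")
  # k = 1, query equal to a training sample: that sample's label, conf 1
  clf <- train_knn(x$mat, labels, sig, k = 1)
  calls <- classify_samples(clf, x$mat)
  expect_equal(stats::setNames(calls$status, calls$sample_id), labels)
  expect_true(all(calls$confidence == 1))
})

test_that("confidence is the majority-vote fraction and always >= 0.5", {
  x <- simulate_expression(20, 20, sig, 1, seed = 26)
  cl <- cluster_two_way(x$mat, sig)
  labels <- derive_labels(cl$sample_cluster, x$mat, sig)
  clf <- train_knn(x$mat, labels, sig, k = 5)
  calls <- classify_samples(clf, x$mat)
  expect_true(all(calls$confidence >= 0.5 & calls$confidence <= 1))
  expect_true(all(calls$confidence %in% (c(3, 4, 5) / 5)))
})

test_that("permuting sample order permutes outputs identically", {
  x <- simulate_expression(15, 15, sig, 3, seed = 27)
  perm <- sample(ncol(x$mat))
  calls1 <- hrd_classify(x$mat, sig, k = 5)
  calls2 <- hrd_classify(x$mat[, perm], sig, k = 5)
  m <- match(calls1$sample_id, calls2$sample_id)
  expect_equal(calls1$hrd_status, calls2$hrd_status[m])
  expect_equal(calls1$hrd_confidence, calls2$hrd_confidence[m])
})

test_that("distances use signature genes only: pre-restriction changes nothing", {
  x <- simulate_expression(10, 10, sig, 2, seed = 28)
  full <- hrd_classify(x$mat, sig, k = 3)
  restricted <- hrd_classify(x$mat[sig, ], sig, k = 3)
  expect_equal(full$hrd_status, restricted$hrd_status)
  expect_equal(full$hrd_confidence, restricted$hrd_confidence)
})

test_that("leave-one-out accuracy is high under strong effect, chance-level under none", {
  x3 <- simulate_expression(50, 50, sig, effect_size = 3, seed = 29)
  cl <- cluster_two_way(x3$mat, sig)
  labels <- derive_labels(cl$sample_cluster, x3$mat, sig)
  clf <- train_knn(x3$mat, labels, sig, k = 5)
  expect_gte(loo_predictive_value(clf), 0.95)
  # no structure: adjusted agreement with hidden labels near zero
  x0 <- simulate_expression(50, 50, sig, effect_size = 0, seed = 30)
  calls0 <- hrd_classify(x0$mat, sig, k = 5)
  expect_lt(label_agreement(calls0$hrd_status,
                            unname(x0$labels[calls0$sample_id])), 0.25)
})

test_that("co-occurrence fractions join HRD calls with HR-gene two-hit evidence", {
  panel <- tiny_panel()
  hits <- data.frame(
    patient_id = sprintf("P%d", 1:6),
    gene = c("BRCA2", "FANCM", "BRCA1", "CHEK2", "BAP1", "BRCA2"),
    hgvs_c = "c.1", tumor_vaf = 0.8, loh = TRUE,
    category = c("LOH", "SOMATIC_SECOND_HIT", "LOH", "LOH", "NONE", "LOH"),
    biallelic_somatic = FALSE, evaluable = TRUE, evidence = "x",
    stringsAsFactors = FALSE)
  calls <- data.frame(
    sample_id = sprintf("P%d", 1:6),
    hrd_status = c("DEFICIENT", "DEFICIENT", "NORMAL", "DEFICIENT",
                   "NORMAL", "DEFICIENT"),
    hrd_confidence = 1,
    parpi_status = c("SENSITIVE", "INSENSITIVE", "INSENSITIVE", "SENSITIVE",
                     "INSENSITIVE", "INSENSITIVE"),
    parpi_confidence = 1, stringsAsFactors = FALSE)
  # denominator: P1, P2, P3, P6 (HR-superpathway LOH or second hit;
  # CHEK2 is checkpoint, BAP1 has no qualifying category)
  co <- hrd_cooccurrence(calls, hits, panel)
  expect_equal(co$n, 4L)
  expect_equal(co$frac_hrd, 3 / 4)
  expect_equal(co$frac_parpi, 1 / 4)
  # 15 of 19 style arithmetic
  expect_equal(round(15 / 19, 2), 0.79)
  empty <- hrd_cooccurrence(calls, hits[hits$category == "NONE", ], panel)
  expect_true(is.na(empty$frac_hrd))
})
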