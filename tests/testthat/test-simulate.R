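test_that("same seed gives identical cohorts; different seeds differ", {
  cfg <- sim_config(n_patients = 150, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$calls, b$calls)
  expect_identical(a$truth, b$truth)
  expect_identical(a$tumor, b$tumor)
  c2 <- simulate_cohort(sim_config(n_patients = 150, seed = 100))
  expect_false(identical(a$calls, c2$calls))
})

test_that("degenerate configs: zero patients and zero carrier fraction", {
  z <- simulate_cohort(sim_config(n_patients = 0, seed = 1))
  expect_equal(nrow(z$patients), 0)
  expect_equal(nrow(z$calls), 0)
  none <- simulate_cohort(sim_config(n_patients = 200, carrier_fraction = 0,
                                     recessive_het_rate = 0, seed = 2))
  expect_equal(sum(none$truth$role == "pathogenic"), 0)
})

test_that("config validation rejects bad weights and probabilities", {
  expect_error(sim_config(cancer_type_weights = c(A = 0.5, B = 0.4)),
               "sum to 1")
  expect_error(sim_config(carrier_fraction = 1.5), "probabilities")
  expect_error(sim_config(tumor_purity_range = c(0.5, 1.2)), "probabilities")
})

test_that("every decoy violates exactly its planted filter stage", {
  cohort <- simulate_cohort(sim_config(n_patients = 300, seed = 5))
  truth <- cohort$truth
  calls <- cohort$calls
  key <- paste(calls$patient_id, calls$hgvs_c)
  decoys <- truth[truth$role == "decoy", ]
  preds <- list(quality = gscreen:::quality_keep,
                population = gscreen:::population_keep,
                consequence = gscreen:::consequence_keep,
                vaf = gscreen:::vaf_keep)
  for (i in seq_len(nrow(decoys))) {
    row <- calls[match(paste(decoys$patient_id[i], decoys$hgvs_c[i]), key), ]
    fails <- names(preds)[!vapply(preds, function(f) f(row), NA)]
    expect_identical(fails, decoys$decoy_stage[i])
  }
})

test_that("planted heterozygous blood VAFs fall in (0.20, 0.65)", {
  cohort <- simulate_cohort(sim_config(n_patients = 2000, seed = 6))
  planted <- cohort$truth[cohort$truth$role != "decoy", ]
  key <- paste(cohort$calls$patient_id, cohort$calls$hgvs_c)
  vafs <- cohort$calls$vaf[match(paste(planted$patient_id, planted$hgvs_c),
                                 key)]
  expect_true(all(vafs > 0.20 & vafs < 0.65))
  expect_true(all(check_blood_heterozygosity(vafs)))
})

test_that("carrier fraction converges to the planted rate (3 SE at n = 5000)", {
  p <- 0.178
  n <- 5000
  cohort <- simulate_cohort(sim_config(n_patients = n, carrier_fraction = p,
                                       common_benign_rate = 0, seed = 7))
  observed <- sum(cohort$truth$role == "pathogenic") / n
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(observed - p), 3 * se)
})

test_that("tumor VAFs hit the closed-form purity expectations", {
  # purity limits
  lim1 <- simulate_tumor_vafs(TRUE, purity = 1, depth = 10000L, seed = 8)
  expect_equal(lim1$expected_vaf, 1)
  expect_equal(lim1$tumor_vaf, 1)
  lim0 <- simulate_tumor_vafs(TRUE, purity = 0, depth = 10000L, seed = 8)
  expect_equal(lim0$expected_vaf, 0.5)
  no_loh <- simulate_tumor_vafs(FALSE, purity = 0.9, depth = 500L, seed = 8)
  expect_equal(no_loh$expected_vaf, 0.5)
  # purity 0.6 with LOH: expected 0.6*1 + 0.4*0.5 = 0.8; Monte Carlo mean
  draws <- simulate_tumor_vafs(rep(TRUE, 10000), purity = 0.6, depth = 50L,
                               seed = 9)
  expect_equal(unique(draws$expected_vaf), 0.8)
  se <- sqrt(0.8 * 0.2 / 50) / sqrt(10000)
  expect_lt(abs(mean(draws$tumor_vaf) - 0.8), 3 * se)
})

test_that("planted LOH frequency converges to loh_fraction", {
  n <- 10000
  cohort <- simulate_cohort(sim_config(n_patients = n, carrier_fraction = 0.2,
                                       loh_fraction = 0.27,
                                       common_benign_rate = 0,
                                       recessive_het_rate = 0, seed = 10))
  planted <- cohort$truth[cohort$truth$role == "pathogenic", ]
  se <- sqrt(0.27 * 0.73 / nrow(planted))
  expect_lt(abs(mean(planted$loh) - 0.27), 3 * se)
})

test_that("expression simulation is deterministic with the stated group shift", {
  x1 <- simulate_expression(20, 30, synthetic_signature_genes("hrd"), 2,
                            seed = 11)
  x2 <- simulate_expression(20, 30, synthetic_signature_genes("hrd"), 2,
                            seed = 11)
  expect_identical(x1$mat, x2$mat)
  expect_equal(sum(x1$labels == "DEFICIENT"), 20)
  sig_means <- rowMeans(x1$mat[x1$signature_genes, x1$labels == "DEFICIENT"]) -
    rowMeans(x1$mat[x1$signature_genes, x1$labels == "NORMAL"])
  expect_lt(abs(mean(sig_means) + 2), 0.5)  # shift ~ -2 on signature genes
})

test_that("reversions are planted with cis frame-restoring somatic indels", {
  cohort <- simulate_cohort(sim_config(n_patients = 4000,
                                       reversion_fraction = 0.3, seed = 12))
  revs <- cohort$truth[cohort$truth$reversion, ]
  expect_gt(nrow(revs), 0)
  for (i in seq_len(nrow(revs))) {
    som <- cohort$somatic[cohort$somatic$patient_id == revs$patient_id[i] &
                            cohort$somatic$gene == revs$gene[i], ]
    germ <- cohort$calls[cohort$calls$patient_id == revs$patient_id[i] &
                           cohort$calls$hgvs_c == revs$hgvs_c[i], ]
    expect_true(any(detect_reversion(germ$indel_net_length,
                                     som$indel_net_length,
                                     som$phase_vs_germline)))
  }
})
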