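test_that("blood heterozygosity check is strict at 0.65", {
  expect_true(check_blood_heterozygosity(0.50))
  expect_false(check_blood_heterozygosity(0.65))
  expect_true(check_blood_heterozygosity(0.64999))
})

test_that("LOH calling is strict at the 0.65 cutoff and monotone in VAF", {
  expect_equal(call_loh(c(0.64, 0.65, 0.66)), c(FALSE, FALSE, TRUE))
  expect_true(call_loh(0.87))  # high-tumor-VAF nonsense-variant case
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(diff(call_loh(grid)) >= 0))  # monotone
  expect_true(is.na(call_loh(NA_real_)))       # no tumor is not "no LOH"
})

test_that("reversion detection: worked BRCA2 pair and phase requirement", {
  # germline 2-bp deletion + somatic 1-bp deletion in cis: net -3, in frame
  expect_true(detect_reversion(-2L, -1L, "CIS"))
  expect_false(detect_reversion(-2L, -1L, "TRANS"))
  expect_false(detect_reversion(-2L, -1L, "UNKNOWN"))  # conservative
  # symmetric in which indel is labelled germline vs somatic
  expect_true(detect_reversion(-1L, -2L, "CIS"))
})

test_that("reversion matches the exhaustive mod-3 oracle on [-6,6]^2 x phases", {
  grid <- expand.grid(g = -6:6, s = -6:6,
                      phase = c("CIS", "TRANS", "UNKNOWN"),
                      stringsAsFactors = FALSE)
  got <- detect_reversion(grid$g, grid$s, grid$phase)
  oracle <- grid$phase == "CIS" & (grid$g + grid$s) %% 3 == 0
  expect_equal(got, oracle)
})

somatic_row <- function(gene = "BRCA2", consequence = "NONSENSE",
                        splice_offset = 0L, net = 0L, phase = "TRANS",
                        pair = "UNKNOWN") {
  data.frame(patient_id = "P1", gene = gene, hgvs_c = "c.som",
             consequence = consequence, splice_offset = splice_offset,
             indel_net_length = net, phase_vs_germline = phase,
             somatic_pair_phase = pair, stringsAsFactors = FALSE)
}

test_that("second-hit precedence: reversion beats second hit beats LOH", {
  germ_fs <- make_calls(1, consequence = "FRAMESHIFT",
                        indel_net_length = -2L)
  # cis frame-restoring deletion: reversion, not second hit
  rev <- detect_second_hit(germ_fs, 0.5,
                           somatic_row(consequence = "FRAMESHIFT",
                                       net = -1L, phase = "CIS"))
  expect_equal(rev$category, "REVERSION")
  # trans somatic hit wins over LOH-level VAF
  hit <- detect_second_hit(germ_fs, 0.80, somatic_row(phase = "TRANS"))
  expect_equal(hit$category, "SOMATIC_SECOND_HIT")
  expect_true(hit$loh)  # VAF verdict still recorded independently
  # unknown phase counts for second hit
  expect_equal(detect_second_hit(germ_fs, 0.5,
                                 somatic_row(phase = "UNKNOWN"))$category,
               "SOMATIC_SECOND_HIT")
  # LOH only
  expect_equal(detect_second_hit(germ_fs, 0.80, NULL)$category, "LOH")
  # nothing
  none <- detect_second_hit(germ_fs, 0.5, NULL)
  expect_equal(none$category, "NONE")
  # no tumor sample: NONE with explicit reason, not an LOH=false claim
  nt <- detect_second_hit(germ_fs, NA_real_, NULL)
  expect_equal(nt$category, "NONE")
  expect_equal(nt$evidence, "no_tumor")
  expect_true(is.na(nt$loh))
})

test_that("two splice hits on opposite alleles flag biallelic somatic inactivation", {
  germ <- make_calls(1, consequence = "FRAMESHIFT", indel_net_length = -2L)
  som <- rbind(
    somatic_row(consequence = "SPLICE_SITE", splice_offset = -1L,
                phase = "UNKNOWN", pair = "OPPOSITE_ALLELES"),
    somatic_row(consequence = "SPLICE_SITE", splice_offset = 3L,
                phase = "UNKNOWN", pair = "OPPOSITE_ALLELES"))
  res <- detect_second_hit(germ, 0.5, som)
  expect_equal(res$category, "SOMATIC_SECOND_HIT")
  expect_true(res$biallelic_somatic)
})

test_that("second-hit results are deterministic for fixed inputs", {
  germ <- make_calls(1, consequence = "FRAMESHIFT", indel_net_length = -2L)
  som <- somatic_row(phase = "UNKNOWN")
  r1 <- detect_second_hit(germ, 0.7, som)
  r2 <- detect_second_hit(germ, 0.7, som)
  expect_identical(r1, r2)
})

test_that("loh_fraction computes over evaluable variants with pathway subsets", {
  panel <- tiny_panel()
  res <- data.frame(
    patient_id = sprintf("P%d", 1:6),
    gene = c("BRCA2", "BRCA1", "FANCM", "CHEK2", "XPC", "BRCA2"),
    hgvs_c = sprintf("c.%d", 1:6),
    tumor_vaf = c(0.9, 0.5, 0.8, 0.5, 0.5, NA),
    loh = c(TRUE, FALSE, TRUE, FALSE, FALSE, NA),
    category = c("LOH", "NONE", "LOH", "NONE", "NONE", "NONE"),
    biallelic_somatic = FALSE,
    evaluable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    evidence = "x", stringsAsFactors = FALSE)
  expect_equal(loh_fraction(res), 2 / 5)   # NA-tumor row excluded
  # HR subset counts FANCONI genes as HR
  expect_equal(loh_fraction(res, panel, "HR"), 2 / 3)
  expect_true(is.na(loh_fraction(res[res$evaluable == FALSE, ])))
})

test_that("19 LOH among 100 evaluable gives 0.19", {
  res <- data.frame(patient_id = sprintf("P%d", 1:100), gene = "BRCA2",
                    hgvs_c = sprintf("c.%d", 1:100),
                    tumor_vaf = 0.5, loh = c(rep(TRUE, 19), rep(FALSE, 81)),
                    category = "NONE", biallelic_somatic = FALSE,
                    evaluable = TRUE, evidence = "x",
                    stringsAsFactors = FALSE)
  expect_equal(loh_fraction(res), 0.19)
})

test_that("second_hit_table joins tumor and somatic data per germline variant", {
  panel <- tiny_panel()
  germ <- select_reportable(classify_variants(
    make_calls(3, patient_id = c("P1", "P2", "P3"),
               gene = c("BRCA2", "ATM", "BAP1"),
               consequence = c("FRAMESHIFT", "NONSENSE", "NONSENSE"),
               indel_net_length = c(-2L, 0L, 0L)), panel))
  tumor <- data.frame(patient_id = c("P1", "P2"),
                      gene = c("BRCA2", "ATM"),
                      hgvs_c = germ$hgvs_c[1:2],
                      tumor_vaf = c(0.5, 0.9), tumor_depth = 60L)
  som <- somatic_row(consequence = "FRAMESHIFT", net = -1L, phase = "CIS")
  tab <- second_hit_table(germ, tumor, som)
  expect_equal(tab$category, c("REVERSION", "LOH", "NONE"))
  expect_equal(tab$evaluable, c(TRUE, TRUE, FALSE))
  expect_equal(tab$evidence[3], "no_tumor")
})
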