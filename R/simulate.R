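#' Synthetic cohort generation
#'
#' Generates cohorts with the statistical structure the screening analysis
#' assumes, so every downstream stage is testable without patient data:
#' heterozygous germline blood VAFs drawn binomially around 0.5 at the
#' stated depth (so calls fall below the 0.65 heterozygosity bound),
#' planted pathogenic variants with the observed consequence mix, decoy
#' variants that each violate exactly one named filter, tumor VAFs shifted
#' under loss of heterozygosity with variable purity, somatic second hits
#' including cis-phased frame-restoring indels, heterozygous carriers of
#' recessive-gene variants, and a two-group expression structure over
#' signature genes. A truth table records every planted event.
#'
#' The defaults are the published cohort's stated world: 636 patients with
#' the Table-1 cancer-type mix, carrier fraction 0.178, mean depth 50,
#' LOH fraction 0.27 among carriers (the HR-gene figure), second-hit
#' fraction 6/113, reversion fraction 1/113, recessive-het rate 16/636,
#' tumor purity uniform on \[0.4, 0.9\].
#'
#' The noise model is binomial read sampling only: filter decoys are
#' planted explicitly rather than arising from substitution noise, because
#' the tests need labelled violations, not realism. Each carrier is
#' planted exactly one pathogenic variant.
#'
#' @name synthetic_cohort
NULL

## Fig-1c-style per-gene prior on pathogenic variants: counts for the most
## frequently hit genes, weight 1 elsewhere (arbitrary beyond the top 10).
TOP_GENE_WEIGHTS <- c(CHEK2 = 15, BRCA2 = 15, BRCA1 = 7, ATM = 6,
                      FANCM = 5, BAP1 = 5, BLM = 4, FANCA = 4, ATR = 4,
                      NBN = 4)

## Consequence mix of the 121 reportable variants (51/42/18/9/1).
CONSEQUENCE_MIX <- c(FRAMESHIFT = 51, NONSENSE = 42, SPLICE_SITE = 18,
                     MISSENSE = 9, START_LOSS = 1) / 121

DECOY_STAGES <- c("quality", "depth", "population", "consequence", "vaf")

## data.frame builder that recycles scalars to an explicit row count
## (base data.frame cannot recycle a scalar against zero-length columns).
vdf <- function(.n, ...) {
  cols <- lapply(list(...), rep_len, .n)
  as.data.frame(cols, stringsAsFactors = FALSE)
}


#' Simulation configuration
#'
#' @param n_patients cohort size; default 636.
#' @param cancer_type_weights named probability vector over cancer types
#'   (must sum to 1 within 1e-9); default: Table-1 cohort proportions.
#' @param carrier_fraction probability a patient carries one planted
#'   pathogenic variant in a dominant panel gene; default 0.178.
#' @param per_gene_weights named sampling weights over dominant panel
#'   genes; default: observed per-gene counts for the top genes, 1
#'   elsewhere.
#' @param mean_depth mean sequencing depth (reads); default 50.
#' @param qual_noise_fraction fraction of planted calls given a borderline
#'   (but passing) quality in \[20, 30); default 0.05.
#' @param common_benign_rate expected decoy variants per patient, each
#'   violating exactly one filter; default 2.
#' @param recessive_het_rate probability of a heterozygous pathogenic
#'   variant in a recessive gene (MUTYH/NTHL1); default 16/636.
#' @param tumor_purity_range tumor purity interval in \[0, 1\]; default
#'   c(0.4, 0.9).
#' @param loh_fraction probability a planted pathogenic variant shows LOH
#'   in the tumor; default 0.27.
#' @param second_hit_fraction probability of a trans/unknown-phase somatic
#'   second hit; default 6/113.
#' @param reversion_fraction probability (among frameshift carriers) of a
#'   cis frame-restoring somatic indel; default 1/113.
#' @param expression_effect_size standardized mean difference on signature
#'   genes between the HRD and normal expression groups; default 3.
#' @param seed integer master seed; all stochastic operations derive
#'   sub-seeds from it deterministically.
#' @param panel gene panel used for gene sampling; default
#'   [default_panel()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 636,
                       cancer_type_weights = NULL,
                       carrier_fraction = 0.178,
                       per_gene_weights = NULL,
                       mean_depth = 50,
                       qual_noise_fraction = 0.05,
                       common_benign_rate = 2,
                       recessive_het_rate = 16 / 636,
                       tumor_purity_range = c(0.4, 0.9),
                       loh_fraction = 0.27,
                       second_hit_fraction = 6 / 113,
                       reversion_fraction = 1 / 113,
                       expression_effect_size = 3,
                       seed = 1L,
                       panel = default_panel()) {
  if (is.null(cancer_type_weights)) {
    t1 <- read_tsv(gscreen_extdata("table1_types.tsv"), comment.char = "#")
    cancer_type_weights <- stats::setNames(t1$n_patients / sum(t1$n_patients),
                                           t1$cancer_type)
  }
  if (abs(sum(cancer_type_weights) - 1) > 1e-9) {
    stop("cancer_type_weights must sum to 1", call. = FALSE)
  }
  probs <- c(carrier_fraction, qual_noise_fraction, recessive_het_rate,
             loh_fraction, second_hit_fraction, reversion_fraction,
             tumor_purity_range)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities and purities must lie in [0, 1]", call. = FALSE)
  }
  dominant <- panel$symbol[panel$inheritance == "DOMINANT"]
  if (is.null(per_gene_weights)) {
    per_gene_weights <- stats::setNames(rep(1, length(dominant)), dominant)
    hit <- intersect(names(TOP_GENE_WEIGHTS), dominant)
    per_gene_weights[hit] <- TOP_GENE_WEIGHTS[hit]
  }
  structure(list(n_patients = n_patients,
                 cancer_type_weights = cancer_type_weights,
                 carrier_fraction = carrier_fraction,
                 per_gene_weights = per_gene_weights,
                 mean_depth = mean_depth,
                 qual_noise_fraction = qual_noise_fraction,
                 common_benign_rate = common_benign_rate,
                 recessive_het_rate = recessive_het_rate,
                 tumor_purity_range = tumor_purity_range,
                 loh_fraction = loh_fraction,
                 second_hit_fraction = second_hit_fraction,
                 reversion_fraction = reversion_fraction,
                 expression_effect_size = expression_effect_size,
                 seed = as.integer(seed), panel = panel),
            class = "sim_config")
}

## Depth draw: Poisson around mean_depth, floored at 10 so planted
## (non-decoy) calls always pass the depth filter.
draw_depth <- function(n, mean_depth) {
  pmax(stats::rpois(n, mean_depth), 10L)
}

## Blood VAF of a planted heterozygous call: binomial around 0.5 at the
## given depth, rejection-sampled into the open interval (0.20, 0.65) —
## the generator's stated world is a cohort in which every germline blood
## VAF was observed below the 65% heterozygosity bound (and above the 20%
## call filter), so planted calls honour both by construction.
draw_blood_vaf <- function(depth) {
  n <- length(depth)
  vaf <- stats::rbinom(n, depth, 0.5) / depth
  bad <- which(vaf <= 0.20 | vaf >= 0.65)
  while (length(bad) > 0) {
    vaf[bad] <- stats::rbinom(length(bad), depth[bad], 0.5) / depth[bad]
    bad <- bad[vaf[bad] <= 0.20 | vaf[bad] >= 0.65]
  }
  vaf
}

frameshift_net <- function(n) {
  sample(c(-4L, -2L, -1L, 1L, 2L), n, replace = TRUE)
}

#' Expected tumor VAF and binomial draws under (possible) LOH
#'
#' Under loss of the wild-type allele, a fraction `purity` of the biopsy's
#' cells carry only the variant allele and the normal remainder is
#' heterozygous, so the expected tumor VAF is
#' `purity * 1 + (1 - purity) * 0.5`; without LOH it stays 0.5. Read
#' counts are drawn binomially at the stated depth.
#'
#' @param loh logical vector: is the event a planted LOH?
#' @param purity tumor purity in \[0, 1\] (scalar or vector).
#' @param depth tumor read depth (scalar or vector).
#' @param seed integer seed.
#' @return data.frame with `expected_vaf`, `tumor_vaf`, `tumor_depth`.
#' @export
simulate_tumor_vafs <- function(loh, purity, depth, seed = 1L) {
  stopifnot(all(purity >= 0 & purity <= 1))
  set.seed(derive_seed(seed, "tumor_vaf"))
  n <- length(loh)
  purity <- rep_len(purity, n)
  depth <- rep_len(as.integer(depth), n)
  expected <- ifelse(loh, purity + (1 - purity) * 0.5, 0.5)
  vaf <- stats::rbinom(n, depth, expected) / depth
  data.frame(expected_vaf = expected, tumor_vaf = vaf, tumor_depth = depth)
}

#' Simulate a screening cohort with ground truth
#'
#' @param config a [sim_config()].
#' @return list with `patients` (patient_id, cancer_type, family_history),
#'   `calls` (variant call table, see [variant_calls]), `tumor` (tumor
#'   observations of the planted pathogenic variants), `somatic` (somatic
#'   second hits and reversions), `curation` (overrides making planted
#'   pathogenic missense variants class 5), and `truth` (one row per
#'   planted variant: `role` pathogenic/decoy/recessive_het, the decoy's
#'   violated stage, and the planted LOH / second-hit / reversion flags
#'   and purity). Fully reproducible from `config$seed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_patients
  empty <- function() {
    list(patients = data.frame(patient_id = character(),
                               cancer_type = character(),
                               family_history = logical()),
         calls = empty_variant_calls(),
         tumor = data.frame(patient_id = character(), gene = character(),
                            hgvs_c = character(), tumor_vaf = numeric(),
                            tumor_depth = integer()),
         somatic = normalize_somatic(NULL),
         curation = data.frame(gene = character(), hgvs_c = character(),
                               acmg_class = integer(), source = character()),
         truth = data.frame(patient_id = character(), gene = character(),
                            hgvs_c = character(), role = character(),
                            decoy_stage = character(), consequence = character(),
                            loh = logical(), second_hit = logical(),
                            reversion = logical(), purity = numeric()),
         config = config)
  }
  if (n == 0) return(empty())

  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    cancer_type = sample(names(config$cancer_type_weights), n, replace = TRUE,
                         prob = config$cancer_type_weights),
    family_history = stats::runif(n) < 0.3,
    stringsAsFactors = FALSE)
  panel <- config$panel

  make_calls_block <- function(pid, gene, hgvs, cons, splice_offset, qual,
                               depth, vaf, pop_af, net, zygosity = "HET") {
    k <- length(pid)
    vdf(k, patient_id = pid, gene = gene, chrom = "chr1",
        pos = 1000L + seq_len(k), ref = "A", alt = "T",
        hgvs_c = hgvs, hgvs_p = NA_character_, consequence = cons,
        splice_offset = splice_offset, call_quality = qual,
        depth = depth, vaf = vaf, pop_af = pop_af,
        known_pathogenic_common = FALSE, indel_net_length = net,
        zygosity = zygosity, phase = "UNKNOWN")
  }

  ## --- planted pathogenic variants (one per carrier, dominant genes) ----
  idx_car <- which(stats::runif(n) < config$carrier_fraction)
  m <- length(idx_car)
  genes <- names(config$per_gene_weights)
  gene <- if (m > 0) sample(genes, m, replace = TRUE,
                            prob = config$per_gene_weights) else character()
  cons <- if (m > 0) sample(names(CONSEQUENCE_MIX), m, replace = TRUE,
                            prob = CONSEQUENCE_MIX) else character()
  depth <- draw_depth(m, config$mean_depth)
  qual <- ifelse(stats::runif(m) < config$qual_noise_fraction,
                 stats::runif(m, 20, 30), stats::runif(m, 30, 60))
  hgvs <- sprintf("c.%d_sim", seq_len(m))
  net <- ifelse(cons == "FRAMESHIFT", frameshift_net(m), 0L)
  path_calls <- make_calls_block(
    patients$patient_id[idx_car], gene, hgvs, cons,
    splice_offset = ifelse(cons == "SPLICE_SITE",
                           sample(c(-2L, -1L, 1L, 2L), m, replace = TRUE), 0L),
    qual = qual, depth = depth, vaf = draw_blood_vaf(depth),
    pop_af = ifelse(stats::runif(m) < 0.9, 0,
                    stats::runif(m, 1e-4, 0.005)),
    net = net)
  curation <- vdf(sum(cons == "MISSENSE"),
                  gene = gene[cons == "MISSENSE"],
                  hgvs_c = hgvs[cons == "MISSENSE"],
                  acmg_class = 5L, source = "simulated")
  ## tumor observation + somatic events
  purity <- stats::runif(m, config$tumor_purity_range[1],
                         config$tumor_purity_range[2])
  loh <- stats::runif(m) < config$loh_fraction
  reversion <- cons == "FRAMESHIFT" &
    stats::runif(m) < config$reversion_fraction
  second_hit <- !reversion & stats::runif(m) < config$second_hit_fraction
  tdepth <- draw_depth(m, config$mean_depth)
  expected <- ifelse(loh, purity + (1 - purity) * 0.5, 0.5)
  tumor <- vdf(m, patient_id = patients$patient_id[idx_car],
               gene = gene, hgvs_c = hgvs,
               tumor_vaf = stats::rbinom(m, tdepth, expected) / tdepth,
               tumor_depth = tdepth)
  som_rev <- vdf(sum(reversion),
    patient_id = patients$patient_id[idx_car][reversion],
    gene = gene[reversion],
    hgvs_c = sprintf("%s_som_rev", hgvs[reversion]),
    consequence = "FRAMESHIFT", splice_offset = 0L,
    indel_net_length = -(net[reversion] %% 3L),
    phase_vs_germline = "CIS", somatic_pair_phase = "UNKNOWN")
  k_hit <- sum(second_hit)
  som_hit <- vdf(k_hit,
    patient_id = patients$patient_id[idx_car][second_hit],
    gene = gene[second_hit],
    hgvs_c = sprintf("%s_som_hit", hgvs[second_hit]),
    consequence = "NONSENSE", splice_offset = 0L, indel_net_length = 0L,
    phase_vs_germline = if (k_hit > 0)
      sample(c("TRANS", "UNKNOWN"), k_hit, replace = TRUE) else character(),
    somatic_pair_phase = "UNKNOWN")
  truth_path <- vdf(m,
    patient_id = patients$patient_id[idx_car], gene = gene, hgvs_c = hgvs,
    role = "pathogenic", decoy_stage = NA_character_, consequence = cons,
    loh = loh, second_hit = second_hit, reversion = reversion,
    purity = purity)

  ## --- heterozygous carriers of recessive-gene variants ----------------
  rec_genes <- intersect(c("MUTYH", "NTHL1"),
                         panel$symbol[panel$inheritance == "RECESSIVE"])
  idx_rec <- if (length(rec_genes) > 0) {
    which(stats::runif(n) < config$recessive_het_rate)
  } else integer()
  r <- length(idx_rec)
  rgene <- if (r > 0) sample(rec_genes, r, replace = TRUE) else character()
  rdepth <- draw_depth(r, config$mean_depth)
  rhgvs <- sprintf("c.%d_rec", seq_len(r))
  rec_calls <- make_calls_block(
    patients$patient_id[idx_rec], rgene, rhgvs, "NONSENSE",
    splice_offset = 0L, qual = stats::runif(r, 30, 60), depth = rdepth,
    vaf = draw_blood_vaf(rdepth), pop_af = 0, net = 0L)
  truth_rec <- vdf(r,
    patient_id = patients$patient_id[idx_rec], gene = rgene, hgvs_c = rhgvs,
    role = "recessive_het", decoy_stage = NA_character_,
    consequence = "NONSENSE", loh = FALSE, second_hit = FALSE,
    reversion = FALSE, purity = NA_real_)

  ## --- decoys: each violates exactly one filter stage -------------------
  n_decoy <- stats::rpois(n, config$common_benign_rate)
  d <- sum(n_decoy)
  dpid <- rep(patients$patient_id, n_decoy)
  stage <- if (d > 0) sample(DECOY_STAGES, d, replace = TRUE) else character()
  ddepth <- draw_depth(d, config$mean_depth)
  dqual <- stats::runif(d, 30, 60)
  dvaf <- draw_blood_vaf(ddepth)
  dcons <- rep("MISSENSE", d)
  daf <- numeric(d)
  dqual[stage == "quality"] <- stats::runif(sum(stage == "quality"), 2, 19.9)
  low <- stage == "depth"
  ddepth[low] <- sample(1:9, sum(low), replace = TRUE)
  dvaf[low] <- 0.5
  daf[stage == "population"] <- stats::runif(sum(stage == "population"),
                                             0.02, 0.30)
  dcons[stage == "consequence"] <- "SYNONYMOUS"
  dvaf[stage == "vaf"] <- stats::runif(sum(stage == "vaf"), 0.02, 0.20)
  dgene <- if (d > 0) sample(panel$symbol, d, replace = TRUE) else character()
  dhgvs <- sprintf("c.%d_dec", seq_len(d))
  decoy_calls <- make_calls_block(dpid, dgene, dhgvs, dcons,
                                  splice_offset = 0L, qual = dqual,
                                  depth = ddepth, vaf = dvaf, pop_af = daf,
                                  net = 0L)
  truth_dec <- vdf(d,
    patient_id = dpid, gene = dgene, hgvs_c = dhgvs, role = "decoy",
    decoy_stage = ifelse(stage == "depth", "quality", stage),
    consequence = dcons, loh = FALSE, second_hit = FALSE, reversion = FALSE,
    purity = NA_real_)

  e <- empty()
  calls <- rbind(path_calls, rec_calls, decoy_calls)
  calls$pos <- 1000L + seq_len(nrow(calls))  # unique positions across blocks
  list(patients = patients,
       calls = if (nrow(calls) > 0) normalize_variant_calls(calls) else e$calls,
       tumor = tumor,
       somatic = rbind(som_rev, som_hit),
       curation = curation,
       truth = rbind(truth_path, truth_rec, truth_dec),
       config = config)
}

#' Simulate a two-group expression matrix over signature genes
#'
#' Signature genes are shifted down by `effect_size` (in units of the
#' within-group standard deviation, 1) in the HRD group; non-signature
#' genes are exchangeable standard-normal noise. The hidden group labels
#' are returned for recovery testing.
#'
#' @param n_hrd,n_normal group sizes (both >= 1).
#' @param signature_genes character vector of signature gene names.
#' @param effect_size standardized mean difference, >= 0.
#' @param seed integer seed.
#' @param n_noise_genes number of additional noise genes; default 180.
#' @return list with `mat` (genes x samples), `labels` (named
#'   DEFICIENT/NORMAL vector, hidden truth), `signature_genes`.
#' @export
simulate_expression <- function(n_hrd, n_normal, signature_genes,
                                effect_size, seed = 1L,
                                n_noise_genes = 180) {
  stopifnot(n_hrd >= 1, n_normal >= 1, effect_size >= 0)
  set.seed(derive_seed(seed, "expression"))
  genes <- c(signature_genes, sprintf("NOISE%04d", seq_len(n_noise_genes)))
  n <- n_hrd + n_normal
  samples <- sprintf("S%04d", seq_len(n))
  labels <- stats::setNames(
    sample(c(rep("DEFICIENT", n_hrd), rep("NORMAL", n_normal))), samples)
  mat <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes),
                dimnames = list(genes, samples))
  ## log-scale baseline intensity 8 keeps values in a realistic array range
  mat <- mat + 8
  hrd_cols <- labels == "DEFICIENT"
  mat[signature_genes, hrd_cols] <- mat[signature_genes, hrd_cols] - effect_size
  list(mat = mat, labels = labels, signature_genes = signature_genes)
}
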