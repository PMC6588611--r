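#' Paired tumor analysis: LOH, second hits, reversions
#'
#' Integrates the tumor observation of each reportable germline variant
#' (tumor VAF plus same-gene somatic calls with phase) into a single
#' second-hit verdict per germline variant, following Knudson's two-hit
#' model:
#' \itemize{
#'   \item LOH is called when the tumor VAF of a germline heterozygous
#'     variant exceeds 0.65 (strict; 0.65 itself is not LOH). Blood VAFs
#'     below 0.65 are consistent with heterozygosity. No purity correction
#'     is applied before thresholding: biopsies contaminated with normal
#'     tissue under-call LOH, which is the documented behaviour.
#'   \item A somatic reversion is a somatic indel in cis with a germline
#'     frameshift whose combined net length is a multiple of 3, restoring
#'     the reading frame and neutralising the germline variant.
#'   \item A somatic second hit is any other reportable-consequence somatic
#'     variant in the same gene with phase TRANS or UNKNOWN (the published
#'     analysis counts hits whose allelic location could not be resolved).
#' }
#'
#' Precedence for the per-variant category: REVERSION, then
#' SOMATIC_SECOND_HIT, then LOH, then NONE. Two somatic hits on opposite
#' alleles additionally raise a `biallelic_somatic` flag (gene inactivated
#' without germline contribution). A variant with no tumor sample is
#' reported NONE with reason `no_tumor` and is excluded from LOH
#' denominators ("evaluable" = tumor VAF observed).
#'
#' @name tumor_integration
NULL

SOMATIC_COLUMNS <- c("patient_id", "gene", "hgvs_c", "consequence",
                     "splice_offset", "indel_net_length",
                     "phase_vs_germline", "somatic_pair_phase")

normalize_somatic <- function(somatic) {
  if (is.null(somatic)) {
    somatic <- data.frame(patient_id = character(), gene = character(),
                          hgvs_c = character(), consequence = character(),
                          splice_offset = integer(),
                          indel_net_length = integer(),
                          phase_vs_germline = character(),
                          somatic_pair_phase = character(),
                          stringsAsFactors = FALSE)
  }
  if (!"somatic_pair_phase" %in% names(somatic)) {
    somatic$somatic_pair_phase <- rep("UNKNOWN", nrow(somatic))
  }
  if (!"splice_offset" %in% names(somatic)) {
    somatic$splice_offset <- rep(0L, nrow(somatic))
  }
  check_columns(somatic, SOMATIC_COLUMNS, "somatic variant table")
  check_enum(somatic$phase_vs_germline, PHASES, "phase_vs_germline")
  check_enum(somatic$somatic_pair_phase,
             c("SAME_ALLELE", "OPPOSITE_ALLELES", "UNKNOWN"),
             "somatic_pair_phase")
  somatic
}

#' Is a blood VAF consistent with heterozygosity?
#'
#' @param vaf_blood blood variant allele fraction(s) in \[0, 1\].
#' @return logical: `vaf_blood < 0.65` (strict).
#' @export
check_blood_heterozygosity <- function(vaf_blood) {
  stopifnot(all(is.na(vaf_blood) | (vaf_blood >= 0 & vaf_blood <= 1)))
  vaf_blood < 0.65
}

#' Call loss of heterozygosity from a tumor VAF
#'
#' @param tumor_vaf tumor variant allele fraction(s); NA (no tumor sample)
#'   returns NA, never FALSE.
#' @param cutoff LOH threshold on the tumor VAF; default 0.65, strict.
#' @return logical vector, `tumor_vaf > cutoff`.
#' @export
call_loh <- function(tumor_vaf, cutoff = 0.65) {
  tumor_vaf > cutoff
}

#' Detect a frame-restoring somatic reversion
#'
#' True iff the somatic variant lies on the same allele (CIS) as the
#' germline frameshift and the summed net indel length is a multiple of 3.
#' UNKNOWN phase is conservative: never a reversion. Symmetric in which
#' indel is labelled germline vs somatic.
#'
#' @param germline_net,somatic_net signed net indel lengths in bases.
#' @param phase phase of the somatic variant relative to the germline
#'   allele: CIS, TRANS or UNKNOWN.
#' @return logical vector.
#' @export
detect_reversion <- function(germline_net, somatic_net, phase) {
  check_enum(phase, PHASES, "phase")
  phase == "CIS" & (germline_net + somatic_net) %% 3 == 0
}

somatic_reportable <- function(somatic) {
  is_lof(somatic$consequence, somatic$splice_offset) |
    (somatic$consequence == "MISSENSE" &
       isTRUE_vec(somatic$curated_pathogenic))
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & x
}

#' Second-hit verdict for one germline variant
#'
#' @param germline one-row data.frame of the reportable germline variant
#'   (needs `consequence`, `indel_net_length`).
#' @param tumor_vaf tumor VAF of the germline variant, NA if no tumor.
#' @param somatic data.frame of same-gene somatic variants for the patient
#'   (see [tumor_integration]; may have 0 rows). Somatic hits count as
#'   reportable when loss-of-function, or MISSENSE with a TRUE
#'   `curated_pathogenic` column.
#' @param loh_cutoff passed to [call_loh()].
#' @return list with `category`, `biallelic_somatic`, `loh` (logical VAF
#'   verdict independent of precedence), `evidence`.
#' @export
detect_second_hit <- function(germline, tumor_vaf, somatic,
                              loh_cutoff = 0.65) {
  somatic <- normalize_somatic(somatic)
  loh <- call_loh(tumor_vaf, loh_cutoff)
  biallelic <- nrow(somatic) >= 2 &&
    any(somatic$somatic_pair_phase == "OPPOSITE_ALLELES")
  reversion <- FALSE
  if (nrow(somatic) > 0 && identical(germline$consequence, "FRAMESHIFT")) {
    reversion <- any(somatic$indel_net_length != 0 &
                       detect_reversion(germline$indel_net_length,
                                        somatic$indel_net_length,
                                        somatic$phase_vs_germline))
  }
  hit <- nrow(somatic) > 0 &&
    any(somatic_reportable(somatic) &
          somatic$phase_vs_germline %in% c("TRANS", "UNKNOWN"))
  category <- if (reversion) {
    "REVERSION"
  } else if (hit) {
    "SOMATIC_SECOND_HIT"
  } else if (isTRUE(loh)) {
    "LOH"
  } else {
    "NONE"
  }
  evidence <- if (is.na(tumor_vaf) && category == "NONE") "no_tumor" else category
  list(category = category, biallelic_somatic = biallelic,
       loh = loh, evidence = evidence)
}

#' Second-hit table for a cohort
#'
#' Applies [detect_second_hit()] to every reportable germline variant,
#' joining tumor observations by (patient_id, gene, hgvs_c) and somatic
#' calls by (patient_id, gene).
#'
#' @param classified reportable germline variants.
#' @param tumor data.frame with `patient_id`, `gene`, `hgvs_c`,
#'   `tumor_vaf`, `tumor_depth` (tumor observation of each germline
#'   variant; missing rows mean no tumor sample).
#' @param somatic somatic variant table (see [tumor_integration]), or NULL.
#' @param loh_cutoff LOH threshold, default 0.65.
#' @return data.frame, one row per germline variant: tumor VAF, `loh`,
#'   `category`, `biallelic_somatic`, `evaluable`, `evidence`.
#' @export
second_hit_table <- function(classified, tumor, somatic = NULL,
                             loh_cutoff = 0.65) {
  somatic <- normalize_somatic(somatic)
  n <- nrow(classified)
  key <- paste(classified$patient_id, classified$gene, classified$hgvs_c,
               sep = "\r")
  tkey <- paste(tumor$patient_id, tumor$gene, tumor$hgvs_c, sep = "\r")
  tidx <- match(key, tkey)
  tumor_vaf <- tumor$tumor_vaf[tidx]
  skey <- paste(somatic$patient_id, somatic$gene, sep = "\r")
  out <- data.frame(patient_id = classified$patient_id,
                    gene = classified$gene, hgvs_c = classified$hgvs_c,
                    tumor_vaf = tumor_vaf, loh = NA, category = NA_character_,
                    biallelic_somatic = FALSE, evaluable = !is.na(tumor_vaf),
                    evidence = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    gkey <- paste(classified$patient_id[i], classified$gene[i], sep = "\r")
    som_i <- somatic[skey == gkey, , drop = FALSE]
    res <- detect_second_hit(classified[i, , drop = FALSE], tumor_vaf[i],
                             som_i, loh_cutoff)
    out$loh[i] <- res$loh
    out$category[i] <- res$category
    out$biallelic_somatic[i] <- res$biallelic_somatic
    out$evidence[i] <- res$evidence
  }
  out
}

#' Fraction of evaluable germline variants showing LOH
#'
#' Evaluable means a tumor VAF was observed; variants without a tumor
#' sample enter neither numerator nor denominator. The optional pathway
#' subset restricts both by the gene's pathway, with FANCONI counting as
#' HR (see [hr_super_pathway()]).
#'
#' @param results output of [second_hit_table()].
#' @param panel a `gene_panel`, required when `pathway` is given.
#' @param pathway optional pathway label (e.g. `"HR"`).
#' @return fraction in \[0, 1\], or NA when no variant is evaluable.
#' @export
loh_fraction <- function(results, panel = NULL, pathway = NULL) {
  sel <- results$evaluable
  if (!is.null(pathway)) {
    stopifnot(!is.null(panel))
    pw <- hr_super_pathway(panel_lookup(results$gene, panel, "pathway"))
    sel <- sel & pw == hr_super_pathway(pathway)
  }
  if (!any(sel)) return(NA_real_)
  sum(results$loh[sel], na.rm = TRUE) / sum(sel)
}
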