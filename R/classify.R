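#' Simplified deterministic ACMG/AMP-style pathogenicity classification
#'
#' The published classification is expert manual curation (population
#' frequency, in-silico splice and missense tools, literature, locus
#' databases). This engine is an explicit simplification faithful to the
#' observed class composition (the large majority of reportable variants
#' are loss-of-function types): a loss-of-function rule plus a curation
#' override channel that absorbs the role of the in-silico tools and expert
#' databases.
#'
#' Rule table, in precedence order, for a variant that has passed the
#' filter cascade and lies in a panel gene:
#' \enumerate{
#'   \item a curated assertion (class 1-5), when supplied, determines the
#'     class (tag `curated_override`);
#'   \item loss-of-function consequence (FRAMESHIFT, NONSENSE, START_LOSS,
#'     or SPLICE_SITE with |splice_offset| <= 2): class 5 when pop_af is 0
#'     or missing (tag `lof_novel`), class 4 otherwise (tag `lof_rare`).
#'     The pop_af = 0 grading of 5 vs 4 is a documented stand-in; the
#'     source procedure does not state one;
#'   \item MISSENSE without curation: class 3 (tag `missense_default`);
#'   \item anything else: class 3 (tag `default_vus`).
#' }
#'
#' Classification is a pure function of (variant, panel, curation): same
#' input, same class.
#'
#' @name variant_classifier
NULL

ACMG_CLASSES <- c("1_BENIGN", "2_LIKELY_BENIGN", "3_VUS",
                  "4_LIKELY_PATHOGENIC", "5_PATHOGENIC")

is_lof <- function(consequence, splice_offset) {
  off <- ifelse(is.na(splice_offset), 0L, splice_offset)
  consequence %in% c("FRAMESHIFT", "NONSENSE", "START_LOSS") |
    (consequence == "SPLICE_SITE" & abs(off) <= 2)
}

#' Classify filtered variants
#'
#' @param calls variant call data.frame that passed [run_cascade()].
#' @param panel a `gene_panel`; calls in genes off the panel raise an
#'   `off_panel` error.
#' @param curation optional curation override table with columns `gene`,
#'   `hgvs_c`, `acmg_class` (integer 1-5) and optionally `source`; matched
#'   by (gene, hgvs_c).
#' @return the input with added columns `acmg_class` (integer 1-5),
#'   `acmg_label` (e.g. `"5_PATHOGENIC"`) and `evidence_tag`.
#' @export
classify_variants <- function(calls, panel, curation = NULL) {
  if (nrow(calls) == 0) {
    calls$acmg_class <- integer(0)
    calls$acmg_label <- character(0)
    calls$evidence_tag <- character(0)
    return(calls)
  }
  off <- setdiff(unique(calls$gene), panel$symbol)
  if (length(off) > 0) {
    stop("off_panel: cannot classify variants in gene(s) not on the panel: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  cur <- rep(NA_integer_, nrow(calls))
  if (!is.null(curation) && nrow(curation) > 0) {
    check_columns(curation, c("gene", "hgvs_c", "acmg_class"),
                  "curation table")
    key <- paste(calls$gene, calls$hgvs_c, sep = "\r")
    ckey <- paste(curation$gene, curation$hgvs_c, sep = "\r")
    idx <- match(key, ckey)
    cur <- as.integer(curation$acmg_class[idx])
  }
  lof <- is_lof(calls$consequence, calls$splice_offset)
  novel <- is.na(calls$pop_af) | calls$pop_af == 0
  cls <- ifelse(!is.na(cur), cur,
                ifelse(lof, ifelse(novel, 5L, 4L), 3L))
  tag <- ifelse(!is.na(cur), "curated_override",
                ifelse(lof, ifelse(novel, "lof_novel", "lof_rare"),
                       ifelse(calls$consequence == "MISSENSE",
                              "missense_default", "default_vus")))
  calls$acmg_class <- as.integer(cls)
  calls$acmg_label <- ACMG_CLASSES[cls]
  calls$evidence_tag <- tag
  calls
}

#' Keep only reportable (class 4 and 5) variants
#'
#' Classes 1-3 (benign, likely benign, uncertain) are disregarded for all
#' downstream analysis. Idempotent; raising a curated assertion never
#' removes a variant from the reportable set.
#'
#' @param classified output of [classify_variants()].
#' @return the class >= 4 subset.
#' @export
select_reportable <- function(classified) {
  classified[classified$acmg_class >= 4L, , drop = FALSE]
}

#' Exclude heterozygous singletons in recessive genes
#'
#' A patient's reportable variants in a RECESSIVE panel gene count toward
#' carrier status only when homozygous, or when the patient carries two or
#' more reportable variants in that gene whose pairwise phase is TRANS or
#' UNKNOWN (potential compound heterozygote; UNKNOWN is counted inclusively
#' since the search is for *potential* compound heterozygotes). Remaining
#' heterozygous singletons — and CIS pairs, which sit on one allele — are
#' diverted to a separate table, reported but not counted as carriers.
#'
#' @param classified reportable classified variants (see
#'   [select_reportable()]); must carry `zygosity` and `phase`.
#' @param panel a `gene_panel`.
#' @return list with `kept` (variants counting toward carrier status) and
#'   `excluded_recessive_het`.
#' @export
apply_inheritance_filter <- function(classified, panel) {
  if (nrow(classified) == 0) {
    return(list(kept = classified, excluded_recessive_het = classified))
  }
  inh <- panel_lookup(classified$gene, panel, "inheritance")
  recessive <- inh == "RECESSIVE"
  keep <- rep(TRUE, nrow(classified))
  idx_rec <- which(recessive)
  if (length(idx_rec) > 0) {
    grp <- paste(classified$patient_id[idx_rec], classified$gene[idx_rec],
                 sep = "\r")
    for (g in unique(grp)) {
      rows <- idx_rec[grp == g]
      hom <- classified$zygosity[rows] == "HOM"
      compound <- length(rows) >= 2 &&
        any(classified$phase[rows] %in% c("TRANS", "UNKNOWN"))
      keep[rows] <- hom | compound
    }
  }
  list(kept = classified[keep, , drop = FALSE],
       excluded_recessive_het = classified[!keep, , drop = FALSE])
}

#' Carrier set after the inheritance filter
#'
#' A patient is a carrier when at least one reportable variant survives the
#' inheritance filter; patients with several variants are counted once.
#'
#' @param kept the `kept` element of [apply_inheritance_filter()].
#' @return character vector of unique carrier patient ids.
#' @export
count_carriers <- function(kept) {
  sort(unique(kept$patient_id))
}
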