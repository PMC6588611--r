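#' Pathway burden summaries
#'
#' Maps reportable variants to DNA-repair pathways and tabulates the
#' burden distribution over variants (each variant counted once by its own
#' gene's pathway; the denominator is the variant count, not the carrier
#' count) and per-cancer-type carrier fractions.
#'
#' @name pathway_burden
NULL

#' Pathway of one or more genes
#'
#' @param genes gene symbols.
#' @param panel a `gene_panel`.
#' @param collapse_fanconi if TRUE, FANCONI is reported as HR (the Fanconi
#'   anemia genes are a labelled sub-group of homologous recombination).
#' @return character vector of pathway labels; off-panel genes error.
#' @export
assign_pathway <- function(genes, panel, collapse_fanconi = FALSE) {
  pw <- panel_lookup(genes, panel, "pathway")
  if (collapse_fanconi) pw <- hr_super_pathway(pw)
  pw
}

#' Pathway distribution over reportable variants
#'
#' @param variants reportable classified variants (each row one variant).
#' @param panel a `gene_panel`.
#' @return data.frame with one row per pathway (controlled order, FANCONI
#'   kept as its own labelled row), columns `pathway`, `n`, `fraction`,
#'   plus an attribute `hr_super_fraction` = (HR + FANCONI) / total.
#'   Fractions are NA for an empty input. Counts partition the variant set.
#' @export
pathway_distribution <- function(variants, panel) {
  pw <- factor(assign_pathway(variants$gene, panel), levels = PATHWAYS)
  n <- as.integer(table(pw))
  total <- nrow(variants)
  out <- data.frame(pathway = PATHWAYS, n = n,
                    fraction = if (total > 0) n / total else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "hr_super_fraction") <-
    if (total > 0) sum(n[PATHWAYS %in% c("HR", "FANCONI")]) / total else NA_real_
  out
}

#' Per-cancer-type carrier fractions
#'
#' @param patients data.frame with `patient_id` and `cancer_type`
#'   (one row per patient).
#' @param carriers character vector of carrier patient ids (a subset of
#'   `patients$patient_id`).
#' @param min_patients types with more than this many patients get
#'   `included = TRUE` (the ranked-figure view); default 10, strict
#'   (a 12-patient type is included, a 10-patient type is not).
#' @return data.frame ranked by descending carrier fraction then type name:
#'   `cancer_type`, `n_patients`, `n_carriers`, `fraction`, `pct`
#'   (half-away-from-zero, 0 digits), `included`.
#' @export
cancer_type_frequency <- function(patients, carriers, min_patients = 10) {
  stopifnot(all(carriers %in% patients$patient_id))
  types <- sort(unique(patients$cancer_type))
  n_pat <- vapply(types, function(t) sum(patients$cancer_type == t), 0L)
  n_car <- vapply(types, function(t) {
    sum(patients$cancer_type == t & patients$patient_id %in% carriers)
  }, 0L)
  out <- data.frame(cancer_type = types, n_patients = n_pat,
                    n_carriers = n_car, fraction = n_car / n_pat,
                    pct = pct(n_car, n_pat, 0),
                    included = n_pat > min_patients,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$fraction, out$cancer_type), , drop = FALSE]
}
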