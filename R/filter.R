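#' The four-stage germline variant filter cascade
#'
#' Re-implements the screening filter chain applied to called germline
#' variants before classification:
#' \enumerate{
#'   \item quality: reject call quality < 20 or read depth < 10,
#'   \item population: reject maximum population allele frequency > 1%
#'     unless the variant is an established pathogenic common variant,
#'   \item consequence: keep only coding non-synonymous variants and
#'     splice-site variants within +/- 2 bp of an exon boundary,
#'   \item VAF: keep only variant allele fraction > 20%.
#' }
#'
#' All thresholds follow the stated inequalities strictly: quality 20 and
#' depth 10 are kept, pop_af exactly 0.01 is kept, vaf exactly 0.20 is
#' rejected. Missing pop_af is treated as 0 (absent from every database is
#' the informative rare-variant case). Missing quality or depth rejects the
#' variant with reason `missing_qc`. The four predicates are independent,
#' so the final kept set is invariant under stage order; the default order
#' matches the published cascade.
#'
#' @name germline_filter
NULL

FILTER_STAGES <- c("quality", "population", "consequence", "vaf")

filter_result <- function(calls, keep, reason) {
  rejected <- calls[!keep, , drop = FALSE]
  reasons <- reason[!keep]
  list(kept = calls[keep, , drop = FALSE],
       rejected = rejected,
       reasons = reasons)
}

quality_keep <- function(calls) {
  ok <- !is.na(calls$call_quality) & !is.na(calls$depth)
  ok & calls$call_quality >= 20 & calls$depth >= 10
}

population_keep <- function(calls) {
  af <- ifelse(is.na(calls$pop_af), 0, calls$pop_af)
  af <= 0.01 | (!is.na(calls$known_pathogenic_common) &
                  calls$known_pathogenic_common)
}

consequence_keep <- function(calls) {
  cons <- calls$consequence
  off <- ifelse(is.na(calls$splice_offset), 0L, calls$splice_offset)
  keep <- cons %in% c("FRAMESHIFT", "NONSENSE", "MISSENSE", "START_LOSS")
  keep | (cons == "SPLICE_SITE" & abs(off) <= 2)
}

vaf_keep <- function(calls) {
  !is.na(calls$vaf) & calls$vaf > 0.20
}

#' @describeIn germline_filter quality filter: keep call_quality >= 20 AND
#'   depth >= 10; missing values reject with reason `missing_qc`.
#' @param calls a variant call data.frame (see [variant_calls]).
#' @return for single filters, a list with `kept`, `rejected` and
#'   `reasons`; for [run_cascade()], a list with `kept` and a `trace`
#'   data.frame of per-stage counts plus per-variant rejection reasons.
#' @export
filter_quality <- function(calls) {
  missing <- is.na(calls$call_quality) | is.na(calls$depth)
  keep <- quality_keep(calls)
  reason <- ifelse(missing, "missing_qc", "low_quality_or_depth")
  filter_result(calls, keep, reason)
}

#' @describeIn germline_filter population filter: keep pop_af <= 0.01 or
#'   established pathogenic common variants; missing pop_af counts as 0.
#' @export
filter_population <- function(calls) {
  filter_result(calls, population_keep(calls),
                rep("common_population_af", nrow(calls)))
}

#' @describeIn germline_filter consequence filter: keep FRAMESHIFT,
#'   NONSENSE, MISSENSE, START_LOSS and SPLICE_SITE with |offset| <= 2.
#' @export
filter_consequence <- function(calls) {
  filter_result(calls, consequence_keep(calls),
                rep("non_reportable_consequence", nrow(calls)))
}

#' @describeIn germline_filter VAF filter: keep vaf > 0.20 (strict).
#' @export
filter_vaf <- function(calls) {
  filter_result(calls, vaf_keep(calls), rep("low_vaf", nrow(calls)))
}

#' @describeIn germline_filter run the full cascade in the published order
#'   (or any permutation via `stages`); returns the kept set, a per-stage
#'   count trace and the per-variant rejection reasons.
#' @param stages character vector, a permutation of
#'   `c("quality", "population", "consequence", "vaf")`.
#' @export
run_cascade <- function(calls, stages = FILTER_STAGES) {
  stopifnot(setequal(stages, FILTER_STAGES))
  funs <- list(quality = filter_quality, population = filter_population,
               consequence = filter_consequence, vaf = filter_vaf)
  trace <- data.frame(stage = stages, n_in = NA_integer_, n_out = NA_integer_,
                      stringsAsFactors = FALSE)
  reasons <- data.frame(patient_id = character(), hgvs_c = character(),
                        gene = character(), stage = character(),
                        reason = character(), stringsAsFactors = FALSE)
  current <- calls
  for (s in seq_along(stages)) {
    res <- funs[[stages[s]]](current)
    trace$n_in[s] <- nrow(current)
    trace$n_out[s] <- nrow(res$kept)
    if (nrow(res$rejected) > 0) {
      reasons <- rbind(reasons, data.frame(
        patient_id = res$rejected$patient_id, hgvs_c = res$rejected$hgvs_c,
        gene = res$rejected$gene, stage = stages[s], reason = res$reasons,
        stringsAsFactors = FALSE))
    }
    current <- res$kept
  }
  list(kept = current, trace = trace, reasons = reasons)
}
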