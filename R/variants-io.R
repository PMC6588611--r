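#' Variant call tables
#'
#' Germline variant calls are carried as a data.frame with one row per call
#' and per alternate allele. Columns (the "variant TSV dialect"):
#' \describe{
#'   \item{patient_id}{sample/patient identifier.}
#'   \item{gene}{gene symbol (may be NA for VCF input, which carries no
#'     annotation).}
#'   \item{chrom, pos, ref, alt}{1-based VCF-convention coordinates and
#'     alleles; positions are preserved exactly as read.}
#'   \item{hgvs_c, hgvs_p}{HGVS labels, treated as opaque strings.}
#'   \item{consequence}{one of FRAMESHIFT, NONSENSE, MISSENSE, SPLICE_SITE,
#'     START_LOSS, SYNONYMOUS, INTRONIC, OTHER_NONCODING.}
#'   \item{splice_offset}{signed distance in bases from the nearest exon
#'     boundary; 0 for exonic variants.}
#'   \item{call_quality}{Phred-scaled call quality.}
#'   \item{depth}{read depth at the site.}
#'   \item{vaf}{variant allele fraction in \[0, 1\] (printed percentages are
#'     produced only at report time).}
#'   \item{pop_af}{maximum population allele frequency across databases,
#'     as a fraction. Pre-aggregation across 1000G/ExAC/GnomAD/ESP is the
#'     caller's duty; missing means "absent from all databases" and is
#'     treated as 0 by the population filter.}
#'   \item{known_pathogenic_common}{logical curation fact: established
#'     pathogenic common variant (exempt from the population filter).}
#'   \item{indel_net_length}{signed net indel length (insertions positive,
#'     deletions negative, 0 for substitutions).}
#'   \item{zygosity}{HET or HOM.}
#'   \item{phase}{pairwise phase relative to other variants in the same gene
#'     and patient: CIS, TRANS or UNKNOWN (optional; defaults UNKNOWN).}
#' }
#'
#' @name variant_calls
NULL

VARIANT_COLUMNS <- c("patient_id", "gene", "chrom", "pos", "ref", "alt",
                     "hgvs_c", "hgvs_p", "consequence", "splice_offset",
                     "call_quality", "depth", "vaf", "pop_af",
                     "known_pathogenic_common", "indel_net_length",
                     "zygosity", "phase")

empty_variant_calls <- function() {
  df <- data.frame(patient_id = character(), gene = character(),
                   chrom = character(), pos = integer(), ref = character(),
                   alt = character(), hgvs_c = character(),
                   hgvs_p = character(), consequence = character(),
                   splice_offset = integer(), call_quality = numeric(),
                   depth = integer(), vaf = numeric(), pop_af = numeric(),
                   known_pathogenic_common = logical(),
                   indel_net_length = integer(), zygosity = character(),
                   phase = character(), stringsAsFactors = FALSE)
  df
}

## Fill optional columns and validate invariants shared by both readers.
normalize_variant_calls <- function(calls) {
  defaults <- list(gene = NA_character_, chrom = NA_character_,
                   pos = NA_integer_, ref = NA_character_,
                   alt = NA_character_, hgvs_c = NA_character_,
                   hgvs_p = NA_character_, consequence = NA_character_,
                   splice_offset = 0L, pop_af = NA_real_,
                   known_pathogenic_common = FALSE, indel_net_length = 0L,
                   zygosity = "HET", phase = "UNKNOWN")
  for (nm in names(defaults)) {
    if (!nm %in% names(calls)) calls[[nm]] <- rep(defaults[[nm]], nrow(calls))
  }
  check_columns(calls, VARIANT_COLUMNS, "variant call table")
  ## coerce column types (an all-NA TSV column reads back as logical)
  for (nm in c("patient_id", "gene", "chrom", "ref", "alt", "hgvs_c",
               "hgvs_p", "consequence", "zygosity", "phase")) {
    calls[[nm]] <- as.character(calls[[nm]])
  }
  for (nm in c("pos", "splice_offset", "depth", "indel_net_length")) {
    calls[[nm]] <- as.integer(calls[[nm]])
  }
  for (nm in c("call_quality", "vaf", "pop_af")) {
    calls[[nm]] <- as.numeric(calls[[nm]])
  }
  check_enum(calls$consequence, CONSEQUENCES, "consequence")
  check_enum(calls$zygosity, c("HET", "HOM"), "zygosity")
  check_enum(calls$phase, PHASES, "phase")
  calls$known_pathogenic_common <- as.logical(calls$known_pathogenic_common)
  bad_vaf <- !is.na(calls$vaf) & (calls$vaf < 0 | calls$vaf > 1)
  if (any(bad_vaf)) stop("vaf outside [0,1] in rows: ",
                         paste(which(bad_vaf), collapse = ", "), call. = FALSE)
  bad_af <- !is.na(calls$pop_af) & (calls$pop_af < 0 | calls$pop_af > 1)
  if (any(bad_af)) stop("pop_af outside [0,1] in rows: ",
                        paste(which(bad_af), collapse = ", "), call. = FALSE)
  calls[, VARIANT_COLUMNS]
}

#' Read germline variant calls from TSV or minimal VCF
#'
#' TSV input must carry the documented column set (see [variant_calls];
#' optional columns are filled with defaults). VCF input is a minimal
#' single-sample VCF 4.x subset: CHROM, POS, ID, REF, ALT, QUAL are used,
#' INFO is ignored, and the per-sample DP and AD FORMAT fields supply depth
#' and allele fraction (VAF = alt allele depth / total depth when not given
#' explicitly). Multi-allelic records yield one call per alternate allele,
#' all sharing the record's position. Annotation columns (gene, consequence,
#' HGVS) are NA for VCF input: consequences must arrive pre-annotated via
#' TSV. No phasing blocks, symbolic alleles or breakends.
#'
#' @param path input file.
#' @param format `"tsv"`, `"vcf"` or `"auto"` (by extension).
#' @param patient_id patient identifier for VCF input (defaults to the VCF
#'   sample name).
#' @return a variant call data.frame (see [variant_calls]).
#' @export
read_variant_calls <- function(path, format = c("auto", "tsv", "vcf"),
                               patient_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "vcf") "vcf" else "tsv"
  }
  if (format == "vcf") return(read_variant_vcf(path, patient_id))
  ## read everything as character: type inference would turn an all-"T"
  ## allele column into logical; normalize_variant_calls coerces types
  calls <- read_tsv(path, colClasses = "character")
  if (nrow(calls) == 0) return(empty_variant_calls())
  check_columns(calls, c("patient_id", "call_quality", "depth", "vaf"),
                "variant TSV")
  normalize_variant_calls(calls)
}

## Minimal VCF reader. Hand-written on purpose: the contract requires parse
## errors with line numbers and per-ALT splitting of AD-derived VAFs on a
## tiny fixed subset; the full-featured readers do not surface line numbers.
## VariantAnnotation::readVcf serves as the independent oracle in the tests.
read_variant_vcf <- function(path, patient_id = NULL) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  header_idx <- which(startsWith(lines, "#CHROM"))
  sample_name <- "SAMPLE"
  if (length(header_idx) == 1) {
    hdr <- strsplit(lines[header_idx], "\t", fixed = TRUE)[[1]]
    if (length(hdr) >= 10) sample_name <- hdr[10]
  }
  if (is.null(patient_id)) patient_id <- sample_name
  out <- list()
  n_skipped <- 0L
  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      stop(sprintf("malformed VCF record at line %d: expected >= 8 fields, got %d",
                   i, length(f)), call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) {
      stop(sprintf("malformed VCF record at line %d: non-integer POS '%s'",
                   i, f[2]), call. = FALSE)
    }
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    qual <- suppressWarnings(as.numeric(f[6]))
    dp <- NA_integer_; ad <- NULL
    if (length(f) >= 10) {
      keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      vals <- strsplit(f[10], ":", fixed = TRUE)[[1]]
      if ("DP" %in% keys) dp <- suppressWarnings(as.integer(vals[match("DP", keys)]))
      if ("AD" %in% keys) {
        ad <- suppressWarnings(as.integer(
          strsplit(vals[match("AD", keys)], ",", fixed = TRUE)[[1]]))
      }
    }
    if (is.null(ad) && is.na(dp)) {
      warning(sprintf("VCF line %d: no depth information; record skipped", i),
              call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    total <- if (!is.na(dp)) dp else sum(ad)
    for (a in seq_along(alts)) {
      vaf <- if (!is.null(ad) && length(ad) >= a + 1 && total > 0) {
        ad[a + 1] / total
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        patient_id = patient_id, chrom = f[1], pos = pos, ref = f[4],
        alt = alts[a], call_quality = qual, depth = total, vaf = vaf,
        stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0) {
    message(sprintf("read_variant_calls: skipped %d record(s) lacking depth",
                    n_skipped))
  }
  if (length(out) == 0) return(empty_variant_calls())
  normalize_variant_calls(do.call(rbind, out))
}

#' Write variant calls as TSV
#'
#' Round-trips losslessly through [read_variant_calls()] for all defined
#' fields.
#'
#' @param calls variant call data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_calls <- function(calls, path) {
  write_tsv(normalize_variant_calls(calls), path)
}

#' Write the cohort summary as a set of TSV report tables
#'
#' Emits `cancer_types.tsv`, `genes.tsv`, `consequences.tsv`,
#' `pathways.tsv` and `headline.tsv` with deterministic column and row
#' order (cancer types by descending carrier fraction then name; genes by
#' descending count then symbol; consequences and pathways in their
#' controlled-vocabulary order). Percentages use the half-away-from-zero
#' rounding convention ([round_half_up()]).
#'
#' @param summary a `cohort_summary` from [build_summary()].
#' @param out_dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_report_tables <- function(summary, out_dir) {
  stopifnot(inherits(summary, "cohort_summary"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  paths <- c(
    cancer_types = file.path(out_dir, "cancer_types.tsv"),
    genes        = file.path(out_dir, "genes.tsv"),
    consequences = file.path(out_dir, "consequences.tsv"),
    pathways     = file.path(out_dir, "pathways.tsv"),
    headline     = file.path(out_dir, "headline.tsv"))
  write_tsv(summary$cancer_types, paths["cancer_types"])
  write_tsv(summary$genes, paths["genes"])
  write_tsv(summary$consequences, paths["consequences"])
  write_tsv(summary$pathways, paths["pathways"])
  headline <- data.frame(metric = names(summary$headline),
                         value = unname(unlist(summary$headline)),
                         stringsAsFactors = FALSE)
  write_tsv(headline, paths["headline"])
  invisible(paths)
}
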