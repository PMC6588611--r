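#' @keywords internal
"_PACKAGE"

## Controlled vocabularies used across the pipeline.
PATHWAYS     <- c("HR", "FANCONI", "CHECKPOINT", "NER", "MMR", "OTHER")
INHERITANCE  <- c("DOMINANT", "RECESSIVE")
ACTIONABLE   <- c("PARPI", "IMMUNOTHERAPY", "NONE")
CONSEQUENCES <- c("FRAMESHIFT", "NONSENSE", "MISSENSE", "SPLICE_SITE",
                  "START_LOSS", "SYNONYMOUS", "INTRONIC", "OTHER_NONCODING")
LOF_CONSEQUENCES <- c("FRAMESHIFT", "NONSENSE", "START_LOSS", "SPLICE_SITE")
PHASES       <- c("CIS", "TRANS", "UNKNOWN")
HIT_CATEGORIES <- c("REVERSION", "SOMATIC_SECOND_HIT", "LOH",
                    "BIALLELIC_SOMATIC", "NONE")

#' Round half away from zero
#'
#' The reporting convention for printed percentages: ties round away from
#' zero (113/636 = 17.767 prints as 17.8; 45.45 prints as 45.5 at one digit
#' and 45 at zero digits). `base::round()` rounds half to even and would
#' disagree on ties.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal digits.
#' @return `x` rounded to `digits` digits, ties away from zero.
#' @examples
#' round_half_up(113 / 636 * 100, 1)  # 17.8
#' round_half_up(2.5, 0)              # 3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a fraction as a printed percentage
#'
#' @param num,den numerator and denominator counts.
#' @param digits decimal digits in the printed percentage.
#' @return numeric percentage (not a string), `NA` when `den` is 0.
#' @export
pct <- function(num, den, digits = 0) {
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(den) & den > 0
  out[ok] <- round_half_up(100 * num[ok] / den[ok], digits)
  out
}

## Deterministic sub-seed derivation: one global seed, per-stream tags.
## Kept below 2^31 - 1 so set.seed() always accepts it.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) %% 2147483647 * 31 + h) %% 2147483647)
}

## match.arg-like validator that reports the offending values.
check_enum <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), allowed)
  if (length(bad) > 0) {
    stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                 paste(bad, collapse = ", "), paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

## Deterministic TSV writer: fixed column order as given, no quoting
## surprises, "NA" for missing. All pipeline outputs funnel through this so
## byte-identical reruns are achievable.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

gscreen_extdata <- function(file) {
  path <- system.file("extdata", file, package = "gscreen")
  if (!nzchar(path)) stop("packaged data file not found: ", file, call. = FALSE)
  path
}
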