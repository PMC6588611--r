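#' Gene panel handling
#'
#' A gene panel is a data.frame with one row per gene and columns:
#' \describe{
#'   \item{symbol}{gene symbol, unique within the panel.}
#'   \item{pathway}{one of HR, FANCONI, CHECKPOINT, NER, MMR, OTHER.
#'     FANCONI is a labelled sub-group of homologous recombination: HR
#'     pathway-fraction summaries count FANCONI genes as HR (see
#'     [hr_super_pathway()]).}
#'   \item{inheritance}{DOMINANT or RECESSIVE; drives the recessive-gene
#'     exclusion in [apply_inheritance_filter()].}
#'   \item{acmg_return}{logical, gene is on the ACMG/AMP return-of-results
#'     list.}
#'   \item{actionable_class}{PARPI (BRCA1/BRCA2 only), IMMUNOTHERAPY
#'     (MLH1/MSH2/MSH6/PMS2 only) or NONE.}
#' }
#'
#' The packaged default panel ([default_panel()]) has 168 genes. The source
#' publication does not enumerate its gene list, so the packaged panel is a
#' reconstruction: it contains every gene named in the text with the
#' annotations the text implies, padded with standard hereditary-cancer
#' genes. Replace it with your own via [read_panel()].
#'
#' @name gene_panel
NULL

PANEL_COLUMNS <- c("symbol", "pathway", "inheritance", "acmg_return",
                   "actionable_class")

validate_panel <- function(panel) {
  check_columns(panel, PANEL_COLUMNS, "gene panel")
  dup <- panel$symbol[duplicated(panel$symbol)]
  if (length(dup) > 0) {
    stop("duplicate gene symbol(s) in panel: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  check_enum(panel$pathway, PATHWAYS, "pathway")
  check_enum(panel$inheritance, INHERITANCE, "inheritance")
  check_enum(panel$actionable_class, ACTIONABLE, "actionable_class")
  bad_parpi <- panel$symbol[panel$actionable_class == "PARPI" &
                              !panel$symbol %in% c("BRCA1", "BRCA2")]
  bad_immu <- panel$symbol[panel$actionable_class == "IMMUNOTHERAPY" &
                             !panel$symbol %in% c("MLH1", "MSH2", "MSH6", "PMS2")]
  if (length(c(bad_parpi, bad_immu)) > 0) {
    stop("actionable_class misassigned for: ",
         paste(c(bad_parpi, bad_immu), collapse = ", "), call. = FALSE)
  }
  panel$acmg_return <- as.logical(panel$acmg_return)
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

#' Read a gene panel from TSV or JSON
#'
#' @param path path to a panel file.
#' @param format `"tsv"`, `"json"`, or `"auto"` (by file extension).
#' @return a validated `gene_panel` data.frame (see [gene_panel]).
#' @export
read_panel <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  panel <- if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    read_tsv(path, comment.char = "#")
  }
  if (nrow(panel) == 0) warning("gene panel is empty: ", path, call. = FALSE)
  validate_panel(panel)
}

#' Write a gene panel
#'
#' @param panel a `gene_panel`.
#' @param path output path; `.json` extension selects JSON, otherwise TSV.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(as.data.frame(panel)[PANEL_COLUMNS], path,
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
  } else {
    write_tsv(as.data.frame(panel)[PANEL_COLUMNS], path)
  }
  invisible(path)
}

#' The packaged 168-gene default panel (reconstructed)
#'
#' @return a `gene_panel` with 168 genes.
#' @export
default_panel <- function() {
  read_panel(gscreen_extdata("default_panel.tsv"), format = "tsv")
}

#' Collapse FANCONI into HR for pathway-fraction summaries
#'
#' Fanconi anemia genes act in homologous recombination; burden summaries
#' report them as a labelled sub-group of HR.
#'
#' @param pathway character vector of pathway labels.
#' @return character vector with FANCONI replaced by HR.
#' @export
hr_super_pathway <- function(pathway) {
  ifelse(pathway == "FANCONI", "HR", pathway)
}

panel_lookup <- function(genes, panel, column) {
  idx <- match(genes, panel$symbol)
  if (anyNA(idx)) {
    stop("off_panel: gene(s) not in panel: ",
         paste(unique(genes[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  panel[[column]][idx]
}
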