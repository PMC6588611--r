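# Builders for in-code fixtures: a fully-populated variant call row with
# overridable fields, a tiny panel, and a minimal VCF writer.

make_calls <- function(n = 1, ...) {
  base <- gscreen:::vdf(n,
    patient_id = sprintf("P%03d", seq_len(n)), gene = "BRCA2",
    chrom = "chr13", pos = 32900000L + seq_len(n), ref = "A", alt = "T",
    hgvs_c = sprintf("c.%d>T", seq_len(n)), hgvs_p = NA_character_,
    consequence = "NONSENSE", splice_offset = 0L, call_quality = 50,
    depth = 50L, vaf = 0.5, pop_af = 0, known_pathogenic_common = FALSE,
    indel_net_length = 0L, zygosity = "HET", phase = "UNKNOWN")
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base
}

tiny_panel <- function() {
  gscreen:::validate_panel(data.frame(
    symbol = c("BRCA1", "BRCA2", "CHEK2", "MLH1", "MSH6", "MUTYH",
               "NTHL1", "FANCM", "XPC", "ATM", "BAP1"),
    pathway = c("HR", "HR", "CHECKPOINT", "MMR", "MMR", "OTHER", "OTHER",
                "FANCONI", "NER", "CHECKPOINT", "HR"),
    inheritance = c(rep("DOMINANT", 5), "RECESSIVE", "RECESSIVE",
                    rep("DOMINANT", 4)),
    acmg_return = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                    FALSE, FALSE, FALSE),
    actionable_class = c("PARPI", "PARPI", "NONE", "IMMUNOTHERAPY",
                         "IMMUNOTHERAPY", rep("NONE", 6)),
    stringsAsFactors = FALSE))
}

write_test_vcf <- function(path, records,
                           sample_name = "PT01") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr13>",
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"),
    records), path)
  path
}

# Independent one-line oracle for the full filter cascade (conjunction of
# the four published predicates), deliberately written from scratch.
cascade_oracle <- function(calls) {
  af <- ifelse(is.na(calls$pop_af), 0, calls$pop_af)
  !is.na(calls$call_quality) & !is.na(calls$depth) &
    calls$call_quality >= 20 & calls$depth >= 10 &
    (af <= 0.01 | calls$known_pathogenic_common) &
    (calls$consequence %in% c("FRAMESHIFT", "NONSENSE", "MISSENSE",
                              "START_LOSS") |
       (calls$consequence == "SPLICE_SITE" & abs(calls$splice_offset) <= 2)) &
    calls$vaf > 0.20
}
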