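# Bundled gene rosters for the synthetic cohort. The study's full 167-gene
# germline and 93-gene somatic panels are supplied by the user as text
# files in a real run; these representative subsets carry the genes the
# synthetic cohort draws from, with synthetic coordinates.

somatic_gene_table <- function() {
  df <- data.frame(
    gene = c("TP53", "KMT2C", "RUNX1", "DNMT3A", "KMT2D", "ARID1B",
             "ASXL1", "CBL", "DIS3", "TET2", "EZH2", "NRAS", "KRAS",
             "PTPN11", "NF1", "FLT3", "JAK2", "KIT", "SRSF2", "SF3B1",
             "U2AF1", "SMC3", "STAG2", "RAD21", "ATM", "CHEK2", "CDKN2A",
             "GATA2", "CEBPA", "WT1", "BCOR", "PHF6", "SETBP1", "NPM1",
             "IDH1", "IDH2"),
    weight = c(8, 4, 4, 3.5, 3, 3, 3, 2.5, 2.5, 2.5, 1, 1, 1, 1, 1, 1, 1,
               1, 0.5, 0.5, 0.5, 0.4, 0.4, 0.4, 0.8, 0.5, 0.5, 0.8, 0.8,
               0.8, 0.8, 0.5, 0.5, 0.3, 0.8, 0.8),
    category = c("transcription factor", "chromatin modification",
                 "transcription factor", "chromatin modification",
                 "chromatin modification", "chromatin modification",
                 "chromatin modification", "RAS pathway", "other",
                 "chromatin modification", "chromatin modification",
                 "RAS pathway", "RAS pathway", "RAS pathway",
                 "RAS pathway", "receptor/kinase", "receptor/kinase",
                 "receptor/kinase", "splicing factor", "splicing factor",
                 "splicing factor", "cohesin", "cohesin", "cohesin",
                 "DNA repair/cell cycle", "DNA repair/cell cycle",
                 "DNA repair/cell cycle", "transcription factor",
                 "transcription factor", "transcription factor",
                 "transcription factor", "other", "other", "other",
                 "chromatin modification", "chromatin modification"),
    stringsAsFactors = FALSE
  )
  df
}

germline_gene_table <- function() {
  data.frame(
    gene = c("BRIP1", "CEBPA", "DDX41", "FANCM", "NBN", "NF1", "RUNX1",
             "BRCA1", "BRCA2", "BARD1", "CHEK2", "PALB2", "TP53", "FANCA",
             "FANCC", "FANCD2", "ATM", "BLM", "ETV6", "GATA2", "ANKRD26",
             "MPL", "TERT", "WRN", "RECQL4", "SBDS", "SAMD9", "SAMD9L"),
    # loss of function as established disease mechanism (PVS1 gate);
    # SAMD9/SAMD9L disease alleles are gain-of-function
    lof_mechanism = c(rep(TRUE, 26), FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default gene registry used by the synthetic cohort
#'
#' Union of the bundled germline and somatic rosters with synthetic,
#' deterministic chromosome placements (the generator fabricates
#' coordinates; it does not emit real genomic positions).
#'
#' @return Data frame with `gene`, `chrom`, `start`.
#' @export
gene_registry <- function() {
  genes <- sort(unique(c(somatic_gene_table()$gene,
                         germline_gene_table()$gene)))
  idx <- seq_along(genes)
  data.frame(gene = genes,
             chrom = as.character((idx - 1L) %% 22L + 1L),
             start = 1000000L + idx * 1000000L,
             stringsAsFactors = FALSE)
}

#' Default functional category map for the bundled somatic roster
#'
#' @return Data frame with `gene` and `category` covering the seven
#'   functional groups used in the cohort summary.
#' @export
default_category_map <- function() {
  somatic_gene_table()[, c("gene", "category")]
}

#' Bundled toy somatic evidence table
#'
#' Gene-level AMP/ASCO/CAP evidence entries covering the synthetic
#' cohort's gene set, for reproducible tiering without a live
#' knowledge-base query.
#'
#' @return Evidence data frame (`gene`, `pattern`, `evidence`).
#' @export
default_evidence_table <- function() {
  data.frame(
    gene = c("TP53", "RUNX1", "DNMT3A", "ASXL1", "NRAS", "KRAS", "FLT3",
             "JAK2", "IDH1", "IDH2", "SF3B1", "SRSF2"),
    pattern = NA_character_,
    evidence = c("fda_guideline", "clinical_trial_or_strong_study",
                 "clinical_trial_or_strong_study",
                 "clinical_trial_or_strong_study",
                 "clinical_trial_or_strong_study",
                 "clinical_trial_or_strong_study", "fda_guideline",
                 "fda_guideline", "fda_guideline", "fda_guideline",
                 "clinical_trial_or_strong_study",
                 "clinical_trial_or_strong_study"),
    stringsAsFactors = FALSE
  )
}
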