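#' Read a somatic evidence table for AMP/ASCO/CAP tiering
#'
#' Tab-delimited with columns `gene`, `pattern` (optional regular
#' expression matched against the protein change; empty or `.` for a
#' gene-level entry) and `evidence`, one of `fda_guideline`,
#' `clinical_trial_or_strong_study`, `unknown_significance`,
#' `benign_or_likely_benign`.
#'
#' @param path TSV path.
#' @return Evidence data frame.
#' @export
read_evidence_table <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "."))
  stopifnot(all(c("gene", "evidence") %in% names(ev)))
  if (!"pattern" %in% names(ev)) ev$pattern <- NA_character_
  allowed <- c("fda_guideline", "clinical_trial_or_strong_study",
               "unknown_significance", "benign_or_likely_benign")
  bad <- !(ev$evidence %in% allowed)
  if (any(bad)) {
    stop("unknown evidence token(s): ",
         paste(unique(ev$evidence[bad]), collapse = ", "))
  }
  ev
}

evidence_to_tier <- c(fda_guideline = "I",
                      clinical_trial_or_strong_study = "II",
                      unknown_significance = "III",
                      benign_or_likely_benign = "IV")

#' Assign AMP/ASCO/CAP tiers to somatic variants
#'
#' Evidence mapping: FDA/guideline-level -> tier I; clinical trial or
#' well-powered study -> tier II; no entry or unknown significance -> tier
#' III, unless a population MAF at or above the common-polymorphism
#' threshold marks the variant benign-like -> tier IV. A protein-change
#' pattern entry takes precedence over a gene-level entry.
#'
#' @param av Annotated-variant data frame of somatic (or dual) variants.
#' @param evidence Evidence data frame from [read_evidence_table()].
#' @param cfg A [cascade_config()] supplying `common_maf_threshold`.
#' @return `av` with a `tier` column (`"I"`–`"IV"`).
#' @export
assign_tier <- function(av, evidence, cfg = cascade_config()) {
  if (nrow(av) == 0L) {
    av$tier <- character(0)
    return(av)
  }
  mf <- max_pop_freq(av)
  tier <- character(nrow(av))
  for (i in seq_len(nrow(av))) {
    rows <- evidence[evidence$gene == av$gene[i], , drop = FALSE]
    hit <- NA_character_
    if (nrow(rows) > 0L) {
      specific <- rows[!is.na(rows$pattern), , drop = FALSE]
      if (nrow(specific) > 0L && !is.na(av$hgvs_p[i])) {
        m <- vapply(specific$pattern, function(p) grepl(p, av$hgvs_p[i]),
                    logical(1))
        if (any(m)) hit <- specific$evidence[which(m)[1]]
      }
      if (is.na(hit)) {
        general <- rows[is.na(rows$pattern), , drop = FALSE]
        if (nrow(general) > 0L) hit <- general$evidence[1]
      }
    }
    tier[i] <- if (!is.na(hit) && hit != "unknown_significance") {
      evidence_to_tier[[hit]]
    } else if (mf[i] >= cfg$common_maf_threshold) {
      "IV"
    } else {
      "III"
    }
  }
  av$tier <- tier
  av
}

#' Select reportable somatic variants (tiers I-III)
#'
#' @param av Annotated-variant data frame with a `tier` column.
#' @return Rows with tier I, II or III, input order preserved.
#' @export
select_reportable <- function(av) {
  stopifnot("tier" %in% names(av))
  out <- av[av$tier %in% c("I", "II", "III"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
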