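#' @name acmg_engine
#' @title ACMG/AMP germline classification engine
#' @description
#' Evidence criteria are represented as tokens: the bare code (`"PVS1"`,
#' `"PM2"`, `"PP3"`, ...) carries its family's default strength; a
#' modified strength is rendered with a suffix, e.g. `"PVS1_Strong"` for
#' the loss-of-function criterion downgraded one level when
#' nonsense-mediated decay is not anticipated. [combine_criteria()] folds a
#' token set into the five-class verdict P / LP / VUS / LB / B.
NULL

acmg_strengths <- c(very_strong = "very_strong", strong = "strong",
                    moderate = "moderate", supporting = "supporting",
                    stand_alone = "stand_alone")

#' Parse an evidence token into code and effective strength
#'
#' @param token Token such as `"PM2"` or `"PVS1_Strong"`.
#' @return List with `code`, `side` ("pathogenic"/"benign") and `strength`.
#' @export
parse_criterion <- function(token) {
  parts <- strsplit(token, "_", fixed = TRUE)[[1]]
  code <- parts[1]
  if (!grepl("^(PVS|PS|PM|PP|BA|BS|BP)[0-9]+$", code)) {
    stop("unrecognized criterion code: ", token)
  }
  family <- sub("[0-9]+$", "", code)
  side <- if (family %in% c("PVS", "PS", "PM", "PP")) "pathogenic" else "benign"
  default <- switch(family,
                    PVS = "very_strong", PS = "strong", PM = "moderate",
                    PP = "supporting", BA = "stand_alone", BS = "strong",
                    BP = "supporting")
  strength <- if (length(parts) == 1L) default else {
    s <- tolower(sub("^Very", "very_", parts[2]))
    s <- c(verystrong = "very_strong", very_strong = "very_strong",
           strong = "strong", moderate = "moderate",
           supporting = "supporting", standalone = "stand_alone")[
             gsub("_", "", tolower(parts[2]))]
    if (is.na(s)) stop("unknown strength token in: ", token)
    s
  }
  list(code = code, side = side, strength = strength)
}

#' Combine ACMG/AMP evidence tokens into a five-class verdict
#'
#' Pathogenic-side rules (counting by effective strength; VS = very strong,
#' S = strong, M = moderate, P = supporting):
#' Pathogenic — 1 VS with (>=1 S, or >=2 M, or 1 M + 1 P, or >=2 P);
#' >=2 VS; >=2 S; or 1 S with (>=3 M, or 2 M + >=2 P, or 1 M + >=4 P).
#' Likely pathogenic — 1 VS + 1 M; 1 S + 1-2 M; 1 S + >=2 P; >=3 M;
#' 2 M + >=2 P; 1 M + >=4 P.
#' Benign — BA1 alone or >=2 BS. Likely benign — 1 BS + 1 BP or >=2 BP.
#' When both a pathogenic-side and a benign-side rule fire the verdict is
#' VUS (conflicting evidence); with no rule fired it is VUS.
#'
#' @param criteria Character vector of evidence tokens.
#' @return Verdict string: one of `"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`.
#' @export
combine_criteria <- function(criteria) {
  if (length(criteria) == 0L) return("VUS")
  parsed <- lapply(criteria, parse_criterion)
  path <- parsed[vapply(parsed, `[[`, "", "side") == "pathogenic"]
  ben <- parsed[vapply(parsed, `[[`, "", "side") == "benign"]
  ps <- table(factor(vapply(path, `[[`, "", "strength"),
                     levels = c("very_strong", "strong", "moderate",
                                "supporting")))
  nVS <- ps[["very_strong"]]; nS <- ps[["strong"]]
  nM <- ps[["moderate"]]; nP <- ps[["supporting"]]
  nBA <- sum(vapply(ben, `[[`, "", "strength") == "stand_alone")
  nBS <- sum(vapply(ben, `[[`, "", "strength") == "strong")
  nBP <- sum(vapply(ben, `[[`, "", "strength") == "supporting")

  is_P <- (nVS >= 1 && (nS >= 1 || nM >= 2 || (nM >= 1 && nP >= 1) ||
                          nP >= 2)) ||
    nVS >= 2 ||
    nS >= 2 ||
    (nS == 1 && (nM >= 3 || (nM == 2 && nP >= 2) || (nM == 1 && nP >= 4)))
  is_LP <- (nVS >= 1 && nM >= 1) ||
    (nS == 1 && nM >= 1 && nM <= 2) ||
    (nS == 1 && nP >= 2) ||
    nM >= 3 ||
    (nM == 2 && nP >= 2) ||
    (nM == 1 && nP >= 4)
  is_B <- nBA >= 1 || nBS >= 2
  is_LB <- (nBS == 1 && nBP >= 1) || nBP >= 2

  path_verdict <- if (is_P) "P" else if (is_LP) "LP" else NA_character_
  ben_verdict <- if (is_B) "B" else if (is_LB) "LB" else NA_character_
  if (!is.na(path_verdict) && !is.na(ben_verdict)) return("VUS")
  if (!is.na(path_verdict)) return(path_verdict)
  if (!is.na(ben_verdict)) return(ben_verdict)
  "VUS"
}

null_consequences <- c("nonsense", "frameshift", "canonical_splice",
                       "initiation_loss")

#' PVS1: null variant in a loss-of-function-mechanism gene
#'
#' Very strong for a null variant predicted to undergo nonsense-mediated
#' decay or disrupting a canonical splice site; downgraded one level to
#' `PVS1_Strong` when NMD is not anticipated (or the NMD status is
#' unknown). Not applicable outside null consequences or in genes without
#' an established loss-of-function disease mechanism.
#'
#' @param ann One-row annotation (list or data frame row) with
#'   `consequence` and `nmd_predicted`.
#' @param lof_gene Whether loss of function is the gene's disease mechanism
#'   (from the germline panel file).
#' @return Token string or `NULL`.
#' @export
evaluate_pvs1 <- function(ann, lof_gene = TRUE) {
  if (!isTRUE(lof_gene)) return(NULL)
  if (is.na(ann$consequence) || !(ann$consequence %in% null_consequences)) {
    return(NULL)
  }
  nmd <- if (is.null(ann$nmd_predicted) || is.na(ann$nmd_predicted)) {
    "unknown"
  } else ann$nmd_predicted
  if (ann$consequence == "canonical_splice" || nmd == "yes") "PVS1"
  else "PVS1_Strong"
}

#' PM2: absent or extremely rare in population databases
#'
#' Uses the gnomAD exome global frequency (missing treated as 0) with a
#' strict cutoff of 1e-5 for dominant/X-linked disease and 1e-4 for
#' recessive disease; unknown inheritance uses the stricter dominant
#' cutoff.
#'
#' @param ann One-row annotation with `freq_gnomad_exome_all` and
#'   `inheritance`.
#' @return `"PM2"` or `NULL`.
#' @export
evaluate_pm2 <- function(ann) {
  freq <- ann$freq_gnomad_exome_all
  if (is.null(freq) || is.na(freq)) freq <- 0
  inh <- if (is.null(ann$inheritance) || is.na(ann$inheritance)) {
    "unknown"
  } else ann$inheritance
  cutoff <- if (inh == "AR") 1e-4 else 1e-5
  if (freq < cutoff) "PM2" else NULL
}

#' PP3: concordant in-silico deleteriousness predictions
#'
#' Requires all three predictors to agree: SIFT `D`, PolyPhen2_HVAR `D` or
#' `P`, and CADD phred strictly greater than 20. A missing predictor
#' withholds the criterion.
#'
#' @param ann One-row annotation with `sift`, `polyphen2_hvar`,
#'   `cadd_phred`.
#' @return `"PP3"` or `NULL`.
#' @export
evaluate_pp3 <- function(ann) {
  if (is.null(ann$sift) || is.na(ann$sift) ||
      is.null(ann$polyphen2_hvar) || is.na(ann$polyphen2_hvar) ||
      is.null(ann$cadd_phred) || is.na(ann$cadd_phred)) {
    return(NULL)
  }
  if (ann$sift == "D" && ann$polyphen2_hvar %in% c("D", "P") &&
      ann$cadd_phred > 20) "PP3" else NULL
}

#' PP5: pathogenic report from a reputable source
#'
#' Granted for a ClinVar pathogenic / likely-pathogenic assertion with at
#' least one review star, or an HGMD high-confidence disease-causing (DM)
#' record. ClinVar VUS or conflicting-only assertions and HGMD DM? (low
#' confidence) do not qualify on their own, but a high-confidence DM record
#' grants the criterion even alongside a conflicting ClinVar entry.
#'
#' @param ann One-row annotation with `clinvar_significance`,
#'   `clinvar_stars` and `hgmd_class`.
#' @return `"PP5"` or `NULL`.
#' @export
evaluate_reputable_source <- function(ann) {
  hgmd <- if (is.null(ann$hgmd_class) || is.na(ann$hgmd_class)) {
    "none"
  } else ann$hgmd_class
  if (hgmd == "DM_high") return("PP5")
  sig <- ann$clinvar_significance
  if (is.null(sig) || is.na(sig)) return(NULL)
  stars <- if (is.null(ann$clinvar_stars) || is.na(ann$clinvar_stars)) {
    0L
  } else ann$clinvar_stars
  sig_lc <- tolower(sig)
  is_plp <- sig_lc %in% c("p", "lp", "p/lp") ||
    (grepl("pathogenic", sig_lc) && !grepl("conflict|benign|uncertain",
                                           sig_lc))
  if (is_plp && stars >= 1L) "PP5" else NULL
}

#' PM1: variant in a mutational hotspot or benign-variation-free domain
#'
#' Domain membership is supplied by annotation (`hotspot_domain` flag), not
#' computed here.
#'
#' @param ann One-row annotation with `hotspot_domain`.
#' @return `"PM1"` or `NULL`.
#' @export
evaluate_pm1 <- function(ann) {
  if (isTRUE(as.logical(ann$hotspot_domain))) "PM1" else NULL
}

#' BA1: stand-alone benign allele frequency
#'
#' Granted when any population frequency reaches 5%.
#'
#' @param ann One-row annotation with the six frequency columns.
#' @return `"BA1"` or `NULL`.
#' @export
evaluate_ba1 <- function(ann) {
  mf <- max_pop_freq(as.data.frame(ann, stringsAsFactors = FALSE))
  if (mf >= 0.05) "BA1" else NULL
}

#' Classify a germline candidate variant
#'
#' Runs the implemented evaluators (PVS1, PM1, PM2, PP3, PP5, BA1),
#' combines the fired criteria with [combine_criteria()] and reports the
#' verdict. A variant is deleterious when the verdict is P or LP.
#'
#' @param av One-row annotated variant (data frame row or list) carrying
#'   the annotation columns and `lof_mechanism`.
#' @param extra_criteria Optional further tokens supplied by the caller
#'   (e.g. segregation evidence), appended before combining.
#' @return List with `verdict`, `criteria` (token vector), `criteria_string`
#'   (tokens joined with `" + "`) and `deleterious`.
#' @export
classify_germline_variant <- function(av, extra_criteria = character()) {
  lof <- if (is.null(av$lof_mechanism)) TRUE else isTRUE(av$lof_mechanism)
  tokens <- c(evaluate_pvs1(av, lof_gene = lof),
              evaluate_pm1(av),
              evaluate_pm2(av),
              evaluate_pp3(av),
              evaluate_reputable_source(av),
              evaluate_ba1(av),
              extra_criteria)
  tokens <- unlist(tokens, use.names = FALSE)
  verdict <- combine_criteria(tokens)
  list(verdict = verdict,
       criteria = tokens,
       criteria_string = paste(tokens, collapse = " + "),
       deleterious = verdict %in% c("P", "LP"))
}

#' Classify every germline-candidate row of a triage result
#'
#' @param av Annotated-variant data frame whose rows have origin
#'   presumed_germline, potential_germline or dual.
#' @return `av` with `acmg_verdict`, `acmg_criteria` and `deleterious`
#'   columns appended.
#' @export
classify_germline_table <- function(av) {
  if (nrow(av) == 0L) {
    av$acmg_verdict <- character(0)
    av$acmg_criteria <- character(0)
    av$deleterious <- logical(0)
    return(av)
  }
  res <- lapply(seq_len(nrow(av)), function(i) {
    classify_germline_variant(as.list(av[i, , drop = FALSE]))
  })
  av$acmg_verdict <- vapply(res, `[[`, "", "verdict")
  av$acmg_criteria <- vapply(res, `[[`, "", "criteria_string")
  av$deleterious <- vapply(res, `[[`, NA, "deleterious")
  av
}
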