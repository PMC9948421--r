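#' Configuration for the variant filtering cascade
#'
#' Thresholds for the quality gate, strand-bias artifact rule, common
#' polymorphism (population MAF) filter, panel-of-normals filter and the
#' germline/somatic origin partition.
#'
#' The strand-bias rule generalizes the canonical 2:8 / 8:2 alternate-count
#' ratio: a call fails when the minor-strand fraction of alternate reads is
#' at most `strand_bias_min_fraction` (default 0.2, i.e. 2:8), so more
#' extreme imbalances such as 1:9 also fail.
#'
#' @param min_depth Minimum total depth for any variant (reads).
#' @param min_vaf_somatic Minimum VAF for somatic candidacy.
#' @param strand_bias_min_fraction Maximum tolerated minor-strand fraction
#'   of alternate reads (inclusive fail boundary).
#' @param common_maf_threshold Population MAF at or above which a variant is
#'   treated as a common polymorphism for somatic candidacy.
#' @param pon_recurrence_fraction Panel-of-normals recurrence at or above
#'   which a somatic candidate is removed.
#' @param germline_het_band Two-element VAF interval compatible with a
#'   heterozygous germline variant.
#' @param germline_hom_min Minimum VAF compatible with a homozygous
#'   germline variant.
#' @param normal_support_min_vaf Minimum VAF in a matched non-malignant
#'   sample for a variant to count as confirmed (presumed) germline.
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(min_depth = 20L,
                           min_vaf_somatic = 0.02,
                           strand_bias_min_fraction = 0.2,
                           common_maf_threshold = 0.01,
                           pon_recurrence_fraction = 0.05,
                           germline_het_band = c(0.30, 0.70),
                           germline_hom_min = 0.90,
                           normal_support_min_vaf = 0.30) {
  cfg <- list(min_depth = min_depth,
              min_vaf_somatic = min_vaf_somatic,
              strand_bias_min_fraction = strand_bias_min_fraction,
              common_maf_threshold = common_maf_threshold,
              pon_recurrence_fraction = pon_recurrence_fraction,
              germline_het_band = germline_het_band,
              germline_hom_min = germline_hom_min,
              normal_support_min_vaf = normal_support_min_vaf)
  fracs <- c(cfg$min_vaf_somatic, cfg$strand_bias_min_fraction,
             cfg$common_maf_threshold, cfg$pon_recurrence_fraction,
             cfg$germline_het_band, cfg$germline_hom_min,
             cfg$normal_support_min_vaf)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0,1]")
  if (!(germline_het_band[1] < germline_het_band[2] &&
        germline_het_band[2] < germline_hom_min)) {
    stop("require germline_het_band lower < upper < germline_hom_min")
  }
  structure(cfg, class = "cascade_config")
}

#' Strand-bias artifact filter
#'
#' Fails a call whose alternate reads are concentrated on one strand:
#' `min(f, r) / (f + r) <= strand_bias_min_fraction` with `f + r > 0`.
#' Missing strand counts pass with reason `"not_evaluated"`.
#'
#' @param alt_forward,alt_reverse Stranded alternate read counts
#'   (vectorized).
#' @param cfg A [cascade_config()].
#' @return Data frame with logical `pass` and character `reason`.
#' @export
strand_bias_filter <- function(alt_forward, alt_reverse,
                               cfg = cascade_config()) {
  if (any(alt_forward < 0 | alt_reverse < 0, na.rm = TRUE)) {
    stop("negative stranded alt counts")
  }
  n <- length(alt_forward)
  total <- alt_forward + alt_reverse
  minfrac <- pmin(alt_forward, alt_reverse) / total
  pass <- rep(TRUE, n)
  reason <- rep("balanced", n)
  biased <- !is.na(minfrac) & total > 0 &
    minfrac <= cfg$strand_bias_min_fraction
  pass[biased] <- FALSE
  reason[biased] <- sprintf("strand_biased(%d:%d)",
                            alt_forward[biased], alt_reverse[biased])
  ne <- is.na(alt_forward) | is.na(alt_reverse)
  reason[ne] <- "not_evaluated"
  data.frame(pass = pass, reason = reason, stringsAsFactors = FALSE)
}

max_pop_freq <- function(av) {
  freq_cols <- c("freq_gnomad_exome_all", "freq_gnomad_exome_eas",
                 "freq_gnomad_genome_all", "freq_gnomad_genome_eas",
                 "freq_kova", "freq_krgdb")
  m <- as.matrix(av[, freq_cols, drop = FALSE])
  m[is.na(m)] <- 0
  apply(m, 1L, max)
}

#' Population-frequency (common polymorphism) filter
#'
#' For somatic candidacy a variant fails when any of the six database
#' frequencies (gnomAD exome/genome ALL and EAS, KOVA, KRGDB; missing
#' treated as 0) is at or above `common_maf_threshold`. For germline
#' candidacy this filter only annotates — rarity is enforced downstream by
#' the PM2 criterion.
#'
#' @param av Annotated-variant data frame (one or more rows).
#' @param cfg A [cascade_config()].
#' @return Data frame with `pass`, `reason` and the `max_freq` observed.
#' @export
population_frequency_filter <- function(av, cfg = cascade_config()) {
  mf <- max_pop_freq(av)
  pass <- mf < cfg$common_maf_threshold
  data.frame(pass = pass,
             reason = ifelse(pass, "rare",
                             sprintf("common_polymorphism(maf=%g)", mf)),
             max_freq = mf, stringsAsFactors = FALSE)
}

#' Panel-of-normals filter
#'
#' A somatic candidate recurring in at least `pon_recurrence_fraction` of
#' the panel of normals fails (inclusive boundary); variants absent from
#' the panel pass.
#'
#' @param av Annotated-variant data frame.
#' @param pon PoN data frame from [read_pon()].
#' @param cfg A [cascade_config()].
#' @return Data frame with `pass` and `reason`.
#' @export
panel_of_normals_filter <- function(av, pon, cfg = cascade_config()) {
  rec <- pon$recurrence_fraction[match(variant_key(av), variant_key(pon))]
  rec[is.na(rec)] <- 0
  pass <- rec < cfg$pon_recurrence_fraction
  data.frame(pass = pass,
             reason = ifelse(pass, "pon_clear",
                             sprintf("pon_recurrent(%g)", rec)),
             stringsAsFactors = FALSE)
}

#' Partition annotated variants by origin
#'
#' Implements the origin rules applied after the quality and strand-bias
#' gates:
#' * presumed germline — same variant present in the patient's matched
#'   non-malignant sample at VAF >= `normal_support_min_vaf`, gene on the
#'   germline panel;
#' * potential germline — no matched normal available, gene on the germline
#'   panel, VAF within the heterozygous band or above the homozygous
#'   minimum;
#' * somatic — gene on the somatic panel, VAF >= `min_vaf_somatic`, passing
#'   the population-frequency and panel-of-normals filters;
#' * dual — both the potential-germline and somatic rules hold;
#' * unresolved — none hold.
#'
#' @param av Annotated-variant data frame (post quality/strand gates).
#' @param normals Calls data frame of non-malignant samples (may be empty);
#'   used both to confirm variants and to know which patients have a
#'   matched normal.
#' @param pon PoN data frame.
#' @param cfg A [cascade_config()].
#' @return `av` with `origin` set and filter columns appended.
#' @export
partition_by_origin <- function(av, normals, pon, cfg = cascade_config()) {
  if (nrow(av) == 0L) return(av)
  has_normal <- av$patient_id %in% normals$patient_id
  nkey <- paste(normals$patient_id, variant_key(normals), sep = "|")
  akey <- paste(av$patient_id, variant_key(av), sep = "|")
  nidx <- match(akey, nkey)
  normal_vaf <- normals$vaf[nidx]
  confirmed <- !is.na(normal_vaf) & normal_vaf >= cfg$normal_support_min_vaf

  popf <- population_frequency_filter(av, cfg)
  ponf <- panel_of_normals_filter(av, pon, cfg)

  germ_band <- (av$vaf >= cfg$germline_het_band[1] &
                av$vaf <= cfg$germline_het_band[2]) |
               av$vaf >= cfg$germline_hom_min

  presumed <- confirmed & av$in_germline_panel
  potential <- !has_normal & av$in_germline_panel & germ_band
  somatic <- av$in_somatic_panel & av$vaf >= cfg$min_vaf_somatic &
    popf$pass & ponf$pass
  # a variant seen in the matched normal below confirmation support, or a
  # confirmed variant, is not a somatic candidate
  somatic <- somatic & !presumed

  origin <- rep("unresolved", nrow(av))
  origin[somatic] <- "somatic"
  origin[potential & !somatic] <- "potential_germline"
  origin[potential & somatic] <- "dual"
  origin[presumed] <- "presumed_germline"

  av$origin <- origin
  av$filter_trail <- paste0(
    av$filter_trail,
    "popfreq:", ifelse(popf$pass, "pass", paste0("fail(", popf$reason, ")")),
    ";pon:", ifelse(ponf$pass, "pass", paste0("fail(", ponf$reason, ")")),
    ";origin:", origin)
  av
}

#' Run the full filtering cascade
#'
#' Stage order: quality gate (depth) -> strand bias -> origin partition
#' (population-frequency and panel-of-normals filters applied inside
#' somatic candidacy). Every input variant is assigned exactly one origin
#' (`rejected` for quality/strand failures) and its `filter_trail` records
#' each stage; dual variants are cross-listed in both the germline and
#' somatic output lists.
#'
#' @param av Annotated-variant data frame (consensus-merged tumor calls).
#' @param normals Calls data frame from non-malignant samples.
#' @param pon PoN data frame.
#' @param cfg A [cascade_config()].
#' @return List with elements `presumed_germline`, `potential_germline`,
#'   `somatic`, `dual`, `rejected`, `unresolved` (data frames) and `all`
#'   (every input row with its final origin and filter trail).
#' @export
run_cascade <- function(av, normals = empty_calls(), pon = empty_pon(),
                        cfg = cascade_config()) {
  if (nrow(av) == 0L) {
    e <- av
    return(list(presumed_germline = e, potential_germline = e, somatic = e,
                dual = e, rejected = e, unresolved = e, all = e))
  }
  qual_pass <- !is.na(av$depth) & av$depth >= cfg$min_depth
  av$filter_trail <- paste0("quality:",
                            ifelse(qual_pass, "pass",
                                   sprintf("fail(depth=%g)", av$depth)), ";")
  sb <- strand_bias_filter(av$alt_forward, av$alt_reverse, cfg)
  av$filter_trail <- paste0(av$filter_trail, "strand_bias:",
                            ifelse(sb$pass,
                                   ifelse(sb$reason == "not_evaluated",
                                          "not_evaluated", "pass"),
                                   paste0("fail(", sb$reason, ")")), ";")
  rejected_mask <- !qual_pass | !sb$pass
  rej <- av[rejected_mask, , drop = FALSE]
  if (nrow(rej) > 0L) {
    rej$origin <- "artifact"
    rej$filter_trail <- paste0(rej$filter_trail, "origin:artifact")
  }
  kept <- partition_by_origin(av[!rejected_mask, , drop = FALSE],
                              normals, pon, cfg)
  all_out <- rbind(kept, rej)
  if (nrow(all_out) > 0L) {
    all_out <- all_out[order(all_out$patient_id, all_out$sample_id,
                             all_out$chrom, all_out$pos, all_out$alt), ,
                       drop = FALSE]
    rownames(all_out) <- NULL
  }
  pick <- function(o) {
    out <- all_out[all_out$origin %in% o, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(
    presumed_germline = pick("presumed_germline"),
    potential_germline = pick(c("potential_germline", "dual")),
    somatic = pick(c("somatic", "dual")),
    dual = pick("dual"),
    rejected = pick("artifact"),
    unresolved = pick("unresolved"),
    all = all_out
  )
}

#' @rdname read_pon
#' @export
empty_pon <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), recurrence_fraction = numeric(),
             stringsAsFactors = FALSE)
}
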