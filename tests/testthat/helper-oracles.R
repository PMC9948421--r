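# Independently written reference implementations ("oracles") used to
# cross-check the package. They deliberately share no code with the
# package paths they verify.

# --- ACMG criterion-combination oracle -----------------------------------
# Data-driven rule table: each pathogenic-side rule is a minimum-count
# vector over (very_strong, strong, moderate, supporting), with optional
# exact-count constraints where the rules say "1 strong" or "2 moderate".
oracle_strength_of <- function(token) {
  parts <- strsplit(token, "_", fixed = TRUE)[[1]]
  if (length(parts) == 2L) {
    return(c(VeryStrong = "VS", Strong = "S", Moderate = "M",
             Supporting = "P", StandAlone = "SA")[parts[2]])
  }
  fam <- sub("[0-9]+$", "", parts[1])
  c(PVS = "VS", PS = "S", PM = "M", PP = "P", BA = "SA", BS = "BSst",
    BP = "BPsu")[fam]
}

oracle_combine <- function(tokens) {
  s <- vapply(tokens, oracle_strength_of, character(1))
  fam <- sub("[0-9]+.*$", "", tokens)
  benign_fam <- fam %in% c("BA", "BS", "BP")
  vs <- sum(s[!benign_fam] == "VS"); st <- sum(s[!benign_fam] == "S")
  mo <- sum(s[!benign_fam] == "M"); su <- sum(s[!benign_fam] == "P")
  ba <- sum(benign_fam & fam == "BA")
  bs <- sum(benign_fam & fam == "BS")
  bp <- sum(benign_fam & fam == "BP")

  p_rules <- list(
    function() vs >= 1 && st >= 1,
    function() vs >= 1 && mo >= 2,
    function() vs >= 1 && mo >= 1 && su >= 1,
    function() vs >= 1 && su >= 2,
    function() vs >= 2,
    function() st >= 2,
    function() st == 1 && mo >= 3,
    function() st == 1 && mo == 2 && su >= 2,
    function() st == 1 && mo == 1 && su >= 4)
  lp_rules <- list(
    function() vs >= 1 && mo >= 1,
    function() st == 1 && mo >= 1 && mo <= 2,
    function() st == 1 && su >= 2,
    function() mo >= 3,
    function() mo == 2 && su >= 2,
    function() mo == 1 && su >= 4)
  pathogenic <- any(vapply(p_rules, function(f) f(), logical(1)))
  likely <- any(vapply(lp_rules, function(f) f(), logical(1)))
  b <- ba >= 1 || bs >= 2
  lb <- (bs == 1 && bp >= 1) || bp >= 2
  pv <- if (pathogenic) "P" else if (likely) "LP" else NA
  bv <- if (b) "B" else if (lb) "LB" else NA
  if (!is.na(pv) && !is.na(bv)) "VUS"
  else if (!is.na(pv)) pv
  else if (!is.na(bv)) bv
  else "VUS"
}

# --- chi-square from the expected-counts definition ----------------------
oracle_chisq <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  d <- abs(tab - E)
  if (yates) d <- pmax(d - 0.5, 0)
  sum(d^2 / E)
}

# --- exact Mann-Whitney two-sided p by enumeration -----------------------
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  mu <- na * (n - na) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  min(p, 1)
}

# --- Cox partial likelihood grid search (single covariate, no ties) ------
oracle_cox_coef <- function(times, events, x, grid = seq(-4, 4, 1e-4)) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]; x <- x[ord]
  loglik <- vapply(grid, function(b) {
    ll <- 0
    for (i in seq_along(times)) {
      if (events[i]) {
        risk <- times >= times[i]
        ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
      }
    }
    ll
  }, numeric(1))
  grid[which.max(loglik)]
}

# --- per-variant brute-force cascade evaluation --------------------------
# re-derives a variant's expected origin from its raw columns; written as
# flat boolean logic, independent of the package's staged implementation.
oracle_origin <- function(av_row, normals, pon, cfg) {
  r <- as.list(av_row)
  if (is.na(r$depth) || r$depth < cfg$min_depth) return("artifact")
  if (!is.na(r$alt_forward) && !is.na(r$alt_reverse) &&
      (r$alt_forward + r$alt_reverse) > 0 &&
      min(r$alt_forward, r$alt_reverse) /
        (r$alt_forward + r$alt_reverse) <= cfg$strand_bias_min_fraction) {
    return("artifact")
  }
  freqs <- unlist(r[c("freq_gnomad_exome_all", "freq_gnomad_exome_eas",
                      "freq_gnomad_genome_all", "freq_gnomad_genome_eas",
                      "freq_kova", "freq_krgdb")])
  freqs[is.na(freqs)] <- 0
  common <- max(freqs) >= cfg$common_maf_threshold
  key <- paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
  pon_key <- paste(pon$chrom, pon$pos, pon$ref, pon$alt, sep = ":")
  rec <- if (key %in% pon_key) {
    pon$recurrence_fraction[match(key, pon_key)]
  } else 0
  in_pon <- rec >= cfg$pon_recurrence_fraction
  has_norm <- r$patient_id %in% normals$patient_id
  nk <- paste(normals$patient_id,
              paste(normals$chrom, normals$pos, normals$ref, normals$alt,
                    sep = ":"), sep = "|")
  hit <- match(paste(r$patient_id, key, sep = "|"), nk)
  confirmed <- !is.na(hit) && normals$vaf[hit] >= cfg$normal_support_min_vaf
  presumed <- confirmed && r$in_germline_panel
  in_band <- (r$vaf >= cfg$germline_het_band[1] &&
                r$vaf <= cfg$germline_het_band[2]) ||
    r$vaf >= cfg$germline_hom_min
  potential <- !has_norm && r$in_germline_panel && in_band
  somatic <- r$in_somatic_panel && r$vaf >= cfg$min_vaf_somatic &&
    !common && !in_pon && !presumed
  if (presumed) return("presumed_germline")
  if (potential && somatic) return("dual")
  if (somatic) return("somatic")
  if (potential) return("potential_germline")
  "unresolved"
}
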