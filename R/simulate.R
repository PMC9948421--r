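`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration for the synthetic T-MN cohort generator
#'
#' Defaults emulate the study conditions of a 53-patient T-MN cohort:
#' seven pediatric patients, twenty matched non-malignant samples, four
#' longitudinal pairs, Table 1-level prevalences of the clinical and
#' cytogenetic flags, a 13.2% deleterious germline carrier rate with
#' Table 2-shaped annotations, a TP53-dominant somatic spectrum with
#' per-sample counts of median 2-3 (range capped at 7, pediatric counts
#' lower than adult), injected strand-bias and common-polymorphism
#' artifacts, and survival drawn from an exponential baseline with the
#' five multivariate hazard ratios (male sex 2.99, prior radiotherapy
#' 4.80, cytotoxic therapy beyond the 15.8-month cut 3.75, diagnostic age
#' beyond the 50-year cut 10.79, del(5q) 3.99) as ground truth.
#'
#' @param n_patients,n_pediatric,n_matched_normals,n_longitudinal Cohort
#'   structure counts.
#' @param prevalences Named list of per-flag probabilities.
#' @param del5q_del7q_odds_ratio Odds ratio inducing co-occurrence of the
#'   chromosome 5 and 7 deletions.
#' @param germline_carrier_rate Probability that a patient carries one
#'   deleterious germline variant.
#' @param somatic_count Parameters of the zero-inflated, truncated Poisson
#'   law of per-sample somatic variant counts (`lambda_adult`,
#'   `zero_adult`, `lambda_pediatric`, `zero_pediatric`, `max`).
#' @param tp53_del5q_boost Multiplier on the TP53 sampling weight for
#'   del(5q) patients (induces the TP53/del(5q) association).
#' @param artifact_rates Per-sample Poisson rates of injected strand-bias
#'   artifacts, carried common-polymorphism sites, and single-caller
#'   noise calls.
#' @param n_poly_sites Number of recurrent common-polymorphism sites
#'   shared across the cohort (these populate the panel of normals).
#' @param true_hazard_ratios Named per-covariate hazard ratios used as
#'   simulation truth.
#' @param age_cut,therapy_cut Dichotomization cut-points (years, months).
#' @param baseline_hazard Exponential baseline hazard (per month).
#' @param censoring_fraction Target fraction of censored patients.
#' @param vaf_jitter SD of the per-caller VAF jitter.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 53L,
                       n_pediatric = 7L,
                       n_matched_normals = 20L,
                       n_longitudinal = 4L,
                       prevalences = list(),
                       del5q_del7q_odds_ratio = 6,
                       germline_carrier_rate = 0.132,
                       somatic_count = list(),
                       tp53_del5q_boost = 6,
                       artifact_rates = list(),
                       n_poly_sites = 12L,
                       true_hazard_ratios = c(male = 2.99,
                                              radiotherapy = 4.80,
                                              long_therapy = 3.75,
                                              age_over_cut = 10.79,
                                              del5q = 3.99),
                       age_cut = 50,
                       therapy_cut = 15.8,
                       baseline_hazard = 0.002,
                       censoring_fraction = 0.2,
                       vaf_jitter = 0.005,
                       seed = NULL) {
  prev_default <- list(
    male = 0.528, aml = 0.453, mds = 0.528, mds_mpn = 0.019,
    del5q = 0.283, del7q = 0.434, del17p = 0.094,
    complex_given_del5q = 0.95, complex_given_no_del5q = 0.28,
    pml_rara = 0.075, kmt2a_r = 0.075, runx1_r = 0.019, mecom_r = 0.057,
    not_assessed = 0.038, radiotherapy = 0.34, alkylating = 0.849,
    topoII = 0.679, antimetabolite = 0.17, antitubulin = 0.472,
    auto_pbsct = 0.17, allo_pbsct = 0.057)
  prev <- utils::modifyList(prev_default, prevalences)
  sc_default <- list(lambda_adult = 3.2, zero_adult = 0.08,
                     lambda_pediatric = 2.3, zero_pediatric = 0.10,
                     max = 7L)
  sc <- utils::modifyList(sc_default, somatic_count)
  ar_default <- list(strand_bias = 0.3, common_polymorphism = 0.3,
                     singleton = 0.5)
  ar <- utils::modifyList(ar_default, artifact_rates)
  stopifnot(all(unlist(prev) >= 0 & unlist(prev) <= 1),
            germline_carrier_rate >= 0, germline_carrier_rate <= 1,
            censoring_fraction >= 0, censoring_fraction < 1,
            del5q_del7q_odds_ratio > 0, all(true_hazard_ratios > 0))
  structure(list(
    n_patients = as.integer(n_patients),
    n_pediatric = as.integer(n_pediatric),
    n_matched_normals = as.integer(n_matched_normals),
    n_longitudinal = as.integer(n_longitudinal),
    prevalences = prev,
    del5q_del7q_odds_ratio = del5q_del7q_odds_ratio,
    germline_carrier_rate = germline_carrier_rate,
    somatic_count = sc,
    tp53_del5q_boost = tp53_del5q_boost,
    artifact_rates = ar,
    n_poly_sites = as.integer(n_poly_sites),
    true_hazard_ratios = true_hazard_ratios,
    age_cut = age_cut,
    therapy_cut = therapy_cut,
    baseline_hazard = baseline_hazard,
    censoring_fraction = censoring_fraction,
    vaf_jitter = vaf_jitter,
    seed = seed
  ), class = "sim_config")
}

# joint 2x2 cell probability giving marginals p1, p2 and odds ratio or
joint_prob_from_or <- function(p1, p2, or) {
  if (abs(or - 1) < 1e-12) return(p1 * p2)
  a <- or - 1
  b <- 1 + (p1 + p2) * a
  disc <- b^2 - 4 * a * or * p1 * p2
  if (disc < 0) stop("infeasible odds ratio / marginal combination")
  p11 <- (b - sqrt(disc)) / (2 * a)
  if (p11 < max(0, p1 + p2 - 1) - 1e-9 || p11 > min(p1, p2) + 1e-9) {
    stop("infeasible odds ratio / marginal combination")
  }
  min(max(p11, 0), min(p1, p2))
}

#' Simulate patient clinical records
#'
#' Flags are drawn at their configured prevalences; del(5q) and del(7q)
#' are drawn jointly at the configured odds ratio; a `not_assessed`
#' karyotype excludes all other cytogenetic flags; pediatric ages are
#' below 20 years. Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return Data frame of patient records (demographics, therapy flags,
#'   durations, cytogenetic flags, matched-normal and longitudinal
#'   indicators).
#' @export
simulate_patients <- function(cfg = sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_patients
  if (n == 0L) return(empty_patients())
  p <- cfg$prevalences
  id <- sprintf("tmn%02d", seq_len(n))
  pediatric <- rep(FALSE, n)
  if (cfg$n_pediatric > 0L) {
    pediatric[sample.int(n, min(n, cfg$n_pediatric))] <- TRUE
  }
  age <- numeric(n)
  age[pediatric] <- round(stats::runif(sum(pediatric), 1.8, 19.9), 1)
  n_ad <- sum(!pediatric)
  ad_age <- stats::rnorm(n_ad, 58, 13)
  ad_age <- pmin(pmax(ad_age, 20.7), 82.4)
  age[!pediatric] <- round(ad_age, 1)

  sex <- ifelse(stats::rbinom(n, 1, p$male) == 1, "M", "F")
  subtype <- sample(c("MDS", "MDS_MPN", "AML"), n, replace = TRUE,
                    prob = c(p$mds, p$mds_mpn, p$aml))
  primary <- sample(c("non_hodgkin_lymphoma", "breast_cancer", "aml",
                      "bone_soft_tissue", "germ_cell_tumor",
                      "colorectal_cancer", "other"),
                    n, replace = TRUE,
                    prob = c(0.302, 0.151, 0.094, 0.094, 0.094, 0.075,
                             0.19))

  radiotherapy <- stats::rbinom(n, 1, p$radiotherapy) == 1
  alkylating <- stats::rbinom(n, 1, p$alkylating) == 1
  topoII <- stats::rbinom(n, 1, p$topoII) == 1
  antimetabolite <- stats::rbinom(n, 1, p$antimetabolite) == 1
  antitubulin <- stats::rbinom(n, 1, p$antitubulin) == 1
  auto_pbsct <- stats::rbinom(n, 1, p$auto_pbsct) == 1
  allo_pbsct <- stats::rbinom(n, 1, p$allo_pbsct) == 1
  therapy_duration <- round(pmin(pmax(
    stats::rlnorm(n, log(18.6), 0.9), 1.2), 122.8), 1)
  latency <- round(pmin(pmax(stats::rlnorm(n, log(52), 0.8), 12), 309.7),
                   1)

  not_assessed <- stats::rbinom(n, 1, p$not_assessed) == 1
  p11 <- joint_prob_from_or(p$del5q, p$del7q, cfg$del5q_del7q_odds_ratio)
  u <- stats::runif(n)
  del5q <- logical(n); del7q <- logical(n)
  both <- u < p11
  only5 <- u >= p11 & u < p$del5q
  only7 <- u >= p$del5q & u < p$del5q + (p$del7q - p11)
  del5q[both | only5] <- TRUE
  del7q[both | only7] <- TRUE
  complex_k <- stats::rbinom(n, 1, ifelse(del5q, p$complex_given_del5q,
                                          p$complex_given_no_del5q)) == 1
  del17p <- stats::rbinom(n, 1, p$del17p) == 1
  pml_rara <- stats::rbinom(n, 1, p$pml_rara) == 1
  kmt2a_r <- stats::rbinom(n, 1, p$kmt2a_r) == 1
  runx1_r <- stats::rbinom(n, 1, p$runx1_r) == 1
  mecom_r <- stats::rbinom(n, 1, p$mecom_r) == 1
  for (flag in c("del5q", "del7q", "complex_k", "del17p", "pml_rara",
                 "kmt2a_r", "runx1_r", "mecom_r")) {
    v <- get(flag); v[not_assessed] <- FALSE; assign(flag, v)
  }
  normal_k <- !not_assessed & !(del5q | del7q | complex_k | del17p |
                                  pml_rara | kmt2a_r | runx1_r | mecom_r)

  has_normal <- rep(FALSE, n)
  if (cfg$n_matched_normals > 0L) {
    has_normal[sample.int(n, min(n, cfg$n_matched_normals))] <- TRUE
  }
  longitudinal <- rep(FALSE, n)
  if (cfg$n_longitudinal > 0L) {
    longitudinal[sample.int(n, min(n, cfg$n_longitudinal))] <- TRUE
  }

  data.frame(
    patient_id = id, age_years = age, pediatric = pediatric, sex = sex,
    primary_disease = primary, subtype = subtype,
    chemo = TRUE, radiotherapy = radiotherapy, alkylating = alkylating,
    topoII = topoII, antimetabolite = antimetabolite,
    antitubulin = antitubulin, auto_pbsct = auto_pbsct,
    allo_pbsct = allo_pbsct,
    therapy_duration_months = therapy_duration,
    latency_months = latency,
    del5q = del5q, del7q = del7q, del17p = del17p, complex = complex_k,
    pml_rara = pml_rara, kmt2a_r = kmt2a_r, runx1_r = runx1_r,
    mecom_r = mecom_r, normal_karyotype = normal_k,
    not_assessed = not_assessed,
    has_matched_normal = has_normal, longitudinal = longitudinal,
    stringsAsFactors = FALSE
  )
}

empty_patients <- function() {
  df <- data.frame(patient_id = character(0))
  df
}

#' Survival covariate matrix used by the prognostic model
#'
#' The five multivariate covariates: male sex, prior radiotherapy,
#' cytotoxic-therapy duration above the configured cut, diagnostic age
#' above the configured cut, and del(5q).
#'
#' @param patients Patient data frame from [simulate_patients()].
#' @param cfg A [sim_config()] supplying the cut-points.
#' @return Numeric 0/1 matrix with columns `male`, `radiotherapy`,
#'   `long_therapy`, `age_over_cut`, `del5q`.
#' @export
survival_covariates <- function(patients, cfg = sim_config()) {
  cbind(
    male = as.integer(patients$sex == "M"),
    radiotherapy = as.integer(patients$radiotherapy),
    long_therapy = dichotomize(patients$therapy_duration_months,
                               cfg$therapy_cut),
    age_over_cut = dichotomize(patients$age_years, cfg$age_cut),
    del5q = as.integer(patients$del5q)
  )
}

#' Simulate overall survival under a proportional-hazards truth
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(sum(log(HR_k) * x_k))`; censoring times are
#' uniform on (0, b) with b solved so the expected censored fraction
#' equals `censoring_fraction` (independent of covariates). Months are
#' rounded to 0.1 with a floor of 0.1.
#'
#' @param cfg A [sim_config()].
#' @param patients Patient data frame.
#' @return `patients` with `os_months` and `death` columns appended.
#' @export
simulate_survival <- function(cfg, patients) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 2L)
  X <- survival_covariates(patients, cfg)
  hr <- cfg$true_hazard_ratios[colnames(X)]
  h <- cfg$baseline_hazard * exp(as.vector(X %*% log(hr)))
  n <- nrow(patients)
  t_event <- stats::rexp(n, rate = h)
  if (cfg$censoring_fraction <= 0) {
    os <- t_event
    death <- rep(TRUE, n)
  } else {
    f <- function(b) mean((1 - exp(-h * b)) / (h * b)) -
      cfg$censoring_fraction
    b <- stats::uniroot(f, lower = 1e-6, upper = 1e8, tol = 1e-8)$root
    cens <- stats::runif(n, 0, b)
    os <- pmin(t_event, cens)
    death <- t_event <= cens
  }
  patients$os_months <- pmax(round(os, 1), 0.1)
  patients$death <- death
  patients
}

# ---- variant generation -------------------------------------------------

blank_annotation <- function() {
  list(gene = NA_character_, transcript = NA_character_,
       hgvs_c = NA_character_, hgvs_p = NA_character_,
       consequence = "other", nmd_predicted = NA_character_,
       freq_gnomad_exome_all = 0, freq_gnomad_exome_eas = 0,
       freq_gnomad_genome_all = 0, freq_gnomad_genome_eas = 0,
       freq_kova = 0, freq_krgdb = 0,
       clinvar_significance = NA_character_, clinvar_stars = NA_integer_,
       hgmd_class = "none", cosmic_present = FALSE,
       sift = NA_character_, polyphen2_hvar = NA_character_,
       cadd_phred = NA_real_, inheritance = "unknown",
       hotspot_domain = FALSE, protein_position = NA_integer_,
       domain_name = NA_character_)
}

# Table 2-shaped deleterious germline variant templates; each fires a
# criterion set that classifies P or LP.
germline_templates <- function() {
  t <- list(
    list(gene = "BRIP1", inheritance = "AR",
         consequence = "canonical_splice", nmd = "unknown",
         freq_all = 0.00000796, freq_eas = 0.000109,
         clinvar = "LP", stars = 2L, hgmd = "none"),
    list(gene = "NF1", inheritance = "AD", consequence = "missense",
         nmd = "unknown", freq_all = 0, freq_eas = 0,
         clinvar = "P", stars = 1L, hgmd = "DM_high",
         sift = "D", polyphen = "D", cadd = 27.4, hotspot = TRUE),
    list(gene = "CEBPA", inheritance = "AD", consequence = "frameshift",
         nmd = "no", freq_all = 0, freq_eas = 0,
         clinvar = NA, stars = NA, hgmd = "none"),
    list(gene = "FANCM", inheritance = "AR", consequence = "nonsense",
         nmd = "yes", freq_all = 0.0000757, freq_eas = 0,
         clinvar = "Conflicting interpretations of pathogenicity",
         stars = 1L, hgmd = "DM_high"),
    list(gene = "DDX41", inheritance = "AD", consequence = "frameshift",
         nmd = "yes", freq_all = 0, freq_eas = 0,
         clinvar = NA, stars = NA, hgmd = "none"),
    list(gene = "RUNX1", inheritance = "AD", consequence = "nonsense",
         nmd = "yes", freq_all = 0, freq_eas = 0,
         clinvar = NA, stars = NA, hgmd = "none"),
    list(gene = "NBN", inheritance = "AR", consequence = "nonsense",
         nmd = "no", freq_all = 0.000004, freq_eas = 0.0000544,
         clinvar = "US", stars = 2L, hgmd = "DM_low")
  )
  t
}

new_pos_counter <- function() {
  env <- new.env(parent = emptyenv())
  reg <- gene_registry()
  function(gene) {
    k <- env[[gene]] %||% 0L
    env[[gene]] <- k + 1L
    i <- match(gene, reg$gene)
    list(chrom = reg$chrom[i], pos = reg$start[i] + k * 10L)
  }
}

random_snv_alleles <- function() {
  ref <- sample(c("A", "C", "G", "T"), 1L)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  list(ref = ref, alt = alt)
}

draw_depth <- function() stats::rnbinom(1L, mu = 200, size = 12) + 20L

make_read_support <- function(vaf, strand_biased = FALSE) {
  depth <- draw_depth()
  alt_total <- max(5L, round(vaf * depth))
  alt_total <- min(alt_total, depth)
  fwd <- if (strand_biased) {
    max(1L, round(0.1 * alt_total))
  } else {
    # clean calls are strand-balanced: keep the minor-strand fraction
    # clear of the artifact boundary
    f <- stats::rbinom(1L, alt_total, 0.5)
    tries <- 0L
    while (min(f, alt_total - f) / alt_total <= 0.25 && tries < 50L) {
      f <- stats::rbinom(1L, alt_total, 0.5)
      tries <- tries + 1L
    }
    f
  }
  list(depth = depth, alt_forward = fwd, alt_reverse = alt_total - fwd,
       vaf = vaf)
}

aa3 <- c("Ala", "Arg", "Asn", "Asp", "Gly", "Leu", "Lys", "Pro", "Ser",
         "Tyr")

# one somatic variant's annotation fields
draw_somatic_annotation <- function(gene) {
  ann <- blank_annotation()
  ann$gene <- gene
  ann$consequence <- sample(c("missense", "nonsense", "frameshift",
                              "canonical_splice", "inframe_indel"),
                            1L, prob = c(0.65, 0.12, 0.12, 0.06, 0.05))
  if (ann$consequence %in% c("nonsense", "frameshift")) {
    ann$nmd_predicted <- sample(c("yes", "no"), 1L, prob = c(0.7, 0.3))
  }
  if (ann$consequence == "missense") {
    ann$sift <- sample(c("D", "T"), 1L, prob = c(0.6, 0.4))
    ann$polyphen2_hvar <- sample(c("D", "P", "B"), 1L,
                                 prob = c(0.5, 0.25, 0.25))
    ann$cadd_phred <- round(stats::runif(1, 10, 35), 1)
  }
  ann$cosmic_present <- stats::runif(1) < 0.7
  pp <- sample.int(600L, 1L)
  ann$protein_position <- pp
  if (gene == "TP53") {
    ann$protein_position <- sample(95:290, 1L)
    ann$hotspot_domain <- TRUE
    ann$domain_name <- "P53_DNA_binding"
  }
  if (stats::runif(1) < 0.4) {
    ann$freq_gnomad_exome_all <- stats::runif(1, 0, 5e-7)
  }
  ann$hgvs_p <- paste0("p.", sample(aa3, 1L), ann$protein_position,
                       switch(ann$consequence,
                              missense = sample(aa3, 1L),
                              nonsense = "*", frameshift = "fs",
                              "del"))
  ann
}

#' Simulate variant call sets with ground-truth labels
#'
#' Generates, per sample: one deleterious germline variant for carrier
#' patients (Table 2-shaped annotation, VAF centered at 0.5, mirrored
#' into the matched normal when one exists), somatic variants drawn from
#' TP53-dominant gene weights with dispersed sub-clonal VAFs, recurrent
#' common-polymorphism sites (which also populate the panel of normals),
#' strand-biased artifact calls, and single-caller noise calls. Every
#' variant carries its ground-truth origin label and a `boundary` flag
#' marking VAFs within 0.02 of a partition threshold. Caller multiplicity
#' (2 or 3 of the three pseudo-callers; 1 for noise calls) exercises the
#' consensus merge.
#'
#' @param cfg A [sim_config()].
#' @param patients Patient data frame from [simulate_patients()].
#' @return List with `variants` (master per-sample table including truth
#'   and annotation fields), `annotations` (unique variant annotation
#'   table), `truth` (sample, key, gene, `true_origin`, `boundary`),
#'   `pon`, and `samples` (sample_id/patient_id/role roster).
#' @export
simulate_variants <- function(cfg, patients) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  next_pos <- new_pos_counter()
  som <- somatic_gene_table()
  germ <- germline_gene_table()
  templates <- germline_templates()
  callers <- c("gatk_ug", "snver", "lofreq")

  # recurrent common-polymorphism site pool (also the panel of normals)
  registry_genes <- gene_registry()$gene
  poly <- vector("list", cfg$n_poly_sites)
  for (i in seq_len(cfg$n_poly_sites)) {
    g <- sample(registry_genes, 1L)
    loc <- next_pos(g)
    al <- random_snv_alleles()
    ann <- blank_annotation()
    ann$gene <- g
    ann$consequence <- sample(c("missense", "synonymous"), 1L)
    f <- stats::runif(1, 0.02, 0.2)
    ann$freq_gnomad_exome_all <- f
    ann$freq_gnomad_exome_eas <- f * stats::runif(1, 0.5, 2)
    ann$freq_gnomad_genome_all <- f * stats::runif(1, 0.8, 1.2)
    ann$freq_gnomad_genome_eas <- f * stats::runif(1, 0.5, 2)
    ann$freq_kova <- min(f * stats::runif(1, 0.5, 3), 0.5)
    ann$freq_krgdb <- min(f * stats::runif(1, 0.5, 3), 0.5)
    ann$sift <- "T"
    poly[[i]] <- c(list(chrom = loc$chrom, pos = loc$pos, ref = al$ref,
                        alt = al$alt,
                        recurrence = stats::runif(1, 0.05, 0.5)), ann)
  }

  rows <- list()
  ann_rows <- list()
  add_ann <- function(key, loc, al, ann) {
    if (is.null(ann_rows[[key]])) {
      ann_rows[[key]] <<- c(list(chrom = loc$chrom, pos = loc$pos,
                                 ref = al$ref, alt = al$alt), ann)
    }
  }
  emit <- function(sample_id, patient_id, role, loc, al, ann, vaf,
                   truth, boundary = FALSE, strand_biased = FALSE,
                   n_callers = NA_integer_) {
    rs <- make_read_support(vaf, strand_biased)
    if (is.na(n_callers)) {
      n_callers <- if (stats::runif(1) < 0.7) 3L else 2L
    }
    key <- paste(loc$chrom, loc$pos, al$ref, al$alt, sep = ":")
    add_ann(key, loc, al, ann)
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, patient_id = patient_id, sample_role = role,
      chrom = loc$chrom, pos = loc$pos, ref = al$ref, alt = al$alt,
      vaf = round(rs$vaf, 4), depth = rs$depth,
      alt_forward = rs$alt_forward, alt_reverse = rs$alt_reverse,
      callers = paste(sample(callers, n_callers), collapse = ","),
      gene = ann$gene, true_origin = truth, boundary = boundary,
      stringsAsFactors = FALSE)
  }

  germline_variant_of <- list()  # patient -> list(loc, al, ann, template)

  sample_roster <- list()
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    sample_a <- paste0(pid, "-A")
    sample_roster[[length(sample_roster) + 1L]] <-
      data.frame(sample_id = sample_a, patient_id = pid,
                 sample_role = "tmn_initial", stringsAsFactors = FALSE)

    # deleterious germline variant for carriers
    is_carrier <- stats::runif(1) < cfg$germline_carrier_rate
    if (is_carrier) {
      tpl <- templates[[sample.int(length(templates), 1L)]]
      loc <- next_pos(tpl$gene)
      al <- if (tpl$consequence == "frameshift") {
        b <- sample(c("A", "C", "G", "T"), 2L, replace = TRUE)
        list(ref = paste(b, collapse = ""), alt = b[1])
      } else {
        random_snv_alleles()
      }
      ann <- blank_annotation()
      ann$gene <- tpl$gene
      ann$consequence <- tpl$consequence
      ann$nmd_predicted <- tpl$nmd
      ann$freq_gnomad_exome_all <- tpl$freq_all
      ann$freq_gnomad_exome_eas <- tpl$freq_eas
      ann$clinvar_significance <- if (is.na(tpl$clinvar[1])) {
        NA_character_
      } else tpl$clinvar
      ann$clinvar_stars <- if (is.na(tpl$clinvar[1])) NA_integer_ else
        tpl$stars
      ann$hgmd_class <- tpl$hgmd
      ann$inheritance <- tpl$inheritance
      ann$sift <- tpl$sift %||% NA_character_
      ann$polyphen2_hvar <- tpl$polyphen %||% NA_character_
      ann$cadd_phred <- tpl$cadd %||% NA_real_
      ann$hotspot_domain <- isTRUE(tpl$hotspot)
      ann$hgvs_p <- paste0("p.", sample(aa3, 1L), sample.int(700L, 1L),
                           switch(tpl$consequence, nonsense = "*",
                                  frameshift = "fs",
                                  missense = sample(aa3, 1L), ""))
      in_som_panel <- tpl$gene %in% som$gene
      truth <- if (patients$has_matched_normal[i]) {
        "presumed_germline"
      } else if (in_som_panel) "dual" else "potential_germline"
      vaf <- stats::rbeta(1, 40, 40)
      emit(sample_a, pid, "tmn_initial", loc, al, ann, vaf, truth)
      germline_variant_of[[pid]] <- list(loc = loc, al = al, ann = ann)
    }

    # somatic variants
    sc <- cfg$somatic_count
    lam <- if (patients$pediatric[i]) sc$lambda_pediatric else
      sc$lambda_adult
    pz <- if (patients$pediatric[i]) sc$zero_pediatric else sc$zero_adult
    n_som <- if (stats::runif(1) < pz) 0L else
      min(stats::rpois(1, lam), sc$max)
    w <- som$weight
    if (patients$del5q[i]) {
      w[som$gene == "TP53"] <- w[som$gene == "TP53"] * cfg$tp53_del5q_boost
    }
    som_records <- list()
    if (n_som > 0L) {
      genes_i <- sample(som$gene, n_som, replace = TRUE, prob = w)
      for (g in genes_i) {
        loc <- next_pos(g)
        ann <- draw_somatic_annotation(g)
        al <- if (ann$consequence == "frameshift") {
          b <- sample(c("A", "C", "G", "T"), 2L, replace = TRUE)
          list(ref = paste(b, collapse = ""), alt = b[1])
        } else random_snv_alleles()
        vaf <- stats::rbeta(1, 2, 6)
        in_germ_panel <- g %in% germ$gene
        if (in_germ_panel && vaf >= 0.285) vaf <- stats::runif(1, 0.05,
                                                               0.27)
        boundary <- (vaf >= 0.28 && vaf <= 0.32) ||
          (vaf >= 0.68 && vaf <= 0.72) || vaf >= 0.88 ||
          vaf < 0.04
        emit(sample_a, pid, "tmn_initial", loc, al, ann, vaf, "somatic",
             boundary)
        som_records[[length(som_records) + 1L]] <-
          list(loc = loc, al = al, ann = ann)
      }
    }

    # carried common-polymorphism sites
    n_poly <- stats::rpois(1, cfg$artifact_rates$common_polymorphism)
    if (n_poly > 0L && cfg$n_poly_sites > 0L) {
      for (s in sample.int(cfg$n_poly_sites, min(n_poly,
                                                 cfg$n_poly_sites))) {
        ps <- poly[[s]]
        loc <- list(chrom = ps$chrom, pos = ps$pos)
        al <- list(ref = ps$ref, alt = ps$alt)
        ann <- ps[setdiff(names(ps), c("chrom", "pos", "ref", "alt",
                                       "recurrence"))]
        vaf <- if (stats::runif(1) < 0.2) stats::rbeta(1, 60, 3) else
          stats::rbeta(1, 40, 40)
        emit(sample_a, pid, "tmn_initial", loc, al, ann, vaf,
             "common_polymorphism")
      }
    }

    # strand-biased artifacts
    n_sb <- stats::rpois(1, cfg$artifact_rates$strand_bias)
    for (k in seq_len(n_sb)) {
      g <- sample(som$gene, 1L)
      loc <- next_pos(g)
      al <- random_snv_alleles()
      ann <- draw_somatic_annotation(g)
      emit(sample_a, pid, "tmn_initial", loc, al, ann,
           stats::rbeta(1, 2, 6), "artifact_strand_bias",
           strand_biased = TRUE)
    }

    # single-caller noise
    n_single <- stats::rpois(1, cfg$artifact_rates$singleton)
    for (k in seq_len(n_single)) {
      g <- sample(som$gene, 1L)
      loc <- next_pos(g)
      al <- random_snv_alleles()
      ann <- draw_somatic_annotation(g)
      emit(sample_a, pid, "tmn_initial", loc, al, ann,
           stats::rbeta(1, 2, 8), "singleton", n_callers = 1L)
    }

    # progression sample: somatic drift, germline retained
    if (patients$longitudinal[i]) {
      sample_b <- paste0(pid, "-B")
      sample_roster[[length(sample_roster) + 1L]] <-
        data.frame(sample_id = sample_b, patient_id = pid,
                   sample_role = "tmn_progression",
                   stringsAsFactors = FALSE)
      gv <- germline_variant_of[[pid]]
      if (!is.null(gv)) {
        truth <- if (patients$has_matched_normal[i]) {
          "presumed_germline"
        } else if (gv$ann$gene %in% som$gene) "dual" else
          "potential_germline"
        emit(sample_b, pid, "tmn_progression", gv$loc, gv$al, gv$ann,
             stats::rbeta(1, 40, 40), truth)
      }
      keep <- som_records
      if (length(keep) > 1L) keep <- keep[-sample.int(length(keep), 1L)]
      for (r in keep) {
        vaf <- stats::rbeta(1, 2, 6)
        if (r$ann$gene %in% germ$gene && vaf >= 0.285) {
          vaf <- stats::runif(1, 0.05, 0.27)
        }
        boundary <- (vaf >= 0.28 && vaf <= 0.32) ||
          (vaf >= 0.68 && vaf <= 0.72) || vaf < 0.04
        emit(sample_b, pid, "tmn_progression", r$loc, r$al, r$ann, vaf,
             "somatic", boundary)
      }
      for (k in seq_len(1L + stats::rpois(1, 0.7))) {
        g <- sample(som$gene, 1L, prob = w)
        loc <- next_pos(g)
        ann <- draw_somatic_annotation(g)
        al <- if (ann$consequence == "frameshift") {
          b <- sample(c("A", "C", "G", "T"), 2L, replace = TRUE)
          list(ref = paste(b, collapse = ""), alt = b[1])
        } else random_snv_alleles()
        vaf <- stats::rbeta(1, 2, 6)
        if (g %in% germ$gene && vaf >= 0.285) vaf <- stats::runif(1, 0.05,
                                                                  0.27)
        boundary <- (vaf >= 0.28 && vaf <= 0.32) ||
          (vaf >= 0.68 && vaf <= 0.72) || vaf < 0.04
        emit(sample_b, pid, "tmn_progression", loc, al, ann, vaf,
             "somatic", boundary)
      }
    }

    # matched non-malignant sample: germline + carried polymorphisms
    if (patients$has_matched_normal[i]) {
      sample_n <- paste0(pid, "-N")
      sample_roster[[length(sample_roster) + 1L]] <-
        data.frame(sample_id = sample_n, patient_id = pid,
                   sample_role = "non_malignant", stringsAsFactors = FALSE)
      gv <- germline_variant_of[[pid]]
      if (!is.null(gv)) {
        emit(sample_n, pid, "non_malignant", gv$loc, gv$al, gv$ann,
             stats::rbeta(1, 40, 40), "presumed_germline")
      }
    }
  }

  if (length(rows) == 0L) {
    v <- empty_calls()
    v$gene <- character(0); v$true_origin <- character(0)
    v$boundary <- logical(0)
    return(list(variants = v, annotations = NULL,
                truth = v[, c("sample_id", "chrom", "pos", "ref", "alt",
                              "gene", "true_origin", "boundary")],
                pon = empty_pon(),
                samples = do.call(rbind, sample_roster)))
  }
  variants <- do.call(rbind, rows)
  annotations <- do.call(rbind, lapply(ann_rows, function(a) {
    as.data.frame(a, stringsAsFactors = FALSE)
  }))
  rownames(annotations) <- NULL
  pon <- do.call(rbind, lapply(poly, function(ps) {
    data.frame(chrom = ps$chrom, pos = ps$pos, ref = ps$ref,
               alt = ps$alt, recurrence_fraction = ps$recurrence,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pon)) pon <- empty_pon()
  samples <- do.call(rbind, sample_roster)
  truth <- variants[, c("sample_id", "chrom", "pos", "ref", "alt",
                        "gene", "true_origin", "boundary")]
  list(variants = variants, annotations = annotations, truth = truth,
       pon = pon, samples = samples)
}

#' Expand the master variant table into per-caller call sets
#'
#' Each variant row is replicated for each caller in its `callers` set,
#' with a small independent VAF jitter per caller.
#'
#' @param sim_variants Result of [simulate_variants()].
#' @param cfg A [sim_config()].
#' @return Named list (caller -> calls data frame).
#' @export
caller_callsets <- function(sim_variants, cfg = sim_config()) {
  v <- sim_variants$variants
  callers <- c("gatk_ug", "snver", "lofreq")
  out <- lapply(callers, function(cl) {
    has <- vapply(strsplit(v$callers, ",", fixed = TRUE),
                  function(s) cl %in% s, logical(1))
    df <- v[has, c("sample_id", "patient_id", "sample_role", "chrom",
                   "pos", "ref", "alt", "vaf", "depth", "alt_forward",
                   "alt_reverse"), drop = FALSE]
    if (nrow(df) > 0L) {
      df$vaf <- pmin(pmax(df$vaf + stats::rnorm(nrow(df), 0,
                                                cfg$vaf_jitter),
                          0.01), 0.999)
      df$callers <- cl
    } else {
      df$callers <- character(0)
    }
    rownames(df) <- NULL
    df
  })
  names(out) <- callers
  out
}

#' Simulate a complete labelled cohort
#'
#' Runs [simulate_patients()], [simulate_variants()] and
#' [simulate_survival()] under `cfg$seed` and returns all components.
#'
#' @param cfg A [sim_config()].
#' @return List with `patients` (including survival), `variants`,
#'   `annotations`, `truth`, `pon`, `samples` and `callsets`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  patients <- simulate_patients(cfg)
  sv <- simulate_variants(cfg, patients)
  patients <- simulate_survival(cfg, patients)
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 3L)
  callsets <- caller_callsets(sv, cfg)
  c(list(patients = patients, callsets = callsets), sv)
}

# ---- file export --------------------------------------------------------

write_minimal_vcf <- function(calls, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tmnseq_simulator",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    paste0("##INFO=<ID=ADF,Number=A,Type=Integer,Description=",
           "\"Alt forward reads\">"),
    paste0("##INFO=<ID=ADR,Number=A,Type=Integer,Description=",
           "\"Alt reverse reads\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls) > 0L) {
    calls <- calls[order(as.integer(calls$chrom), calls$pos, calls$alt), ,
                   drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f;ADF=%d;ADR=%d",
                    calls$chrom, calls$pos, calls$ref, calls$alt,
                    calls$depth, calls$vaf, calls$alt_forward,
                    calls$alt_reverse)
  }
  writeLines(c(hdr, body), con)
  invisible(path)
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", eol = "\n")
  invisible(path)
}

#' Write a simulated cohort to a directory of standard input files
#'
#' Produces per-sample, per-caller VCFs under `vcf/`, the annotation TSV,
#' germline and somatic panel files, panel-of-normals TSV, clinical TSV,
#' ground-truth TSV and a toy somatic evidence TSV — the complete input
#' set for [run_all()].
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  for (cl in names(sim$callsets)) {
    calls <- sim$callsets[[cl]]
    for (sid in sim$samples$sample_id) {
      write_minimal_vcf(calls[calls$sample_id == sid, , drop = FALSE],
                        file.path(dir, "vcf",
                                  paste0(sid, ".", cl, ".vcf")))
    }
  }
  write_tsv(sim$annotations, file.path(dir, "annotations.tsv"))
  g <- germline_gene_table()
  writeLines(paste(g$gene, g$lof_mechanism, sep = "\t"),
             file.path(dir, "germline_panel.txt"))
  writeLines(somatic_gene_table()$gene,
             file.path(dir, "somatic_panel.txt"))
  write_tsv(sim$pon, file.path(dir, "pon.tsv"))
  write_tsv(sim$patients, file.path(dir, "clinical.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  write_tsv(default_evidence_table(), file.path(dir, "evidence.tsv"))
  write_tsv(default_category_map(), file.path(dir, "category_map.tsv"))
  invisible(dir)
}
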