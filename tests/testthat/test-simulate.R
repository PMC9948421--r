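test_that("cohort generation is fully determined by the seed", {
  cfg <- sim_config(seed = 12)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$variants, b$variants)
  expect_identical(a$callsets, b$callsets)
  c2 <- simulate_cohort(sim_config(seed = 13))
  expect_false(identical(a$variants, c2$variants))
})

test_that("generated records satisfy the type invariants", {
  sim <- simulate_cohort(sim_config(seed = 4))
  p <- sim$patients
  expect_equal(nrow(p), 53L)
  expect_identical(p$pediatric, p$age_years < 20)
  expect_true(all(p$os_months >= 0))
  expect_true(all(p$therapy_duration_months >= 0))
  # not_assessed excludes every other cytogenetic flag
  na_rows <- p[p$not_assessed, ]
  if (nrow(na_rows) > 0) {
    expect_false(any(na_rows$del5q | na_rows$del7q | na_rows$complex |
                       na_rows$normal_karyotype))
  }
  v <- sim$variants
  expect_true(all(v$pos >= 1))
  expect_true(all(v$ref != v$alt))
  expect_true(all(v$alt_forward + v$alt_reverse <= v$depth))
  expect_true(all(v$vaf >= 0 & v$vaf <= 1))
  expect_true(all(nchar(v$callers) > 0))
  # every variant key is annotated
  expect_true(all(paste(v$chrom, v$pos, v$ref, v$alt) %in%
                    paste(sim$annotations$chrom, sim$annotations$pos,
                          sim$annotations$ref, sim$annotations$alt)))
  # empty cohort degenerates cleanly
  expect_equal(nrow(simulate_patients(sim_config(n_patients = 0,
                                                 n_pediatric = 0))), 0L)
})

test_that("configured prevalences are recovered over replicates", {
  # del7q prevalence among karyotyped patients over 120 replicates of
  # n=53 (not-assessed patients carry no cytogenetic flags)
  del7q_rate <- vapply(1:120, function(i) {
    p <- simulate_patients(sim_config(seed = 1000 + i))
    mean(p$del7q[!p$not_assessed])
  }, numeric(1))
  se <- sqrt(0.434 * (1 - 0.434) / (53 * 120))
  expect_lt(abs(mean(del7q_rate) - 0.434), 3 * se)
})

test_that("del5q/del7q co-occur at the configured odds ratio", {
  big <- simulate_patients(sim_config(n_patients = 20000, n_pediatric = 0,
                                      seed = 6,
                                      prevalences = list(not_assessed = 0)))
  tab <- table(big$del5q, big$del7q)
  or_hat <- tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  expect_lt(abs(log(or_hat) - log(6)), 0.2)
  # independence recovered at odds ratio 1
  expect_equal(tmnseq:::joint_prob_from_or(0.3, 0.4, 1), 0.12)
})

test_that("somatic counts have the configured pediatric/adult medians", {
  cfg <- sim_config(n_patients = 600, n_pediatric = 300,
                    n_matched_normals = 0, n_longitudinal = 0,
                    germline_carrier_rate = 0,
                    artifact_rates = list(strand_bias = 0,
                                          common_polymorphism = 0,
                                          singleton = 0),
                    seed = 9)
  pats <- simulate_patients(cfg)
  sv <- simulate_variants(cfg, pats)
  counts <- table(factor(sv$variants$patient_id,
                         levels = pats$patient_id))
  ped <- pats$pediatric[match(names(counts), pats$patient_id)]
  expect_equal(stats::median(counts[!ped]), 3)
  expect_equal(stats::median(counts[ped]), 2)
  expect_lte(max(counts), 7)
})

test_that("variant truth labels carry the structure the cascade expects", {
  sim <- simulate_cohort(sim_config(seed = 4))
  v <- sim$variants
  # artifact-free configuration injects no artifacts
  clean <- simulate_variants(
    sim_config(seed = 4, artifact_rates = list(strand_bias = 0,
                                               common_polymorphism = 0,
                                               singleton = 0)),
    simulate_patients(sim_config(seed = 4)))
  expect_false(any(grepl("artifact|polymorphism|singleton",
                         clean$variants$true_origin)))
  # strand-biased injections actually carry biased counts
  sb <- v[v$true_origin == "artifact_strand_bias", ]
  if (nrow(sb) > 0) {
    frac <- pmin(sb$alt_forward, sb$alt_reverse) /
      (sb$alt_forward + sb$alt_reverse)
    expect_true(all(frac <= 0.2))
  }
  # germline carriers sit in the heterozygous band and mirror to normals
  germ <- v[v$true_origin == "presumed_germline" &
              v$sample_role == "tmn_initial", ]
  if (nrow(germ) > 0) {
    nrm <- v[v$sample_role == "non_malignant", ]
    expect_true(all(paste(germ$patient_id, germ$pos) %in%
                      paste(nrm$patient_id, nrm$pos)))
  }
  # singleton noise is reported by exactly one caller
  singles <- v[v$true_origin == "singleton", ]
  expect_false(any(grepl(",", singles$callers)))
})

test_that("a simulated NMD-escape carrier classifies LP via PVS1_Strong", {
  # draw cohorts until a frameshift/no-NMD carrier appears, then classify
  found <- FALSE
  for (seed in 1:25) {
    sim <- simulate_cohort(sim_config(seed = seed))
    v <- sim$variants
    g <- v[grepl("germline|dual", v$true_origin) &
             v$sample_role == "tmn_initial", ]
    if (nrow(g) == 0) next
    ann <- sim$annotations
    key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt)
    for (i in seq_len(nrow(g))) {
      a <- ann[match(paste(g$chrom[i], g$pos[i], g$ref[i], g$alt[i]),
                     key), ]
      if (a$consequence %in% c("frameshift", "nonsense") &&
          identical(a$nmd_predicted, "no")) {
        res <- classify_germline_variant(c(as.list(a),
                                           list(lof_mechanism = TRUE)))
        expect_equal(res$verdict, "LP")
        expect_match(res$criteria_string, "PVS1_Strong")
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
})

test_that("survival generation honors censoring and null configurations", {
  cfg0 <- sim_config(seed = 5, censoring_fraction = 0)
  p0 <- simulate_survival(cfg0, simulate_patients(cfg0))
  expect_true(all(p0$death))
  cfg2 <- sim_config(n_patients = 2000, n_pediatric = 250, seed = 5)
  p2 <- simulate_survival(cfg2, simulate_patients(cfg2))
  expect_lt(abs(mean(!p2$death) - 0.2), 0.035)
  # exchangeable groups under all-unit hazard ratios: log-rank p uniform-ish
  cfg1 <- sim_config(n_patients = 400, n_pediatric = 50,
                     true_hazard_ratios = c(male = 1, radiotherapy = 1,
                                            long_therapy = 1,
                                            age_over_cut = 1, del5q = 1))
  ps <- vapply(1:20, function(i) {
    cfg1$seed <- 300 + i
    p <- simulate_survival(cfg1, simulate_patients(cfg1))
    m <- p$sex == "M"
    logrank_test(p$os_months[m], p$death[m],
                 p$os_months[!m], p$death[!m])$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
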