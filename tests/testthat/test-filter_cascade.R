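cfg <- cascade_config()

test_that("strand-bias rule fails 2:8-type imbalance and passes balance", {
  expect_false(strand_bias_filter(2, 8, cfg)$pass)
  expect_false(strand_bias_filter(8, 2, cfg)$pass)
  expect_true(strand_bias_filter(5, 5, cfg)$pass)
  # more extreme than 2:8 also fails under the min-fraction rule
  expect_false(strand_bias_filter(1, 9, cfg)$pass)
  # missing counts pass but are flagged unevaluated
  res <- strand_bias_filter(NA, NA, cfg)
  expect_true(res$pass)
  expect_equal(res$reason, "not_evaluated")
  expect_error(strand_bias_filter(-1, 5, cfg), "negative")
})

test_that("population-frequency filter flags common polymorphisms", {
  common <- make_av(ann = make_ann(freq_kova = 0.05))
  expect_false(population_frequency_filter(common, cfg)$pass)
  absent <- make_av(ann = make_ann(
    freq_gnomad_exome_all = NA, freq_gnomad_exome_eas = NA,
    freq_gnomad_genome_all = NA, freq_gnomad_genome_eas = NA,
    freq_kova = NA, freq_krgdb = NA))
  expect_true(population_frequency_filter(absent, cfg)$pass)
  rare <- make_av(ann = make_ann(freq_gnomad_exome_eas = 0.002))
  expect_true(population_frequency_filter(rare, cfg)$pass)
})

test_that("panel-of-normals filter is boundary-inclusive", {
  pon <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "T",
                    recurrence_fraction = 0.10)
  av <- make_av()
  expect_false(panel_of_normals_filter(av, pon, cfg)$pass)
  pon$recurrence_fraction <- 0.05
  expect_false(panel_of_normals_filter(av, pon, cfg)$pass)
  pon$pos <- 999L  # absent from PoN
  expect_true(panel_of_normals_filter(av, pon, cfg)$pass)
})

test_that("origin partition reproduces the canonical cases", {
  # germline variant confirmed in the matched normal
  av <- make_av(make_call(vaf = 0.50), in_germline_panel = TRUE,
                in_somatic_panel = FALSE)
  nrm <- make_call(sample_id = "p1-N", sample_role = "non_malignant",
                   vaf = 0.48)
  out <- partition_by_origin(av, nrm, empty_pon(), cfg)
  expect_equal(out$origin, "presumed_germline")

  # low-VAF somatic-panel variant, no matched normal
  av2 <- make_av(make_call(vaf = 0.12), in_somatic_panel = TRUE)
  out2 <- partition_by_origin(av2, empty_calls(), empty_pon(), cfg)
  expect_equal(out2$origin, "somatic")

  # gene on both panels, heterozygous band, no matched normal -> dual
  av3 <- make_av(make_call(vaf = 0.35), in_germline_panel = TRUE,
                 in_somatic_panel = TRUE)
  out3 <- partition_by_origin(av3, empty_calls(), empty_pon(), cfg)
  expect_equal(out3$origin, "dual")

  # heterozygous band but a matched normal exists without the variant:
  # germline is excluded, somatic candidacy remains
  out4 <- partition_by_origin(av3, make_call(sample_id = "p1-N",
                                             sample_role = "non_malignant",
                                             pos = 999L),
                              empty_pon(), cfg)
  expect_equal(out4$origin, "somatic")
})

test_that("cascade rejects artifacts and partitions completely", {
  res <- run_cascade(make_av()[0, ])
  expect_true(all(vapply(res, nrow, 0L) == 0L))

  biased <- make_av(make_call(pos = 10L, alt_forward = 2,
                              alt_reverse = 8))
  clean <- make_av(make_call(pos = 20L, vaf = 0.15, alt_forward = 8,
                             alt_reverse = 7))
  res <- run_cascade(rbind(biased, clean))
  expect_equal(nrow(res$rejected), 1L)
  expect_equal(res$rejected$pos, 10L)
  expect_equal(nrow(res$somatic), 1L)
  expect_equal(res$somatic$pos, 20L)
  expect_match(res$rejected$filter_trail, "strand_bias:fail")
  expect_match(res$somatic$filter_trail, "origin:somatic")

  # partition completeness: each input appears exactly once in `all`
  set.seed(42)
  n <- 60
  av <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_av(make_call(pos = i * 10L, vaf = stats::runif(1),
                      depth = sample(c(10, 100), 1),
                      alt_forward = sample(0:10, 1),
                      alt_reverse = sample(0:10, 1)),
            ann = make_ann(freq_kova = sample(c(0, 0.05), 1)),
            in_germline_panel = sample(c(TRUE, FALSE), 1),
            in_somatic_panel = sample(c(TRUE, FALSE), 1))
  }))
  res <- run_cascade(av)
  expect_equal(nrow(res$all), n)
  tallies <- table(res$all$origin)
  expect_equal(sum(tallies), n)
  # dual cross-listed in both downstream lists
  expect_equal(nrow(res$potential_germline),
               sum(res$all$origin %in% c("potential_germline", "dual")))
  expect_equal(nrow(res$somatic),
               sum(res$all$origin %in% c("somatic", "dual")))
})

test_that("cascade matches the per-variant brute-force oracle", {
  set.seed(99)
  pon <- data.frame(chrom = "1", pos = c(100L, 200L),
                    ref = "A", alt = "T",
                    recurrence_fraction = c(0.30, 0.02),
                    stringsAsFactors = FALSE)
  normals <- rbind(
    make_call(sample_id = "p2-N", patient_id = "p2",
              sample_role = "non_malignant", pos = 300L, vaf = 0.5),
    make_call(sample_id = "p2-N", patient_id = "p2",
              sample_role = "non_malignant", pos = 400L, vaf = 0.1))
  for (rep in 1:4) {
    av <- do.call(rbind, lapply(1:50, function(i) {
      make_av(make_call(patient_id = sample(c("p1", "p2"), 1),
                        pos = sample(c(100L, 200L, 300L, 400L,
                                       i * 1000L), 1),
                        vaf = round(stats::runif(1), 3),
                        depth = sample(c(15, 120), 1),
                        alt_forward = sample(0:12, 1),
                        alt_reverse = sample(0:12, 1)),
              ann = make_ann(freq_gnomad_exome_all =
                               sample(c(0, 0.002, 0.02), 1)),
              in_germline_panel = sample(c(TRUE, FALSE), 1),
              in_somatic_panel = sample(c(TRUE, FALSE), 1))
    }))
    av$patient_id <- as.character(av$patient_id)
    av$sample_id <- paste0(av$patient_id, "-A")
    res <- run_cascade(av, normals, pon, cfg)
    expected <- vapply(seq_len(nrow(av)), function(i) {
      oracle_origin(av[i, ], normals, pon, cfg)
    }, character(1))
    key <- paste(av$sample_id, av$chrom, av$pos, av$ref, av$alt, av$vaf,
                 av$alt_forward, av$alt_reverse)
    got_key <- paste(res$all$sample_id, res$all$chrom, res$all$pos,
                     res$all$ref, res$all$alt, res$all$vaf,
                     res$all$alt_forward, res$all$alt_reverse)
    got <- res$all$origin[match(key, got_key)]
    expect_equal(got, expected)
  }
})

test_that("tightening thresholds never adds variants to a kept list", {
  set.seed(7)
  av <- do.call(rbind, lapply(1:80, function(i) {
    make_av(make_call(pos = i * 10L, vaf = round(stats::runif(1), 3),
                      depth = sample(20:250, 1),
                      alt_forward = sample(0:15, 1),
                      alt_reverse = sample(0:15, 1)),
            ann = make_ann(freq_kova = sample(c(0, 0.005, 0.02), 1)),
            in_germline_panel = sample(c(TRUE, FALSE), 1),
            in_somatic_panel = TRUE)
  }))
  base <- run_cascade(av, cfg = cfg)
  tight <- cascade_config(min_depth = 50, min_vaf_somatic = 0.05,
                          strand_bias_min_fraction = 0.3,
                          common_maf_threshold = 0.005,
                          pon_recurrence_fraction = 0.02)
  res_t <- run_cascade(av, cfg = tight)
  for (lst in c("presumed_germline", "somatic")) {
    base_keys <- paste(base[[lst]]$chrom, base[[lst]]$pos)
    tight_keys <- paste(res_t[[lst]]$chrom, res_t[[lst]]$pos)
    expect_true(all(tight_keys %in% base_keys))
  }
  # output is a subset of input
  expect_true(nrow(base$all) == nrow(av))
})
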