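test_that("VCF records parse into per-allele calls with derived VAF", {
  path <- write_test_vcf(c(
    "17\t7578406\t.\tC\tT\t.\tPASS\tDP=164;ADF=45;ADR=45",
    "2\t25463289\t.\tG\tA\t.\tPASS\tDP=100;AF=0.12;ADF=6;ADR=6"))
  calls <- read_variant_calls(path, "tmn01-A", "gatk_ug")
  expect_equal(nrow(calls), 2L)
  # VAF derived as stranded alt sum / depth when AF absent
  expect_equal(calls$vaf[1], 90 / 164, tolerance = 1e-10)
  expect_equal(calls$depth[1], 164)
  # explicit AF takes precedence over the ratio
  expect_equal(calls$vaf[2], 0.12)
  expect_equal(calls$patient_id, c("tmn01", "tmn01"))
  expect_equal(calls$sample_role, c("tmn_initial", "tmn_initial"))
})

test_that("empty VCF body yields an empty call list", {
  path <- write_test_vcf(character(0))
  calls <- read_variant_calls(path, "s1", "snver")
  expect_equal(nrow(calls), 0L)
})

test_that("multi-allelic records split per ALT and partition alt counts", {
  path <- write_test_vcf(
    "1\t500\t.\tG\tA,T\t.\tPASS\tDP=200;AF=0.30,0.10;ADF=30,10;ADR=30,10")
  calls <- read_variant_calls(path, "s1", "snver")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$pos, c(500L, 500L))
  expect_setequal(calls$alt, c("A", "T"))
  # alt-count partition re-sums to the per-record totals
  expect_equal(sum(calls$alt_forward), 40)
  expect_equal(sum(calls$alt_reverse), 40)
})

test_that("missing strand information warns and leaves counts missing", {
  path <- write_test_vcf("1\t500\t.\tG\tA\t.\tPASS\tDP=100;AF=0.4")
  expect_warning(calls <- read_variant_calls(path, "s1", "lofreq"),
                 "strand")
  expect_true(is.na(calls$alt_forward))
})

test_that("indel representations are left-normalized before keying", {
  # same deletion written two ways
  n1 <- tmnseq:::normalize_variant(100L, "ACG", "A")
  n2 <- tmnseq:::normalize_variant(99L, "TACG", "TA")
  expect_equal(n1$pos, n2$pos)
  expect_equal(n1$ref, n2$ref)
  expect_equal(n1$alt, n2$alt)
})

test_that("consensus keeps variants seen by enough callers", {
  v <- make_call(pos = 100L)
  u <- make_call(pos = 200L)
  sets <- list(a = rbind(v, u), b = v, c = v)
  merged <- consensus_merge(sets, min_callers = 2)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$callers, "a,b,c")
  # singleton dropped at threshold 2, kept at threshold 1
  merged1 <- consensus_merge(sets, min_callers = 1)
  expect_equal(nrow(merged1), 2L)
  expect_error(consensus_merge(sets, min_callers = 4), "exceeds")
})

test_that("consensus VAF falls back to the across-caller median", {
  v1 <- make_call(vaf = 0.40)
  v2 <- make_call(vaf = 0.44)
  merged <- consensus_merge(list(a = v1, b = v2), min_callers = 2)
  expect_equal(merged$vaf, 0.42)
  # designated primary caller takes precedence
  merged_p <- consensus_merge(list(a = v1, b = v2), min_callers = 2,
                              primary_caller = "b")
  expect_equal(merged_p$vaf, 0.44)
})

test_that("consensus with min_callers=1 equals the deduplicated union", {
  set.seed(11)
  for (rep in 1:5) {
    mk <- function() {
      n <- sample(0:8, 1)
      if (n == 0) return(make_call()[0, ])
      make_call(pos = sample(1:12, n, replace = TRUE) * 10L,
                vaf = round(stats::runif(n), 3))
    }
    sets <- list(a = mk(), b = mk(), c = mk())
    merged <- consensus_merge(sets, min_callers = 1)
    union_keys <- unique(unlist(lapply(sets, function(s) {
      if (nrow(s)) paste(s$sample_id, s$chrom, s$pos, s$ref, s$alt) else
        character(0)
    })))
    got <- paste(merged$sample_id, merged$chrom, merged$pos, merged$ref,
                 merged$alt)
    expect_setequal(got, union_keys)
    expect_false(anyDuplicated(got) > 0)
  }
})

test_that("annotation table reads frequencies and missing cells", {
  path <- tempfile(fileext = ".tsv")
  hdr <- c("chrom", "pos", "ref", "alt", tmnseq:::annotation_columns)
  rows <- c(
    paste(c("17", "100", "C", "T", "BRIP1", "NM_032043.3", "c.1794+1G>A",
            ".", "canonical_splice", ".", "0.00000796", "0.000109", "0",
            "0", "0", "0", "LP", "2", "none", "FALSE", ".", ".", ".",
            "AR", "FALSE", ".", "."), collapse = "\t"),
    paste(c("2", "200", "G", "A", "NF1", "NM_000267.3", "c.1595T>G",
            "p.Leu532Arg", "missense", ".", "0", "0", "0", "0", "0", "0",
            "P", "1", "DM_high", "FALSE", "D", "D", "27.4", "AD", "TRUE",
            "532", "."), collapse = "\t"))
  writeLines(c(paste(hdr, collapse = "\t"), rows), path)
  ann <- read_annotation_table(path)
  expect_equal(ann$freq_gnomad_exome_all[1], 0.00000796)
  expect_equal(ann$freq_gnomad_exome_eas[1], 0.000109)
  # "0" cells are present and zero, not missing
  expect_identical(ann$freq_gnomad_exome_all[2], 0)
  # blank CADD is missing
  expect_true(is.na(ann$cadd_phred[1]))
  # duplicate keys rejected
  writeLines(c(paste(hdr, collapse = "\t"), rows[1], rows[1]), path)
  expect_error(read_annotation_table(path), "duplicate")
  # unknown consequence token rejected with the vocabulary listed
  bad <- sub("canonical_splice", "weird_token", rows[1])
  writeLines(c(paste(hdr, collapse = "\t"), bad), path)
  expect_error(read_annotation_table(path), "missense")
})

test_that("triage report round-trips and is byte-deterministic", {
  av <- rbind(make_av(make_call(pos = 300L)),
              make_av(make_call(pos = 100L)),
              make_av(make_call(patient_id = "p0", sample_id = "p0-A",
                                pos = 200L)))
  f1 <- tempfile(); f2 <- tempfile()
  write_triage_report(av, f1)
  write_triage_report(av, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_triage_report(f1)
  expect_equal(nrow(back), 3L)
  # deterministic (patient, chrom, pos, alt) order
  expect_equal(back$pos, c(200L, 100L, 300L))
  expect_equal(back$vaf, rep(0.4, 3))
  # empty input writes a header-only file
  f3 <- tempfile()
  write_triage_report(av[0, ], f3)
  expect_equal(nrow(read_triage_report(f3)), 0L)
})
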