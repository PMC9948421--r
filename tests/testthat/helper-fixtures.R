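# Shared fixtures built in code.

# minimal VCF writer for tests (independent of the package's writer)
write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"vaf\">",
    "##INFO=<ID=ADF,Number=A,Type=Integer,Description=\"fwd\">",
    "##INFO=<ID=ADR,Number=A,Type=Integer,Description=\"rev\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, lines), path)
  path
}

# a single annotation "bundle" as a one-row list with all fields present
make_ann <- function(...) {
  ann <- list(
    gene = "GENE1", transcript = "NM_000001.1", hgvs_c = "c.1A>G",
    hgvs_p = "p.Met1Val", consequence = "missense",
    nmd_predicted = NA_character_,
    freq_gnomad_exome_all = 0, freq_gnomad_exome_eas = 0,
    freq_gnomad_genome_all = 0, freq_gnomad_genome_eas = 0,
    freq_kova = 0, freq_krgdb = 0,
    clinvar_significance = NA_character_, clinvar_stars = NA_integer_,
    hgmd_class = "none", cosmic_present = FALSE,
    sift = NA_character_, polyphen2_hvar = NA_character_,
    cadd_phred = NA_real_, inheritance = "unknown",
    hotspot_domain = FALSE, protein_position = NA_integer_,
    domain_name = NA_character_)
  utils::modifyList(ann, list(...))
}

# calls data frame row(s) for cascade tests
make_call <- function(sample_id = "p1-A", patient_id = "p1",
                      sample_role = "tmn_initial", chrom = "1",
                      pos = 100L, ref = "A", alt = "T", vaf = 0.4,
                      depth = 100, alt_forward = 20, alt_reverse = 20,
                      callers = "a,b") {
  data.frame(sample_id = sample_id, patient_id = patient_id,
             sample_role = sample_role, chrom = chrom, pos = pos,
             ref = ref, alt = alt, vaf = vaf, depth = depth,
             alt_forward = alt_forward, alt_reverse = alt_reverse,
             callers = callers, stringsAsFactors = FALSE)
}

# annotated variant row: call + annotation + panel flags
make_av <- function(call = make_call(), ann = make_ann(),
                    in_germline_panel = FALSE, in_somatic_panel = TRUE,
                    lof_mechanism = TRUE) {
  av <- cbind(call, as.data.frame(ann, stringsAsFactors = FALSE))
  av$in_germline_panel <- in_germline_panel
  av$in_somatic_panel <- in_somatic_panel
  av$lof_mechanism <- lof_mechanism
  av$origin <- "unresolved"
  av$filter_trail <- ""
  av
}

# The seven deleterious germline variants reconstructed from their
# printed fields (consequence, NMD note, gnomAD frequencies, inheritance,
# ClinVar review stars, HGMD class), with the expected verdicts and
# criterion sets.
germline_worked_examples <- function() {
  list(
    list(id = "tmn01", gene = "BRIP1", inheritance = "AR",
         ann = make_ann(gene = "BRIP1", consequence = "canonical_splice",
                        hgvs_c = "c.1794+1G>A",
                        freq_gnomad_exome_all = 0.00000796,
                        freq_gnomad_exome_eas = 0.000109,
                        clinvar_significance = "LP", clinvar_stars = 2L,
                        inheritance = "AR"),
         verdict = "P", criteria = "PVS1 + PM2 + PP5"),
    list(id = "tmn12", gene = "NF1", inheritance = "AD",
         ann = make_ann(gene = "NF1", consequence = "missense",
                        hgvs_p = "p.Leu532Arg",
                        clinvar_significance = "P", clinvar_stars = 1L,
                        hgmd_class = "DM_high", sift = "D",
                        polyphen2_hvar = "D", cadd_phred = 27.4,
                        hotspot_domain = TRUE, inheritance = "AD"),
         verdict = "LP", criteria = "PM1 + PM2 + PP3 + PP5"),
    list(id = "tmn30", gene = "CEBPA", inheritance = "AD",
         ann = make_ann(gene = "CEBPA", consequence = "frameshift",
                        hgvs_p = "p.Gly268fs", nmd_predicted = "no",
                        inheritance = "AD"),
         verdict = "LP", criteria = "PVS1_Strong + PM2"),
    list(id = "tmn36", gene = "FANCM", inheritance = "AR",
         ann = make_ann(gene = "FANCM", consequence = "nonsense",
                        hgvs_p = "p.Arg658*", nmd_predicted = "yes",
                        freq_gnomad_exome_all = 0.0000757,
                        clinvar_significance =
                          "Conflicting interpretations of pathogenicity",
                        clinvar_stars = 1L, hgmd_class = "DM_high",
                        inheritance = "AR"),
         verdict = "P", criteria = "PVS1 + PM2 + PP5"),
    list(id = "tmn40", gene = "DDX41", inheritance = "AD",
         ann = make_ann(gene = "DDX41", consequence = "frameshift",
                        hgvs_p = "p.Glu103fs", nmd_predicted = "yes",
                        inheritance = "AD"),
         verdict = "LP", criteria = "PVS1 + PM2"),
    list(id = "tmn49", gene = "RUNX1", inheritance = "AD",
         ann = make_ann(gene = "RUNX1", consequence = "nonsense",
                        hgvs_p = "p.Tyr13*", nmd_predicted = "yes",
                        inheritance = "AD"),
         verdict = "LP", criteria = "PVS1 + PM2"),
    list(id = "tmn52", gene = "NBN", inheritance = "AR",
         ann = make_ann(gene = "NBN", consequence = "nonsense",
                        hgvs_p = "p.Glu736*", nmd_predicted = "no",
                        freq_gnomad_exome_all = 0.000004,
                        freq_gnomad_exome_eas = 0.0000544,
                        clinvar_significance = "US", clinvar_stars = 2L,
                        hgmd_class = "DM_low", inheritance = "AR"),
         verdict = "LP", criteria = "PVS1_Strong + PM2")
  )
}
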