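#' Read per-caller variant calls from a VCF file
#'
#' Parses one caller's VCF for one sample into a calls data frame, one row
#' per ALT allele (multi-allelic records are split). Depth, stranded
#' alternate counts and VAF are taken from the `DP`, `ADF`, `ADR` and `AF`
#' INFO fields; when no `AF` is present the VAF is computed as
#' `(ADF + ADR) / DP`.
#'
#' @param path Path to a VCF 4.x file (uncompressed or bgzipped).
#' @param sample_id Sample identifier to stamp on every record. Sample ids
#'   of the form `<patient>-A`, `<patient>-B`, `<patient>-N` are mapped to
#'   the roles initial T-MN, T-MN progression and non-malignant,
#'   respectively; any other id is treated as an initial T-MN sample of a
#'   patient with the same name.
#' @param caller Name of the variant caller that produced the file.
#' @return A data frame of variant calls with columns `sample_id`,
#'   `patient_id`, `sample_role`, `chrom`, `pos`, `ref`, `alt`, `vaf`,
#'   `depth`, `alt_forward`, `alt_reverse`, `callers`.
#' @export
read_variant_calls <- function(path, sample_id, caller) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0L) {
    return(empty_calls())
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  dp  <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "DP")))
  af  <- vcfR::extract.info(vcf, "AF")
  adf <- vcfR::extract.info(vcf, "ADF")
  adr <- vcfR::extract.info(vcf, "ADR")

  ids <- parse_sample_id(sample_id)
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    af_i  <- split_info_field(af[i], n_alt)
    adf_i <- split_info_field(adf[i], n_alt)
    adr_i <- split_info_field(adr[i], n_alt)
    if (is.na(dp[i])) {
      warning("record ", fix$CHROM[i], ":", fix$POS[i],
              " has no DP field; depth set missing", call. = FALSE)
    }
    if (all(is.na(adf_i)) || all(is.na(adr_i))) {
      warning("record ", fix$CHROM[i], ":", fix$POS[i],
              " lacks stranded alt counts (ADF/ADR); ",
              "strand-bias filter will not evaluate it", call. = FALSE)
    }
    vaf_i <- af_i
    no_af <- is.na(vaf_i)
    vaf_i[no_af] <- (adf_i[no_af] + adr_i[no_af]) / dp[i]
    norm <- normalize_variant(as.integer(fix$POS[i]),
                              rep(fix$REF[i], n_alt), alts)
    out[[i]] <- data.frame(
      sample_id = sample_id,
      patient_id = ids$patient_id,
      sample_role = ids$sample_role,
      chrom = fix$CHROM[i],
      pos = norm$pos,
      ref = norm$ref,
      alt = norm$alt,
      vaf = vaf_i,
      depth = dp[i],
      alt_forward = adf_i,
      alt_reverse = adr_i,
      callers = caller,
      stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  validate_calls(calls)
  calls
}

empty_calls <- function() {
  data.frame(sample_id = character(), patient_id = character(),
             sample_role = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             vaf = numeric(), depth = numeric(),
             alt_forward = numeric(), alt_reverse = numeric(),
             callers = character(), stringsAsFactors = FALSE)
}

split_info_field <- function(x, n_alt) {
  if (is.na(x)) return(rep(NA_real_, n_alt))
  vals <- suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
  if (length(vals) == 1L && n_alt > 1L) vals <- rep(vals / n_alt, n_alt)
  length(vals) <- n_alt
  vals
}

#' Parse a sample identifier into patient id and sample role
#'
#' @param sample_id Character vector of sample ids.
#' @return Data frame with `patient_id` and `sample_role`.
#' @export
parse_sample_id <- function(sample_id) {
  role <- rep("tmn_initial", length(sample_id))
  role[grepl("-B$", sample_id)] <- "tmn_progression"
  role[grepl("-N$", sample_id)] <- "non_malignant"
  patient <- sub("-(A|B|N)$", "", sample_id)
  data.frame(patient_id = patient, sample_role = role,
             stringsAsFactors = FALSE)
}

# Left-normalize indel representation: strip shared trailing then shared
# leading bases (keeping at least one), adjusting pos, so different callers
# key the same event identically.
normalize_variant <- function(pos, ref, alt) {
  pos <- rep_len(as.integer(pos), length(ref))
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trailing
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # leading
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(pos = pos, ref = ref, alt = alt)
}

validate_calls <- function(calls) {
  if (nrow(calls) == 0L) return(invisible(calls))
  stopifnot(all(calls$pos >= 1L), all(calls$ref != calls$alt))
  bad_vaf <- !is.na(calls$vaf) & (calls$vaf < 0 | calls$vaf > 1)
  if (any(bad_vaf)) stop("VAF outside [0,1] at row ", which(bad_vaf)[1])
  invisible(calls)
}

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Merge per-caller call sets into consensus calls
#'
#' A variant (same sample, chrom, pos, ref, alt) is kept when observed by at
#' least `min_callers` callers. VAF, depth and stranded counts are taken
#' from `primary_caller` when it observed the variant, otherwise the median
#' across observing callers.
#'
#' @param callsets Named list of calls data frames, one per caller.
#' @param min_callers Minimum number of callers that must report a variant.
#' @param primary_caller Optional caller whose per-variant measurements take
#'   precedence.
#' @return Consensus calls data frame; `callers` holds the comma-joined,
#'   sorted set of observing callers.
#' @export
consensus_merge <- function(callsets, min_callers = 2L, primary_caller = NULL) {
  stopifnot(min_callers >= 1L)
  if (min_callers > length(callsets)) {
    stop("min_callers (", min_callers, ") exceeds number of call sets (",
         length(callsets), ")")
  }
  if (is.null(names(callsets)) || anyDuplicated(names(callsets))) {
    stop("callsets must be a named list with distinct caller names")
  }
  all_calls <- do.call(rbind, lapply(names(callsets), function(cl) {
    df <- callsets[[cl]]
    if (nrow(df) > 0L) df$callers <- cl
    df
  }))
  if (is.null(all_calls) || nrow(all_calls) == 0L) return(empty_calls())
  key <- paste(all_calls$sample_id, variant_key(all_calls), sep = "|")
  groups <- split(seq_len(nrow(all_calls)), key)
  keep <- vapply(groups, function(idx) {
    length(unique(all_calls$callers[idx])) >= min_callers
  }, logical(1))
  groups <- groups[keep]
  if (length(groups) == 0L) return(empty_calls())
  rows <- lapply(groups, function(idx) {
    g <- all_calls[idx, , drop = FALSE]
    pick <- if (!is.null(primary_caller) && primary_caller %in% g$callers) {
      g[g$callers == primary_caller, , drop = FALSE][1, , drop = FALSE]
    } else {
      m <- g[1, , drop = FALSE]
      m$vaf <- stats::median(g$vaf, na.rm = TRUE)
      m$depth <- round(stats::median(g$depth, na.rm = TRUE))
      m$alt_forward <- round(stats::median(g$alt_forward, na.rm = TRUE))
      m$alt_reverse <- round(stats::median(g$alt_reverse, na.rm = TRUE))
      m
    }
    pick$callers <- paste(sort(unique(g$callers)), collapse = ",")
    pick
  })
  merged <- do.call(rbind, rows)
  merged <- merged[order(merged$sample_id, merged$chrom, merged$pos,
                         merged$alt), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

annotation_columns <- c(
  "gene", "transcript", "hgvs_c", "hgvs_p", "consequence", "nmd_predicted",
  "freq_gnomad_exome_all", "freq_gnomad_exome_eas",
  "freq_gnomad_genome_all", "freq_gnomad_genome_eas",
  "freq_kova", "freq_krgdb",
  "clinvar_significance", "clinvar_stars", "hgmd_class", "cosmic_present",
  "sift", "polyphen2_hvar", "cadd_phred", "inheritance", "hotspot_domain",
  "protein_position", "domain_name"
)

consequence_vocab <- c("missense", "nonsense", "frameshift",
                       "canonical_splice", "initiation_loss",
                       "inframe_indel", "synonymous", "other")

#' Read a variant annotation table
#'
#' Tab-delimited with a header row; empty cells or `.` mean missing. Rows
#' are keyed by (chrom, pos, ref, alt) and keys must be unique.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame keyed by `chrom`, `pos`, `ref`, `alt` with the
#'   annotation bundle columns (gene, transcript, HGVS, consequence, NMD
#'   prediction, the six population frequencies, ClinVar/HGMD status,
#'   in-silico predictors, inheritance mode, hotspot-domain flag).
#' @export
read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("", ".", "NA"))
  needed <- c("chrom", "pos", "ref", "alt", annotation_columns)
  missing_cols <- setdiff(needed, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  ann$chrom <- as.character(ann$chrom)
  bad <- !is.na(ann$consequence) & !(ann$consequence %in% consequence_vocab)
  if (any(bad)) {
    stop("unknown consequence token(s): ",
         paste(unique(ann$consequence[bad]), collapse = ", "),
         "; allowed: ", paste(consequence_vocab, collapse = ", "))
  }
  freq_cols <- grep("^freq_", annotation_columns, value = TRUE)
  for (fc in freq_cols) {
    v <- ann[[fc]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("frequency column ", fc, " outside [0,1]")
    }
  }
  if (any(!is.na(ann$clinvar_stars) & is.na(ann$clinvar_significance))) {
    stop("clinvar_stars present without clinvar_significance")
  }
  key <- variant_key(ann)
  if (anyDuplicated(key)) {
    stop("duplicate annotation keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  ann$cosmic_present <- as.logical(ann$cosmic_present)
  ann$hotspot_domain <- as.logical(ann$hotspot_domain)
  ann
}

#' Read a gene panel file
#'
#' One gene symbol per line; an optional second tab-separated column flags
#' whether loss of function is an established disease mechanism for that
#' gene (consumed by the PVS1 evaluator). Missing flag defaults to TRUE.
#'
#' @param path Path to the panel file.
#' @return Data frame with `gene` and `lof_mechanism`.
#' @export
read_gene_panel <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    gene = vapply(parts, `[`, character(1), 1L),
    lof_mechanism = vapply(parts, function(p) {
      if (length(p) < 2L) TRUE else as.logical(p[2L])
    }, logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Read a panel-of-normals variant list
#'
#' @param path TSV with columns chrom, pos, ref, alt, recurrence_fraction.
#' @return Data frame of PoN sites with recurrence fractions in [0,1].
#' @export
read_pon <- function(path) {
  pon <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "recurrence_fraction")
                %in% names(pon)))
  if (any(pon$recurrence_fraction < 0 | pon$recurrence_fraction > 1)) {
    stop("PoN recurrence fractions must be in [0,1]")
  }
  pon$chrom <- as.character(pon$chrom)
  pon
}

#' Join consensus calls to annotations and panel membership
#'
#' @param calls Consensus calls data frame.
#' @param annotation Annotation table from [read_annotation_table()].
#' @param germline_panel,somatic_panel Panel data frames from
#'   [read_gene_panel()].
#' @return Annotated-variant data frame with panel flags, the LOF-mechanism
#'   flag from the germline panel, `origin = "unresolved"` and an empty
#'   `filter_trail`.
#' @export
annotate_variants <- function(calls, annotation, germline_panel,
                              somatic_panel) {
  key_c <- variant_key(calls)
  key_a <- variant_key(annotation)
  idx <- match(key_c, key_a)
  if (anyNA(idx)) {
    stop("no annotation for variant(s): ",
         paste(utils::head(key_c[is.na(idx)], 5), collapse = ", "))
  }
  ann <- annotation[idx, annotation_columns, drop = FALSE]
  rownames(ann) <- NULL
  av <- cbind(calls, ann)
  av$in_germline_panel <- av$gene %in% germline_panel$gene
  av$in_somatic_panel <- av$gene %in% somatic_panel$gene
  av$lof_mechanism <- germline_panel$lof_mechanism[
    match(av$gene, germline_panel$gene)]
  av$lof_mechanism[is.na(av$lof_mechanism)] <- FALSE
  av$origin <- "unresolved"
  av$filter_trail <- ""
  av
}

#' Write a triage report
#'
#' One row per annotated variant with origin, filter trail and (when
#' present) classification columns, in deterministic
#' (patient, chrom, pos, alt) order. Writing the same input twice produces
#' byte-identical files.
#'
#' @param variants Annotated-variant data frame.
#' @param path Output TSV path.
#' @export
write_triage_report <- function(variants, path) {
  if (nrow(variants) > 0L) {
    ord <- order(variants$patient_id, variants$chrom, variants$pos,
                 variants$alt)
    variants <- variants[ord, , drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(variants, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", eol = "\n")
  invisible(path)
}

#' Read a triage report written by [write_triage_report()]
#' @param path TSV path.
#' @return Annotated-variant data frame.
#' @export
read_triage_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("", ".", "NA"))
}
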