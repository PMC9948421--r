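#' Configuration for a full pipeline run
#'
#' Collects input paths and every tunable threshold so that one object
#' (serializable to/from YAML) reproduces a run end to end.
#'
#' @param input_dir Directory laid out as written by [write_cohort()]:
#'   `vcf/<sample>.<caller>.vcf`, `annotations.tsv`,
#'   `germline_panel.txt`, `somatic_panel.txt`, `pon.tsv`,
#'   `clinical.tsv`, `evidence.tsv`, `category_map.tsv`.
#' @param out_dir Output directory.
#' @param cascade A [cascade_config()].
#' @param min_callers Consensus threshold for the caller merge.
#' @param age_cut,therapy_cut Survival dichotomization cut-points.
#' @param collinearity_threshold Absolute association at which a
#'   covariate is dropped before the multivariate Cox fit.
#' @param collinearity_anchor Covariate retained unconditionally in the
#'   screen.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir,
                       cascade = cascade_config(),
                       min_callers = 2L,
                       age_cut = 50, therapy_cut = 15.8,
                       collinearity_threshold = 0.7,
                       collinearity_anchor = "del5q",
                       seed = 1L) {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 cascade = cascade, min_callers = min_callers,
                 age_cut = age_cut, therapy_cut = therapy_cut,
                 collinearity_threshold = collinearity_threshold,
                 collinearity_anchor = collinearity_anchor,
                 seed = seed),
            class = "run_config")
}

#' Serialize / restore a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path YAML path.
#' @return `write_run_config` returns `path`; `read_run_config` a
#'   `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$cascade <- unclass(x$cascade)
  yaml::write_yaml(x, path)
  path
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cas <- do.call(cascade_config, x$cascade)
  x$cascade <- NULL
  do.call(run_config, c(x, list(cascade = cas)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline aborted at stage '", name, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full triage / classification / tiering / summary / survival
#' pipeline
#'
#' Stage order: consensus merge of per-caller VCFs; annotation and
#' filtering cascade (triage); ACMG/AMP germline classification;
#' AMP/ASCO/CAP tiering with reportable selection; cohort landscape and
#' gene-frequency summary; collinearity-screened multivariate Cox fit.
#' All outputs are written as TSV/JSON under `cfg$out_dir` together with
#' a manifest (input digests, thresholds, package version); a rerun with
#' identical inputs and config is byte-identical.
#'
#' @param cfg A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_all <- function(cfg) {
  ind <- cfg$input_dir
  outd <- cfg$out_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  req <- c("annotations.tsv", "germline_panel.txt", "somatic_panel.txt",
           "pon.tsv", "clinical.tsv", "evidence.tsv", "category_map.tsv")
  missing_in <- req[!file.exists(file.path(ind, req))]
  if (length(missing_in) > 0L || !dir.exists(file.path(ind, "vcf"))) {
    stop("pipeline aborted at stage 'triage': missing input(s): ",
         paste(c(missing_in,
                 if (!dir.exists(file.path(ind, "vcf"))) "vcf/"),
               collapse = ", "))
  }

  # stage 1: read + consensus
  consensus <- stage("consensus", {
    vcfs <- sort(list.files(file.path(ind, "vcf"), pattern = "\\.vcf$",
                            full.names = TRUE))
    meta <- do.call(rbind, lapply(vcfs, function(f) {
      parts <- strsplit(basename(f), ".", fixed = TRUE)[[1]]
      data.frame(file = f, sample_id = parts[1], caller = parts[2],
                 stringsAsFactors = FALSE)
    }))
    per_sample <- lapply(split(meta, meta$sample_id), function(m) {
      sets <- lapply(seq_len(nrow(m)), function(i) {
        read_variant_calls(m$file[i], m$sample_id[i], m$caller[i])
      })
      names(sets) <- m$caller
      consensus_merge(sets, min_callers = cfg$min_callers)
    })
    do.call(rbind, per_sample)
  })
  rownames(consensus) <- NULL

  # stage 2: triage cascade
  triage <- stage("triage", {
    ann <- read_annotation_table(file.path(ind, "annotations.tsv"))
    gp <- read_gene_panel(file.path(ind, "germline_panel.txt"))
    sp <- read_gene_panel(file.path(ind, "somatic_panel.txt"))
    pon <- read_pon(file.path(ind, "pon.tsv"))
    tumor <- consensus[consensus$sample_role != "non_malignant", ,
                       drop = FALSE]
    normals <- consensus[consensus$sample_role == "non_malignant", ,
                         drop = FALSE]
    av <- annotate_variants(tumor, ann, gp, sp)
    run_cascade(av, normals, pon, cfg$cascade)
  })
  write_triage_report(triage$all, file.path(outd, "triage.tsv"))

  # stage 3: germline classification
  germline <- stage("classify_germline", {
    cand <- triage$all[triage$all$origin %in%
                         c("presumed_germline", "potential_germline",
                           "dual"), , drop = FALSE]
    classify_germline_table(cand)
  })
  write_triage_report(germline, file.path(outd, "germline.tsv"))

  # stage 4: somatic tiering
  somatic <- stage("tier_somatic", {
    ev <- read_evidence_table(file.path(ind, "evidence.tsv"))
    tiered <- assign_tier(triage$somatic, ev, cfg$cascade)
    select_reportable(tiered)
  })
  write_triage_report(somatic, file.path(outd, "somatic.tsv"))

  # stage 5: cohort summary
  clinical <- utils::read.delim(file.path(ind, "clinical.tsv"),
                                stringsAsFactors = FALSE)
  summary_out <- stage("summarize", {
    roster <- unique(consensus[consensus$sample_role != "non_malignant",
                               c("sample_id", "patient_id")])
    landscape <- build_landscape(somatic, roster)
    cm <- utils::read.delim(file.path(ind, "category_map.tsv"),
                            stringsAsFactors = FALSE)
    cats <- suppressWarnings(
      categorize_genes(somatic, cm, sort(unique(clinical$patient_id))))
    list(landscape = landscape, categories = cats)
  })
  land <- summary_out$landscape
  write_tsv(data.frame(gene = land$genes,
                       patient_freq_pct = round(100 * land$patient_freq,
                                                1),
                       land$counts, check.names = FALSE),
            file.path(outd, "landscape.tsv"))
  write_tsv(data.frame(patient_id = rownames(summary_out$categories),
                       summary_out$categories * 1L, check.names = FALSE),
            file.path(outd, "categories.tsv"))

  # stage 6: survival
  surv_fit <- stage("survival", {
    tp53_pat <- unique(somatic$patient_id[somatic$gene == "TP53"])
    X <- cbind(
      male = as.integer(clinical$sex == "M"),
      radiotherapy = as.integer(clinical$radiotherapy),
      long_therapy = dichotomize(clinical$therapy_duration_months,
                                 cfg$therapy_cut),
      age_over_cut = dichotomize(clinical$age_years, cfg$age_cut),
      del5q = as.integer(clinical$del5q),
      del7q = as.integer(clinical$del7q),
      complex = as.integer(clinical$complex),
      tp53_somatic = as.integer(clinical$patient_id %in% tp53_pat))
    keep_cols <- colnames(X)[apply(X, 2, stats::var) > 0]
    X <- X[, keep_cols, drop = FALSE]
    anchor <- if (cfg$collinearity_anchor %in% colnames(X)) {
      cfg$collinearity_anchor
    } else NULL
    scr <- collinearity_screen(X, clinical$os_months, clinical$death,
                               threshold = cfg$collinearity_threshold,
                               anchor = anchor)
    fit <- cox_fit(clinical$os_months, clinical$death,
                   X[, scr$retained, drop = FALSE])
    list(fit = fit, screen = scr)
  })
  forest <- list(
    variables = surv_fit$fit$covariates,
    hazard_ratio = round(surv_fit$fit$hazard_ratios, 4),
    ci_lower = round(surv_fit$fit$ci_95[, "lower"], 4),
    ci_upper = round(surv_fit$fit$ci_95[, "upper"], 4),
    p_value = signif(surv_fit$fit$p_values, 6),
    dropped_collinear = surv_fit$screen$dropped)
  jsonlite::write_json(forest, file.path(outd, "survival.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # manifest
  inputs <- sort(c(file.path(ind, req),
                   list.files(file.path(ind, "vcf"), full.names = TRUE)))
  manifest <- list(
    pipeline = "tmnseq",
    version = as.character(utils::packageVersion("tmnseq")),
    seed = cfg$seed,
    stages = c("consensus", "triage", "classify_germline",
               "tier_somatic", "summarize", "survival"),
    thresholds = c(unclass(cfg$cascade),
                   list(min_callers = cfg$min_callers,
                        age_cut = cfg$age_cut,
                        therapy_cut = cfg$therapy_cut,
                        collinearity_threshold =
                          cfg$collinearity_threshold)),
    n_consensus_variants = nrow(consensus),
    n_somatic_reportable = nrow(somatic),
    n_deleterious_germline = sum(germline$deleterious),
    input_md5 = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                        basename(inputs))))
  jsonlite::write_json(manifest, file.path(outd, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
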