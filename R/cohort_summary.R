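#' Build the gene-by-sample mutation landscape matrix
#'
#' Entry (g, s) counts the distinct variants of gene g in sample s, so a
#' gene hit by several variants in one sample contributes each of them
#' (multi-hit counting); the per-sample variant count is the column sum.
#' Genes are ordered by descending number of mutated patients, ties broken
#' alphabetically.
#'
#' @param variants Somatic annotated-variant data frame (`sample_id`,
#'   `gene`, `chrom`, `pos`, `ref`, `alt`; a `patient_id` column is used
#'   for the patient-frequency ordering and defaults to the sample id).
#' @param samples Data frame with `sample_id` and `patient_id` covering
#'   every sample in scope (zero columns are kept for unmutated samples).
#' @return List of class `cohort_matrix` with `counts` (gene x sample
#'   integer matrix), `genes`, `samples` and `patient_freq` (fraction of
#'   patients with >=1 variant per gene, patient denominator).
#' @export
build_landscape <- function(variants, samples) {
  stopifnot(all(c("sample_id", "patient_id") %in% names(samples)))
  unknown <- setdiff(variants$sample_id, samples$sample_id)
  if (length(unknown) > 0L) {
    stop("variant(s) reference unknown sample(s): ",
         paste(unknown, collapse = ", "))
  }
  sample_ids <- samples$sample_id
  n_patients <- length(unique(samples$patient_id))
  if (nrow(variants) == 0L) {
    counts <- matrix(0L, nrow = 0L, ncol = length(sample_ids),
                     dimnames = list(character(0), sample_ids))
    return(structure(list(counts = counts, genes = character(0),
                          samples = sample_ids,
                          patient_freq = numeric(0)),
                     class = "cohort_matrix"))
  }
  # distinct variants per (gene, sample)
  uv <- unique(variants[, c("sample_id", "gene", "chrom", "pos", "ref",
                            "alt")])
  uv$patient_id <- samples$patient_id[match(uv$sample_id,
                                            samples$sample_id)]
  genes <- sort(unique(uv$gene))
  counts <- table(factor(uv$gene, levels = genes),
                  factor(uv$sample_id, levels = sample_ids))
  counts <- matrix(as.integer(counts), nrow = length(genes),
                   dimnames = list(genes, sample_ids))
  pat_per_gene <- vapply(genes, function(g) {
    length(unique(uv$patient_id[uv$gene == g]))
  }, integer(1))
  ord <- order(-pat_per_gene, genes)
  counts <- counts[ord, , drop = FALSE]
  structure(list(counts = counts, genes = genes[ord],
                 samples = sample_ids,
                 patient_freq = pat_per_gene[ord] / n_patients),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("cohort mutation landscape:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  if (nrow(x$counts) > 0L) {
    top <- utils::head(data.frame(gene = x$genes,
                                  patient_freq = round(x$patient_freq, 3)),
                       10L)
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Flag patients by functional gene category
#'
#' A patient is flagged for a category when at least one somatic variant
#' falls in a gene of that category. Genes absent from the category map
#' raise a warning and are grouped as "other".
#'
#' @param variants Somatic annotated-variant data frame with `patient_id`
#'   and `gene`.
#' @param category_map Data frame with `gene` and `category` (the seven
#'   functional groups: chromatin modification, transcription factor, RAS
#'   pathway, receptor/kinase, DNA repair/cell cycle, splicing factor,
#'   cohesin).
#' @param patients Character vector of all patient ids (rows of the
#'   result).
#' @return Logical patient x category matrix.
#' @export
categorize_genes <- function(variants, category_map, patients) {
  cat_of <- category_map$category[match(variants$gene, category_map$gene)]
  unmapped <- unique(variants$gene[is.na(cat_of)])
  if (length(unmapped) > 0L) {
    warning("gene(s) missing from category map, assigned 'other': ",
            paste(unmapped, collapse = ", "), call. = FALSE)
    cat_of[is.na(cat_of)] <- "other"
  }
  cats <- sort(unique(c(category_map$category, cat_of)))
  out <- matrix(FALSE, nrow = length(patients), ncol = length(cats),
                dimnames = list(patients, cats))
  if (nrow(variants) > 0L) {
    for (i in seq_along(cat_of)) {
      out[variants$patient_id[i], cat_of[i]] <- TRUE
    }
  }
  out
}

#' Pairwise phi correlation of binary features
#'
#' Phi is the Pearson correlation of 0/1 vectors; p-values come from the t
#' transform with n - 2 degrees of freedom. Zero-variance features yield
#' missing entries (off the diagonal).
#'
#' @param features Numeric/logical patient x feature matrix.
#' @return List with symmetric matrices `phi` and `p` (unit diagonal,
#'   diagonal p missing).
#' @export
pairwise_phi <- function(features) {
  features <- as.matrix(features) * 1
  n <- nrow(features)
  if (n < 3L) stop("need at least 3 patients")
  phi <- suppressWarnings(stats::cor(features))
  tstat <- phi * sqrt((n - 2) / (1 - phi^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.finite(p)] <- NA_real_
  diag(phi) <- 1
  diag(p) <- NA_real_
  list(phi = phi, p = p)
}

#' Chi-square test of association on a 2x2 table
#'
#' Standard Pearson chi-square, optionally with Yates' continuity
#' correction; the p-value is the 1-df upper tail.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param yates Apply Yates' continuity correction.
#' @return List with `statistic` and `p`.
#' @export
chi_square_association <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0), sum(tab) >= 1)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in 2x2 table")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Compare a continuous variable between two groups (Mann-Whitney)
#'
#' Exact two-sided p-value when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @return List with `U` and `p`.
#' @export
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0L, length(values_b) > 0L)
  n <- length(values_a) + length(values_b)
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- n <= 20L && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            exact = exact,
                                            correct = !exact))
  p <- unname(wt$p.value)
  # degenerate case: no variation between groups
  if (is.nan(p)) p <- 1
  list(U = unname(wt$statistic), p = min(p, 1))
}

#' Compare per-gene somatic variant frequencies across cohorts
#'
#' @param own Data frame with `gene` and `pct` for this cohort.
#' @param others Named list of data frames with `gene` and `pct`.
#' @param shared_genes Character vector of genes to compare; a gene absent
#'   from a table is treated as 0% with a message.
#' @return Data frame with one row per shared gene: each cohort's
#'   frequency, its descending rank within that cohort, and the difference
#'   of each other cohort from `own`; sorted by descending own frequency.
#' @export
compare_cohort_frequencies <- function(own, others, shared_genes) {
  get_pct <- function(tab, name) {
    pct <- tab$pct[match(shared_genes, tab$gene)]
    if (anyNA(pct)) {
      message("gene(s) absent from ", name, ", treated as 0%: ",
              paste(shared_genes[is.na(pct)], collapse = ", "))
      pct[is.na(pct)] <- 0
    }
    pct
  }
  out <- data.frame(gene = shared_genes,
                    own_pct = get_pct(own, "own"),
                    stringsAsFactors = FALSE)
  out$own_rank <- rank(-out$own_pct, ties.method = "min")
  for (nm in names(others)) {
    pct <- get_pct(others[[nm]], nm)
    out[[paste0(nm, "_pct")]] <- pct
    out[[paste0(nm, "_rank")]] <- rank(-pct, ties.method = "min")
    out[[paste0(nm, "_diff")]] <- pct - out$own_pct
  }
  out <- out[order(-out$own_pct, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
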