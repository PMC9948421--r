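#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative follow-up times.
#' @param events Logical/0-1 event indicators (TRUE = death).
#' @return List of class `km_fit` with the step table (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`) and the underlying
#'   [survival::survfit()] object.
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0)) stop("negative survival time")
  sf <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  tab <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv)
  structure(list(table = tab, survfit = sf), class = "km_fit")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step function with S(0) = 1.
#'
#' @param fit A `km_fit` from [km_estimate()].
#' @param t Times at which to evaluate S(t).
#' @return Numeric survival probabilities.
#' @export
km_surv <- function(fit, t) {
  tab <- fit$table[fit$table$n_event > 0, , drop = FALSE]
  if (nrow(tab) == 0L) return(rep(1, length(t)))
  f <- stats::stepfun(tab$time, c(1, tab$surv), right = FALSE)
  f(t)
}

#' Two-group log-rank test
#'
#' @param times_a,events_a Follow-up times and event indicators, group A.
#' @param times_b,events_b Follow-up times and event indicators, group B.
#' @return List with the 1-df `statistic` and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) > 0L, length(times_b) > 0L)
  if (sum(events_a) + sum(events_b) == 0) {
    stop("log-rank test undefined: no events in either group")
  }
  time <- c(times_a, times_b)
  event <- as.integer(c(events_a, events_b))
  group <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Screen covariates for multicollinearity before a multivariate Cox fit
#'
#' Greedy rule: features are ranked by univariate log-rank/Wald
#' significance (an optional `anchor` is forced to the top); walking down
#' the ranking, a feature is dropped when its absolute pairwise association
#' (phi for binary features, Pearson otherwise) with an already-retained
#' feature reaches `threshold`, and the retained feature is named as the
#' reason. Deterministic for a given input order (ranking ties broken by
#' column order).
#'
#' @param features Numeric patient x feature matrix or data frame.
#' @param times,events Survival outcome used for the univariate ranking.
#' @param threshold Absolute association at or above which a pair is
#'   considered collinear.
#' @param anchor Optional feature name retained unconditionally.
#' @return List with `retained` (character), `dropped` (data frame of
#'   `variable` and `reason`).
#' @export
collinearity_screen <- function(features, times, events, threshold = 0.7,
                                anchor = NULL) {
  X <- as.matrix(features) * 1
  nm <- colnames(X)
  if (is.null(nm)) stop("features must have column names")
  assoc <- suppressWarnings(stats::cor(X))
  assoc[is.na(assoc)] <- 0
  # univariate significance: Wald p from a single-covariate Cox fit
  up <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::var(X[, j]) == 0) return(1)
    fit <- tryCatch(
      survival::coxph(survival::Surv(times, as.integer(events)) ~ X[, j],
                      ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) 1 else summary(fit)$coefficients[1, "Pr(>|z|)"]
  }, numeric(1))
  ord <- order(up)
  if (!is.null(anchor)) {
    ai <- match(anchor, nm)
    if (is.na(ai)) stop("anchor not among features: ", anchor)
    ord <- c(ai, setdiff(ord, ai))
  }
  retained <- integer(0)
  dropped <- list()
  for (j in ord) {
    clash <- retained[abs(assoc[j, retained]) >= threshold]
    if (length(clash) > 0L) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        variable = nm[j],
        reason = sprintf("|assoc|=%.3f with %s",
                         abs(assoc[j, clash[1]]), nm[clash[1]]),
        stringsAsFactors = FALSE)
    } else {
      retained <- c(retained, j)
    }
  }
  list(retained = nm[sort(retained)],
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(variable = character(0), reason = character(0)))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron handling of tied event times
#' (configurable), Wald 95% confidence intervals and p-values.
#'
#' @param times,events Survival outcome.
#' @param covariates Numeric patient x covariate matrix or data frame with
#'   column names.
#' @param ties Tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return Object of class `tmn_cox_fit`: `covariates`, `coefficients`,
#'   `hazard_ratios`, `ci_95` (matrix with lower/upper), `p_values`,
#'   `log_likelihood` and the underlying `coxph` fit.
#' @export
cox_fit <- function(times, events, covariates, ties = "efron") {
  X <- as.matrix(covariates) * 1
  if (is.null(colnames(X))) stop("covariates must have column names")
  if (sum(events) < 1) stop("need at least one event")
  zv <- vapply(seq_len(ncol(X)), function(j) stats::var(X[, j]) == 0,
               logical(1))
  if (any(zv)) {
    stop("zero-variance covariate(s): ",
         paste(colnames(X)[zv], collapse = ", "))
  }
  df <- data.frame(.time = times, .event = as.integer(events), X,
                   check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        stop("Cox fit failed (monotone likelihood or non-convergence): ",
             conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- cbind(lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
              upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]))
  structure(list(
    covariates = colnames(X),
    coefficients = unname(co[, "coef"]),
    hazard_ratios = unname(exp(co[, "coef"])),
    ci_95 = ci,
    p_values = unname(co[, "Pr(>|z|)"]),
    log_likelihood = fit$loglik[2],
    coxph = fit
  ), class = "tmn_cox_fit")
}

#' @export
print.tmn_cox_fit <- function(x, ...) {
  tab <- data.frame(variable = x$covariates,
                    HR = round(x$hazard_ratios, 3),
                    ci_lower = round(x$ci_95[, "lower"], 3),
                    ci_upper = round(x$ci_95[, "upper"], 3),
                    p = signif(x$p_values, 3))
  cat("Cox proportional-hazards fit (Efron ties)\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Dichotomize a continuous variable at a configured cut-point
#'
#' Strictly-greater-than rule ("over 50 years" puts exactly 50 in the
#' lower group). Missing values propagate as NA with a message.
#'
#' @param x Numeric vector.
#' @param cut_point Cut-point.
#' @return Integer 0/1 vector (1 = above the cut-point).
#' @export
dichotomize <- function(x, cut_point) {
  if (anyNA(x)) message(sum(is.na(x)), " missing value(s) excluded")
  as.integer(x > cut_point)
}
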