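# Mobile-threshold univariate screening and cross-correlation pruning.
#
# The mobile threshold scans every admissible dichotomizing cut-point of a
# continuous covariate and keeps the one with the smallest test p-value —
# exhaustively, with no approximation. The selected p is reported raw (no
# correction for having scanned), matching the screening design; an optional
# permutation-adjusted p is available as an extension.

candidate_thresholds <- function(values) {
  v <- sort(unique(values))
  if (length(v) < 2L) degenerate_error("covariate has fewer than 2 distinct values")
  (v[-1] + v[-length(v)]) / 2
}

admissible <- function(values, thr, min_frac) {
  n <- length(values)
  n_hi <- sum(values > thr)
  n_lo <- n - n_hi
  n_lo >= min_frac * n && n_hi >= min_frac * n
}

binary_split_p <- function(values, thr, labels, test) {
  g <- as.numeric(values > thr)
  if (test == "pearson") {
    stats::cor.test(g, as.numeric(labels))$p.value
  } else {
    # Mann-Whitney between the dichotomized covariate and the outcome labels
    suppressWarnings(stats::wilcox.test(g[labels == 1], g[labels == 0],
                                        exact = FALSE)$p.value)
  }
}

#' Best dichotomizing threshold against a binary outcome
#'
#' Candidate thresholds are the midpoints of consecutive sorted distinct
#' covariate values; splits leaving either side below `min_frac * n` cases
#' are excluded. For each candidate the chosen test is run between the
#' dichotomized covariate and the labels, and the candidate with the lowest
#' p-value wins (ties break toward the smaller threshold).
#'
#' @param values Numeric covariate.
#' @param labels Binary outcome (0/1 or logical), same length.
#' @param test `"pearson"` (correlation test on the 0/1 codings; default) or
#'   `"mann_whitney"`.
#' @param min_frac Minimum fraction of cases on each side (default 0.10).
#' @param name Covariate name carried into the result.
#' @return Object of class `threshold_result`: `covariate`, `threshold`,
#'   `p_value`, `test`, `n_low`, `n_high`.
#' @export
best_threshold_binary <- function(values, labels,
                                  test = c("pearson", "mann_whitney"),
                                  min_frac = 0.10, name = "covariate") {
  test <- match.arg(test)
  keep <- stats::complete.cases(values, labels)
  values <- values[keep]; labels <- as.numeric(labels[keep])
  if (length(unique(labels)) < 2L)
    degenerate_error("all outcome labels identical")
  if (length(unique(values)) < 2L)
    degenerate_error("covariate is constant")
  cand <- candidate_thresholds(values)
  cand <- cand[vapply(cand, function(t) admissible(values, t, min_frac), logical(1))]
  if (!length(cand))
    degenerate_error("no admissible split satisfies the minimum group size")
  ps <- vapply(cand, function(t) binary_split_p(values, t, labels, test),
               numeric(1))
  best <- which(ps == min(ps, na.rm = TRUE))[1]  # cand ascending: tie -> smaller
  thr <- cand[best]
  structure(list(covariate = name, threshold = thr, p_value = ps[best],
                 test = test, n_low = sum(values <= thr),
                 n_high = sum(values > thr)),
            class = "threshold_result")
}

#' Best dichotomizing threshold against a survival outcome
#'
#' As [best_threshold_binary()] but the criterion is the two-group log-rank
#' test p-value between the populations split at each candidate threshold.
#'
#' @param values Numeric covariate.
#' @param times Follow-up times in months (> 0).
#' @param events Event indicators (1 = death/event, 0 = censored).
#' @param min_frac Minimum fraction of cases on each side.
#' @param name Covariate name.
#' @return A `threshold_result` with `test = "logrank"`.
#' @export
best_threshold_survival <- function(values, times, events, min_frac = 0.10,
                                    name = "covariate") {
  keep <- stats::complete.cases(values, times, events)
  values <- values[keep]; times <- times[keep]; events <- events[keep]
  if (sum(events) < 1) no_events_error("no events in the data")
  if (length(unique(values)) < 2L)
    degenerate_error("covariate is constant")
  cand <- candidate_thresholds(values)
  cand <- cand[vapply(cand, function(t) admissible(values, t, min_frac), logical(1))]
  if (!length(cand))
    degenerate_error("no admissible split satisfies the minimum group size")
  ps <- vapply(cand, function(t) {
    g <- values > t
    logrank_test(times[!g], events[!g], times[g], events[g])$p
  }, numeric(1))
  best <- which(ps == min(ps, na.rm = TRUE))[1]
  thr <- cand[best]
  structure(list(covariate = name, threshold = thr, p_value = ps[best],
                 test = "logrank", n_low = sum(values <= thr),
                 n_high = sum(values > thr)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s: threshold %.4g, %s p = %.4g (n %d/%d)\n",
              x$covariate, x$threshold, x$test, x$p_value, x$n_low, x$n_high))
  invisible(x)
}

#' Permutation-adjusted selection p-value for a mobile threshold
#'
#' The raw minimal p-value of a threshold scan is optimistic because the
#' threshold was selected to minimize it. This extension re-runs the scan on
#' `n_perm` outcome permutations and returns the fraction of permutations
#' achieving a minimal p at least as small — a selection-corrected p-value.
#' It is an add-on diagnostic, not part of the screening pipeline's default
#' reporting.
#'
#' @param values Numeric covariate.
#' @param labels Binary outcome.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @inheritParams best_threshold_binary
#' @return List: `p_raw` (selected minimal p), `p_adjusted`.
#' @export
threshold_permutation_p <- function(values, labels, n_perm = 200, seed = 1,
                                    test = "pearson", min_frac = 0.10) {
  obs <- best_threshold_binary(values, labels, test = test, min_frac = min_frac)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      bp <- try(best_threshold_binary(values, sample(labels), test = test,
                                      min_frac = min_frac), silent = TRUE)
      if (inherits(bp, "try-error")) FALSE else bp$p_value <= obs$p_value
    }, logical(1)))
  })
  list(p_raw = obs$p_value, p_adjusted = (hits + 1) / (n_perm + 1))
}

#' Two-group log-rank test
#'
#' Standard log-rank test (observed minus expected events over the pooled
#' distinct event times, hypergeometric variance), with the p-value from a
#' 1-df chi-square.
#'
#' @param times_a,events_a Times and event flags of group A.
#' @param times_b,events_b Times and event flags of group B.
#' @return List: `chi_square`, `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b))
    parameter_error("both groups must be nonempty")
  if (sum(events_a) + sum(events_b) < 1)
    no_events_error("no pooled events")
  grp <- c(rep(0L, length(times_a)), rep(1L, length(times_b)))
  sd <- tryCatch(
    survival::survdiff(survival::Surv(c(times_a, times_b),
                                      c(events_a, events_b)) ~ grp),
    error = function(e) NULL)
  # zero hypergeometric variance (e.g. all events tied at one time) carries
  # no information: statistic 0, p 1
  chi <- if (is.null(sd) || !is.finite(sd$chisq)) 0 else as.numeric(sd$chisq)
  list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator wrapped as a right-continuous step function with
#' S(0) = 1.
#'
#' @param times Follow-up times.
#' @param events Event flags.
#' @return Object of class `km_curve`: `time`, `surv`, `median` (first time
#'   the curve drops to <= 0.5, `NA` if it never does) and `fn`, the step
#'   function time -> survival probability.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) parameter_error("no observations")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  fn <- stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
  med <- unname(summary(sf)$table["median"])
  structure(list(time = sf$time, surv = sf$surv, median = med, fn = fn),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d time points, median %.3g\n",
              length(x$time), x$median))
  invisible(x)
}

#' Prune covariates into mutually uncorrelated groups
#'
#' Computes pairwise Pearson correlations (and test p-values) on complete
#' cases, connects covariate pairs with p < `alpha` ("correlated"), and
#' greedily enumerates maximal groups with no internal edge. Group seeds are
#' taken in `order_by` order (e.g. ascending univariate p); within a group,
#' remaining covariates are added in the same order when uncorrelated with
#' every member. Constant covariates are excluded with a warning.
#'
#' @param X Numeric matrix or data frame, cases x covariates.
#' @param alpha Correlation-test significance cut (default 0.05): pairs with
#'   p >= alpha are considered not cross-related.
#' @param order_by Optional numeric vector (one per covariate) used to order
#'   seeds ascending, typically the univariate screening p-values; default
#'   column order.
#' @return List: `groups` (list of character vectors), `r` and `p` (pairwise
#'   matrices), `dropped` (constant covariates).
#' @export
correlation_prune <- function(X, alpha = 0.05, order_by = NULL) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) parameter_error("need at least 2 covariates")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 4L) parameter_error("need at least 4 complete cases")
  sds <- vapply(X, stats::sd, numeric(1))
  dropped <- names(X)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning(sprintf("excluding constant covariates: %s",
                    paste(dropped, collapse = ", ")))
    if (!is.null(order_by)) order_by <- order_by[!(names(X) %in% dropped)]
    X <- X[, !(names(X) %in% dropped), drop = FALSE]
  }
  k <- ncol(X)
  nm <- names(X)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ct <- stats::cor.test(X[[i]], X[[j]])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  edge <- p < alpha
  diag(edge) <- FALSE
  ord <- if (is.null(order_by)) seq_len(k) else order(order_by, nm)
  groups <- list()
  for (s in ord) {
    grp <- s
    for (cnd in ord) {
      if (cnd %in% grp) next
      if (!any(edge[cnd, grp])) grp <- c(grp, cnd)
    }
    grp <- sort(grp)
    if (!any(vapply(groups, function(g) identical(g, grp), logical(1))))
      groups <- c(groups, list(grp))
  }
  list(groups = lapply(groups, function(g) nm[g]), r = r, p = p,
       dropped = dropped)
}
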