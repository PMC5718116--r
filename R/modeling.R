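# Multivariate models: logistic backward elimination for the binary
# response, elastic-net-regularised Cox selection plus stepwise refit for
# survival, and discrimination / calibration evaluation.

model_fit <- function(endpoint, covariates, coef_table, lr_stat, lr_p,
                      auc = NA_real_, auc_ci = c(NA_real_, NA_real_),
                      scores = NULL, flags = character(0), fit = NULL) {
  structure(list(endpoint = endpoint, covariates = covariates,
                 coefficients = coef_table, lr_stat = lr_stat, lr_p = lr_p,
                 auc = auc, auc_ci = auc_ci, scores = scores, flags = flags,
                 fit = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> endpoint %s: %d covariate(s) retained\n",
              x$endpoint, length(x$covariates)))
  if (nrow(x$coefficients)) print(round(x$coefficients, 4))
  cat(sprintf("LR test: stat %.3f, p %.4g; AUC %.4f (%.4f-%.4f)\n",
              x$lr_stat, x$lr_p, x$auc, x$auc_ci[1], x$auc_ci[2]))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

coef_table_glm <- function(fit) {
  s <- summary(fit)$coefficients
  colnames(s) <- c("estimate", "se", "z", "p")
  s
}

# Wald p per model term (one row per covariate for 1-df terms; multi-level
# factors use the drop1 likelihood-ratio p).
term_p_values <- function(fit, data, terms) {
  s <- summary(fit)$coefficients
  out <- vapply(terms, function(tm) {
    rows <- grep(paste0("^", tm), rownames(s))
    rows <- rows[rownames(s)[rows] != "(Intercept)"]
    if (length(rows) == 1L) s[rows, 4]
    else {
      d1 <- stats::drop1(fit, scope = stats::as.formula(paste("~", tm)),
                         test = "Chisq")
      d1[tm, "Pr(>Chi)"]
    }
  }, numeric(1))
  names(out) <- terms
  out
}

#' Logistic regression with backward elimination
#'
#' Fits the full maximum-likelihood logistic model, then repeatedly removes
#' the covariate with the largest Wald p-value above `alpha_stay` and refits
#' until every retained covariate has p <= `alpha_stay` (an intercept-only
#' model is allowed). Complete separation is detected and flagged, and a
#' small-ridge fit (via glmnet) is attached for reference.
#'
#' @param X Data frame of covariates (dichotomized factors or numerics).
#' @param y Binary response.
#' @param alpha_stay Stay threshold (default 0.05).
#' @return A `model_fit` with fitted probabilities as scores, ROC AUC with
#'   DeLong CI, and a model likelihood-ratio test against the null.
#' @export
logistic_backward <- function(X, y, alpha_stay = 0.05) {
  X <- as.data.frame(X)
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  if (!nrow(X)) data_error("no complete cases")
  if (length(unique(y)) < 2L) degenerate_error("response has a single class")

  flags <- character(0)
  terms <- names(X)
  dat <- cbind(X, .y = y)
  repeat {
    fml <- stats::as.formula(paste(".y ~",
      if (length(terms)) paste(terms, collapse = " + ") else "1"))
    warned <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (warned && !("separation" %in% flags)) flags <- c(flags, "separation")
    if (!length(terms)) break
    pv <- term_p_values(fit, dat, terms)
    worst <- which.max(pv)
    if (pv[worst] > alpha_stay) terms <- terms[-worst] else break
  }

  null_fit <- stats::glm(.y ~ 1, data = dat, family = stats::binomial())
  lr <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(null_fit)))
  lr_df <- length(stats::coef(fit)) - 1L
  lr_p <- if (lr_df > 0) stats::pchisq(lr, lr_df, lower.tail = FALSE) else 1
  scores <- stats::fitted(fit)
  roc <- if (length(terms)) roc_auc(scores, y) else
    list(auc = 0.5, ci_lo = NA_real_, ci_hi = NA_real_)

  ridge <- NULL
  if ("separation" %in% flags && length(terms)) {
    mm <- stats::model.matrix(fit)[, -1, drop = FALSE]
    if (ncol(mm) >= 1L) {
      rf <- glmnet::glmnet(cbind(mm, 0), y, family = "binomial", alpha = 0,
                           lambda = 1e-3)
      ridge <- as.numeric(stats::coef(rf))[seq_len(ncol(mm) + 1L)]
      names(ridge) <- c("(Intercept)", colnames(mm))
    }
  }

  out <- model_fit("response", terms, coef_table_glm(fit), lr, lr_p,
                   roc$auc, c(roc$ci_lo, roc$ci_hi), scores, flags, fit)
  out$ridge_coefficients <- ridge
  out
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron tie correction.
#' Zero-variance covariates are excluded with a warning; monotone likelihood
#' (a covariate perfectly ordering the events) is flagged.
#'
#' @param X Data frame or matrix of covariates.
#' @param times Follow-up times.
#' @param events Event flags.
#' @return A `model_fit` with linear predictors as scores and a
#'   likelihood-ratio test against the null model.
#' @export
cox_fit <- function(X, times, events) {
  X <- as.data.frame(X)
  keep <- stats::complete.cases(X) & !is.na(times) & !is.na(events)
  X <- X[keep, , drop = FALSE]
  times <- times[keep]; events <- events[keep]
  if (sum(events) < 1) no_events_error("no events")
  sds <- vapply(X, function(v) stats::sd(as.numeric(v)), numeric(1))
  if (any(sds == 0 | is.na(sds))) {
    warning(sprintf("excluding zero-variance covariates: %s",
                    paste(names(X)[sds == 0 | is.na(sds)], collapse = ", ")))
    X <- X[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  if (!ncol(X)) {
    return(model_fit("survival", character(0),
                     matrix(numeric(0), 0, 4,
                            dimnames = list(NULL, c("estimate", "se", "z", "p"))),
                     0, 1, scores = rep(0, length(times))))
  }
  dat <- cbind(X, .t = times, .e = events)
  fml <- stats::as.formula(paste("survival::Surv(.t, .e) ~",
                                 paste(names(X), collapse = " + ")))
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        flags <<- unique(c(flags, "monotone_likelihood"))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)$coefficients
  ct <- s[, c("coef", "se(coef)", "z", "Pr(>|z|)"), drop = FALSE]
  colnames(ct) <- c("estimate", "se", "z", "p")
  lr <- as.numeric(2 * (fit$loglik[2] - fit$loglik[1]))
  lr_p <- stats::pchisq(lr, df = length(stats::coef(fit)), lower.tail = FALSE)
  model_fit("survival", names(X), ct, lr, lr_p,
            scores = unname(stats::predict(fit, type = "lp")),
            flags = flags, fit = fit)
}

#' Elastic-net-regularised Cox path with cross-validated deviance
#'
#' Fits the penalized Cox coefficient path over a descending lambda grid and
#' k-fold cross-validates the partial-likelihood deviance. `lambda_min`
#' minimizes the mean CV deviance; `lambda_1se` is the largest (sparser)
#' lambda whose mean deviance is within one standard error of the minimum —
#' the conventional reading of the one-standard-deviation rule. Covariates
#' are standardized internally; coefficients are reported on the original
#' scale.
#'
#' @param X Numeric matrix of covariates (>= 2 columns).
#' @param times Follow-up times.
#' @param events Event flags; at least `n_folds` events required.
#' @param mixing Elastic-net mixing parameter in (0, 1] (default 0.5).
#' @param n_folds CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param nlambda Length of the lambda grid (default 100).
#' @return Object of class `penalized_path`: `lambda`, `cvm`, `cvsd`,
#'   `lambda_min`, `lambda_1se`, `beta` (covariates x lambda), `selected`
#'   (nonzero covariates at `lambda_1se`) and `seed`.
#' @export
cox_elasticnet_path <- function(X, times, events, mixing = 0.5, n_folds = 10L,
                                seed = 1L, nlambda = 100L) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) parameter_error("need at least 2 covariates")
  if (sum(events) < n_folds)
    parameter_error("fewer events than cross-validation folds")
  if (mixing <= 0 || mixing > 1) parameter_error("mixing must be in (0, 1]")
  y <- survival::Surv(times, events)
  foldid <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = nrow(X))))
  cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = mixing,
                          foldid = foldid, nlambda = nlambda,
                          type.measure = "deviance", standardize = TRUE)
  beta <- as.matrix(cv$glmnet.fit$beta)
  sel <- rownames(beta)[as.numeric(stats::coef(cv, s = "lambda.1se")) != 0]
  structure(list(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                 lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
                 beta = beta, selected = sel, mixing = mixing,
                 n_folds = n_folds, seed = seed, cv = cv),
            class = "penalized_path")
}

#' @export
print.penalized_path <- function(x, ...) {
  cat(sprintf(paste0("<penalized_path> mixing %.2f, %d lambdas; lambda_min ",
                     "%.4g, lambda_1se %.4g\nselected at 1se: %s\n"),
              x$mixing, length(x$lambda), x$lambda_min, x$lambda_1se,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Backward stepwise Cox on pre-selected covariates
#'
#' Backward elimination on Wald p-values, as in [logistic_backward()], for
#' the covariates retained by the elastic-net stage. An empty selection
#' yields the null model (LR statistic 0).
#'
#' @param X Data frame of pre-selected covariates (may be empty).
#' @param times,events Survival outcome.
#' @param alpha_stay Stay threshold (default 0.05).
#' @return A `model_fit`.
#' @export
cox_stepwise <- function(X, times, events, alpha_stay = 0.05) {
  X <- as.data.frame(X)
  terms <- names(X)
  repeat {
    fit <- cox_fit(X[, terms, drop = FALSE], times, events)
    if (!length(fit$covariates)) return(fit)
    pv <- fit$coefficients[, "p"]
    names(pv) <- fit$covariates
    worst <- which.max(pv)
    if (pv[worst] > alpha_stay) terms <- setdiff(terms, names(pv)[worst])
    else return(fit)
    if (!length(terms)) return(cox_fit(X[, character(0), drop = FALSE],
                                       times, events))
  }
}

#' ROC AUC with confidence interval
#'
#' AUC by the pair-counting (Mann-Whitney) identity, ties counted 1/2; the
#' orientation is not normalized, so an anti-predictive score can give
#' AUC < 0.5. The CI comes from DeLong's method (default) or a stratified
#' bootstrap.
#'
#' @param scores Numeric predictions.
#' @param labels Binary outcome.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @param n_boot Bootstrap resamples (default 2000).
#' @return List: `auc`, `ci_lo`, `ci_hi`.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    seed = 1L, n_boot = 2000L) {
  ci_method <- match.arg(ci_method)
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) class_error("both outcome classes must be present")
  rk <- rank(scores)
  auc <- (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (ci_method == "delong") {
    if (stats::var(scores) == 0) {
      ci <- c(NA_real_, NA_real_)
    } else {
      r <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                     quiet = TRUE)
      ci <- suppressWarnings(
        as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)])
    }
  } else {
    ab <- with_seed(seed, {
      i1 <- which(labels == 1); i0 <- which(labels == 0)
      vapply(seq_len(n_boot), function(b) {
        s1 <- scores[sample(i1, n1, replace = TRUE)]
        s0 <- scores[sample(i0, n0, replace = TRUE)]
        rkb <- rank(c(s1, s0))
        (sum(rkb[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
      }, numeric(1))
    })
    ci <- unname(stats::quantile(ab, c(0.025, 0.975)))
  }
  list(auc = auc, ci_lo = ci[1], ci_hi = ci[2])
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups cases by deciles (or `n_groups`-tiles) of predicted risk and
#' compares observed with expected events by a Pearson chi-square on
#' `n_groups - 2` degrees of freedom. Tied predictions that empty a group
#' cause groups to be merged, the df adjusted, and the result flagged;
#' constant predictions collapse to a single group and are flagged
#' degenerate (p is `NA`).
#'
#' @param pred Predicted event probabilities in (0, 1).
#' @param y Binary outcomes.
#' @param n_groups Number of risk groups (default 10).
#' @return List: `chi_square`, `p`, `df`, `n_groups_used`, `flags`.
#' @export
hosmer_lemeshow <- function(pred, y, n_groups = 10L) {
  y <- as.numeric(y)
  if (length(pred) < 2 * n_groups)
    parameter_error("need at least 2 cases per intended group")
  if (any(pred <= 0 | pred >= 1)) parameter_error("predictions must be in (0,1)")
  br <- unique(stats::quantile(pred, probs = seq(0, 1, length.out = n_groups + 1)))
  flags <- character(0)
  if (length(br) - 1L < n_groups) flags <- "groups_merged"
  if (length(br) < 3L) {
    return(list(chi_square = NA_real_, p = NA_real_, df = NA_integer_,
                n_groups_used = 1L, flags = c(flags, "degenerate")))
  }
  g <- cut(pred, breaks = br, include.lowest = TRUE)
  O <- tapply(y, g, sum)
  E <- tapply(pred, g, sum)
  n_g <- tapply(y, g, length)
  chi <- sum((O - E)^2 / (E * (1 - E / n_g)))
  used <- length(levels(g))
  df <- used - 2L
  list(chi_square = chi,
       p = if (df > 0) stats::pchisq(chi, df, lower.tail = FALSE) else NA_real_,
       df = df, n_groups_used = used, flags = flags)
}

#' Cox model calibration at fixed horizons
#'
#' Splits cases into risk groups by the linear predictor (ties broken by
#' case order so groups always form), and compares the mean model-predicted
#' survival at each horizon (Breslow baseline) with the Kaplan-Meier
#' estimate of the group.
#'
#' @param fit A `model_fit` from [cox_fit()]/[cox_stepwise()] (or a bare
#'   `coxph` fit).
#' @param times,events The outcome the model was fitted on.
#' @param horizons Horizons in months (default c(12, 24)).
#' @param n_risk_groups Number of risk groups (default 3).
#' @return Data frame with columns `horizon`, `group`, `n`, `predicted`,
#'   `observed`, `extrapolated`.
#' @export
cox_calibration <- function(fit, times, events, horizons = c(12, 24),
                            n_risk_groups = 3L) {
  cox <- if (inherits(fit, "model_fit")) fit$fit else fit
  n <- length(times)
  if (is.null(cox)) {
    lp <- rep(0, n)
    psurv <- function(h) {
      km <- km_estimate(times, events)
      rep(km$fn(h), n)
    }
  } else {
    lp <- as.numeric(stats::predict(cox, type = "lp"))
    sf <- survival::survfit(cox, newdata = stats::model.frame(cox)[, -1, drop = FALSE])
    psurv <- function(h) {
      sm <- summary(sf, times = h, extend = TRUE)
      as.numeric(sm$surv)
    }
  }
  grp <- cut(rank(lp, ties.method = "first"),
             breaks = stats::quantile(seq_len(n), probs = seq(0, 1, length.out = n_risk_groups + 1)),
             include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(horizons, function(h) {
    ps <- psurv(h)
    extrap <- h > max(times)
    do.call(rbind, lapply(sort(unique(grp)), function(g) {
      sel <- grp == g
      km <- km_estimate(times[sel], events[sel])
      data.frame(horizon = h, group = g, n = sum(sel),
                 predicted = mean(ps[sel]),
                 observed = km$fn(h),
                 extrapolated = extrap)
    }))
  }))
  rownames(out) <- NULL
  out
}
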