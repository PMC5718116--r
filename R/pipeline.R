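# End-to-end orchestration: screen -> prune -> model -> evaluate, with a
# reproducible report bundle (univariate tables, correlation matrices,
# uncorrelated groups, model summaries, calibration tables).

#' Pipeline configuration
#'
#' @param endpoints Endpoints to analyse: any of `"response"`, `"survival"`.
#' @param alpha Univariate significance cut and correlation-prune alpha.
#' @param min_frac Minimum per-side fraction for the mobile threshold.
#' @param test Binary-endpoint screening test (`"pearson"` or
#'   `"mann_whitney"`).
#' @param alpha_stay Backward-elimination stay threshold.
#' @param mixing Elastic-net mixing parameter.
#' @param n_folds Elastic-net CV folds.
#' @param seed Seed for every stochastic step (CV folds, bootstrap).
#' @param horizons Calibration horizons in months.
#' @param n_risk_groups Calibration risk groups.
#' @param make_plots Also write PNG plots into the output directory.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(endpoints = c("response", "survival"),
                            alpha = 0.05, min_frac = 0.10, test = "pearson",
                            alpha_stay = 0.05, mixing = 0.5, n_folds = 10L,
                            seed = 1L, horizons = c(12, 24),
                            n_risk_groups = 3L, make_plots = FALSE) {
  structure(list(endpoints = endpoints, alpha = alpha, min_frac = min_frac,
                 test = test, alpha_stay = alpha_stay, mixing = mixing,
                 n_folds = n_folds, seed = as.integer(seed),
                 horizons = horizons, n_risk_groups = n_risk_groups,
                 make_plots = make_plots),
            class = "run_config")
}

# Clinical covariates offered to screening, as numeric codings (ordered
# stages as integer scores, binary flags as 0/1).
clinical_covariate_matrix <- function(cohort) {
  data.frame(
    age = cohort$age,
    sex = as.numeric(cohort$sex == "M"),
    pvt = cohort$pvt,
    location = as.numeric(cohort$location),
    ajcc = cohort$ajcc,
    okuda = cohort$okuda,
    bclc = cohort$bclc,
    child = cohort$child,
    hepatitis = cohort$hepatitis,
    afp = cohort$afp,
    dose = cohort$dose,
    tumor_volume = cohort$tumor_volume)
}

covariate_matrix <- function(cohort) {
  fn <- intersect(feature_names(), names(cohort))
  cbind(clinical_covariate_matrix(cohort),
        as.data.frame(cohort)[, fn, drop = FALSE])
}

#' Univariate mobile-threshold screening of a cohort
#'
#' Runs the mobile-threshold scan for every clinical covariate and feature
#' against the chosen endpoint. Degenerate covariates (constant, or no
#' admissible split) are reported with `NA` p-values rather than dropped
#' silently.
#'
#' @param cohort A `cohort_table` (or data frame with the same columns).
#' @param endpoint `"response"` or `"survival"`.
#' @param alpha Significance cut recorded in the `significant` column.
#' @param min_frac Mobile-threshold minimum per-side fraction.
#' @param test Binary-endpoint test.
#' @return Data frame: covariate, threshold, p_value, n_low, n_high,
#'   significant.
#' @export
screen_cohort <- function(cohort, endpoint = c("response", "survival"),
                          alpha = 0.05, min_frac = 0.10, test = "pearson") {
  endpoint <- match.arg(endpoint)
  X <- covariate_matrix(cohort)
  if (endpoint == "response") {
    if (!"response" %in% names(cohort))
      data_error("stage screen/response: column \"response\" is missing")
    keep <- !is.na(cohort$response)
    out <- lapply(names(X), function(nm) {
      tr <- tryCatch(
        best_threshold_binary(X[[nm]][keep], cohort$response[keep],
                              test = test, min_frac = min_frac, name = nm),
        error = function(e) NULL)
      data.frame(covariate = nm,
                 threshold = if (is.null(tr)) NA_real_ else tr$threshold,
                 p_value = if (is.null(tr)) NA_real_ else tr$p_value,
                 n_low = if (is.null(tr)) NA_integer_ else tr$n_low,
                 n_high = if (is.null(tr)) NA_integer_ else tr$n_high)
    })
  } else {
    if (!all(c("time", "event") %in% names(cohort)))
      data_error("stage screen/survival: columns \"time\"/\"event\" missing")
    out <- lapply(names(X), function(nm) {
      tr <- tryCatch(
        best_threshold_survival(X[[nm]], cohort$time, cohort$event,
                                min_frac = min_frac, name = nm),
        error = function(e) NULL)
      data.frame(covariate = nm,
                 threshold = if (is.null(tr)) NA_real_ else tr$threshold,
                 p_value = if (is.null(tr)) NA_real_ else tr$p_value,
                 n_low = if (is.null(tr)) NA_integer_ else tr$n_low,
                 n_high = if (is.null(tr)) NA_integer_ else tr$n_high)
    })
  }
  res <- do.call(rbind, out)
  res$significant <- !is.na(res$p_value) & res$p_value <= alpha
  res
}

dichotomize <- function(X, thresholds) {
  out <- as.data.frame(lapply(names(thresholds), function(nm)
    factor(as.numeric(X[[nm]] > thresholds[[nm]]), levels = c(0, 1))))
  names(out) <- names(thresholds)
  out
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("stage %s: %s", stage, conditionMessage(e)),
                        class = c("pipeline_error", "hccradiomics_error")))
  })
}

#' Run the full radiomics outcome pipeline
#'
#' Orchestrates univariate mobile-threshold screening, cross-correlation
#' pruning, per-group logistic modelling of the binary response (thresholded
#' covariates as factors, backward elimination), elastic-net Cox selection
#' with stepwise refit for survival, and evaluation (ROC AUC with CI,
#' Hosmer-Lemeshow, survival calibration). Deterministic given `(cohort,
#' config)`.
#'
#' When `out_dir` is given the report bundle is written there: univariate
#' tables, correlation matrices, uncorrelated groups, model summaries
#' (JSON), calibration tables, an omitted-cases log, and a manifest with
#' the config echo and its hash.
#'
#' @param cohort A `cohort_table` or data frame with clinical covariates,
#'   features, `response` (optional), `time`, `event`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the report bundle.
#' @return Object of class `pipeline_result`; see Details.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  res <- list(config = config)
  X <- covariate_matrix(cohort)

  # omitted-case log: cases without all variables required per endpoint
  omitted <- data.frame(id = character(0), endpoint = character(0),
                        reason = character(0))
  if ("response" %in% config$endpoints && "response" %in% names(cohort)) {
    miss <- is.na(cohort$response)
    if (any(miss))
      omitted <- rbind(omitted, data.frame(
        id = cohort$id[miss], endpoint = "response",
        reason = "missing response"))
  }
  res$omitted_cases <- omitted

  if ("response" %in% config$endpoints) {
    scr <- pipeline_stage("screen/response",
      screen_cohort(cohort, "response", config$alpha, config$min_frac,
                    config$test))
    res$univariate_response <- scr
    sig <- scr[scr$significant, ]
    keep <- !is.na(cohort$response)
    res$models_response <- list()
    if (nrow(sig) >= 2) {
      pr <- pipeline_stage("prune/response",
        correlation_prune(X[keep, sig$covariate, drop = FALSE],
                          alpha = config$alpha, order_by = sig$p_value))
      res$correlation_response <- pr
      thr <- stats::setNames(sig$threshold, sig$covariate)
      res$models_response <- lapply(pr$groups, function(g) {
        Xd <- dichotomize(X[keep, , drop = FALSE], thr[g])
        fit <- pipeline_stage("model/response",
          logistic_backward(Xd, cohort$response[keep],
                            alpha_stay = config$alpha_stay))
        fit$hosmer_lemeshow <- if (length(fit$covariates))
          tryCatch(hosmer_lemeshow(pmin(pmax(fit$scores, 1e-8), 1 - 1e-8),
                                   cohort$response[keep][stats::complete.cases(Xd)]),
                   error = function(e) NULL)
        else NULL
        fit$group <- g
        fit
      })
    } else if (nrow(sig) == 1) {
      thr <- stats::setNames(sig$threshold, sig$covariate)
      Xd <- dichotomize(X[keep, , drop = FALSE], thr)
      fit <- pipeline_stage("model/response",
        logistic_backward(Xd, cohort$response[keep],
                          alpha_stay = config$alpha_stay))
      fit$group <- sig$covariate
      res$models_response <- list(fit)
    }
  }

  if ("survival" %in% config$endpoints) {
    scr_s <- pipeline_stage("screen/survival",
      screen_cohort(cohort, "survival", config$alpha, config$min_frac))
    res$univariate_survival <- scr_s
    sig_s <- scr_s[scr_s$significant, ]
    if (nrow(sig_s) >= 1) {
      if (nrow(sig_s) >= 2) {
        pr_s <- pipeline_stage("prune/survival",
          correlation_prune(X[, sig_s$covariate, drop = FALSE],
                            alpha = config$alpha, order_by = sig_s$p_value))
        res$correlation_survival <- pr_s
        Xs <- scale(as.matrix(X[, sig_s$covariate, drop = FALSE]))
        path <- pipeline_stage("model/survival",
          cox_elasticnet_path(Xs, cohort$time, cohort$event,
                              mixing = config$mixing,
                              n_folds = config$n_folds, seed = config$seed))
        res$elasticnet_path <- path
        selected <- path$selected
      } else {
        selected <- sig_s$covariate
      }
      Xsel <- X[, selected, drop = FALSE]
      fit_s <- pipeline_stage("model/survival",
        cox_stepwise(Xsel, cohort$time, cohort$event,
                     alpha_stay = config$alpha_stay))
      if (length(fit_s$covariates)) {
        keep_s <- stats::complete.cases(Xsel)
        ev <- cohort$event[keep_s]
        roc_s <- roc_auc(fit_s$scores, ev)
        fit_s$auc <- roc_s$auc; fit_s$auc_ci <- c(roc_s$ci_lo, roc_s$ci_hi)
        # horizon-restricted variant: vital status at 12 months among those
        # observable to 12 months
        obs12 <- cohort$time[keep_s] >= 12 | (ev == 1 & cohort$time[keep_s] < 12)
        dead12 <- as.numeric(ev == 1 & cohort$time[keep_s] <= 12)
        fit_s$auc_12mo <- if (length(unique(dead12[obs12])) == 2)
          roc_auc(fit_s$scores[obs12], dead12[obs12])$auc else NA_real_
        res$calibration_survival <- pipeline_stage("calibrate/survival",
          cox_calibration(fit_s, cohort$time[keep_s], ev,
                          horizons = config$horizons,
                          n_risk_groups = config$n_risk_groups))
      }
      res$model_survival <- fit_s
    }
    res$km_overall <- km_estimate(cohort$time, cohort$event)
  }

  res <- structure(res, class = "pipeline_result")
  if (!is.null(out_dir)) write_bundle(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$univariate_response))
    cat(sprintf("  response screening: %d covariates, %d significant\n",
                nrow(x$univariate_response),
                sum(x$univariate_response$significant)))
  if (!is.null(x$models_response))
    for (i in seq_along(x$models_response))
      cat(sprintf("  response model %d: %s (AUC %.4f)\n", i,
                  paste(x$models_response[[i]]$covariates, collapse = "+"),
                  x$models_response[[i]]$auc))
  if (!is.null(x$univariate_survival))
    cat(sprintf("  survival screening: %d covariates, %d significant\n",
                nrow(x$univariate_survival),
                sum(x$univariate_survival$significant)))
  if (!is.null(x$model_survival))
    cat(sprintf("  survival model: %s (AUC %.4f)\n",
                paste(x$model_survival$covariates, collapse = "+"),
                x$model_survival$auc))
  if (!is.null(x$km_overall))
    cat(sprintf("  median OS: %.2f months\n", x$km_overall$median))
  invisible(x)
}

model_summary_list <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(covariates = fit$covariates,
       coefficients = if (nrow(fit$coefficients))
         cbind(term = rownames(fit$coefficients),
               as.data.frame(fit$coefficients)) else NULL,
       lr_stat = fit$lr_stat, lr_p = fit$lr_p,
       auc = fit$auc, auc_ci = fit$auc_ci,
       auc_12mo = fit$auc_12mo,
       flags = fit$flags,
       hosmer_lemeshow = fit$hosmer_lemeshow[c("chi_square", "p", "df")])
}

write_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                           row.names = FALSE)
  wjson <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null")

  if (!is.null(res$univariate_response))
    wcsv(res$univariate_response, "univariate_response.csv")
  if (!is.null(res$univariate_survival))
    wcsv(res$univariate_survival, "univariate_survival.csv")
  if (!is.null(res$correlation_response)) {
    wcsv(as.data.frame(res$correlation_response$r), "correlation_response.csv")
    wjson(res$correlation_response$groups, "groups_response.json")
  }
  if (!is.null(res$correlation_survival)) {
    wcsv(as.data.frame(res$correlation_survival$r), "correlation_survival.csv")
    wjson(res$correlation_survival$groups, "groups_survival.json")
  }
  models <- list(
    response = lapply(res$models_response, model_summary_list),
    survival = model_summary_list(res$model_survival),
    elasticnet = if (!is.null(res$elasticnet_path)) list(
      lambda_min = res$elasticnet_path$lambda_min,
      lambda_1se = res$elasticnet_path$lambda_1se,
      selected = res$elasticnet_path$selected,
      mixing = res$elasticnet_path$mixing,
      seed = res$elasticnet_path$seed) else NULL)
  wjson(models, "models.json")
  if (!is.null(res$calibration_survival))
    wcsv(res$calibration_survival, "calibration_survival.csv")
  wcsv(res$omitted_cases, "omitted_cases.csv")

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(res$config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   artifacts = sort(list.files(out_dir)))
  wjson(manifest, "run_manifest.json")

  if (isTRUE(res$config$make_plots)) write_plots(res, out_dir)
  invisible(out_dir)
}

write_plots <- function(res, out_dir) {
  safe_png <- function(name, expr) {
    f <- file.path(out_dir, name)
    grDevices::png(f, width = 900, height = 700)
    on.exit(grDevices::dev.off())
    try(expr, silent = TRUE)
  }
  if (!is.null(res$correlation_survival))
    safe_png("correlation_survival.png", {
      r <- res$correlation_survival$r
      graphics::image(seq_len(nrow(r)), seq_len(ncol(r)), r, zlim = c(-1, 1),
                      xlab = "", ylab = "", axes = FALSE,
                      main = "Cross-correlation (survival covariates)")
      graphics::axis(1, seq_len(nrow(r)), rownames(r), las = 2, cex.axis = 0.6)
      graphics::axis(2, seq_len(ncol(r)), colnames(r), las = 2, cex.axis = 0.6)
    })
  if (!is.null(res$elasticnet_path))
    safe_png("deviance_path.png", {
      p <- res$elasticnet_path
      plot(log(p$lambda), p$cvm, type = "l",
           xlab = "log(lambda)", ylab = "partial-likelihood deviance",
           main = "Cross-validated deviance")
      graphics::arrows(log(p$lambda), p$cvm - p$cvsd, log(p$lambda),
                       p$cvm + p$cvsd, angle = 90, code = 3, length = 0.02,
                       col = "grey")
      graphics::abline(v = log(c(p$lambda_min, p$lambda_1se)), lty = 3)
    })
  if (!is.null(res$calibration_survival))
    safe_png("calibration_survival.png", {
      cal <- res$calibration_survival
      plot(cal$predicted, cal$observed, pch = as.integer(factor(cal$horizon)),
           xlim = 0:1, ylim = 0:1, xlab = "predicted survival",
           ylab = "observed (KM) survival", main = "Cox calibration")
      graphics::abline(0, 1, lty = 2)
    })
  if (!is.null(res$km_overall))
    safe_png("km_overall.png", {
      plot(res$km_overall$fn, do.points = FALSE, xlab = "months",
           ylab = "S(t)", main = "Overall survival")
    })
  invisible(NULL)
}
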