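# Synthetic lesion phantoms and cohort generator.
#
# The generator emulates the study conditions the pipeline is designed for:
# 138 patients with survival follow-up, a 106-patient subset with a binary
# local-control response, clinical covariate marginals matching the cohort
# demographics, planning-CT voxel geometry (0.8 x 0.8 x 3 mm), right-censored
# survival with a median OS near 10 months, and planted feature-outcome
# effects (a protective shape effect on survival, a texture effect on
# response) so selection behaviour is testable end to end.

#' Phantom specification for a synthetic lesion
#'
#' @param grid Integer length-3 grid shape (default 48 x 48 x 24).
#' @param spacing Voxel spacing in mm; default the planning-CT geometry
#'   c(0.8, 0.8, 3.0).
#' @param family Lesion shape family: `"ellipsoid"` or `"lobulated"`.
#' @param radii_mm Ellipsoid semi-axes in mm.
#' @param lobulation Radial perturbation amplitude in [0, 1); 0 gives an
#'   exact digitized ellipsoid. Larger values lower sphericity/compacity.
#' @param int_mean,int_sd Mean and SD of the interior intensity (arbitrary
#'   units emulating HU).
#' @param corr_len Spatial correlation length of the intensity field, in
#'   voxels (>= 0); larger values raise GLCM homogeneity.
#' @param skew Mixture skew parameter in [0, 1); shifts histogram skewness
#'   and energy.
#' @param seed RNG seed; recorded in the output metadata.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(48L, 48L, 24L), spacing = c(0.8, 0.8, 3.0),
                         family = c("ellipsoid", "lobulated"),
                         radii_mm = c(12, 12, 15), lobulation = 0.2,
                         int_mean = 60, int_sd = 12, corr_len = 1.5,
                         skew = 0, seed = 1L) {
  family <- match.arg(family)
  if (corr_len < 0) parameter_error("corr_len must be >= 0")
  if (lobulation < 0 || lobulation >= 1)
    parameter_error("lobulation must be in [0, 1)")
  structure(list(grid = as.integer(grid), spacing = as.numeric(spacing),
                 family = family, radii_mm = as.numeric(radii_mm),
                 lobulation = lobulation, int_mean = int_mean,
                 int_sd = int_sd, corr_len = corr_len, skew = skew,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

gaussian_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  R <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-R:R, sd = sigma)
  k <- k / sum(k)
  d <- dim(a)
  conv_axis <- function(x, ax) {
    out <- array(0, dim(x))
    wt <- array(0, dim(x))
    n <- dim(x)[ax]
    for (j in -R:R) {
      s <- max(1L, 1L - j); e <- min(n, n - j)
      if (s > e) next
      src <- (s:e) + j
      w <- k[j + R + 1L]
      if (ax == 1L) { out[s:e, , ] <- out[s:e, , , drop = FALSE] + w * x[src, , , drop = FALSE]
                      wt[s:e, , ] <- wt[s:e, , , drop = FALSE] + w }
      if (ax == 2L) { out[, s:e, ] <- out[, s:e, , drop = FALSE] + w * x[, src, , drop = FALSE]
                      wt[, s:e, ] <- wt[, s:e, , drop = FALSE] + w }
      if (ax == 3L) { out[, , s:e] <- out[, , s:e, drop = FALSE] + w * x[, , src, drop = FALSE]
                      wt[, , s:e] <- wt[, , s:e, drop = FALSE] + w }
    }
    out / wt
  }
  conv_axis(conv_axis(conv_axis(a, 1L), 2L), 3L)
}

#' Generate a synthetic lesion volume and mask
#'
#' The mask is a digitized (optionally radially perturbed) ellipsoid centred
#' in the grid; interior intensities come from a stationary correlated
#' Gaussian random field (smoothed white noise at the stated correlation
#' length) plus an optional skew component. Deterministic given the spec's
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (`voxel_volume`) and `mask` (`roi_mask`).
#' @export
generate_lesion <- function(spec = phantom_spec()) {
  g <- spec$grid; sp <- spec$spacing
  half_extent <- (g - 1) / 2 * sp
  if (any(spec$radii_mm > half_extent))
    geometry_error("lesion radii exceed the grid half-extent")
  with_seed(spec$seed, {
    cx <- (g + 1) / 2
    xs <- (seq_len(g[1]) - cx[1]) * sp[1]
    ys <- (seq_len(g[2]) - cx[2]) * sp[2]
    zs <- (seq_len(g[3]) - cx[3]) * sp[3]
    X <- array(rep(xs, times = g[2] * g[3]), g)
    Y <- array(rep(rep(ys, each = g[1]), times = g[3]), g)
    Z <- array(rep(zs, each = g[1] * g[2]), g)
    rad <- sqrt((X / spec$radii_mm[1])^2 + (Y / spec$radii_mm[2])^2 +
                  (Z / spec$radii_mm[3])^2)
    bound <- 1
    if (spec$family == "lobulated" && spec$lobulation > 0) {
      ph <- stats::runif(3, 0, 2 * pi)
      r3 <- sqrt(X^2 + Y^2 + Z^2); r3[r3 == 0] <- 1e-9
      theta <- acos(pmin(pmax(Z / r3, -1), 1))
      phi <- atan2(Y, X)
      pert <- 0.6 * cos(3 * theta + ph[1]) * cos(2 * phi + ph[2]) +
        0.4 * cos(4 * phi + ph[3])
      bound <- 1 + spec$lobulation * pert
    }
    mask <- rad <= bound
    if (!any(mask)) geometry_error("lesion mask is empty")
    w1 <- array(stats::rnorm(prod(g)), g)
    f <- gaussian_smooth3(w1, spec$corr_len)
    if (spec$skew > 0) {
      w2 <- gaussian_smooth3(array(stats::rnorm(prod(g)), g), spec$corr_len)
      f <- (1 - spec$skew) * f + spec$skew * (w2^2 - 1) / sqrt(2)
    }
    f <- (f - mean(f)) / stats::sd(f)
    data <- spec$int_mean + spec$int_sd * f
    list(volume = voxel_volume(data, sp), mask = roi_mask(mask))
  })
}

#' Outcome model specification for synthetic cohorts
#'
#' Defaults mirror the pipeline's target finding pattern: a protective shape
#' effect (compacity, log-HR -1.5 per SD) drives survival and a histogram
#' texture effect (energy, log-odds 1.0 per SD) drives the binary response.
#' The baseline exponential hazard 0.0606/month puts the marginal median OS
#' near 10 months under the default censoring (administrative cut-off at 28
#' months with uniform accrual over 22 months).
#'
#' @param response_intercept Log-odds intercept of the response model.
#' @param response_coef Named log-odds coefficients on standardized features.
#' @param surv_h0 Baseline exponential hazard, per month (> 0).
#' @param surv_shape Weibull shape (1 = exponential).
#' @param surv_coef Named log-HR coefficients on standardized features.
#' @param admin_cutoff Administrative censoring horizon, months.
#' @param accrual_span Uniform accrual span, months (follow-up is
#'   `admin_cutoff - U(0, accrual_span)`).
#' @param censor_rate Rate of additional independent exponential censoring
#'   (0 disables it).
#' @return An `outcome_model_spec` list.
#' @export
outcome_model_spec <- function(response_intercept = 0,
                               response_coef = c(energy_H = 1.0),
                               surv_h0 = 0.0606, surv_shape = 1,
                               surv_coef = c(compacity = -1.5),
                               admin_cutoff = 28, accrual_span = 22,
                               censor_rate = 0) {
  if (surv_h0 <= 0 || surv_shape <= 0)
    parameter_error("hazard parameters must be positive")
  structure(list(response_intercept = response_intercept,
                 response_coef = response_coef, surv_h0 = surv_h0,
                 surv_shape = surv_shape, surv_coef = surv_coef,
                 admin_cutoff = admin_cutoff, accrual_span = accrual_span,
                 censor_rate = censor_rate),
            class = "outcome_model_spec")
}

# Plausible reporting scales for the feature-level shortcut: the latent
# standardized value of each feature is mapped affinely onto these (mean, sd)
# pairs. Affine maps leave thresholds, correlations and model selection
# unchanged, so the scales are cosmetic.
feature_scale_table <- function() {
  m <- rbind(
    sphericity = c(0.85, 0.08), compacity = c(0.040, 0.010),
    skewness = c(1.0, 1.5), kurtosis = c(5, 2), entropy_H = c(4, 1),
    energy_H = c(0.12, 0.06),
    glcm_homogeneity = c(0.45, 0.10), glcm_energy = c(0.05, 0.03),
    glcm_contrast = c(30, 15), glcm_correlation = c(0.5, 0.15),
    glcm_entropy = c(6, 1), glcm_dissimilarity = c(4, 1.5),
    ngldm_contrast = c(0.10, 0.05), ngldm_coarseness = c(0.010, 0.005),
    SRE = c(0.95, 0.03), LRE = c(1.5, 0.4), LGRE = c(0.010, 0.008),
    HGRE = c(1500, 700), SRLGE = c(0.010, 0.008), SRHGE = c(1400, 650),
    LRLGE = c(0.020, 0.010), LRHGE = c(2400, 1100), GLNU_r = c(300, 200),
    RLNU = c(3000, 2000), RP = c(0.90, 0.05),
    SZE = c(0.7, 0.1), LZE = c(500, 400), LGZE = c(0.010, 0.008),
    HGZE = c(1500, 700), SZLGE = c(0.008, 0.006), SZHGE = c(1100, 500),
    LZLGE = c(0.05, 0.04), LZHGE = c(60000, 40000), GLNU_z = c(60, 40),
    ZLNU = c(400, 300), ZP = c(0.35, 0.15))
  colnames(m) <- c("mean", "sd")
  m[feature_names(), ]
}

# Feature cross-correlation: a weak global component plus stronger
# within-family blocks, giving the kind of heavily cross-related feature set
# the pruning stage exists for.
feature_sigma <- function(rho_global = 0.15, rho_family = 0.45) {
  fam <- c(rep("shape", 2), rep("hist", 4), rep("glcm", 6), rep("ngldm", 2),
           rep("glrlm", 11), rep("glzlm", 11))
  k <- length(fam)
  S <- matrix(rho_global, k, k)
  for (f in unique(fam)) {
    i <- which(fam == f)
    S[i, i] <- S[i, i] + rho_family
  }
  diag(S) <- 1
  dimnames(S) <- list(feature_names(), feature_names())
  S
}

# Cohort demographics: category probabilities for the clinical covariates.
clinical_marginals <- function() {
  list(sex = c(F = 26, M = 112) / 138,
       pvt = 74 / 138,
       location = c(right = 57, left = 10, bilateral = 71) / 138,
       ajcc = c(7, 9, 83, 39) / 138,
       okuda = c(31, 109) / 140,
       bclc = c(9, 29, 100) / 138,
       child = c(96, 42) / 138,
       hepatitis = 119 / 138,
       dose = c(`54` = 16, `60` = 114, `66` = 8) / 138)
}

#' Generate a synthetic patient cohort
#'
#' Draws clinical covariates approximating the cohort demographics, a
#' feature matrix from a cross-correlated multivariate normal (the
#' feature-level shortcut; see [generate_lesion()] for the voxel-level
#' route), a binary response from the logistic outcome model on a subset of
#' patients, and right-censored survival from the hazard model. All true
#' parameters and the seed are recorded in the `ground_truth` attribute.
#'
#' @param n_total Number of patients (default 138).
#' @param n_response_subset Patients with a non-missing response
#'   (default 106).
#' @param outcome An [outcome_model_spec()].
#' @param seed RNG seed.
#' @return A data frame of class `cohort_table` with id, clinical
#'   covariates, the features of [feature_names()], `response` (0/1 or NA),
#'   `time` (months) and `event`, and attribute `ground_truth`.
#' @export
generate_cohort <- function(n_total = 138L, n_response_subset = 106L,
                            outcome = outcome_model_spec(), seed = 1L) {
  n <- as.integer(n_total)
  if (n_response_subset > n)
    parameter_error("n_response_subset cannot exceed n_total")
  mg <- clinical_marginals()
  scl <- feature_scale_table()
  Sig <- feature_sigma()
  dat <- with_seed(seed, {
    cl <- data.frame(
      id = sprintf("P%03d", seq_len(n)),
      sex = factor(sample(c("F", "M"), n, TRUE, mg$sex), levels = c("F", "M")),
      age = pmin(pmax(round(stats::rnorm(n, 64, 11)), 30), 87),
      pvt = stats::rbinom(n, 1, mg$pvt),
      location = factor(sample(names(mg$location), n, TRUE, mg$location),
                        levels = names(mg$location)),
      ajcc = sample(1:4, n, TRUE, mg$ajcc),
      okuda = sample(1:2, n, TRUE, mg$okuda),
      bclc = sample(1:3, n, TRUE, mg$bclc),
      child = sample(1:2, n, TRUE, mg$child),
      hepatitis = stats::rbinom(n, 1, mg$hepatitis),
      afp = round(exp(stats::rnorm(n, 4.85, 3.0)), 1),
      dose = as.numeric(sample(names(mg$dose), n, TRUE, mg$dose)),
      tumor_volume = round(exp(stats::rnorm(n, log(3e5), 0.8))),
      stringsAsFactors = FALSE)
    Z <- MASS::mvrnorm(n, mu = rep(0, nrow(scl)), Sigma = Sig)
    colnames(Z) <- rownames(scl)
    feats <- sweep(sweep(Z, 2, scl[, "sd"], `*`), 2, scl[, "mean"], `+`)

    eta <- outcome$response_intercept
    for (nmc in names(outcome$response_coef))
      eta <- eta + outcome$response_coef[[nmc]] * Z[, nmc]
    response <- stats::rbinom(n, 1, stats::plogis(eta))
    miss <- sample.int(n, n - n_response_subset)
    response[miss] <- NA_integer_

    loghr <- rep(0, n)
    for (nmc in names(outcome$surv_coef))
      loghr <- loghr + outcome$surv_coef[[nmc]] * Z[, nmc]
    u <- stats::runif(n)
    # Weibull with scale from the cumulative hazard inverse
    t_event <- (-log(u) / (outcome$surv_h0 * exp(loghr)))^(1 / outcome$surv_shape)
    cens <- outcome$admin_cutoff - stats::runif(n) * outcome$accrual_span
    if (outcome$censor_rate > 0)
      cens <- pmin(cens, stats::rexp(n, outcome$censor_rate))
    time <- round(pmax(pmin(t_event, cens), 0.03), 2)
    event <- as.integer(t_event <= cens)
    cbind(cl, as.data.frame(feats),
          data.frame(response = response, time = time, event = event))
  })
  oc_truth <- unclass(outcome)
  # named lists survive JSON round trips; length-1 named vectors do not
  oc_truth$response_coef <- as.list(outcome$response_coef)
  oc_truth$surv_coef <- as.list(outcome$surv_coef)
  truth <- list(n_total = n, n_response_subset = as.integer(n_response_subset),
                seed = as.integer(seed), outcome = oc_truth,
                feature_scales = list(mean = scl[, "mean"], sd = scl[, "sd"]),
                sigma = list(rho_global = 0.15, rho_family = 0.45))
  attr(dat, "ground_truth") <- truth
  class(dat) <- c("cohort_table", "data.frame")
  dat
}

#' Write the ground-truth sidecar of a synthetic cohort
#'
#' Records the true coefficients, seeds and censoring parameters of a
#' [generate_cohort()] run as JSON — the oracle for parameter-recovery
#' tests.
#'
#' @param cohort A `cohort_table`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
emit_ground_truth <- function(cohort, path) {
  truth <- attr(cohort, "ground_truth")
  if (is.null(truth)) data_error("cohort carries no ground-truth attribute")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Regenerate a cohort from its ground-truth sidecar
#'
#' @param truth A ground-truth list or a path to the JSON written by
#'   [emit_ground_truth()].
#' @return The regenerated `cohort_table` (bit-identical to the original).
#' @export
regenerate_cohort <- function(truth) {
  if (is.character(truth)) truth <- jsonlite::read_json(truth, simplifyVector = TRUE)
  oc <- do.call(outcome_model_spec, truth$outcome[names(formals(outcome_model_spec))[
    names(formals(outcome_model_spec)) %in% names(truth$outcome)]])
  generate_cohort(truth$n_total, truth$n_response_subset, oc, truth$seed)
}
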