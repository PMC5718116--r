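# Feature formulas for every family, plus the one-call extractor.

#' Names of the radiomic features the extractor reports
#'
#' Shape (2), intensity histogram (4), GLCM (6), NGLDM (2), GLRLM (11) and
#' GLZLM (11) families.
#'
#' @return Character vector of feature names, in reporting order.
#' @export
feature_names <- function() {
  c("sphericity", "compacity",
    "skewness", "kurtosis", "entropy_H", "energy_H",
    "glcm_homogeneity", "glcm_energy", "glcm_contrast", "glcm_correlation",
    "glcm_entropy", "glcm_dissimilarity",
    "ngldm_contrast", "ngldm_coarseness",
    "SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
    "GLNU_r", "RLNU", "RP",
    "SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE", "LZLGE", "LZHGE",
    "GLNU_z", "ZLNU", "ZP")
}

log_b <- function(x, base) log(x) / log(base)

#' Intensity-histogram features
#'
#' Skewness `m3/sigma^3` and kurtosis `m4/sigma^4` use population moments of
#' the raw in-mask intensities (kurtosis of a normal is 3; set
#' `excess = TRUE` to subtract 3). Entropy `-sum p log p` (empty bins
#' excluded) and energy `sum p^2` use the `n_bins` equal-width histogram of
#' the in-mask range. A constant ROI yields undefined skewness/kurtosis,
#' entropy 0 and energy 1.
#'
#' @param volume A `voxel_volume`.
#' @param mask A `roi_mask`.
#' @param n_bins Histogram bin count (default 64).
#' @param log_base Entropy log base: 2 (default), `exp(1)`, or 10.
#' @param excess Report excess kurtosis instead of raw.
#' @return List: `skewness`, `kurtosis`, `entropy_H`, `energy_H`,
#'   `moments_valid`.
#' @export
histogram_features <- function(volume, mask, n_bins = 64L, log_base = 2,
                               excess = FALSE) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "roi_mask"))
  x <- volume$data[mask$mask]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 <= 0) {
    return(list(skewness = NA_real_, kurtosis = NA_real_, entropy_H = 0,
                energy_H = 1, moments_valid = FALSE))
  }
  skew <- mean((x - mu)^3) / m2^1.5
  kurt <- mean((x - mu)^4) / m2^2
  if (excess) kurt <- kurt - 3
  roi <- discretize(volume, mask, n_bins = n_bins, mode = "relative")
  p <- tabulate(roi$levels[mask$mask], nbins = n_bins) / roi$n_voxels
  pp <- p[p > 0]
  list(skewness = skew, kurtosis = kurt,
       entropy_H = -sum(pp * log_b(pp, log_base)),
       energy_H = sum(p^2),
       moments_valid = TRUE)
}

#' GLCM features
#'
#' Features of the pooled symmetric co-occurrence probability matrix:
#' homogeneity `sum p/(1+|i-j|)`, energy `sum p^2`, contrast
#' `sum (i-j)^2 p`, dissimilarity `sum |i-j| p`, entropy `-sum p log p`, and
#' correlation `sum (i-mu)(j-mu) p / sigma^2` with `mu`, `sigma` of the
#' marginal (undefined when the marginal variance is zero).
#'
#' @param roi A `discretized_roi`.
#' @param distance Offset magnitude in voxels.
#' @param directions Direction set; default [directions_13()].
#' @param log_base Entropy log base.
#' @return List of the six features plus `correlation_valid` and
#'   `matrix_empty`.
#' @export
glcm_features <- function(roi, distance = 1L, directions = directions_13(),
                          log_base = 2) {
  if (nrow(directions) == 0L) parameter_error("directions must be nonempty")
  g <- glcm_matrix(roi, distance, directions)
  if (g$n_pairs == 0) {
    return(list(homogeneity = NA_real_, energy = NA_real_, contrast = NA_real_,
                correlation = NA_real_, entropy = NA_real_,
                dissimilarity = NA_real_,
                correlation_valid = FALSE, matrix_empty = TRUE))
  }
  p <- g$p
  Ng <- nrow(p)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  adiff <- abs(i - j)
  px <- rowSums(p)                      # marginal (symmetric matrix)
  mu <- sum(seq_len(Ng) * px)
  s2 <- sum((seq_len(Ng) - mu)^2 * px)
  corr <- if (s2 > 0) sum((i - mu) * (j - mu) * p) / s2 else NA_real_
  pp <- p[p > 0]
  list(homogeneity = sum(p / (1 + adiff)),
       energy = sum(p^2),
       contrast = sum(adiff^2 * p),
       correlation = corr,
       entropy = -sum(pp * log_b(pp, log_base)),
       dissimilarity = sum(adiff * p),
       correlation_valid = s2 > 0,
       matrix_empty = FALSE)
}

# Shared Galloway-family formulas for a (level x length) count matrix.
rl_family <- function(M, n_norm, n_voxels, prefix = c("run", "zone")) {
  N <- sum(M)
  i <- matrix(seq_len(nrow(M)), nrow(M), ncol(M))
  l <- t(matrix(seq_len(ncol(M)), ncol(M), nrow(M)))
  list(
    short = sum(M / l^2) / N,
    long = sum(M * l^2) / N,
    low = sum(M / i^2) / N,
    high = sum(M * i^2) / N,
    short_low = sum(M / (i^2 * l^2)) / N,
    short_high = sum(M * i^2 / l^2) / N,
    long_low = sum(M * l^2 / i^2) / N,
    long_high = sum(M * i^2 * l^2) / N,
    glnu = sum(rowSums(M)^2) / N,
    lnu = sum(colSums(M)^2) / N,
    pct = N / n_norm
  )
}

#' GLRLM features
#'
#' The 11 run-length features of the pooled (all-direction) matrix. Run
#' percentage is `Nr / (Nv * D)` with `D` the number of pooled directions,
#' keeping it in (0, 1].
#'
#' @inheritParams glcm_features
#' @return Named list: `SRE`, `LRE`, `LGRE`, `HGRE`, `SRLGE`, `SRHGE`,
#'   `LRLGE`, `LRHGE`, `GLNU_r`, `RLNU`, `RP`.
#' @export
glrlm_features <- function(roi, directions = directions_13()) {
  g <- glrlm_matrix(roi, directions)
  f <- rl_family(g$r, g$n_voxels * g$n_directions, g$n_voxels)
  list(SRE = f$short, LRE = f$long, LGRE = f$low, HGRE = f$high,
       SRLGE = f$short_low, SRHGE = f$short_high, LRLGE = f$long_low,
       LRHGE = f$long_high, GLNU_r = f$glnu, RLNU = f$lnu, RP = f$pct)
}

#' GLZLM features
#'
#' The 11 zone-length (size-zone) features; the run-length formulas with
#' connected-component zone size replacing run length, and
#' `ZP = Nz / Nv`.
#'
#' @param roi A `discretized_roi`.
#' @param connectivity Zone connectivity, 26 (default) or 6.
#' @return Named list: `SZE`, `LZE`, `LGZE`, `HGZE`, `SZLGE`, `SZHGE`,
#'   `LZLGE`, `LZHGE`, `GLNU_z`, `ZLNU`, `ZP`.
#' @export
glzlm_features <- function(roi, connectivity = 26L) {
  g <- glzlm_matrix(roi, connectivity)
  f <- rl_family(g$z, g$n_voxels, g$n_voxels)
  list(SZE = f$short, LZE = f$long, LGZE = f$low, HGZE = f$high,
       SZLGE = f$short_low, SZHGE = f$short_high, LZLGE = f$long_low,
       LZHGE = f$long_high, GLNU_z = f$glnu, ZLNU = f$lnu, ZP = f$pct)
}

#' NGLDM coarseness and contrast
#'
#' Amadasun-King neighbourhood grey-level difference statistics over the
#' 26-neighbourhood: with `s_i` the per-level sums of |level - neighbourhood
#' mean| and `p_i` the level occupancy fractions, coarseness is
#' `1/(eps + sum p_i s_i)` and contrast is
#' `[sum_ij p_i p_j (i-j)^2 / (Ngp (Ngp-1))] * [(1/n) sum s_i]`. A single
#' occupied level gives contrast 0 and coarseness saturated at `1/eps`.
#'
#' @param roi A `discretized_roi`.
#' @param epsilon Saturation guard for coarseness (default 1e-6).
#' @return List: `contrast`, `coarseness`, `saturated`, `matrix_empty`.
#' @export
ngldm_features <- function(roi, epsilon = 1e-6) {
  st <- ngldm_stats(roi)
  if (st$n == 0L) {
    return(list(contrast = NA_real_, coarseness = NA_real_,
                saturated = FALSE, matrix_empty = TRUE))
  }
  occ <- which(st$n_i > 0L)
  Ngp <- length(occ)
  p <- st$n_i / st$n
  if (Ngp <= 1L) {
    return(list(contrast = 0, coarseness = 1 / epsilon,
                saturated = TRUE, matrix_empty = FALSE))
  }
  pij <- outer(p[occ], p[occ])
  dij2 <- outer(occ, occ, function(a, b) (a - b)^2)
  contrast <- sum(pij * dij2) / (Ngp * (Ngp - 1)) * sum(st$s) / st$n
  coarse <- 1 / (epsilon + sum(p * st$s))
  list(contrast = contrast, coarseness = coarse,
       saturated = FALSE, matrix_empty = FALSE)
}

#' Default feature-extraction configuration
#'
#' @param n_bins Grey levels for discretization and the histogram (default 64).
#' @param mode Discretization mode, `"relative"` or `"absolute"`.
#' @param bounds Absolute-mode bounds.
#' @param distance GLCM offset magnitude in voxels.
#' @param connectivity GLZLM zone connectivity (26 or 6).
#' @param log_base Entropy log base.
#' @param epsilon NGLDM coarseness saturation guard.
#' @param excess_kurtosis Report excess instead of raw kurtosis.
#' @return A named list of settings for [extract_features()].
#' @export
extract_config <- function(n_bins = 64L, mode = "relative", bounds = NULL,
                           distance = 1L, connectivity = 26L, log_base = 2,
                           epsilon = 1e-6, excess_kurtosis = FALSE) {
  list(n_bins = n_bins, mode = mode, bounds = bounds, distance = distance,
       connectivity = connectivity, log_base = log_base, epsilon = epsilon,
       excess_kurtosis = excess_kurtosis)
}

#' Extract the full radiomic feature vector
#'
#' Computes every feature of [feature_names()] from a volume/mask pair,
#' deterministically. Features that are undefined on the input (constant
#' intensity, degenerate surface, empty matrices) are reported as `NA` with
#' `valid = FALSE`; nothing is silently dropped.
#'
#' @param volume A `voxel_volume`.
#' @param mask A congruent `roi_mask`.
#' @param config Settings from [extract_config()].
#' @return Object of class `feature_vector`: named numeric `values`, named
#'   logical `valid`, and `meta` (config echo plus degeneracy flags).
#' @export
extract_features <- function(volume, mask, config = extract_config()) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$data), dim(mask$mask)))
    geometry_error("volume and mask grids differ")

  sh <- shape_features(mask, volume$spacing)
  hs <- histogram_features(volume, mask, n_bins = config$n_bins,
                           log_base = config$log_base,
                           excess = config$excess_kurtosis)
  roi <- discretize(volume, mask, n_bins = config$n_bins,
                    mode = config$mode, bounds = config$bounds)
  gl <- glcm_features(roi, distance = config$distance,
                      log_base = config$log_base)
  ng <- ngldm_features(roi, epsilon = config$epsilon)
  rl <- glrlm_features(roi)
  zl <- glzlm_features(roi, connectivity = config$connectivity)

  values <- c(
    sphericity = sh$sphericity, compacity = sh$compacity,
    skewness = hs$skewness, kurtosis = hs$kurtosis,
    entropy_H = hs$entropy_H, energy_H = hs$energy_H,
    glcm_homogeneity = gl$homogeneity, glcm_energy = gl$energy,
    glcm_contrast = gl$contrast, glcm_correlation = gl$correlation,
    glcm_entropy = gl$entropy, glcm_dissimilarity = gl$dissimilarity,
    ngldm_contrast = ng$contrast, ngldm_coarseness = ng$coarseness,
    unlist(rl), unlist(zl)
  )
  values <- values[feature_names()]
  valid <- !is.na(values)
  valid[c("sphericity", "compacity")] <- sh$valid
  valid[c("skewness", "kurtosis")] <- hs$moments_valid
  valid["glcm_correlation"] <- isTRUE(gl$correlation_valid)
  valid["ngldm_coarseness"] <- !isTRUE(ng$saturated) && !isTRUE(ng$matrix_empty)

  structure(list(values = values, valid = valid,
                 meta = c(config, list(
                   degenerate_intensity = roi$degenerate,
                   glcm_empty = isTRUE(gl$matrix_empty),
                   ngldm_saturated = isTRUE(ng$saturated),
                   volume_mm3 = sh$volume_mm3, surface_mm2 = sh$surface_mm2))),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d features (%d valid)\n",
              length(x$values), sum(x$valid)))
  print(utils::head(round(x$values, 4), 12))
  invisible(x)
}

#' @export
as.data.frame.feature_vector <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- as.data.frame(as.list(x$values))
  vv <- as.list(x$valid)
  names(vv) <- paste0(names(x$valid), "_valid")
  cbind(df, as.data.frame(vv))
}
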