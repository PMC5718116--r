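# Independent brute-force oracles. These deliberately use naive explicit
# loops (voxel-pair enumeration, lattice-line walking, stack flood fill,
# per-voxel neighbourhood averaging) so they share no code path with the
# vectorized implementations they check.

all_offsets_26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(g != 0) > 0, , drop = FALSE]
}

make_random_roi <- function(dims, n_levels, seed, p_mask = 0.85) {
  set.seed(seed)
  lv <- array(0L, dims)
  inm <- array(runif(prod(dims)) < p_mask, dims)
  if (!any(inm)) inm[1] <- TRUE
  lv[inm] <- sample.int(n_levels, sum(inm), replace = TRUE)
  structure(list(levels = lv, n_levels = as.integer(n_levels),
                 bin_edges = seq(0.5, n_levels + 0.5), degenerate = FALSE,
                 n_voxels = sum(inm)),
            class = "discretized_roi")
}

inb <- function(p, d) all(p >= 1) && all(p <= d)

# --- GLCM: enumerate every ordered voxel pair at every +/- offset ---------
oracle_glcm_matrix <- function(roi, distance = 1L, directions) {
  L <- roi$levels; d <- dim(L); Ng <- roi$n_levels
  # both orientations of each direction = symmetrization
  offs <- rbind(directions, -directions) * as.integer(distance)
  counts <- matrix(0, Ng, Ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (L[x, y, z] == 0L) next
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (!inb(q, d)) next
      lq <- L[q[1], q[2], q[3]]
      if (lq == 0L) next
      counts[L[x, y, z], lq] <- counts[L[x, y, z], lq] + 1
    }
  }
  list(p = counts / sum(counts), counts = counts, n_pairs = sum(counts))
}

oracle_glcm_features <- function(roi, distance = 1L,
                                 directions = directions_13(), log_base = 2) {
  p <- oracle_glcm_matrix(roi, distance, directions)$p
  Ng <- nrow(p)
  hom <- en <- con <- dis <- ent <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    if (p[i, j] > 0) {
      hom <- hom + p[i, j] / (1 + abs(i - j))
      en <- en + p[i, j]^2
      con <- con + (i - j)^2 * p[i, j]
      dis <- dis + abs(i - j) * p[i, j]
      ent <- ent - p[i, j] * log(p[i, j], base = log_base)
    }
  }
  px <- rowSums(p)
  mu <- sum((1:Ng) * px)
  s2 <- sum(((1:Ng) - mu)^2 * px)
  corr <- if (s2 > 0) {
    acc <- 0
    for (i in 1:Ng) for (j in 1:Ng) acc <- acc + (i - mu) * (j - mu) * p[i, j]
    acc / s2
  } else NA_real_
  list(homogeneity = hom, energy = en, contrast = con, correlation = corr,
       entropy = ent, dissimilarity = dis)
}

# --- GLRLM: walk every lattice line in every direction --------------------
oracle_glrlm_runs <- function(roi, directions) {
  L <- roi$levels; d <- dim(L)
  run_lev <- integer(0); run_len <- integer(0)
  for (r in seq_len(nrow(directions))) {
    dd <- directions[r, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      p <- c(x, y, z)
      if (inb(p - dd, d)) next   # not a line start
      seqlev <- integer(0)
      while (inb(p, d)) {
        seqlev <- c(seqlev, L[p[1], p[2], p[3]])
        p <- p + dd
      }
      i <- 1
      while (i <= length(seqlev)) {
        if (seqlev[i] == 0L) { i <- i + 1; next }
        j <- i
        while (j < length(seqlev) && seqlev[j + 1] == seqlev[i]) j <- j + 1
        run_lev <- c(run_lev, seqlev[i]); run_len <- c(run_len, j - i + 1L)
        i <- j + 1
      }
    }
  }
  list(level = run_lev, length = run_len)
}

oracle_rl_features <- function(level, len, Ng, n_norm) {
  N <- length(level)
  f <- list(short = 0, long = 0, low = 0, high = 0, short_low = 0,
            short_high = 0, long_low = 0, long_high = 0)
  for (k in seq_len(N)) {
    i <- level[k]; l <- len[k]
    f$short <- f$short + 1 / l^2
    f$long <- f$long + l^2
    f$low <- f$low + 1 / i^2
    f$high <- f$high + i^2
    f$short_low <- f$short_low + 1 / (i^2 * l^2)
    f$short_high <- f$short_high + i^2 / l^2
    f$long_low <- f$long_low + l^2 / i^2
    f$long_high <- f$long_high + i^2 * l^2
  }
  f <- lapply(f, function(v) v / N)
  by_lev <- tapply(rep(1, N), factor(level, levels = 1:Ng), sum)
  by_len <- tapply(rep(1, N), factor(len, levels = 1:max(len)), sum)
  f$glnu <- sum(by_lev[!is.na(by_lev)]^2) / N
  f$lnu <- sum(by_len[!is.na(by_len)]^2) / N
  f$pct <- N / n_norm
  f
}

oracle_glrlm_features <- function(roi, directions = directions_13()) {
  runs <- oracle_glrlm_runs(roi, directions)
  f <- oracle_rl_features(runs$level, runs$length, roi$n_levels,
                          roi$n_voxels * nrow(directions))
  list(SRE = f$short, LRE = f$long, LGRE = f$low, HGRE = f$high,
       SRLGE = f$short_low, SRHGE = f$short_high, LRLGE = f$long_low,
       LRHGE = f$long_high, GLNU_r = f$glnu, RLNU = f$lnu, RP = f$pct)
}

# --- GLZLM: stack-based flood fill per level ------------------------------
oracle_zones <- function(roi, connectivity = 26L) {
  L <- roi$levels; d <- dim(L)
  offs <- all_offsets_26()
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  seen <- array(FALSE, d)
  zlev <- integer(0); zsize <- integer(0)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (L[x, y, z] == 0L || seen[x, y, z]) next
    lv <- L[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (!inb(q, d)) next
        if (!seen[q[1], q[2], q[3]] && L[q[1], q[2], q[3]] == lv) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    zlev <- c(zlev, lv); zsize <- c(zsize, size)
  }
  list(level = zlev, size = zsize)
}

oracle_glzlm_features <- function(roi, connectivity = 26L) {
  zt <- oracle_zones(roi, connectivity)
  f <- oracle_rl_features(zt$level, zt$size, roi$n_levels, roi$n_voxels)
  list(SZE = f$short, LZE = f$long, LGZE = f$low, HGZE = f$high,
       SZLGE = f$short_low, SZHGE = f$short_high, LZLGE = f$long_low,
       LZHGE = f$long_high, GLNU_z = f$glnu, ZLNU = f$lnu, ZP = f$pct)
}

# --- NGLDM: per-voxel neighbourhood means ---------------------------------
oracle_ngldm_features <- function(roi, epsilon = 1e-6) {
  L <- roi$levels; d <- dim(L); Ng <- roi$n_levels
  offs <- all_offsets_26()
  s <- numeric(Ng); n_i <- integer(Ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (L[x, y, z] == 0L) next
    nb <- integer(0)
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (inb(q, d) && L[q[1], q[2], q[3]] > 0L)
        nb <- c(nb, L[q[1], q[2], q[3]])
    }
    if (!length(nb)) next
    i <- L[x, y, z]
    s[i] <- s[i] + abs(i - mean(nb))
    n_i[i] <- n_i[i] + 1L
  }
  n <- sum(n_i)
  if (n == 0L) return(list(contrast = NA_real_, coarseness = NA_real_))
  occ <- which(n_i > 0L)
  p <- n_i / n
  if (length(occ) <= 1L) return(list(contrast = 0, coarseness = 1 / epsilon))
  acc <- 0
  for (i in occ) for (j in occ) acc <- acc + p[i] * p[j] * (i - j)^2
  list(contrast = acc / (length(occ) * (length(occ) - 1)) * sum(s) / n,
       coarseness = 1 / (epsilon + sum(p * s)))
}

# --- statistics oracles ---------------------------------------------------

# Pearson correlation test p, coded from the t transform of r.
oracle_pearson_p <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (!is.finite(r) || abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# Two-group log-rank by direct accumulation over distinct event times.
oracle_logrank <- function(t1, e1, t2, e2) {
  dt <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O_minus_E <- 0; V <- 0
  for (t in dt) {
    n1 <- sum(t1 >= t); n2 <- sum(t2 >= t); n <- n1 + n2
    d1 <- sum(t1 == t & e1 == 1); d2 <- sum(t2 == t & e2 == 1); d <- d1 + d2
    if (n < 2) next
    O_minus_E <- O_minus_E + d1 - d * n1 / n
    V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) O_minus_E^2 / V else 0
  list(chi = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# Exhaustive threshold scan with the independently coded tests above.
oracle_scan_binary <- function(values, labels, min_frac = 0.10) {
  v <- sort(unique(values))
  cand <- (v[-1] + v[-length(v)]) / 2
  n <- length(values)
  best_p <- Inf; best_t <- NA
  for (t in cand) {
    g <- as.numeric(values > t)
    if (sum(g) < min_frac * n || sum(1 - g) < min_frac * n) next
    p <- oracle_pearson_p(g, as.numeric(labels))
    if (p < best_p) { best_p <- p; best_t <- t }
  }
  list(threshold = best_t, p = best_p)
}

oracle_scan_survival <- function(values, times, events, min_frac = 0.10) {
  v <- sort(unique(values))
  cand <- (v[-1] + v[-length(v)]) / 2
  n <- length(values)
  best_p <- Inf; best_t <- NA
  for (t in cand) {
    g <- values > t
    if (sum(g) < min_frac * n || sum(!g) < min_frac * n) next
    p <- oracle_logrank(times[!g], events[!g], times[g], events[g])$p
    if (p < best_p) { best_p <- p; best_t <- t }
  }
  list(threshold = best_t, p = best_p)
}

# AUC by exhaustive positive-negative pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  acc <- 0
  for (a in pos) for (b in neg)
    acc <- acc + (a > b) + 0.5 * (a == b)
  acc / (length(pos) * length(neg))
}

# Population moments by direct sums.
oracle_moments <- function(x) {
  n <- length(x); mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

# A small wrapped volume/mask pair around a level array, for extract tests.
roi_from_levels <- function(levels_arr, n_levels) {
  vol <- voxel_volume(levels_arr + 0)
  msk <- roi_mask(levels_arr > 0)
  list(volume = vol, mask = msk, n_levels = n_levels)
}
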