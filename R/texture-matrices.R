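# Grey-level matrix construction. Offsets are in voxel units on the native
# (anisotropic) grid; mm spacing is deliberately ignored here.

#' The 13 unique 3D directions at Chebyshev distance 1
#'
#' One representative per +/- pair of the 26 neighbourhood, i.e. the standard
#' direction set for pooled 3D co-occurrence and run-length matrices.
#'
#' @return Integer matrix, 13 rows x 3 columns (dx, dy, dz).
#' @export
directions_13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

# All 26 neighbour offsets (or the 6 face neighbours).
neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(g != 0) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  storage.mode(g) <- "integer"
  rownames(g) <- NULL
  g
}

# Valid index range along an axis of length n for lag o (empty when the lag
# exceeds the extent).
.axis_range <- function(n, o) {
  s <- max(1L, 1L - o); e <- min(n, n - o)
  if (s > e) integer(0) else s:e
}

# Aligned sub-arrays of L at lag `off`: returns list(a, b) with a[i] and b[i]
# the values at voxel p and p + off for every in-bounds p.
shifted_pairs <- function(L, off) {
  d <- dim(L)
  rng <- .axis_range
  xs <- rng(d[1], off[1]); ys <- rng(d[2], off[2]); zs <- rng(d[3], off[3])
  if (!length(xs) || !length(ys) || !length(zs))
    return(list(a = numeric(0), b = numeric(0)))
  list(a = L[xs, ys, zs, drop = FALSE],
       b = L[xs + off[1], ys + off[2], zs + off[3], drop = FALSE])
}

#' Pooled symmetric grey-level co-occurrence matrix
#'
#' Counts co-occurring level pairs at `distance` times each direction,
#' symmetrizes, pools all directions into one matrix and normalizes to
#' probabilities.
#'
#' @param roi A `discretized_roi`.
#' @param distance Offset magnitude in voxels (default 1).
#' @param directions Integer matrix of direction triples; default
#'   [directions_13()].
#' @return List: `p` (Ng x Ng probability matrix), `counts`, `n_pairs`.
#' @export
glcm_matrix <- function(roi, distance = 1L, directions = directions_13()) {
  Ng <- roi$n_levels
  L <- roi$levels
  counts <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(directions))) {
    off <- directions[r, ] * as.integer(distance)
    sp <- shifted_pairs(L, off)
    ok <- sp$a > 0L & sp$b > 0L
    if (!any(ok)) next
    a <- sp$a[ok]; b <- sp$b[ok]
    tab <- tabulate((a - 1L) * Ng + b, nbins = Ng * Ng)
    m <- matrix(tab, Ng, Ng, byrow = TRUE)
    counts <- counts + m + t(m)   # symmetrize: count (i,j) and (j,i)
  }
  n_pairs <- sum(counts)
  p <- if (n_pairs > 0) counts / n_pairs else counts
  list(p = p, counts = counts, n_pairs = n_pairs)
}

#' Pooled grey-level run-length matrix
#'
#' Extracts maximal runs of equal level along each direction (out-of-mask
#' voxels break runs) and sums the per-direction matrices.
#'
#' @inheritParams glcm_matrix
#' @return List: `r` (Ng x max-run-length count matrix), `n_runs`,
#'   `n_voxels`, `n_directions`.
#' @export
glrlm_matrix <- function(roi, directions = directions_13()) {
  L <- roi$levels
  Ng <- roi$n_levels
  idx <- which(L > 0L)
  if (!length(idx)) empty_roi_error("ROI is empty")
  d <- dim(L)
  co <- arrayInd(idx, d)
  lev <- L[idx]
  run_lev <- integer(0); run_len <- integer(0)
  for (r in seq_len(nrow(directions))) {
    off <- directions[r, ]
    ax <- which(off != 0)[1]
    t <- co[, ax] * sign(off[ax])
    u <- co[, 1] - t * off[1]
    v <- co[, 2] - t * off[2]
    w <- co[, 3] - t * off[3]
    ord <- order(u, v, w, t)
    lo <- lev[ord]
    nb <- c(TRUE, diff(u[ord]) != 0 | diff(v[ord]) != 0 | diff(w[ord]) != 0 |
              diff(t[ord]) != 1L | diff(lo) != 0L)
    grp <- cumsum(nb)
    run_len <- c(run_len, tabulate(grp))
    run_lev <- c(run_lev, lo[nb])
  }
  lmax <- max(run_len)
  tab <- tabulate((run_lev - 1L) * lmax + run_len, nbins = Ng * lmax)
  R <- matrix(tab, Ng, lmax, byrow = TRUE)
  list(r = R, n_runs = length(run_len), n_voxels = length(idx),
       n_directions = nrow(directions))
}

# Connected-component labelling of equal-level zones by iterative minimum-
# label propagation with path compression. Returns per-zone (level, size).
zone_table <- function(roi, connectivity = 26L) {
  L <- roi$levels
  d <- dim(L)
  idx <- which(L > 0L)
  if (!length(idx)) empty_roi_error("ROI is empty")
  lab <- array(0L, d)
  lab[idx] <- idx
  offs <- neighbor_offsets(connectivity)
  offs <- offs[seq_len(nrow(offs) / 2), , drop = FALSE]  # half set, used both ways
  rng <- .axis_range
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(offs))) {
      off <- offs[r, ]
      xs <- rng(d[1], off[1]); ys <- rng(d[2], off[2]); zs <- rng(d[3], off[3])
      if (!length(xs) || !length(ys) || !length(zs)) next
      la <- lab[xs, ys, zs, drop = FALSE]
      lb <- lab[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
      va <- L[xs, ys, zs, drop = FALSE]
      vb <- L[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
      ok <- la > 0L & lb > 0L & va == vb & la != lb
      if (any(ok)) {
        changed <- TRUE
        mn <- pmin(la[ok], lb[ok])
        # always pmin against the current value so labels only decrease
        la[ok] <- pmin(la[ok], mn)
        lab[xs, ys, zs] <- la
        lb2 <- lab[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
        v <- lb2[ok]
        lb2[ok] <- pmin(v, mn)
        lab[xs + off[1], ys + off[2], zs + off[3]] <- lb2
      }
    }
    # path compression
    repeat {
      nxt <- lab[lab[idx]]
      if (all(nxt == lab[idx])) break
      lab[idx] <- nxt
    }
    if (!changed) break
  }
  zid <- lab[idx]
  f <- factor(zid)
  sizes <- as.integer(tabulate(f))
  levels_of_zone <- L[as.integer(levels(f))]
  list(level = levels_of_zone, size = sizes)
}

#' Grey-level zone (size-zone) matrix
#'
#' Zones are connected components of equal grey level at the stated
#' connectivity; the matrix is indexed (level, zone size).
#'
#' @param roi A `discretized_roi`.
#' @param connectivity 26 (default) or 6.
#' @return List: `z` (Ng x max-zone-size count matrix), `n_zones`, `n_voxels`.
#' @export
glzlm_matrix <- function(roi, connectivity = 26L) {
  zt <- zone_table(roi, connectivity)
  Ng <- roi$n_levels
  smax <- max(zt$size)
  tab <- tabulate((zt$level - 1L) * smax + zt$size, nbins = Ng * smax)
  Z <- matrix(tab, Ng, smax, byrow = TRUE)
  list(z = Z, n_zones = length(zt$size), n_voxels = roi$n_voxels)
}

# Per-level neighbourhood grey-level difference sums: for every in-mask voxel
# with at least one in-mask 26-neighbour, |level - mean(neighbour levels)|,
# accumulated by level. Returns s_i, n_i and n.
ngldm_stats <- function(roi) {
  L <- roi$levels
  d <- dim(L)
  offs <- neighbor_offsets(26L)
  S <- array(0, d)
  C <- array(0, d)
  rng <- .axis_range
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    xs <- rng(d[1], off[1]); ys <- rng(d[2], off[2]); zs <- rng(d[3], off[3])
    if (!length(xs) || !length(ys) || !length(zs)) next
    lb <- L[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
    S[xs, ys, zs] <- S[xs, ys, zs, drop = FALSE] + lb
    C[xs, ys, zs] <- C[xs, ys, zs, drop = FALSE] + (lb > 0L)
  }
  ok <- L > 0L & C > 0
  if (!any(ok)) return(list(s = numeric(roi$n_levels), n_i = integer(roi$n_levels), n = 0L))
  lev <- L[ok]
  dbar <- abs(lev - S[ok] / C[ok])
  s <- as.numeric(rowsum(dbar, group = factor(lev, levels = seq_len(roi$n_levels))))
  n_i <- tabulate(lev, nbins = roi$n_levels)
  list(s = s, n_i = n_i, n = sum(n_i))
}
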