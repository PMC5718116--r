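# Mobile-threshold screening, log-rank/KM wrappers and correlation pruning.

test_that("perfect separation picks the unique gap threshold", {
  v <- 1:10
  y <- as.numeric(v > 5)
  tr <- best_threshold_binary(v, y, min_frac = 0.2)
  expect_equal(tr$threshold, 5.5)
  expect_equal(tr$p_value, oracle_pearson_p(as.numeric(v > 5.5), y),
               tolerance = 1e-12)
})

test_that("degenerate inputs raise typed errors", {
  expect_error(best_threshold_binary(rep(3, 10), rbinom(10, 1, 0.5)),
               class = "degenerate_error")
  expect_error(best_threshold_binary(1:10, rep(1, 10)),
               class = "degenerate_error")
  expect_error(best_threshold_survival(1:10, 1:10, rep(0, 10)),
               class = "no_events_error")
})

test_that("binary threshold scan equals the exhaustive oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    v <- round(rnorm(n), 2)
    y <- rbinom(n, 1, plogis(v))
    if (length(unique(y)) < 2) next
    tr <- best_threshold_binary(v, y)
    oc <- oracle_scan_binary(v, y)
    expect_equal(tr$threshold, oc$threshold)
    expect_equal(tr$p_value, oc$p, tolerance = 1e-10)
  }
})

test_that("survival threshold scan equals the exhaustive log-rank oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 40
    v <- rnorm(n)
    rate <- ifelse(v > median(v), 0.25, 0.08)
    t <- rexp(n, rate)
    cens <- runif(n, 5, 30)
    time <- pmin(t, cens); ev <- as.numeric(t <= cens)
    if (sum(ev) == 0) next
    tr <- best_threshold_survival(v, time, ev)
    oc <- oracle_scan_survival(v, time, ev)
    expect_equal(tr$threshold, oc$threshold)
    expect_equal(tr$p_value, oc$p, tolerance = 1e-8)
  }
})

test_that("exchangeable outcomes tie all splits; smallest threshold returned", {
  # identical time/event for every case: every split gives log-rank p = 1
  v <- c(1, 2, 3, 4, 5, 6, 7, 8)
  time <- rep(7, 8)
  ev <- rep(1, 8)
  tr <- best_threshold_survival(v, time, ev, min_frac = 0.25)
  expect_equal(tr$p_value, 1)
  # smallest admissible candidate (>= 2 cases per side at min_frac 0.25)
  expect_equal(tr$threshold, 2.5)
})

test_that("log-rank: symmetry gives p = 1, hand computation matches", {
  lr <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  ta <- c(1, 2, 3); tb <- c(10, 20, 30)
  lr2 <- logrank_test(ta, c(1, 1, 1), tb, c(1, 1, 1))
  oc <- oracle_logrank(ta, c(1, 1, 1), tb, c(1, 1, 1))
  expect_equal(lr2$chi_square, oc$chi, tolerance = 1e-9)
  expect_equal(lr2$p, oc$p, tolerance = 1e-9)
})

test_that("Kaplan-Meier estimator: closed forms and median", {
  km <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  expect_true(is.na(km$median))

  km2 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km2$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km2$fn(0.5), 1)
  expect_equal(km2$fn(2.5), 1 / 3)

  set.seed(3)
  t <- rexp(80, 0.1); c0 <- runif(80, 0, 25)
  time <- pmin(t, c0); ev <- as.numeric(t <= c0)
  km3 <- km_estimate(time, ev)
  sf <- survival::survfit(survival::Surv(time, ev) ~ 1)
  expect_equal(km3$median, unname(summary(sf)$table["median"]))
})

test_that("correlation pruning yields internally uncorrelated maximal groups", {
  set.seed(21)
  n <- 120
  A <- rnorm(n)
  B <- rnorm(n)
  C <- B + rnorm(n, sd = 0.2)   # B ~ C strongly correlated; both indep of A
  pr <- correlation_prune(data.frame(A = A, B = B, C = C), alpha = 0.05)
  gsets <- lapply(pr$groups, sort)
  expect_true(list(c("A", "B")) %in% gsets || any(sapply(gsets, identical, c("A", "B"))))
  expect_true(any(sapply(gsets, identical, c("A", "C"))))
  expect_false(any(sapply(gsets, function(g) all(c("B", "C") %in% g))))
  # internal edge-freedom
  for (g in pr$groups) {
    pg <- pr$p[g, g]; diag(pg) <- 1
    expect_true(all(pg >= 0.05))
  }
})

test_that("collinear covariates never share a group; independents unite", {
  set.seed(8)
  x <- rnorm(100)
  pr <- correlation_prune(data.frame(a = x, b = 2 * x + 1, c = rnorm(100)))
  expect_false(any(sapply(pr$groups, function(g) all(c("a", "b") %in% g))))

  set.seed(12)
  Xi <- as.data.frame(matrix(rnorm(200 * 4), 200, 4))
  pri <- correlation_prune(Xi)
  expect_true(any(sapply(pri$groups, function(g) length(g) == 4)) ||
                length(pri$groups) <= 2)  # rare single false-positive edge
})

test_that("constant covariates are excluded with a warning", {
  expect_warning(
    pr <- correlation_prune(data.frame(a = rnorm(50), b = rep(1, 50),
                                       c = rnorm(50))),
    "constant")
  expect_false("b" %in% unlist(pr$groups))
  expect_identical(pr$dropped, "b")
})

test_that("permutation-adjusted selection p exceeds the raw selected p", {
  set.seed(31)
  v <- rnorm(40); y <- rbinom(40, 1, 0.5)   # null: raw selected p optimistic
  out <- threshold_permutation_p(v, y, n_perm = 60, seed = 2)
  expect_gte(out$p_adjusted, out$p_raw)
  expect_lte(out$p_adjusted, 1)
})
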