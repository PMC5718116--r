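# Logistic backward elimination, Cox fits, penalized path, AUC,
# Hosmer-Lemeshow and Cox calibration.

sim_logistic <- function(n, beta, k_noise, seed) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * (1 + k_noise)), n))
  names(X) <- c("signal", paste0("noise", seq_len(k_noise)))
  y <- rbinom(n, 1, plogis(beta * X$signal))
  list(X = X, y = y)
}

test_that("backward elimination keeps a planted effect and drops noise", {
  kept <- logical(10)
  for (s in 1:10) {
    d <- sim_logistic(300, log(5), 5, s)
    fit <- logistic_backward(d$X, d$y)
    kept[s] <- "signal" %in% fit$covariates
  }
  expect_gte(mean(kept), 0.8)
})

test_that("under the null the final logistic model is usually empty", {
  empty <- logical(25)
  for (s in 1:25) {
    d <- sim_logistic(300, 0, 5, 1000 + s)
    fit <- logistic_backward(d$X, d$y)
    empty[s] <- length(fit$covariates) == 0
  }
  expect_gte(mean(empty), 0.6)
})

test_that("complete separation is detected and flagged", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- as.numeric(x > 0)
  fit <- logistic_backward(data.frame(x = x), y)
  expect_true("separation" %in% fit$flags)
})

test_that("Cox fit recovers a hazard ratio of 2", {
  set.seed(77)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * 2^x)
  cens <- runif(n, 0, 40)
  fit <- cox_fit(data.frame(x = x), pmin(t, cens), as.numeric(t <= cens))
  hr <- exp(fit$coefficients["x", "estimate"])
  expect_gt(hr, 1.8); expect_lt(hr, 2.2)
  expect_lt(fit$lr_p, 1e-6)
})

test_that("null Cox covariate has roughly uniform Wald p", {
  over <- logical(100)
  for (s in 1:100) {
    set.seed(2000 + s)
    n <- 60
    t <- rexp(n, 0.1); cens <- runif(n, 0, 30)
    fit <- cox_fit(data.frame(x = rnorm(n)), pmin(t, cens),
                   as.numeric(t <= cens))
    over[s] <- fit$coefficients["x", "p"] > 0.05
  }
  expect_gte(mean(over), 0.90); expect_lte(mean(over), 1.0)
})

test_that("zero-variance covariates are excluded with a warning", {
  set.seed(4)
  t <- rexp(50, 0.1)
  expect_warning(
    fit <- cox_fit(data.frame(x = rnorm(50), z = rep(2, 50)), t, rep(1, 50)),
    "zero-variance")
  expect_identical(fit$covariates, "x")
})

test_that("elastic-net path: full shrinkage at top, Cox limit at bottom", {
  set.seed(10)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  t <- rexp(n, 0.1 * exp(0.7 * X[, 1]))
  cens <- runif(n, 0, 30)
  time <- pmin(t, cens); ev <- as.numeric(t <= cens)
  path <- cox_elasticnet_path(X, time, ev, mixing = 0.5, n_folds = 5, seed = 3)
  expect_true(all(path$beta[, 1] == 0))
  expect_gte(path$lambda_1se, path$lambda_min)
  expect_true(all(path$cvsd >= 0))

  # unpenalized limit: lasso path pushed to tiny lambda on one covariate
  x1 <- X[, 1, drop = FALSE]
  gl <- glmnet::glmnet(cbind(x1, 0), survival::Surv(time, ev), family = "cox",
                       alpha = 1, lambda = c(0.2, 0.05, 0.01, 1e-4, 1e-6),
                       thresh = 1e-14)
  b_pen <- as.numeric(stats::coef(gl, s = 1e-6))[1]
  b_cox <- cox_fit(data.frame(a = X[, 1]), time, ev)$coefficients["a", "estimate"]
  expect_lt(abs(b_pen - b_cox) / abs(b_cox), 0.01)
})

test_that("stepwise Cox: fixed point on one covariate, null model when empty", {
  set.seed(15)
  n <- 300
  x <- rnorm(n)
  t <- rexp(n, 0.1 * exp(0.8 * x)); cens <- runif(n, 0, 30)
  time <- pmin(t, cens); ev <- as.numeric(t <= cens)
  st <- cox_stepwise(data.frame(x = x), time, ev)
  cf <- cox_fit(data.frame(x = x), time, ev)
  expect_equal(st$coefficients, cf$coefficients)

  nullm <- cox_stepwise(data.frame()[seq_len(n), , drop = FALSE], time, ev)
  expect_identical(nullm$covariates, character(0))
  expect_equal(nullm$lr_stat, 0)

  # planted + null covariate: the null one is eliminated most of the time
  drops <- logical(10)
  for (s in 1:10) {
    set.seed(300 + s)
    x1 <- rnorm(n); x2 <- rnorm(n)
    t <- rexp(n, 0.1 * exp(0.9 * x1)); cens <- runif(n, 0, 30)
    st2 <- cox_stepwise(data.frame(x1 = x1, x2 = x2), pmin(t, cens),
                        as.numeric(t <= cens))
    drops[s] <- identical(st2$covariates, "x1")
  }
  expect_gte(mean(drops), 0.8)
})

test_that("AUC: trivial values, pair-counting oracle, monotone invariance", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(2, 8), rep(c(0, 1), 4))$auc, 0.5)

  set.seed(9)
  s <- c(rnorm(6), rnorm(6, 1)); l <- rep(c(0, 1), each = 6)
  s[2] <- s[8]  # force a tie
  r <- roc_auc(s, l)
  expect_equal(r$auc, oracle_auc(s, l), tolerance = 1e-12)
  expect_true(r$ci_lo <= r$auc && r$auc <= r$ci_hi)
  r2 <- roc_auc(exp(2 * s), l)           # strictly increasing transform
  expect_equal(r2$auc, r$auc, tolerance = 1e-12)

  rb <- roc_auc(s, l, ci_method = "bootstrap", seed = 5, n_boot = 200)
  expect_equal(rb$auc, r$auc)
  expect_true(rb$ci_lo <= rb$auc && rb$auc <= rb$ci_hi)

  expect_error(roc_auc(1:5, rep(1, 5)), class = "class_error")
})

test_that("Hosmer-Lemeshow: exact calibration gives statistic 0", {
  # 10 groups x 10 cases, within-group constant risk, observed = expected
  pred <- rep(seq(0.05, 0.95, by = 0.1), each = 10)
  y <- unlist(lapply(seq(0.05, 0.95, by = 0.1), function(p)
    c(rep(1, round(10 * p)), rep(0, 10 - round(10 * p)))))
  # expected counts are integers at p = .05,...: 0.5 not integer; use 0.1..0.9 x10
  pred <- rep(seq(0.1, 0.9, length.out = 9), each = 10)
  y <- unlist(lapply(seq(0.1, 0.9, length.out = 9), function(p)
    c(rep(1, round(10 * p)), rep(0, 10 - round(10 * p)))))
  hl <- hosmer_lemeshow(pred, y, n_groups = 9)
  expect_equal(hl$chi_square, 0, tolerance = 1e-12)
  expect_equal(hl$p, 1)
})

test_that("Hosmer-Lemeshow flags constant predictions as degenerate", {
  hl <- hosmer_lemeshow(rep(0.4, 40), rbinom(40, 1, 0.4))
  expect_true("degenerate" %in% hl$flags)
  expect_true(is.na(hl$p))
})

test_that("null-model Cox calibration reproduces the pooled KM", {
  set.seed(44)
  n <- 200
  t <- rexp(n, 0.08); cens <- runif(n, 0, 30)
  time <- pmin(t, cens); ev <- as.numeric(t <= cens)
  nullm <- cox_fit(data.frame()[seq_len(n), , drop = FALSE], time, ev)
  cal <- cox_calibration(nullm, time, ev, horizons = 12, n_risk_groups = 3)
  km <- km_estimate(time, ev)
  expect_equal(cal$predicted, rep(km$fn(12), 3), tolerance = 1e-9)
  expect_false(any(cal$extrapolated))
  cal2 <- cox_calibration(nullm, time, ev, horizons = max(time) + 5)
  expect_true(all(cal2$extrapolated))
})

test_that("well-specified Cox calibration agrees with observed survival", {
  set.seed(55)
  n <- 500
  x <- rnorm(n)
  t <- rexp(n, 0.06 * exp(0.7 * x)); cens <- runif(n, 5, 40)
  time <- pmin(t, cens); ev <- as.numeric(t <= cens)
  fit <- cox_fit(data.frame(x = x), time, ev)
  cal <- cox_calibration(fit, time, ev, horizons = 12, n_risk_groups = 3)
  expect_true(all(abs(cal$predicted - cal$observed) < 0.1))
})
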