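test_that("inverse probability weights are reciprocal selection probabilities", {
  st <- rep(c("case", "control"), c(50, 50))
  w <- compute_ipw(st, 100, 900)
  expect_equal(unique(w[st == "case"]), 2)
  expect_equal(unique(w[st == "control"]), 18)
  expect_equal(compute_ipw(st, 50, 50), rep(1, 100))
  st2 <- rep(c("case", "control"), c(52, 109))
  w2 <- compute_ipw(st2, 130, 1470)
  expect_equal(unique(w2[st2 == "case"]), 2.5)
  expect_equal(unique(w2[st2 == "control"]), 1470 / 109, tolerance = 1e-12)
  expect_error(compute_ipw(rep("case", 5), 10, 10), "both strata")
})

test_that("weighted least squares is exact on noiseless data and weight-invariant", {
  set.seed(1)
  X <- cbind(1, stats::rnorm(50), stats::rnorm(50))
  b <- c(2, -1, 0.5)
  y <- drop(X %*% b)
  f <- fit_weighted_linear(y, X, stats::runif(50, 0.5, 3))
  expect_equal(unname(f$coefficients), b, tolerance = 1e-10)
  expect_equal(f$residual_variance, 0, tolerance = 1e-16)

  # doubling a row equals giving it weight 2
  y2 <- y + stats::rnorm(50)
  f_dup <- fit_weighted_linear(c(y2, y2[1:10]), rbind(X, X[1:10, ]),
                               rep(1, 60))
  w <- rep(1, 50); w[1:10] <- 2
  f_wt <- fit_weighted_linear(y2, X, w)
  expect_equal(f_dup$coefficients, f_wt$coefficients, tolerance = 1e-10)
})

test_that("weighted least squares recovers a simulated slope within Monte-Carlo error", {
  set.seed(7)
  n <- 10000
  x <- stats::rnorm(n)
  y <- 2 * x + stats::rnorm(n)
  f <- fit_weighted_linear(y, cbind(1, x = x), stats::runif(n, 0.5, 2))
  expect_lt(abs(f$coefficients["x"] - 2), 3 * f$standard_errors["x"])
})

test_that("sandwich variances match the established oracle implementation", {
  skip_if_not_installed("sandwich")
  set.seed(3)
  n <- 300
  x <- stats::rnorm(n)
  w <- stats::runif(n, 0.5, 4)
  y <- 1 + x + stats::rnorm(n) * (1 + abs(x))   # heteroskedastic
  f <- fit_weighted_linear(y, cbind(`(Intercept)` = 1, x = x), w)
  lmfit <- stats::lm(y ~ x, weights = w)
  V <- sandwich::vcovHC(lmfit, type = "HC0")
  expect_equal(unname(f$standard_errors), unname(sqrt(diag(V))),
               tolerance = 1e-8)

  yb <- stats::rbinom(n, 1, stats::plogis(x))
  fb <- fit_weighted_logistic(yb, cbind(`(Intercept)` = 1, x = x), w)
  gfit <- suppressWarnings(stats::glm(yb ~ x, family = stats::quasibinomial(),
                                      weights = w))
  Vb <- sandwich::vcovHC(gfit, type = "HC0")
  expect_equal(unname(fb$coefficients), unname(stats::coef(gfit)),
               tolerance = 1e-8)
  expect_equal(unname(fb$standard_errors), unname(sqrt(diag(Vb))),
               tolerance = 1e-4)
})

test_that("rank deficiency is reported with the collinear column named", {
  X <- cbind(a = rep(1, 10), b = 1:10, dup = 2 * (1:10))
  expect_error(fit_weighted_linear(stats::rnorm(10), X), "dup",
               class = "mixmediate_rank_error")
})

test_that("weighted logistic regression matches closed forms and duplication", {
  y <- rep(c(1, 0), c(25, 75))
  f <- fit_weighted_logistic(y, matrix(1, 100, 1,
                                       dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(f$coefficients), log(1 / 3), tolerance = 1e-8)

  set.seed(2)
  x <- stats::rnorm(200)
  yb <- stats::rbinom(200, 1, stats::plogis(x))
  idx_dup <- which(yb == 1)
  f_dup <- fit_weighted_logistic(c(yb, yb[idx_dup]),
                                 cbind(1, c(x, x[idx_dup])))
  w <- rep(1, 200); w[idx_dup] <- 2
  f_wt <- fit_weighted_logistic(yb, cbind(1, x), w)
  expect_equal(unname(f_dup$coefficients), unname(f_wt$coefficients),
               tolerance = 1e-7)
})

test_that("weighted logistic regression recovers a simulated slope", {
  set.seed(11)
  n <- 20000
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(x))
  f <- fit_weighted_logistic(y, cbind(1, x = x))
  expect_lt(abs(f$coefficients["x"] - 1), 3 * f$standard_errors["x"])
})

test_that("perfect separation raises a typed error", {
  x <- c(-(10:1), 1:10)
  y <- as.integer(x > 0)
  expect_error(fit_weighted_logistic(y, cbind(1, x)),
               class = "mixmediate_separation_error")
})

test_that("q-values follow step-up arithmetic and preserve order", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03), method = "bh"),
               rep(0.03, 3))
  expect_equal(qvalues(rep(0.2, 5), method = "bh"), rep(0.2, 5))
  set.seed(4)
  p <- stats::runif(500)
  q <- qvalues(p, method = "storey")
  expect_true(all(q >= 0 & q <= 1))
  # monotone: ordering by p orders q
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(qvalues(c(0.1, 1.3)), "0, 1")
})

test_that("Storey pi0 is near 1 under the global null", {
  pi0s <- vapply(1:50, function(s) {
    set.seed(s)
    mixmediate:::storey_pi0(stats::runif(1000))
  }, numeric(1))
  expect_lt(abs(mean(pi0s) - 1), 0.1)
})

test_that("weighted descriptives reduce to the unweighted summary at equal weights", {
  set.seed(6)
  covars <- data.frame(age = stats::rnorm(40),
                       group = factor(sample(c("a", "b"), 40, TRUE)))
  cohort <- make_cohort(stats::rnorm(40, 39), covariates = covars)
  desc <- weighted_descriptives(cohort)
  age_med <- desc$value[desc$variable == "age" & desc$statistic == "median"]
  expect_equal(age_med, unname(stats::median(covars$age)), tolerance = 1e-8)
  pct <- desc$value[desc$variable == "group"]
  expect_equal(sum(pct), 100, tolerance = 0.1)
})

test_that("IPW-weighted case fraction matches cohort prevalence", {
  sim <- generate_cohort(sim_config(seed = 9))
  w <- sim$cohort$ipw_weight
  wt_case <- sum(w[sim$cohort$case_status == "case"]) / sum(w)
  prev <- mean(sim$full$cohort$outcome_binary)
  expect_lt(abs(wt_case - prev), 0.01)
})

test_that("weighted quantiles interpolate the weighted empirical CDF", {
  x <- c(1, 2, 3, 4)
  expect_equal(weighted_quantile(x, rep(1, 4), 0.5),
               unname(stats::quantile(x, 0.5, type = 5)), tolerance = 1e-8)
  # one dominant weight pulls the median to that value
  expect_equal(weighted_quantile(x, c(1, 1, 1e6, 1), 0.5), 3,
               tolerance = 1e-3)
})
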