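test_that("MCP threshold interpolates between soft and hard thresholding", {
  u <- seq(-3, 3, by = 0.25)
  lam <- 0.8
  # gamma -> Inf: soft threshold
  expect_equal(mcp_threshold(u, lam, gamma = 1e8),
               sign(u) * pmax(abs(u) - lam, 0), tolerance = 1e-6)
  # gamma -> 1+: hard threshold (at unit curvature)
  expect_equal(mcp_threshold(u, lam, gamma = 1 + 1e-9),
               ifelse(abs(u) <= lam, 0, u), tolerance = 1e-6)
  expect_error(mcp_threshold(1, 1, gamma = 0.5), "gamma")
})

test_that("MCP with zero penalty reproduces least squares", {
  set.seed(1)
  n <- 200
  X <- cbind(1, matrix(stats::rnorm(n * 5), n, 5))
  y <- drop(X %*% c(1, 0.5, -0.5, 0.2, 0, 0)) + stats::rnorm(n)
  fit <- mixmediate:::mcp_fit(y, X, lambda = 0, gamma = 3, n_unpen = 1)
  ols <- stats::lm.fit(X, y)$coefficients
  expect_equal(fit$beta, unname(ols), tolerance = 1e-8)
})

test_that("pathway lasso at zero penalty matches the two-equation least squares", {
  set.seed(2)
  n <- 300; q <- 8
  a <- drop(scale(stats::rnorm(n)))
  M <- scale(outer(a, stats::runif(q, -0.5, 0.5)) +
               matrix(stats::rnorm(n * q), n, q))
  colnames(M) <- paste0("m", 1:q)
  covars <- data.frame(z = stats::rnorm(n))
  y <- drop(M %*% c(0.8, -0.6, rep(0, q - 2))) + 0.3 * a +
    0.5 * covars$z + stats::rnorm(n)
  pl <- pathway_lasso_fit(a, M, y, covariates = covars,
                          lambda_path = 1e-10, cv_folds = 0)
  f <- pl$fits[[1]]
  Xc <- cbind(1, covars$z)
  Q <- qr(Xc)
  ar <- qr.resid(Q, a); Mr <- qr.resid(Q, M); yr <- qr.resid(Q, y)
  alpha_ols <- drop(crossprod(Mr, ar)) / sum(ar^2)
  out_ols <- stats::lm.fit(cbind(ar, Mr), yr)$coefficients
  expect_equal(unname(f$alpha_hat), unname(alpha_ols), tolerance = 1e-6)
  expect_equal(unname(f$beta_hat), unname(out_ols[-1]), tolerance = 1e-6)
  expect_equal(f$beta_a, unname(out_ols[1]), tolerance = 1e-6)
})

test_that("large penalties empty the selected set and the path is monotone at the ends", {
  set.seed(3)
  n <- 200; q <- 10
  a <- drop(scale(stats::rnorm(n)))
  M <- scale(outer(a, c(1, 0.8, rep(0, q - 2))) +
               matrix(stats::rnorm(n * q), n, q))
  colnames(M) <- paste0("m", 1:q)
  y <- drop(M %*% c(0.9, -0.7, rep(0, q - 2))) + stats::rnorm(n)
  pl <- pathway_lasso_fit(a, M, y, cv_folds = 0)
  expect_equal(pl$path$n_selected[1], 0L)           # at lambda_max
  expect_gt(pl$path$n_selected[nrow(pl$path)], 0L)  # at the path foot
  expect_true(all(pl$path$converged))
  # objective at the solution never exceeds the all-zero objective
  for (li in c(1, 10, 20, 30)) {
    f <- pl$fits[[li]]
    rd <- mixmediate:::residualize_on_covariates(y, a, M, NULL)
    lam <- pl$path$lambda[li]
    obj_zero <- mixmediate:::plasso_objective(
      rd$y, rd$a, rd$M, rep(0, q), rep(0, q), 0, lam, lam, 2)
    expect_lte(f$objective, obj_zero + 1e-10)
  }
})

test_that("pathway lasso recovers active pathways with substantial sparsification", {
  stats_out <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 400; q <- 20
    a <- drop(scale(stats::rnorm(n)))
    M <- matrix(stats::rnorm(n * q), n, q)
    M[, 1] <- M[, 1] + a; M[, 2] <- M[, 2] + 0.8 * a; M[, 3] <- M[, 3] - 0.8 * a
    M <- scale(M); colnames(M) <- paste0("m", 1:q)
    y <- 0.2 * a + drop(M[, 1:3] %*% c(0.8, 0.6, -0.6)) + stats::rnorm(n)
    pl <- pathway_lasso_fit(a, M, drop(scale(y, scale = FALSE)),
                            cv_folds = 5, seed = s)
    c(recall = length(intersect(pl$selected, paste0("m", 1:3))) / 3,
      nsel = length(pl$selected))
  }, numeric(2))
  expect_gte(mean(stats_out["recall", ] >= 2 / 3), 0.8)
  expect_lt(mean(stats_out["nsel", ]), 20 / 2)
})

test_that("joint significance p-value is the maximum of the path p-values", {
  set.seed(4)
  n <- 400; q <- 12
  a <- drop(scale(stats::rnorm(n)))
  M <- matrix(stats::rnorm(n * q), n, q)
  M[, 5] <- M[, 5] + 0.8 * a
  M <- scale(M); colnames(M) <- paste0("m", 1:q)
  y <- drop(M[, 5]) + 0.2 * a + stats::rnorm(n)
  js <- mcp_joint_significance(a, M, drop(scale(y, scale = FALSE)))
  expect_true("m5" %in% js$mediator_id)
  expect_equal(js$p_joint, pmax(js$p_alpha, js$p_beta), tolerance = 1e-15)
  expect_true(all(js$q_joint_bh >= js$p_joint - 1e-15))
  expect_true(all(js$p_joint_bonferroni >= js$p_joint - 1e-15))
})

test_that("an all-noise screen returns an empty selection with status, not an error", {
  set.seed(5)
  n <- 150; q <- 10
  a <- drop(scale(stats::rnorm(n)))
  M <- scale(matrix(stats::rnorm(n * q), n, q))
  colnames(M) <- paste0("m", 1:q)
  y <- stats::rnorm(n)
  js <- mcp_joint_significance(a, M, y)
  expect_s3_class(js, "data.frame")
  if (nrow(js) == 0) expect_match(attr(js, "status"), "survived")
})

test_that("sure independence screening bounds the survivor count", {
  set.seed(6)
  n <- 100; q <- 40
  a <- drop(scale(stats::rnorm(n)))
  M <- scale(matrix(stats::rnorm(n * q), n, q))
  colnames(M) <- paste0("m", 1:q)
  y <- drop(M[, 1]) + stats::rnorm(n)
  js <- mcp_joint_significance(a, M, y, screen_size = 5)
  expect_lte(nrow(js), 5)
})
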