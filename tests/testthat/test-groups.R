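test_that("a single-mediator group has the trivial direction", {
  set.seed(1)
  n <- 100
  a <- stats::rnorm(n)
  m <- matrix(drop(scale(0.5 * a + stats::rnorm(n))), ncol = 1,
              dimnames = list(NULL, "m1"))
  y <- stats::rnorm(n)
  d <- estimate_direction(a, m, y, group = "solo")
  expect_equal(unname(d$w_g), 1)
  expect_equal(d$mge, drop(m), tolerance = 1e-12)
  expect_equal(unname(d$contribution_rho), 1, tolerance = 1e-12)
})

test_that("the fitted direction dominates the principal-component direction", {
  set.seed(7)
  n <- 500; qg <- 8
  a <- stats::rnorm(n)
  # mediation signal along w*, but the largest variance direction differs
  w_star <- c(1, -1, rep(0, qg - 2)) / sqrt(2)
  E <- matrix(stats::rnorm(n * qg), n, qg)
  E[, 3] <- 2 * E[, 3]                     # variance-dominant noise axis
  M <- outer(a, w_star) + E
  M <- scale(M); colnames(M) <- paste0("m", 1:qg)
  y <- drop(M %*% w_star) + stats::rnorm(n)
  d <- estimate_direction(a, M, y, n_starts = 8, seed = 2)
  expect_true(d$converged)
  expect_equal(sqrt(sum(d$w_g^2)), 1, tolerance = 1e-8)

  # oracle comparison: profile objective at the first PC of the residualized
  # mediators cannot beat the optimized direction
  X <- cbind(1, a)
  RM <- qr.resid(qr(X), M)
  pc1 <- svd(RM, nu = 0, nv = 1)$v[, 1]
  obj_at <- function(w) {
    Ry <- qr.resid(qr(X), y)
    G <- crossprod(RM); b <- drop(crossprod(RM, Ry)); c0 <- sum(Ry^2)
    s <- drop(crossprod(w, G %*% w))
    -log(s) - log(c0 - sum(b * w)^2 / s)
  }
  expect_gte(d$objective_value, obj_at(pc1) - 1e-8)
  # and it recovers the generating direction on this strong-signal design
  expect_gte(abs(sum(d$w_g * w_star)), 0.9)
})

test_that("the optimizer's objective trace is non-decreasing", {
  set.seed(3)
  n <- 300; qg <- 5
  a <- stats::rnorm(n)
  M <- scale(outer(a, c(1, 0.5, rep(0, 3))) + matrix(stats::rnorm(n * qg), n, qg))
  colnames(M) <- paste0("m", 1:qg)
  y <- drop(M %*% c(0.8, 0.4, 0, 0, 0)) + stats::rnorm(n)
  d <- estimate_direction(a, M, y, n_starts = 3, seed = 5)
  expect_true(all(diff(d$objective_trace) >= -1e-12))
})

test_that("direction estimates are invariant to mediator column order", {
  set.seed(4)
  n <- 800; qg <- 6
  a <- stats::rnorm(n)
  w_star <- c(0.8, -0.5, 0.3, 0, 0, 0); w_star <- w_star / sqrt(sum(w_star^2))
  M <- scale(outer(a, w_star) + matrix(stats::rnorm(n * qg), n, qg))
  colnames(M) <- paste0("m", 1:qg)
  y <- drop(M %*% w_star) + stats::rnorm(n)
  d1 <- estimate_direction(a, M, y, seed = 9)
  perm <- c(3, 1, 6, 2, 5, 4)
  d2 <- estimate_direction(a, M[, perm], y, seed = 9)
  expect_equal(abs(stats::cor(d1$mge, d2$mge)), 1, tolerance = 1e-6)
})

test_that("sparse exposure-mediator correlation surfaces as a typed status", {
  set.seed(6)
  n <- 400
  a <- stats::rnorm(n)
  M <- scale(matrix(stats::rnorm(n * 5), n, 5))
  colnames(M) <- paste0("m", 1:5)
  y <- stats::rnorm(n)
  d <- estimate_direction(a, M, y, seed = 3)
  expect_equal(d$status, "sparse_signal")
  # a null direction transmits essentially no indirect effect
  r <- mge_mediation(a, d, make_cohort(y))
  expect_lt(abs(r$nie), 3 * r$se_nie + 0.05)
})

test_that("contribution correlations identify the driving mediators", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 1000; qg <- 8
    a <- stats::rnorm(n)
    w_star <- c(1, -1, rep(0, qg - 2)) / sqrt(2)
    M <- scale(outer(a, w_star) * 1.5 + matrix(stats::rnorm(n * qg), n, qg))
    colnames(M) <- paste0("m", 1:qg)
    y <- drop(M %*% w_star) + stats::rnorm(n)
    d <- estimate_direction(a, M, y, n_starts = 5, seed = s)
    rho <- contribution_correlations(d, M)
    all(abs(rho[1:2]) > 0.3) && all(abs(rho[3:qg]) < 0.3)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("group scan returns s + 1 rows with small groups excluded", {
  sim <- generate_cohort(sim_config(seed = 25))
  a <- drop(scale(log(sim$exposures$values[, 1])))
  scan <- group_mediation_scan(a, sim$mediators, sim$cohort, seed = 2,
                               n_starts = 5)
  expect_equal(nrow(scan$results), 6)   # 5 eligible groups + "all"
  expect_setequal(scan$results$group,
                  c("cox", "cyp450", "lox", "parent", "inflam", "all"))
  # the simulated pathway runs through cytochrome p450: largest |NIE|
  # among the eligible biological groups
  bio <- scan$results[scan$results$group != "all", ]
  expect_equal(bio$group[which.max(abs(bio$nie))], "cyp450")
})

test_that("zero-penalty sparse components reproduce ordinary PCA", {
  set.seed(8)
  X <- scale(matrix(stats::rnorm(200 * 10), 200, 10))
  colnames(X) <- paste0("x", 1:10)
  sp <- sparse_pc(X, variance_target = 1, penalty = 0)
  pca <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  expect_equal(sp$n_components, qr(X)$rank)
  for (k in 1:4) {
    expect_equal(abs(sum(sp$loadings[, k] * pca$rotation[, k])), 1,
                 tolerance = 1e-8)
    expect_equal(stats::var(sp$scores[, k]) /
                   sum(apply(X, 2, stats::var)),
                 unname(pca$sdev[k]^2 / sum(pca$sdev^2)), tolerance = 1e-8)
  }
  # deflation orthogonality at zero penalty
  G <- crossprod(sp$loadings[, 1:5])
  expect_equal(G, diag(5), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("sparse components recover a low-rank mediator structure", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 1000
    F_ <- matrix(stats::rnorm(n * 3), n, 3)
    L <- matrix(stats::rnorm(3 * 12, sd = 1.2), 3, 12)
    X <- scale(F_ %*% L + 0.4 * matrix(stats::rnorm(n * 12), n, 12))
    sparse_pc(X, variance_target = 0.8, penalty = 0)$n_components == 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("over-penalized sparse PCA errors and component scores mediate", {
  set.seed(10)
  X <- scale(matrix(stats::rnorm(100 * 5), 100, 5))
  colnames(X) <- paste0("x", 1:5)
  expect_error(sparse_pc(X, penalty = 1e6),
               class = "mixmediate_penalty_error")
  a <- stats::rnorm(100)
  res <- sparse_pc_mediation(a, X, make_cohort(stats::rnorm(100, 39)),
                             variance_target = 0.6)
  expect_true(nrow(res$results) >= 1)
  expect_true(all(c("nie", "te", "p_nie") %in% names(res$results)))
  expect_true(res$nie_sign_fraction >= 0.5)
})
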