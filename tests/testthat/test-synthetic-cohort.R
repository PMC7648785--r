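test_that("default cohort reproduces the study's panel structure", {
  sim <- generate_cohort(sim_config(seed = 1))
  expect_equal(ncol(sim$exposures$values), 38)
  expect_equal(as.integer(table(sim$exposures$map)[c("phthalate", "phenol",
                                                     "pah", "metal")]),
               c(9L, 9L, 8L, 12L))
  expect_equal(ncol(sim$mediators$values), 61)
  expect_equal(as.integer(table(sim$mediators$map)[c("cox", "cyp450", "lox",
                                                     "parent", "inflam",
                                                     "oxstress", "protein")]),
               c(14L, 18L, 14L, 5L, 5L, 2L, 3L))
  expect_equal(nrow(sim$cohort), 161)
  expect_equal(sum(sim$cohort$case_status == "case"), 52)
  expect_equal(ncol(cohort_covariates(sim$cohort)), 6)
  expect_true(all(sim$exposures$values > 0))
  expect_true(all(sim$mediators$values > 0))
})

test_that("independence configuration yields uncorrelated exposures and null truth", {
  cfg <- sim_config(n_cohort = 2000, n_cases_sampled = 30,
                    n_controls_sampled = 100,
                    within_class_rho = 0, between_class_rho = 0,
                    alpha_matrix = matrix(0, 61, 38),
                    beta_m = rep(0, 61), seed = 11)
  sim <- generate_cohort(cfg)
  A <- log(sim$full$exposures$values[, 1:12])
  cm <- stats::cor(A)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.15)
  expect_true(all(sim$truth$true_nie == 0))
  expect_equal(nrow(sim$truth$active_pairs), 0)
})

test_that("two-stage regression on the full cohort recovers a unit pathway effect", {
  # independent oracle: plain OLS product-of-coefficients, 200 seeds
  nies <- vapply(1:200, function(s) {
    sim <- generate_cohort(small_active_config(seed = s))
    A <- log(sim$full$exposures$values[, 1])
    M <- log(sim$full$mediators$values[, 1])
    y <- sim$full$cohort$outcome_continuous
    alpha <- stats::coef(stats::lm(M ~ A))["A"]
    beta <- stats::coef(stats::lm(y ~ A + M))["M"]
    unname(alpha * beta)
  }, numeric(1))
  mc_se <- stats::sd(nies) / sqrt(length(nies))
  expect_lt(abs(mean(nies) - 1), 3 * mc_se)
})

test_that("ground truth decomposes additively for every pair", {
  cfg <- sim_config(seed = 2)
  tr <- generate_cohort(cfg)$truth
  te_mat <- matrix(tr$true_te, nrow = nrow(tr$true_nie),
                   ncol = length(tr$true_te), byrow = TRUE)
  expect_equal(tr$true_nde + tr$true_nie, te_mat, tolerance = 1e-12)
})

test_that("selection probabilities follow the sampling-fraction definition", {
  expect_equal(
    unname(selection_probabilities(rep(c("case", "control"), c(50, 10)),
                                   100, 100)["case"]), 0.5)
  st <- rep(c("case", "control"), c(5, 7))
  expect_equal(unname(selection_probabilities(st, 5, 7)), c(1, 1))
  st2 <- rep(c("case", "control"), c(52, 109))
  pr <- selection_probabilities(st2, 130, 1470)
  expect_equal(unname(pr["case"]), 0.4)
  expect_equal(unname(pr["control"]), 109 / 1470, tolerance = 1e-12)
  expect_error(selection_probabilities(st2, 10, 1470), "cannot exceed")
})

test_that("within-class correlation converges to its target and oversampling raises prevalence", {
  cfg <- sim_config(n_cohort = 5000, n_cases_sampled = 52,
                    n_controls_sampled = 109, seed = 5)
  sim <- generate_cohort(cfg)
  A <- log(sim$full$exposures$values)
  phth <- A[, sim$exposures$map == "phthalate"]
  cm <- stats::cor(phth)
  expect_lt(max(abs(cm[upper.tri(cm)] - cfg$within_class_rho)), 0.05)
  prev_cohort <- mean(sim$full$cohort$outcome_binary)
  prev_subset <- mean(sim$cohort$outcome_binary)
  expect_gt(prev_subset, prev_cohort)
})

test_that("regeneration with the same seed is bit-identical", {
  s1 <- generate_cohort(sim_config(seed = 42))
  s2 <- generate_cohort(sim_config(seed = 42))
  expect_identical(s1$exposures$values, s2$exposures$values)
  expect_identical(s1$mediators$values, s2$mediators$values)
  expect_identical(s1$cohort, s2$cohort)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(within_class_rho = 1.2), "within_class_rho")
  expect_error(sim_config(n_cohort = 100), "cannot exceed")
  expect_error(sim_config(alpha_matrix = matrix(0, 3, 3)), "alpha_matrix")
  expect_error(
    sim_config(class_sizes = c(phthalate = 3),
               group_sizes = c(cox = 2),
               alpha_matrix = matrix(0, 2, 3), beta_m = rep(0, 2),
               beta_a = rep(0, 3), within_class_rho = -0.9),
    "within_class_rho")
})

test_that("cohort CSV and manifest round-trip preserves panels and weights", {
  sim <- generate_cohort(small_active_config(seed = 3))
  dir <- withr::local_tempdir()
  write_cohort_csv(sim, dir)
  back <- read_cohort_csv(dir)
  expect_equal(back$exposures$values, sim$exposures$values,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$exposures$map, sim$exposures$map)
  expect_equal(back$mediators$map, sim$mediators$map)
  expect_equal(back$cohort$ipw_weight, sim$cohort$ipw_weight,
               tolerance = 1e-12)
  expect_s3_class(back$cohort, "cohort_table")
})
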