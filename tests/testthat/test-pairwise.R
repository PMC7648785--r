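test_that("effect decomposition identities hold exactly on a fixed dataset", {
  dat <- make_mediation_data(300, alpha = 0.8, beta_m = 0.5, beta_a = 0.3,
                             seed = 21)
  covars <- data.frame(z = stats::rnorm(300))
  cohort <- make_cohort(dat$cohort$outcome_continuous, covariates = covars,
                        weights = stats::runif(300, 0.5, 3))
  r <- mediate_pair(dat$a, dat$m, cohort)
  # TE = NDE + NIE
  expect_equal(r$te, r$beta_a + r$nie, tolerance = 1e-10)
  # product method = difference method (nested WLS identity)
  Xc <- stats::model.matrix(~ z, covars)[, -1, drop = FALSE]
  f_marg <- fit_weighted_linear(cohort$outcome_continuous,
                                cbind(1, exposure = dat$a, Xc),
                                cohort$ipw_weight)
  diff_nie <- unname(f_marg$coefficients["exposure"]) - r$beta_a
  expect_equal(r$nie, diff_nie, tolerance = 1e-8)
  expect_true(r$ci_low <= r$nie && r$nie <= r$ci_high)
})

test_that("Sobel arithmetic composes the path estimates and their errors", {
  set.seed(20)
  a <- stats::rnorm(100)
  m <- 0.5 * a + stats::rnorm(100)    # noisy exposure-to-mediator path
  y <- 0.4 * m                        # exact mediator-to-outcome path
  cohort <- make_cohort(y)
  r <- mediate_pair(a, m, cohort)
  expect_equal(r$beta_m, 0.4, tolerance = 1e-10)
  expect_equal(r$se_beta_m, 0, tolerance = 1e-8)
  expect_equal(r$nie, 0.4 * r$alpha_a, tolerance = 1e-10)
  # with a noiseless outcome path the Sobel error is |beta_m| * se(alpha)
  expect_equal(r$se_nie, 0.4 * r$se_alpha_a, tolerance = 1e-8)
  # general delta-method composition
  expect_equal(r$se_nie,
               sqrt(r$alpha_a^2 * r$se_beta_m^2 + r$beta_m^2 * r$se_alpha_a^2),
               tolerance = 1e-12)
})

test_that("null exposure-mediator path gives an indirect effect near zero", {
  dat <- make_mediation_data(5000, alpha = 0, beta_m = 1, seed = 8)
  r <- mediate_pair(dat$a, dat$m, dat$cohort)
  expect_lt(abs(r$nie), 3 * r$se_nie + 1e-12)
})

test_that("bootstrap and Sobel standard errors agree on well-behaved data", {
  dat <- make_mediation_data(1000, alpha = 1, beta_m = 1, seed = 13)
  rs <- mediate_pair(dat$a, dat$m, dat$cohort, se_method = "sobel")
  rb <- mediate_pair(dat$a, dat$m, dat$cohort, se_method = "bootstrap",
                     n_boot = 600, seed = 99)
  expect_lt(abs(rb$se_nie - rs$se_nie) / rs$se_nie, 0.15)
})

test_that("proportion mediated handles null, complete, inconsistent, and undefined cases", {
  base <- list(nie = 0, te = 1)
  class(base) <- "mediation_result"
  expect_equal(proportion_mediated(base)$estimate, 0)
  full <- structure(list(nie = 0.7, te = 0.7), class = "mediation_result")
  expect_equal(proportion_mediated(full)$estimate, 1)
  abstract_like <- structure(list(nie = 0.278, te = 1.07),
                             class = "mediation_result")
  expect_equal(proportion_mediated(abstract_like)$estimate, 0.26,
               tolerance = 0.01)
  incons <- structure(list(nie = -0.2, te = 0.5), class = "mediation_result")
  pm <- proportion_mediated(incons)
  expect_true(pm$inconsistent)
  undef <- structure(list(nie = 0.1, te = 1e-14), class = "mediation_result")
  expect_equal(proportion_mediated(undef)$status, "undefined")
  expect_true(is.na(proportion_mediated(undef)$estimate))
})

test_that("pairwise screen enumerates all pairs and flags failures without aborting", {
  set.seed(30)
  n <- 80
  A <- exp(matrix(stats::rnorm(n * 2), n, 2,
                  dimnames = list(NULL, c("phthalate_01", "phthalate_02"))))
  M <- exp(matrix(stats::rnorm(n * 3), n, 3,
                  dimnames = list(NULL, c("cox_01", "cox_02", "cox_03"))))
  ep <- exposure_panel(A, c(phthalate_01 = "phthalate",
                            phthalate_02 = "phthalate"))
  mp <- mediator_panel(M, c(cox_01 = "cox", cox_02 = "cox", cox_03 = "cox"))
  cohort <- make_cohort(stats::rnorm(n, 39))
  scr <- run_pairwise_screen(ep, mp, cohort)
  expect_equal(nrow(scr), 6)
  expect_true(all(scr$status == "ok"))
  expect_true(all(diff(match(scr$exposure_id,
                             c("phthalate_01", "phthalate_02"))) >= 0))

  # single pair
  scr1 <- run_pairwise_screen(
    exposure_panel(A[, 1, drop = FALSE], c(phthalate_01 = "phthalate")),
    mediator_panel(M[, 1, drop = FALSE], c(cox_01 = "cox")), cohort)
  expect_equal(nrow(scr1), 1)

  # a constant mediator produces a flagged row, not an error
  M_bad <- M; M_bad[, 2] <- 1
  mp_bad <- mediator_panel(M_bad, c(cox_01 = "cox", cox_02 = "cox",
                                    cox_03 = "cox"))
  scr_bad <- run_pairwise_screen(ep, mp_bad, cohort)
  expect_equal(nrow(scr_bad), 6)
  expect_equal(sum(grepl("error", scr_bad$status)), 2)
  expect_true(all(is.na(scr_bad$nie[grepl("error", scr_bad$status)])))
})

test_that("binary outcomes use the log-odds product with a rare-outcome warning", {
  set.seed(31)
  n <- 600
  a <- stats::rnorm(n)
  m <- 0.8 * a + stats::rnorm(n)
  lp <- -1 + 0.5 * m + 0.3 * a
  yb <- stats::rbinom(n, 1, stats::plogis(lp))
  y_cont <- 39 - lp + stats::rnorm(n)
  cohort <- make_cohort(y_cont)
  cohort$outcome_binary <- yb
  cohort$case_status <- factor(ifelse(yb == 1, "case", "control"),
                               levels = c("control", "case"))
  expect_warning(
    r <- mediate_pair(a, m, cohort, outcome_kind = "binary"),
    class = "mixmediate_rare_outcome_warning")
  expect_equal(r$nie, r$alpha_a * r$beta_m, tolerance = 1e-12)
  # binary TE comes from the mediator-omitted model, not the decomposition
  fit_te <- fit_weighted_logistic(yb, cbind(1, exposure = a),
                                  cohort$ipw_weight)
  expect_equal(r$te, unname(fit_te$coefficients["exposure"]),
               tolerance = 1e-8)
})

test_that("screen q-values are computed across the screen's NIE p-values", {
  sim <- generate_cohort(small_active_config(seed = 17))
  scr <- run_pairwise_screen(sim$exposures, sim$mediators, sim$cohort)
  expect_equal(nrow(scr), 4)
  expect_true(all(is.finite(scr$q_nie[scr$status == "ok"])))
  expect_true(all(scr$q_nie >= scr$p_nie * 0 &
                    scr$q_nie <= 1, na.rm = TRUE))
})
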