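#' Error-correlation sensitivity of the natural indirect effect
#'
#' In the linear mediation model the no-unmeasured-confounding assumption
#' for the mediator-outcome relation can be probed by positing a
#' correlation `rho` between the mediator-equation and outcome-equation
#' errors. For each `rho` the mediator-to-outcome coefficient is
#' re-identified in closed form from the observed fits,
#' \deqn{\beta_m(\rho) = \hat\beta_m -
#'   \rho\,\hat\sigma_Y / (\hat\sigma_M \sqrt{1-\rho^2}),}
#' and the adjusted indirect effect is `alpha_a * beta_m(rho)`. The
#' crossing point where the effect vanishes is root-found by bisection on
#' the bracketing grid interval, and is also reported on the
#' variance-explained parameterization: the product of the fractions of
#' total variance an unmeasured confounder would need to explain in the
#' two models for the effect to vanish.
#'
#' The computation is exact (no simulation), so repeated calls are
#' identical.
#'
#' @param mediation_fit a `mediation_result` from [mediate_pair()] with a
#'   continuous outcome.
#' @param rho_grid grid of error correlations in (-1, 1).
#' @return A `sensitivity_profile`: `rho_grid`, `nie_at_rho`, `rho_zero`
#'   (`NA` if the effect never crosses zero on the grid),
#'   `r2_product_zero` (total-variance parameterization),
#'   `r2_star_product_zero` (residual-variance parameterization).
#' @export
rho_sensitivity <- function(mediation_fit,
                            rho_grid = seq(-0.9, 0.9, by = 0.01)) {
  assert_that(inherits(mediation_fit, "mediation_result"),
              "mediation_fit must come from mediate_pair()")
  assert_that(mediation_fit$outcome_kind == "continuous",
              "rho sensitivity requires a continuous-outcome linear fit")
  assert_that(all(rho_grid > -1 & rho_grid < 1), "rho_grid must lie in (-1, 1)")
  alpha <- mediation_fit$alpha_a
  b_obs <- mediation_fit$beta_m
  sig_m <- sqrt(mediation_fit$fit_mediator$residual_variance)
  sig_y <- sqrt(mediation_fit$fit_outcome$residual_variance)

  beta_rho <- function(rho) b_obs - rho * sig_y / (sig_m * sqrt(1 - rho^2))
  nie_at_rho <- alpha * beta_rho(rho_grid)

  rho_zero <- NA_real_
  sgn <- sign(nie_at_rho)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (alpha != 0 && length(cross)) {
    lo <- rho_grid[cross[1]]; hi <- rho_grid[cross[1] + 1]
    for (i in seq_len(100)) {
      mid <- (lo + hi) / 2
      if (sign(beta_rho(mid)) == sign(beta_rho(lo))) lo <- mid else hi <- mid
    }
    rho_zero <- (lo + hi) / 2
  }

  # variance-explained parameterizations of the crossing point
  r2_star <- if (is.na(rho_zero)) NA_real_ else rho_zero^2
  r2_of <- function(fit, v) {
    mu <- sum(fit$weights * v) / sum(fit$weights)
    1 - sum(fit$weights * fit$residuals^2) / sum(fit$weights * (v - mu)^2)
  }
  m_obs <- mediation_fit$fit_mediator$fitted + mediation_fit$fit_mediator$residuals
  y_obs <- mediation_fit$fit_outcome$fitted + mediation_fit$fit_outcome$residuals
  r2_m <- r2_of(mediation_fit$fit_mediator, m_obs)
  r2_y <- r2_of(mediation_fit$fit_outcome, y_obs)
  r2_tilde <- if (is.na(rho_zero)) NA_real_ else
    rho_zero^2 * (1 - r2_m) * (1 - r2_y)

  structure(
    list(rho_grid = rho_grid, nie_at_rho = nie_at_rho, rho_zero = rho_zero,
         r2_product_zero = r2_tilde, r2_star_product_zero = r2_star,
         nie_hat = mediation_fit$nie),
    class = "sensitivity_profile"
  )
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf("<sensitivity_profile> NIE(rho = 0) = %.4f; crossing at rho = %s\n",
              x$nie_hat,
              if (is.na(x$rho_zero)) "none on grid" else sprintf("%.3f", x$rho_zero)))
  if (!is.na(x$r2_product_zero)) {
    cat(sprintf("  variance-explained product at crossing: %.3f (total), %.3f (residual)\n",
                x$r2_product_zero, x$r2_star_product_zero))
  }
  invisible(x)
}

#' E-value for an effect on a standardized continuous outcome
#'
#' Converts a standardized effect to an approximate risk ratio,
#' `RR = exp(0.91 * beta)`, and computes the E-value: the minimum strength
#' of association (risk-ratio scale) an unmeasured confounder would need
#' with both exposure and outcome to fully explain the effect,
#' `E = RR + sqrt(RR (RR - 1))` (after inverting RR < 1). The confidence
#' bound uses the interval limit closer to the null, with `E = 1` when the
#' interval crosses the null.
#'
#' @param beta_standardized effect estimate per standard deviation of the
#'   outcome.
#' @param se its standard error (0 allowed for a point-only E-value).
#' @param conf_level confidence level of the interval.
#' @param rr_constant the standardized-effect-to-risk-ratio constant.
#' @return Named numeric: `evalue`, `ci_bound`, `rr`.
#' @export
evalue_continuous <- function(beta_standardized, se, conf_level = 0.95,
                              rr_constant = 0.91) {
  assert_that(se >= 0, "standard error must be nonnegative")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rr <- exp(rr_constant * beta_standardized)
  rr_lo <- exp(rr_constant * (beta_standardized - z * se))
  rr_hi <- exp(rr_constant * (beta_standardized + z * se))
  ev <- function(r) {
    if (r < 1) r <- 1 / r
    if (r == 1) return(1)
    r + sqrt(r * (r - 1))
  }
  ci_bound <- if (rr_lo <= 1 && rr_hi >= 1) 1 else
    ev(if (rr > 1) rr_lo else rr_hi)
  c(evalue = ev(rr), ci_bound = ci_bound, rr = rr)
}

#' Mediation effect stability across covariate subsets
#'
#' Refits one exposure-mediator mediation model under every non-empty
#' subset of the conceptual covariates (63 subsets for the default roster
#' of 6) and summarizes the sign stability and range of the indirect
#' effect.
#'
#' @param exposure,mediator vectors as in [mediate_pair()].
#' @param cohort a `cohort_table`.
#' @param covariate_names covariates to scan (default: all cohort
#'   covariates).
#' @param ... passed to [mediate_pair()].
#' @return A data.frame with one row per subset (`covariates`, `n_covars`,
#'   `nie`, `te`, `p_nie`, `status`), with attributes
#'   `sign_stability` (largest fraction of estimable subsets sharing one
#'   NIE sign) and `nie_range`.
#' @export
covariate_combination_scan <- function(exposure, mediator, cohort,
                                       covariate_names = NULL, ...) {
  all_cov <- names(cohort_covariates(cohort))
  covariate_names <- covariate_names %||% all_cov
  assert_that(length(covariate_names) >= 1, "at least one covariate required")
  assert_that(all(covariate_names %in% all_cov),
              "unknown covariate(s): %s",
              paste(setdiff(covariate_names, all_cov), collapse = ", "))
  reserved <- c("subject_id", "outcome_continuous", "outcome_binary",
                "outcome_binary_spontaneous", "case_status", "ipw_weight")
  subsets <- unlist(lapply(seq_along(covariate_names), function(k)
    utils::combn(covariate_names, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(ss) {
    sub_cohort <- as.data.frame(cohort)[, c(reserved, ss), drop = FALSE]
    class(sub_cohort) <- class(cohort)
    r <- tryCatch(
      mediate_pair(exposure, mediator, sub_cohort, ...),
      error = function(e) e)
    if (inherits(r, "error")) {
      data.frame(covariates = paste(ss, collapse = ","),
                 n_covars = length(ss), nie = NA_real_, te = NA_real_,
                 p_nie = NA_real_,
                 status = paste0("error: ", conditionMessage(r)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(covariates = paste(ss, collapse = ","),
                 n_covars = length(ss), nie = r$nie, te = r$te,
                 p_nie = r$p_nie, status = "ok", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  ok <- out$status == "ok"
  if (any(ok)) {
    sg <- sign(out$nie[ok])
    attr(out, "sign_stability") <- max(mean(sg >= 0), mean(sg <= 0))
    attr(out, "nie_range") <- range(out$nie[ok])
  }
  out
}
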