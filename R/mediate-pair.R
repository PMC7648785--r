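#' Single exposure-mediator counterfactual mediation
#'
#' Fits the two-equation linear structural mediation model with inverse
#' probability weights: the mediator model (mediator on exposure and
#' covariates) and the outcome model (outcome on exposure, mediator, and
#' covariates). The natural indirect effect (NIE) is the product of
#' coefficients `alpha_a * beta_m`; the natural direct effect (NDE) is the
#' exposure coefficient of the outcome model. For a continuous outcome the
#' total effect is `NDE + NIE`; for a binary outcome (log-odds scale) the
#' total effect is the exposure coefficient of the outcome model with the
#' mediator omitted, and a structured warning notes the non-rare-outcome
#' caveat of odds-ratio mediation.
#'
#' @param exposure numeric vector, log-transformed exposure (or a
#'   standardized risk score).
#' @param mediator numeric vector, log-transformed mediator (or a
#'   standardized group effect).
#' @param cohort a `cohort_table` supplying covariates, outcomes, and
#'   `ipw_weight`.
#' @param outcome_kind `"continuous"` (gestational age, weeks),
#'   `"binary"` (overall preterm), or `"binary_spontaneous"`.
#' @param se_method `"sobel"` delta-method standard error for the NIE
#'   (default, used for full screens) or `"bootstrap"` (subject resampling
#'   with weights kept fixed as design constants).
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @param conf_level confidence level for NIE intervals.
#' @param exposure_id,mediator_id labels carried into the result.
#' @return A `mediation_result` list: `alpha_a`, `beta_m`, `beta_a` (NDE),
#'   `nie`, `te`, `prop_mediated`, `se_nie`, `ci_low`, `ci_high`, `p_nie`,
#'   `p_te`, `p_nde`, `outcome_kind`, plus the two `fit_result`s
#'   (`fit_mediator`, `fit_outcome`) for downstream sensitivity analyses.
#' @export
mediate_pair <- function(exposure, mediator, cohort,
                         outcome_kind = c("continuous", "binary",
                                          "binary_spontaneous"),
                         se_method = c("sobel", "bootstrap"),
                         n_boot = 1000, seed = 1L, conf_level = 0.95,
                         exposure_id = "exposure", mediator_id = "mediator") {
  outcome_kind <- match.arg(outcome_kind)
  se_method <- match.arg(se_method)
  assert_that(stats::sd(exposure) > 0, "exposure has zero variance")
  assert_that(stats::sd(mediator) > 0, "mediator has zero variance")

  y <- switch(outcome_kind,
              continuous = cohort$outcome_continuous,
              binary = cohort$outcome_binary,
              binary_spontaneous = cohort$outcome_binary_spontaneous)
  keep <- !is.na(y)
  y <- y[keep]
  a <- exposure[keep]; m <- mediator[keep]
  w <- cohort$ipw_weight[keep]
  Xc <- covariate_design(cohort_covariates(cohort)[keep, , drop = FALSE])

  est <- mediation_estimates(y, a, m, Xc, w, outcome_kind)

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (se_method == "sobel") {
    se_nie <- sqrt(est$alpha_a^2 * est$se_beta_m^2 + est$beta_m^2 * est$se_alpha_a^2)
    ci <- est$nie + c(-1, 1) * z * se_nie
  } else {
    set.seed(seed)
    n <- length(y)
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      eb <- tryCatch(
        mediation_estimates(y[idx], a[idx], m[idx], Xc[idx, , drop = FALSE],
                            w[idx], outcome_kind),
        error = function(e) NULL)
      if (is.null(eb)) NA_real_ else eb$nie
    }, numeric(1))
    boot <- boot[is.finite(boot)]
    se_nie <- stats::sd(boot)
    ci <- unname(stats::quantile(boot, c((1 - conf_level) / 2,
                                         1 - (1 - conf_level) / 2)))
  }
  p_nie <- if (se_nie > 0) 2 * stats::pnorm(-abs(est$nie) / se_nie) else
    as.numeric(est$nie == 0)

  if (outcome_kind != "continuous") {
    warn_mm(paste0("binary-outcome NIE is on the log-odds scale; the ",
                   "product-of-coefficients decomposition is approximate ",
                   "unless the outcome is rare"),
            class = "mixmediate_rare_outcome_warning")
  }

  res <- structure(
    c(list(exposure_id = exposure_id, mediator_id = mediator_id),
      est[c("alpha_a", "beta_m", "beta_a", "nie", "te",
            "se_alpha_a", "se_beta_m", "se_nde", "se_te")],
      list(se_nie = se_nie, ci_low = ci[1], ci_high = ci[2],
           p_nie = p_nie, p_nde = est$p_nde, p_te = est$p_te,
           outcome_kind = outcome_kind, se_method = se_method,
           fit_mediator = est$fit_mediator, fit_outcome = est$fit_outcome)),
    class = "mediation_result"
  )
  res$prop_mediated <- proportion_mediated(res)$estimate
  res
}

# Point estimates and per-path SEs for one pair; shared by the bootstrap.
mediation_estimates <- function(y, a, m, Xc, w, outcome_kind) {
  n <- length(y)
  X_med <- cbind(`(Intercept)` = 1, exposure = a, Xc)
  fit_m <- fit_weighted_linear(m, X_med, w)
  alpha_a <- unname(fit_m$coefficients["exposure"])
  se_alpha <- unname(fit_m$standard_errors["exposure"])

  X_out <- cbind(`(Intercept)` = 1, exposure = a, mediator = m, Xc)
  if (outcome_kind == "continuous") {
    fit_y <- fit_weighted_linear(y, X_out, w)
  } else {
    fit_y <- fit_weighted_logistic(y, X_out, w)
  }
  beta_a <- unname(fit_y$coefficients["exposure"])
  beta_m <- unname(fit_y$coefficients["mediator"])
  se_beta_m <- unname(fit_y$standard_errors["mediator"])
  se_nde <- unname(fit_y$standard_errors["exposure"])
  nie <- alpha_a * beta_m

  if (outcome_kind == "continuous") {
    te <- beta_a + nie
    # TE inference from the marginal (mediator-omitted) model; identical
    # point estimate by the nested-WLS algebraic identity
    fit_te <- fit_weighted_linear(y, X_med, w)
    se_te <- unname(fit_te$standard_errors["exposure"])
  } else {
    fit_te <- fit_weighted_logistic(y, X_med, w)
    te <- unname(fit_te$coefficients["exposure"])
    se_te <- unname(fit_te$standard_errors["exposure"])
  }
  list(alpha_a = alpha_a, beta_m = beta_m, beta_a = beta_a, nie = nie, te = te,
       se_alpha_a = se_alpha, se_beta_m = se_beta_m, se_nde = se_nde,
       se_te = se_te,
       p_nde = 2 * stats::pnorm(-abs(beta_a) / se_nde),
       p_te = 2 * stats::pnorm(-abs(te) / se_te),
       fit_mediator = fit_m, fit_outcome = fit_y)
}

#' Proportion of the total effect transmitted through the mediator
#'
#' `NIE / TE`, flagged as inconsistent mediation when the indirect and total
#' effects disagree in sign, and returned as an undefined sentinel (`NA`
#' with status) when the total effect is numerically zero.
#'
#' @param result a `mediation_result`.
#' @param tol magnitude below which the total effect is treated as zero.
#' @return List with `estimate`, `inconsistent` (logical), `status`
#'   (`"ok"` or `"undefined"`).
#' @export
proportion_mediated <- function(result, tol = 1e-10) {
  nie <- result$nie; te <- result$te
  if (abs(te) < tol) {
    return(list(estimate = NA_real_, inconsistent = NA, status = "undefined"))
  }
  list(estimate = nie / te,
       inconsistent = (sign(nie) != sign(te)) && nie != 0,
       status = "ok")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s ~ %s (%s outcome)\n",
              x$exposure_id, x$mediator_id, x$outcome_kind))
  cat(sprintf("  NIE = %.4f (se %.4f, %s), NDE = %.4f, TE = %.4f, prop. mediated = %.3f\n",
              x$nie, x$se_nie, x$se_method, x$beta_a, x$te,
              x$prop_mediated %||% NA))
  invisible(x)
}

#' Exhaustive pairwise exposure-by-mediator mediation screen
#'
#' Runs [mediate_pair()] for every (analyte, biomarker) combination -- the
#' one-at-a-time screen over all p x q pathways (2318 models at the default
#' study dimensions) -- and attaches false-discovery q-values across the
#' screen's NIE p-values. Per-pair failures are recorded as flagged rows;
#' the screen never aborts.
#'
#' @param exposures an [exposure_panel()] (raw or log; logged internally).
#' @param mediators a [mediator_panel()].
#' @param cohort a `cohort_table`.
#' @param outcome_kind as in [mediate_pair()].
#' @param standardize z-score features after logging (used when exposures
#'   are risk scores; the plain analyte screen is log-only).
#' @param qvalue_method passed to [qvalues()].
#' @return A data.frame, one row per pair in deterministic order (exposure
#'   class, analyte, mediator group, biomarker), with the effect
#'   decomposition, p-values, `q_nie`, and a `status` column.
#' @export
run_pairwise_screen <- function(exposures, mediators, cohort,
                                outcome_kind = "continuous",
                                standardize = FALSE,
                                qvalue_method = "storey") {
  A <- panel_log(exposures, standardize = standardize)
  M <- panel_log(mediators, standardize = standardize)
  screen_matrices(A$values, A$map, M$values, M$map, cohort, outcome_kind,
                  qvalue_method)
}

screen_matrices <- function(Av, Amap, Mv, Mmap, cohort, outcome_kind,
                            qvalue_method = "storey") {
  rows <- vector("list", ncol(Av) * ncol(Mv))
  k <- 0
  for (j in seq_len(ncol(Av))) {
    for (l in seq_len(ncol(Mv))) {
      k <- k + 1
      rows[[k]] <- tryCatch({
        r <- suppressWarnings(mediate_pair(
          Av[, j], Mv[, l], cohort, outcome_kind = outcome_kind,
          se_method = "sobel",
          exposure_id = colnames(Av)[j], mediator_id = colnames(Mv)[l]))
        data.frame(
          exposure_id = r$exposure_id, exposure_class = unname(Amap[j]),
          mediator_id = r$mediator_id, mediator_group = unname(Mmap[l]),
          alpha_a = r$alpha_a, beta_m = r$beta_m, beta_a = r$beta_a,
          nie = r$nie, te = r$te, prop_mediated = r$prop_mediated,
          se_nie = r$se_nie, ci_low = r$ci_low, ci_high = r$ci_high,
          p_nie = r$p_nie, p_nde = r$p_nde, p_te = r$p_te,
          outcome_kind = outcome_kind, status = "ok",
          stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(
          exposure_id = colnames(Av)[j], exposure_class = unname(Amap[j]),
          mediator_id = colnames(Mv)[l], mediator_group = unname(Mmap[l]),
          alpha_a = NA_real_, beta_m = NA_real_, beta_a = NA_real_,
          nie = NA_real_, te = NA_real_, prop_mediated = NA_real_,
          se_nie = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          p_nie = NA_real_, p_nde = NA_real_, p_te = NA_real_,
          outcome_kind = outcome_kind,
          status = paste0("error: ", conditionMessage(e)),
          stringsAsFactors = FALSE)
      })
    }
  }
  out <- do.call(rbind, rows)
  ok <- out$status == "ok" & is.finite(out$p_nie)
  out$q_nie <- NA_real_
  if (any(ok)) out$q_nie[ok] <- qvalues(out$p_nie[ok], method = qvalue_method)
  out
}
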