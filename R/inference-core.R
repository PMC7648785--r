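#' Inverse probability weights for nested case-control sampling
#'
#' Cases are deliberately over-represented in the analytic subset; weighting
#' each subject by the reciprocal of its stratum's selection probability
#' makes weighted analyses representative of the source cohort.
#'
#' @param case_status factor/character vector for the sampled subjects
#'   (`"case"` / `"control"`).
#' @param cohort_case_count,cohort_control_count stratum totals in the full
#'   source cohort.
#' @return Numeric vector of weights, constant within each stratum.
#' @export
compute_ipw <- function(case_status, cohort_case_count, cohort_control_count) {
  status <- as.character(case_status)
  assert_that(all(status %in% c("case", "control")),
              "case_status must be 'case' or 'control'")
  assert_that(any(status == "case") && any(status == "control"),
              "both strata must be present in the sample")
  pr <- selection_probabilities(status, cohort_case_count, cohort_control_count)
  unname(1 / pr[status])
}

#' Weighted linear regression with design-robust standard errors
#'
#' Weighted least squares used by every mediation stage, with HC0 sandwich
#' (design-robust) standard errors appropriate for inverse-probability
#' weighting. With equal weights it reduces to ordinary least squares.
#'
#' @param y numeric response.
#' @param design numeric model matrix including any intercept column; must
#'   have full column rank.
#' @param weights positive weights, one per row.
#' @return A `fit_result`: list with `coefficients`, `standard_errors`
#'   (sandwich), `vcov`, `residual_variance`, `residuals`, `fitted`,
#'   `n_used`, `model_kind`.
#' @export
fit_weighted_linear <- function(y, design, weights = rep(1, length(y))) {
  design <- as.matrix(design)
  assert_that(length(y) == nrow(design) && length(weights) == nrow(design),
              "y, design, and weights must have matching rows")
  assert_that(all(weights > 0), "weights must be strictly positive")
  check_full_rank(design)
  fit <- stats::lm.wfit(design, y, weights)
  coef <- fit$coefficients
  res <- y - drop(design %*% coef)
  XtWX_inv <- chol2inv(chol(crossprod(design * sqrt(weights))))
  meat <- crossprod(design * (weights * res))
  V <- XtWX_inv %*% meat %*% XtWX_inv
  sw <- sum(weights)
  new_fit_result(
    coefficients = coef,
    vcov = V,
    residual_variance = sum(weights * res^2) / (sw - ncol(design)),
    residuals = res, fitted = drop(design %*% coef),
    n_used = length(y), model_kind = "linear", weights = weights
  )
}

#' Weighted logistic regression with design-robust standard errors
#'
#' Weighted maximum-likelihood logit fit (via [stats::glm()] with a
#' quasibinomial family so non-integer inverse-probability weights are
#' legitimate), with HC0 sandwich standard errors. Perfect separation and
#' non-convergence raise errors rather than returning silently divergent
#' estimates.
#'
#' @inheritParams fit_weighted_linear
#' @param y binary 0/1 response containing both classes.
#' @export
fit_weighted_logistic <- function(y, design, weights = rep(1, length(y))) {
  design <- as.matrix(design)
  assert_that(all(y %in% c(0, 1)), "y must be binary 0/1")
  assert_that(length(unique(y)) == 2, "binary outcome has a single class")
  assert_that(all(weights > 0), "weights must be strictly positive")
  check_full_rank(design)
  fit <- suppressWarnings(stats::glm.fit(design, y, weights = weights,
                                         family = stats::quasibinomial()))
  mu <- fit$fitted.values
  eps <- 1e-8
  if (any(mu < eps | mu > 1 - eps) && max(abs(fit$coefficients)) > 15) {
    stop_mm("perfect or quasi-perfect separation detected in logistic fit",
            class = "mixmediate_separation_error")
  }
  if (!fit$converged) {
    stop_mm("weighted logistic fit did not converge after %d IWLS iterations",
            fit$iter, class = "mixmediate_convergence_error")
  }
  coef <- fit$coefficients
  # sandwich: bread = expected information inverse, meat = weighted score outer product
  w_irls <- weights * mu * (1 - mu)
  bread <- chol2inv(chol(crossprod(design * sqrt(w_irls))))
  score <- design * (weights * (y - mu))
  V <- bread %*% crossprod(score) %*% bread
  new_fit_result(
    coefficients = coef, vcov = V,
    residual_variance = NA_real_,
    residuals = y - mu, fitted = mu,
    n_used = length(y), model_kind = "logistic", weights = weights
  )
}

new_fit_result <- function(coefficients, vcov, residual_variance, residuals,
                           fitted, n_used, model_kind, weights) {
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- names(coefficients)
  structure(
    list(coefficients = coefficients, standard_errors = se, vcov = vcov,
         residual_variance = residual_variance, residuals = residuals,
         fitted = fitted, n_used = n_used, model_kind = model_kind,
         weights = weights),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model, n = %d\n", x$model_kind, x$n_used))
  print(cbind(estimate = x$coefficients, se = x$standard_errors))
  invisible(x)
}

check_full_rank <- function(design) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop_mm("design matrix is rank deficient; collinear column(s): %s",
            paste(dropped %||% "(unnamed)", collapse = ", "),
            class = "mixmediate_rank_error")
  }
  invisible(TRUE)
}

#' False discovery rate q-values
#'
#' Benjamini-Hochberg step-up q-values, or Storey q-values with the null
#' proportion pi0 estimated on a lambda grid with a cubic smoother
#' (the default in the genomics literature this screen follows).
#'
#' @param p numeric p-values in [0, 1].
#' @param method `"storey"` (default) or `"bh"`.
#' @param lambda grid for Storey's pi0 estimate.
#' @return q-values, same length and order as `p`.
#' @export
qvalues <- function(p, method = c("storey", "bh"),
                    lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  assert_that(all(is.finite(p)) && all(p >= 0 & p <= 1),
              "p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (method == "bh") return(stats::p.adjust(p, method = "BH"))
  pi0 <- storey_pi0(p, lambda)
  q_bh <- stats::p.adjust(p, method = "BH")
  pmin(1, pi0 * q_bh)
}

# Storey's pi0: fraction of p-values above each lambda, smoothed with a
# natural cubic spline and read off at the largest lambda. Degenerates
# gracefully to 1 for tiny m or flat histograms.
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m < 20) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1 / m), 1)
}

#' Weighted descriptive statistics for a cohort table
#'
#' Weighted medians and interquartile ranges for continuous variables and
#' weighted percentages for categorical variables, using the inverse
#' probability weights so the table describes the source cohort rather than
#' the case-enriched subset.
#'
#' @param cohort a `cohort_table`.
#' @return A data.frame with columns `variable`, `level`, `statistic`,
#'   `value`.
#' @export
weighted_descriptives <- function(cohort) {
  assert_that(inherits(cohort, "cohort_table"), "cohort must be a cohort_table")
  w <- cohort$ipw_weight
  covars <- cohort_covariates(cohort)
  covars$gestational_age <- cohort$outcome_continuous
  covars$case_status <- cohort$case_status
  rows <- list()
  for (v in names(covars)) {
    x <- covars[[v]]
    if (is.numeric(x) && length(unique(x)) > 2) {
      qs <- weighted_quantile(x, w, c(0.25, 0.5, 0.75))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = NA_character_,
        statistic = c("median", "iqr"),
        value = c(qs[2], qs[3] - qs[1])
      )
    } else {
      x <- factor(x)
      pct <- vapply(levels(x), function(l) 100 * sum(w[x == l]) / sum(w), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = levels(x),
        statistic = "weighted_pct", value = unname(pct)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Weighted quantiles on the interpolated weighted empirical CDF
#'
#' @param x numeric values.
#' @param w positive weights.
#' @param probs quantile levels in [0, 1].
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs = 0.5) {
  assert_that(length(x) == length(w) && all(w > 0), "weights must be positive, one per value")
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)
  vapply(probs, function(pp) {
    if (pp <= cw[1]) return(x[1])
    if (pp >= cw[length(cw)]) return(x[length(x)])
    stats::approx(cw, x, xout = pp, ties = "ordered")$y
  }, numeric(1))
}
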