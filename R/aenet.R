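#' Adaptive elastic net for one exposure class
#'
#' Estimates per-analyte weights for an environmental risk score (ERS) by
#' minimizing
#' \deqn{\frac1n\sum_i (y_i - \gamma_c C_i - \gamma_k A_{ik})^2
#'   + \lambda_1 \sum_j w_j |\gamma_{kj}|
#'   + \frac{\lambda_2}{2} \sum_j \gamma_{kj}^2,}
#' with covariates unpenalized and coefficient-specific adaptive L1 weights
#' \eqn{w_j = (|\gamma^{init}_j| + 1/n)^{-1}} taken from an initial
#' ridge fit at its own cross-validated penalty. The solver is cyclic
#' coordinate descent with exact soft-threshold updates; the
#' Karush-Kuhn-Tucker conditions are verified at the returned solution.
#' `(lambda1, lambda2)` are selected on a two-dimensional grid by seeded
#' k-fold cross-validation of squared prediction error.
#'
#' @param y continuous outcome (gestational age at delivery, weeks).
#' @param exposures_k numeric matrix of the class's analytes,
#'   log-transformed and standardized.
#' @param covariates data.frame or matrix of covariates (dummy-coded
#'   internally, always unpenalized); may be `NULL`.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed seed controlling fold assignment (folds are a pure function
#'   of `(seed, n)`).
#' @param lambda2_grid ridge penalties searched.
#' @param n_lambda1 number of L1 penalties per ridge level, log-spaced over
#'   four decades down from the smallest all-zero penalty.
#' @param class_k label stored on the model.
#' @param adaptive_weights optional fixed adaptive weights (length
#'   `ncol(exposures_k)`), bypassing the initial ridge fit.
#' @return A `risk_score_model`: `class_k`, `gamma_k`, `adaptive_weights`,
#'   `lambda1`, `lambda2`, `cv_folds`, `cv_error_path` (data.frame over the
#'   grid), `ers` (standardized in-sample score), `degenerate` flag,
#'   `kkt_max_violation`, and the unpenalized coefficients.
#' @export
fit_adaptive_elastic_net <- function(y, exposures_k, covariates = NULL,
                                     folds = 5, seed = 1L,
                                     lambda2_grid = c(0, 0.01, 0.1, 1, 10),
                                     n_lambda1 = 50, class_k = "class",
                                     adaptive_weights = NULL) {
  A <- as.matrix(exposures_k)
  n <- length(y)
  assert_that(nrow(A) == n, "y and exposures_k must have matching rows")
  assert_that(folds >= 2, "folds must be at least 2")
  Xc <- cbind(`(Intercept)` = rep(1, n), covariate_design(covariates))

  if (is.null(adaptive_weights)) {
    lam2_init <- cv_ridge_lambda(y, A, Xc, folds, child_seed(seed, "init"))
    g_init <- aenet_cd(y, A, Xc, lambda1 = 0, lambda2 = lam2_init,
                       w_ad = rep(1, ncol(A)))$gamma
    adaptive_weights <- 1 / (abs(g_init) + 1 / n)
  }
  assert_that(length(adaptive_weights) == ncol(A) && all(adaptive_weights > 0),
              "adaptive_weights must be positive, one per analyte")

  # lambda1 path: from the smallest penalty that zeroes every coefficient
  # (given the adaptive weights) down four decades
  e0 <- stats::lm.fit(Xc, y)$residuals
  lam_max <- max((2 / n) * abs(crossprod(A, e0)) / adaptive_weights)
  lam1_path <- exp(seq(log(lam_max), log(lam_max * 1e-4),
                       length.out = n_lambda1))

  fold_id <- cv_fold_ids(n, folds, child_seed(seed, "cv"))
  grid <- expand.grid(lambda1 = lam1_path, lambda2 = lambda2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cv_err <- matrix(0, nrow(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    prep <- aenet_prep(y[tr], A[tr, , drop = FALSE], Xc[tr, , drop = FALSE])
    g_warm <- NULL
    for (gi in seq_len(nrow(grid))) {
      fit <- aenet_solve(prep, grid$lambda1[gi], grid$lambda2[gi],
                         adaptive_weights, init = g_warm, tol = 1e-7)
      g_warm <- fit$gamma
      pred <- drop(A[!tr, , drop = FALSE] %*% fit$gamma +
                     Xc[!tr, , drop = FALSE] %*% fit$gamma_c)
      cv_err[gi, f] <- mean((y[!tr] - pred)^2)
    }
  }
  mean_err <- rowMeans(cv_err)
  best <- which.min(mean_err)

  fit <- aenet_cd(y, A, Xc, grid$lambda1[best], grid$lambda2[best],
                  adaptive_weights)
  kkt <- aenet_kkt(y, A, Xc, fit$gamma, fit$gamma_c, grid$lambda1[best],
                   grid$lambda2[best], adaptive_weights)
  degenerate <- all(fit$gamma == 0)
  if (degenerate) {
    warn_mm("all class '%s' coefficients are zero at the selected penalty; the class carries no detectable signal",
            class_k, class = "mixmediate_null_class_warning")
  }
  ers <- drop(A %*% fit$gamma)
  if (!degenerate) ers <- drop(scale(ers))

  structure(
    list(class_k = class_k, gamma_k = stats::setNames(fit$gamma, colnames(A)),
         adaptive_weights = adaptive_weights,
         lambda1 = grid$lambda1[best], lambda2 = grid$lambda2[best],
         cv_folds = folds,
         cv_error_path = cbind(grid, cv_error = mean_err),
         gamma_c = fit$gamma_c, ers = ers, degenerate = degenerate,
         kkt_max_violation = kkt, seed = seed),
    class = "risk_score_model"
  )
}

#' @export
print.risk_score_model <- function(x, ...) {
  cat(sprintf("<risk_score_model> class '%s': %d/%d nonzero weights, lambda1 = %.4g, lambda2 = %.4g%s\n",
              x$class_k, sum(x$gamma_k != 0), length(x$gamma_k),
              x$lambda1, x$lambda2,
              if (x$degenerate) " [degenerate: no signal]" else ""))
  invisible(x)
}

# Solver state for one dataset: the unpenalized block (intercept +
# covariates) is partialled out exactly once (Frisch-Waugh-Lovell: with an
# unpenalized covariate block, the penalized coefficients solve the
# residualized problem), and coordinate descent then runs in covariance
# form, O(p) per coordinate update.
aenet_prep <- function(y, A, Xc) {
  Q <- qr(Xc)
  Ar <- qr.resid(Q, A)
  yr <- qr.resid(Q, y)
  n <- length(y)
  list(AtA = crossprod(Ar) / n, Aty = drop(crossprod(Ar, yr)) / n,
       col_ss = colSums(Ar^2) / n, Q = Q, n = n, y = y, A = A)
}

aenet_solve <- function(prep, lambda1, lambda2, w_ad, init = NULL,
                        tol = 1e-10, max_iter = 10000) {
  p <- length(prep$Aty)
  gamma <- init %||% rep(0, p)
  AtA <- prep$AtA; Aty <- prep$Aty; css <- prep$col_ss
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      gj_old <- gamma[j]
      u <- Aty[j] - sum(AtA[j, ] * gamma) + css[j] * gj_old
      gj <- soft_threshold(2 * u, lambda1 * w_ad[j]) / (2 * css[j] + lambda2)
      if (gj != gj_old) {
        delta <- max(delta, abs(gj - gj_old))
        gamma[j] <- gj
      }
    }
    if (delta < tol) break
  }
  gamma_c <- drop(qr.coef(prep$Q, prep$y - drop(prep$A %*% gamma)))
  list(gamma = gamma, gamma_c = gamma_c, iterations = it)
}

# full-data entry point kept for oracle checks and one-off fits
aenet_cd <- function(y, A, Xc, lambda1, lambda2, w_ad, init = NULL,
                     tol = 1e-10, max_iter = 10000) {
  aenet_solve(aenet_prep(y, A, Xc), lambda1, lambda2, w_ad, init = init,
              tol = tol, max_iter = max_iter)
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Maximum KKT stationarity violation at a candidate solution.
aenet_kkt <- function(y, A, Xc, gamma, gamma_c, lambda1, lambda2, w_ad) {
  n <- length(y)
  e <- y - drop(A %*% gamma) - drop(Xc %*% gamma_c)
  g <- -(2 / n) * drop(crossprod(A, e)) + lambda2 * gamma
  viol <- ifelse(gamma != 0,
                 abs(g + lambda1 * w_ad * sign(gamma)),
                 pmax(abs(g) - lambda1 * w_ad, 0))
  viol_c <- abs(drop(crossprod(Xc, e))) / n
  max(c(viol, viol_c))
}

cv_fold_ids <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

cv_ridge_lambda <- function(y, A, Xc, folds, seed,
                            grid = 10^seq(-3, 2, length.out = 20)) {
  fold_id <- cv_fold_ids(length(y), folds, seed)
  preps <- lapply(seq_len(folds), function(f)
    aenet_prep(y[fold_id != f], A[fold_id != f, , drop = FALSE],
               Xc[fold_id != f, , drop = FALSE]))
  err <- vapply(grid, function(l2) {
    e <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- aenet_solve(preps[[f]], lambda1 = 0, lambda2 = l2,
                         w_ad = rep(1, ncol(A)), tol = 1e-7)
      pred <- drop(A[!tr, , drop = FALSE] %*% fit$gamma +
                     Xc[!tr, , drop = FALSE] %*% fit$gamma_c)
      e <- e + sum((y[!tr] - pred)^2)
    }
    e
  }, numeric(1))
  grid[which.min(err)]
}

#' Compute an environmental risk score from a fitted model
#'
#' The per-subject linear combination of (identically transformed) class
#' analytes with the adaptive-elastic-net weights, then standardized.
#'
#' @param exposures_k analyte matrix transformed exactly as in the fit.
#' @param model a `risk_score_model`.
#' @return Standardized numeric score per subject; a zero constant vector
#'   (with a warning) if the model is degenerate.
#' @export
compute_ers <- function(exposures_k, model) {
  A <- as.matrix(exposures_k)
  assert_that(ncol(A) == length(model$gamma_k),
              "exposure columns (%d) do not match model weights (%d)",
              ncol(A), length(model$gamma_k))
  if (!is.null(colnames(A)) && !is.null(names(model$gamma_k))) {
    assert_that(identical(colnames(A), names(model$gamma_k)),
                "exposure column names do not match model weights")
  }
  s <- drop(A %*% model$gamma_k)
  if (model$degenerate || stats::sd(s) == 0) {
    warn_mm("degenerate risk score (all weights zero): returning constant 0",
            class = "mixmediate_degenerate_ers_warning")
    return(rep(0, nrow(A)))
  }
  drop(scale(s))
}

#' Build the four-class environmental risk score panel
#'
#' Fits one adaptive elastic net per exposure class against the continuous
#' outcome and assembles the standardized scores into a subjects-by-classes
#' matrix that replaces the raw analyte panel in downstream mediation.
#'
#' @param exposures an [exposure_panel()] (logged and standardized
#'   internally).
#' @param cohort a `cohort_table` supplying outcome and covariates.
#' @param folds,seed cross-validation controls per class.
#' @param ... further arguments (e.g. `n_lambda1`, `lambda2_grid`) passed
#'   to [fit_adaptive_elastic_net()].
#' @return List with `scores` (n x K matrix, one standardized ERS per
#'   class) and `models` (named list of `risk_score_model`s).
#' @export
build_ers_panel <- function(exposures, cohort, folds = 5, seed = 1L, ...) {
  Az <- panel_log(exposures, standardize = TRUE)
  classes <- unique(unname(Az$map))
  covars <- cohort_covariates(cohort)
  y <- cohort$outcome_continuous
  models <- list()
  scores <- matrix(0, nrow(Az$values), length(classes),
                   dimnames = list(NULL, paste0("ers_", classes)))
  for (k in seq_along(classes)) {
    cols <- names(Az$map)[Az$map == classes[k]]
    models[[classes[k]]] <- withCallingHandlers(
      fit_adaptive_elastic_net(y, Az$values[, cols, drop = FALSE], covars,
                               folds = folds,
                               seed = child_seed(seed, classes[k]),
                               class_k = classes[k], ...),
      mixmediate_null_class_warning = function(w) invokeRestart("muffleWarning"))
    if (!models[[classes[k]]]$degenerate) {
      scores[, k] <- models[[classes[k]]]$ers
    }
  }
  list(scores = scores, models = models)
}

#' Mediation screen of environmental risk scores against all mediators
#'
#' Each standardized class score enters [mediate_pair()] one-at-a-time as
#' the exposure against every log-standardized mediator: K x q models
#' (244 at the default study dimensions).
#'
#' @param ers_panel result of [build_ers_panel()], or a numeric score
#'   matrix with one column per class.
#' @param mediators a [mediator_panel()].
#' @param cohort a `cohort_table`.
#' @param qvalue_method passed to [qvalues()].
#' @return Screen data.frame as in [run_pairwise_screen()].
#' @export
ers_mediation_screen <- function(ers_panel, mediators, cohort,
                                 qvalue_method = "storey") {
  scores <- if (is.list(ers_panel) && !is.null(ers_panel$scores))
    ers_panel$scores else as.matrix(ers_panel)
  Amap <- stats::setNames(sub("^ers_", "", colnames(scores)), colnames(scores))
  M <- panel_log(mediators, standardize = TRUE)
  screen_matrices(scores, Amap, M$values, M$map, cohort,
                  outcome_kind = "continuous", qvalue_method = qvalue_method)
}

#' Persist a risk score model as JSON
#'
#' @param model a `risk_score_model`.
#' @param path output file.
#' @export
write_risk_score_model <- function(model, path) {
  jsonlite::write_json(
    list(class_k = model$class_k,
         gamma_k = as.list(model$gamma_k),
         adaptive_weights = unname(model$adaptive_weights),
         lambda1 = model$lambda1, lambda2 = model$lambda2,
         cv_folds = model$cv_folds, seed = model$seed,
         degenerate = model$degenerate),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
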