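#' Pathway lasso: penalizing the product of mediation path coefficients
#'
#' Jointly fits the mediator equations (each mediator on the exposure) and
#' the outcome equation (outcome on exposure and all mediators),
#' penalizing each pathway by
#' \deqn{\lambda(|\alpha_j\beta_j| + \phi(\alpha_j^2+\beta_j^2))
#'   + \omega(|\alpha_j|+|\beta_j|),}
#' so that shrinkage acts directly on the indirect-effect products.
#' Covariates and the direct effect are unpenalized (covariates are
#' partialled out exactly beforehand). The solver is block coordinate
#' descent with an exact closed-form solution of every 2-by-2
#' (alpha_j, beta_j) subproblem obtained by sign-quadrant enumeration;
#' the objective is non-increasing across iterations. With `phi >= 1/2`
#' every subproblem is strictly convex.
#'
#' @param exposure numeric vector (standardized).
#' @param mediators numeric matrix, n x q (standardized columns).
#' @param outcome numeric vector (standardized or centered).
#' @param covariates optional covariates, always unpenalized.
#' @param lambda_path decreasing penalty sequence; `NULL` for 30
#'   log-spaced values from the smallest all-zero penalty down three
#'   decades.
#' @param omega_ratio ratio of the plain L1 penalty to `lambda`.
#' @param phi convexifying quadratic weight.
#' @param cv_folds folds for selecting `lambda` by cross-validated
#'   combined residual loss (`0` skips selection).
#' @param seed fold seed.
#' @param tol,max_iter convergence controls (maximum coefficient change).
#' @return A `pathway_selection`: `path` (data.frame per lambda:
#'   `lambda`, `n_selected`, `converged`, `objective`, optional
#'   `cv_error`), `fits` (list per lambda with `alpha_hat`, `beta_hat`,
#'   `beta_a`, `selected`), `lambda_selected`, `selected` (mediator ids at
#'   the selected lambda), `method = "pathway_lasso"`.
#' @export
pathway_lasso_fit <- function(exposure, mediators, outcome,
                              covariates = NULL, lambda_path = NULL,
                              omega_ratio = 1, phi = 2, cv_folds = 5,
                              seed = 1L, tol = 1e-8, max_iter = 2000) {
  M <- as.matrix(mediators)
  n <- length(outcome)
  q <- ncol(M)
  med_ids <- colnames(M) %||% paste0("m", seq_len(q))
  colnames(M) <- med_ids

  rd <- residualize_on_covariates(outcome, exposure, M, covariates)

  if (is.null(lambda_path)) {
    c1 <- sum(rd$a^2) / n
    atil <- drop(crossprod(rd$M, rd$a)) / sum(rd$a^2)
    cs <- colSums(rd$M^2) / n
    btil <- drop(crossprod(rd$M, rd$y)) / colSums(rd$M^2)
    lam_max <- max(c(c1 * abs(atil), cs * abs(btil))) / omega_ratio * 1.05
    lambda_path <- exp(seq(log(lam_max), log(lam_max * 1e-3), length.out = 30))
  }
  lambda_path <- sort(lambda_path, decreasing = TRUE)

  fits <- plasso_path(rd$y, rd$a, rd$M, lambda_path, omega_ratio, phi, tol,
                      max_iter)

  cv_error <- rep(NA_real_, length(lambda_path))
  if (cv_folds >= 2) {
    fold_id <- cv_fold_ids(n, cv_folds, child_seed(seed, "plasso_cv"))
    errs <- matrix(0, length(lambda_path), cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- fold_id != f
      ftr <- plasso_path(rd$y[tr], rd$a[tr], rd$M[tr, , drop = FALSE],
                         lambda_path, omega_ratio, phi, tol, max_iter)
      for (li in seq_along(lambda_path)) {
        al <- ftr[[li]]$alpha_hat; be <- ftr[[li]]$beta_hat
        ba <- ftr[[li]]$beta_a
        e_med <- rd$M[!tr, , drop = FALSE] - outer(rd$a[!tr], al)
        e_out <- rd$y[!tr] - rd$a[!tr] * ba -
          drop(rd$M[!tr, , drop = FALSE] %*% be)
        errs[li, f] <- mean(e_out^2) + mean(e_med^2)
      }
    }
    cv_error <- rowMeans(errs)
    cv_se <- apply(errs, 1, stats::sd) / sqrt(cv_folds)
  }

  path <- data.frame(
    lambda = lambda_path,
    n_selected = vapply(fits, function(f) length(f$selected), integer(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    objective = vapply(fits, function(f) f$objective, numeric(1)),
    cv_error = cv_error
  )
  # one-standard-error rule: the largest penalty whose CV loss is within
  # one SE of the minimum (the plain minimum is almost always the densest
  # fit here, because the unpenalized mediator equations dominate the loss)
  best <- if (all(is.na(cv_error))) length(lambda_path) else {
    i_min <- which.min(cv_error)
    min(which(cv_error <= cv_error[i_min] + cv_se[i_min]))
  }
  for (li in seq_along(fits)) {
    names(fits[[li]]$alpha_hat) <- names(fits[[li]]$beta_hat) <- med_ids
    fits[[li]]$selected <- med_ids[fits[[li]]$selected]
  }
  structure(
    list(method = "pathway_lasso", path = path, fits = fits,
         lambda_selected = lambda_path[best],
         selected = fits[[best]]$selected,
         alpha_hat = fits[[best]]$alpha_hat,
         beta_hat = fits[[best]]$beta_hat,
         tuning_meta = list(omega_ratio = omega_ratio, phi = phi,
                            cv_folds = cv_folds, seed = seed)),
    class = "pathway_selection"
  )
}

#' @export
print.pathway_selection <- function(x, ...) {
  cat(sprintf("<pathway_selection> %s: %d mediators selected at lambda = %.4g\n",
              x$method, length(x$selected), x$lambda_selected %||% NA))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

residualize_on_covariates <- function(y, a, M, covariates) {
  n <- length(y)
  X <- cbind(rep(1, n), covariate_design(covariates))
  Q <- qr(X)
  list(y = qr.resid(Q, y), a = qr.resid(Q, a),
       M = qr.resid(Q, M))
}

# full regularization path with warm starts (inputs already residualized)
plasso_path <- function(y, a, M, lambda_path, omega_ratio, phi, tol,
                        max_iter) {
  n <- length(y); q <- ncol(M)
  c1 <- sum(a * a) / n
  cs <- colSums(M^2) / n
  atil_num <- drop(crossprod(M, a)) / sum(a * a)   # per-mediator OLS alpha
  alpha <- rep(0, q); beta <- rep(0, q); beta_a <- 0
  r_out <- y                                # outcome residual
  fits <- vector("list", length(lambda_path))
  for (li in seq_along(lambda_path)) {
    lam <- lambda_path[li]
    omega <- omega_ratio * lam
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      delta <- 0
      # unpenalized direct effect
      ba_new <- sum(a * (r_out + a * beta_a)) / (n * c1)
      r_out <- r_out - a * (ba_new - beta_a)
      delta <- max(delta, abs(ba_new - beta_a))
      beta_a <- ba_new
      for (j in seq_len(q)) {
        # quadratic profiles: (c/2)(t - u)^2 for each path coefficient
        u_a <- atil_num[j]
        u_b <- (sum(M[, j] * r_out) / n + cs[j] * beta[j]) / cs[j]
        sol <- plasso_pair_solve(c1, u_a, cs[j], u_b, lam, omega, phi)
        if (sol[2] != beta[j]) {
          r_out <- r_out - M[, j] * (sol[2] - beta[j])
        }
        delta <- max(delta, abs(sol[1] - alpha[j]), abs(sol[2] - beta[j]))
        alpha[j] <- sol[1]; beta[j] <- sol[2]
      }
      if (delta < tol) { converged <- TRUE; break }
    }
    obj <- plasso_objective(y, a, M, alpha, beta, beta_a, lam, omega, phi)
    fits[[li]] <- list(alpha_hat = alpha, beta_hat = beta, beta_a = beta_a,
                       selected = which(abs(alpha * beta) > 1e-12),
                       converged = converged, objective = obj,
                       residual_norms = c(outcome = sqrt(mean(r_out^2))))
  }
  fits
}

plasso_objective <- function(y, a, M, alpha, beta, beta_a, lam, omega, phi) {
  n <- length(y)
  e_med <- M - outer(a, alpha)
  e_out <- y - a * beta_a - drop(M %*% beta)
  sum(e_med^2) / (2 * n) + sum(e_out^2) / (2 * n) +
    lam * sum(abs(alpha * beta) + phi * (alpha^2 + beta^2)) +
    omega * sum(abs(alpha) + abs(beta))
}

# exact minimizer of
#   (c1/2)(a-ua)^2 + (c2/2)(b-ub)^2 + lam|ab| + lam*phi*(a^2+b^2)
#   + omega(|a|+|b|)
# by enumerating the axes and the four sign quadrants
plasso_pair_solve <- function(c1, ua, c2, ub, lam, omega, phi) {
  cand <- list(c(0, 0),
               c(0, soft_threshold(c2 * ub, omega) / (c2 + 2 * lam * phi)),
               c(soft_threshold(c1 * ua, omega) / (c1 + 2 * lam * phi), 0))
  d1 <- c1 + 2 * lam * phi
  d2 <- c2 + 2 * lam * phi
  for (sa in c(-1, 1)) for (sb in c(-1, 1)) {
    s <- sa * sb
    det <- d1 * d2 - lam^2
    if (det <= 0) next
    rhs1 <- c1 * ua - omega * sa
    rhs2 <- c2 * ub - omega * sb
    a <- (d2 * rhs1 - lam * s * rhs2) / det
    b <- (d1 * rhs2 - lam * s * rhs1) / det
    if (sign(a) == sa && sign(b) == sb) cand[[length(cand) + 1]] <- c(a, b)
  }
  vals <- vapply(cand, function(v) {
    c1 / 2 * (v[1] - ua)^2 + c2 / 2 * (v[2] - ub)^2 +
      lam * abs(v[1] * v[2]) + lam * phi * (v[1]^2 + v[2]^2) +
      omega * (abs(v[1]) + abs(v[2]))
  }, numeric(1))
  cand[[which.min(vals)]]
}

#' Minimax concave penalty threshold operator
#'
#' Univariate minimizer of `(c/2)(t - u)^2 + MCP(t; lambda, gamma)`.
#' Interpolates between soft thresholding (`gamma -> Inf`) and hard
#' thresholding (`gamma -> 1+`, at `c = 1`).
#'
#' @param u unpenalized (least-squares) coordinate target.
#' @param lambda penalty level.
#' @param gamma concavity parameter (> 1/c).
#' @param c curvature of the quadratic loss.
#' @return The thresholded value.
#' @export
mcp_threshold <- function(u, lambda, gamma = 3, c = 1) {
  assert_that(gamma * c > 1, "mcp gamma must exceed 1/c for a unique minimizer")
  ifelse(abs(u) <= gamma * lambda,
         soft_threshold(c * u, lambda) / (c - 1 / gamma),
         u)
}

# MCP-penalized least squares by coordinate descent; first `n_unpen`
# columns of X are never penalized.
mcp_fit <- function(y, X, lambda, gamma = 3, n_unpen = 0, init = NULL,
                    tol = 1e-9, max_iter = 5000) {
  n <- length(y)
  p <- ncol(X)
  beta <- init %||% rep(0, p)
  cs <- colSums(X^2) / n
  r <- y - drop(X %*% beta)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      u <- (sum(X[, j] * r) / n + cs[j] * beta[j]) / cs[j]
      bj <- if (j <= n_unpen) u else
        mcp_threshold(u, lambda / cs[j], gamma, c = 1) * 1
      if (bj != beta[j]) {
        r <- r - X[, j] * (bj - beta[j])
        delta <- max(delta, abs(bj - beta[j]))
        beta[j] <- bj
      }
    }
    if (delta < tol) break
  }
  list(beta = beta, residuals = r, iterations = it)
}

#' High-dimensional mediator selection by MCP and joint significance
#'
#' Three-stage screen for mediators of one exposure: (1) sure independence
#' screening keeps the `d` mediators most associated with the outcome
#' (conditional on exposure and covariates; default
#' `d = ceiling(2 n / log n)`); (2) an MCP-penalized outcome regression
#' over the survivors (exposure and covariates unpenalized), tuned by BIC
#' along a penalty path, retains mediators with nonzero coefficients;
#' (3) for those, the exposure-path p-value comes from the mediator model
#' and the outcome-path p-value from an unpenalized joint refit; the joint
#' significance p-value is the maximum of the two, adjusted by both
#' Benjamini-Hochberg and Bonferroni. The outcome-path p-values are
#' post-selection quantities without selective-inference correction, as in
#' the source procedure.
#'
#' @param exposure,mediators,outcome,covariates standardized inputs as in
#'   [pathway_lasso_fit()].
#' @param screen_size number of mediators kept by screening (`NULL` for
#'   the default).
#' @param mcp_gamma MCP concavity parameter.
#' @param lambda_path MCP penalty path (`NULL` for 30 log-spaced values).
#' @param weights optional subject weights used in the stage-3 path
#'   regressions.
#' @return A data.frame of `JointSigResult` rows for mediators surviving
#'   MCP (possibly zero rows, with attribute `status`): `mediator_id`,
#'   `alpha_hat`, `beta_mcp`, `beta_refit`, `p_alpha`, `p_beta`,
#'   `p_joint`, `q_joint_bh`, `p_joint_bonferroni`.
#' @export
mcp_joint_significance <- function(exposure, mediators, outcome,
                                   covariates = NULL, screen_size = NULL,
                                   mcp_gamma = 3, lambda_path = NULL,
                                   weights = NULL) {
  M <- as.matrix(mediators)
  n <- length(outcome)
  q <- ncol(M)
  med_ids <- colnames(M) %||% paste0("m", seq_len(q))
  colnames(M) <- med_ids
  w <- weights %||% rep(1, n)
  Xc <- cbind(`(Intercept)` = rep(1, n), covariate_design(covariates))
  d <- min(q, screen_size %||% ceiling(2 * n / log(n)))

  # stage 1: sure independence screening on conditional outcome association
  base <- cbind(Xc, exposure = exposure)
  tstats <- vapply(seq_len(q), function(l) {
    f <- fit_weighted_linear(outcome, cbind(base, mediator = M[, l]), w)
    abs(f$coefficients["mediator"] / f$standard_errors["mediator"])
  }, numeric(1))
  survivors <- order(tstats, decreasing = TRUE)[seq_len(d)]
  survivors <- sort(survivors)

  # stage 2: MCP on the survivors, exposure and covariates unpenalized
  Xp <- cbind(base, M[, survivors, drop = FALSE])
  n_unpen <- ncol(base)
  if (is.null(lambda_path)) {
    rr <- stats::lm.fit(base, outcome)$residuals
    lam_max <- max(abs(crossprod(M[, survivors, drop = FALSE], rr)) / n)
    lambda_path <- exp(seq(log(lam_max), log(lam_max * 1e-3),
                           length.out = 30))
  }
  best <- NULL; best_bic <- Inf; init <- NULL
  for (lam in sort(lambda_path, decreasing = TRUE)) {
    fit <- mcp_fit(outcome, Xp, lam, gamma = mcp_gamma, n_unpen = n_unpen,
                   init = init)
    init <- fit$beta
    df <- sum(fit$beta != 0)
    bic <- n * log(sum(fit$residuals^2) / n) + log(n) * df
    if (bic < best_bic) { best_bic <- bic; best <- fit }
  }
  sel_local <- which(best$beta[(n_unpen + 1):ncol(Xp)] != 0)
  if (length(sel_local) == 0) {
    out <- data.frame(mediator_id = character(0), alpha_hat = numeric(0),
                      beta_mcp = numeric(0), beta_refit = numeric(0),
                      p_alpha = numeric(0), p_beta = numeric(0),
                      p_joint = numeric(0), q_joint_bh = numeric(0),
                      p_joint_bonferroni = numeric(0))
    attr(out, "status") <- "no mediators survived MCP selection"
    return(out)
  }
  sel <- survivors[sel_local]

  # stage 3: joint significance with unpenalized refit on the selected set
  refit <- fit_weighted_linear(
    outcome, cbind(base, M[, sel, drop = FALSE]), w)
  idx <- n_unpen + seq_along(sel)
  beta_refit <- refit$coefficients[idx]
  p_beta <- 2 * stats::pnorm(-abs(beta_refit / refit$standard_errors[idx]))
  alpha_hat <- numeric(length(sel)); p_alpha <- numeric(length(sel))
  for (i in seq_along(sel)) {
    fm <- fit_weighted_linear(M[, sel[i]], base, w)
    alpha_hat[i] <- fm$coefficients["exposure"]
    p_alpha[i] <- 2 * stats::pnorm(-abs(alpha_hat[i] /
                                          fm$standard_errors["exposure"]))
  }
  p_joint <- pmax(p_alpha, p_beta)
  data.frame(
    mediator_id = med_ids[sel],
    alpha_hat = alpha_hat,
    beta_mcp = best$beta[n_unpen + sel_local],
    beta_refit = unname(beta_refit),
    p_alpha = p_alpha, p_beta = unname(p_beta), p_joint = unname(p_joint),
    q_joint_bh = stats::p.adjust(p_joint, "BH"),
    p_joint_bonferroni = stats::p.adjust(p_joint, "bonferroni"),
    stringsAsFactors = FALSE
  )
}
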