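#' Estimate the first direction of mediation for a mediator group
#'
#' Finds the unit-norm loading vector `w` such that the linear combination
#' `M w` of a group's (standardized) mediators, used as the single mediator
#' in the two-equation structural mediation model, maximizes the Gaussian
#' profile log-likelihood of the system. Because both equations are linear,
#' the profile likelihood has closed form in the weighted cross-product
#' matrices of covariate-residualized data; it is maximized on the unit
#' sphere by projected gradient ascent with backtracking from multiple
#' seeded random starts plus the first-principal-component start. The sign
#' is fixed so the largest-magnitude loading is positive.
#'
#' Groups whose mediators are all essentially uncorrelated with the
#' exposure carry no estimable direction; these surface with status
#' `"sparse_signal"` rather than an error, mirroring how such groups drop
#' out of reported forest plots.
#'
#' @param exposure numeric vector (log exposure or standardized risk
#'   score).
#' @param mediators_g numeric matrix of the group's standardized
#'   mediators.
#' @param outcome continuous outcome vector.
#' @param covariates optional covariate data.frame/matrix.
#' @param weights positive subject weights (IPW).
#' @param group label stored on the result.
#' @param n_starts number of random restarts on the sphere.
#' @param seed seed for the restarts.
#' @param tol convergence tolerance on the objective change.
#' @param max_iter iteration cap per start.
#' @param sparse_cor_threshold below this maximum absolute
#'   exposure-mediator correlation the group is flagged `sparse_signal`.
#' @return A `direction_of_mediation`: `group_g`, `w_g` (unit Euclidean
#'   norm), `mge` (`mediators_g %*% w_g`), `objective_value`, `converged`,
#'   `status`, `contribution_rho` (correlation of the MGE with each member
#'   mediator).
#' @export
estimate_direction <- function(exposure, mediators_g, outcome,
                               covariates = NULL,
                               weights = rep(1, length(outcome)),
                               group = "group", n_starts = 20, seed = 1L,
                               tol = 1e-8, max_iter = 1000,
                               sparse_cor_threshold = 0.1) {
  Mg <- as.matrix(mediators_g)
  qg <- ncol(Mg)
  n <- length(outcome)
  assert_that(qg >= 1, "mediator group is empty")
  assert_that(nrow(Mg) == n && length(exposure) == n,
              "inputs must have matching rows")

  marg_cor <- suppressWarnings(abs(stats::cor(exposure, Mg)))
  status <- if (max(marg_cor, na.rm = TRUE) < sparse_cor_threshold)
    "sparse_signal" else "ok"

  if (qg == 1) {
    w <- 1
    mge <- drop(Mg)
    return(new_direction(group, w, mge, objective = NA_real_,
                         converged = TRUE, status = status, Mg = Mg,
                         trace = NULL))
  }

  # covariate-residualized weighted cross-products: the profile likelihood
  # depends on w only through G = M'R'WRM, b = M'R'W Ry, c0 = Ry'W Ry
  X <- cbind(`(Intercept)` = rep(1, n), exposure = exposure,
             covariate_design(covariates))
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(weights))))
  resid_w <- function(v) v - X %*% (XtWX_inv %*% crossprod(X, weights * v))
  RM <- apply(Mg, 2, resid_w)
  Ry <- drop(resid_w(outcome))
  G <- crossprod(RM, RM * weights)
  b <- drop(crossprod(RM, Ry * weights))
  c0 <- sum(weights * Ry^2)

  obj <- function(w) {
    s <- drop(crossprod(w, G %*% w))
    t_ <- sum(b * w)
    h <- c0 - t_^2 / s
    if (s <= 0 || h <= 0) return(-Inf)
    -log(s) - log(h)
  }
  grad <- function(w) {
    Gw <- drop(G %*% w)
    s <- sum(w * Gw)
    t_ <- sum(b * w)
    h <- c0 - t_^2 / s
    -2 * Gw / s + (2 * t_ * b / s - 2 * t_^2 * Gw / s^2) / h
  }

  # starts: first principal component of the residualized group + random
  set.seed(child_seed(seed, paste0("dom_", group)))
  starts <- cbind(svd(RM, nu = 0, nv = 1)$v,
                  matrix(stats::rnorm(qg * n_starts), qg))
  starts <- apply(starts, 2, function(v) v / sqrt(sum(v^2)))

  best <- list(value = -Inf, w = starts[, 1], converged = FALSE, trace = NULL)
  for (s_i in seq_len(ncol(starts))) {
    res <- sphere_ascent(starts[, s_i], obj, grad, tol, max_iter)
    if (res$value > best$value) best <- res
  }
  if (!best$converged) {
    stop_mm("direction-of-mediation optimization failed to converge from all %d starts (best objective %.6g)",
            ncol(starts), best$value, class = "mixmediate_convergence_error")
  }
  w <- best$w
  w <- w * sign(w[which.max(abs(w))])          # sign convention
  mge <- drop(Mg %*% w)
  new_direction(group, w, mge, objective = best$value,
                converged = best$converged, status = status, Mg = Mg,
                trace = best$trace)
}

# projected gradient ascent on the unit sphere with backtracking;
# the objective trace is non-decreasing by construction
sphere_ascent <- function(w, obj, grad, tol, max_iter) {
  f <- obj(w)
  step <- 1
  trace <- f
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad(w)
    g_t <- g - sum(g * w) * w          # tangent-space projection
    gn <- sqrt(sum(g_t^2))
    if (gn < 1e-14) { converged <- TRUE; break }
    improved <- FALSE
    while (step > 1e-14) {
      w_new <- w + step * g_t
      w_new <- w_new / sqrt(sum(w_new^2))
      f_new <- obj(w_new)
      if (f_new > f) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    if (f_new - f < tol) {
      w <- w_new; f <- f_new; trace <- c(trace, f)
      converged <- TRUE; break
    }
    w <- w_new; f <- f_new; trace <- c(trace, f)
    step <- min(step * 2, 1e3)
  }
  list(w = w, value = f, converged = converged, trace = trace)
}

new_direction <- function(group, w, mge, objective, converged, status, Mg,
                          trace) {
  rho <- suppressWarnings(drop(stats::cor(mge, Mg)))
  structure(
    list(group_g = group,
         w_g = stats::setNames(w, colnames(Mg)),
         mge = mge, objective_value = objective, converged = converged,
         status = status,
         contribution_rho = stats::setNames(rho, colnames(Mg)),
         objective_trace = trace),
    class = "direction_of_mediation"
  )
}

#' @export
print.direction_of_mediation <- function(x, ...) {
  cat(sprintf("<direction_of_mediation> group '%s' (q = %d), status %s%s\n",
              x$group_g, length(x$w_g), x$status,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Mediation through a mediator group effect
#'
#' Uses the (standardized) mediator group effect `MGE = M_g w_g` from a
#' fitted direction of mediation as the single mediator in
#' [mediate_pair()].
#'
#' @param exposure numeric exposure or standardized risk score.
#' @param direction a converged [estimate_direction()] result.
#' @param cohort a `cohort_table`.
#' @param ... passed to [mediate_pair()].
#' @return A `mediation_result` labelled with the group; carries the
#'   direction's `status` (`"ok"` or `"sparse_signal"`).
#' @export
mge_mediation <- function(exposure, direction, cohort, ...) {
  assert_that(inherits(direction, "direction_of_mediation"),
              "direction must be a direction_of_mediation")
  assert_that(direction$converged,
              "direction of mediation did not converge; refusing to mediate through it")
  res <- mediate_pair(exposure, drop(scale(direction$mge)), cohort,
                      mediator_id = paste0("mge_", direction$group_g), ...)
  res$group <- direction$group_g
  res$direction_status <- direction$status
  res
}

#' Correlations of member mediators with a direction of mediation
#'
#' Pearson correlation between the mediator group effect and every
#' mediator in a panel, used to identify which biomarkers drive a
#' dimension-reduced mediation signal (drivers conventionally flagged at
#' |rho| > 0.3).
#'
#' @param direction a [estimate_direction()] result.
#' @param mediators a [mediator_panel()] (standardized internally) or a
#'   numeric matrix.
#' @return Named numeric vector of correlations (`NA` for zero-variance
#'   mediators).
#' @export
contribution_correlations <- function(direction, mediators) {
  Mz <- if (inherits(mediators, "mm_panel"))
    panel_log(mediators, standardize = TRUE)$values else as.matrix(mediators)
  sds <- apply(Mz, 2, stats::sd)
  out <- rep(NA_real_, ncol(Mz))
  ok <- sds > 0
  out[ok] <- drop(stats::cor(direction$mge, Mz[, ok, drop = FALSE]))
  stats::setNames(out, colnames(Mz))
}

#' Directions of mediation for every eligible group plus all mediators
#'
#' Convenience wrapper running [estimate_direction()] and
#' [mge_mediation()] for each biological group with at least
#' `min_group_size` mediators and once for the full panel (`"all"`),
#' giving the s + 1 group-level mediation results for one exposure.
#'
#' @inheritParams estimate_direction
#' @param mediators a [mediator_panel()].
#' @param cohort a `cohort_table`.
#' @param min_group_size smallest eligible group.
#' @param ... passed to [estimate_direction()].
#' @return List with `directions` (named list) and `results` (data.frame
#'   of group-level mediation effects with `status`).
#' @export
group_mediation_scan <- function(exposure, mediators, cohort,
                                 min_group_size = 5, seed = 1L, ...) {
  Mz <- panel_log(mediators, standardize = TRUE)
  sizes <- table(Mz$map)
  eligible <- names(sizes)[sizes >= min_group_size]
  groups <- c(stats::setNames(lapply(eligible, function(g)
    names(Mz$map)[Mz$map == g]), eligible),
    list(all = colnames(Mz$values)))
  covars <- cohort_covariates(cohort)
  dirs <- list(); rows <- list()
  for (g in names(groups)) {
    d <- tryCatch(
      estimate_direction(exposure, Mz$values[, groups[[g]], drop = FALSE],
                         cohort$outcome_continuous, covars,
                         weights = cohort$ipw_weight, group = g,
                         seed = seed, ...),
      error = function(e) e)
    if (inherits(d, "error")) {
      rows[[g]] <- data.frame(group = g, q_g = length(groups[[g]]),
                              nie = NA_real_, te = NA_real_, nde = NA_real_,
                              se_nie = NA_real_, p_nie = NA_real_,
                              p_te = NA_real_, p_nde = NA_real_,
                              status = paste0("error: ", conditionMessage(d)),
                              stringsAsFactors = FALSE)
      next
    }
    dirs[[g]] <- d
    r <- mge_mediation(exposure, d, cohort)
    rows[[g]] <- data.frame(group = g, q_g = length(groups[[g]]),
                            nie = r$nie, te = r$te, nde = r$beta_a,
                            se_nie = r$se_nie, p_nie = r$p_nie,
                            p_te = r$p_te, p_nde = r$p_nde,
                            status = d$status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(directions = dirs, results = out)
}
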