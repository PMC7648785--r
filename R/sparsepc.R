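#' Sparse principal components of a mediator matrix
#'
#' L1-penalized power iteration with projection deflation: each component's
#' loading vector is obtained by alternating the power step with
#' soft-thresholding and renormalization, the fitted direction is deflated
#' from the working matrix, and components accumulate until the cumulative
#' explained-variance fraction reaches `variance_target`. With zero
#' penalty the procedure reduces exactly to ordinary principal component
#' analysis.
#'
#' @param x numeric matrix (subjects x features), standardized columns.
#' @param variance_target cumulative explained-variance fraction to reach
#'   (components are capped at the matrix rank).
#' @param penalty nonnegative soft-threshold level applied to loadings at
#'   each power step.
#' @param max_iter,tol power-iteration controls.
#' @return A `sparse_pc_set`: `loadings` (features x components),
#'   `explained_variance_fraction`, `n_components`, `scores`
#'   (subjects x components), `penalty`.
#' @export
sparse_pc <- function(x, variance_target = 0.8, penalty = 0,
                      max_iter = 5000, tol = 1e-13) {
  X <- as.matrix(x)
  assert_that(variance_target > 0 && variance_target <= 1,
              "variance_target must lie in (0, 1]")
  assert_that(penalty >= 0, "penalty must be nonnegative")
  total_var <- sum(apply(X, 2, stats::var))
  rank_max <- qr(X)$rank
  loadings <- NULL; ev <- numeric(0); scores <- NULL
  Xd <- X
  for (k in seq_len(rank_max)) {
    v <- sparse_power_iteration(Xd, penalty, max_iter, tol)
    if (is.null(v)) {
      if (k == 1) {
        stop_mm("penalty %.4g removes every loading; no component can be extracted",
                penalty, class = "mixmediate_penalty_error")
      }
      break
    }
    s <- drop(Xd %*% v)
    ev_k <- stats::var(s) / total_var
    loadings <- cbind(loadings, v)
    ev <- c(ev, ev_k)
    scores <- cbind(scores, drop(X %*% v))
    if (sum(ev) >= variance_target) break
    Xd <- Xd - outer(s, v)               # projection deflation
  }
  dimnames(loadings) <- list(colnames(X), paste0("pc", seq_along(ev)))
  colnames(scores) <- paste0("pc", seq_along(ev))
  structure(
    list(loadings = loadings, explained_variance_fraction = ev,
         n_components = length(ev), scores = scores, penalty = penalty),
    class = "sparse_pc_set"
  )
}

# one penalized power iteration; returns NULL if thresholding removes
# every loading
sparse_power_iteration <- function(Xd, penalty, max_iter, tol) {
  C_mult <- function(v) drop(crossprod(Xd, Xd %*% v))
  v <- svd(Xd, nu = 0, nv = 1)$v[, 1]
  for (it in seq_len(max_iter)) {
    z <- C_mult(v)
    z <- soft_threshold(z, penalty)
    nz <- sqrt(sum(z^2))
    if (nz == 0) return(NULL)
    v_new <- z / nz
    if (sum(abs(v_new - v)) < tol || sum(abs(v_new + v)) < tol) {
      v <- v_new; break
    }
    v <- v_new
  }
  v
}

#' @export
print.sparse_pc_set <- function(x, ...) {
  cat(sprintf("<sparse_pc_set> %d components, penalty %.4g, cumulative explained variance %.3f\n",
              x$n_components, x$penalty,
              sum(x$explained_variance_fraction)))
  invisible(x)
}

#' Sparse principal component mediation analysis
#'
#' Constructs sparse principal components of the full (standardized)
#' mediator matrix and mediates each component score one-at-a-time between
#' the exposure and the continuous outcome. The sign distribution of the
#' per-component indirect effects summarizes whether the dimensionally
#' reduced mediator space transmits the effect coherently in one
#' direction.
#'
#' @param exposure numeric exposure or standardized risk score.
#' @param mediators a [mediator_panel()] or standardized matrix.
#' @param cohort a `cohort_table`.
#' @param variance_target,penalty passed to [sparse_pc()].
#' @return List with `results` (data.frame, one row per component:
#'   effects, p-values, q-values), `pcs` (the `sparse_pc_set`), and
#'   `nie_sign_fraction` (fraction of components whose NIE shares the sign
#'   of the majority).
#' @export
sparse_pc_mediation <- function(exposure, mediators, cohort,
                                variance_target = 0.8, penalty = 0) {
  Mz <- if (inherits(mediators, "mm_panel"))
    panel_log(mediators, standardize = TRUE)$values else as.matrix(mediators)
  pcs <- sparse_pc(Mz, variance_target = variance_target, penalty = penalty)
  rows <- lapply(seq_len(pcs$n_components), function(k) {
    r <- mediate_pair(exposure, drop(scale(pcs$scores[, k])), cohort,
                      mediator_id = colnames(pcs$scores)[k],
                      exposure_id = "exposure")
    data.frame(component = colnames(pcs$scores)[k],
               explained_variance = pcs$explained_variance_fraction[k],
               nie = r$nie, te = r$te, nde = r$beta_a, se_nie = r$se_nie,
               p_nie = r$p_nie, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_nie <- qvalues(res$p_nie, method = "bh")
  signs <- sign(res$nie)
  majority <- if (sum(signs > 0) >= sum(signs < 0)) 1 else -1
  list(results = res, pcs = pcs,
       nie_sign_fraction = mean(signs == majority))
}
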