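#' Prior specification for Bayesian shrinkage mediation
#'
#' Two-component normal mixture ("continuous spike and slab") priors are
#' placed independently on each exposure-to-mediator coefficient and each
#' mediator-to-outcome coefficient. Component variances carry
#' inverse-gamma hyperpriors with the slab constrained to be at least
#' `slab_min_ratio` times the spike (enforced by rejection); mixture
#' membership is Bernoulli(`pi_inclusion`). The slab variance uses
#' IG(`a0`, `b0`); the spike variance uses IG(`a0`, `b0`/100) so its
#' prior mass sits near zero, as a component representing essentially
#' null coefficients should.
#'
#' @param a0,b0 inverse-gamma shape/rate for the variance components
#'   (residual variances and the slab; the spike rate is `b0`/100).
#' @param pi_inclusion prior inclusion probability of the slab component.
#' @param slab_min_ratio minimum slab-to-spike variance ratio.
#' @param coef_var prior variance of unpenalized coefficients (direct
#'   effect and covariates).
#' @param fixed_alpha_var,fixed_beta_var optional fixed `c(spike, slab)`
#'   variances, bypassing the hyperprior update (setting spike = slab
#'   collapses the mixture to a single ridge-like normal prior).
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(a0 = 2, b0 = 1, pi_inclusion = 0.5,
                       slab_min_ratio = 100, coef_var = 100,
                       fixed_alpha_var = NULL, fixed_beta_var = NULL) {
  structure(list(a0 = a0, b0 = b0, pi_inclusion = pi_inclusion,
                 slab_min_ratio = slab_min_ratio, coef_var = coef_var,
                 fixed_alpha_var = fixed_alpha_var,
                 fixed_beta_var = fixed_beta_var),
            class = "prior_spec")
}

#' Bayesian multivariate mediation with continuous shrinkage
#'
#' Jointly models all mediators of one exposure: the multivariate mediator
#' model (each mediator on exposure and covariates) and the outcome model
#' (outcome on exposure, all mediators, and covariates), with spike/slab
#' mixture priors on every pathway coefficient. A Gibbs sampler with
#' conjugate normal / inverse-gamma updates and Bernoulli membership
#' updates yields, per mediator, the posterior inclusion probability (PIP):
#' the posterior probability that both its pathway coefficients sit in the
#' large-variance component. Subject weights enter as a weighted
#' likelihood (an approximation for inverse-probability-weighted designs).
#'
#' @param exposure numeric vector (standardized).
#' @param mediators numeric matrix, n x q (standardized columns).
#' @param outcome numeric vector (standardized or centered continuous
#'   outcome; the method is restricted to continuous outcomes).
#' @param covariates optional covariate data.frame/matrix (dummy-coded,
#'   standardized internally); an intercept is always included.
#' @param prior a [prior_spec()].
#' @param iter,burnin,thin MCMC controls.
#' @param seed integer seed; chains with the same seed are bit-identical.
#' @param weights optional positive subject weights.
#' @return A `shrinkage_posterior`: `draws` (post-burnin matrices `alpha`,
#'   `beta_m`, `beta_a`, `sigma`), `pip`, `global_nie`, `global_effect_sq`,
#'   `rhat` (max split-chain diagnostic over pathway coefficients), and
#'   `chain_meta`.
#' @export
fit_bayes_mediation <- function(exposure, mediators, outcome,
                                covariates = NULL, prior = prior_spec(),
                                iter = 30000, burnin = 15000, thin = 1,
                                seed = 1L, weights = NULL) {
  M <- as.matrix(mediators)
  n <- length(outcome)
  q <- ncol(M)
  assert_that(all(is.finite(exposure)) && all(is.finite(M)) &&
                all(is.finite(outcome)),
              "non-finite values in mediation inputs")
  assert_that(nrow(M) == n && length(exposure) == n,
              "exposure, mediators, and outcome must have matching rows")
  assert_that(burnin < iter, "burnin must be smaller than iter")
  w <- weights %||% rep(1, n)
  assert_that(all(w > 0), "weights must be positive")
  if (q >= n) {
    warn_mm("q = %d mediators with only n = %d subjects; posterior will be prior-dominated",
            q, n)
  }
  Xc <- cbind(`(Intercept)` = rep(1, n), covariate_design(covariates))
  r <- ncol(Xc)
  a <- exposure

  set.seed(seed)
  # precomputations (weighted cross-products)
  Xo <- cbind(exposure = a, M, Xc)
  ko <- ncol(Xo)
  XtWXo <- crossprod(Xo * sqrt(w))
  XtWyo <- drop(crossprod(Xo, w * outcome))
  atWa <- sum(w * a * a)
  CtWC_diag <- colSums(Xc^2 * w)
  sw <- sum(w)

  # state
  alpha <- rep(0, q); Ac <- matrix(0, r, q)
  theta_o <- rep(0, ko)
  Ia <- rep(TRUE, q); Ib <- rep(TRUE, q)
  v_a <- c(spike = 0.01, slab = 1); v_b <- c(spike = 0.01, slab = 1)
  sig2_m <- 1; sig2_y <- 1
  pi_inc <- prior$pi_inclusion

  n_keep <- floor((iter - burnin) / thin)
  dr_alpha <- matrix(NA_real_, n_keep, q)
  dr_beta <- matrix(NA_real_, n_keep, q)
  dr_beta_a <- numeric(n_keep)
  dr_sigma <- matrix(NA_real_, n_keep, 4,
                     dimnames = list(NULL, c("sig2_m", "sig2_y",
                                             "v_a_slab", "v_b_slab")))
  dr_inc <- matrix(NA_real_, n_keep, q)
  keep_i <- 0

  Rm <- M - outer(a, alpha) - Xc %*% Ac   # mediator-model residuals

  for (it in seq_len(iter)) {
    # --- outcome equation: joint conjugate draw of (beta_a, beta_m, beta_c)
    vb_vec <- ifelse(Ib, v_b["slab"], v_b["spike"])
    prec_prior <- c(1 / prior$coef_var, 1 / vb_vec, rep(1 / prior$coef_var, r))
    P <- XtWXo / sig2_y
    diag(P) <- diag(P) + prec_prior
    U <- chol(P)
    mu <- backsolve(U, forwardsolve(t(U), XtWyo / sig2_y))
    theta_o <- mu + backsolve(U, stats::rnorm(ko))
    beta_a <- theta_o[1]
    beta_m <- theta_o[2:(q + 1)]
    res_y <- outcome - drop(Xo %*% theta_o)

    # --- mediator equations: vectorized scalar updates across mediators
    va_vec <- ifelse(Ia, v_a["slab"], v_a["spike"])
    RmA <- Rm + outer(a, alpha)            # residual with exposure term removed
    prec <- atWa / sig2_m + 1 / va_vec
    mean_a <- drop(crossprod(RmA, w * a)) / sig2_m / prec
    alpha <- stats::rnorm(q, mean_a, sqrt(1 / prec))
    Rm <- RmA - outer(a, alpha)
    for (cj in seq_len(r)) {
      Rj <- Rm + outer(Xc[, cj], Ac[cj, ])
      prec_c <- CtWC_diag[cj] / sig2_m + 1 / prior$coef_var
      mean_c <- drop(crossprod(Rj, w * Xc[, cj])) / sig2_m / prec_c
      Ac[cj, ] <- stats::rnorm(q, mean_c, sqrt(1 / prec_c))
      Rm <- Rj - outer(Xc[, cj], Ac[cj, ])
    }

    # --- mixture membership
    Ia <- draw_membership(alpha, v_a, pi_inc)
    Ib <- draw_membership(beta_m, v_b, pi_inc)

    # --- variance components
    if (is.null(prior$fixed_alpha_var)) {
      v_a <- draw_spike_slab_var(alpha, Ia, prior)
    } else v_a <- c(spike = prior$fixed_alpha_var[1], slab = prior$fixed_alpha_var[2])
    if (is.null(prior$fixed_beta_var)) {
      v_b <- draw_spike_slab_var(beta_m, Ib, prior)
    } else v_b <- c(spike = prior$fixed_beta_var[1], slab = prior$fixed_beta_var[2])

    sig2_m <- 1 / stats::rgamma(1, prior$a0 + sw * q / 2,
                                prior$b0 + 0.5 * sum(w * Rm^2))
    sig2_y <- 1 / stats::rgamma(1, prior$a0 + sw / 2,
                                prior$b0 + 0.5 * sum(w * res_y^2))
    if (!is.finite(sig2_m) || !is.finite(sig2_y) ||
        sig2_m <= 0 || sig2_y <= 0) {
      stop_mm("divergent variance draw at iteration %d", it,
              class = "mixmediate_mcmc_error")
    }

    if (it > burnin && (it - burnin) %% thin == 0) {
      keep_i <- keep_i + 1
      dr_alpha[keep_i, ] <- alpha
      dr_beta[keep_i, ] <- beta_m
      dr_beta_a[keep_i] <- beta_a
      dr_sigma[keep_i, ] <- c(sig2_m, sig2_y, v_a["slab"], v_b["slab"])
      dr_inc[keep_i, ] <- as.numeric(Ia & Ib)
    }
  }

  med_names <- colnames(M) %||% paste0("m", seq_len(q))
  colnames(dr_alpha) <- colnames(dr_beta) <- colnames(dr_inc) <- med_names
  prod_draws <- dr_alpha * dr_beta
  structure(
    list(
      draws = list(alpha = dr_alpha, beta_m = dr_beta, beta_a = dr_beta_a,
                   sigma = dr_sigma, inclusion = dr_inc),
      pip = colMeans(dr_inc),
      global_nie = posterior_summary(rowSums(prod_draws)),
      global_effect_sq = posterior_summary(rowSums(prod_draws^2)),
      rhat = max(c(apply(dr_alpha, 2, split_rhat),
                   apply(dr_beta, 2, split_rhat))),
      chain_meta = list(iterations = iter, burnin = burnin, thin = thin,
                        seed = seed, n_kept = keep_i)
    ),
    class = "shrinkage_posterior"
  )
}

draw_membership <- function(coef, v, pi_inc) {
  l_slab <- stats::dnorm(coef, 0, sqrt(v["slab"])) * pi_inc
  l_spike <- stats::dnorm(coef, 0, sqrt(v["spike"])) * (1 - pi_inc)
  pr <- l_slab / (l_slab + l_spike)
  pr[!is.finite(pr)] <- 0.5
  stats::runif(length(coef)) < pr
}

# inverse-gamma draws for spike and slab variances with the ordering
# constraint slab >= ratio * spike enforced by rejection, then clipping
draw_spike_slab_var <- function(coef, in_slab, prior, max_tries = 20) {
  n1 <- sum(in_slab); n0 <- sum(!in_slab)
  ss1 <- sum(coef[in_slab]^2); ss0 <- sum(coef[!in_slab]^2)
  for (tr in seq_len(max_tries)) {
    slab <- 1 / stats::rgamma(1, prior$a0 + n1 / 2, prior$b0 + ss1 / 2)
    spike <- 1 / stats::rgamma(1, prior$a0 + n0 / 2, prior$b0 / 100 + ss0 / 2)
    if (slab >= prior$slab_min_ratio * spike) break
  }
  if (slab < prior$slab_min_ratio * spike) spike <- slab / prior$slab_min_ratio
  c(spike = spike, slab = slab)
}

posterior_summary <- function(x, level = 0.95) {
  qs <- stats::quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2))
  c(mean = mean(x), ci_low = unname(qs[1]), ci_high = unname(qs[2]))
}

# split-chain potential scale reduction factor on one parameter's draws
split_rhat <- function(x) {
  ns <- floor(length(x) / 2)
  if (ns < 4) return(NA_real_)
  halves <- cbind(x[seq_len(ns)], x[ns + seq_len(ns)])
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- ns * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((ns - 1) / ns * W + B / ns) / W)
}

#' @export
print.shrinkage_posterior <- function(x, ...) {
  cat(sprintf("<shrinkage_posterior> q = %d mediators, %d kept draws (max split-Rhat %.3f)\n",
              length(x$pip), x$chain_meta$n_kept, x$rhat))
  cat(sprintf("  global NIE (sum of products): %.4f [%.4f, %.4f]\n",
              x$global_nie["mean"], x$global_nie["ci_low"], x$global_nie["ci_high"]))
  cat(sprintf("  max PIP: %.3f (%s)\n", max(x$pip), names(which.max(x$pip))))
  invisible(x)
}

#' Global mediation effect from a shrinkage posterior
#'
#' Two summaries of the joint pathway effect, computed draw-by-draw and
#' then summarized: `sum_products` is the conventional global natural
#' indirect effect, the sum over mediators of the per-draw coefficient
#' products; `sum_sq_products` is the sum of squared products, a
#' non-negative pathway-activity measure. Both are reported because the
#' two summaries answer different questions (signed total transmission vs.
#' aggregate pathway strength).
#'
#' @param post a `shrinkage_posterior`.
#' @param form `"sum_products"` or `"sum_sq_products"`.
#' @param level credible-interval level.
#' @return Named numeric: posterior `mean`, `ci_low`, `ci_high`.
#' @export
global_mediation_effect <- function(post, form = c("sum_products",
                                                   "sum_sq_products"),
                                    level = 0.95) {
  form <- match.arg(form)
  pr <- post$draws$alpha * post$draws$beta_m
  val <- if (form == "sum_products") rowSums(pr) else rowSums(pr^2)
  posterior_summary(val, level)
}

#' Shrinkage mediation over an exposure (or risk score) panel
#'
#' Runs [fit_bayes_mediation()] one-at-a-time for each exposure column,
#' either against all mediators jointly or within each biological group.
#' Groups with fewer than `min_group_size` mediators are excluded from
#' by-group runs (at the default roster: oxidative stress and protein
#' damage). Per-combination failures are flagged; the run continues.
#'
#' @param exposures numeric matrix of standardized exposures or risk
#'   scores (columns are run one-at-a-time).
#' @param mediators a [mediator_panel()] (logged and standardized
#'   internally).
#' @param cohort a `cohort_table` (continuous outcome only).
#' @param grouping `"by_group"` or `"all"`.
#' @param min_group_size smallest group retained under `by_group`.
#' @param prior,iter,burnin,seed passed to [fit_bayes_mediation()].
#' @param use_weights if `TRUE`, IPW weights enter as a weighted
#'   likelihood.
#' @return A data.frame with one row per (exposure, group): global NIE and
#'   squared-product summaries, max PIP and its mediator, the convergence
#'   diagnostic, and `status`.
#' @export
run_shrinkage_over_exposures <- function(exposures, mediators, cohort,
                                         grouping = c("by_group", "all"),
                                         min_group_size = 5,
                                         prior = prior_spec(),
                                         iter = 30000, burnin = 15000,
                                         seed = 1L, use_weights = TRUE) {
  grouping <- match.arg(grouping)
  E <- as.matrix(exposures)
  Mz <- panel_log(mediators, standardize = TRUE)
  y <- drop(scale(cohort$outcome_continuous, scale = FALSE))
  covars <- cohort_covariates(cohort)
  w <- if (use_weights) cohort$ipw_weight else NULL

  groups <- if (grouping == "all") list(all = colnames(Mz$values)) else {
    sizes <- table(Mz$map)
    keep <- names(sizes)[sizes >= min_group_size]
    stats::setNames(lapply(keep, function(g) names(Mz$map)[Mz$map == g]), keep)
  }

  rows <- list()
  for (j in seq_len(ncol(E))) {
    for (g in names(groups)) {
      res <- tryCatch({
        post <- fit_bayes_mediation(
          drop(scale(E[, j])), Mz$values[, groups[[g]], drop = FALSE], y,
          covariates = covars, prior = prior, iter = iter, burnin = burnin,
          seed = child_seed(seed, paste(colnames(E)[j] %||% j, g)),
          weights = w)
        data.frame(
          exposure_id = colnames(E)[j] %||% paste0("exposure_", j), group = g,
          q_g = length(groups[[g]]),
          global_nie = post$global_nie["mean"],
          global_nie_lo = post$global_nie["ci_low"],
          global_nie_hi = post$global_nie["ci_high"],
          global_effect_sq = post$global_effect_sq["mean"],
          max_pip = max(post$pip), top_mediator = names(which.max(post$pip)),
          rhat = post$rhat, status = "ok", stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(exposure_id = colnames(E)[j] %||% paste0("exposure_", j),
                   group = g, q_g = length(groups[[g]]),
                   global_nie = NA_real_, global_nie_lo = NA_real_,
                   global_nie_hi = NA_real_, global_effect_sq = NA_real_,
                   max_pip = NA_real_, top_mediator = NA_character_,
                   rhat = NA_real_,
                   status = paste0("error: ", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
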