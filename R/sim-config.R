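#' Simulation configuration for the synthetic pregnancy cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. Defaults
#' reproduce the structure of the motivating nested case-control study of
#' environmental toxicant mixtures and gestational age at delivery: a source
#' cohort of 1600 pregnancies from which 52 preterm cases and 109 controls
#' are sampled; 38 urinary exposure analytes in 4 correlated classes
#' (9 phthalates, 9 phenols, 8 polycyclic aromatic hydrocarbons, 12 metals);
#' 61 plasma/urine biomarker mediators in 7 biological groups (14
#' cyclooxygenase, 18 cytochrome p450, 14 lipoxygenase, 5 parent lipids,
#' 5 inflammation, 2 oxidative stress, 3 protein damage); and 6 covariates.
#'
#' The default effect pattern is sparse: a handful of phthalate analytes act
#' on a small set of cytochrome p450 mediators, which in turn lower
#' gestational age, alongside a weak direct phthalate effect. Noise scales
#' are chosen so the outcome model explains roughly 30% of outcome variance
#' and the cohort preterm prevalence (gestational age < 37 weeks) is around
#' 8%, a realistic epidemiologic regime.
#'
#' @param n_cohort number of subjects in the full source cohort.
#' @param n_cases_sampled,n_controls_sampled analytic-subset strata sizes.
#' @param class_sizes named integer vector, exposure class sizes (sums to p).
#' @param group_sizes named integer vector, mediator group sizes (sums to q).
#' @param within_class_rho exchangeable correlation of log-exposures within
#'   a class, in [0, 1).
#' @param between_class_rho correlation of log-exposures across classes.
#' @param within_group_rho exchangeable correlation of mediator noise within
#'   a group, in [0, 1).
#' @param alpha_matrix q-by-p matrix of exposure-to-mediator effects on the
#'   log-standardized scale. `NULL` uses the sparse default pattern.
#' @param beta_m length-q mediator-to-outcome effects (weeks per log-SD).
#' @param beta_a length-p direct exposure-to-outcome effects.
#' @param covariate_effects list with elements `outcome` (effects of the
#'   dummy-coded covariates on gestational age) and `mediator` (common
#'   magnitude of covariate effects on mediators).
#' @param noise_sd_mediator,noise_sd_outcome residual standard deviations.
#' @param outcome_mean mean gestational age at delivery, weeks.
#' @param preterm_threshold gestational age below which delivery is preterm.
#' @param spontaneous_fraction fraction of preterm cases that are spontaneous.
#' @param seed integer seed; identical configuration and seed reproduce the
#'   cohort bit-for-bit.
#' @return A list of class `sim_config`.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_cohort = 1600,
                       n_cases_sampled = 52,
                       n_controls_sampled = 109,
                       class_sizes = c(phthalate = 9, phenol = 9, pah = 8, metal = 12),
                       group_sizes = c(cox = 14, cyp450 = 18, lox = 14, parent = 5,
                                       inflam = 5, oxstress = 2, protein = 3),
                       within_class_rho = 0.65,
                       between_class_rho = 0.1,
                       within_group_rho = 0.4,
                       alpha_matrix = NULL,
                       beta_m = NULL,
                       beta_a = NULL,
                       covariate_effects = NULL,
                       noise_sd_mediator = 1,
                       noise_sd_outcome = 1.45,
                       outcome_mean = 39.5,
                       preterm_threshold = 37,
                       spontaneous_fraction = 30 / 52,
                       seed = 1L) {
  p <- sum(class_sizes)
  q <- sum(group_sizes)
  if (is.null(alpha_matrix)) {
    alpha_matrix <- matrix(0, q, p)
    # active pathway: first three phthalates act on four cytochrome p450 mediators
    cyp_idx <- sum(group_sizes[seq_len(which(names(group_sizes) == "cyp450") - 1)]) +
      seq_len(4)
    alpha_matrix[cyp_idx, 1:3] <- 0.4
  }
  if (is.null(beta_m)) {
    beta_m <- numeric(q)
    cyp_idx <- sum(group_sizes[seq_len(which(names(group_sizes) == "cyp450") - 1)]) +
      seq_len(4)
    beta_m[cyp_idx] <- -0.15
  }
  if (is.null(beta_a)) {
    beta_a <- numeric(p)
    beta_a[1:3] <- -0.08
  }
  if (is.null(covariate_effects)) {
    covariate_effects <- list(
      # dummy-coded order: age_z, specific_gravity, bmi 2 dummies,
      # education 3 dummies, smoker, alcohol
      outcome = c(-0.35, 0.25, -0.25, -0.45, 0.15, 0.25, 0.35, -0.6, -0.3),
      mediator = 0.1
    )
  }
  cfg <- list(
    n_cohort = as.integer(n_cohort),
    n_cases_sampled = as.integer(n_cases_sampled),
    n_controls_sampled = as.integer(n_controls_sampled),
    class_sizes = class_sizes, group_sizes = group_sizes,
    within_class_rho = within_class_rho,
    between_class_rho = between_class_rho,
    within_group_rho = within_group_rho,
    alpha_matrix = alpha_matrix, beta_m = beta_m, beta_a = beta_a,
    covariate_effects = covariate_effects,
    noise_sd_mediator = noise_sd_mediator,
    noise_sd_outcome = noise_sd_outcome,
    outcome_mean = outcome_mean,
    preterm_threshold = preterm_threshold,
    spontaneous_fraction = spontaneous_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  p <- sum(cfg$class_sizes)
  q <- sum(cfg$group_sizes)
  assert_that(p >= 1 && q >= 1, "class_sizes and group_sizes must be non-empty")
  assert_that(all(dim(cfg$alpha_matrix) == c(q, p)),
              "alpha_matrix must be q-by-p (%d x %d)", q, p)
  assert_that(length(cfg$beta_m) == q, "beta_m must have length q = %d", q)
  assert_that(length(cfg$beta_a) == p, "beta_a must have length p = %d", p)
  assert_that(cfg$n_cases_sampled + cfg$n_controls_sampled <= cfg$n_cohort,
              "sampled subset cannot exceed the cohort size")
  assert_that(cfg$within_class_rho >= 0 && cfg$within_class_rho < 1,
              "within_class_rho must lie in [0, 1)")
  assert_that(cfg$within_group_rho >= 0 && cfg$within_group_rho < 1,
              "within_group_rho must lie in [0, 1)")
  assert_that(cfg$noise_sd_mediator > 0 && cfg$noise_sd_outcome > 0,
              "noise standard deviations must be positive")
  # correlation structure must be positive definite before any draw
  check_block_pd(cfg$class_sizes, cfg$within_class_rho, cfg$between_class_rho,
                 "exposure class")
  check_block_pd(cfg$group_sizes, cfg$within_group_rho, 0, "mediator group")
  invisible(cfg)
}

# Exchangeable-within-block correlation with a constant between-block level;
# errors naming the offending block if not positive definite.
block_correlation <- function(sizes, rho_within, rho_between = 0) {
  m <- sum(sizes)
  R <- matrix(rho_between, m, m)
  start <- 0L
  for (b in seq_along(sizes)) {
    idx <- start + seq_len(sizes[b])
    R[idx, idx] <- rho_within
    start <- start + sizes[b]
  }
  diag(R) <- 1
  R
}

check_block_pd <- function(sizes, rho_within, rho_between, what) {
  for (b in seq_along(sizes)) {
    m <- sizes[b]
    if (m > 1 && rho_within <= -1 / (m - 1)) {
      stop_mm("%s block '%s' correlation %.3f is not positive definite",
              what, names(sizes)[b], rho_within, class = "mixmediate_config_error")
    }
  }
  R <- block_correlation(sizes, rho_within, rho_between)
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    stop_mm("%s correlation structure is not positive definite (min eigenvalue %.2e)",
            what, ev, class = "mixmediate_config_error")
  }
  invisible(TRUE)
}
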