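# Shared fixtures, all generated in code.

# Minimal cohort table around a given continuous outcome (optionally with
# covariates), for unit tests that do not need the full generator.
make_cohort <- function(y, covariates = NULL, weights = rep(1, length(y)),
                        preterm_threshold = stats::median(y)) {
  preterm <- as.integer(y < preterm_threshold)
  if (all(preterm == 0L)) preterm[which.min(y)] <- 1L
  if (all(preterm == 1L)) preterm[which.max(y)] <- 0L
  df <- data.frame(subject_id = sprintf("T%03d", seq_along(y)))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df$outcome_continuous <- y
  df$outcome_binary <- preterm
  df$outcome_binary_spontaneous <- preterm
  df$case_status <- factor(ifelse(preterm == 1L, "case", "control"),
                           levels = c("control", "case"))
  df$ipw_weight <- weights
  validate_cohort_table(df)
}

# Tiny mediation dataset with one exposure, one mediator, known effects.
make_mediation_data <- function(n, alpha = 1, beta_m = 1, beta_a = 0,
                                noise_m = 1, noise_y = 1, seed = 1) {
  set.seed(seed)
  a <- stats::rnorm(n)
  m <- alpha * a + stats::rnorm(n, sd = noise_m)
  y <- beta_a * a + beta_m * m + stats::rnorm(n, sd = noise_y)
  list(a = a, m = m, cohort = make_cohort(y))
}

# Small simulation configuration (2 exposures, 2 mediators, no covariate
# effects) with a single active pathway alpha = beta = 1.
small_active_config <- function(seed, n_cohort = 600, alpha = 1, beta = 1) {
  sim_config(
    n_cohort = n_cohort, n_cases_sampled = 25, n_controls_sampled = 75,
    class_sizes = c(phthalate = 2), group_sizes = c(cox = 2),
    within_class_rho = 0, between_class_rho = 0, within_group_rho = 0,
    alpha_matrix = matrix(c(alpha, 0, 0, 0), 2, 2),
    beta_m = c(beta, 0), beta_a = c(0, 0),
    covariate_effects = list(outcome = 0, mediator = 0),
    noise_sd_mediator = 1, noise_sd_outcome = 1,
    outcome_mean = 39.5, seed = seed
  )
}
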