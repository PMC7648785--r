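#' Generate a synthetic nested case-control cohort
#'
#' Draws a full source cohort under a linear structural mediation model with
#' known ground-truth effects, then samples the analytic case-control subset
#' and attaches inverse-probability weights. Exposures are generated as
#' correlated Gaussians on the log scale (block-exchangeable by class) and
#' exponentiated, so that downstream log-transformation recovers
#' Gaussianity. Mediators follow the mediator model (exposure effects plus
#' covariate effects plus group-correlated Gaussian noise) on the log scale
#' and are exponentiated to positive raw values. The continuous outcome
#' (gestational age at delivery, weeks) follows the outcome model; the
#' binary outcome is the indicator of delivery before the preterm threshold.
#'
#' Ground-truth effects are defined on the log-standardized scale, the scale
#' on which all analytic models operate.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{cohort}{`cohort_table` for the analytic subset, with
#'       `ipw_weight` reflecting the case-control sampling fractions.}
#'     \item{exposures,mediators}{raw-scale [exposure_panel()] and
#'       [mediator_panel()] aligned to the subset rows.}
#'     \item{truth}{`sim_truth`: `true_nie` (q-by-p matrix of
#'       alpha-times-beta products), `true_nde` (q-by-p), `true_te`
#'       (length p), and `active_pairs`.}
#'     \item{full}{the same three data objects for the entire source cohort
#'       (all weights 1), for oracle computations at population scale.}
#'     \item{selection}{named selection probabilities by case status.}
#'   }
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_cohort
  p <- sum(config$class_sizes)
  q <- sum(config$group_sizes)

  exp_names <- unlist(lapply(names(config$class_sizes), function(k) {
    sprintf("%s_%02d", k, seq_len(config$class_sizes[[k]]))
  }))
  med_names <- unlist(lapply(names(config$group_sizes), function(g) {
    sprintf("%s_%02d", g, seq_len(config$group_sizes[[g]]))
  }))
  class_map <- stats::setNames(rep(names(config$class_sizes), config$class_sizes),
                               exp_names)
  group_map <- stats::setNames(rep(names(config$group_sizes), config$group_sizes),
                               med_names)

  # covariates: continuous standardized age, positive urinary specific
  # gravity, 3-level BMI category, 4-level education, two binaries
  covars <- data.frame(
    maternal_age_z = stats::rnorm(n),
    specific_gravity = 1.015 + 0.005 * stats::rnorm(n),
    bmi_cat = factor(sample(c("normal", "overweight", "obese"), n, TRUE,
                            prob = c(0.52, 0.29, 0.19)),
                     levels = c("normal", "overweight", "obese")),
    education = factor(sample(c("highschool", "technical", "somecollege", "college"),
                              n, TRUE, prob = c(0.12, 0.09, 0.35, 0.44)),
                       levels = c("highschool", "technical", "somecollege", "college")),
    smoker = stats::rbinom(n, 1, 0.06),
    alcohol = stats::rbinom(n, 1, 0.05)
  )
  Xc <- covariate_design(covars)
  ce_out <- rep_len(config$covariate_effects$outcome, ncol(Xc))
  # fixed alternating-sign covariate effects on each mediator
  ce_med <- config$covariate_effects$mediator *
    outer((-1)^(seq_len(q)), rep_len(c(1, -1, 0.5, -0.5), ncol(Xc)))
  Xc_c <- scale(Xc, center = TRUE, scale = FALSE)

  # log-exposures: block-correlated standard Gaussians, exponentiated
  R_exp <- block_correlation(config$class_sizes, config$within_class_rho,
                             config$between_class_rho)
  A_log <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R_exp)
  colnames(A_log) <- exp_names

  # log-mediators: exposure effects + covariate effects + correlated noise
  R_med <- block_correlation(config$group_sizes, config$within_group_rho, 0)
  E_med <- MASS::mvrnorm(n, mu = rep(0, q),
                         Sigma = config$noise_sd_mediator^2 * R_med)
  M_log <- A_log %*% t(config$alpha_matrix) + Xc_c %*% t(ce_med) + E_med
  colnames(M_log) <- med_names

  # continuous outcome: gestational age at delivery (weeks)
  y <- config$outcome_mean +
    drop(A_log %*% config$beta_a) +
    drop(M_log %*% config$beta_m) +
    drop(Xc_c %*% ce_out) +
    stats::rnorm(n, sd = config$noise_sd_outcome)
  preterm <- as.integer(y < config$preterm_threshold)
  spont <- integer(n)
  case_idx_all <- which(preterm == 1L)
  if (length(case_idx_all)) {
    n_sp <- round(config$spontaneous_fraction * length(case_idx_all))
    spont[sample(case_idx_all, n_sp)] <- 1L
  }

  full_cohort <- new_cohort_table(
    subject_id = sprintf("S%04d", seq_len(n)),
    covariates = covars,
    outcome_continuous = y,
    outcome_binary = preterm,
    outcome_binary_spontaneous = ifelse(preterm == 1L & spont == 0L, NA_integer_, spont),
    case_status = factor(ifelse(preterm == 1L, "case", "control"),
                         levels = c("control", "case")),
    ipw_weight = rep(1, n)
  )

  n_cases <- sum(preterm == 1L)
  n_controls <- n - n_cases
  assert_that(n_cases >= config$n_cases_sampled,
              "cohort produced only %d cases; %d requested for sampling",
              n_cases, config$n_cases_sampled)
  assert_that(n_controls >= config$n_controls_sampled,
              "cohort produced only %d controls; %d requested for sampling",
              n_controls, config$n_controls_sampled)
  sel <- c(sort(sample(which(preterm == 1L), config$n_cases_sampled)),
           sort(sample(which(preterm == 0L), config$n_controls_sampled)))
  sel_prob <- c(case = config$n_cases_sampled / n_cases,
                control = config$n_controls_sampled / n_controls)

  cohort <- full_cohort[sel, , drop = FALSE]
  cohort$ipw_weight <- compute_ipw(cohort$case_status, n_cases, n_controls)
  rownames(cohort) <- NULL
  class(cohort) <- class(full_cohort)

  truth <- sim_truth(config)

  list(
    cohort = cohort,
    exposures = exposure_panel(exp(A_log[sel, , drop = FALSE]), class_map),
    mediators = mediator_panel(exp(M_log[sel, , drop = FALSE]), group_map),
    truth = truth,
    full = list(
      cohort = full_cohort,
      exposures = exposure_panel(exp(A_log), class_map),
      mediators = mediator_panel(exp(M_log), group_map)
    ),
    selection = sel_prob
  )
}

# Ground truth on the log-standardized analytic scale.
sim_truth <- function(config) {
  nie <- config$alpha_matrix * config$beta_m       # q x p, row l scaled by beta_m[l]
  te <- config$beta_a + colSums(nie)               # per-exposure total effect
  nde <- sweep(-nie, 2, te, "+")                   # per-pair: te - nie
  active <- which(nie != 0, arr.ind = TRUE)
  structure(
    list(true_nie = nie, true_nde = nde, true_te = te,
         active_pairs = data.frame(mediator = active[, 1], exposure = active[, 2])),
    class = "sim_truth"
  )
}

new_cohort_table <- function(subject_id, covariates, outcome_continuous,
                             outcome_binary, outcome_binary_spontaneous,
                             case_status, ipw_weight) {
  out <- data.frame(subject_id = subject_id, covariates,
                    outcome_continuous = outcome_continuous,
                    outcome_binary = outcome_binary,
                    outcome_binary_spontaneous = outcome_binary_spontaneous,
                    case_status = case_status, ipw_weight = ipw_weight,
                    stringsAsFactors = FALSE)
  validate_cohort_table(out)
}

#' Validate and classify a cohort table
#'
#' The cohort table is the spine every analysis stage joins against:
#' covariates, outcomes, case status, and inverse-probability weights.
#'
#' @param x a data.frame with columns `subject_id`, covariates,
#'   `outcome_continuous`, `outcome_binary`, `outcome_binary_spontaneous`,
#'   `case_status`, `ipw_weight`.
#' @return `x` with class `cohort_table` prepended.
#' @export
validate_cohort_table <- function(x) {
  need <- c("subject_id", "outcome_continuous", "outcome_binary",
            "case_status", "ipw_weight")
  missing <- setdiff(need, names(x))
  assert_that(length(missing) == 0, "cohort table lacks columns: %s",
              paste(missing, collapse = ", "))
  assert_that(all(x$ipw_weight > 0), "ipw_weight must be positive for all subjects")
  assert_that(all((x$outcome_binary == 1L) == (x$case_status == "case")),
              "outcome_binary must agree with case_status")
  if (!inherits(x, "cohort_table")) class(x) <- c("cohort_table", class(x))
  x
}

#' Extract the covariate columns of a cohort table
#'
#' @param cohort a `cohort_table`.
#' @return A data.frame of the covariate columns (everything that is not
#'   an identifier, outcome, case status, or weight).
#' @export
cohort_covariates <- function(cohort) {
  drop_cols <- c("subject_id", "outcome_continuous", "outcome_binary",
                 "outcome_binary_spontaneous", "case_status", "ipw_weight")
  as.data.frame(cohort)[, setdiff(names(cohort), drop_cols), drop = FALSE]
}

#' Selection probabilities of the nested case-control subset
#'
#' @param case_status factor/character of sampled subjects' status
#'   (`"case"`/`"control"`), or a `cohort_table`.
#' @param cohort_case_count,cohort_control_count stratum counts in the full
#'   source cohort.
#' @return Named numeric: `P(selected | case)` and `P(selected | control)`.
#' @export
selection_probabilities <- function(case_status, cohort_case_count,
                                    cohort_control_count) {
  if (inherits(case_status, "cohort_table")) case_status <- case_status$case_status
  n_case <- sum(case_status == "case")
  n_control <- sum(case_status == "control")
  assert_that(cohort_case_count >= 1, "cohort must contain at least one case")
  assert_that(cohort_control_count >= 1, "cohort must contain at least one control")
  assert_that(n_case <= cohort_case_count && n_control <= cohort_control_count,
              "sampled strata cannot exceed cohort strata")
  c(case = n_case / cohort_case_count,
    control = n_control / cohort_control_count)
}

#' Write / read a synthetic cohort as CSV plus a column-role manifest
#'
#' The cohort, exposure, and mediator columns are written to a single
#' delimited file; a JSON manifest maps every column to its role (exposure
#' class, mediator group, covariate, outcome, selection/weight) so that the
#' dataset is self-describing.
#'
#' @param sim the list returned by [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `write_cohort_csv`: invisibly, the paths written.
#'   `read_cohort_csv`: a list with `cohort`, `exposures`, `mediators`.
#' @export
write_cohort_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cbind(as.data.frame(sim$cohort),
               as.data.frame(sim$exposures$values),
               as.data.frame(sim$mediators$values))
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  manifest <- list(
    columns = c(
      stats::setNames(as.list(rep("identifier", 1)), "subject_id"),
      stats::setNames(as.list(rep("covariate", ncol(cohort_covariates(sim$cohort)))),
                      names(cohort_covariates(sim$cohort))),
      list(outcome_continuous = "outcome", outcome_binary = "outcome",
           outcome_binary_spontaneous = "outcome",
           case_status = "selection", ipw_weight = "selection"),
      as.list(stats::setNames(paste0("exposure:", sim$exposures$map),
                              names(sim$exposures$map))),
      as.list(stats::setNames(paste0("mediator:", sim$mediators$map),
                              names(sim$mediators$map)))
    )
  )
  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, man, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = csv, manifest = man))
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  roles <- unlist(manifest$columns)
  exp_cols <- names(roles)[startsWith(roles, "exposure:")]
  med_cols <- names(roles)[startsWith(roles, "mediator:")]
  cov_cols <- names(roles)[roles == "covariate"]
  cohort <- tab[, c("subject_id", cov_cols, "outcome_continuous", "outcome_binary",
                    "outcome_binary_spontaneous", "case_status", "ipw_weight")]
  for (cc in cov_cols) if (is.character(cohort[[cc]])) cohort[[cc]] <- factor(cohort[[cc]])
  cohort$case_status <- factor(cohort$case_status, levels = c("control", "case"))
  cohort <- validate_cohort_table(cohort)
  list(
    cohort = cohort,
    exposures = exposure_panel(as.matrix(tab[, exp_cols, drop = FALSE]),
                               stats::setNames(sub("^exposure:", "", roles[exp_cols]),
                                               exp_cols)),
    mediators = mediator_panel(as.matrix(tab[, med_cols, drop = FALSE]),
                               stats::setNames(sub("^mediator:", "", roles[med_cols]),
                                               med_cols))
  )
}
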