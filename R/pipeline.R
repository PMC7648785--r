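#' Configuration for a full framework run
#'
#' Bundles the simulation (or input data), the stages to execute, and the
#' per-stage settings into one object consumed by [run_framework()].
#'
#' @param sim a [sim_config()] describing the synthetic cohort, or `NULL`
#'   when `input_dir` points at an existing cohort CSV + manifest written
#'   by [write_cohort_csv()].
#' @param input_dir directory with `cohort.csv` and `manifest.json`
#'   (ignored when `sim` is supplied).
#' @param stages character vector of stages, any of `"simulate"`,
#'   `"pairwise"`, `"ers"`, `"ers_pairwise"`, `"bayes"`, `"groups"`,
#'   `"select"`, `"sensitivity"`. Dependencies are enforced at run time
#'   (`ers` must precede the score-based stages).
#' @param outcome outcome for the pairwise screen.
#' @param out_dir directory under which the run directory is created.
#' @param run_id run-directory name; default is a timestamp.
#' @param seed master seed; every stochastic stage derives its own stream.
#' @param settings named list of per-stage overrides: `ers_folds`,
#'   `bayes_iter`, `bayes_burnin`, `bayes_grouping`, `plasso_folds`,
#'   `sensitivity_exposure`, `sensitivity_rho_grid`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       stages = c("simulate", "pairwise", "ers",
                                  "ers_pairwise", "groups"),
                       outcome = "continuous",
                       out_dir = tempdir(), run_id = NULL, seed = 1L,
                       settings = list()) {
  known <- c("simulate", "pairwise", "ers", "ers_pairwise", "bayes",
             "groups", "select", "sensitivity")
  assert_that(all(stages %in% known), "unknown stage(s): %s",
              paste(setdiff(stages, known), collapse = ", "))
  assert_that(!is.null(sim) || !is.null(input_dir),
              "either a simulation config or an input directory is required")
  defaults <- list(ers_folds = 5, bayes_iter = 4000, bayes_burnin = 2000,
                   bayes_grouping = "by_group", plasso_folds = 5,
                   sensitivity_exposure = NULL,
                   sensitivity_rho_grid = seq(-0.9, 0.9, by = 0.01))
  settings <- utils::modifyList(defaults, settings)
  structure(list(sim = sim, input_dir = input_dir, stages = stages,
                 outcome = outcome, out_dir = out_dir, run_id = run_id,
                 seed = as.integer(seed), settings = settings),
            class = "run_config")
}

#' Execute the analytical framework end-to-end
#'
#' Runs the requested stages in dependency order, writing every artifact
#' (tidy result tables as CSV, model objects as JSON, a structured log,
#' and a manifest sufficient for exact re-execution) under a run
#' directory. A stage failure halts its dependents but independent stages
#' continue; the returned object records per-stage status.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `run_dir`, `status` (named character per
#'   stage), and `artifacts` (paths). The `failed` attribute is `TRUE` if
#'   any requested stage errored.
#' @export
run_framework <- function(config = run_config()) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  run_id <- config$run_id %||% format(Sys.time(), "run_%Y%m%d_%H%M%S")
  run_dir <- file.path(config$out_dir, run_id)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(run_dir, "log.txt")
  status <- stats::setNames(rep("pending", length(config$stages)),
                            config$stages)
  artifacts <- list()
  st <- config$settings
  cfg_hash <- config_hash(config)

  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  run_stage <- function(name, deps, expr) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    bad <- deps[status[deps] %in% c("failed", "skipped (dependency failed)")]
    if (length(bad)) {
      status[name] <<- "skipped (dependency failed)"
      log_line("stage %s skipped (failed dependency: %s)", name,
               paste(bad, collapse = ", "))
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    res <- tryCatch({ force(expr); "ok" },
                    error = function(e) paste0("failed: ", conditionMessage(e)))
    status[name] <<- if (res == "ok") "ok" else "failed"
    log_line("stage %s: %s (%.2fs)", name, res,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  stamp <- function(df, stage) {
    df$stage <- stage; df$seed <- config$seed; df$config_hash <- cfg_hash
    df
  }
  write_table <- function(df, name, stage) {
    path <- file.path(run_dir, name)
    utils::write.csv(stamp(df, stage), path, row.names = FALSE)
    artifacts[[name]] <<- path
  }

  data_env <- new.env()
  run_stage("simulate", character(0), {
    sim <- generate_cohort(config$sim)
    write_cohort_csv(sim, run_dir)
    assign("data", sim[c("cohort", "exposures", "mediators")],
           envir = data_env)
    assign("truth", sim$truth, envir = data_env)
  })
  if (is.null(data_env$data)) {
    src <- config$input_dir %||% run_dir
    if (file.exists(file.path(src, "cohort.csv"))) {
      assign("data", read_cohort_csv(src), envir = data_env)
    }
  }
  dat <- function() {
    d <- get0("data", envir = data_env)
    assert_that(!is.null(d), "no cohort data available (simulate stage or input_dir required)")
    d
  }

  run_stage("pairwise", "simulate", {
    d <- dat()
    tab <- run_pairwise_screen(d$exposures, d$mediators, d$cohort,
                               outcome_kind = config$outcome)
    write_table(tab, "pairwise.csv", "pairwise")
  })

  run_stage("ers", "simulate", {
    d <- dat()
    ers <- build_ers_panel(d$exposures, d$cohort, folds = st$ers_folds,
                           seed = child_seed(config$seed, "ers"))
    assign("ers", ers, envir = data_env)
    for (k in names(ers$models)) {
      p <- file.path(run_dir, sprintf("ers_model_%s.json", k))
      write_risk_score_model(ers$models[[k]], p)
      artifacts[[basename(p)]] <- p
    }
    write_table(as.data.frame(ers$scores), "ers_scores.csv", "ers")
  })

  run_stage("ers_pairwise", c("simulate", "ers"), {
    d <- dat()
    tab <- ers_mediation_screen(data_env$ers, d$mediators, d$cohort)
    write_table(tab, "ers_pairwise.csv", "ers_pairwise")
  })

  run_stage("bayes", c("simulate", "ers"), {
    d <- dat()
    tab <- run_shrinkage_over_exposures(
      data_env$ers$scores, d$mediators, d$cohort,
      grouping = st$bayes_grouping, iter = st$bayes_iter,
      burnin = st$bayes_burnin, seed = child_seed(config$seed, "bayes"))
    write_table(tab, "bayes_shrinkage.csv", "bayes")
  })

  run_stage("groups", c("simulate", "ers"), {
    d <- dat()
    rows <- list(); dirs <- list()
    for (k in colnames(data_env$ers$scores)) {
      scan <- group_mediation_scan(data_env$ers$scores[, k], d$mediators,
                                   d$cohort,
                                   seed = child_seed(config$seed, k))
      scan$results$exposure_id <- k
      rows[[k]] <- scan$results
      dirs[[k]] <- lapply(scan$directions, function(dd)
        list(group = dd$group_g, loadings = as.list(dd$w_g),
             objective = dd$objective_value, status = dd$status))
    }
    write_table(do.call(rbind, rows), "group_mediation.csv", "groups")
    p <- file.path(run_dir, "directions.json")
    jsonlite::write_json(dirs, p, auto_unbox = TRUE, digits = NA)
    artifacts[["directions.json"]] <- p
  })

  run_stage("select", c("simulate", "ers"), {
    d <- dat()
    Mz <- panel_log(d$mediators, standardize = TRUE)
    y <- drop(scale(d$cohort$outcome_continuous, scale = FALSE))
    covars <- cohort_covariates(d$cohort)
    rows <- list()
    for (k in colnames(data_env$ers$scores)) {
      a <- drop(scale(data_env$ers$scores[, k]))
      pl <- pathway_lasso_fit(a, Mz$values, y, covars,
                              cv_folds = st$plasso_folds,
                              seed = child_seed(config$seed, paste0("pl_", k)))
      js <- mcp_joint_significance(a, Mz$values, y, covars)
      rows[[k]] <- rbind(
        if (length(pl$selected))
          data.frame(exposure_id = k, method = "pathway_lasso",
                     mediator_id = pl$selected,
                     mediator_group = unname(Mz$map[pl$selected]),
                     q_joint = NA_real_, stringsAsFactors = FALSE),
        if (nrow(js))
          data.frame(exposure_id = k, method = "mcp_joint",
                     mediator_id = js$mediator_id,
                     mediator_group = unname(Mz$map[js$mediator_id]),
                     q_joint = js$q_joint_bh, stringsAsFactors = FALSE))
    }
    sel <- do.call(rbind, rows)
    if (is.null(sel)) sel <- data.frame(exposure_id = character(0),
                                        method = character(0),
                                        mediator_id = character(0),
                                        mediator_group = character(0),
                                        q_joint = numeric(0))
    write_table(sel, "selection.csv", "select")
  })

  run_stage("sensitivity", c("simulate", "ers"), {
    d <- dat()
    exp_id <- st$sensitivity_exposure %||% colnames(data_env$ers$scores)[1]
    a <- drop(scale(data_env$ers$scores[, exp_id]))
    Mz <- panel_log(d$mediators, standardize = TRUE)
    dir_all <- estimate_direction(a, Mz$values, d$cohort$outcome_continuous,
                                  cohort_covariates(d$cohort),
                                  weights = d$cohort$ipw_weight,
                                  group = "all",
                                  seed = child_seed(config$seed, "sens"))
    fit <- mge_mediation(a, dir_all, d$cohort)
    prof <- rho_sensitivity(fit, st$sensitivity_rho_grid)
    y_sd <- stats::sd(d$cohort$outcome_continuous)
    ev <- evalue_continuous(fit$nie / y_sd, fit$se_nie / y_sd)
    scan <- covariate_combination_scan(a, drop(scale(dir_all$mge)), d$cohort)
    write_table(scan, "covariate_scan.csv", "sensitivity")
    p <- file.path(run_dir, "sensitivity.json")
    jsonlite::write_json(
      list(exposure = exp_id, nie = fit$nie, te = fit$te,
           rho_zero = prof$rho_zero,
           r2_product_zero = prof$r2_product_zero,
           evalue = ev[["evalue"]], evalue_ci_bound = ev[["ci_bound"]],
           covariate_sign_stability = attr(scan, "sign_stability")),
      p, auto_unbox = TRUE, digits = NA)
    artifacts[["sensitivity.json"]] <- p
  })

  manifest <- list(run_id = run_id, seed = config$seed,
                   stages = config$stages, status = as.list(status),
                   outcome = config$outcome, settings = st,
                   config_hash = cfg_hash,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(run_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out <- list(run_dir = run_dir, status = status, artifacts = artifacts)
  attr(out, "failed") <- any(status == "failed")
  invisible(out)
}

# deterministic hash of the configuration (stages, seeds, settings)
config_hash <- function(config) {
  raw <- serialize(config[c("sim", "stages", "outcome", "seed", "settings")],
                   NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 257 + b) %% 2147483629
  sprintf("%08x", h)
}

#' Render report tables from a run directory
#'
#' Builds plot-ready data tables from whatever stage outputs are present:
#' minus-log10 p-value tables (volcano/dot charts) for the pairwise and
#' risk-score screens keyed by exposure class, and a forest table of
#' TE/NDE/NIE rows per (score, group) for the group-effect stage, with
#' class color-coding metadata.
#'
#' @param run_dir a directory produced by [run_framework()].
#' @return A list of data.frames (also written as CSV under
#'   `run_dir/report/`), or a list with `status = "nothing to report"`.
#' @export
render_report <- function(run_dir) {
  out <- list()
  class_colors <- c(phthalate = "orange", phenol = "purple", pah = "green",
                    metal = "gray")
  rep_dir <- file.path(run_dir, "report")
  for (stage_file in c("pairwise.csv", "ers_pairwise.csv")) {
    path <- file.path(run_dir, stage_file)
    if (!file.exists(path)) next
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    ok <- tab$status == "ok"
    t2 <- data.frame(
      exposure_id = tab$exposure_id[ok],
      exposure_class = tab$exposure_class[ok],
      mediator_id = tab$mediator_id[ok],
      neglog10_p_nie = -log10(pmax(tab$p_nie[ok], 1e-300)),
      nie = tab$nie[ok],
      color = unname(class_colors[tab$exposure_class[ok]]),
      stringsAsFactors = FALSE)
    out[[sub(".csv", "_neglog10p", stage_file, fixed = TRUE)]] <- t2
  }
  path <- file.path(run_dir, "group_mediation.csv")
  if (file.exists(path)) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    long <- do.call(rbind, lapply(c("te", "nde", "nie"), function(eff) {
      data.frame(exposure_id = tab$exposure_id, group = tab$group,
                 effect = toupper(eff), estimate = tab[[eff]],
                 status = tab$status, stringsAsFactors = FALSE)
    }))
    out[["forest_group_mediation"]] <- long
  }
  if (length(out) == 0) return(list(status = "nothing to report"))
  dir.create(rep_dir, showWarnings = FALSE)
  for (nm in names(out)) {
    utils::write.csv(out[[nm]], file.path(rep_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  out
}
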