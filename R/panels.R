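#' Feature panels: exposures and mediators
#'
#' An exposure panel holds a subjects-by-analytes matrix together with the
#' partition of analytes into exposure classes (phthalates, phenols,
#' polycyclic aromatic hydrocarbons, metals) and a record of the transform
#' applied so far (`raw`, `log`, or `log-z`). A mediator panel is the same
#' structure for endogenous biomarkers partitioned into biological groups
#' (cyclooxygenase, cytochrome p450, lipoxygenase, parent lipids,
#' inflammation, oxidative stress, protein damage).
#'
#' @param values numeric matrix, subjects in rows, features in columns;
#'   raw values must be strictly positive so the log transform is defined.
#' @param class_map,group_map named character vector mapping each column
#'   name to its class/group label; must cover every column exactly once.
#' @param transform_state one of `"raw"`, `"log"`, `"log-z"`.
#' @return An object of class `exposure_panel` / `mediator_panel`: a list
#'   with elements `values`, `class_map` (or `group_map`), and
#'   `transform_state`.
#' @export
exposure_panel <- function(values, class_map, transform_state = "raw") {
  new_panel(values, class_map, transform_state, "exposure_panel", "class")
}

#' @rdname exposure_panel
#' @export
mediator_panel <- function(values, group_map, transform_state = "raw") {
  new_panel(values, group_map, transform_state, "mediator_panel", "group")
}

new_panel <- function(values, map, transform_state, cls, role) {
  values <- as.matrix(values)
  assert_that(!is.null(colnames(values)), "panel matrix must have column names")
  assert_that(is.character(map) && !is.null(names(map)),
              "%s_map must be a named character vector", role)
  assert_that(setequal(names(map), colnames(values)) &&
                length(map) == ncol(values),
              "%s_map must partition the panel columns exactly", role)
  transform_state <- match.arg(transform_state, c("raw", "log", "log-z"))
  if (transform_state == "raw" && any(values <= 0)) {
    stop_mm("raw panel values must be strictly positive (log transform must be defined)")
  }
  structure(
    list(values = values, map = map[colnames(values)],
         transform_state = transform_state),
    class = c(cls, "mm_panel")
  )
}

#' @export
print.mm_panel <- function(x, ...) {
  role <- if (inherits(x, "exposure_panel")) "exposure classes" else "mediator groups"
  cat(sprintf("<%s> %d subjects x %d features [%s], %s: %s\n",
              class(x)[1], nrow(x$values), ncol(x$values), x$transform_state,
              role, paste(sprintf("%s=%d", names(table(x$map)), table(x$map)),
                          collapse = ", ")))
  invisible(x)
}

#' Log-transform and optionally standardize a panel
#'
#' Analytes and biomarkers are right-skewed concentrations; all analytic
#' models operate on the log scale, and score-based stages additionally
#' z-score each column.
#'
#' @param panel an [exposure_panel()] or [mediator_panel()].
#' @param standardize if `TRUE`, z-score each column after logging.
#' @return The panel with transformed `values` and updated `transform_state`.
#' @export
panel_log <- function(panel, standardize = FALSE) {
  assert_that(inherits(panel, "mm_panel"), "panel must be an exposure/mediator panel")
  v <- panel$values
  if (panel$transform_state == "raw") {
    assert_that(all(v > 0), "cannot log-transform non-positive values")
    v <- log(v)
    panel$transform_state <- "log"
  }
  if (standardize && panel$transform_state != "log-z") {
    v <- zscore_cols(v, "feature")
    panel$transform_state <- "log-z"
  }
  panel$values <- v
  panel
}

panel_map <- function(panel) panel$map

# subset a panel's rows (used when aligning to an analytic subset)
panel_rows <- function(panel, idx) {
  panel$values <- panel$values[idx, , drop = FALSE]
  panel
}
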