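#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mm <- function(fmt, ..., class = "mixmediate_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error")))
}

warn_mm <- function(fmt, ..., class = "mixmediate_warning") {
  warning(warningCondition(sprintf(fmt, ...), class = c(class, "warning")))
}

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_mm(fmt, ...)
  invisible(TRUE)
}

# Deterministic child seed derived from a master seed and a stream label.
# Kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, stream) {
  bytes <- utf8ToInt(paste0(stream, ":", seed))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

# Column-standardize a matrix (mean 0, sd 1); errors on zero-variance columns.
zscore_cols <- function(x, what = "column") {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  bad <- which(sds <= .Machine$double.eps^0.5)
  if (length(bad)) {
    stop_mm("zero-variance %s(s): %s", what,
            paste(colnames(x)[bad] %||% bad, collapse = ", "))
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

# Dummy-code a covariate data.frame (first-level reference), no intercept.
covariate_design <- function(covariates) {
  if (is.null(covariates) ||
      (!is.null(ncol(covariates)) && ncol(covariates) == 0)) {
    return(NULL)   # cbind(<x>, NULL) drops the block cleanly
  }
  if (is.matrix(covariates)) return(covariates)
  mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  mm[, -1, drop = FALSE]
}
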