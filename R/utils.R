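# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# z-standardize a numeric vector, preserving names.
# Errors on zero variance because a constant score/phenotype cannot enter a
# standardized association model.
zstd <- function(x, what = "variable") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize '", what, "': zero or non-finite variance",
         call. = FALSE)
  }
  structure((x - mean(x)) / s, names = names(x))
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x)) {
    stop("'", name, "' must be a single positive integer", call. = FALSE)
  }
  invisible(as.integer(x))
}

# align named vectors / tables on a common subject id set, in covariate order
align_subjects <- function(ids, ...) {
  vs <- list(...)
  for (v in vs) {
    if (is.null(names(v))) {
      stop("subject-keyed vectors must be named by subject id", call. = FALSE)
    }
  }
  common <- ids
  for (v in vs) common <- intersect(common, names(v))
  common
}
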