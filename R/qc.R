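#' Remove subjects flagged for relatedness or cohort overlap
#'
#' Subjects flagged TRUE (e.g. biologically related to another
#' participant, or included in a discovery study's sample) are dropped
#' before any analysis.
#'
#' @param subject_ids character vector of subjects under consideration.
#' @param flags named logical vector (names are subject ids); every
#'   flagged id must be a known subject.
#' @return retained subject ids, with attribute \code{"n_removed"}.
#' @export
exclude_flagged <- function(subject_ids, flags) {
  stopifnot(is.logical(flags))
  if (is.null(names(flags))) {
    stop("'flags' must be named by subject id", call. = FALSE)
  }
  unknown <- setdiff(names(flags), subject_ids)
  if (length(unknown)) {
    stop("flags refer to unknown subject id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  bad <- names(flags)[flags]
  out <- setdiff(subject_ids, bad)
  message(length(subject_ids) - length(out),
          " subject(s) removed by relatedness/overlap flag")
  structure(out, n_removed = length(subject_ids) - length(out))
}

#' Exclude subjects more than k SD from the sample mean
#'
#' Single-pass outlier exclusion on a global measure: the mean and SD are
#' computed once over all supplied subjects and subjects with
#' \code{|value - mean| > k * SD} are dropped. The filter is applied
#' separately per measure (FA and MD), so the two analysis samples may
#' differ. The pass is deliberately not iterated.
#'
#' @param values named numeric vector (names are subject ids).
#' @param k SD multiplier; default 3.
#' @return retained subject ids, with attribute \code{"n_removed"}.
#' @export
exclude_outliers <- function(values, k = 3) {
  stopifnot(is.numeric(values), length(values) >= 2L, k > 0)
  if (is.null(names(values))) {
    stop("'values' must be named by subject id", call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero standard deviation; no outlier exclusions applied")
    return(structure(names(values), n_removed = 0L))
  }
  keep <- abs(values - m) <= k * s
  structure(names(values)[keep], n_removed = sum(!keep))
}

phenotype_wide <- function(phen_table, variables, measure) {
  tab <- phen_table[phen_table$measure == measure, , drop = FALSE]
  tab$variable <- ifelse(tab$hemisphere == "none", tab$tract_id,
                         paste(tab$tract_id, tab$hemisphere, sep = "_"))
  tab <- tab[tab$variable %in% variables, , drop = FALSE]
  wide <- stats::reshape(tab[, c("subject_id", "variable", "value")],
                         idvar = "subject_id", timevar = "variable",
                         direction = "wide")
  colnames(wide) <- sub("^value\\.", "", colnames(wide))
  missing_vars <- setdiff(variables, colnames(wide))
  if (length(missing_vars)) {
    stop("phenotype table lacks variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  rownames(wide) <- wide$subject_id
  wide[, variables, drop = FALSE]
}

#' Derive a latent phenotype as the first unrotated principal component
#'
#' Runs PCA over a tract-variable set (all 27 variables for the global
#' measure; 12, 6 or 9 for the association, thalamic and projection
#' categories) on the correlation scale (columns mean-centered and
#' unit-scaled) and extracts subject scores on the first unrotated
#' component. The component sign is fixed so that the mean loading is
#' positive, making effect directions reproducible. Subjects with any
#' missing variable are dropped.
#'
#' @param phen_table long phenotype table (subject_id, measure, tract_id,
#'   hemisphere, value).
#' @param atlas a [make_tract_atlas()] atlas.
#' @param subset \code{"global"} or a tract category.
#' @param measure \code{"FA"} or \code{"MD"}.
#' @return object of class \code{latent_phenotype}: list(scores
#'   (data.frame subject_id, value), loadings (unit-norm named vector),
#'   explained_variance, n_variables, subset, measure).
#' @export
derive_latent <- function(phen_table, atlas,
                          subset = c("global", "association", "thalamic",
                                     "projection"),
                          measure = c("FA", "MD")) {
  subset <- match.arg(subset)
  measure <- match.arg(measure)
  vars <- if (subset == "global") {
    atlas_variables(atlas)$variable
  } else {
    atlas_variables(atlas, category = subset)$variable
  }
  wide <- phenotype_wide(phen_table, vars, measure)
  cc <- stats::complete.cases(wide)
  if (any(!cc)) {
    message(sum(!cc), " subject(s) dropped from ", subset, " ", measure,
            " PCA for incomplete tract data")
  }
  wide <- wide[cc, , drop = FALSE]
  if (nrow(wide) <= ncol(wide)) {
    stop("PCA needs more subjects (", nrow(wide), ") than tract variables (",
         ncol(wide), ")", call. = FALSE)
  }
  pc <- stats::prcomp(as.matrix(wide), center = TRUE, scale. = TRUE)
  loadings <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  if (mean(loadings) < 0) {            # fixed sign convention
    loadings <- -loadings
    scores <- -scores
  }
  structure(list(
    scores = data.frame(subject_id = rownames(wide), value = unname(scores),
                        stringsAsFactors = FALSE),
    loadings = loadings,
    explained_variance = pc$sdev[1]^2 / sum(pc$sdev^2),
    n_variables = ncol(wide),
    subset = subset, measure = measure
  ), class = "latent_phenotype")
}

#' Long (repeated-measures) format for one bilateral tract
#'
#' Produces the two-rows-per-subject table the bilateral mixed model
#' consumes: one row per hemisphere with covariates replicated. Subjects
#' missing either hemisphere are dropped. Unilateral tracts are rejected
#' with a pointer to the linear-model path.
#'
#' @param phen_table long phenotype table.
#' @param atlas a [make_tract_atlas()] atlas.
#' @param tract tract id; must be bilateral.
#' @param measure \code{"FA"} or \code{"MD"}.
#' @param covariates optional covariate data.frame keyed by subject_id to
#'   replicate onto both rows.
#' @return data.frame: subject_id, hemisphere ("left"/"right"), value,
#'   plus any covariate columns.
#' @export
hemisphere_long_format <- function(phen_table, atlas, tract,
                                   measure = c("FA", "MD"),
                                   covariates = NULL) {
  measure <- match.arg(measure)
  row <- atlas[atlas$tract_id == tract, , drop = FALSE]
  if (!nrow(row)) stop("unknown tract '", tract, "'", call. = FALSE)
  if (!row$bilateral) {
    stop("tract '", tract, "' is unilateral; use the linear-model path ",
         "(fit_linear) instead", call. = FALSE)
  }
  tab <- phen_table[phen_table$measure == measure &
                      phen_table$tract_id == tract &
                      phen_table$hemisphere %in% c("left", "right"), ,
                    drop = FALSE]
  counts <- table(tab$subject_id)
  complete <- names(counts)[counts == 2L]
  dropped <- setdiff(unique(tab$subject_id), complete)
  if (length(dropped)) {
    message(length(dropped), " subject(s) dropped from tract '", tract,
            "' for a missing hemisphere")
  }
  out <- tab[tab$subject_id %in% complete,
             c("subject_id", "hemisphere", "value")]
  out <- out[order(out$subject_id, out$hemisphere), , drop = FALSE]
  if (!is.null(covariates)) {
    out <- merge(out, covariates, by = "subject_id", sort = TRUE)
  }
  rownames(out) <- NULL
  out
}
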