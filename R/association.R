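#' Modeled covariate columns
#'
#' The fixed covariate set of every association model: age, age squared,
#' sex, fifteen genetic principal components, three scanner head-position
#' coordinates, scanner site and genotype array.
#'
#' @return character vector of column names.
#' @export
covariate_columns <- function() {
  c("age", "age_squared", "sex", paste0("pc", 1:15),
    "pos_x", "pos_y", "pos_z", "site", "array")
}

#' Validate and prepare a covariate table for modeling
#'
#' Checks completeness, enforces \code{age_squared == age^2} (recomputing
#' it if absent), and converts site and array to treatment-coded factors
#' with the first level as reference.
#'
#' @param cov_table data.frame with \code{subject_id} and the
#'   [covariate_columns()] (age_squared may be omitted).
#' @return data.frame with subject_id plus the modeled columns.
#' @export
prepare_covariates <- function(cov_table) {
  stopifnot(is.data.frame(cov_table), "subject_id" %in% names(cov_table))
  if (!"age_squared" %in% names(cov_table)) {
    cov_table$age_squared <- cov_table$age^2
  }
  if (max(abs(cov_table$age_squared - cov_table$age^2)) > 0) {
    stop("'age_squared' must equal age^2 exactly", call. = FALSE)
  }
  need <- setdiff(covariate_columns(), names(cov_table))
  if (length(need)) {
    stop("covariate table lacks column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- cov_table[, c("subject_id", covariate_columns())]
  if (anyNA(out)) stop("covariates contain missing values", call. = FALSE)
  out$site <- factor(out$site)
  out$array <- factor(out$array)
  out
}

# Align phenotype, score and covariates on common subjects; both vectors
# must be named by subject id.
model_frame <- function(phenotype, score, covariates, standardize) {
  ids <- align_subjects(covariates$subject_id, phenotype, score)
  if (length(ids) < 2L) stop("fewer than 2 common subjects", call. = FALSE)
  y <- phenotype[ids]
  s <- score[ids]
  if (standardize) {
    y <- zstd(y, "phenotype")
    s <- zstd(s, "score")
  }
  cv <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
  check_design(cv)
  data.frame(.y = unname(y), .score = unname(s),
             cv[, setdiff(names(cv), "subject_id"), drop = FALSE],
             row.names = NULL, check.names = FALSE)
}

check_design <- function(cv) {
  for (nm in setdiff(names(cv), "subject_id")) {
    v <- cv[[nm]]
    distinct <- if (is.factor(v)) nlevels(droplevels(v)) else
      length(unique(v))
    if (distinct < 2L) {
      stop("rank-deficient design: covariate '", nm, "' is constant",
           call. = FALSE)
    }
  }
  invisible(cv)
}

new_association_result <- function(score_id, phenotype, measure, model,
                                   effect, se, tval, p, r2_pct, n,
                                   converged = TRUE) {
  data.frame(score_id = score_id, phenotype = phenotype, measure = measure,
             model = model, effect = effect, se = se, t = tval, p = p,
             q = NA_real_, r2_increment_pct = r2_pct, n_subjects = n,
             converged = converged, stringsAsFactors = FALSE)
}

#' Linear association model for unilateral, global and category phenotypes
#'
#' Ordinary least squares of the (standardized) phenotype on the
#' (standardized) score plus the full covariate set. Reports the score
#' coefficient, its SE, t and two-sided p, and the incremental variance
#' explained beyond the covariates-only model, in percent (floored at 0
#' against floating-point underruns).
#'
#' @param phenotype named numeric vector (subject ids as names).
#' @param score named numeric vector.
#' @param covariates prepared covariate table ([prepare_covariates()]).
#' @param standardize z-standardize phenotype and score first
#'   (default TRUE).
#' @param score_id,phenotype_id,measure labels carried into the result.
#' @return one-row \code{AssociationResult} data.frame.
#' @export
fit_linear <- function(phenotype, score, covariates, standardize = TRUE,
                       score_id = "score", phenotype_id = "phenotype",
                       measure = NA_character_) {
  d <- model_frame(phenotype, score, covariates, standardize)
  full <- stats::lm(.y ~ ., data = d)
  if (anyNA(stats::coef(full))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("rank-deficient design; aliased term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  reduced <- stats::lm(.y ~ . - .score, data = d)
  co <- summary(full)$coefficients[".score", ]
  r2_inc <- max(summary(full)$r.squared - summary(reduced)$r.squared, 0)
  new_association_result(score_id, phenotype_id, measure, "linear",
                         co[["Estimate"]], co[["Std. Error"]],
                         co[["t value"]], co[["Pr(>|t|)"]],
                         100 * r2_inc, nrow(d))
}

#' Bilateral mixed model with hemisphere as a within-subject variable
#'
#' Linear mixed model for one bilateral tract: fixed effects are the
#' score, the covariate set and a hemisphere indicator; a random
#' intercept per subject captures the shared left-right component.
#' Estimation is by REML (nlme, tolerance 1e-8, up to 200 iterations).
#'
#' At the degenerate boundary where left and right values coincide for
#' every subject (up to a constant hemisphere offset), the within-subject
#' residual variance is zero and iterative REML is numerically unstable;
#' there the fitter uses the analytic limit of the random-intercept GLS
#' estimator, which is OLS on the subject means (the hemisphere offset is
#' the mean left-right difference).
#'
#' Incremental variance explained is computed at the subject level
#' (between-subject R2 of the subject-mean regression with and without
#' the score), matching the linear path's definition.
#'
#' @param long_table two rows per subject: subject_id, hemisphere
#'   ("left"/"right"), value (see [hemisphere_long_format()]).
#' @param score named numeric vector.
#' @param covariates prepared covariate table.
#' @param standardize z-standardize the tract values (across all rows)
#'   and the score first (default TRUE).
#' @param score_id,phenotype_id,measure labels carried into the result.
#' @return one-row \code{AssociationResult} data.frame; on REML
#'   non-convergence the row is returned with \code{converged = FALSE}
#'   and NA statistics, with a warning.
#' @export
fit_bilateral_mixed <- function(long_table, score, covariates,
                                standardize = TRUE, score_id = "score",
                                phenotype_id = "tract",
                                measure = NA_character_) {
  stopifnot(all(c("subject_id", "hemisphere", "value") %in%
                  names(long_table)))
  ids <- align_subjects(covariates$subject_id, score)
  ids <- intersect(ids, long_table$subject_id)
  tab <- long_table[long_table$subject_id %in% ids, , drop = FALSE]
  counts <- table(tab$subject_id)
  ids <- names(counts)[counts == 2L]
  tab <- tab[tab$subject_id %in% ids, , drop = FALSE]
  if (length(ids) < 3L) stop("fewer than 3 complete subjects", call. = FALSE)
  tab <- tab[order(tab$subject_id, tab$hemisphere), , drop = FALSE]

  s <- if (standardize) zstd(score[ids], "score") else score[ids]
  yraw <- tab$value
  cv <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
  check_design(cv)

  # subject-level summaries, used for incremental R2 and the boundary
  ymat <- matrix(yraw, nrow = 2L)                    # col per subject
  ymean <- colMeans(ymat)
  ydiff <- ymat[2L, ] - ymat[1L, ]                   # right - left
  dmean <- data.frame(.y = ymean, .score = unname(s),
                      cv[, setdiff(names(cv), "subject_id"), drop = FALSE],
                      row.names = NULL, check.names = FALSE)
  full_mean <- stats::lm(.y ~ ., data = dmean)
  red_mean <- stats::lm(.y ~ . - .score, data = dmean)
  r2_inc <- max(summary(full_mean)$r.squared - summary(red_mean)$r.squared, 0)

  degenerate <- stats::var(ydiff) <= 1e-12 * max(stats::var(yraw), 1e-300)
  if (degenerate) {
    # sigma^2 -> 0 limit of the random-intercept GLS estimator: the
    # subject-level regression, standardized on the collapsed data
    dd <- dmean
    if (standardize) dd$.y <- zstd(dd$.y, "tract value")
    fd <- stats::lm(.y ~ ., data = dd)
    co <- summary(fd)$coefficients[".score", ]
    return(new_association_result(score_id, phenotype_id, measure,
                                  "mixed_bilateral", co[["Estimate"]],
                                  co[["Std. Error"]], co[["t value"]],
                                  co[["Pr(>|t|)"]], 100 * r2_inc,
                                  length(ids)))
  }
  y <- if (standardize) zstd(yraw, "tract value") else yraw

  dlong <- data.frame(.y = y, .score = rep(unname(s), each = 2L),
                      .hemi = factor(tab$hemisphere,
                                     levels = c("left", "right")),
                      .subject = factor(tab$subject_id),
                      cv[rep(seq_along(ids), each = 2L),
                         setdiff(names(cv), "subject_id"), drop = FALSE],
                      row.names = NULL, check.names = FALSE)
  fixed_terms <- setdiff(names(dlong), c(".y", ".subject"))
  fml <- stats::as.formula(paste(".y ~", paste(fixed_terms, collapse = " + ")))
  fit <- tryCatch(
    nlme::lme(fixed = fml, random = ~ 1 | .subject, data = dlong,
              method = "REML",
              control = nlme::lmeControl(maxIter = 200L, msMaxIter = 200L,
                                         tolerance = 1e-8)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    # retry with the derivative-free optimizer before giving up
    fit <- tryCatch(
      nlme::lme(fixed = fml, random = ~ 1 | .subject, data = dlong,
                method = "REML",
                control = nlme::lmeControl(maxIter = 200L,
                                           msMaxIter = 200L,
                                           tolerance = 1e-8,
                                           opt = "optim")),
      error = function(e) e
    )
  }
  if (inherits(fit, "error")) {
    warning("mixed model for '", phenotype_id, "' (", score_id,
            ") did not converge: ", conditionMessage(fit), call. = FALSE)
    return(new_association_result(score_id, phenotype_id, measure,
                                  "mixed_bilateral", NA_real_, NA_real_,
                                  NA_real_, NA_real_, NA_real_,
                                  length(ids), converged = FALSE))
  }
  tt <- summary(fit)$tTable[".score", ]
  new_association_result(score_id, phenotype_id, measure, "mixed_bilateral",
                         tt[["Value"]], tt[["Std.Error"]], tt[["t-value"]],
                         tt[["p-value"]], 100 * r2_inc, length(ids))
}

#' Quadratic-term model for non-linear score effects
#'
#' OLS with the standardized score and its square (the square computed
#' after standardization, then itself centered) alongside the covariates.
#' Reports the additional variance explained by the quadratic term beyond
#' the linear model, in percent, and the quadratic term's p-value.
#'
#' @inheritParams fit_linear
#' @return one-row data.frame: score_id, phenotype, measure,
#'   r2_quadratic_pct, p_quadratic, n_subjects.
#' @export
fit_quadratic <- function(phenotype, score, covariates, standardize = TRUE,
                          score_id = "score", phenotype_id = "phenotype",
                          measure = NA_character_) {
  d <- model_frame(phenotype, score, covariates, standardize)
  sq <- d$.score^2
  d$.score_sq <- sq - mean(sq)
  quad <- stats::lm(.y ~ ., data = d)
  if (anyNA(stats::coef(quad))) {
    bad <- names(stats::coef(quad))[is.na(stats::coef(quad))]
    stop("rank-deficient design; aliased term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  lin <- stats::lm(.y ~ . - .score_sq, data = d)
  co <- summary(quad)$coefficients[".score_sq", ]
  r2q <- max(summary(quad)$r.squared - summary(lin)$r.squared, 0)
  data.frame(score_id = score_id, phenotype = phenotype_id,
             measure = measure, r2_quadratic_pct = 100 * r2q,
             p_quadratic = co[["Pr(>|t|)"]], n_subjects = nrow(d),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR correction within test families
#'
#' Adjusts p-values with \code{stats::p.adjust(method = "fdr")}
#' separately within each family (e.g. individual tracts vs global and
#' category latents, per measure) and flags results with q below the
#' significance level. Rows without a p-value (non-converged fits) are
#' excluded from the family with a warning and keep \code{q = NA}.
#'
#' @param results data.frame of association results with a \code{p}
#'   column.
#' @param family optional vector (length nrow) of family labels; a single
#'   family if omitted.
#' @param q_threshold significance level on q; default 0.05.
#' @return \code{results} with columns \code{q} and \code{significant}
#'   filled in, plus attribute \code{"family_sizes"}.
#' @export
fdr_correct <- function(results, family = NULL, q_threshold = 0.05) {
  stopifnot(is.data.frame(results), "p" %in% names(results))
  if (!nrow(results)) {
    results$q <- numeric(0)
    results$significant <- logical(0)
    attr(results, "family_sizes") <- integer(0)
    return(results)
  }
  family <- family %||% rep("all", nrow(results))
  stopifnot(length(family) == nrow(results))
  if (anyNA(results$p)) {
    warning(sum(is.na(results$p)),
            " result(s) without p-value excluded from FDR correction",
            call. = FALSE)
  }
  results$q <- NA_real_
  for (f in unique(family)) {
    idx <- which(family == f & !is.na(results$p))
    results$q[idx] <- stats::p.adjust(results$p[idx], method = "fdr")
  }
  results$significant <- !is.na(results$q) & results$q < q_threshold
  fs <- table(family[!is.na(results$p)])
  attr(results, "family_sizes") <- stats::setNames(as.integer(fs), names(fs))
  results
}

#' Size of a score-by-phenotype test family
#'
#' @param n_scores number of retained eQTL scores.
#' @param n_phenotypes number of phenotypes each score is tested against.
#' @return integer number of tests.
#' @export
family_size <- function(n_scores, n_phenotypes) {
  stopifnot_scalar_count(n_scores, "n_scores")
  stopifnot_scalar_count(n_phenotypes, "n_phenotypes")
  as.integer(n_scores) * as.integer(n_phenotypes)
}

#' Side-by-side comparison of a gene scored by both discovery studies
#'
#' For genes present in both studies (bypassing de-duplication), fits the
#' linear model for each study's score against the same phenotype and
#' returns the paired results.
#'
#' @param gene gene identifier.
#' @param defs_a,defs_b per-study \code{score_definitions} (before
#'   de-duplication).
#' @param genotypes cohort \code{genotype_matrix}.
#' @param phenotype named numeric phenotype vector.
#' @param covariates prepared covariate table.
#' @param phenotype_id,measure labels carried into the results.
#' @return two-row AssociationResult data.frame (one per study).
#' @export
overlap_comparison <- function(gene, defs_a, defs_b, genotypes, phenotype,
                               covariates, phenotype_id = "phenotype",
                               measure = NA_character_) {
  pick <- function(defs, label) {
    genes <- vapply(defs, `[[`, "", "gene")
    i <- match(gene, genes)
    if (is.na(i)) {
      stop("gene '", gene, "' absent from study ", label, call. = FALSE)
    }
    defs[[i]]
  }
  da <- pick(defs_a, "A")
  db <- pick(defs_b, "B")
  res <- lapply(list(da, db), function(def) {
    sc <- compute_scores(structure(list(def), class = "score_definitions"),
                         genotypes)
    fit_linear(phenotype, stats::setNames(sc[, 1], rownames(sc)),
               covariates, score_id = score_column_id(def),
               phenotype_id = phenotype_id, measure = measure)
  })
  do.call(rbind, res)
}
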