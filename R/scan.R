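#' Association scan of every score against every phenotype, with FDR
#'
#' Runs the full association stage for one measure (FA or MD): derives
#' the four latent phenotypes (global + three tract categories), fits the
#' linear model for each score against each latent and each unilateral
#' tract, fits the hemisphere-aware mixed model for each bilateral tract,
#' and applies Benjamini-Hochberg FDR correction separately within the
#' two test families (individual tracts; global and category latents).
#'
#' @param scores subjects x scores matrix from [compute_scores()]
#'   (standardized or not; fits standardize internally).
#' @param phen_table long phenotype table.
#' @param covariates prepared covariate table ([prepare_covariates()]).
#' @param atlas a [make_tract_atlas()] atlas.
#' @param measure \code{"FA"} or \code{"MD"}.
#' @param subjects optional subject ids to restrict to (post-QC sample).
#' @param quadratic also fit quadratic-term models for the latent
#'   phenotypes? Default FALSE.
#' @param q_threshold FDR significance level; default 0.05.
#' @param families which test families to run: \code{"latent"} (global +
#'   category PCA phenotypes), \code{"tract"} (individual tracts), or
#'   both (default).
#' @return list with \code{results} (AssociationResult rows with columns
#'   \code{family} and \code{q}), \code{family_sizes}, \code{latents}
#'   (the four \code{latent_phenotype} objects) and, if requested,
#'   \code{quadratic} results.
#' @export
run_association_scan <- function(scores, phen_table, covariates, atlas,
                                 measure = c("FA", "MD"), subjects = NULL,
                                 quadratic = FALSE, q_threshold = 0.05,
                                 families = c("latent", "tract")) {
  measure <- match.arg(measure)
  families <- match.arg(families, several.ok = TRUE)
  if (!is.null(subjects)) {
    scores <- scores[rownames(scores) %in% subjects, , drop = FALSE]
    phen_table <- phen_table[phen_table$subject_id %in% subjects, ,
                             drop = FALSE]
    covariates <- covariates[covariates$subject_id %in% subjects, ,
                             drop = FALSE]
  }
  score_ids <- colnames(scores)
  score_vec <- function(j) stats::setNames(scores[, j], rownames(scores))

  latents <- lapply(c("global", "association", "thalamic", "projection"),
                    function(ss) derive_latent(phen_table, atlas,
                                               subset = ss,
                                               measure = measure))
  names(latents) <- vapply(latents, `[[`, "", "subset")

  res <- list()
  quad <- list()
  if ("latent" %in% families) for (lat in latents) {
    y <- stats::setNames(lat$scores$value, lat$scores$subject_id)
    for (j in score_ids) {
      r <- fit_linear(y, score_vec(j), covariates, score_id = j,
                      phenotype_id = lat$subset, measure = measure)
      r$family <- "latent"
      res[[length(res) + 1L]] <- r
      if (quadratic) {
        quad[[length(quad) + 1L]] <-
          fit_quadratic(y, score_vec(j), covariates, score_id = j,
                        phenotype_id = lat$subset, measure = measure)
      }
    }
  }

  if ("tract" %in% families) for (t in seq_len(nrow(atlas))) {
    tid <- atlas$tract_id[t]
    if (atlas$bilateral[t]) {
      long <- hemisphere_long_format(phen_table, atlas, tid,
                                     measure = measure)
      for (j in score_ids) {
        r <- fit_bilateral_mixed(long, score_vec(j), covariates,
                                 score_id = j, phenotype_id = tid,
                                 measure = measure)
        r$family <- "tract"
        res[[length(res) + 1L]] <- r
      }
    } else {
      tab <- phen_table[phen_table$measure == measure &
                          phen_table$tract_id == tid, , drop = FALSE]
      y <- stats::setNames(tab$value, tab$subject_id)
      for (j in score_ids) {
        r <- fit_linear(y, score_vec(j), covariates, score_id = j,
                        phenotype_id = tid, measure = measure)
        r$family <- "tract"
        res[[length(res) + 1L]] <- r
      }
    }
  }

  results <- do.call(rbind, res)
  results <- fdr_correct(results, family = results$family,
                         q_threshold = q_threshold)
  out <- list(results = results,
              family_sizes = attr(results, "family_sizes"),
              latents = latents)
  if (quadratic) out$quadratic <- do.call(rbind, quad)
  out
}
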