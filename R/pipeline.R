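#' Pipeline configuration
#'
#' One structured configuration drives the full run: the synthetic-data
#' generator settings plus scoring, QC and association parameters.
#'
#' @param sim a [simulation_config()].
#' @param p_threshold inclusive discovery p-value threshold (default
#'   1e-5).
#' @param fdr_q FDR significance level (default 0.05).
#' @param tol relative singular-value cutoff for the generalized inverse.
#' @param outlier_sd SD multiplier of the global-measure exclusion
#'   (default 3).
#' @param quadratic also fit quadratic-term models? Default FALSE.
#' @param overlap_comparison fit overlapping genes from both studies
#'   side by side? Default FALSE.
#' @param measures which measures to analyze (default FA and MD).
#' @param out_dir optional output directory; when set, every artifact is
#'   written as tab-separated text plus a JSON manifest.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = simulation_config(), p_threshold = 1e-5,
                            fdr_q = 0.05, tol = 1e-8, outlier_sd = 3,
                            quadratic = FALSE, overlap_comparison = FALSE,
                            measures = c("FA", "MD"), out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"),
            p_threshold > 0, p_threshold <= 1,
            fdr_q > 0, fdr_q < 1, tol > 0, outlier_sd > 0,
            all(measures %in% c("FA", "MD")))
  structure(list(sim = sim, p_threshold = p_threshold, fdr_q = fdr_q,
                 tol = tol, outlier_sd = outlier_sd, quadratic = quadratic,
                 overlap_comparison = overlap_comparison,
                 measures = measures, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full pipeline: simulate, score, QC, associate, report
#'
#' Executes every stage end to end on synthetic data with known ground
#' truth: block-LD reference panel and cohort; two eQTL discovery
#' studies; p-value thresholding, allele harmonization, LD-adjusted score
#' construction and cross-study de-duplication; relatedness-flag and
#' +/- 3 SD global-outlier exclusions (per measure, on the derived global
#' latent); and the two-family association scan with FDR correction.
#' Reruns with the same configuration reproduce all outputs
#' bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return list of class \code{eqtl_pipeline}: manifest (stage counts),
#'   results (per measure), scores, score manifest, latents, truth,
#'   config.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$sim

  # --- simulate -------------------------------------------------------
  panel <- simulate_reference_panel(cfg)
  sums <- simulate_eqtl_summaries(panel, cfg)
  cohort <- simulate_cohort(panel, cfg)
  atlas <- make_tract_atlas()
  phen <- simulate_tract_phenotypes(cohort$genotypes, sums$truth, atlas,
                                    cfg, cohort$covariates)

  # --- score ----------------------------------------------------------
  amap <- cohort_allele_map(cohort$genotypes)
  stage <- function(records) {
    sel <- select_snps(records, config$p_threshold)
    harm <- suppressWarnings(harmonize_alleles(sel, amap))
    list(n_read = nrow(records), n_after_threshold = nrow(sel),
         n_dropped_harmonization = nrow(sel) - nrow(harm),
         records = harm)
  }
  st_a <- stage(sums$study_a)
  st_b <- stage(sums$study_b)
  defs_a <- build_score_definitions(st_a$records, panel, tol = config$tol)
  defs_b <- build_score_definitions(st_b$records, panel, tol = config$tol)
  defs <- deduplicate_scores(defs_a, defs_b)
  accounting <- attr(defs, "accounting")
  scores <- compute_scores(defs, cohort$genotypes, standardize = TRUE)

  # --- QC -------------------------------------------------------------
  covs <- prepare_covariates(cohort$covariates)
  flags <- stats::setNames(cohort$covariates$excluded,
                           cohort$covariates$subject_id)
  kept0 <- suppressMessages(
    exclude_flagged(cohort$covariates$subject_id, flags))

  subjects <- list()
  qc_counts <- list()
  for (m in config$measures) {
    glob <- derive_latent(phen[phen$subject_id %in% kept0, , drop = FALSE],
                          atlas, subset = "global", measure = m)
    vals <- stats::setNames(glob$scores$value, glob$scores$subject_id)
    kept <- exclude_outliers(vals, k = config$outlier_sd)
    subjects[[m]] <- kept
    qc_counts[[m]] <- list(
      n_initial = cfg$n_subjects,
      n_after_flag = length(kept0),
      n_after_outlier = length(kept)
    )
  }

  # --- associate ------------------------------------------------------
  results <- list()
  family_sizes <- list()
  latents <- list()
  quad <- list()
  for (m in config$measures) {
    scan <- run_association_scan(scores, phen, covs, atlas, measure = m,
                                 subjects = subjects[[m]],
                                 quadratic = config$quadratic,
                                 q_threshold = config$fdr_q)
    results[[m]] <- scan$results
    family_sizes[[m]] <- scan$family_sizes
    latents[[m]] <- scan$latents
    if (config$quadratic) quad[[m]] <- scan$quadratic
  }

  overlap <- NULL
  if (config$overlap_comparison && accounting$n_overlap > 0) {
    genes_a <- vapply(defs_a, `[[`, "", "gene")
    genes_b <- vapply(defs_b, `[[`, "", "gene")
    shared <- intersect(genes_a, genes_b)
    m1 <- config$measures[1]
    glat <- latents[[m1]]$global
    y <- stats::setNames(glat$scores$value, glat$scores$subject_id)
    overlap <- do.call(rbind, lapply(shared, function(g) {
      overlap_comparison(g, defs_a, defs_b, cohort$genotypes, y, covs,
                         phenotype_id = "global", measure = m1)
    }))
  }

  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("eqtlwm")),
    p_threshold = config$p_threshold,
    fdr_q = config$fdr_q,
    snps_read = c(study_a = st_a$n_read, study_b = st_b$n_read),
    snps_after_threshold = c(study_a = st_a$n_after_threshold,
                             study_b = st_b$n_after_threshold),
    snps_dropped_harmonization = c(study_a = st_a$n_dropped_harmonization,
                                   study_b = st_b$n_dropped_harmonization),
    scores_built = c(study_a = accounting$n_built_a,
                     study_b = accounting$n_built_b),
    overlap_genes = accounting$n_overlap,
    scores_retained = accounting$n_retained,
    scores_retained_by_study = c(study_a = accounting$n_retained_a,
                                 study_b = accounting$n_retained_b),
    subjects = qc_counts,
    family_sizes = family_sizes
  )

  out <- list(manifest = manifest, results = results, scores = scores,
              score_manifest = score_manifest(defs), latents = latents,
              truth = sums$truth, defs = defs, defs_a = defs_a,
              defs_b = defs_b, overlap_comparison = overlap,
              quadratic = if (config$quadratic) quad,
              subjects = subjects, covariates = covs, phenotypes = phen,
              cohort_genotypes = cohort$genotypes, panel = panel,
              config = config)
  class(out) <- "eqtl_pipeline"

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(out, config$out_dir)
  }
  out
}

#' Write all pipeline outputs to a directory
#'
#' @param run an \code{eqtl_pipeline} result.
#' @param dir output directory (created if absent).
#' @export
write_pipeline_outputs <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_score_matrix(run$scores, file.path(dir, "scores.tsv"))
  write_phenotypes(run$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_covariates(run$covariates, file.path(dir, "covariates.tsv"))
  for (m in names(run$results)) {
    tsv_write(run$results[[m]],
              file.path(dir, sprintf("associations_%s.tsv", m)))
    if (!is.null(run$quadratic[[m]])) {
      tsv_write(run$quadratic[[m]],
                file.path(dir, sprintf("quadratic_%s.tsv", m)))
    }
  }
  write_ground_truth(run$truth, file.path(dir, "ground_truth.json"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.eqtl_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("eQTL score pipeline run (seed ", m$seed, ")\n", sep = "")
  cat("  scores built: ", m$scores_built[["study_a"]], " + ",
      m$scores_built[["study_b"]], "; retained after de-duplication: ",
      m$scores_retained, " (overlap ", m$overlap_genes, ")\n", sep = "")
  for (meas in names(x$results)) {
    cat("  ", meas, ": ", sum(x$results[[meas]]$significant),
        " significant association(s) of ", nrow(x$results[[meas]]),
        " tests\n", sep = "")
  }
  invisible(x)
}
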