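# Tab-separated readers/writers for every pipeline artifact. All files
# are plain text with headers so runs are inspectable and diffable.

tsv_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tsv_read <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read eQTL summary statistics
#'
#' Columns: snp, chr, pos, effect_allele, other_allele, beta, se, p,
#' gene, study.
#'
#' @param records summary-statistic data.frame.
#' @param path file path.
#' @export
write_sumstats <- function(records, path) {
  cols <- c("snp", "chr", "pos", "effect_allele", "other_allele",
            "beta", "se", "p", "gene", "study")
  tsv_write(records[, intersect(cols, names(records))], path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) tsv_read(path)

#' Write / read a dosage matrix with its allele sidecar
#'
#' The dosage file has a \code{subject_id} column plus one column per SNP
#' (0/1/2 copies of the reference allele); the sidecar
#' (\code{<path>.alleles}) records snp_id, chr, pos, ref_allele,
#' alt_allele so effect alleles can be harmonized.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param path dosage file path.
#' @export
write_dosages <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  df <- data.frame(subject_id = rownames(genotypes$dosage),
                   genotypes$dosage, check.names = FALSE)
  tsv_write(df, path)
  sidecar <- genotypes$snp_info[, c("snp_id", "chr", "pos",
                                    "ref_allele", "alt_allele")]
  tsv_write(sidecar, paste0(path, ".alleles"))
  invisible(path)
}

#' @rdname write_dosages
#' @export
read_dosages <- function(path) {
  df <- tsv_read(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject_id
  info <- tsv_read(paste0(path, ".alleles"))
  stopifnot(identical(info$snp_id, colnames(m)))
  new_genotype_matrix(m, info)
}

#' Write / read the long tract-phenotype table
#'
#' Columns: subject_id, measure, tract_id, hemisphere, value.
#' @param phen_table long phenotype data.frame.
#' @param path file path.
#' @export
write_phenotypes <- function(phen_table, path) tsv_write(phen_table, path)

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) tsv_read(path)

#' Write / read the covariate table
#' @param covariates covariate data.frame keyed by subject_id.
#' @param path file path.
#' @export
write_covariates <- function(covariates, path) tsv_write(covariates, path)

#' @rdname write_covariates
#' @export
read_covariates <- function(path) tsv_read(path)

#' Write the score matrix and its manifest
#'
#' @param scores matrix from [compute_scores()].
#' @param path score file path; the manifest goes to
#'   \code{<path>.manifest}.
#' @export
write_score_matrix <- function(scores, path) {
  df <- data.frame(subject_id = rownames(scores), scores,
                   check.names = FALSE)
  tsv_write(df, path)
  mf <- attr(scores, "manifest")
  if (!is.null(mf)) tsv_write(mf, paste0(path, ".manifest"))
  invisible(path)
}

#' Write ground truth as structured text (JSON)
#' @param truth the truth element of [simulate_eqtl_summaries()].
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(planted = truth$planted,
         planted_genes = truth$planted_genes,
         gene_effects = truth$gene_effects),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
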