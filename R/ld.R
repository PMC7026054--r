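#' SNP-SNP correlation matrix from a reference panel
#'
#' Pearson correlation of dosage columns over the listed SNPs, in the
#' given order. This is the matrix R whose generalized inverse adjusts the
#' eQTL effect-size vector for linkage disequilibrium.
#'
#' @param panel a \code{genotype_matrix} reference panel.
#' @param snp_ids character vector of SNP identifiers, all present in the
#'   panel; duplicates allowed (duplicate columns are perfectly
#'   correlated).
#' @return object of class \code{ld_matrix}: list(snp_ids, R).
#' @export
compute_ld_matrix <- function(panel, snp_ids) {
  stopifnot(inherits(panel, "genotype_matrix"), length(snp_ids) >= 1L)
  if (nrow(panel$dosage) < 2L) {
    stop("reference panel must contain at least 2 individuals", call. = FALSE)
  }
  missing <- setdiff(snp_ids, colnames(panel$dosage))
  if (length(missing)) {
    stop("SNP(s) absent from reference panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- panel$dosage[, snp_ids, drop = FALSE]
  if (anyNA(x)) {
    stop("missing dosages are not supported; found NA in reference panel",
         call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance SNP(s) in reference panel: ",
         paste(snp_ids[sds == 0], collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(x)
  dimnames(R) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, R = R), class = "ld_matrix")
}

#' Moore-Penrose generalized inverse of an LD matrix
#'
#' Computed via singular value decomposition; singular values below
#' \code{tol} times the largest are treated as zero, which handles
#' perfectly collinear SNPs (rank-deficient R) gracefully. The effective
#' rank actually used is recorded.
#'
#' @param ld an \code{ld_matrix}, or a plain symmetric matrix.
#' @param tol relative singular-value cutoff (default 1e-8).
#' @return object of class \code{ld_inverse}: list(snp_ids, Rinv, rank).
#' @export
generalized_inverse <- function(ld, tol = 1e-8) {
  if (inherits(ld, "ld_matrix")) {
    R <- ld$R
    ids <- ld$snp_ids
  } else {
    R <- as.matrix(ld)
    ids <- colnames(R) %||% as.character(seq_len(ncol(R)))
  }
  stopifnot(nrow(R) == ncol(R))
  sv <- svd(R)
  keep <- sv$d > tol * sv$d[1]
  rank <- sum(keep)
  if (rank == 0L) {
    Rinv <- matrix(0, nrow(R), ncol(R))
  } else {
    Rinv <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  }
  dimnames(Rinv) <- dimnames(R)
  structure(list(snp_ids = ids, Rinv = Rinv, rank = rank),
            class = "ld_inverse")
}

#' Write a per-gene LD block for inspection
#'
#' @param ld an \code{ld_matrix}.
#' @param path output file; tab-separated with a SNP-id header column.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  df <- data.frame(snp_id = ld$snp_ids, ld$R, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
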