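#' Threshold summary statistics on the discovery p-value
#'
#' Retains records with p at or below the threshold (the threshold is read
#' as the largest admissible p-value); genes whose SNPs all fail the
#' threshold drop out of the score set entirely.
#'
#' @param records summary-statistic data.frame (columns snp,
#'   effect_allele, other_allele, beta, se, p, gene, study, ...).
#' @param p_threshold inclusive p-value threshold; default 1e-5.
#' @return the retained records.
#' @export
select_snps <- function(records, p_threshold = 1e-5) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) return(records)
  if (any(records$p <= 0 | records$p > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  records[records$p <= p_threshold, , drop = FALSE]
}

#' Allele map of a genotyped cohort
#'
#' @param genotypes a \code{genotype_matrix}.
#' @return data.frame (snp_id, ref_allele, alt_allele); \code{ref_allele}
#'   is the allele counted by the dosages.
#' @export
cohort_allele_map <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  genotypes$snp_info[, c("snp_id", "ref_allele", "alt_allele")]
}

is_strand_ambiguous <- function(a1, a2) {
  pair <- paste(pmin(toupper(a1), toupper(a2)),
                pmax(toupper(a1), toupper(a2)))
  pair %in% c("A T", "C G")
}

#' Harmonize summary-statistic alleles to the cohort's counted allele
#'
#' Aligns each record's effect direction with the allele the cohort
#' dosages count (the reference allele). Where the record's effect allele
#' already is the counted allele, beta is unchanged; where it is the other
#' allele, beta is sign-flipped and the alleles swapped. Strand-ambiguous
#' SNPs (A/T, C/G) are dropped, as are SNPs absent from the cohort map and
#' records whose allele pair cannot be reconciled; each category of drop
#' is reported in a single warning.
#'
#' @param records summary-statistic data.frame.
#' @param allele_map cohort allele map from [cohort_allele_map()].
#' @return harmonized records, with an attribute \code{"dropped"} holding
#'   the per-reason drop counts.
#' @export
harmonize_alleles <- function(records, allele_map) {
  stopifnot(is.data.frame(records), is.data.frame(allele_map))
  if (!nrow(records)) {
    attr(records, "dropped") <-
      c(missing = 0L, ambiguous = 0L, mismatch = 0L)
    return(records)
  }
  idx <- match(records$snp, allele_map$snp_id)
  missing <- is.na(idx)
  ref <- allele_map$ref_allele[idx]
  alt <- allele_map$alt_allele[idx]
  ambiguous <- !missing &
    is_strand_ambiguous(records$effect_allele, records$other_allele)
  same <- !missing & !ambiguous &
    records$effect_allele == ref & records$other_allele == alt
  flipped <- !missing & !ambiguous &
    records$effect_allele == alt & records$other_allele == ref
  mismatch <- !missing & !ambiguous & !same & !flipped

  dropped <- c(missing = sum(missing), ambiguous = sum(ambiguous),
               mismatch = sum(mismatch))
  if (any(dropped > 0)) {
    warning(sprintf(
      "harmonization dropped %d record(s): %d absent from cohort, %d strand-ambiguous (A/T, C/G), %d irreconcilable alleles",
      sum(dropped), dropped[["missing"]], dropped[["ambiguous"]],
      dropped[["mismatch"]]), call. = FALSE)
  }

  out <- records[same | flipped, , drop = FALSE]
  fl <- flipped[same | flipped]
  if (any(fl)) {
    ea <- out$effect_allele
    out$effect_allele[fl] <- out$other_allele[fl]
    out$other_allele[fl] <- ea[fl]
    out$beta[fl] <- -out$beta[fl]
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Build LD-adjusted score definitions per (gene, study)
#'
#' For each gene within each study: SNPs are ordered deterministically by
#' chromosome, position, then id; the per-gene SNP correlation matrix R is
#' estimated from the reference panel; and the LD-adjusted weight vector
#' is \eqn{w = R^{-}\beta} with \eqn{R^{-}} the Moore-Penrose generalized
#' inverse. The minimum SNP p-value of the score (\code{best_p}) is
#' recorded for cross-study de-duplication.
#'
#' @param records harmonized, thresholded summary statistics.
#' @param panel reference panel (\code{genotype_matrix}) for LD.
#' @param tol relative singular-value cutoff passed to
#'   [generalized_inverse()].
#' @return a \code{score_definitions} list; each element has fields gene,
#'   study, snp_ids, betas, weights, best_p, n_snps, ld_rank.
#' @export
build_score_definitions <- function(records, panel, tol = 1e-8) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    return(structure(list(), class = "score_definitions"))
  }
  key <- paste(records$gene, records$study, sep = "\r")
  groups <- split(records, key)
  defs <- lapply(groups, function(gr) {
    ord <- order(gr$chr %||% 0L, gr$pos %||% 0L, gr$snp)
    gr <- gr[ord, , drop = FALSE]
    if (nrow(gr) == 1L) {
      w <- gr$beta
      rank <- 1L
    } else {
      ld <- compute_ld_matrix(panel, gr$snp)
      gi <- generalized_inverse(ld, tol = tol)
      w <- drop(gi$Rinv %*% gr$beta)
      rank <- gi$rank
    }
    structure(list(gene = gr$gene[1], study = gr$study[1],
                   snp_ids = gr$snp, betas = gr$beta, weights = w,
                   best_p = min(gr$p), n_snps = nrow(gr), ld_rank = rank),
              class = "score_definition")
  })
  ord <- order(vapply(defs, `[[`, "", "gene"),
               vapply(defs, `[[`, "", "study"))
  structure(unname(defs[ord]), class = "score_definitions")
}

score_column_id <- function(def) paste(def$gene, def$study, sep = ".")

#' Compute per-subject eQTL scores
#'
#' The score of individual i for gene/trait t is the dosage-weighted sum
#' \eqn{score(i,t) = \sum_j g_{ij} w_{tj} = g_i R^{-}\beta_t}, one column
#' per retained score definition.
#'
#' @param defs \code{score_definitions}.
#' @param genotypes cohort \code{genotype_matrix}; every definition SNP
#'   must be present.
#' @param standardize z-standardize each score column across subjects
#'   (mean 0, SD 1)? Default FALSE (raw weighted allele counts).
#' @return numeric matrix subjects x scores with a \code{"manifest"}
#'   attribute (gene, study, n_snps, best_p, snps per column).
#' @export
compute_scores <- function(defs, genotypes, standardize = FALSE) {
  stopifnot(inherits(defs, "score_definitions"),
            inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes$dosage)
  if (!length(defs)) {
    return(structure(matrix(numeric(0), n, 0,
                            dimnames = list(rownames(genotypes$dosage),
                                            NULL)),
                     manifest = score_manifest(defs)))
  }
  cols <- lapply(defs, function(def) {
    missing <- setdiff(def$snp_ids, colnames(genotypes$dosage))
    if (length(missing)) {
      stop("cohort genotypes lack SNP(s) ", paste(missing, collapse = ", "),
           " required by the score for gene ", def$gene, call. = FALSE)
    }
    drop(genotypes$dosage[, def$snp_ids, drop = FALSE] %*% def$weights)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(defs, score_column_id, "")
  rownames(m) <- rownames(genotypes$dosage)
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      stop("cannot standardize constant score column(s): ",
           paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
    }
    m <- scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  attr(m, "manifest") <- score_manifest(defs)
  m
}

#' Manifest table of a score-definition set
#'
#' @param defs \code{score_definitions}.
#' @return data.frame: score_id, gene, study, n_snps, best_p, snps
#'   (comma-separated).
#' @export
score_manifest <- function(defs) {
  if (!length(defs)) {
    return(data.frame(score_id = character(0), gene = character(0),
                      study = character(0), n_snps = integer(0),
                      best_p = numeric(0), snps = character(0)))
  }
  data.frame(
    score_id = vapply(defs, score_column_id, ""),
    gene = vapply(defs, `[[`, "", "gene"),
    study = vapply(defs, `[[`, "", "study"),
    n_snps = vapply(defs, `[[`, 0L, "n_snps"),
    best_p = vapply(defs, `[[`, 0, "best_p"),
    snps = vapply(defs, function(d) paste(d$snp_ids, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}

#' De-duplicate scores across two discovery studies
#'
#' For each gene scored by both studies, only the score containing the SNP
#' with the lowest discovery p-value (\code{best_p}) is kept; genes
#' present in one study only are kept unconditionally. Exact ties go to
#' the first-listed study, making the outcome deterministic. Output is
#' sorted by gene.
#'
#' @param defs_a,defs_b \code{score_definitions} from the two studies;
#'   \code{defs_a} has tie-break priority.
#' @return retained \code{score_definitions} with an attribute
#'   \code{"accounting"}: n_built_a, n_built_b, n_overlap, n_retained,
#'   n_retained_a, n_retained_b.
#' @export
deduplicate_scores <- function(defs_a, defs_b) {
  stopifnot(inherits(defs_a, "score_definitions"),
            inherits(defs_b, "score_definitions"))
  genes_a <- vapply(defs_a, `[[`, "", "gene")
  genes_b <- vapply(defs_b, `[[`, "", "gene")
  if (anyDuplicated(genes_a) || anyDuplicated(genes_b)) {
    stop("each study must contribute at most one score per gene",
         call. = FALSE)
  }
  overlap <- intersect(genes_a, genes_b)
  keep_a <- defs_a[!(genes_a %in% overlap)]
  keep_b <- defs_b[!(genes_b %in% overlap)]
  for (g in overlap) {
    da <- defs_a[[match(g, genes_a)]]
    db <- defs_b[[match(g, genes_b)]]
    if (da$best_p <= db$best_p) {           # tie -> first-listed study
      keep_a <- c(keep_a, list(da))
    } else {
      keep_b <- c(keep_b, list(db))
    }
  }
  out <- c(keep_a, keep_b)
  out <- out[order(vapply(out, `[[`, "", "gene"))]
  studies_a <- unique(vapply(defs_a, `[[`, "", "study"))
  st <- vapply(out, `[[`, "", "study")
  accounting <- list(
    n_built_a = length(defs_a), n_built_b = length(defs_b),
    n_overlap = length(overlap), n_retained = length(out),
    n_retained_a = sum(st %in% studies_a),
    n_retained_b = sum(!(st %in% studies_a))
  )
  structure(out, class = "score_definitions", accounting = accounting)
}

#' Score-count accounting identities
#'
#' Bookkeeping used in the run manifest: total scores built across two
#' discovery studies, total retained after cross-study de-duplication, and
#' the number of overlapping genes implied by the conservation identity
#' retained = built_A + built_B - overlap.
#'
#' @param n_built_a,n_built_b scores built per study.
#' @param n_retained_a,n_retained_b scores retained per study after
#'   de-duplication.
#' @return list: total_built, total_retained, n_overlap_excluded.
#' @export
score_accounting <- function(n_built_a, n_built_b,
                             n_retained_a, n_retained_b) {
  total_built <- n_built_a + n_built_b
  total_retained <- n_retained_a + n_retained_b
  list(total_built = total_built,
       total_retained = total_retained,
       n_overlap_excluded = total_built - total_retained)
}
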