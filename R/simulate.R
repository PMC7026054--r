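#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every parameter of the simulated study: a
#' block-LD reference panel standing in for an external haplotype
#' reference, two whole-blood eQTL discovery studies with partially
#' overlapping gene sets, an imaging cohort with genotypes and covariates,
#' and bilateral FA/MD tract phenotypes carrying a planted standardized
#' effect of the true expression score of designated genes.
#'
#' Defaults encode the simulated study conditions: per-gene SNP counts
#' uniform on 1..15, a planted standardized effect of 0.05 (the magnitude
#' of the headline effect sizes the pipeline is designed to detect at
#' cohort scale), cohort ages uniform on 45.92-80.67 years, two scanner
#' sites with frequencies 0.843/0.157 and two genotyping arrays at
#' 0.9/0.1, moderate within-block LD (rho = 0.5) and left-right tract
#' correlation 0.7.
#'
#' @param n_ref reference-panel size (individuals) used for LD and for the
#'   discovery-study regressions.
#' @param n_subjects imaging-cohort size.
#' @param n_blocks,snps_per_block LD structure: independent blocks of
#'   exchangeably correlated SNPs.
#' @param rho within-block latent correlation, in \[0, 1).
#' @param maf_range minor-allele-frequency bounds (low, high).
#' @param n_genes_study_a,n_genes_study_b,n_overlap_genes study
#'   composition; overlapping genes are scored independently by both
#'   studies.
#' @param snps_per_gene_range inclusive bounds for the per-gene SNP count.
#' @param expr_h2_per_snp range of expression variance explained per causal
#'   SNP (controls discovery-study power).
#' @param effect_size planted standardized effect of the true expression
#'   score on every tract variable (FA negative, MD positive).
#' @param n_planted_genes how many genes carry the planted effect.
#' @param hemi_corr left-right correlation of bilateral tract values,
#'   in \[0, 1\].
#' @param exclusion_fraction expected fraction of cohort subjects flagged
#'   for relatedness/cohort-overlap exclusion.
#' @param seed integer random seed; every generator derives its stream
#'   from it, so identical configurations reproduce outputs bit-identically.
#' @return a validated list of class \code{sim_config}.
#' @export
simulation_config <- function(n_ref = 1000L,
                              n_subjects = 2000L,
                              n_blocks = 24L,
                              snps_per_block = 16L,
                              rho = 0.5,
                              maf_range = c(0.05, 0.5),
                              n_genes_study_a = 25L,
                              n_genes_study_b = 30L,
                              n_overlap_genes = 8L,
                              snps_per_gene_range = c(1L, 15L),
                              expr_h2_per_snp = c(0.01, 0.05),
                              effect_size = 0.05,
                              n_planted_genes = 2L,
                              hemi_corr = 0.7,
                              exclusion_fraction = 0.02,
                              seed = 42L) {
  for (nm in c("n_ref", "n_subjects", "n_blocks", "snps_per_block",
               "n_genes_study_a", "n_genes_study_b")) {
    stopifnot_scalar_count(get(nm), nm)
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    stop("'rho' must lie in [0, 1)", call. = FALSE)
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("'maf_range' must satisfy 0 < low <= high <= 0.5", call. = FALSE)
  }
  if (n_overlap_genes < 0 ||
      n_overlap_genes > min(n_genes_study_a, n_genes_study_b)) {
    stop("'n_overlap_genes' must be between 0 and the smaller study size",
         call. = FALSE)
  }
  if (length(snps_per_gene_range) != 2L || snps_per_gene_range[1] < 1 ||
      snps_per_gene_range[1] > snps_per_gene_range[2]) {
    stop("'snps_per_gene_range' must be increasing and start at >= 1",
         call. = FALSE)
  }
  if (snps_per_gene_range[2] > snps_per_block) {
    stop("'snps_per_gene_range' upper bound exceeds 'snps_per_block'",
         call. = FALSE)
  }
  if (hemi_corr < 0 || hemi_corr > 1) {
    stop("'hemi_corr' must lie in [0, 1]", call. = FALSE)
  }
  if (exclusion_fraction < 0 || exclusion_fraction > 1) {
    stop("'exclusion_fraction' must lie in [0, 1]", call. = FALSE)
  }
  if (n_planted_genes < 0 || n_planted_genes > n_genes_study_a) {
    stop("'n_planted_genes' must not exceed 'n_genes_study_a'", call. = FALSE)
  }
  cfg <- list(
    n_ref = as.integer(n_ref), n_subjects = as.integer(n_subjects),
    n_blocks = as.integer(n_blocks),
    snps_per_block = as.integer(snps_per_block),
    rho = rho, maf_range = maf_range,
    n_genes_study_a = as.integer(n_genes_study_a),
    n_genes_study_b = as.integer(n_genes_study_b),
    n_overlap_genes = as.integer(n_overlap_genes),
    snps_per_gene_range = as.integer(snps_per_gene_range),
    expr_h2_per_snp = expr_h2_per_snp,
    effect_size = effect_size,
    n_planted_genes = as.integer(n_planted_genes),
    hemi_corr = hemi_corr,
    exclusion_fraction = exclusion_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# SNP map shared by the reference panel and the cohort: ids, block
# membership, chromosome/position, allele pair and MAF. Alleles are drawn
# from non-strand-ambiguous pairs; harmonization tests construct A/T and
# C/G records explicitly.
make_snp_map <- function(cfg) {
  m <- cfg$n_blocks * cfg$snps_per_block
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pick <- sample.int(length(pairs), m, replace = TRUE)
  al <- do.call(rbind, pairs[pick])
  data.frame(
    snp_id = sprintf("snp%05d", seq_len(m)),
    block = rep(seq_len(cfg$n_blocks), each = cfg$snps_per_block),
    chr = rep((seq_len(cfg$n_blocks) - 1L) %% 22L + 1L,
              each = cfg$snps_per_block),
    pos = as.integer(rep(seq_len(cfg$snps_per_block), cfg$n_blocks) * 1000L +
                       rep(seq_len(cfg$n_blocks), each = cfg$snps_per_block) *
                       1000000L),
    ref_allele = al[, 1],
    alt_allele = al[, 2],
    maf = stats::runif(m, cfg$maf_range[1], cfg$maf_range[2]),
    stringsAsFactors = FALSE
  )
}

# Draw an n x m dosage matrix under the block-LD model: per haplotype a
# latent Gaussian with exchangeable within-block correlation rho is
# thresholded at the MAF quantile; two haplotypes are summed and dosage
# counts copies of the reference (major) allele.
draw_dosages <- function(n, snp_map, rho, id_prefix) {
  m <- nrow(snp_map)
  dos <- matrix(0L, n, m)
  thr <- stats::qnorm(snp_map$maf)
  for (b in unique(snp_map$block)) {
    idx <- which(snp_map$block == b)
    k <- length(idx)
    minor <- matrix(0L, n, k)
    for (h in 1:2) {
      f <- stats::rnorm(n)
      e <- matrix(stats::rnorm(n * k), n, k)
      lat <- sqrt(rho) * f + sqrt(1 - rho) * e
      minor <- minor + (lat < rep(thr[idx], each = n))
    }
    dos[, idx] <- 2L - minor
  }
  rownames(dos) <- sprintf("%s%05d", id_prefix, seq_len(n))
  colnames(dos) <- snp_map$snp_id
  dos
}

new_genotype_matrix <- function(dosage, snp_info) {
  structure(list(dosage = dosage, snp_info = snp_info),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs\n")
  invisible(x)
}

#' Simulate a reference panel with block LD
#'
#' Generates the genotype panel used both to estimate SNP-SNP correlation
#' matrices and as the discovery sample for the simulated eQTL studies.
#' Within each block, latent Gaussians with pairwise correlation
#' \code{rho} are thresholded at each SNP's MAF quantile to yield two
#' haplotypes, which are summed; dosage counts copies of the reference
#' (major) allele. Blocks are mutually independent.
#'
#' @param cfg a [simulation_config()].
#' @return a \code{genotype_matrix}: list with \code{dosage}
#'   (individuals x SNPs integer matrix) and \code{snp_info}
#'   (snp_id, block, chr, pos, ref_allele, alt_allele, maf).
#' @export
simulate_reference_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  snp_map <- make_snp_map(cfg)
  dos <- draw_dosages(cfg$n_ref, snp_map, cfg$rho, "ref")
  new_genotype_matrix(dos, snp_map)
}

#' Simulate two eQTL discovery studies with overlapping genes
#'
#' Assigns each gene a contiguous set of 1-15 SNPs inside one LD block and
#' a vector of true standardized effects on its expression. Each study
#' then draws its own expression realization on the reference panel
#' (shared genetics, independent noise) and reports per-SNP marginal
#' regression summary statistics (beta, SE, p). Exactly
#' \code{n_overlap_genes} genes appear in both studies, with independently
#' estimated statistics. Roughly half of the records are emitted with the
#' alternate allele as effect allele (beta sign flipped accordingly), so
#' downstream allele harmonization is exercised.
#'
#' @param panel reference panel from [simulate_reference_panel()].
#' @param cfg the same [simulation_config()].
#' @return list with elements \code{study_a}, \code{study_b} (summary
#'   statistic data.frames with columns snp, chr, pos, effect_allele,
#'   other_allele, beta, se, p, gene, study) and \code{truth}
#'   (per-gene true SNP effects, planted gene/measure/direction table).
#' @export
simulate_eqtl_summaries <- function(panel, cfg) {
  stopifnot(inherits(panel, "genotype_matrix"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n_genes <- cfg$n_genes_study_a + cfg$n_genes_study_b - cfg$n_overlap_genes
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  genes_a <- genes[seq_len(cfg$n_genes_study_a)]
  genes_b <- genes[seq.int(cfg$n_genes_study_a - cfg$n_overlap_genes + 1L,
                           n_genes)]

  snp_map <- panel$snp_info
  blocks <- split(seq_len(nrow(snp_map)), snp_map$block)

  gene_effects <- vector("list", n_genes)
  names(gene_effects) <- genes
  for (g in seq_len(n_genes)) {
    blk <- blocks[[(g - 1L) %% cfg$n_blocks + 1L]]
    k <- sample(seq.int(cfg$snps_per_gene_range[1],
                        cfg$snps_per_gene_range[2]), 1L)
    start <- sample.int(length(blk) - k + 1L, 1L)
    idx <- blk[start:(start + k - 1L)]
    h2 <- stats::runif(k, cfg$expr_h2_per_snp[1], cfg$expr_h2_per_snp[2])
    eff <- sqrt(h2) * sample(c(-1, 1), k, replace = TRUE)
    gene_effects[[g]] <- data.frame(snp_id = snp_map$snp_id[idx],
                                    effect = eff,
                                    stringsAsFactors = FALSE)
  }

  study_stats <- function(gene_set, label) {
    recs <- lapply(gene_set, function(g) {
      ge <- gene_effects[[g]]
      x <- panel$dosage[, ge$snp_id, drop = FALSE]
      poly <- apply(x, 2, stats::sd) > 0
      x <- x[, poly, drop = FALSE]
      xz <- scale(x)
      expr <- drop(xz %*% ge$effect[poly]) + stats::rnorm(nrow(x))
      marginal_stats(x, expr, snp_map, g, label)
    })
    do.call(rbind, recs)
  }
  out_a <- study_stats(genes_a, "studyA")
  out_b <- study_stats(genes_b, "studyB")

  # report ~half the records with the alternate allele as effect allele
  flip_study <- function(df) {
    fl <- stats::runif(nrow(df)) < 0.5
    ea <- ifelse(fl, df$other_allele, df$effect_allele)
    oa <- ifelse(fl, df$effect_allele, df$other_allele)
    df$effect_allele <- ea
    df$other_allele <- oa
    df$beta <- ifelse(fl, -df$beta, df$beta)
    df
  }
  out_a <- flip_study(out_a)
  out_b <- flip_study(out_b)

  planted_genes <- if (cfg$n_planted_genes > 0) {
    genes_a[seq_len(cfg$n_planted_genes)]
  } else character(0)
  planted <- if (length(planted_genes)) {
    expand.grid(gene = planted_genes, measure = c("FA", "MD"),
                stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), measure = character(0))
  }
  if (nrow(planted)) {
    planted$direction <- ifelse(planted$measure == "FA", -1, 1)
    planted$effect_size <- cfg$effect_size
  }

  truth <- list(gene_effects = gene_effects, planted = planted,
                planted_genes = planted_genes,
                genes_a = genes_a, genes_b = genes_b)
  list(study_a = out_a, study_b = out_b, truth = truth)
}

# per-SNP marginal simple-regression summary statistics of expr on raw dosage
marginal_stats <- function(x, expr, snp_map, gene, study) {
  sx0 <- apply(x, 2, stats::sd)
  x <- x[, sx0 > 0, drop = FALSE]       # monomorphic SNPs carry no signal
  n <- nrow(x)
  sx <- sx0[sx0 > 0]
  r <- drop(stats::cor(x, expr))
  b <- r * stats::sd(expr) / sx
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  se <- b / tval
  se[!is.finite(se)] <- abs(b[!is.finite(se)])
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  info <- snp_map[match(colnames(x), snp_map$snp_id), ]
  data.frame(snp = colnames(x), chr = info$chr, pos = info$pos,
             effect_allele = info$ref_allele, other_allele = info$alt_allele,
             beta = b, se = se, p = p, gene = gene, study = study,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate the imaging cohort: genotypes and covariates
#'
#' Draws cohort dosages from the same block-LD process and SNP map as the
#' reference panel (shared MAFs and block structure, independent
#' individuals), together with the covariate set used by the association
#' models: age (uniform on 45.92-80.67 years) and its square, sex, 15
#' genetic principal components (iid standard normal stand-ins), scanner
#' site (2 levels, 0.843/0.157), genotype array (2 levels, 0.9/0.1), three
#' head-position coordinates, and a relatedness/cohort-overlap exclusion
#' flag set on an expected \code{exclusion_fraction} of subjects.
#'
#' @param panel reference panel (supplies the SNP map).
#' @param cfg the same [simulation_config()].
#' @return list with \code{genotypes} (a \code{genotype_matrix}) and
#'   \code{covariates} (data.frame keyed by \code{subject_id}).
#' @export
simulate_cohort <- function(panel, cfg) {
  stopifnot(inherits(panel, "genotype_matrix"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  dos <- draw_dosages(cfg$n_subjects, panel$snp_info, cfg$rho, "subj")
  n <- cfg$n_subjects
  age <- stats::runif(n, 45.92, 80.67)
  cov <- data.frame(
    subject_id = rownames(dos),
    age = age,
    age_squared = age^2,
    sex = stats::rbinom(n, 1L, 0.48),
    stringsAsFactors = FALSE
  )
  pcs <- matrix(stats::rnorm(n * 15L), n, 15L)
  colnames(pcs) <- paste0("pc", 1:15)
  cov <- cbind(cov, as.data.frame(pcs))
  cov$pos_x <- stats::rnorm(n)
  cov$pos_y <- stats::rnorm(n)
  cov$pos_z <- stats::rnorm(n)
  cov$site <- sample(c(1L, 2L), n, replace = TRUE, prob = c(0.843, 0.157))
  cov$array <- sample(c(1L, 2L), n, replace = TRUE, prob = c(0.9, 0.1))
  cov$excluded <- stats::runif(n) < cfg$exclusion_fraction
  list(genotypes = new_genotype_matrix(dos, panel$snp_info),
       covariates = cov)
}

#' True (noise-free) expression scores of the cohort
#'
#' The planted genetic signal: for each gene, the cohort's standardized
#' dosages weighted by the true SNP effects, then z-standardized. Used to
#' plant effects in the phenotypes and in parameter-recovery tests.
#'
#' @param genotypes cohort \code{genotype_matrix}.
#' @param truth the \code{truth} element of [simulate_eqtl_summaries()].
#' @param genes genes to score; defaults to all.
#' @return matrix subjects x genes of standardized true scores.
#' @export
true_expression_scores <- function(genotypes, truth, genes = NULL) {
  genes <- genes %||% names(truth$gene_effects)
  out <- sapply(genes, function(g) {
    ge <- truth$gene_effects[[g]]
    xz <- scale(genotypes$dosage[, ge$snp_id, drop = FALSE])
    zstd(drop(xz %*% ge$effect), what = g)
  })
  out <- matrix(out, nrow = nrow(genotypes$dosage),
                dimnames = list(rownames(genotypes$dosage), genes))
  out
}

#' Simulate bilateral FA/MD tract phenotypes with a planted score effect
#'
#' Each tract variable is built from a per-measure global latent factor, a
#' tract-category factor, a tract-specific subject component, small
#' covariate effects, the planted standardized effect of the true
#' expression scores of the planted genes (negative on FA, positive on MD
#' by default), and hemisphere-level noise calibrated so that the
#' left-right correlation of bilateral tracts equals \code{hemi_corr} and
#' every variable has unit variance on the standardized scale. Values are
#' then mapped affinely onto plausible FA (~0.5) and MD (arbitrary
#' diffusivity-like ~0.8) scales; affine maps leave all standardized
#' effects untouched.
#'
#' @param genotypes cohort \code{genotype_matrix}.
#' @param truth ground truth from [simulate_eqtl_summaries()].
#' @param atlas a [make_tract_atlas()] atlas.
#' @param cfg the same [simulation_config()].
#' @param covariates cohort covariate table from [simulate_cohort()].
#' @return long data.frame: subject_id, measure ("FA"/"MD"), tract_id,
#'   hemisphere ("left"/"right"/"none"), value.
#' @export
simulate_tract_phenotypes <- function(genotypes, truth, atlas, cfg,
                                      covariates) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 4L)
  n <- nrow(genotypes$dosage)
  subjects <- rownames(genotypes$dosage)
  stopifnot(identical(subjects, covariates$subject_id))

  planted <- truth$planted
  ts <- if (length(truth$planted_genes)) {
    true_expression_scores(genotypes, truth, truth$planted_genes)
  } else NULL

  # small fixed covariate effects so adjustment is exercised
  cov_part <- 0.10 * zstd(covariates$age, "age") +
    0.05 * (covariates$sex - mean(covariates$sex)) +
    0.04 * (covariates$site == 2L) +
    0.03 * covariates$pos_x + 0.02 * covariates$pos_y +
    0.02 * covariates$pos_z
  cov_part <- cov_part - mean(cov_part)

  vars <- atlas_variables(atlas)
  tracts <- unique(vars[, c("tract_id", "category")])
  hc <- cfg$hemi_corr

  out <- vector("list", 2L * nrow(vars))
  k <- 0L
  for (measure in c("FA", "MD")) {
    g_fac <- stats::rnorm(n)
    c_fac <- sapply(c("association", "thalamic", "projection"),
                    function(cc) stats::rnorm(n))
    eff_part <- numeric(n)
    if (!is.null(ts)) {
      pm <- planted[planted$measure == measure, , drop = FALSE]
      for (i in seq_len(nrow(pm))) {
        eff_part <- eff_part +
          pm$effect_size[i] * pm$direction[i] * ts[, pm$gene[i]]
      }
    }
    fixed <- eff_part + cov_part
    v_fixed <- stats::var(fixed)
    # shared (within-subject) variance targets hemi_corr; the structural
    # latent factors fill whatever the fixed effects leave
    v_struct <- max(hc - v_fixed, 0)
    if (hc > 0 && v_struct == 0) {
      warning("fixed-effect variance exceeds hemi_corr; ",
              "left-right correlation will exceed the target")
    }
    a_g <- sqrt(0.45 * v_struct)
    a_c <- sqrt(0.25 * v_struct)
    a_u <- sqrt(0.30 * v_struct)
    s_noise <- sqrt(1 - hc)
    for (t in seq_len(nrow(tracts))) {
      tid <- tracts$tract_id[t]
      cat_t <- tracts$category[t]
      shared <- fixed + a_g * g_fac + a_c * c_fac[, cat_t] +
        a_u * stats::rnorm(n)
      hemis <- vars$hemisphere[vars$tract_id == tid]
      for (h in hemis) {
        x <- shared + s_noise * stats::rnorm(n)
        value <- if (measure == "FA") 0.5 + 0.07 * x else 0.8 + 0.05 * x
        k <- k + 1L
        out[[k]] <- data.frame(subject_id = subjects, measure = measure,
                               tract_id = tid, hemisphere = h,
                               value = value, stringsAsFactors = FALSE)
      }
    }
  }
  phen <- do.call(rbind, out[seq_len(k)])
  rownames(phen) <- NULL
  phen
}
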