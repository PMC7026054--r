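# Shared fixtures, all generated in code.

# a small but complete simulation configuration for fast tests
small_config <- function(...) {
  args <- list(n_ref = 400L, n_subjects = 300L, n_blocks = 6L,
               snps_per_block = 16L, n_genes_study_a = 6L,
               n_genes_study_b = 7L, n_overlap_genes = 3L, seed = 101L)
  args[names(list(...))] <- list(...)
  if (is.null(list(...)$snps_per_gene_range)) {
    args$snps_per_gene_range <- c(1L, min(15L, args$snps_per_block))
  }
  do.call(simulation_config, args)
}

# genotype container from a plain dosage matrix (ref allele A, alt G)
toy_genotypes <- function(dosage, snp_ids = colnames(dosage),
                          ref = "A", alt = "G") {
  colnames(dosage) <- snp_ids
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("s%03d", seq_len(nrow(dosage)))
  }
  info <- data.frame(snp_id = snp_ids,
                     block = 1L, chr = 1L,
                     pos = seq_along(snp_ids) * 100L,
                     ref_allele = rep(ref, length(snp_ids)),
                     alt_allele = rep(alt, length(snp_ids)),
                     maf = 0.3, stringsAsFactors = FALSE)
  eqtlwm:::new_genotype_matrix(dosage, info)
}

# minimal covariate table: two continuous nuisance variables plus a
# balanced binary factor, enough to exercise covariate adjustment fast
toy_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%03d", seq_len(n)),
             c1 = rnorm(n), c2 = rnorm(n),
             grp = factor(rep(c("a", "b"), length.out = n)),
             stringsAsFactors = FALSE)
}

# full-size covariate table matching prepare_covariates()
full_covariates <- function(n, seed = 1, prefix = "s") {
  set.seed(seed)
  age <- runif(n, 45.92, 80.67)
  cov <- data.frame(subject_id = sprintf("%s%05d", prefix, seq_len(n)),
                    age = age, age_squared = age^2,
                    sex = rbinom(n, 1, 0.5), stringsAsFactors = FALSE)
  pcs <- matrix(rnorm(n * 15), n, 15)
  colnames(pcs) <- paste0("pc", 1:15)
  cov <- cbind(cov, as.data.frame(pcs))
  cov$pos_x <- rnorm(n); cov$pos_y <- rnorm(n); cov$pos_z <- rnorm(n)
  cov$site <- sample(1:2, n, replace = TRUE)
  cov$array <- sample(1:2, n, replace = TRUE)
  cov
}

# long phenotype table from a named list tract_id -> list(left=, right=)
# or tract_id -> vector (unilateral); subject ids s001...
toy_phenotypes <- function(values, measure = "FA") {
  rows <- list()
  for (tid in names(values)) {
    v <- values[[tid]]
    if (is.list(v)) {
      for (h in names(v)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("s%03d", seq_along(v[[h]])),
          measure = measure, tract_id = tid, hemisphere = h,
          value = v[[h]], stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("s%03d", seq_along(v)),
        measure = measure, tract_id = tid, hemisphere = "none",
        value = v, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# tiny atlas of unilateral tracts for PCA toys
toy_atlas <- function(tract_ids, category = "association") {
  a <- data.frame(tract_id = tract_ids, name = tract_ids,
                  category = category, bilateral = FALSE,
                  stringsAsFactors = FALSE)
  class(a) <- c("tract_atlas", "data.frame")
  a
}

# independent brute-force Benjamini-Hochberg step-up oracle:
# q_i = min_{k >= rank(i)} m * p_(k) / k
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  run_min <- Inf
  for (k in m:1) {
    run_min <- min(run_min, m * p[o[k]] / k)
    q_sorted[k] <- min(run_min, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
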