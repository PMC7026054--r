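sumstat_row <- function(snp, ea, oa, beta, p, gene = "G1",
                        study = "studyA", chr = 1L, pos = 100L) {
  data.frame(snp = snp, chr = chr, pos = pos, effect_allele = ea,
             other_allele = oa, beta = beta, se = abs(beta) / 2, p = p,
             gene = gene, study = study, stringsAsFactors = FALSE)
}

test_that("p-value thresholding is inclusive and defaults to 1e-5", {
  recs <- rbind(sumstat_row("s1", "A", "G", 0.1, 1e-6),
                sumstat_row("s2", "A", "G", 0.2, 1e-5),
                sumstat_row("s3", "A", "G", 0.3, 2e-5))
  kept <- select_snps(recs, 1e-5)
  expect_equal(kept$snp, c("s1", "s2"))
  expect_equal(formals(select_snps)$p_threshold, 1e-5)
  expect_equal(nrow(select_snps(recs[0, ], 1e-5)), 0L)
  bad <- sumstat_row("s4", "A", "G", 0.1, 0)
  expect_error(select_snps(bad), "p-values")
})

test_that("allele harmonization keeps, flips, and drops correctly", {
  amap <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                     ref_allele = c("A", "A", "A", "C"),
                     alt_allele = c("G", "G", "T", "G"),
                     stringsAsFactors = FALSE)
  recs <- rbind(
    sumstat_row("s1", "A", "G", 0.5, 1e-6),   # matches counted allele
    sumstat_row("s2", "G", "A", 0.5, 1e-6),   # flipped representation
    sumstat_row("s3", "A", "T", 0.5, 1e-6),   # strand-ambiguous
    sumstat_row("s4", "C", "G", 0.5, 1e-6),   # strand-ambiguous
    sumstat_row("s5", "A", "G", 0.5, 1e-6),   # absent from cohort
    sumstat_row("s2", "C", "T", 0.5, 1e-6))   # irreconcilable alleles
  expect_warning(out <- harmonize_alleles(recs, amap), "dropped 4")
  expect_equal(out$snp, c("s1", "s2"))
  expect_equal(out$beta, c(0.5, -0.5))
  expect_equal(out$effect_allele, c("A", "A"))
  dropped <- attr(out, "dropped")
  expect_equal(dropped[["ambiguous"]], 2L)
  expect_equal(dropped[["missing"]], 1L)
  expect_equal(dropped[["mismatch"]], 1L)
})

test_that("single-SNP scores reduce to the raw effect size", {
  g <- toy_genotypes(cbind(s1 = c(0, 1, 2, 1, 0, 2)))
  recs <- sumstat_row("s1", "A", "G", 0.37, 1e-6)
  defs <- build_score_definitions(recs, g)
  expect_length(defs, 1L)
  expect_equal(defs[[1]]$weights, 0.37)
  expect_equal(defs[[1]]$best_p, 1e-6)
})

test_that("perfectly correlated SNP pair with equal betas splits the effect", {
  x <- c(0, 1, 2, 1, 0, 2)
  g <- toy_genotypes(cbind(s1 = x, s2 = x))
  b <- 0.8
  recs <- rbind(sumstat_row("s1", "A", "G", b, 1e-6, pos = 100L),
                sumstat_row("s2", "A", "G", b, 1e-7, pos = 200L))
  defs <- build_score_definitions(recs, g)
  # rank-1 pseudoinverse oracle: R = ones(2), R+ = ones/4, w = (b/2, b/2)
  expect_equal(unname(defs[[1]]$weights), c(b / 2, b / 2),
               tolerance = 1e-10)
  expect_equal(defs[[1]]$ld_rank, 1L)
  expect_equal(defs[[1]]$best_p, 1e-7)
})

test_that("LD-adjusted weights match a linear-solve oracle on a 3-SNP toy", {
  set.seed(5)
  dos <- matrix(sample(0:2, 90, replace = TRUE), 30, 3,
                dimnames = list(NULL, c("s1", "s2", "s3")))
  g <- toy_genotypes(dos)
  beta <- c(0.4, -0.2, 0.1)
  recs <- rbind(sumstat_row("s1", "A", "G", beta[1], 1e-6, pos = 100L),
                sumstat_row("s2", "A", "G", beta[2], 1e-7, pos = 200L),
                sumstat_row("s3", "A", "G", beta[3], 1e-8, pos = 300L))
  defs <- build_score_definitions(recs, g)
  R <- stats::cor(dos)
  expect_equal(unname(defs[[1]]$weights), unname(drop(solve(R, beta))),
               tolerance = 1e-10)
})

test_that("matrix-form scores equal the per-individual brute-force sum", {
  set.seed(6)
  dos <- matrix(sample(0:2, 15, replace = TRUE), 5, 3,
                dimnames = list(NULL, c("s1", "s2", "s3")))
  g <- toy_genotypes(dos)
  def <- structure(list(list(gene = "G1", study = "studyA",
                             snp_ids = c("s1", "s2", "s3"),
                             betas = c(1, 2, 3), weights = c(0.5, -1, 2),
                             best_p = 1e-6, n_snps = 3L, ld_rank = 3L)),
                   class = "score_definitions")
  sc <- compute_scores(def, g)
  for (i in 1:5) {
    oracle <- sum(dos[i, ] * c(0.5, -1, 2))
    expect_equal(unname(sc[i, 1]), oracle, tolerance = 1e-12)
  }
  # zero weights give zero scores; single unit weight returns the dosage
  def0 <- def
  def0[[1]]$weights <- c(0, 0, 0)
  expect_true(all(compute_scores(structure(def0,
                                           class = "score_definitions"),
                                 g) == 0))
})

test_that("with identity LD the score is the unadjusted weighted allele count", {
  # two exactly uncorrelated dosage columns
  dos <- cbind(s1 = c(0, 0, 2, 2), s2 = c(0, 2, 0, 2))
  expect_equal(stats::cor(dos)[1, 2], 0)
  g <- toy_genotypes(dos)
  beta <- c(0.3, -0.7)
  recs <- rbind(sumstat_row("s1", "A", "G", beta[1], 1e-6, pos = 100L),
                sumstat_row("s2", "A", "G", beta[2], 1e-7, pos = 200L))
  defs <- build_score_definitions(recs, g)
  expect_equal(unname(defs[[1]]$weights), beta, tolerance = 1e-12)
  sc <- compute_scores(defs, g)
  expect_equal(unname(sc[, 1]), drop(dos %*% beta), tolerance = 1e-12)
})

test_that("scores are invariant to SNP listing order within a gene", {
  set.seed(7)
  cfg <- small_config()
  panel <- simulate_reference_panel(cfg)
  ids <- panel$snp_info$snp_id[1:5]
  recs <- do.call(rbind, lapply(seq_along(ids), function(i) {
    sumstat_row(ids[i], "A", "G", rnorm(1), 1e-6 * i, pos = i * 100L)
  }))
  amap <- data.frame(snp_id = ids, ref_allele = "A", alt_allele = "G")
  defs1 <- build_score_definitions(harmonize_alleles(recs, amap), panel)
  perm <- sample(nrow(recs))
  defs2 <- build_score_definitions(harmonize_alleles(recs[perm, ], amap),
                                   panel)
  g <- toy_genotypes(panel$dosage[1:10, ids, drop = FALSE], snp_ids = ids)
  expect_equal(compute_scores(defs1, g), compute_scores(defs2, g),
               tolerance = 1e-10)
})

test_that("harmonization makes scores invariant to allele representation", {
  set.seed(8)
  dos <- matrix(sample(0:2, 60, replace = TRUE), 20, 3,
                dimnames = list(NULL, c("s1", "s2", "s3")))
  g <- toy_genotypes(dos)
  amap <- cohort_allele_map(g)
  recs <- rbind(sumstat_row("s1", "A", "G", 0.4, 1e-6, pos = 100L),
                sumstat_row("s2", "A", "G", -0.2, 1e-7, pos = 200L),
                sumstat_row("s3", "A", "G", 0.1, 1e-8, pos = 300L))
  flipped <- recs
  flipped$effect_allele <- "G"
  flipped$other_allele <- "A"
  flipped$beta <- -flipped$beta
  s1 <- compute_scores(build_score_definitions(
    harmonize_alleles(recs, amap), g), g)
  s2 <- compute_scores(build_score_definitions(
    harmonize_alleles(flipped, amap), g), g)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("cross-study de-duplication keeps the score with the lowest p", {
  mkdef <- function(gene, study, best_p) {
    structure(list(gene = gene, study = study, snp_ids = "s1",
                   betas = 0.1, weights = 0.1, best_p = best_p,
                   n_snps = 1L, ld_rank = 1L), class = "score_definition")
  }
  defs_a <- structure(list(mkdef("GX", "studyA", 1e-8),
                           mkdef("GZ", "studyA", 1e-6)),
                      class = "score_definitions")
  defs_b <- structure(list(mkdef("GX", "studyB", 1e-6),
                           mkdef("GY", "studyB", 1e-7)),
                      class = "score_definitions")
  out <- deduplicate_scores(defs_a, defs_b)
  genes <- vapply(out, `[[`, "", "gene")
  studies <- vapply(out, `[[`, "", "study")
  expect_equal(genes, c("GX", "GY", "GZ"))                 # sorted by gene
  expect_equal(studies[genes == "GX"], "studyA")           # lower p wins
  expect_equal(studies[genes == "GY"], "studyB")           # single-study kept
  acc <- attr(out, "accounting")
  expect_equal(acc$n_retained, acc$n_built_a + acc$n_built_b - acc$n_overlap)

  # exact tie goes to the first-listed study, deterministically
  defs_bt <- structure(list(mkdef("GX", "studyB", 1e-8)),
                       class = "score_definitions")
  for (i in 1:3) {
    tie <- deduplicate_scores(defs_a, defs_bt)
    win <- vapply(tie, `[[`, "", "study")[
      vapply(tie, `[[`, "", "gene") == "GX"]
    expect_equal(win, "studyA")
  }
})

test_that("retained-score conservation holds on simulated configurations", {
  cases <- list(c(31, 0), c(32, 3))
  for (cs in cases) {
    seed <- cs[1]
    cfg <- small_config(seed = seed, n_overlap_genes = cs[2])
    panel <- simulate_reference_panel(cfg)
    sums <- simulate_eqtl_summaries(panel, cfg)
    amap <- data.frame(snp_id = panel$snp_info$snp_id,
                       ref_allele = panel$snp_info$ref_allele,
                       alt_allele = panel$snp_info$alt_allele)
    mk <- function(recs) build_score_definitions(
      suppressWarnings(harmonize_alleles(select_snps(recs), amap)), panel)
    out <- deduplicate_scores(mk(sums$study_a), mk(sums$study_b))
    acc <- attr(out, "accounting")
    expect_equal(acc$n_retained,
                 acc$n_built_a + acc$n_built_b - acc$n_overlap)
    expect_equal(length(out), acc$n_retained)
  }
})

test_that("missing cohort SNPs abort scoring with gene context", {
  g <- toy_genotypes(cbind(s1 = c(0, 1, 2, 1)))
  def <- structure(list(list(gene = "G9", study = "studyA",
                             snp_ids = c("s1", "sX"), betas = c(1, 1),
                             weights = c(1, 1), best_p = 1e-6,
                             n_snps = 2L, ld_rank = 2L)),
                   class = "score_definitions")
  expect_error(compute_scores(def, g), "sX.*G9")
})

test_that("score accounting reproduces the conservation identity", {
  acc <- score_accounting(5, 7, 3, 4)
  expect_equal(acc$total_built, 12)
  expect_equal(acc$total_retained, 7)
  expect_equal(acc$n_overlap_excluded, 5)
})
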