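# Helpers local to the association tests -------------------------------

named <- function(x, n = length(x), prefix = "s") {
  stats::setNames(x, sprintf("%s%03d", prefix, seq_len(n)))
}

# covariates exactly orthogonal to a given score (and the intercept)
orthogonal_covariates <- function(score, k = 3, seed = 1) {
  set.seed(seed)
  n <- length(score)
  Q <- qr.Q(qr(cbind(1, score, matrix(rnorm(n * k), n, k))))
  covs <- as.data.frame(Q[, 3:(2 + k)])
  names(covs) <- paste0("c", seq_len(k))
  cbind(data.frame(subject_id = names(score), stringsAsFactors = FALSE),
        covs)
}

test_that("a phenotype equal to the score gives effect 1 and 100% R2", {
  set.seed(31)
  s <- named(rnorm(200))
  covs <- orthogonal_covariates(s)
  # lm warns about the (intentionally) perfect fit
  res <- suppressWarnings(fit_linear(s, s, covs))
  expect_equal(res$effect, 1.0, tolerance = 1e-10)
  expect_equal(res$r2_increment_pct, 100, tolerance = 1e-8)
  expect_equal(res$model, "linear")
})

test_that("linear model recovers a planted 0.05 effect within its CI", {
  set.seed(32)
  n <- 5000
  covs <- full_covariates(n, seed = 32)
  s <- stats::setNames(rnorm(n), covs$subject_id)
  y <- 0.05 * scale(s)[, 1] + rnorm(n) * sqrt(1 - 0.05^2) +
    0.1 * scale(covs$age)[, 1]
  res <- fit_linear(stats::setNames(y, covs$subject_id), s,
                    prepare_covariates(covs))
  expect_lt(abs(res$effect - 0.05), 1.96 * res$se)
  expect_gt(res$r2_increment_pct, 0)
  expect_equal(res$n_subjects, n)
})

test_that("null linear associations reject at close to the nominal rate", {
  set.seed(33)
  n <- 400
  covs <- prepare_covariates(full_covariates(n, seed = 33))
  rej <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    s <- stats::setNames(rnorm(n), covs$subject_id)
    y <- stats::setNames(rnorm(n), covs$subject_id)
    rej <- rej + (fit_linear(y, s, covs)$p < 0.05)
  }
  # 3 binomial SDs around 0.05 with 200 replicates
  expect_lt(abs(rej / reps - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("constant covariates abort with the offending column named", {
  set.seed(34)
  s <- named(rnorm(50))
  covs <- orthogonal_covariates(s)
  covs$c2 <- 1
  expect_error(fit_linear(s, s, covs), "c2")
})

test_that("mixed model equals OLS when hemispheres are identical", {
  set.seed(35)
  n <- 400
  covs <- full_covariates(n, seed = 35)
  s <- stats::setNames(rnorm(n), covs$subject_id)
  y <- 0.1 * s + rnorm(n)
  phen <- data.frame(subject_id = rep(covs$subject_id, each = 2),
                     hemisphere = rep(c("left", "right"), n),
                     value = rep(y, each = 2), stringsAsFactors = FALSE)
  pc <- prepare_covariates(covs)
  mixed <- fit_bilateral_mixed(phen, s, pc)
  ols <- fit_linear(stats::setNames(y, covs$subject_id), s, pc)
  expect_equal(mixed$effect, ols$effect, tolerance = 1e-6)
  expect_equal(mixed$model, "mixed_bilateral")
  expect_true(mixed$converged)
})

test_that("mixed model recovers a planted subject-level effect", {
  set.seed(36)
  n <- 1500
  covs <- full_covariates(n, seed = 36)
  s <- stats::setNames(rnorm(n), covs$subject_id)
  subject_part <- 0.05 * scale(s)[, 1] + rnorm(n) * sqrt(0.7 - 0.05^2)
  lr <- cbind(subject_part + rnorm(n) * sqrt(0.3),
              subject_part + rnorm(n) * sqrt(0.3))
  phen <- data.frame(subject_id = rep(covs$subject_id, each = 2),
                     hemisphere = rep(c("left", "right"), n),
                     value = as.vector(t(lr)), stringsAsFactors = FALSE)
  res <- fit_bilateral_mixed(phen, s, prepare_covariates(covs))
  expect_true(res$converged)
  expect_lt(abs(res$effect - 0.05), 1.96 * res$se)
})

test_that("mixed model recovers a planted hemisphere offset", {
  set.seed(37)
  n <- 800
  covs <- full_covariates(n, seed = 37)
  s <- stats::setNames(rnorm(n), covs$subject_id)
  delta <- 0.3
  base <- rnorm(n)
  phen <- data.frame(subject_id = rep(covs$subject_id, each = 2),
                     hemisphere = rep(c("left", "right"), n),
                     value = as.vector(rbind(base + rnorm(n) * 0.4,
                                             base + delta +
                                               rnorm(n) * 0.4)),
                     stringsAsFactors = FALSE)
  pc <- prepare_covariates(covs)
  # refit on the unstandardized scale so delta keeps its units
  res <- fit_bilateral_mixed(phen, s, pc, standardize = FALSE)
  expect_true(res$converged)
  # pull the hemisphere fixed effect out of a direct refit for the check
  long <- phen
  long$s <- rep(unname(s), each = 2)
  fit <- nlme::lme(value ~ s + hemisphere, random = ~ 1 | subject_id,
                   data = long, method = "REML")
  est <- nlme::fixef(fit)[["hemisphereright"]]
  se <- summary(fit)$tTable["hemisphereright", "Std.Error"]
  expect_lt(abs(est - delta), 1.96 * se)
})

test_that("quadratic term is null for linear truth, large for squared truth", {
  set.seed(38)
  n <- 5000
  covs <- full_covariates(n, seed = 38)
  ids <- covs$subject_id
  pc <- prepare_covariates(covs)
  s <- stats::setNames(rnorm(n), ids)
  y_lin <- stats::setNames(0.3 * s + rnorm(n), ids)
  q1 <- fit_quadratic(y_lin, s, pc)
  expect_lt(q1$r2_quadratic_pct, 0.1)

  y_sq <- stats::setNames(scale(s)[, 1]^2 + 0.3 * rnorm(n), ids)
  q2 <- fit_quadratic(y_sq, s, pc)
  expect_gt(q2$r2_quadratic_pct, 50)
  expect_lt(q2$p_quadratic, 1e-10)

  s_const <- stats::setNames(rep(1, n), ids)
  expect_error(fit_quadratic(y_lin, s_const, pc), "standardize|constant")
})

test_that("BH correction matches the hand example and trivial cases", {
  res <- data.frame(p = c(0.01, 0.02, 0.03, 0.04))
  out <- fdr_correct(res)
  expect_equal(out$q, rep(0.04, 4), tolerance = 1e-12)

  expect_equal(fdr_correct(data.frame(p = 0.0123))$q, 0.0123)
  expect_equal(fdr_correct(data.frame(p = rep(1, 6)))$q, rep(1, 6))
  empty <- fdr_correct(data.frame(p = numeric(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("BH correction equals the brute-force step-up oracle", {
  set.seed(39)
  for (r in 1:50) {
    m <- sample(1:60, 1)
    p <- runif(m)^sample(1:3, 1)
    out <- fdr_correct(data.frame(p = p))
    expect_equal(out$q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(out$q >= p))
    expect_true(all(diff(out$q[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("FDR families are corrected separately and sized correctly", {
  set.seed(40)
  res <- data.frame(p = runif(30))
  fam <- rep(c("tract", "latent"), c(20, 10))
  out <- fdr_correct(res, family = fam)
  expect_equal(out$q[fam == "tract"], bh_oracle(res$p[fam == "tract"]),
               tolerance = 1e-12)
  expect_equal(out$q[fam == "latent"], bh_oracle(res$p[fam == "latent"]),
               tolerance = 1e-12)
  fs <- attr(out, "family_sizes")
  expect_equal(fs[["tract"]], 20L)
  expect_equal(fs[["latent"]], 10L)

  # non-converged rows keep NA q, with a warning
  res$p[3] <- NA
  expect_warning(out2 <- fdr_correct(res, family = fam), "excluded")
  expect_true(is.na(out2$q[3]))
})

test_that("test-family sizes multiply scores by phenotypes", {
  expect_equal(family_size(10, 4), 40L)
  expect_error(family_size(0, 4))
})

test_that("overlap comparison pairs both studies' fits for one gene", {
  set.seed(41)
  dos <- matrix(sample(0:2, 200 * 3, replace = TRUE), 200, 3,
                dimnames = list(sprintf("s%03d", 1:200),
                                c("s1", "s2", "s3")))
  g <- toy_genotypes(dos)
  mkdefs <- function(study, w) {
    structure(list(structure(list(
      gene = "GX", study = study, snp_ids = c("s1", "s2", "s3"),
      betas = w, weights = w, best_p = 1e-6, n_snps = 3L, ld_rank = 3L),
      class = "score_definition")), class = "score_definitions")
  }
  w <- c(0.5, -0.2, 0.1)
  defs_a <- mkdefs("studyA", w)
  defs_b <- mkdefs("studyB", w)
  y <- named(rnorm(200))
  covs <- orthogonal_covariates(y, seed = 41)
  out <- overlap_comparison("GX", defs_a, defs_b, g, y, covs)
  expect_equal(nrow(out), 2L)
  # identical SNPs and weights give identical statistics
  expect_equal(out$effect[1], out$effect[2], tolerance = 1e-12)
  expect_equal(out$p[1], out$p[2], tolerance = 1e-12)
  expect_error(overlap_comparison("GY", defs_a, defs_b, g, y, covs),
               "absent")
})

test_that("overlapping studies of the same gene agree in effect sign", {
  # both studies estimate the same true SNP effects, so cohort fits of a
  # phenotype carrying that signal should agree in direction
  cfg <- small_config(n_ref = 1500L, n_subjects = 1500L,
                      effect_size = 0.4, n_planted_genes = 0L,
                      n_genes_study_a = 4L, n_genes_study_b = 4L,
                      n_overlap_genes = 4L,
                      expr_h2_per_snp = c(0.03, 0.06), seed = 99L)
  panel <- simulate_reference_panel(cfg)
  sums <- simulate_eqtl_summaries(panel, cfg)
  cohort <- simulate_cohort(panel, cfg)
  amap <- cohort_allele_map(cohort$genotypes)
  mk <- function(recs) build_score_definitions(
    suppressWarnings(harmonize_alleles(select_snps(recs), amap)), panel)
  defs_a <- mk(sums$study_a)
  defs_b <- mk(sums$study_b)
  genes <- intersect(vapply(defs_a, `[[`, "", "gene"),
                     vapply(defs_b, `[[`, "", "gene"))
  covs <- prepare_covariates(cohort$covariates)
  agree <- 0L
  for (gene in genes) {
    ts <- true_expression_scores(cohort$genotypes, sums$truth, gene)[, 1]
    y <- stats::setNames(0.4 * ts + rnorm(length(ts)), names(ts))
    out <- overlap_comparison(gene, defs_a, defs_b, cohort$genotypes, y,
                              covs)
    agree <- agree + (sign(out$effect[1]) == sign(out$effect[2]))
  }
  expect_gte(agree, length(genes) - 1L)
  expect_gte(length(genes), 2L)
})
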