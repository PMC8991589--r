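test_that("principal components separate simulated subpopulations", {
  panel <- tiny_panel(150, maf = 0.25)
  co <- quick_cohort(250, 250, panel, seed = 30, subpop2_fraction = 0.5,
                     subpop_maf_shift = 0.15, covariate_effects = numeric(0))
  pcs <- compute_pcs(co$genotypes, 2)
  lab <- co$samples$population[match(rownames(pcs), co$samples$sample_id)]
  expect_gt(abs(stats::cor(pcs[, 1], lab)), 0.9)
  # orthogonality of score vectors
  expect_lt(abs(sum(pcs[, 1] * pcs[, 2])) / sqrt(sum(pcs[, 1]^2) * sum(pcs[, 2]^2)),
            1e-8)
})

test_that("duplicating every sample leaves PC directions unchanged up to sign", {
  co <- quick_cohort(60, 60, tiny_panel(30), seed = 31)
  g <- co$genotypes
  m2 <- rbind(unclass(g), unclass(g))
  rownames(m2) <- c(rownames(g), paste0(rownames(g), "_d"))
  g2 <- genotype_matrix(m2)
  p1 <- compute_pcs(g, 2)
  p2 <- compute_pcs(g2, 2)[seq_len(nrow(g)), ]
  for (k in 1:2) {
    ali <- abs(stats::cor(p1[, k], p2[, k]))
    expect_gt(ali, 1 - 1e-8)
  }
  expect_error(compute_pcs(g[, 1], 2), "fewer polymorphic SNPs")
})

test_that("RLR recovers per-SNP effects and nulls at moderate n", {
  panel <- tiny_panel(3, maf = 0.3)
  panel$log_or <- c(0.3, 0, -0.2)
  co <- quick_cohort(4000, 4000, panel, seed = 32, covariate_effects = numeric(0))
  fit <- prs_fit(co$genotypes, co$samples, "rlr")
  b <- coef(fit)
  expect_equal(length(b), 3)
  expect_gt(b[["t01"]], 0.22); expect_lt(b[["t01"]], 0.38)
  expect_lt(abs(b[["t02"]]), 0.07)
  expect_lt(b[["t03"]], -0.12)
})

test_that("PRS scoring is the dot product of weights and dosages", {
  m <- rbind(c(1, 2, 0), c(0, 1, 2))
  g <- genotype_matrix(m, sample_ids = c("s1", "s2"), snp_ids = c("a", "b", "c"))
  mk <- function(betas) structure(
    list(method = "rlr", snp_ids = c("a", "b", "c"),
         effect_alleles = effect_alleles(g),
         other_alleles = attr(g, "other_alleles"), betas = betas, intercept = 0),
    class = c("prs_rlr", "prs_model"))
  expect_equal(unname(predict(mk(c(0, 0, 0)), g)), c(0, 0))
  expect_equal(unname(predict(mk(c(0.1, -0.2, 0.3)), g)), c(-0.3, 0.4))
  expect_equal(unname(predict(mk(c(log(2), 0, 0)), g))[1], log(2))
  # linearity in the weights
  expect_equal(predict(mk(3 * c(0.1, -0.2, 0.3)), g),
               3 * predict(mk(c(0.1, -0.2, 0.3)), g))
  # single SNP, beta = ln 2, dosage 2
  g1 <- genotype_matrix(matrix(2, 1, 1), "s", "a")
  m1 <- structure(list(method = "rlr", snp_ids = "a",
                       effect_alleles = c(a = "A"), other_alleles = c(a = "G"),
                       betas = log(2), intercept = 0),
                  class = c("prs_rlr", "prs_model"))
  expect_equal(unname(predict(m1, g1)), 2 * log(2))
})

test_that("scoring refuses mismatched panels and flips swapped alleles", {
  co <- quick_cohort(50, 50, tiny_panel(4), seed = 33)
  fit <- prs_fit(co$genotypes, co$samples, "rlr")
  expect_error(predict(fit, co$genotypes[, 1:3]), "panel mismatch")
  m <- unclass(co$genotypes)
  g_sw <- genotype_matrix(2 - m,
                          effect_alleles = attr(co$genotypes, "other_alleles"),
                          other_alleles = effect_alleles(co$genotypes))
  expect_message(s_sw <- predict(fit, g_sw), "flipping")
  expect_equal(s_sw, predict(fit, co$genotypes))
  g_bad <- genotype_matrix(m, effect_alleles = rep("T", 4),
                           other_alleles = rep("C", 4))
  expect_error(predict(fit, g_bad), "effect-allele mismatch")
})

test_that("ridge fit approaches the joint MLE as the penalty vanishes", {
  co <- quick_cohort(1500, 1500, tiny_panel(5, log_or = 0.15), seed = 34)
  tab <- co$samples
  # externally supplied structure scores (panel-derived PCs would be
  # collinear with the SNP columns and leave the MLE unidentified)
  set.seed(1)
  tab$pc1 <- rnorm(nrow(tab)); tab$pc2 <- rnorm(nrow(tab))
  fit0 <- prs_fit(co$genotypes, tab, "lrr", lambda_grid = 1e-8)
  X <- unclass(co$genotypes)
  df <- data.frame(y = as.numeric(tab$status == "case"),
                   age = tab$age, pc1 = tab$pc1, pc2 = tab$pc2, X)
  ref <- stats::glm(y ~ ., data = df, family = stats::binomial())
  mle <- stats::coef(ref)[colnames(X)]
  expect_lt(max(abs(unname(coef(fit0)) - unname(mle))), 1e-3)
})

test_that("extreme penalty shrinks SNP effects but not covariates", {
  co <- quick_cohort(800, 800, tiny_panel(5, log_or = 0.2),
                     covariate_effects = c(age = 0.05), seed = 35)
  fit <- prs_fit(co$genotypes, co$samples, "lrr", lambda_grid = 1e6)
  expect_true(all(abs(coef(fit)) < 1e-3))
  expect_gt(abs(fit$covariate_betas[["age"]]), 0.01)
})

test_that("the L2 norm of SNP coefficients is non-increasing in lambda", {
  co <- quick_cohort(600, 600, tiny_panel(8, log_or = 0.2), seed = 36)
  norms <- vapply(c(0.01, 1, 10, 100, 1e4), function(l) {
    f <- prs_fit(co$genotypes, co$samples, "lrr", lambda_grid = l)
    sqrt(sum(coef(f)^2))
  }, 0)
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("correlated SNPs sharing a signal are jointly shrunk below the marginal", {
  panel <- rbind(snp_spec("c1", 0.3, 0.35, "b", 0.8),
                 snp_spec("c2", 0.3, 0.00, "b", 0.8),
                 snp_spec("x1", 0.3, 0.10))
  co <- quick_cohort(4000, 4000, panel, seed = 37, covariate_effects = numeric(0))
  # external structure scores: with a 3-SNP panel, panel-derived PCs span
  # the SNP space and the unpenalized pathway would absorb the signal
  set.seed(2)
  co$samples$pc1 <- rnorm(8000); co$samples$pc2 <- rnorm(8000)
  rlr <- prs_fit(co$genotypes, co$samples, "rlr")
  # penalty on the scale of the per-SNP information: the pair shares the
  # signal and both weights sit below the causal SNP's marginal estimate
  lrr <- prs_fit(co$genotypes, co$samples, "lrr", lambda_grid = 1000)
  expect_gt(coef(lrr)[["c1"]], 0)
  expect_lt(abs(coef(lrr)[["c1"]]), coef(rlr)[["c1"]])
  expect_lt(abs(coef(lrr)[["c2"]]), coef(rlr)[["c1"]])
  # in the heavy-penalty limit the direction follows the (positive)
  # marginal association for both SNPs
  lrr2 <- prs_fit(co$genotypes, co$samples, "lrr", lambda_grid = 2e4)
  expect_gt(coef(lrr2)[["c1"]], 0)
  expect_gt(coef(lrr2)[["c2"]], 0)
})

test_that("cross-validation partitions samples and scores the grid", {
  y <- rep(c(0, 1), c(60, 40))
  cv <- cross_validate(y, data.frame(dummy = 1:2),
                       function(params, tr, va) rep(0.5, length(va)),
                       folds = 10, seed = 3)
  expect_equal(unname(cv$grid$mean_logloss), rep(log(2), 2), tolerance = 1e-12)
  expect_equal(cv$best, 1L)  # tie goes to the first (simplest) row
  expect_equal(sort(unique(cv$fold_id)), 1:10)
  expect_true(all(table(cv$fold_id) == 10))
  # stratification: every fold carries both classes proportionally
  expect_true(all(table(cv$fold_id, y) == 6 | table(cv$fold_id, y) == 4))
  expect_error(cross_validate(y, data.frame()[0, , drop = FALSE],
                              function(...) 0.5), "empty")
})

test_that("CV-chosen lambda generalizes at least as well as the largest lambda", {
  co <- quick_cohort(1200, 1200, tiny_panel(8, log_or = 0.2), seed = 38)
  va <- quick_cohort(800, 800, tiny_panel(8, log_or = 0.2), seed = 39)
  grid <- c(0.1, 10, 1e5)
  fit <- prs_fit(co$genotypes, co$samples, "lrr", lambda_grid = grid, seed = 4)
  fmax <- prs_fit(co$genotypes, co$samples, "lrr", lambda_grid = 1e5)
  tabv <- va$samples
  pcs <- compute_pcs(va$genotypes, 2); tabv$pc1 <- pcs[, 1]; tabv$pc2 <- pcs[, 2]
  y <- as.numeric(tabv$status == "case")
  ll <- function(f) {
    p <- predict(f, va$genotypes, type = "response", samples = tabv)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  expect_lte(ll(fit), ll(fmax) + 1e-8)
})

test_that("ANN fitting is reproducible and its score ignores covariates", {
  co <- quick_cohort(300, 300, tiny_panel(8, log_or = 0.25), seed = 40)
  cfg <- ann_config(n_iterations = 30, seed = 7)
  f1 <- prs_fit(co$genotypes, co$samples, "ann", config = cfg)
  f2 <- prs_fit(co$genotypes, co$samples, "ann", config = cfg)
  s1 <- predict(f1, co$genotypes)
  expect_identical(s1, predict(f2, co$genotypes))
  # identical genotype rows score identically regardless of covariates
  m <- unclass(co$genotypes)
  m2 <- rbind(m[1, ], m[1, ]); rownames(m2) <- c("x1", "x2")
  g2 <- genotype_matrix(m2, effect_alleles = effect_alleles(co$genotypes))
  s2 <- predict(f1, g2)
  expect_equal(unname(s2[1]), unname(s2[2]))
})

test_that("a zeroed genotype pathway yields a constant score (the bias)", {
  co <- quick_cohort(100, 100, tiny_panel(4), seed = 41)
  f <- prs_fit(co$genotypes, co$samples, "ann",
               config = ann_config(n_iterations = 5, n_restarts = 1, seed = 2))
  f$ann[[1]]$w_out <- rep(0, length(f$ann[[1]]$w_out))
  s <- predict(f, co$genotypes)
  expect_equal(unname(s), rep(f$ann[[1]]$b_out, nrow(co$genotypes)))
})

test_that("subtype-specific training uses subtype cases plus all controls", {
  co <- quick_cohort(200, 150, tiny_panel(4, log_or = 0.3), seed = 42)
  fit <- prs_fit(co$genotypes, co$samples, "rlr", case_set = "er_neg")
  tab <- co$samples
  expected <- tab$sample_id[tab$status == "control" |
                              (tab$status == "case" & tab$er_status == "negative")]
  expect_setequal(fit$training_samples, expected)
  expect_equal(fit$case_set, "er_neg")
})

test_that("ANN hyperparameter tuning selects over the supplied grid", {
  co <- quick_cohort(250, 250, tiny_panel(6, log_or = 0.3), seed = 43)
  grid <- data.frame(n_iterations = c(5, 25))
  f <- prs_fit(co$genotypes, co$samples, "ann", tune_grid = grid,
               config = ann_config(n_hidden_layers = 1, n_restarts = 1, seed = 3),
               folds = 5, seed = 3)
  expect_s3_class(f$cv, "cv_result")
  expect_equal(nrow(f$cv$grid), 2)
  expect_true(f$config$n_iterations %in% grid$n_iterations)
})
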