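test_that("IQ-OR matches an independent logistic fit on a toy set", {
  scores <- c(0, 1, 2, 3, 2, 3, 4, 5)
  status <- rep(c("control", "case"), each = 4)
  res <- iq_or(scores, status)
  # control IQR = 1.5 (type-7 quartiles of 0,1,2,3); oracle slope by Newton
  iqr <- stats::IQR(c(0, 1, 2, 3))
  b <- logistic_slope_oracle(scores / iqr, c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(res$or, exp(b), tolerance = 1e-6)
  expect_equal(res$iqr, iqr)
  # scale invariance
  res2 <- iq_or(scores * 17.3, status)
  expect_equal(res2$or, res$or, tolerance = 1e-8)
  expect_error(iq_or(rep(1, 8), status), "zero control IQR")
})

test_that("null scores give an IQ-OR interval covering 1", {
  set.seed(5)
  scores <- rnorm(4000)
  status <- rep(c("case", "control"), 2000)
  res <- iq_or(scores, status)
  expect_gt(1, res$ci[1]); expect_lt(1, res$ci[2])
})

test_that("extreme-quartile OR reproduces the hand-computed cross product", {
  # counts: cases Q4 = 30, controls Q4 = 25, cases Q1 = 10, controls Q1 = 25
  ctrl <- c(rep(1, 25), rep(2, 25), rep(3, 25), rep(4, 25)) + 0.001 * seq_len(100)
  case <- c(rep(1, 10), rep(2, 15), rep(3, 20), rep(4, 30)) + 0.0011 * seq_len(75)
  scores <- c(ctrl, case)
  status <- rep(c("control", "case"), c(100, 75))
  res <- quartile_or(scores, status)
  expect_equal(res$or, (30 * 25) / (10 * 25))
  # cut points come from controls only: adding extreme cases changes nothing
  res2 <- quartile_or(c(scores, 100, -100), c(status, "case", "case"))
  expect_equal(res2$table["control", ], res$table["control", ])
})

test_that("cases spread like controls give OR near 1", {
  set.seed(8)
  scores <- runif(3000)
  status <- rep(c("case", "control"), 1500)
  res <- quartile_or(scores, status)
  expect_gt(res$ci[2], 1); expect_lt(res$ci[1], 1)
})

test_that("AUC equals exhaustive pair counting with Hanley-McNeil width", {
  expect_error(auc_ci(c(2, 3), c("case", "case")), "both classes")
  res <- auc_ci(c(2, 3, 1, 2.5), c("case", "case", "control", "control"))
  expect_equal(res$auc, 3 / 4)
  # perfect separation
  expect_equal(auc_ci(c(5, 6, 1, 2), c("case", "case", "control", "control"))$auc, 1)
  # antisymmetry
  set.seed(2)
  s <- rnorm(60); st <- rep(c("case", "control"), 30)
  expect_equal(auc_ci(-s, st)$auc, 1 - auc_ci(s, st)$auc)
  # oracle equivalence on random fixtures with ties
  for (i in 1:5) {
    set.seed(i)
    n <- sample(20:200, 1)
    st <- sample(c("case", "control"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(st)) < 2) next
    sc <- sample(seq(0, 2, by = 0.25), n, replace = TRUE)
    expect_equal(auc_ci(sc, st)$auc, auc_oracle(sc, st))
  }
})

test_that("O/E slope matches the closed form and behaves under scaling", {
  x <- c(-0.2, 0.1, 0.3); y <- c(-0.1, 0.2, 0.25)
  res <- oe_slope(x, y)
  expect_equal(res$slope, sum(x * y) / sum(x^2))
  # generating log-odds scores are well calibrated at large n; varied
  # effects keep the score distribution effectively continuous
  panel <- tiny_panel(8)
  panel$log_or <- seq(0.1, 0.38, length.out = 8)
  co <- quick_cohort(5000, 5000, panel, seed = 44,
                     covariate_effects = numeric(0))
  cal <- prs_calibration(co$samples$true_eta, co$samples$status)
  expect_gt(1, cal$ci[1]); expect_lt(1, cal$ci[2])
  # doubling the scores halves the slope (observed unchanged, expected doubled)
  cal2 <- prs_calibration(2 * co$samples$true_eta, co$samples$status)
  expect_equal(cal2$slope, cal$slope / 2, tolerance = 0.05)
  expect_equal(nrow(cal$table), 8)          # ten bins minus pooled middle two
  expect_equal(cal$reference_bins, c(5, 6))
})

test_that("residual adjustment is an OLS projection", {
  co <- quick_cohort(300, 300, tiny_panel(3), seed = 45)
  tab <- co$samples
  set.seed(9)
  # score orthogonal to covariates: residuals are the centered scores
  sc <- rnorm(600)
  r <- residual_adjust(sc, tab, mode = "classical")
  fit <- stats::lm(sc ~ age + age_menarche + live_births + family_history +
                     bmi + menopausal, data = tab)
  expect_equal(r, unname(stats::resid(fit)))
  # score exactly linear in covariates: residuals vanish
  sc2 <- 2 * tab$age - 0.5 * tab$bmi
  expect_lt(max(abs(residual_adjust(sc2, tab, mode = "classical"))), 1e-8)
  # orthogonality: residuals uncorrelated with age
  sc3 <- 2 * tab$age + rnorm(600)
  expect_lt(abs(stats::cor(residual_adjust(sc3, tab, "classical"), tab$age)), 1e-8)
  # gail mode uses the external risk column only
  r4 <- residual_adjust(sc3, tab, mode = "gail")
  expect_lt(abs(stats::cor(r4, tab$external_5yr_risk)), 1e-8)
  tab$age[3] <- NA
  expect_error(residual_adjust(sc, tab, "classical"), "missing covariate")
})

test_that("interaction scan reports the Bonferroni threshold and finds signals", {
  panel <- tiny_panel(4, maf = 0.3)
  inter <- data.frame(snp_i = "t01", snp_j = "t02", delta = 0.6)
  co <- simulate_cohort(sim_config(3000, 3000, panel, interactions = inter,
                                   covariate_effects = numeric(0), seed = 46))
  scan <- interaction_scan(co$genotypes, co$samples)
  expect_equal(nrow(scan$pairs), choose(4, 2))
  expect_equal(scan$bonferroni_alpha, 0.05 / 6)
  hit <- scan$pairs[scan$pairs$snp_i == "t01" & scan$pairs$snp_j == "t02", ]
  expect_lt(hit$p, scan$bonferroni_alpha)
  expect_gt(hit$delta, 0.3)
  # two SNPs: one pair, threshold alpha itself
  scan2 <- interaction_scan(co$genotypes[, 1:2], co$samples)
  expect_equal(nrow(scan2$pairs), 1)
  expect_equal(scan2$bonferroni_alpha, 0.05)
  expect_error(interaction_scan(co$genotypes[, 1], co$samples), "at least 2")
})

test_that("evaluate_prs emits one complete metric row per adjustment", {
  co <- quick_cohort(400, 400, tiny_panel(6, log_or = 0.3), seed = 47)
  sc <- predict(prs_fit(co$genotypes, co$samples, "rlr"), co$genotypes)
  ev <- evaluate_prs(sc, co$samples$status, co$samples,
                     adjustments = c("none", "gail", "classical"),
                     case_set = "overall", method = "rlr")
  expect_equal(nrow(ev), 3)
  expect_true(all(c("q4_q1_or", "iq_or", "oe_or", "auc",
                    "iq_or_lo", "iq_or_hi", "auc_lo", "auc_hi") %in% names(ev)))
  expect_true(all(ev$iq_or > 0))
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  expect_true(all(ev$iq_or_lo <= ev$iq_or & ev$iq_or <= ev$iq_or_hi))
  # determinism
  ev2 <- evaluate_prs(sc, co$samples$status, co$samples,
                      adjustments = c("none", "gail", "classical"),
                      case_set = "overall", method = "rlr")
  expect_identical(ev, ev2)
})
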