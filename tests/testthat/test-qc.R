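test_that("exact HWE test matches full-enumeration oracle on assorted tables", {
  cases <- list(c(3, 5, 2), c(0, 0, 50), c(10, 1, 10), c(4, 12, 9),
                c(1, 1, 1), c(25, 0, 25), c(0, 21, 0), c(7, 0, 3))
  for (cc in cases)
    expect_equal(hwe_exact_test(cc[1], cc[2], cc[3]),
                 hwe_oracle(cc[1], cc[2], cc[3]), tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "empty")
})

test_that("HWE deviations are detected and monomorphics are exact 1", {
  # massive heterozygote excess
  expect_lt(hwe_exact_test(0, 40, 0), 1e-6)
  # equilibrium-looking table is not significant
  expect_gt(hwe_exact_test(49, 42, 9), 0.05)
  expect_identical(hwe_exact_test(0, 0, 50), 1)
  expect_identical(hwe_exact_test(33, 0, 0), 1)
})

test_that("KING kinship has the expected values and invariances", {
  v <- c(0, 1, 2, 1, 0, 1, 2, 0, 1, 1)
  expect_equal(king_kinship(v, v), 0.5)
  w <- c(2, 1, 0, 1, 2, 0, 1, 1, 0, 2)
  expect_equal(king_kinship(v, w), king_kinship(w, v))
  # appending loci missing in either sample changes nothing
  v2 <- c(v, NA, 2, NA)
  w2 <- c(w, 1, NA, NA)
  expect_equal(king_kinship(v2, w2), king_kinship(v, w))
  # no heterozygotes in either sample: not evaluable
  expect_true(is.na(king_kinship(c(0, 2, 2), c(2, 0, 2))))
})

test_that("kinship matrix agrees with the pairwise estimator under missingness", {
  co <- quick_cohort(15, 15, tiny_panel(60), seed = 2)
  g <- inject_missingness(co$genotypes, 0.1, seed = 3)
  phi <- prsforge:::kinship_matrix(g)
  ids <- rownames(g)
  for (pair in list(c(1, 2), c(5, 20), c(13, 29))) {
    expect_equal(phi[pair[1], pair[2]],
                 king_kinship(g[ids[pair[1]], , drop = TRUE],
                              g[ids[pair[2]], , drop = TRUE]))
  }
})

test_that("duplicate concordance counts discordant calls per SNP", {
  co <- quick_cohort(10, 10, tiny_panel(3), seed = 4)
  dup <- add_related_samples(co$genotypes, co$samples, "duplicate", 5, seed = 5)
  pairs <- data.frame(id_a = dup$pairs$base, id_b = dup$pairs$added)
  conc <- duplicate_concordance(dup$genotypes, pairs)
  expect_equal(unname(conc), rep(1, 3))
  # introduce one discordant call at SNP 1
  m <- unclass(dup$genotypes)
  m[dup$pairs$added[1], 1] <- (m[dup$pairs$added[1], 1] + 1) %% 3
  g2 <- genotype_matrix(m, effect_alleles = effect_alleles(dup$genotypes))
  conc2 <- duplicate_concordance(g2, pairs)
  expect_equal(unname(conc2[1]), 4 / 5)
  # all-missing SNP in duplicates: not evaluable
  m[c(dup$pairs$base, dup$pairs$added), 2] <- NA
  g3 <- genotype_matrix(m, fractional = TRUE)
  expect_true(is.na(duplicate_concordance(g3, pairs)[2]))
  expect_error(duplicate_concordance(g2, NULL), "no duplicate pairs")
})

test_that("mean imputation fills missing entries with the column mean", {
  m <- rbind(c(0, 2, 1), c(1, 2, 0), c(2, NA, NA), c(NA, 2, 1))
  g <- genotype_matrix(m, sample_ids = paste0("s", 1:4),
                       snp_ids = c("a", "b", "c"), fractional = TRUE)
  gi <- mean_impute(g)
  expect_equal(unname(unclass(gi)[4, 1]), 1)     # mean of 0,1,2
  expect_equal(unname(unclass(gi)[3, 2]), 2)     # constant column
  expect_equal(unname(unclass(gi)[3, 3]), 2 / 3) # fractional mean
  expect_identical(mean_impute(gi), gi)          # identity with no missing
  m[, 1] <- NA
  expect_error(mean_impute(genotype_matrix(m, fractional = TRUE)), "all-missing")
})

test_that("apply_qc passes a clean panel through untouched", {
  co <- quick_cohort(200, 200, tiny_panel(8, maf = 0.3), seed = 6)
  # 8 SNPs are far too few for kinship estimation: the filter must step aside
  expect_warning(r <- apply_qc(co$genotypes, co$samples, qc_thresholds("array")),
                 "kinship filter skipped")
  expect_equal(r$report$summary$snps_out, 8)
  expect_equal(r$report$summary$samples_out, 400)
  expect_true(all(r$report$snp_decisions$pass))
  expect_identical(unclass(r$genotypes), unclass(co$genotypes))
})

test_that("apply_qc removes entities for the documented reasons", {
  co <- quick_cohort(100, 100, tiny_panel(5, maf = 0.3), seed = 8)
  m <- unclass(co$genotypes)
  # SNP 1: call rate 0.97 < 0.98
  m[1:6, 1] <- NA
  # sample 1: misses 3 SNPs -> failed-SNP exclusion at threshold 3
  m[10, 2:4] <- NA
  g <- genotype_matrix(m, effect_alleles = effect_alleles(co$genotypes),
                       fractional = TRUE)
  th <- qc_thresholds("panel", snp_call_rate_min = 0.98,
                      max_failed_snps_per_sample = 3,
                      hwe_p_min_controls = 0)
  r <- apply_qc(g, co$samples, th)
  dec <- r$report$snp_decisions
  expect_false(dec$pass[dec$snp_id == "t01"])
  expect_match(dec$reasons[dec$snp_id == "t01"], "call_rate")
  sdec <- r$report$sample_decisions
  bad_id <- rownames(m)[10]
  expect_false(sdec$pass[sdec$sample_id == bad_id])
  expect_match(sdec$reasons[sdec$sample_id == bad_id], "failed_snps")
  expect_false(anyNA(r$genotypes))  # imputation is the final step
})

test_that("stratified HWE filter flags control-stratum violations", {
  co <- quick_cohort(150, 150, tiny_panel(4, maf = 0.3), seed = 9)
  m <- unclass(co$genotypes)
  ctrl <- co$samples$sample_id[co$samples$status == "control"]
  # force heterozygote excess in controls at SNP 2
  m[ctrl, 2] <- 1
  g <- genotype_matrix(m)
  p_ctrl <- hwe_exact_test(0, length(ctrl), 0)
  expect_lt(p_ctrl, 1e-10)
  r <- apply_qc(g, co$samples, qc_thresholds("array", kinship_max = Inf,
                                             hwe_p_min_controls = 1e-6))
  dec <- r$report$snp_decisions
  expect_match(dec$reasons[dec$snp_id == "t02"], "hwe_controls")
  expect_true(all(dec$pass[dec$snp_id != "t02"]))
})

test_that("kinship filter removes one member per related pair", {
  co <- quick_cohort(40, 40, tiny_panel(1500), seed = 10)
  dup <- add_related_samples(co$genotypes, co$samples, "duplicate", 4, seed = 11)
  r <- apply_qc(dup$genotypes, dup$samples,
                qc_thresholds("array", kinship_max = 0.0884))
  removed <- r$report$sample_decisions
  removed <- removed$sample_id[!removed$pass]
  expect_equal(length(removed), 4)
  # exactly one member of each duplicate pair survives
  for (i in 1:4)
    expect_equal(sum(c(dup$pairs$base[i], dup$pairs$added[i]) %in% removed), 1)
  expect_true(all(grepl("kinship", r$report$sample_decisions$reasons[
    !r$report$sample_decisions$pass])))
})

test_that("apply_qc is idempotent", {
  co <- quick_cohort(120, 120, tiny_panel(6), seed = 12)
  g <- inject_missingness(co$genotypes, 0.01, seed = 13)
  th <- qc_thresholds("array", kinship_max = Inf)
  r1 <- apply_qc(g, co$samples, th)
  r2 <- apply_qc(r1$genotypes, r1$samples, th)
  expect_identical(unclass(r2$genotypes), unclass(r1$genotypes))
  expect_equal(r2$report$summary$snps_out, r1$report$summary$snps_out)
  expect_equal(r2$report$summary$samples_out, r1$report$summary$samples_out)
})

test_that("unrelated samples stay below the kinship threshold", {
  panel <- tiny_panel(1000, maf = 0.3)
  co <- quick_cohort(100, 100, panel, seed = 14, covariate_effects = numeric(0))
  phi <- prsforge:::kinship_matrix(co$genotypes)
  up <- phi[upper.tri(phi)]
  expect_lt(stats::quantile(up, 0.999), 0.0884)
})
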