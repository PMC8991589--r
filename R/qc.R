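#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of Hardy-Weinberg proportions: conditioning on the
#' observed allele counts, heterozygote counts follow a hypergeometric-type
#' null, and the two-sided P-value is the sum of the probabilities of every
#' attainable configuration whose probability does not exceed that of the
#' observed one.
#'
#' @param n_ref count of reference-homozygote genotypes.
#' @param n_het count of heterozygote genotypes.
#' @param n_eff count of effect-homozygote genotypes.
#' @return the exact P-value in (0, 1].
#' @examples
#' hwe_exact_test(3, 5, 2)
#' hwe_exact_test(0, 0, 50)  # monomorphic: 1
#' @export
hwe_exact_test <- function(n_ref, n_het, n_eff) {
  stopifnot(n_ref >= 0, n_het >= 0, n_eff >= 0)
  n <- n_ref + n_het + n_eff
  if (n == 0) stop("empty genotype table")
  n_rare <- min(2 * n_ref + n_het, 2 * n_eff + n_het)
  if (n_rare == 0) return(1)
  # log-probability of h heterozygotes given n diploids, n_rare rare alleles
  hs <- seq(n_rare %% 2, n_rare, by = 2)
  lp <- h_loglik(hs, n, n_rare)
  lp <- lp - max(lp)
  p <- exp(lp); p <- p / sum(p)
  p_obs <- p[match(n_het, hs)]
  if (is.na(p_obs)) stop("heterozygote count not attainable for these allele counts")
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

h_loglik <- function(h, n, n_rare) {
  n_common <- 2 * n - n_rare
  h * log(2) + lgamma(n + 1) -
    (lgamma((n_rare - h) / 2 + 1) + lgamma(h + 1) + lgamma((n_common - h) / 2 + 1)) +
    lgamma(n_rare + 1) + lgamma(n_common + 1) - lgamma(2 * n + 1)
}

#' KING-robust kinship coefficient for one sample pair
#'
#' Between-family relatedness estimator from heterozygote and
#' opposing-homozygote counts:
#' `phi = (N_AaAa - 2 N_AAaa) / (N_Aa(i) + N_Aa(j))`,
#' computed over loci genotyped in both samples. Expected values: 0.5 for
#' duplicates/MZ twins, 0.25 for parent-offspring, 0.125 for second-degree
#' pairs, ~0 for unrelated pairs; 0.0884 is the conventional second-degree
#' cutoff.
#'
#' @param dos_i,dos_j dosage vectors of equal length (0/1/2/NA).
#' @return the kinship coefficient, or `NA` if neither sample has a
#'   heterozygous call on the jointly observed loci (not evaluable).
#' @export
king_kinship <- function(dos_i, dos_j) {
  dos_i <- as.vector(unclass(dos_i)); dos_j <- as.vector(unclass(dos_j))
  stopifnot(length(dos_i) == length(dos_j))
  ok <- !is.na(dos_i) & !is.na(dos_j)
  di <- dos_i[ok]; dj <- dos_j[ok]
  het_i <- sum(di == 1); het_j <- sum(dj == 1)
  if (het_i + het_j == 0) return(NA_real_)
  n_hethet <- sum(di == 1 & dj == 1)
  n_opp <- sum(abs(di - dj) == 2)
  (n_hethet - 2 * n_opp) / (het_i + het_j)
}

# all pairwise KING-robust coefficients via indicator-matrix products;
# missing entries handled exactly (per-pair counts restricted to joint loci)
kinship_matrix <- function(g) {
  m <- unclass(g)
  H <- (m == 1); H[is.na(H)] <- FALSE
  A0 <- (m == 0); A0[is.na(A0)] <- FALSE
  A2 <- (m == 2); A2[is.na(A2)] <- FALSE
  M <- !is.na(m)
  storage.mode(H) <- "double"; storage.mode(A0) <- "double"
  storage.mode(A2) <- "double"; storage.mode(M) <- "double"
  n_hethet <- tcrossprod(H)
  n_opp <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  den <- tcrossprod(H, M) + tcrossprod(M, H)
  phi <- (n_hethet - 2 * n_opp) / den
  phi[den == 0] <- NA
  dimnames(phi) <- list(rownames(g), rownames(g))
  phi
}

#' Per-SNP concordance across blind duplicate pairs
#'
#' @param g a `genotype_matrix`.
#' @param pairs data.frame with columns `id_a`, `id_b` naming duplicate
#'   sample pairs present in `g`.
#' @return named numeric vector: per SNP, the fraction of jointly
#'   non-missing duplicate observations with identical dosage; `NA` where no
#'   pair is jointly observed (not evaluable).
#' @export
duplicate_concordance <- function(g, pairs) {
  stopifnot_genotype(g)
  if (is.null(pairs) || nrow(pairs) == 0) stop("no duplicate pairs supplied")
  a <- unclass(g)[pairs$id_a, , drop = FALSE]
  b <- unclass(g)[pairs$id_b, , drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  agree <- (a == b) & ok
  n_ok <- colSums(ok)
  out <- colSums(agree) / n_ok
  out[n_ok == 0] <- NA
  out
}

#' Impute sporadic missing dosages by the population mean
#'
#' Each missing dosage is replaced by that SNP's mean observed dosage over
#' the full dataset (cases and controls combined); imputed values may be
#' fractional. Non-missing entries are untouched.
#'
#' @param g a `genotype_matrix`.
#' @return the imputed matrix (no `NA`s).
#' @export
mean_impute <- function(g) {
  stopifnot_genotype(g)
  m <- unclass(g)
  mu <- colMeans(m, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu)))
    stop("all-missing SNP(s): ", paste(colnames(m)[is.nan(mu)], collapse = ", "),
         " (remove by call-rate filter first)")
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- mu[idx[, 2]]
  genotype_matrix(m, effect_alleles = effect_alleles(g),
                  other_alleles = attr(g, "other_alleles"), fractional = TRUE)
}

#' Quality-control thresholds
#'
#' Two conventional presets are provided: `preset = "array"` mirrors
#' GWAS-array QC (SNP/sample call rate 99%, MAF 1%, stratified HWE cutoffs
#' 1e-6 in controls and 1e-10 in cases, kinship cutoff 0.0884);
#' `preset = "panel"` mirrors small-panel validation QC (SNP call rate 98%,
#' duplicate concordance 99%, HWE P 0.05 in controls, monomorphic SNPs
#' dropped, samples excluded at >= 3 failed SNPs).
#'
#' @param preset `"array"`, `"panel"`, or `"none"` (all filters off unless set).
#' @param snp_call_rate_min,sample_call_rate_min minimum call rates.
#' @param maf_min minimum minor-allele frequency.
#' @param hwe_p_min_controls,hwe_p_min_cases minimum exact HWE P per stratum
#'   (0 disables).
#' @param kinship_max maximum pairwise kinship; pairs above it lose one member.
#' @param kinship_min_snps minimum marker count for kinship estimation; with
#'   fewer SNPs the KING estimator is too noisy to act on and the filter is
#'   skipped with a warning (default 100).
#' @param duplicate_concordance_min minimum duplicate concordance per SNP.
#' @param max_failed_snps_per_sample samples with at least this many failed
#'   (missing) calls are removed (`Inf` disables).
#' @param drop_monomorphic drop SNPs with no variation.
#' @return a `qc_thresholds` object.
#' @export
qc_thresholds <- function(preset = c("none", "array", "panel"),
                          snp_call_rate_min = NULL, sample_call_rate_min = NULL,
                          maf_min = NULL, hwe_p_min_controls = NULL,
                          hwe_p_min_cases = NULL, kinship_max = NULL,
                          kinship_min_snps = NULL,
                          duplicate_concordance_min = NULL,
                          max_failed_snps_per_sample = NULL,
                          drop_monomorphic = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    array = list(snp_call_rate_min = 0.99, sample_call_rate_min = 0.99,
                 maf_min = 0.01, hwe_p_min_controls = 1e-6,
                 hwe_p_min_cases = 1e-10, kinship_max = 0.0884,
                 kinship_min_snps = 100,
                 duplicate_concordance_min = 0,
                 max_failed_snps_per_sample = Inf, drop_monomorphic = TRUE),
    panel = list(snp_call_rate_min = 0.98, sample_call_rate_min = 0,
                 maf_min = 0, hwe_p_min_controls = 0.05, hwe_p_min_cases = 0,
                 kinship_max = Inf, kinship_min_snps = 100,
                 duplicate_concordance_min = 0.99,
                 max_failed_snps_per_sample = 3, drop_monomorphic = TRUE),
    none = list(snp_call_rate_min = 0, sample_call_rate_min = 0, maf_min = 0,
                hwe_p_min_controls = 0, hwe_p_min_cases = 0, kinship_max = Inf,
                kinship_min_snps = 100,
                duplicate_concordance_min = 0,
                max_failed_snps_per_sample = Inf, drop_monomorphic = FALSE))
  override <- list(snp_call_rate_min = snp_call_rate_min,
                   sample_call_rate_min = sample_call_rate_min,
                   maf_min = maf_min, hwe_p_min_controls = hwe_p_min_controls,
                   hwe_p_min_cases = hwe_p_min_cases, kinship_max = kinship_max,
                   kinship_min_snps = kinship_min_snps,
                   duplicate_concordance_min = duplicate_concordance_min,
                   max_failed_snps_per_sample = max_failed_snps_per_sample,
                   drop_monomorphic = drop_monomorphic)
  for (nm in names(override)) if (!is.null(override[[nm]])) def[[nm]] <- override[[nm]]
  probs <- unlist(def[c("snp_call_rate_min", "sample_call_rate_min", "maf_min",
                        "hwe_p_min_controls", "hwe_p_min_cases",
                        "duplicate_concordance_min")])
  stopifnot(all(probs >= 0 & probs <= 1), def$kinship_max >= 0)
  structure(def, class = "qc_thresholds")
}

#' Apply the quality-control pipeline
#'
#' Deterministic, report-producing QC. Filters run in a fixed order — SNP
#' call rate, sample call rate, MAF, stratified exact HWE (controls then
#' cases), duplicate concordance, monomorphic SNPs, kinship-based sample
#' exclusion, failed-SNP-count sample exclusion — with per-SNP statistics
#' recomputed after every sample-removal step, and end with population-mean
#' imputation of surviving sporadic missingness. Kinship exclusion removes
#' one member per flagged pair, preferring the member with the lower call
#' rate (ties: the later sample in input order is removed).
#'
#' @param g a `genotype_matrix`.
#' @param samples sample table with `sample_id` and `status` columns.
#' @param thresholds a [qc_thresholds()] object.
#' @param duplicates optional data.frame (`id_a`, `id_b`) of blind duplicate
#'   pairs for the concordance filter; if the filter is enabled but no pairs
#'   are supplied it is skipped with a warning.
#' @return `list(genotypes, samples, report)`; the report is a `qc_report`
#'   with per-SNP and per-sample decisions, reason codes, kinship pairs and
#'   summary counts.
#' @export
apply_qc <- function(g, samples, thresholds = qc_thresholds("array"),
                     duplicates = NULL) {
  stopifnot_genotype(g)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  samples <- align_table(g, samples)
  th <- thresholds

  snp_reasons <- stats::setNames(vector("list", ncol(g)), colnames(g))
  smp_reasons <- stats::setNames(vector("list", nrow(g)), rownames(g))
  snp_values <- list()
  drop_snp <- function(ids, reason) {
    for (id in ids) snp_reasons[[id]] <<- c(snp_reasons[[id]], reason)
  }
  drop_smp <- function(ids, reason) {
    for (id in ids) smp_reasons[[id]] <<- c(smp_reasons[[id]], reason)
  }
  keep_snps <- colnames(g); keep_smps <- rownames(g)
  cur <- function() g[keep_smps, keep_snps]

  fail_if_empty <- function(stage) {
    if (!length(keep_snps)) stop("QC removed every SNP at stage: ", stage)
    if (!length(keep_smps)) stop("QC removed every sample at stage: ", stage)
  }

  # 1. SNP call rate
  cr <- call_rate(cur(), "snp")
  snp_values$call_rate <- cr
  bad <- names(cr)[cr < th$snp_call_rate_min]
  drop_snp(bad, "call_rate"); keep_snps <- setdiff(keep_snps, bad)
  fail_if_empty("snp_call_rate")

  # 2. sample call rate (on surviving SNPs)
  scr <- call_rate(cur(), "sample")
  bad <- names(scr)[scr < th$sample_call_rate_min]
  drop_smp(bad, "call_rate"); keep_smps <- setdiff(keep_smps, bad)
  fail_if_empty("sample_call_rate")

  # 3. MAF (observed dosages, current samples)
  f <- observed_maf(cur())
  maf <- pmin(f, 1 - f)
  snp_values$maf <- maf
  bad <- names(maf)[maf < th$maf_min]
  drop_snp(bad, "maf"); keep_snps <- setdiff(keep_snps, bad)
  fail_if_empty("maf")

  # 4. HWE, stratified
  st <- samples$status[match(keep_smps, samples$sample_id)]
  for (stratum in c("controls", "cases")) {
    p_min <- if (stratum == "controls") th$hwe_p_min_controls else th$hwe_p_min_cases
    if (p_min <= 0) next
    who <- keep_smps[st == (if (stratum == "controls") "control" else "case")]
    if (!length(who)) next
    cnt <- genotype_counts(cur(), samples = who)
    pv <- apply(cnt, 1, function(x) {
      if (sum(x) == 0) return(1)
      hwe_exact_test(x[1], x[2], x[3])
    })
    snp_values[[paste0("hwe_p_", stratum)]] <- pv
    bad <- keep_snps[pv < p_min]
    drop_snp(bad, paste0("hwe_", stratum)); keep_snps <- setdiff(keep_snps, bad)
    fail_if_empty(paste0("hwe_", stratum))
  }

  # 5. duplicate concordance
  if (th$duplicate_concordance_min > 0) {
    if (is.null(duplicates) || nrow(duplicates) == 0) {
      warning("duplicate-concordance filter enabled but no pairs supplied; skipped")
    } else {
      dup <- duplicates[duplicates$id_a %in% keep_smps &
                          duplicates$id_b %in% keep_smps, , drop = FALSE]
      if (nrow(dup)) {
        conc <- duplicate_concordance(cur(), dup)
        snp_values$dup_concordance <- conc
        bad <- names(conc)[!is.na(conc) & conc < th$duplicate_concordance_min]
        drop_snp(bad, "dup_concordance"); keep_snps <- setdiff(keep_snps, bad)
        fail_if_empty("dup_concordance")
      }
    }
  }

  # 6. monomorphic
  if (isTRUE(th$drop_monomorphic)) {
    f <- observed_maf(cur())
    bad <- names(f)[pmin(f, 1 - f) == 0]
    drop_snp(bad, "monomorphic"); keep_snps <- setdiff(keep_snps, bad)
    fail_if_empty("monomorphic")
  }

  # 7. kinship exclusion
  kin_pairs <- NULL
  if (is.finite(th$kinship_max) && length(keep_smps) > 1 &&
      length(keep_snps) < th$kinship_min_snps) {
    warning("kinship filter skipped: ", length(keep_snps), " SNPs < ",
            th$kinship_min_snps, " required for a usable KING estimate")
  } else if (is.finite(th$kinship_max) && length(keep_smps) > 1) {
    phi <- kinship_matrix(cur())
    ut <- which(upper.tri(phi) & !is.na(phi) & phi > th$kinship_max,
                arr.ind = TRUE)
    if (nrow(ut)) {
      kin_pairs <- data.frame(sample_i = rownames(phi)[ut[, 1]],
                              sample_j = colnames(phi)[ut[, 2]],
                              phi = phi[ut], stringsAsFactors = FALSE)
      kin_pairs <- kin_pairs[order(match(kin_pairs$sample_i, keep_smps),
                                   match(kin_pairs$sample_j, keep_smps)), ]
      crs <- call_rate(cur(), "sample")
      for (r in seq_len(nrow(kin_pairs))) {
        a <- kin_pairs$sample_i[r]; b <- kin_pairs$sample_j[r]
        if (!(a %in% keep_smps) || !(b %in% keep_smps)) next
        victim <- if (crs[a] < crs[b]) a else if (crs[b] < crs[a]) b else
          keep_smps[max(match(a, keep_smps), match(b, keep_smps))]
        drop_smp(victim, "kinship"); keep_smps <- setdiff(keep_smps, victim)
      }
      fail_if_empty("kinship")
    }
  }

  # 8. failed-SNP-count sample exclusion (missing calls on surviving SNPs)
  if (is.finite(th$max_failed_snps_per_sample)) {
    nmiss <- rowSums(is.na(unclass(cur())))
    bad <- names(nmiss)[nmiss >= th$max_failed_snps_per_sample]
    drop_smp(bad, "failed_snps"); keep_smps <- setdiff(keep_smps, bad)
    fail_if_empty("failed_snps")
  }

  # 9. mean imputation of whatever sporadic missingness remains
  g_out <- cur()
  if (anyNA(g_out)) g_out <- mean_impute(g_out)
  samples_out <- samples[samples$sample_id %in% keep_smps, , drop = FALSE]

  snp_dec <- data.frame(
    snp_id = colnames(g),
    pass = colnames(g) %in% keep_snps,
    reasons = vapply(snp_reasons, function(x) paste(x, collapse = ";"), ""),
    call_rate = snp_values$call_rate[colnames(g)],
    maf = snp_values$maf[colnames(g)],
    row.names = NULL, stringsAsFactors = FALSE)
  for (nm in intersect(c("hwe_p_controls", "hwe_p_cases", "dup_concordance"),
                       names(snp_values)))
    snp_dec[[nm]] <- snp_values[[nm]][snp_dec$snp_id]
  smp_dec <- data.frame(
    sample_id = rownames(g),
    pass = rownames(g) %in% keep_smps,
    reasons = vapply(smp_reasons, function(x) paste(x, collapse = ";"), ""),
    row.names = NULL, stringsAsFactors = FALSE)

  report <- structure(list(
    snp_decisions = snp_dec, sample_decisions = smp_dec,
    kinship_pairs = kin_pairs,
    summary = list(snps_in = ncol(g), snps_out = length(keep_snps),
                   samples_in = nrow(g), samples_out = length(keep_smps)),
    thresholds = unclass(th)), class = "qc_report")
  list(genotypes = g_out, samples = samples_out, report = report)
}

#' Write a QC report as TSV tables plus a JSON summary
#'
#' Emits `qc_snps.tsv` and `qc_samples.tsv` (one row per entity with
#' pass/fail and reason codes), `qc_kinship_pairs.tsv` when kinship pairs
#' were flagged, and `qc_summary.json`.
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_qc_report <- function(report, dir) {
  stopifnot(inherits(report, "qc_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$snp_decisions, file.path(dir, "qc_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$sample_decisions, file.path(dir, "qc_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$kinship_pairs))
    utils::write.table(report$kinship_pairs,
                       file.path(dir, "qc_kinship_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(report$summary, list(thresholds = report$thresholds)),
                       file.path(dir, "qc_summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @export
print.qc_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("QC report: SNPs %d -> %d, samples %d -> %d\n",
              s$snps_in, s$snps_out, s$samples_in, s$samples_out))
  fails <- x$snp_decisions[!x$snp_decisions$pass, c("snp_id", "reasons")]
  if (nrow(fails)) {
    cat("SNP failures:\n"); print(utils::head(fails, 10), row.names = FALSE)
  }
  sfails <- x$sample_decisions[!x$sample_decisions$pass, c("sample_id", "reasons")]
  if (nrow(sfails))
    cat(sprintf("sample failures: %d (%s...)\n", nrow(sfails),
                paste(utils::head(sfails$sample_id, 3), collapse = ", ")))
  invisible(x)
}
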