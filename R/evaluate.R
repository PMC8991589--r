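#' Odds ratio per control interquartile-range increase (IQ-OR)
#'
#' The primary predictive-ability metric for a PRS in a case-control study:
#' scores are divided by the interquartile range of the control
#' distribution, status is regressed on the rescaled score by logistic
#' regression, and the IQ-OR is the exponentiated slope with a Wald 95% CI.
#' Invariant to increasing affine transforms of the score.
#'
#' @param scores numeric PRS vector.
#' @param status `"case"`/`"control"` vector (or 0/1).
#' @return list with `or`, `ci` (length 2), `iqr`, `log_or`, `se`.
#' @export
iq_or <- function(scores, status) {
  y <- as_status01(status)
  if (length(unique(y)) < 2) stop("both classes required")
  iqr <- stats::IQR(scores[y == 0], type = 7)
  if (iqr <= 0) stop("zero control IQR")
  x <- scores / iqr
  fit <- stats::glm(y ~ x, family = stats::binomial())
  b <- stats::coef(fit)[["x"]]
  se <- summary(fit)$coefficients["x", "Std. Error"]
  list(or = exp(b), ci = exp(b + c(-1, 1) * 1.96 * se), iqr = iqr,
       log_or = b, se = se)
}

as_status01 <- function(status) {
  if (is.numeric(status)) return(as.numeric(status != 0))
  as.numeric(status == "case")
}

#' Extreme-quartile odds ratio (Q4 vs Q1)
#'
#' Cut points are the quartiles of the control score distribution; the OR
#' contrasts the top against the bottom quartile via the 2x2 cross-product,
#' with a Woolf log-scale 95% CI. If any cell is zero the Haldane-Anscombe
#' +0.5 correction is applied and flagged.
#'
#' @param scores numeric PRS vector.
#' @param status case/control vector.
#' @return list with `or`, `ci`, `table` (2x2 counts), `haldane` flag.
#' @export
quartile_or <- function(scores, status) {
  y <- as_status01(status)
  cuts <- stats::quantile(scores[y == 0], c(0.25, 0.5, 0.75), type = 7)
  if (anyDuplicated(cuts)) stop("control quartile cut points not distinct")
  q <- cut(scores, c(-Inf, cuts, Inf), labels = FALSE)
  a <- sum(y == 1 & q == 4); b <- sum(y == 0 & q == 4)
  c_ <- sum(y == 1 & q == 1); d <- sum(y == 0 & q == 1)
  if ((a + b) == 0 || (c_ + d) == 0) stop("an extreme quartile is empty")
  haldane <- any(c(a, b, c_, d) == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  or <- (a * d) / (c_ * b)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = or, ci = exp(log(or) + c(-1, 1) * 1.96 * se),
       table = matrix(c(a, b, c_, d), 2, 2,
                      dimnames = list(c("case", "control"), c("Q4", "Q1"))),
       haldane = haldane)
}

#' AUC with the Hanley-McNeil confidence interval
#'
#' AUC as the Mann-Whitney statistic (ties count 1/2) over all
#' case-control pairs; the standard error follows Hanley and McNeil's
#' closed form with `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`, and the normal 95%
#' CI is truncated to \[0, 1\].
#'
#' @param scores numeric PRS vector.
#' @param status case/control vector.
#' @return list with `auc`, `ci`, `se`, `n_case`, `n_control`.
#' @export
auc_ci <- function(scores, status) {
  y <- as_status01(status)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores, ties.method = "average")
  a <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n1 * n0))
  list(auc = a, ci = clamp(a + c(-1, 1) * 1.96 * se, 0, 1), se = se,
       n_case = n1, n_control = n0)
}

#' Through-origin observed-on-expected log-OR slope
#'
#' The calibration coefficient: least-squares slope of observed on expected
#' log odds ratios with no intercept, `sum(x*y) / sum(x^2)`, with the
#' through-origin regression standard error.
#'
#' @param expected,observed per-bin log odds ratios.
#' @return list with `slope`, `se`, `ci` (normal 95%).
#' @export
oe_slope <- function(expected, observed) {
  stopifnot(length(expected) == length(observed), length(expected) >= 2)
  slope <- sum(expected * observed) / sum(expected^2)
  resid <- observed - slope * expected
  se <- sqrt(sum(resid^2) / ((length(expected) - 1) * sum(expected^2)))
  list(slope = slope, se = se, ci = slope + c(-1, 1) * 1.96 * se)
}

#' Decile calibration and the observed/expected OR slope
#'
#' Bins samples by the deciles of the control score distribution (the score
#' is assumed to live on the log-OR scale, as PRSs built from log-OR
#' weights do). With the pooled middle bins (5th-6th) as reference, the
#' expected log-OR of bin d is the difference in mean score between bin d
#' and the reference, and the observed log-OR comes from the bin-vs-
#' reference 2x2 table (Haldane +0.5 on zero cells, flagged). The O/E OR
#' slope is the through-origin least-squares regression of observed on
#' expected log-ORs over non-reference bins; 1 indicates perfect
#' calibration of relative risks. Its 95% CI uses the through-origin
#' regression standard error.
#'
#' @param scores numeric PRS vector (log-OR scale).
#' @param status case/control vector.
#' @param n_bins number of bins (default 10).
#' @param reference `"middle"` (pooled central bins, default) or `"first"`.
#' @return list with `slope`, `ci`, `se`, `table` (per-bin expected and
#'   observed log-ORs and counts), `reference_bins`.
#' @export
prs_calibration <- function(scores, status, n_bins = 10,
                            reference = c("middle", "first")) {
  reference <- match.arg(reference)
  stopifnot(n_bins >= 2)
  y <- as_status01(status)
  cuts <- stats::quantile(scores[y == 0], seq_len(n_bins - 1) / n_bins, type = 7)
  if (anyDuplicated(cuts))
    stop("control decile cut points not distinct (score too discrete)")
  bin <- cut(scores, c(-Inf, cuts, Inf), labels = FALSE)
  counts <- table(factor(bin, levels = seq_len(n_bins)))
  if (any(counts == 0))
    stop("empty calibration bin(s): ",
         paste(which(counts == 0), collapse = ", "))
  ref_bins <- if (reference == "middle") {
    if (n_bins %% 2 == 0) c(n_bins / 2, n_bins / 2 + 1) else (n_bins + 1) / 2
  } else 1L
  in_ref <- bin %in% ref_bins
  mean_ref <- mean(scores[in_ref])
  case_ref <- sum(y == 1 & in_ref); ctrl_ref <- sum(y == 0 & in_ref)

  rows <- lapply(setdiff(seq_len(n_bins), ref_bins), function(d) {
    sel <- bin == d
    a <- sum(y == 1 & sel); b <- sum(y == 0 & sel)
    haldane <- any(c(a, b, case_ref, ctrl_ref) == 0)
    aa <- a + 0.5 * haldane; bb <- b + 0.5 * haldane
    cr <- case_ref + 0.5 * haldane; br <- ctrl_ref + 0.5 * haldane
    data.frame(bin = d, n_case = a, n_control = b,
               expected_log_or = mean(scores[sel]) - mean_ref,
               observed_log_or = log((aa * br) / (bb * cr)),
               haldane = haldane, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  x <- tab$expected_log_or; yy <- tab$observed_log_or
  slope <- sum(x * yy) / sum(x^2)
  resid <- yy - slope * x
  se <- sqrt(sum(resid^2) / ((length(x) - 1) * sum(x^2)))
  list(slope = slope, ci = slope + c(-1, 1) * 1.96 * se, se = se,
       table = tab, reference_bins = ref_bins)
}

#' Residual-adjust a PRS for non-genetic risk factors
#'
#' Regresses the PRS (as the dependent variable) on non-genetic factors by
#' ordinary least squares and returns the residuals, so downstream metrics
#' measure the risk information the PRS adds beyond those factors.
#' `mode = "gail"` adjusts for the externally computed 5-year absolute risk
#' column alone; `mode = "classical"` adjusts for age, age at menarche,
#' number of live births, family history, BMI and menopausal status
#' (categorical factors as indicator contrasts).
#'
#' @param scores numeric PRS vector.
#' @param covariate_table sample table aligned with `scores`.
#' @param mode `"gail"` or `"classical"`.
#' @return numeric vector of residuals (same order as `scores`).
#' @export
residual_adjust <- function(scores, covariate_table, mode = c("classical", "gail")) {
  mode <- match.arg(mode)
  need <- if (mode == "gail") "external_5yr_risk" else
    c("age", "age_menarche", "live_births", "family_history", "bmi", "menopausal")
  miss <- setdiff(need, names(covariate_table))
  if (length(miss)) stop("missing covariate columns: ", paste(miss, collapse = ", "))
  df <- covariate_table[, need, drop = FALSE]
  bad <- !stats::complete.cases(df)
  if (any(bad))
    stop("missing covariate values for samples: ",
         paste(utils::head(covariate_table$sample_id[bad], 5), collapse = ", "))
  df$.score <- scores
  fit <- stats::lm(.score ~ ., data = df)
  unname(stats::resid(fit))
}

#' Pairwise SNP-SNP interaction scan
#'
#' For every unordered SNP pair, fits a logistic regression of case status
#' on both dosages and their product and Wald-tests the product term.
#' Reports nominally significant pairs (P < `alpha`) and pairs passing the
#' Bonferroni-corrected threshold `alpha / choose(n_snps, 2)`. On
#' separation the P-value falls back to the likelihood-ratio test, flagged.
#'
#' @param g QC-passed, imputed `genotype_matrix`.
#' @param samples sample table with `status`.
#' @param alpha nominal significance level (default 0.05).
#' @return an `interaction_scan` object: `pairs` (snp_i, snp_j, delta, p,
#'   flagged), `bonferroni_alpha`, `n_nominal`, `n_significant`.
#' @export
interaction_scan <- function(g, samples, alpha = 0.05) {
  stopifnot_genotype(g)
  if (ncol(g) < 2) stop("need at least 2 SNPs")
  samples <- align_table(g, samples)
  y <- as.numeric(samples$status == "case")
  ids <- colnames(g); m <- unclass(g)
  combs <- utils::combn(length(ids), 2)
  res <- lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    xi <- m[, i]; xj <- m[, j]; xij <- xi * xj
    fit <- suppressWarnings(stats::glm(y ~ xi + xj + xij,
                                       family = stats::binomial()))
    cf <- summary(fit)$coefficients
    flagged <- !fit$converged || !"xij" %in% rownames(cf) ||
      abs(cf["xij", "Estimate"]) > 15
    if (flagged) {
      fit0 <- suppressWarnings(stats::glm(y ~ xi + xj, family = stats::binomial()))
      p <- stats::pchisq(fit0$deviance - fit$deviance, 1, lower.tail = FALSE)
      delta <- if ("xij" %in% rownames(cf)) cf["xij", "Estimate"] else NA_real_
    } else {
      p <- cf["xij", "Pr(>|z|)"]; delta <- cf["xij", "Estimate"]
    }
    data.frame(snp_i = ids[i], snp_j = ids[j], delta = delta, p = p,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, res)
  bonf <- alpha / choose(ncol(g), 2)
  structure(list(pairs = pairs, alpha = alpha, bonferroni_alpha = bonf,
                 n_nominal = sum(pairs$p < alpha, na.rm = TRUE),
                 n_significant = sum(pairs$p < bonf, na.rm = TRUE)),
            class = "interaction_scan")
}

#' @export
print.interaction_scan <- function(x, ...) {
  cat(sprintf("interaction scan: %d pairs; Bonferroni alpha = %.3g\n",
              nrow(x$pairs), x$bonferroni_alpha))
  cat(sprintf("  nominal (P < %.2g): %d; Bonferroni-significant: %d\n",
              x$alpha, x$n_nominal, x$n_significant))
  invisible(x)
}

#' Full evaluation report for a PRS
#'
#' Computes, for each requested adjustment (`none`, `gail`, `classical`),
#' the complete metric set: IQ-OR, extreme-quartile OR, AUC with
#' Hanley-McNeil CI, and the decile O/E-OR calibration slope, each with 95%
#' CIs. Adjusted rows evaluate the OLS residual of the PRS on the
#' corresponding covariates (see [residual_adjust()]).
#'
#' @param scores numeric PRS vector.
#' @param status case/control vector aligned with `scores`.
#' @param covariate_table sample table (required for adjusted rows).
#' @param adjustments subset of `c("none", "gail", "classical")`.
#' @param case_set label recorded in the report.
#' @param method label recorded in the report.
#' @return a `prs_evaluation` data.frame, one row per adjustment, with
#'   point estimates and CI bounds for every metric.
#' @export
evaluate_prs <- function(scores, status, covariate_table = NULL,
                         adjustments = "none", case_set = "overall",
                         method = "prs") {
  rows <- lapply(adjustments, function(adj) {
    s <- if (adj == "none") scores else
      residual_adjust(scores, covariate_table, mode = adj)
    iq <- iq_or(s, status)
    q <- quartile_or(s, status)
    a <- auc_ci(s, status)
    cal <- prs_calibration(s, status)
    data.frame(method = method, case_set = case_set, adjustment = adj,
               n_case = a$n_case, n_control = a$n_control,
               q4_q1_or = q$or, q4_q1_lo = q$ci[1], q4_q1_hi = q$ci[2],
               iq_or = iq$or, iq_or_lo = iq$ci[1], iq_or_hi = iq$ci[2],
               oe_or = cal$slope, oe_or_lo = cal$ci[1], oe_or_hi = cal$ci[2],
               auc = a$auc, auc_lo = a$ci[1], auc_hi = a$ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("prs_evaluation", "data.frame")
  out
}

#' @export
print.prs_evaluation <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  fmt <- function(est, lo, hi)
    sprintf("%.*f (%.*f-%.*f)", digits, est, digits, lo, digits, hi)
  out <- data.frame(method = df$method, case_set = df$case_set,
                    adjustment = df$adjustment,
                    `Q4 vs Q1 OR` = fmt(df$q4_q1_or, df$q4_q1_lo, df$q4_q1_hi),
                    `IQ-OR` = fmt(df$iq_or, df$iq_or_lo, df$iq_or_hi),
                    `O/E OR` = fmt(df$oe_or, df$oe_or_lo, df$oe_or_hi),
                    AUC = fmt(df$auc, df$auc_lo, df$auc_hi),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}
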