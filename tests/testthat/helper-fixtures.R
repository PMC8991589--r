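# shared fixture builders and independent oracles

# small LD-free panel for fast unit tests
tiny_panel <- function(n_snps = 6, maf = 0.3, log_or = 0) {
  data.frame(snp_id = sprintf("t%02d", seq_len(n_snps)),
             maf = rep_len(maf, n_snps), log_or = rep_len(log_or, n_snps),
             ld_block = NA_character_, target_r2 = NA_real_,
             stringsAsFactors = FALSE)
}

quick_cohort <- function(n_cases, n_controls, panel = tiny_panel(), seed = 1, ...) {
  simulate_cohort(sim_config(n_cases, n_controls, panel, seed = seed, ...))
}

# independent HWE oracle: direct factorial enumeration of every attainable
# heterozygote count (no logs, no recurrence); valid for totals <= 85
hwe_oracle <- function(n_ref, n_het, n_eff) {
  n <- n_ref + n_het + n_eff
  n_rare <- min(2 * n_ref + n_het, 2 * n_eff + n_het)
  if (n_rare == 0) return(1)
  n_common <- 2 * n - n_rare
  hs <- seq(n_rare %% 2, n_rare, by = 2)
  pr <- vapply(hs, function(h) {
    2^h * factorial(n) /
      (factorial((n_rare - h) / 2) * factorial(h) * factorial((n_common - h) / 2)) *
      factorial(n_rare) * factorial(n_common) / factorial(2 * n)
  }, 0)
  p_obs <- pr[match(n_het, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

# dosage matrix stripped of allele metadata, for format round trips that
# cannot carry every attribute
bare_dosages <- function(g) {
  m <- unclass(g)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# exhaustive pairwise-comparison AUC (ties count 1/2)
auc_oracle <- function(scores, status) {
  y <- if (is.numeric(status)) status != 0 else status == "case"
  ca <- scores[y]; co <- scores[!y]
  tot <- 0
  for (a in ca) tot <- tot + sum(a > co) + 0.5 * sum(a == co)
  tot / (length(ca) * length(co))
}

# independent logistic slope by plain Newton iterations on (intercept, slope)
logistic_slope_oracle <- function(x, y, iters = 50) {
  b <- c(0, 0)
  X <- cbind(1, x)
  for (i in seq_len(iters)) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    w <- p * (1 - p)
    b <- b + solve(t(X) %*% (X * w), t(X) %*% (y - p))
  }
  b[2]
}
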