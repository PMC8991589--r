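#' Describe one simulated SNP
#'
#' @param snp_id SNP identifier.
#' @param maf effect (minor) allele frequency in (0, 0.5].
#' @param log_or per-effect-allele log odds ratio contributed to the disease
#'   liability (0 for a null SNP).
#' @param ld_block optional block label; SNPs sharing a label are simulated
#'   with correlated dosages.
#' @param target_r2 target pairwise composite r2 within the block, in \[0, 1\].
#' @return one-row data.frame; rbind rows to build a panel.
#' @export
snp_spec <- function(snp_id, maf, log_or = 0, ld_block = NA, target_r2 = NA) {
  stopifnot(maf > 0, maf <= 0.5)
  if (!is.na(target_r2)) stopifnot(target_r2 >= 0, target_r2 <= 1)
  data.frame(snp_id = as.character(snp_id), maf = maf, log_or = log_or,
             ld_block = as.character(ld_block), target_r2 = target_r2,
             stringsAsFactors = FALSE)
}

#' A fixed 24-SNP synthetic demonstration panel
#'
#' Effect sizes and frequencies mimic a literature-curated breast-cancer
#' susceptibility panel: per-allele odds ratios between about 1.05 and 1.30
#' in either direction, MAFs spread over 0.08-0.50, and two loose LD blocks
#' (r2 0.5 and 0.3). Identifiers are synthetic (`snp01`..`snp24`); the panel
#' carries no real rs numbers.
#'
#' @param null_effects if `TRUE`, zero out every log-OR (null panel).
#' @return data.frame of [snp_spec()] rows.
#' @export
demo_snp_panel <- function(null_effects = FALSE) {
  maf <- c(0.38, 0.35, 0.12, 0.26, 0.47, 0.30, 0.22, 0.41, 0.16, 0.49,
           0.28, 0.09, 0.33, 0.44, 0.19, 0.36, 0.25, 0.13, 0.40, 0.31,
           0.21, 0.46, 0.17, 0.29)
  log_or <- c(0.18, 0.11, -0.14, 0.22, 0.08, 0.16, -0.10, 0.13, 0.20, 0.06,
              -0.12, 0.26, 0.09, 0.15, -0.08, 0.19, 0.10, 0.24, 0.07, -0.11,
              0.14, 0.05, 0.21, 0.12)
  if (null_effects) log_or <- rep(0, 24)
  blk <- rep(NA_character_, 24); r2 <- rep(NA_real_, 24)
  blk[c(1, 2)] <- "b1"; r2[c(1, 2)] <- 0.5
  blk[c(13, 16)] <- "b2"; r2[c(13, 16)] <- 0.3
  maf[2] <- maf[1]; maf[16] <- maf[13]  # equal MAFs within a block hit r2 exactly
  data.frame(snp_id = sprintf("snp%02d", 1:24), maf = maf, log_or = log_or,
             ld_block = blk, target_r2 = r2, stringsAsFactors = FALSE)
}

#' A fixed epistasis study design for method comparisons
#'
#' The synthetic analogue of a loosely pruned susceptibility panel in which
#' non-additive structure favours joint and non-linear weighting over
#' per-SNP marginal weights: three 3-SNP LD blocks at composite r2 0.78
#' (just under the conventional 0.8 tight-LD exclusion bound) carry a large
#' share of the additive signal, so univariate weights double-count them,
#' and one common-allele SNP pair (MAF 0.45) carries a pure pairwise
#' interaction of strength `delta` with no marginal effects.
#'
#' @param delta interaction log-OR per dosage product (default 0.7, a
#'   strong epistatic effect).
#' @return `list(snps, interactions)` ready for [sim_config()].
#' @export
demo_epistasis_design <- function(delta = 0.7) {
  panel <- demo_snp_panel()
  for (b in 1:3) {
    idx <- (b - 1) * 3 + 1:3
    panel$ld_block[idx] <- paste0("blk", b)
    panel$target_r2[idx] <- 0.78
    panel$maf[idx] <- c(0.35, 0.3, 0.4)[b]
  }
  panel$ld_block[c(13, 16)] <- NA
  panel$target_r2[c(13, 16)] <- NA
  panel$log_or[1:9] <- rep(c(0.17, 0.12, 0.15), 3)
  panel$maf[c(10, 21)] <- 0.45
  panel$log_or[c(10, 21)] <- 0
  list(snps = panel,
       interactions = data.frame(snp_i = "snp10", snp_j = "snp21",
                                 delta = delta, stringsAsFactors = FALSE))
}

#' Configure a synthetic case-control cohort
#'
#' Defines the generating model for [simulate_cohort()]: genotypes in
#' Hardy-Weinberg proportions (with optional block LD), disease status from
#' an additive logistic liability with optional covariate effects and
#' pairwise SNP-SNP interactions, estrogen-receptor subtype labels for
#' cases, and optional sporadic missingness, duplicates and relatives.
#'
#' @param n_cases,n_controls target sample counts (sampling continues until
#'   both quotas are filled exactly).
#' @param snps data.frame of [snp_spec()] rows.
#' @param covariate_effects named numeric vector of per-unit log-ORs for any
#'   of `age`, `bmi`, `age_menarche`, `live_births`, `family_history`,
#'   `menopausal` (post = 1), `external_5yr_risk`.
#' @param interactions data.frame with columns `snp_i`, `snp_j`, `delta`
#'   (log-OR per dosage product), or `NULL`.
#' @param er_pos_fraction expected fraction of cases that are ER-positive.
#' @param subtype_effects optional `list(er_pos = , er_neg = )` of named
#'   per-SNP log-OR overrides; when supplied, ER+ and ER- cases arise from
#'   two distinct liabilities instead of label thinning.
#' @param missing_rate sporadic missing-call probability applied after
#'   simulation (see [inject_missingness()]).
#' @param n_duplicate_pairs,n_related_pairs pairs appended after simulation
#'   (see [add_related_samples()]); relatives use `related_degree`.
#' @param related_degree `"parent_offspring"` or `"second_degree"`.
#' @param subpop2_fraction,subpop_maf_shift two-subpopulation mode for
#'   population-structure tests: a fraction of samples draws genotypes at
#'   MAFs shifted by `subpop_maf_shift` (clamped to (0.01, 0.99)).
#' @param genetic_covariate_corr correlation induced between age and the
#'   true genetic score (default 0: covariates independent of genotypes).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_cases, n_controls, snps,
                       covariate_effects = c(age = 0.02),
                       interactions = NULL,
                       er_pos_fraction = 0.7,
                       subtype_effects = NULL,
                       missing_rate = 0,
                       n_duplicate_pairs = 0,
                       n_related_pairs = 0,
                       related_degree = "parent_offspring",
                       subpop2_fraction = 0,
                       subpop_maf_shift = 0,
                       genetic_covariate_corr = 0,
                       seed = 1L) {
  stopifnot(n_cases >= 0, n_controls >= 0, n_cases + n_controls > 0)
  if (!is.data.frame(snps) || nrow(snps) == 0)
    stop("config must contain at least one SNP")
  stopifnot(all(snps$maf > 0), all(snps$maf <= 0.5))
  stopifnot(er_pos_fraction > 0, er_pos_fraction <= 1)
  stopifnot(missing_rate >= 0, missing_rate < 1)
  stopifnot(subpop2_fraction >= 0, subpop2_fraction <= 1)
  if (!is.null(interactions)) {
    stopifnot(all(c("snp_i", "snp_j", "delta") %in% names(interactions)))
    miss <- setdiff(c(interactions$snp_i, interactions$snp_j), snps$snp_id)
    if (length(miss)) stop("interaction SNPs not in panel: ",
                           paste(miss, collapse = ", "))
  }
  if (!is.null(subtype_effects))
    stopifnot(is.list(subtype_effects),
              all(names(subtype_effects) %in% c("er_pos", "er_neg")))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), snps = snps,
                 covariate_effects = covariate_effects,
                 interactions = interactions,
                 er_pos_fraction = er_pos_fraction,
                 subtype_effects = subtype_effects,
                 missing_rate = missing_rate,
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 n_related_pairs = as.integer(n_related_pairs),
                 related_degree = related_degree,
                 subpop2_fraction = subpop2_fraction,
                 subpop_maf_shift = subpop_maf_shift,
                 genetic_covariate_corr = genetic_covariate_corr,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# --- genotype drawing ------------------------------------------------------

# one haplotype allele matrix for a block: shared latent Bernoulli copied
# with weight w_k, else a fresh Bernoulli at q_k chosen to preserve MAF.
# For equal block MAFs the realized allele (and dosage) correlation equals
# sqrt(target_r2) exactly; unequal MAFs are capped at the attainable bound.
draw_block_haplotype <- function(n, maf, r2) {
  k <- length(maf)
  if (k == 1 || is.na(r2) || r2 <= 0) {
    return(vapply(maf, function(p) stats::rbinom(n, 1, p), numeric(n)))
  }
  r <- sqrt(r2)
  p <- min(maf)
  v <- maf * (1 - maf)
  w <- sqrt(r) * sqrt(v / (p * (1 - p)))
  w <- pmin(w, 0.999, maf / p, (1 - maf) / (1 - p))
  q <- clamp((maf - w * p) / (1 - w), 0, 1)
  z <- stats::rbinom(n, 1, p)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    copy <- stats::runif(n) < w[j]
    out[, j] <- ifelse(copy, z, stats::rbinom(n, 1, q[j]))
  }
  out
}

draw_genotypes <- function(n, snps, maf_shift = 0) {
  m <- nrow(snps)
  maf <- clamp(snps$maf + maf_shift, 0.01, 0.99)
  dos <- matrix(0, n, m, dimnames = list(NULL, snps$snp_id))
  blocks <- ifelse(is.na(snps$ld_block), paste0(".solo", seq_len(m)),
                   snps$ld_block)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    r2 <- suppressWarnings(max(snps$target_r2[idx], na.rm = TRUE))
    if (!is.finite(r2)) r2 <- NA
    h1 <- draw_block_haplotype(n, maf[idx], r2)
    h2 <- draw_block_haplotype(n, maf[idx], r2)
    dos[, idx] <- h1 + h2
  }
  dos
}

# --- covariates ------------------------------------------------------------

# conventions for an urban Chinese female study population; see the methods
# vignette for the rationale behind each default
draw_covariates <- function(n) {
  age <- stats::runif(n, 35, 70)
  data.frame(
    age = age,
    bmi = clamp(stats::rnorm(n, 23.5, 3), 15, 40),
    age_menarche = clamp(round(stats::rnorm(n, 14, 1.5)), 10, 18),
    live_births = stats::rbinom(n, 4, 0.3),
    family_history = ifelse(stats::runif(n) < 0.02, "yes", "no"),
    menopausal = ifelse(stats::runif(n) < stats::plogis((age - 49) / 2),
                        "post", "pre"),
    external_5yr_risk = stats::plogis(stats::rnorm(n, stats::qlogis(0.0054), 0.35)),
    stringsAsFactors = FALSE)
}

covariate_design <- function(cov) {
  cbind(age = cov$age, bmi = cov$bmi, age_menarche = cov$age_menarche,
        live_births = cov$live_births,
        family_history = as.numeric(cov$family_history == "yes"),
        menopausal = as.numeric(cov$menopausal == "post"),
        external_5yr_risk = cov$external_5yr_risk)
}

linear_predictor <- function(dos, cov, snps, covariate_effects, interactions,
                             log_or = snps$log_or) {
  eta <- drop(dos %*% log_or)
  if (length(covariate_effects)) {
    X <- covariate_design(cov)
    bad <- setdiff(names(covariate_effects), colnames(X))
    if (length(bad)) stop("unknown covariate effects: ", paste(bad, collapse = ", "))
    eta <- eta + drop(X[, names(covariate_effects), drop = FALSE] %*%
                        covariate_effects)
  }
  if (!is.null(interactions) && nrow(interactions)) {
    for (r in seq_len(nrow(interactions)))
      eta <- eta + interactions$delta[r] *
        dos[, interactions$snp_i[r]] * dos[, interactions$snp_j[r]]
  }
  eta
}

# bisection for the liability intercept so that E[plogis(alpha + eta)]
# matches the target prevalence to within tol
calibrate_alpha <- function(eta, target, tol = 1e-4) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("unreachable case fraction: intercept bounds exhausted")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol) return(mid)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# --- main entry ------------------------------------------------------------

#' Simulate a case-control cohort
#'
#' Draws genotypes in Hardy-Weinberg proportions (with block LD at the
#' configured composite r2), covariates, and disease status from the
#' additive logistic liability
#' `logit P(case) = alpha + sum_k beta_k x_k + covariate terms +
#' sum delta x_i x_j`, with `alpha` calibrated by bisection so the expected
#' case fraction matches `n_cases / (n_cases + n_controls)`. Individuals are
#' drawn until both quotas are filled exactly. ER subtype is assigned to
#' cases by label thinning at `er_pos_fraction`, or from two distinct
#' subtype liabilities when `subtype_effects` overrides are configured.
#' Missingness, duplicate and related samples are then applied per the
#' config. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return `list(genotypes = genotype_matrix, samples = data.frame)`; the
#'   sample table carries status, ER status, covariates, the true liability
#'   (`true_eta`, genetic + interaction part only, for calibration studies)
#'   and placeholder `pc1`/`pc2` columns.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    snps <- config$snps
    n_target <- config$n_cases + config$n_controls
    prev <- config$n_cases / n_target

    sub_frac <- config$subpop2_fraction
    shift <- config$subpop_maf_shift
    draw_batch_geno <- function(n) {
      if (sub_frac > 0 && shift != 0) {
        pop <- 1L + stats::rbinom(n, 1, sub_frac)
        d <- matrix(0, n, nrow(snps), dimnames = list(NULL, snps$snp_id))
        if (any(pop == 1L)) d[pop == 1L, ] <- draw_genotypes(sum(pop == 1L), snps, 0)
        if (any(pop == 2L)) d[pop == 2L, ] <- draw_genotypes(sum(pop == 2L), snps, shift)
        list(dos = d, pop = pop)
      } else {
        list(dos = draw_genotypes(n, snps, 0), pop = rep(1L, n))
      }
    }

    subtype <- config$subtype_effects
    lor_for <- function(overrides) {
      lo <- snps$log_or
      if (!is.null(overrides)) {
        idx <- match(names(overrides), snps$snp_id)
        if (anyNA(idx)) stop("subtype override names SNPs not in panel")
        lo[idx] <- overrides
      }
      lo
    }

    # calibration batch: estimate the liability intercept(s)
    ncal <- max(20000L, 2L * n_target)
    cal <- draw_batch_geno(ncal)
    cal_cov <- draw_covariates(ncal)
    if (config$genetic_covariate_corr > 0) {
      cc <- config$genetic_covariate_corr
      zg <- drop(scale(drop(cal$dos %*% snps$log_or)))
      cal_cov$age <- 52.5 +
        10.1 * (sqrt(1 - cc^2) * drop(scale(cal_cov$age)) + cc * zg)
    }
    if (is.null(subtype)) {
      eta_cal <- linear_predictor(cal$dos, cal_cov, snps,
                                  config$covariate_effects, config$interactions)
      alpha <- calibrate_alpha(eta_cal, prev)
    } else {
      eta_pos <- linear_predictor(cal$dos, cal_cov, snps,
                                  config$covariate_effects, config$interactions,
                                  log_or = lor_for(subtype$er_pos))
      eta_neg <- linear_predictor(cal$dos, cal_cov, snps,
                                  config$covariate_effects, config$interactions,
                                  log_or = lor_for(subtype$er_neg))
      alpha_pos <- calibrate_alpha(eta_pos, prev * config$er_pos_fraction)
      alpha_neg <- calibrate_alpha(eta_neg, prev * (1 - config$er_pos_fraction))
    }

    acc_dos <- list(); acc_tab <- list()
    got_cases <- 0L; got_controls <- 0L; batches <- 0L
    while (got_cases < config$n_cases || got_controls < config$n_controls) {
      batches <- batches + 1L
      if (batches > 500L)
        stop("unreachable case fraction: sampling quota not met after 500 batches")
      nb <- max(1000L, n_target)
      b <- draw_batch_geno(nb)
      cov <- draw_covariates(nb)
      if (config$genetic_covariate_corr > 0) {
        cc <- config$genetic_covariate_corr
        zg <- drop(scale(drop(b$dos %*% snps$log_or)))
        cov$age <- 52.5 +
          10.1 * (sqrt(1 - cc^2) * drop(scale(cov$age)) + cc * zg)
      }
      if (is.null(subtype)) {
        eta <- linear_predictor(b$dos, cov, snps, config$covariate_effects,
                                config$interactions)
        p <- stats::plogis(alpha + eta)
        is_case <- stats::runif(nb) < p
        er <- ifelse(is_case,
                     ifelse(stats::runif(nb) < config$er_pos_fraction,
                            "positive", "negative"),
                     "unknown")
      } else {
        ep <- linear_predictor(b$dos, cov, snps, config$covariate_effects,
                               config$interactions, log_or = lor_for(subtype$er_pos))
        en <- linear_predictor(b$dos, cov, snps, config$covariate_effects,
                               config$interactions, log_or = lor_for(subtype$er_neg))
        p_pos <- stats::plogis(alpha_pos + ep)
        p_neg <- stats::plogis(alpha_neg + en)
        tot <- p_pos + p_neg
        over <- tot > 0.99
        if (any(over)) {  # guard: competing liabilities must leave control mass
          p_pos[over] <- p_pos[over] * 0.99 / tot[over]
          p_neg[over] <- p_neg[over] * 0.99 / tot[over]
        }
        u <- stats::runif(nb)
        er <- ifelse(u < p_pos, "positive",
                     ifelse(u < p_pos + p_neg, "negative", "unknown"))
        is_case <- er != "unknown"
        eta <- drop(b$dos %*% snps$log_or)
      }
      gen_eta <- linear_predictor(b$dos, cov, snps, numeric(0),
                                  config$interactions)
      need_case <- config$n_cases - got_cases
      need_ctrl <- config$n_controls - got_controls
      take_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
      take_ctrl <- which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))]
      take <- sort(c(take_case, take_ctrl))
      if (!length(take)) next
      acc_dos[[batches]] <- b$dos[take, , drop = FALSE]
      acc_tab[[batches]] <- data.frame(
        status = ifelse(is_case[take], "case", "control"),
        er_status = er[take], cov[take, , drop = FALSE],
        population = b$pop[take], true_eta = gen_eta[take],
        stringsAsFactors = FALSE)
      got_cases <- got_cases + length(take_case)
      got_controls <- got_controls + length(take_ctrl)
    }

    dos <- do.call(rbind, acc_dos)
    tab <- do.call(rbind, acc_tab)
    ids <- sprintf("S%05d", seq_len(nrow(dos)))
    tab <- data.frame(sample_id = ids, tab, pc1 = NA_real_, pc2 = NA_real_,
                      row.names = NULL, stringsAsFactors = FALSE)
    bases <- c("A", "C", "G", "T")
    ea <- bases[(seq_len(nrow(snps)) - 1L) %% 4L + 1L]
    oa <- bases[seq_len(nrow(snps)) %% 4L + 1L]
    g <- genotype_matrix(dos, sample_ids = ids, snp_ids = snps$snp_id,
                         effect_alleles = ea, other_alleles = oa)

    if (config$n_duplicate_pairs > 0 || config$n_related_pairs > 0) {
      if (config$n_duplicate_pairs > 0) {
        r <- add_related_samples(g, tab, "duplicate", config$n_duplicate_pairs,
                                 seed = NULL)
        g <- r$genotypes; tab <- r$samples
      }
      if (config$n_related_pairs > 0) {
        r <- add_related_samples(g, tab, config$related_degree,
                                 config$n_related_pairs, seed = NULL)
        g <- r$genotypes; tab <- r$samples
      }
    }
    if (config$missing_rate > 0)
      g <- inject_missingness(g, config$missing_rate, seed = NULL)
    list(genotypes = g, samples = tab)
  })
}

#' Set dosages missing at random
#'
#' Each dosage is independently set missing with probability `rate`,
#' emulating sporadic genotyping failure.
#'
#' @param g a `genotype_matrix`.
#' @param rate missing probability in \[0, 1).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return the matrix with `NA`s injected.
#' @export
inject_missingness <- function(g, rate, seed = NULL) {
  stopifnot_genotype(g)
  if (rate >= 1 || rate < 0) stop("rate must be in [0, 1)")
  if (rate == 0) return(g)
  with_seed(seed, {
    m <- unclass(g)
    m[stats::runif(length(m)) < rate] <- NA
    genotype_matrix(m, effect_alleles = effect_alleles(g),
                    other_alleles = attr(g, "other_alleles"), fractional = TRUE)
  })
}

#' Append duplicate or related samples
#'
#' Appends pairs with a requested genetic relationship for kinship-filter
#' testing: `duplicate` copies dosages exactly; `parent_offspring` transmits
#' one allele per locus from the parent (the other drawn at the observed
#' allele frequency); `second_degree` transmits the parental allele along a
#' single ancestral path with probability 1/2. New samples copy the base
#' sample's phenotype row under a derived id.
#'
#' @param g a `genotype_matrix`.
#' @param samples the matching sample table.
#' @param relationship `"duplicate"`, `"parent_offspring"` or `"second_degree"`.
#' @param n_pairs number of pairs to append.
#' @param seed integer seed, or `NULL` for the current stream.
#' @return `list(genotypes, samples, pairs)`; `pairs` lists (base id, new id).
#' @export
add_related_samples <- function(g, samples, relationship, n_pairs, seed = NULL) {
  stopifnot_genotype(g)
  if (nrow(g) == 0) stop("base cohort is empty")
  if (!relationship %in% c("duplicate", "parent_offspring", "second_degree"))
    stop("unknown relationship: ", relationship)
  if (n_pairs == 0) return(list(genotypes = g, samples = samples, pairs = NULL))
  with_seed(seed, {
    base_idx <- sample(nrow(g), n_pairs, replace = n_pairs > nrow(g))
    p_hat <- observed_maf(g)
    m <- unclass(g)
    new <- matrix(NA_real_, n_pairs, ncol(g))
    for (i in seq_len(n_pairs)) {
      parent <- m[base_idx[i], ]
      if (relationship == "duplicate") {
        new[i, ] <- parent
      } else {
        transmitted <- stats::rbinom(ncol(g), 1, ifelse(is.na(parent), p_hat,
                                                        parent / 2))
        other <- stats::rbinom(ncol(g), 1, p_hat)
        if (relationship == "second_degree") {
          path <- stats::runif(ncol(g)) < 0.5
          pop <- stats::rbinom(ncol(g), 1, p_hat)
          transmitted <- ifelse(path, transmitted, pop)
        }
        new[i, ] <- transmitted + other
      }
    }
    suffix <- c(duplicate = "dup", parent_offspring = "off",
                second_degree = "rel")[[relationship]]
    new_ids <- sprintf("%s_%s%d", rownames(g)[base_idx], suffix,
                       seq_len(n_pairs))
    all_dos <- rbind(m, new)
    rownames(all_dos) <- c(rownames(g), new_ids)
    g2 <- genotype_matrix(all_dos, effect_alleles = effect_alleles(g),
                          other_alleles = attr(g, "other_alleles"),
                          fractional = TRUE)
    add <- samples[match(rownames(g)[base_idx], samples$sample_id), ,
                   drop = FALSE]
    add$sample_id <- new_ids
    samples2 <- rbind(samples, add)
    rownames(samples2) <- NULL
    list(genotypes = g2, samples = samples2,
         pairs = data.frame(base = rownames(g)[base_idx], added = new_ids,
                            relationship = relationship,
                            stringsAsFactors = FALSE))
  })
}
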