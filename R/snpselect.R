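#' Composite LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation of additive dosages over jointly non-missing
#' samples (composite LD; phase-free, so it differs from haplotype-based r2
#' reported by reference-panel tools).
#'
#' @param dos_i,dos_j dosage vectors of equal length.
#' @return r2 in \[0, 1\], or `NA` if fewer than 2 joint observations or
#'   either SNP is monomorphic on the joint subset (not evaluable).
#' @export
ld_r2 <- function(dos_i, dos_j) {
  dos_i <- as.vector(unclass(dos_i)); dos_j <- as.vector(unclass(dos_j))
  stopifnot(length(dos_i) == length(dos_j))
  ok <- !is.na(dos_i) & !is.na(dos_j)
  if (sum(ok) < 2) return(NA_real_)
  x <- dos_i[ok]; y <- dos_j[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' All-pairs composite LD matrix
#'
#' @param g a `genotype_matrix`.
#' @return symmetric matrix of pairwise [ld_r2()] values with unit diagonal
#'   (`ld_matrix` class).
#' @export
ld_matrix <- function(g) {
  stopifnot_genotype(g)
  m <- unclass(g)
  r2 <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))^2
  diag(r2) <- 1
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Write an LD matrix as a square TSV
#'
#' @param ld an [ld_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(snp_id = rownames(ld), unclass(ld), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Find a proxy SNP in tight LD with a target
#'
#' Returns the candidate with the largest r2 to the target among candidates
#' exceeding `r2_min` (the conventional proxy threshold is r2 > 0.9); ties
#' are broken by lexicographic SNP id.
#'
#' @param target target SNP id (absent from `candidates`).
#' @param candidates character vector of candidate ids.
#' @param ld an [ld_matrix()] covering target and candidates.
#' @param r2_min minimum r2 (strict inequality).
#' @return the proxy id, or `NULL` if no candidate qualifies.
#' @export
find_proxy <- function(target, candidates, ld, r2_min = 0.9) {
  if (!target %in% rownames(ld)) stop("target absent from LD matrix: ", target)
  if (target %in% candidates) stop("target must not be among candidates")
  candidates <- intersect(candidates, rownames(ld))
  if (!length(candidates)) return(NULL)
  r2 <- ld[target, candidates]
  ok <- !is.na(r2) & r2 > r2_min
  if (!any(ok)) return(NULL)
  r2 <- r2[ok]
  best <- names(r2)[r2 == max(r2)]
  sort(best)[1]
}

#' Greedy tight-LD pruning
#'
#' Processes SNPs in input order and drops any SNP with r2 above `r2_max`
#' to an already-kept SNP; deterministic given the input order.
#'
#' @param snps character vector of SNP ids, in panel order.
#' @param ld an [ld_matrix()] covering `snps`.
#' @param r2_max pruning threshold (strict inequality; 0.8 for the loose
#'   panel convention, 0.3 for rigorous pruning).
#' @return data.frame of selection decisions (`snp_id`, `action`, `detail`);
#'   actions are `keep` or `drop_ld` with the partner SNP as detail.
#' @export
prune_tight_ld <- function(snps, ld, r2_max = 0.8) {
  stopifnot(all(snps %in% rownames(ld)))
  kept <- character(0)
  dec <- vector("list", length(snps))
  for (i in seq_along(snps)) {
    s <- snps[i]
    partner <- NA_character_
    if (length(kept)) {
      r2 <- ld[s, kept]
      hit <- which(!is.na(r2) & r2 > r2_max)
      if (length(hit)) partner <- kept[hit[which.max(r2[hit])]]
    }
    if (is.na(partner)) {
      kept <- c(kept, s)
      dec[[i]] <- data.frame(snp_id = s, action = "keep", detail = NA_character_,
                             stringsAsFactors = FALSE)
    } else {
      dec[[i]] <- data.frame(snp_id = s, action = "drop_ld", detail = partner,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, dec)
}

#' Genome-wide significance screen
#'
#' Per-SNP univariate logistic regression of case status on dosage; keeps
#' SNPs whose Wald P-value is strictly below `alpha_gw` (conventionally
#' 5e-8). On separation or non-convergence the P-value falls back to the
#' likelihood-ratio test and the decision is flagged.
#'
#' @param g QC-passed `genotype_matrix`.
#' @param samples sample table with `status`.
#' @param alpha_gw significance threshold (strict).
#' @return data.frame of decisions: `snp_id`, `action`
#'   (`keep`/`drop_not_significant`), `detail` (the P-value), `flagged`.
#' @export
significance_filter <- function(g, samples, alpha_gw = 5e-8) {
  stopifnot_genotype(g)
  samples <- align_table(g, samples)
  y <- as.numeric(samples$status == "case")
  res <- lapply(colnames(g), function(s) {
    x <- unclass(g)[, s]
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    beta <- stats::coef(fit)[["x"]]
    flagged <- !fit$converged || abs(beta) > 15
    p <- if (flagged) {
      stats::anova(fit, test = "LRT")$`Pr(>Chi)`[2]
    } else {
      summary(fit)$coefficients["x", "Pr(>|z|)"]
    }
    data.frame(snp_id = s,
               action = if (!is.na(p) && p < alpha_gw) "keep" else "drop_not_significant",
               detail = as.character(p), flagged = flagged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cross-dataset effect-direction concordance
#'
#' Keeps SNPs whose univariate log-OR estimates carry the same (nonzero)
#' sign in two datasets, regardless of significance; a zero estimate in
#' either dataset demonstrates no effect and the SNP is dropped with a flag.
#'
#' @param weights_a,weights_b `prs_model` objects (or anything with
#'   `snp_ids`/`betas` fields) fitted on the same panel.
#' @return data.frame of decisions: `snp_id`, `action`
#'   (`keep`/`drop_discordant`), `detail`, `flagged` (zero-effect boundary).
#' @export
direction_concordance <- function(weights_a, weights_b) {
  ids <- weights_a$snp_ids
  if (!identical(sort(ids), sort(weights_b$snp_ids)))
    stop("weight sets cover different SNP panels")
  ba <- stats::setNames(weights_a$betas, weights_a$snp_ids)[ids]
  bb <- stats::setNames(weights_b$betas, weights_b$snp_ids)[ids]
  zero <- ba == 0 | bb == 0
  same <- sign(ba) == sign(bb) & !zero
  data.frame(snp_id = ids,
             action = ifelse(same, "keep", "drop_discordant"),
             detail = sprintf("%.4g/%.4g", ba, bb),
             flagged = zero, row.names = NULL, stringsAsFactors = FALSE)
}
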