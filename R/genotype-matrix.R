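#' Construct a genotype dosage matrix
#'
#' The central genotype container: a numeric samples x SNPs matrix of
#' additive dosages coded 0/1/2 (copies of the effect allele) with `NA` for
#' missing calls. The effect allele is, by convention, the minor allele in
#' the reference (control) stratum of the cohort the panel was defined on;
#' downstream scoring checks allele labels and refuses silently mismatched
#' panels.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns; values
#'   must be in \{0, 1, 2, NA\} unless `fractional = TRUE` (post-imputation
#'   matrices carry fractional dosages in \[0, 2\]).
#' @param sample_ids character vector of unique sample identifiers.
#' @param snp_ids character vector of unique SNP identifiers.
#' @param effect_alleles character vector of per-SNP effect-allele labels
#'   (single bases); recycled `"A"` if omitted.
#' @param other_alleles character vector of per-SNP alternate-allele labels;
#'   recycled `"G"` if omitted.
#' @param fractional allow fractional dosages (imputed matrices).
#' @return an object of class `genotype_matrix` (a numeric matrix with
#'   allele metadata attributes).
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2),
#'                      sample_ids = c("s1", "s2"), snp_ids = c("rsA", "rsB"))
#' observed_maf(g)
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            snp_ids = colnames(dosages),
                            effect_alleles = NULL, other_alleles = NULL,
                            fractional = FALSE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%03d", seq_len(ncol(dosages)))
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != nrow(dosages))
    stop("sample_ids length does not match number of rows")
  if (length(snp_ids) != ncol(dosages))
    stop("snp_ids length does not match number of columns")
  if (anyDuplicated(sample_ids)) stop("duplicated sample_ids")
  if (anyDuplicated(snp_ids)) stop("duplicated snp_ids")
  obs <- dosages[!is.na(dosages)]
  if (length(obs)) {
    if (any(obs < 0 | obs > 2)) stop("dosages must lie in [0, 2]")
    if (!fractional && any(obs != round(obs)))
      stop("dosages must be integer 0/1/2 (use fractional = TRUE for imputed matrices)")
  }
  if (is.null(effect_alleles)) effect_alleles <- rep("A", ncol(dosages))
  if (is.null(other_alleles)) other_alleles <- rep("G", ncol(dosages))
  effect_alleles <- rep_len(as.character(effect_alleles), ncol(dosages))
  other_alleles <- rep_len(as.character(other_alleles), ncol(dosages))
  dimnames(dosages) <- list(sample_ids, snp_ids)
  structure(dosages,
            effect_alleles = stats::setNames(effect_alleles, snp_ids),
            other_alleles = stats::setNames(other_alleles, snp_ids),
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (isTRUE(drop)) return(unclass(x)[i, j, drop = TRUE])
  ea <- attr(x, "effect_alleles")
  oa <- attr(x, "other_alleles")
  y <- unclass(x)[i, j, drop = FALSE]
  if (!missing(j)) {
    ea <- ea[colnames(y)]
    oa <- oa[colnames(y)]
  }
  genotype_matrix(y, effect_alleles = ea, other_alleles = oa, fractional = TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs; %.2f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  k <- min(5L, ncol(x)); n <- min(5L, nrow(x))
  print(unclass(x)[seq_len(n), seq_len(k), drop = FALSE])
  if (ncol(x) > k || nrow(x) > n) cat("...\n")
  invisible(x)
}

#' Effect alleles of a genotype matrix
#' @param g a `genotype_matrix`.
#' @return named character vector of effect-allele labels per SNP.
#' @export
effect_alleles <- function(g) attr(g, "effect_alleles")

#' Observed effect-allele frequency per SNP
#'
#' Frequencies are computed on observed (non-missing) dosages only,
#' optionally restricted to a stratum of samples (e.g. controls, the
#' reference stratum used for MAF filters).
#'
#' @param g a `genotype_matrix`.
#' @param samples optional character or logical vector selecting the stratum.
#' @return named numeric vector of effect-allele frequencies.
#' @export
observed_maf <- function(g, samples = NULL) {
  m <- unclass(g)
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  colMeans(m, na.rm = TRUE) / 2
}

#' Per-entity call rates
#' @param g a `genotype_matrix`.
#' @param margin `"snp"` or `"sample"`.
#' @return named numeric vector of non-missing fractions.
#' @export
call_rate <- function(g, margin = c("snp", "sample")) {
  margin <- match.arg(margin)
  m <- unclass(g)
  if (margin == "snp") 1 - colMeans(is.na(m)) else 1 - rowMeans(is.na(m))
}

# genotype counts per SNP restricted to hard calls (0/1/2 exactly);
# fractional imputed dosages never count toward HWE tables
genotype_counts <- function(g, samples = NULL) {
  m <- unclass(g)
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  cbind(n_ref = colSums(m == 0, na.rm = TRUE),
        n_het = colSums(m == 1, na.rm = TRUE),
        n_eff = colSums(m == 2, na.rm = TRUE))
}

stopifnot_genotype <- function(g) {
  if (!inherits(g, "genotype_matrix")) stop("expected a genotype_matrix")
  invisible(g)
}

# align a sample table to a genotype matrix by sample_id, erroring on mismatch
align_table <- function(g, tab) {
  if (!all(rownames(g) %in% tab$sample_id))
    stop("sample table is missing ids present in the genotype matrix")
  tab[match(rownames(g), tab$sample_id), , drop = FALSE]
}
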