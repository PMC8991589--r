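#' Write and read genotypes in PLINK text formats and TSV
#'
#' Three text dialects are supported and round-trip bit-exactly:
#' * `.ped`/`.map`: one sample per line (`FID IID PAT MAT SEX PHENOTYPE`
#'   then two allele columns per SNP; missing = `0 0`), with a companion
#'   `.map` (chrom, snp id, cM, bp).
#' * additive `.raw`: header `FID IID PAT MAT SEX PHENOTYPE` then one
#'   `snp_EFFECTALLELE` dosage column per SNP; missing = `NA`.
#' * plain TSV: `sample_id` column then one dosage column per SNP
#'   (header `snp:EFFECT:OTHER`); missing = empty field.
#'
#' Dosages count the effect (minor) allele.
#'
#' @param g a `genotype_matrix`.
#' @param path output path (for `.ped`, the `.map` path is derived).
#' @param samples optional sample table supplying `status` for the
#'   PHENOTYPE column (1 = control, 2 = case, 0 = unknown).
#' @return `path`, invisibly.
#' @name genotype_io
NULL

#' @rdname genotype_io
#' @export
write_plink_ped <- function(g, path, samples = NULL) {
  stopifnot_genotype(g)
  m <- unclass(g)
  if (any(m != round(m), na.rm = TRUE))
    stop("ped format requires hard-call dosages (0/1/2)")
  ea <- effect_alleles(g); oa <- attr(g, "other_alleles")
  pheno <- plink_pheno(rownames(g), samples)
  lines <- vapply(seq_len(nrow(m)), function(i) {
    alle <- character(2 * ncol(m))
    for (j in seq_len(ncol(m))) {
      d <- m[i, j]
      pair <- if (is.na(d)) c("0", "0")
      else if (d == 0) c(oa[j], oa[j])
      else if (d == 1) c(ea[j], oa[j])
      else c(ea[j], ea[j])
      alle[c(2 * j - 1, 2 * j)] <- pair
    }
    paste(c(rownames(m)[i], rownames(m)[i], "0", "0", "0", pheno[i], alle),
          collapse = " ")
  }, "")
  writeLines(lines, path)
  map <- data.frame(chrom = 1, snp = colnames(m), cm = 0,
                    bp = seq_len(ncol(m)) * 1000)
  utils::write.table(map, map_path(path), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

map_path <- function(ped_path) sub("\\.ped$", ".map", ped_path)

plink_pheno <- function(ids, samples) {
  if (is.null(samples)) return(rep("0", length(ids)))
  st <- samples$status[match(ids, samples$sample_id)]
  ifelse(is.na(st), "0", ifelse(st == "case", "2", "1"))
}

#' @rdname genotype_io
#' @export
read_plink_ped <- function(path) {
  lines <- readLines(path)
  map <- utils::read.table(map_path(path), sep = "\t",
                           col.names = c("chrom", "snp", "cm", "bp"),
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  n_snp <- nrow(map)
  rows <- strsplit(lines, " +")
  n_field <- 6 + 2 * n_snp
  dos <- matrix(NA_real_, length(rows), n_snp)
  ids <- character(length(rows)); pheno <- character(length(rows))
  parsed <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != n_field)
      stop("malformed .ped line ", i, ": expected ", n_field, " fields, got ",
           length(f))
    ids[i] <- f[2]; pheno[i] <- f[6]
    alle <- matrix(f[-(1:6)], nrow = 2)
    if (!all(alle %in% c("A", "C", "G", "T", "0")))
      stop("malformed .ped line ", i, ": allele codes outside {A,C,G,T,0}")
    parsed[[i]] <- alle
  }
  # effect allele = minor allele across the file; decode in a second pass
  ea <- character(n_snp); oa <- character(n_snp)
  for (j in seq_len(n_snp)) {
    als <- unlist(lapply(parsed, function(a) setdiff(a[, j], "0")))
    if (!length(als)) { ea[j] <- "A"; oa[j] <- "G"; next }
    tab <- sort(table(als))
    ea[j] <- names(tab)[1]
    oa[j] <- if (length(tab) > 1) names(tab)[length(tab)] else
      setdiff(c("A", "C", "G", "T"), ea[j])[1]
  }
  for (i in seq_along(parsed)) {
    a <- parsed[[i]]
    for (j in seq_len(n_snp)) {
      pair <- a[, j]
      dos[i, j] <- if (any(pair == "0")) NA_real_ else sum(pair == ea[j])
    }
  }
  g <- genotype_matrix(dos, sample_ids = ids, snp_ids = map$snp,
                       effect_alleles = ea, other_alleles = oa)
  stub <- data.frame(sample_id = ids,
                     status = c("0" = NA, "1" = "control", "2" = "case")[pheno],
                     stringsAsFactors = FALSE)
  list(genotypes = g, samples = stub)
}

#' @rdname genotype_io
#' @export
write_plink_raw <- function(g, path, samples = NULL) {
  stopifnot_genotype(g)
  m <- unclass(g)
  ea <- effect_alleles(g)
  header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
              paste0(colnames(m), "_", ea))
  df <- data.frame(FID = rownames(m), IID = rownames(m), PAT = 0, MAT = 0,
                   SEX = 0, PHENOTYPE = plink_pheno(rownames(m), samples),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- header
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = " ", check.names = FALSE,
                          na.strings = "NA", stringsAsFactors = FALSE)
  snp_cols <- setdiff(names(df), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  ids <- sub("_[ACGT0]+$", "", snp_cols)
  ea <- sub("^.*_", "", snp_cols)
  dos <- as.matrix(df[, snp_cols, drop = FALSE])
  g <- genotype_matrix(dos, sample_ids = df$IID, snp_ids = ids,
                       effect_alleles = ea, fractional = TRUE)
  stub <- data.frame(sample_id = df$IID,
                     status = c("0" = NA, "1" = "control", "2" = "case")[
                       as.character(df$PHENOTYPE)],
                     stringsAsFactors = FALSE)
  list(genotypes = g, samples = stub)
}

#' @rdname genotype_io
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot_genotype(g)
  m <- unclass(g)
  ea <- effect_alleles(g); oa <- attr(g, "other_alleles")
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("sample_id", paste0(colnames(m), ":", ea, ":", oa))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = "", stringsAsFactors = FALSE)
  snp_cols <- setdiff(names(df), "sample_id")
  parts <- strsplit(snp_cols, ":", fixed = TRUE)
  g <- genotype_matrix(as.matrix(df[, snp_cols, drop = FALSE]),
                       sample_ids = df$sample_id,
                       snp_ids = vapply(parts, `[`, "", 1),
                       effect_alleles = vapply(parts, `[`, "", 2),
                       other_alleles = vapply(parts, `[`, "", 3),
                       fractional = TRUE)
  list(genotypes = g, samples = data.frame(sample_id = df$sample_id,
                                           stringsAsFactors = FALSE))
}

#' Read or write a sample phenotype/covariate table as TSV
#'
#' Columns: `sample_id`, `status` (case/control), `er_status`
#' (positive/negative/unknown), `age`, `bmi`, `age_menarche`, `live_births`,
#' `family_history` (yes/no), `menopausal` (pre/post), optional
#' `external_5yr_risk`, `pc1`, `pc2`.
#'
#' @param samples sample table data.frame.
#' @param path file path.
#' @return the table (reader) or `path` invisibly (writer).
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE)
}

#' Write or read PRS weights as TSV
#'
#' The de-facto PRS weight-file layout: `snp_id`, `effect_allele`,
#' `other_allele`, `beta` (log-OR scale), plus a JSON sidecar
#' (`<path>.json`) carrying the method, covariate coefficients, penalty and
#' case set, so a written model can score new cohorts after reading.
#'
#' @param model a `prs_model` (RLR or LRR; the ANN serializes to JSON only).
#' @param path TSV path.
#' @return `path` (writer) / a reduced `prs_model` (reader).
#' @export
write_prs_weights <- function(model, path) {
  if (is.null(model$betas)) stop("ANN models serialize via write_ann_model()")
  df <- data.frame(snp_id = model$snp_ids,
                   effect_allele = unname(model$effect_alleles[model$snp_ids]),
                   other_allele = unname(model$other_alleles[model$snp_ids]),
                   beta = unname(model$betas[model$snp_ids]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(method = model$method, case_set = model$case_set,
               intercept = model$intercept, lambda = model$lambda,
               covariate_betas = as.list(model$covariate_betas %||% list()))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_prs_weights
#' @export
read_prs_weights <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  model <- list(method = meta$method, case_set = meta$case_set,
                snp_ids = df$snp_id,
                effect_alleles = stats::setNames(df$effect_allele, df$snp_id),
                other_alleles = stats::setNames(df$other_allele, df$snp_id),
                betas = stats::setNames(df$beta, df$snp_id),
                intercept = meta$intercept %||% 0,
                lambda = meta$lambda,
                covariate_betas = unlist(meta$covariate_betas) %||% NULL)
  class(model) <- c(paste0("prs_", meta$method), "prs_model")
  model
}

#' Serialize an ANN PRS model to portable JSON
#'
#' @param model a `prs_ann` model.
#' @param path JSON path.
#' @return `path` (writer) / the model (reader).
#' @export
write_ann_model <- function(model, path) {
  stopifnot(inherits(model, "prs_ann"))
  dump <- list(snp_ids = model$snp_ids,
               effect_alleles = as.list(model$effect_alleles),
               other_alleles = as.list(model$other_alleles),
               case_set = model$case_set,
               config = unclass(model$config),
               cov_center = as.list(model$cov_center),
               cov_scale = as.list(model$cov_scale),
               snp_center = as.list(model$snp_center),
               snp_scale = as.list(model$snp_scale),
               score_center = model$score_center,
               score_scale = model$score_scale,
               ann = model$ann)
  jsonlite::write_json(dump, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  cfg <- do.call(ann_config, d$config[setdiff(names(d$config), NULL)])
  ann <- lapply(d$ann, function(par) {
    # undo jsonlite simplification: per-layer lists may come back as
    # matrices/arrays when layer shapes coincide
    if (is.array(par$W) && length(dim(par$W)) == 3)
      par$W <- lapply(seq_len(dim(par$W)[1]), function(i) par$W[i, , ])
    if (is.matrix(par$W)) par$W <- list(par$W)
    par$W <- lapply(par$W, as.matrix)
    if (is.matrix(par$b)) par$b <- lapply(asplit(par$b, 1), as.numeric)
    if (!is.list(par$b)) par$b <- list(as.numeric(par$b))
    par$b <- lapply(par$b, as.numeric)
    par$WB <- as.matrix(par$WB)
    par$bB <- as.numeric(par$bB)
    par$w_out <- as.numeric(par$w_out)
    par$w_cov <- as.numeric(par$w_cov)
    par$b_out <- as.numeric(par$b_out)
    par
  })
  model <- list(method = "ann", case_set = d$case_set, snp_ids = d$snp_ids,
                effect_alleles = stats::setNames(unlist(d$effect_alleles), d$snp_ids),
                other_alleles = stats::setNames(unlist(d$other_alleles), d$snp_ids),
                ann = ann, config = cfg,
                cov_center = unlist(d$cov_center),
                cov_scale = unlist(d$cov_scale),
                snp_center = unlist(d$snp_center),
                snp_scale = unlist(d$snp_scale),
                score_center = as.numeric(d$score_center),
                score_scale = as.numeric(d$score_scale),
                intercept = ann[[1]]$b_out)
  class(model) <- c("prs_ann", "prs_model")
  model
}
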