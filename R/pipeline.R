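#' Configure an end-to-end PRS development-and-validation run
#'
#' Bundles everything [run_pipeline()] needs: either simulation configs for
#' the training (GWAS-like) and validation (case-control) cohorts, or paths
#' to genotype/phenotype files; QC thresholds per cohort; selection
#' thresholds; model settings; evaluation options; a global seed; and the
#' output directory.
#'
#' @param train,validation either a [sim_config()] (simulated cohort) or a
#'   `list(genotypes = path, dialect = "ped"|"raw"|"tsv", samples = path)`.
#' @param qc_train,qc_validation [qc_thresholds()] per cohort.
#' @param prune_r2 tight-LD pruning threshold (`NULL` disables pruning).
#' @param methods subset of `c("rlr", "lrr", "ann")`.
#' @param case_sets subset of `c("overall", "er_pos", "er_neg")`.
#' @param adjustments subset of `c("none", "gail", "classical")`.
#' @param lambda_grid ridge grid for LRR.
#' @param ann ANN settings ([ann_config()]).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing stage outputs.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(train, validation,
                            qc_train = qc_thresholds("array"),
                            qc_validation = qc_thresholds("panel"),
                            prune_r2 = 0.8,
                            methods = c("rlr", "lrr", "ann"),
                            case_sets = c("overall", "er_pos", "er_neg"),
                            adjustments = c("none", "gail", "classical"),
                            lambda_grid = default_lambda_grid(),
                            ann = ann_config(),
                            seed = 1L, out_dir = NULL) {
  structure(list(train = train, validation = validation,
                 qc_train = qc_train, qc_validation = qc_validation,
                 prune_r2 = prune_r2, methods = methods,
                 case_sets = case_sets, adjustments = adjustments,
                 lambda_grid = lambda_grid, ann = ann,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

load_cohort <- function(spec, stage_seed) {
  if (inherits(spec, "sim_config")) {
    spec$seed <- derive_seed(stage_seed, "simulate")
    simulate_cohort(spec)
  } else if (is.list(spec) && !is.null(spec$genotypes)) {
    dialect <- spec$dialect %||% "tsv"
    r <- switch(dialect,
                ped = read_plink_ped(spec$genotypes),
                raw = read_plink_raw(spec$genotypes),
                tsv = read_dosage_tsv(spec$genotypes),
                stop("unknown genotype dialect: ", dialect))
    if (!is.null(spec$samples)) r$samples <- read_sample_table(spec$samples)
    r
  } else stop("cohort spec must be a sim_config or a list of file paths")
}

#' Run the full PRS development-and-validation pipeline
#'
#' Executes, in order: cohort acquisition (simulation or file input) for the
#' training and validation cohorts; QC on each (array-style thresholds for
#' training, panel-style for validation by default); tight-LD pruning of
#' the panel on the QC-passed training cohort; PC computation; model
#' fitting on the training cohort for each requested method and case set;
#' scoring of the validation cohort; and evaluation of each score under
#' each requested adjustment. Any stage failure aborts with the stage name.
#' All randomness derives from the global seed; a manifest records the
#' config, seeds, per-stage dimensions and output checksums.
#'
#' @param config a [pipeline_config()].
#' @return `list(evaluation, models, scores, qc_train, qc_validation,
#'   selection, manifest)`; `evaluation` is a `prs_evaluation` table with
#'   one row per method x case set x adjustment.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(version = as.character(utils::packageVersion("prsforge")),
                   seed = config$seed, started = format(Sys.time()),
                   stages = list())
  note <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  train <- stage("acquire_train", load_cohort(config$train, config$seed))
  valid <- stage("acquire_validation",
                 load_cohort(config$validation, derive_seed(config$seed, "valid")))
  note("acquire", train_n = nrow(train$genotypes),
       valid_n = nrow(valid$genotypes))

  qc_tr <- stage("qc_train",
                 apply_qc(train$genotypes, train$samples, config$qc_train))
  qc_va <- stage("qc_validation",
                 apply_qc(valid$genotypes, valid$samples, config$qc_validation))
  note("qc", train_snps = qc_tr$report$summary$snps_out,
       train_samples = qc_tr$report$summary$samples_out,
       valid_snps = qc_va$report$summary$snps_out,
       valid_samples = qc_va$report$summary$samples_out)

  sel <- NULL
  panel <- intersect(colnames(qc_tr$genotypes), colnames(qc_va$genotypes))
  if (!is.null(config$prune_r2)) {
    ld <- ld_matrix(qc_tr$genotypes[, panel])
    sel <- stage("select", prune_tight_ld(panel, ld, config$prune_r2))
    panel <- sel$snp_id[sel$action == "keep"]
  }
  if (!length(panel)) stop("pipeline stage 'select' failed: empty panel")
  g_tr <- qc_tr$genotypes[, panel]
  g_va <- qc_va$genotypes[, panel]
  note("select", panel_size = length(panel))

  tr_tab <- qc_tr$samples
  va_tab <- qc_va$samples
  pcs_tr <- stage("pca_train", compute_pcs(g_tr, 2))
  tr_tab$pc1 <- pcs_tr[match(tr_tab$sample_id, rownames(pcs_tr)), 1]
  tr_tab$pc2 <- pcs_tr[match(tr_tab$sample_id, rownames(pcs_tr)), 2]
  pcs_va <- stage("pca_validation", compute_pcs(g_va, 2))
  va_tab$pc1 <- pcs_va[match(va_tab$sample_id, rownames(pcs_va)), 1]
  va_tab$pc2 <- pcs_va[match(va_tab$sample_id, rownames(pcs_va)), 2]

  models <- list(); scores <- list(); evals <- list()
  for (cs in config$case_sets) {
    for (m in config$methods) {
      key <- paste(m, cs, sep = ".")
      fit <- stage(paste0("train_", key),
                   prs_fit(g_tr, tr_tab, method = m, case_set = cs,
                           lambda_grid = config$lambda_grid,
                           config = config$ann,
                           seed = derive_seed(config$seed, key)))
      models[[key]] <- fit
      sc <- stage(paste0("score_", key), predict(fit, g_va))
      scores[[key]] <- sc
      vmask <- case_set_mask(va_tab, cs)
      evals[[key]] <- stage(paste0("evaluate_", key),
                            evaluate_prs(sc[vmask], va_tab$status[vmask],
                                         va_tab[vmask, , drop = FALSE],
                                         adjustments = config$adjustments,
                                         case_set = cs, method = m))
    }
  }
  evaluation <- do.call(rbind, evals)
  rownames(evaluation) <- NULL
  class(evaluation) <- c("prs_evaluation", "data.frame")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      scores = file.path(config$out_dir, "validation_scores.tsv"),
      evaluation = file.path(config$out_dir, "evaluation_report.tsv"))
    sc_df <- data.frame(sample_id = rownames(g_va),
                        do.call(cbind, scores), check.names = FALSE)
    utils::write.table(sc_df, paths["scores"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(as.data.frame(evaluation), paths["evaluation"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (m in names(models))
      if (!is.null(models[[m]]$betas))
        write_prs_weights(models[[m]],
                          file.path(config$out_dir, paste0("weights_", m, ".tsv")))
      else
        write_ann_model(models[[m]],
                        file.path(config$out_dir, paste0("weights_", m, ".json")))
    manifest$checksums <- as.list(tools::md5sum(paths))
  }
  manifest$finished <- format(Sys.time())
  if (!is.null(config$out_dir))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)

  list(evaluation = evaluation, models = models, scores = scores,
       qc_train = qc_tr$report, qc_validation = qc_va$report,
       selection = sel, manifest = manifest)
}
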