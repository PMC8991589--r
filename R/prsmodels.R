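#' Principal components of the genotype matrix
#'
#' Column-standardizes dosages (zero-variance SNPs dropped), computes the
#' eigendecomposition of the sample covariance and returns the top-k sample
#' scores, the standard population-structure adjustment. Sign convention:
#' the loading of largest magnitude of each component is positive.
#'
#' @param g imputed (no `NA`) `genotype_matrix`.
#' @param k number of components (default 2, the usual adjustment set).
#' @return n x k matrix of sample scores, columns `PC1`, `PC2`, ...
#' @export
compute_pcs <- function(g, k = 2) {
  stopifnot_genotype(g)
  if (anyNA(g)) stop("genotype matrix must be imputed before PCA")
  m <- unclass(g)
  v <- apply(m, 2, stats::var)
  m <- m[, v > 0, drop = FALSE]
  if (ncol(m) < k) stop("fewer polymorphic SNPs than requested components")
  ms <- scale(m)
  pr <- stats::prcomp(ms, center = FALSE, scale. = FALSE)
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- rot[, j]; sign(l[which.max(abs(l))])
  }, 0)
  scores <- pr$x[, seq_len(k), drop = FALSE] %*% diag(flip, k)
  dimnames(scores) <- list(rownames(g), paste0("PC", seq_len(k)))
  scores
}

# --- penalized logistic solver --------------------------------------------

# Newton-IRLS for logistic regression minimizing
#   -loglik + (lambda/2) * sum(beta[penalized]^2)
# intercept/covariates unpenalized; step-halving safeguards convergence
ridge_logistic <- function(X, y, penalized, lambda, max_iter = 200, tol = 1e-10) {
  p <- ncol(X)
  pen <- rep(0, p); pen[penalized] <- lambda
  beta <- rep(0, p)
  obj <- function(b) {
    eta <- drop(X %*% b)
    # overflow-safe -loglik: log(1+e^eta) = max(eta,0) + log1p(e^-|eta|)
    -sum(y * eta) + sum(pmax(eta, 0) + log1p(exp(-abs(eta)))) +
      sum(pen * b^2) / 2
  }
  f_old <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X * w, X); diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-8, p), grad))
    s <- 1
    repeat {
      beta_new <- beta + s * step
      f_new <- obj(beta_new)
      if (is.finite(f_new) && f_new <= f_old + 1e-12) break
      s <- s / 2
      if (s < 1e-10) { beta_new <- beta; f_new <- f_old; break }
    }
    done <- max(abs(beta_new - beta)) < tol || abs(f_old - f_new) < tol
    beta <- beta_new; f_old <- f_new
    if (done) break
  }
  beta
}

#' ANN configuration for the bottleneck PRS
#'
#' Hyperparameters of the feed-forward network used by
#' `prs_fit(method = "ann")`. Defaults follow the tuned values of the
#' approach this package implements: 60 full-batch iterations (epochs),
#' 3 hidden layers, dropout 0.4, hidden width `round(sqrt(n_inputs)) + 2`
#' (7 for a 24-SNP panel), a linear bottleneck of length 6, leaky-ReLU
#' (negative slope 0.01), sigmoid output with cross-entropy loss, and the
#' Adam optimizer at learning rate 0.01.
#'
#' @param n_iterations full-batch training epochs.
#' @param n_hidden_layers number of fully connected hidden layers.
#' @param dropout_rate dropout probability in \[0, 1), active only in training.
#' @param learning_rate Adam step size.
#' @param bottleneck_dim width of the linear bottleneck the score is read from.
#' @param leaky_slope negative slope of the leaky-ReLU activation.
#' @param score_mode `"bottleneck"` (genotype-pathway contribution to the
#'   pre-sigmoid logit; covariate-free, the default) or `"full_minus_cov"`
#'   (full logit minus covariate terms).
#' @param n_restarts independent training restarts; with more than one, the
#'   PRS is the average of the per-restart standardized genotype-pathway
#'   scores, which stabilizes the small network against initialization and
#'   dropout noise. `1` gives the bare single-network score.
#' @param seed integer seed for initialization and dropout.
#' @return an `ann_config` object.
#' @export
ann_config <- function(n_iterations = 60, n_hidden_layers = 3,
                       dropout_rate = 0.4, learning_rate = 0.01,
                       bottleneck_dim = 6, leaky_slope = 0.01,
                       score_mode = c("bottleneck", "full_minus_cov"),
                       n_restarts = 3, seed = 1L) {
  stopifnot(n_iterations >= 1, n_hidden_layers >= 1,
            dropout_rate >= 0, dropout_rate < 1, bottleneck_dim >= 1,
            n_restarts >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 bottleneck_dim = as.integer(bottleneck_dim),
                 leaky_slope = leaky_slope,
                 score_mode = match.arg(score_mode),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "ann_config")
}

hidden_width <- function(n_inputs) as.integer(round(sqrt(n_inputs)) + 2)

ann_init <- function(n_in, cfg, n_cov) {
  h <- hidden_width(n_in)
  dims <- c(n_in, rep(h, cfg$n_hidden_layers))
  W <- list(); b <- list()
  for (l in seq_len(cfg$n_hidden_layers)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * h, 0, sqrt(2 / dims[l])), dims[l], h)
    b[[l]] <- rep(0, h)
  }
  list(W = W, b = b,
       WB = matrix(stats::rnorm(h * cfg$bottleneck_dim, 0, sqrt(1 / h)),
                   h, cfg$bottleneck_dim),
       bB = rep(0, cfg$bottleneck_dim),
       w_out = stats::rnorm(cfg$bottleneck_dim, 0, sqrt(1 / cfg$bottleneck_dim)),
       w_cov = rep(0, n_cov), b_out = 0)
}

leaky <- function(a, slope) ifelse(a > 0, a, slope * a)
dleaky <- function(a, slope) ifelse(a > 0, 1, slope)

# forward pass; returns activations needed for backprop (or just the
# bottleneck when scoring)
ann_forward <- function(par, X, C, cfg, train = FALSE) {
  L <- length(par$W)
  H <- X; A <- vector("list", L); Hs <- vector("list", L); M <- vector("list", L)
  for (l in seq_len(L)) {
    A[[l]] <- sweep(H %*% par$W[[l]], 2, par$b[[l]], `+`)
    H <- leaky(A[[l]], cfg$leaky_slope)
    if (train && cfg$dropout_rate > 0) {
      M[[l]] <- matrix(stats::runif(length(H)) >= cfg$dropout_rate,
                       nrow(H), ncol(H)) / (1 - cfg$dropout_rate)
      H <- H * M[[l]]
    }
    Hs[[l]] <- H
  }
  Z <- sweep(H %*% par$WB, 2, par$bB, `+`)
  logit <- drop(Z %*% par$w_out) + par$b_out
  if (!is.null(C) && length(par$w_cov)) logit <- logit + drop(C %*% par$w_cov)
  list(A = A, H = Hs, M = M, Z = Z, logit = logit, p = stats::plogis(logit))
}

ann_backward <- function(par, X, C, y, fw, cfg) {
  n <- length(y)
  dlogit <- (fw$p - y) / n
  g <- list(w_out = drop(crossprod(fw$Z, dlogit)), b_out = sum(dlogit),
            w_cov = if (length(par$w_cov)) drop(crossprod(C, dlogit)) else numeric(0))
  dZ <- tcrossprod(dlogit, par$w_out)
  L <- length(par$W)
  g$WB <- crossprod(fw$H[[L]], dZ); g$bB <- colSums(dZ)
  dH <- tcrossprod(dZ, par$WB)
  g$W <- vector("list", L); g$b <- vector("list", L)
  for (l in rev(seq_len(L))) {
    if (!is.null(fw$M[[l]])) dH <- dH * fw$M[[l]]
    dA <- dH * dleaky(fw$A[[l]], cfg$leaky_slope)
    Hin <- if (l == 1) X else fw$H[[l - 1]]
    g$W[[l]] <- crossprod(Hin, dA); g$b[[l]] <- colSums(dA)
    if (l > 1) dH <- tcrossprod(dA, par$W[[l]])
  }
  g
}

adam_state <- function(par) rapply(par, function(x) x * 0, how = "replace")

adam_step <- function(par, g, m, v, t, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  upd <- function(p, gr, mm, vv) {
    mm <- b1 * mm + (1 - b1) * gr
    vv <- b2 * vv + (1 - b2) * gr^2
    mhat <- mm / (1 - b1^t); vhat <- vv / (1 - b2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
  }
  walk <- function(p, gr, mm, vv) {
    if (is.list(p)) {
      if (!is.null(names(p))) gr <- gr[names(p)]
      out <- Map(walk, p, gr, mm, vv)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else upd(p, gr, mm, vv)
  }
  walk(par, g, m, v)
}

ann_train <- function(X, C, y, cfg) {
  with_seed(cfg$seed, {
    par <- ann_init(ncol(X), cfg, if (is.null(C)) 0 else ncol(C))
    m <- adam_state(par); v <- adam_state(par)
    for (t in seq_len(cfg$n_iterations)) {
      fw <- ann_forward(par, X, C, cfg, train = TRUE)
      loss <- -mean(y * log(pmax(fw$p, 1e-12)) +
                      (1 - y) * log(pmax(1 - fw$p, 1e-12)))
      if (!is.finite(loss)) stop("NaN loss at epoch ", t)
      g <- ann_backward(par, X, C, y, fw, cfg)
      st <- adam_step(par, g, m, v, t, cfg$learning_rate)
      par <- st$p; m <- st$m; v <- st$v
    }
    par
  })
}

# --- fold assignment and cross-validation ---------------------------------

# seeded random partition into near-equal folds stratified by class
fold_assign <- function(y, folds, seed) {
  with_seed(seed, {
    fid <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fid[idx[sample(length(idx))]] <- rep_len(seq_len(folds), length(idx))
    }
    fid
  })
}

logloss <- function(y, p) {
  p <- clamp(p, 1e-12, 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' K-fold cross-validated grid search
#'
#' Seeded random partition into near-equal folds stratified by case status;
#' for each grid row, the mean validation log-loss over folds. The chosen
#' row is the first row attaining the minimum (within 1e-12), so order the
#' grid with the preferred (simpler) settings first to encode tie-breaking.
#'
#' @param y 0/1 outcome vector.
#' @param grid data.frame of candidate hyperparameter rows.
#' @param fit_predict `function(params, train_idx, val_idx)` returning
#'   predicted probabilities for `val_idx` from a model fitted on `train_idx`.
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return a `cv_result`: `grid` with a `mean_logloss` column, `best` (row
#'   index), `chosen` (that row), `fold_id`, `seed`.
#' @export
cross_validate <- function(y, grid, fit_predict, folds = 10, seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0) stop("empty hyperparameter grid")
  if (length(y) < folds) stop("fewer samples than folds")
  fid <- fold_assign(y, folds, seed)
  ll <- vapply(seq_len(nrow(grid)), function(i) {
    params <- grid[i, , drop = FALSE]
    mean(vapply(seq_len(folds), function(f) {
      tr <- which(fid != f); va <- which(fid == f)
      logloss(y[va], fit_predict(params, tr, va))
    }, 0))
  }, 0)
  best <- which(ll <= min(ll) + 1e-12)[1]
  structure(list(grid = cbind(grid, mean_logloss = ll), best = best,
                 chosen = grid[best, , drop = FALSE], fold_id = fid,
                 seed = seed), class = "cv_result")
}

# --- the fitting front end -------------------------------------------------

case_set_mask <- function(samples, case_set) {
  switch(case_set,
         overall = rep(TRUE, nrow(samples)),
         er_pos = samples$status == "control" |
           (samples$status == "case" & samples$er_status == "positive"),
         er_neg = samples$status == "control" |
           (samples$status == "case" & samples$er_status == "negative"),
         stop("unknown case_set: ", case_set))
}

default_lambda_grid <- function() 10^seq(-2, 4, length.out = 13)

#' Fit a polygenic risk score model
#'
#' The single fitting entry point for the three weighting approaches:
#'
#' * `"rlr"` (repeated logistic regression): one unadjusted univariate
#'   logistic regression per SNP; the per-dosage log-OR is the SNP's weight.
#'   This is the summary-statistic-compatible classic.
#' * `"lrr"` (logistic ridge regression): one multivariate logistic model
#'   containing every SNP simultaneously, adjusted for age and the first
#'   two genotype principal components; the L2 penalty applies to SNP
#'   coefficients only and its strength is chosen by 10-fold
#'   cross-validated log-loss (ties to the stronger penalty).
#' * `"ann"`: a feed-forward network (see [ann_config()]) whose linear
#'   bottleneck compresses the SNP panel; the output layer sees the
#'   bottleneck plus age and the two PCs, and the PRS is the genotype
#'   pathway's contribution to the pre-sigmoid logit.
#'
#' Subtype-specific scores (`case_set = "er_pos"` / `"er_neg"`) are trained
#' on exactly the subtype's cases plus all controls.
#'
#' @param genotypes imputed `genotype_matrix` (training cohort).
#' @param samples sample table with `sample_id`, `status`, `er_status`,
#'   `age`; `pc1`/`pc2` are computed from `genotypes` when absent.
#' @param method `"rlr"`, `"lrr"` or `"ann"`.
#' @param case_set `"overall"`, `"er_pos"` or `"er_neg"`.
#' @param lambda_grid ridge penalty grid (LRR only).
#' @param config an [ann_config()] (ANN only).
#' @param tune_grid optional data.frame over `n_iterations`,
#'   `n_hidden_layers`, `dropout_rate` to tune the ANN by 10-fold CV
#'   (rows should be ordered simplest first); `NULL` uses `config` as-is.
#' @param folds CV folds.
#' @param seed fold-assignment seed (and ANN seed unless set in `config`).
#' @return a `prs_model` object (subclass `prs_rlr`, `prs_lrr` or
#'   `prs_ann`) with `print`, `summary`, `coef` and `predict` methods.
#' @examples
#' cfg <- sim_config(300, 300, demo_snp_panel(), seed = 7)
#' cohort <- simulate_cohort(cfg)
#' fit <- prs_fit(cohort$genotypes, cohort$samples, method = "rlr")
#' head(coef(fit))
#' scores <- predict(fit, cohort$genotypes)
#' @export
prs_fit <- function(genotypes, samples, method = c("rlr", "lrr", "ann"),
                    case_set = c("overall", "er_pos", "er_neg"),
                    lambda_grid = default_lambda_grid(),
                    config = ann_config(seed = seed), tune_grid = NULL,
                    folds = 10, seed = 1L) {
  method <- match.arg(method)
  case_set <- match.arg(case_set)
  stopifnot_genotype(genotypes)
  if (anyNA(genotypes)) stop("genotypes must be imputed before fitting")
  samples <- align_table(genotypes, samples)

  mask <- case_set_mask(samples, case_set)
  g <- genotypes[mask, ]
  tab <- samples[mask, , drop = FALSE]
  y <- as.numeric(tab$status == "case")
  if (length(unique(y)) < 2) stop("training set needs both cases and controls")

  needs_cov <- method %in% c("lrr", "ann")
  Cmat <- NULL
  if (needs_cov) {
    if (all(c("pc1", "pc2") %in% names(tab)) && !anyNA(tab$pc1) && !anyNA(tab$pc2)) {
      pcs <- cbind(PC1 = tab$pc1, PC2 = tab$pc2)
    } else {
      pcs <- compute_pcs(g, 2)
    }
    Cmat <- cbind(age = tab$age, pc1 = pcs[, 1], pc2 = pcs[, 2])
  }

  model <- list(method = method, case_set = case_set,
                snp_ids = colnames(g),
                effect_alleles = effect_alleles(g),
                other_alleles = attr(g, "other_alleles"),
                training_samples = tab$sample_id,
                n_train = nrow(g), seed = seed)
  X <- unclass(g)

  if (method == "rlr") {
    flagged <- logical(ncol(X))
    betas <- vapply(seq_len(ncol(X)), function(j) {
      fit <- suppressWarnings(stats::glm(y ~ X[, j], family = stats::binomial()))
      b <- stats::coef(fit)[2]
      if (!fit$converged || !is.finite(b) || abs(b) > 15) {
        flagged[j] <<- TRUE
        # penalized fallback for separated SNPs
        b <- ridge_logistic(cbind(1, X[, j]), y, penalized = 2, lambda = 1e-3)[2]
      }
      b
    }, 0)
    model$betas <- stats::setNames(betas, colnames(X))
    model$flagged <- colnames(X)[flagged]
    model$intercept <- 0
    class(model) <- c("prs_rlr", "prs_model")
  } else if (method == "lrr") {
    D <- cbind(`(Intercept)` = 1, Cmat, X)
    pen_idx <- seq(ncol(Cmat) + 2, ncol(D))
    fit_predict <- function(params, tr, va) {
      b <- ridge_logistic(D[tr, , drop = FALSE], y[tr], pen_idx, params$lambda)
      stats::plogis(drop(D[va, , drop = FALSE] %*% b))
    }
    grid <- data.frame(lambda = sort(unique(lambda_grid), decreasing = TRUE))
    cv <- if (nrow(grid) > 1)
      cross_validate(y, grid, fit_predict, folds = folds, seed = seed)
    else list(chosen = grid, grid = grid, best = 1L)
    lambda <- cv$chosen$lambda
    b <- ridge_logistic(D, y, pen_idx, lambda)
    if (any(!is.finite(b))) stop("ridge fit diverged over grid [",
                                 min(lambda_grid), ", ", max(lambda_grid), "]")
    model$betas <- stats::setNames(b[pen_idx], colnames(X))
    model$covariate_betas <- stats::setNames(b[2:(ncol(Cmat) + 1)], colnames(Cmat))
    model$intercept <- b[1]
    model$lambda <- lambda
    model$cv <- cv
    class(model) <- c("prs_lrr", "prs_model")
  } else {
    cfg <- config
    cov_mu <- colMeans(Cmat); cov_sd <- apply(Cmat, 2, stats::sd)
    cov_sd[cov_sd == 0] <- 1
    Cs <- scale(Cmat, center = cov_mu, scale = cov_sd)
    # standardized dosage inputs: keeps the network well-conditioned;
    # centers/scales travel with the model so scoring matches training
    snp_mu <- colMeans(X); snp_sd <- apply(X, 2, stats::sd)
    snp_sd[snp_sd == 0] <- 1
    X <- scale(X, center = snp_mu, scale = snp_sd)
    if (!is.null(tune_grid)) {
      # tuning compares configurations with a single restart; the final fit
      # uses the full restart ensemble
      fit_predict <- function(params, tr, va) {
        cfg_i <- cfg
        for (nm in names(params)) cfg_i[[nm]] <- params[[nm]]
        par <- ann_train(X[tr, , drop = FALSE], Cs[tr, , drop = FALSE], y[tr], cfg_i)
        ann_forward(par, X[va, , drop = FALSE], Cs[va, , drop = FALSE], cfg_i)$p
      }
      cv <- cross_validate(y, tune_grid, fit_predict, folds = folds, seed = seed)
      for (nm in names(cv$chosen)) cfg[[nm]] <- cv$chosen[[nm]]
      model$cv <- cv
    }
    R <- cfg$n_restarts
    pars <- vector("list", R)
    s_ctr <- numeric(R); s_scl <- rep(1, R)
    for (r in seq_len(R)) {
      cfg_r <- cfg
      cfg_r$seed <- if (R == 1) cfg$seed else
        derive_seed(cfg$seed, paste0("restart", r))
      pars[[r]] <- ann_train(X, Cs, y, cfg_r)
      if (R > 1) {
        fw <- ann_forward(pars[[r]], X, NULL, cfg_r, train = FALSE)
        s_tr <- drop(fw$Z %*% pars[[r]]$w_out) + pars[[r]]$b_out
        s_ctr[r] <- mean(s_tr)
        s_scl[r] <- stats::sd(s_tr)
        if (!is.finite(s_scl[r]) || s_scl[r] < 1e-12) s_scl[r] <- 1
      }
    }
    model$ann <- pars
    model$score_center <- s_ctr
    model$score_scale <- s_scl
    model$config <- cfg
    model$cov_center <- cov_mu
    model$cov_scale <- cov_sd
    model$snp_center <- snp_mu
    model$snp_scale <- snp_sd
    model$intercept <- pars[[1]]$b_out
    class(model) <- c("prs_ann", "prs_model")
  }
  model
}

# panel harmonization: ids must match; an effect/other allele swap flips the
# dosage (2 - x) with a notice; any other allele mismatch is an error
harmonize_dosages <- function(model, g) {
  if (!all(model$snp_ids %in% colnames(g))) {
    missing <- setdiff(model$snp_ids, colnames(g))
    stop("panel mismatch; genotype matrix lacks SNPs: ",
         paste(missing, collapse = ", "))
  }
  g <- g[, model$snp_ids]
  ea_g <- effect_alleles(g); oa_g <- attr(g, "other_alleles")
  ea_m <- model$effect_alleles; oa_m <- model$other_alleles
  same <- ea_g == ea_m
  swapped <- !same & ea_g == oa_m & oa_g == ea_m
  bad <- !same & !swapped
  if (any(bad))
    stop("effect-allele mismatch for SNPs: ",
         paste(model$snp_ids[bad], collapse = ", "))
  m <- unclass(g)
  if (any(swapped)) {
    message("flipping dosages (2 - x) for ", sum(swapped),
            " SNP(s) with swapped allele labels")
    m[, swapped] <- 2 - m[, swapped]
  }
  m
}

#' Score samples with a fitted PRS model
#'
#' `type = "score"` (the default) is the PRS itself: for RLR/LRR the dot
#' product `sum_k beta_k x_k` of SNP weights with dosages (covariate
#' coefficients excluded); for the ANN the genotype pathway's contribution
#' to the pre-sigmoid logit (output weights applied to the bottleneck
#' activations, dropout disabled), so identical genotype rows score
#' identically regardless of covariates. `type = "link"`/`"response"` give
#' the full linear predictor / probability and require `samples` with
#' `age`, `pc1`, `pc2` for covariate-adjusted models.
#'
#' @param object a `prs_model`.
#' @param genotypes imputed `genotype_matrix` on the model's SNP panel
#'   (allele-label swaps are flipped automatically; other mismatches error).
#' @param type `"score"`, `"link"` or `"response"`.
#' @param samples sample table (only for `"link"`/`"response"` on
#'   covariate-adjusted models).
#' @param ... unused.
#' @return named numeric vector of per-sample values.
#' @export
predict.prs_model <- function(object, genotypes, type = c("score", "link", "response"),
                              samples = NULL, ...) {
  type <- match.arg(type)
  stopifnot_genotype(genotypes)
  if (anyNA(genotypes)) stop("genotypes must be imputed before scoring")
  m <- harmonize_dosages(object, genotypes)

  if (object$method %in% c("rlr", "lrr")) {
    score <- drop(m %*% object$betas)
  } else {
    cfg <- object$config
    m <- scale(m, center = object$snp_center, scale = object$snp_scale)
    R <- length(object$ann)
    per <- vapply(seq_len(R), function(r) {
      par <- object$ann[[r]]
      fw0 <- ann_forward(par, m, NULL, cfg, train = FALSE)
      s <- drop(fw0$Z %*% par$w_out) + par$b_out
      if (cfg$score_mode == "full_minus_cov") s <- fw0$logit
      if (R > 1) (s - object$score_center[r]) / object$score_scale[r] else s
    }, numeric(nrow(m)))
    score <- rowMeans(matrix(per, nrow = nrow(m)))
  }
  names(score) <- rownames(genotypes)
  if (type == "score") return(score)

  link <- score
  if (object$method == "lrr") {
    link <- link + object$intercept
    if (!is.null(samples)) {
      samples <- samples[match(rownames(genotypes), samples$sample_id), ]
      Cmat <- cbind(age = samples$age, pc1 = samples$pc1, pc2 = samples$pc2)
      link <- link + drop(Cmat %*% object$covariate_betas)
    }
  } else if (object$method == "ann" && !is.null(samples)) {
    # diagnostic covariate path from the first restart
    samples <- samples[match(rownames(genotypes), samples$sample_id), ]
    Cmat <- cbind(age = samples$age, pc1 = samples$pc1, pc2 = samples$pc2)
    Cs <- scale(Cmat, center = object$cov_center, scale = object$cov_scale)
    link <- link + drop(Cs %*% object$ann[[1]]$w_cov)
  }
  if (type == "link") link else stats::plogis(link)
}

#' @export
coef.prs_model <- function(object, ...) object$betas

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("PRS model (%s), case set: %s\n", toupper(x$method), x$case_set))
  cat(sprintf("  %d SNPs, trained on %d samples\n", length(x$snp_ids), x$n_train))
  if (!is.null(x$lambda)) cat(sprintf("  ridge lambda (10-fold CV): %.4g\n", x$lambda))
  if (x$method == "ann")
    cat(sprintf("  ANN: %d hidden layers x %d, bottleneck %d, %d epochs, dropout %.2f\n",
                x$config$n_hidden_layers, hidden_width(length(x$snp_ids)),
                x$config$bottleneck_dim, x$config$n_iterations,
                x$config$dropout_rate))
  invisible(x)
}

#' @export
summary.prs_model <- function(object, ...) {
  print(object)
  if (!is.null(object$betas)) {
    cat("SNP weights (log-OR scale):\n")
    print(summary(object$betas))
  }
  if (!is.null(object$covariate_betas)) {
    cat("covariate coefficients:\n"); print(object$covariate_betas)
  }
  if (length(object$flagged %||% character(0)))
    cat("flagged (penalized fallback):", paste(object$flagged, collapse = ", "), "\n")
  invisible(object)
}
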