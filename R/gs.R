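# CV accuracy rule: Pearson r truncated at 0; undefined (zero-variance or
# too-short input) also recorded as 0
.cv_accuracy <- function(pred, obs) {
  if (length(pred) < 3) return(0)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
  max(stats::cor(pred, obs), 0)
}

# kinship blocks with training-set allele frequencies, for honest CV folds
.kinship_blocks <- function(g_train, g_test) {
  p <- colMeans(g_train$dosage) / 2
  poly <- p > 0 & p < 1
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  w_tr <- sweep(g_train$dosage[, poly, drop = FALSE], 2L, 2 * p[poly])
  w_te <- sweep(g_test$dosage[, poly, drop = FALSE], 2L, 2 * p[poly])
  list(K_ct = tcrossprod(w_te, w_tr) / denom)
}

#' Fit a GBLUP prediction model
#'
#' Intercept-only mixed model (no fixed effects besides the mean): the
#' polygenic effect, with covariance proportional to the VanRaden kinship of
#' the training set, is the breeding value. Reuses the REML machinery of
#' [fit_null_mlm()].
#'
#' @param y_train training phenotypes (no missing values)
#' @param g_train training genotype_matrix (complete dosages)
#' @return list of class `gblup_model`
#' @export
gblup_fit <- function(y_train, g_train) {
  if (length(y_train) < 30) stop("training set must have >= 30 individuals")
  if (anyNA(y_train)) stop("training phenotypes must be complete")
  K <- vanraden_kinship(g_train)
  fit <- fit_null_mlm(y_train, covariates = NULL, K = K)
  structure(list(mu = fit$beta[1], sigma2_g = fit$sigma2_g,
                 sigma2_e = fit$sigma2_e, delta = fit$delta,
                 K = K, y = y_train, g_train = g_train,
                 map = g_train$map),
            class = "gblup_model")
}

#' Predict breeding values with a GBLUP model
#'
#' u_test = K_test,train (K_train,train + delta I)^-1 (y_train - mu), with
#' both kinship blocks built from training-set allele frequencies; the
#' returned prediction is mu + u_test.
#'
#' @param model a [gblup_fit()] result
#' @param g_test genotype_matrix of the individuals to predict; markers must
#'   be identical to the training markers
#' @return named numeric vector of predicted values
#' @export
gblup_predict <- function(model, g_test) {
  if (!identical(model$map$marker, g_test$map$marker)) {
    stop("test markers do not match the training markers")
  }
  n <- nrow(model$K)
  blocks <- .kinship_blocks(model$g_train, g_test)
  rhs <- solve(model$K + model$delta * diag(n), model$y - model$mu)
  u <- drop(blocks$K_ct %*% rhs)
  stats::setNames(model$mu + u, individual_ids(g_test))
}

#' Predict breeding values with a fitted vBayesB model
#'
#' Sum of the estimated SNP effects multiplied by the SNP weights over all
#' SNPs: g_i = mu + sum_j x_ij gamma_j atilde_j, with test dosages centered
#' by the training means. Family effects are not added: test families are
#' unseen by construction.
#'
#' @param fit a [fit_vbayesb()] result
#' @param g_test genotype_matrix with the training markers
#' @return named numeric vector of predicted values
#' @export
vb_predict <- function(fit, g_test) {
  if (!identical(fit$map$marker, g_test$map$marker)) {
    stop("test markers do not match the training markers")
  }
  X <- sweep(g_test$dosage, 2L, fit$centers)
  stats::setNames(fit$mu + drop(X %*% (fit$gamma * fit$atilde)),
                  individual_ids(g_test))
}

#' Leave-one-family-out cross-validation
#'
#' Each F1 family in turn is the test set; all other families plus the
#' cultivar collection train the model (the collection is never a test
#' fold). Accuracy is Pearson's r between predicted and observed values;
#' negative or undefined r is recorded as 0. Reports the per-family
#' accuracies, their mean, and the pooled r over all F1 individuals.
#'
#' @param y phenotypes aligned to `g` (missing allowed; missing individuals
#'   are dropped from training and from accuracy computation)
#' @param g genotype_matrix, complete dosages
#' @param families family labels (vector or data.frame id/family);
#'   `"collection"` marks the cultivars
#' @param method `"gblup"` or `"vbayesb"`
#' @param hyper [vb_hyper()] used when method is `"vbayesb"`
#' @return list of class `cv_report`: `per_family` (data.frame family, n, r),
#'   `mean_r`, `pooled_r`, `method`
#' @export
leave_one_family_out_cv <- function(y, g, families, method = c("gblup", "vbayesb"),
                                    hyper = vb_hyper()) {
  method <- match.arg(method)
  if (is.data.frame(families)) {
    families <- families$family[match(individual_ids(g), families$id)]
  }
  test_fams <- setdiff(sort(unique(families)), "collection")
  if (length(test_fams) < 2) stop("need >= 2 F1 families for leave-one-family-out CV")
  per <- data.frame(family = test_fams, n = NA_integer_, r = NA_real_)
  pooled_pred <- numeric(0)
  pooled_obs <- numeric(0)
  for (fi in seq_along(test_fams)) {
    fam <- test_fams[fi]
    test_idx <- which(families == fam & !is.na(y))
    if (length(test_idx) < 3) {
      warning("family ", fam, " has < 3 phenotyped members; skipped")
      next
    }
    train_idx <- which(families != fam & !is.na(y))
    stopifnot(length(intersect(train_idx, which(families == fam))) == 0)
    g_tr <- g[train_idx, ]
    g_te <- g[test_idx, ]
    pred <- if (method == "gblup") {
      gblup_predict(gblup_fit(y[train_idx], g_tr), g_te)
    } else {
      fit <- fit_vbayesb(y[train_idx], g_tr, families[train_idx], hyper)
      vb_predict(fit, g_te)
    }
    obs <- y[test_idx]
    per$n[fi] <- length(test_idx)
    per$r[fi] <- .cv_accuracy(pred, obs)
    pooled_pred <- c(pooled_pred, pred)
    pooled_obs <- c(pooled_obs, obs)
  }
  done <- !is.na(per$r)
  pooled_r <- .cv_accuracy(pooled_pred, pooled_obs)
  structure(list(per_family = per, mean_r = mean(per$r[done]),
                 pooled_r = pooled_r, method = method),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("leave-one-family-out CV (%s): mean r = %.3f, pooled r = %.3f over %d families\n",
              x$method, x$mean_r, x$pooled_r, sum(!is.na(x$per_family$r))))
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes QC, structure (kinship, PCA, LD decay), both GWAS scans, effect
#' summaries and leave-one-family-out CV, writing tab-separated outputs and a
#' parameter log to `out_dir`. Inputs come either from files (`vcf`,
#' `phenotypes`, `families`) or from the synthetic preset (`sim: true`, with
#' optional [sim_config()] overrides under `sim_args`). Reruns with the same
#' configuration are bit-identical.
#'
#' @param config a YAML file path or a list with elements `out_dir`, `seed`,
#'   `traits`, `methods`, and either `sim`/`sim_args` or `vcf` +
#'   `phenotypes` + `families`; optional `qc` (maf, max_missing), `n_pcs`,
#'   `fdr`, `vb_threshold`, `cv` (logical)
#' @return the output directory, invisibly; a `summary.tsv` file inside lists
#'   the headline numbers per trait
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(seed = 1L, traits = pear_traits(),
                                methods = c("gblup", "vbayesb"),
                                qc = list(maf = 0.01, max_missing = 0.25),
                                n_pcs = 3, fdr = 0.05, vb_threshold = 0.85,
                                cv = TRUE, sim = FALSE, sim_args = list()),
                          config)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  unknown <- setdiff(cfg$traits, pear_traits())
  if (length(unknown)) stop("unknown trait name: ", paste(unknown, collapse = ", "))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("pearGS pipeline",
                 paste0("seed: ", cfg$seed),
                 paste0("traits: ", paste(cfg$traits, collapse = ",")),
                 paste0("methods: ", paste(cfg$methods, collapse = ",")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  ## --- input ---
  if (isTRUE(cfg$sim)) {
    sim <- stage("simulate", {
      sc <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed), cfg$sim_args))
      sim_pear_population(sc)
    })
    g <- sim$genotypes; pheno <- sim$phenotypes; fams <- sim$families
    log_lines <- c(log_lines, "input: synthetic preset")
  } else {
    g <- stage("read_vcf", read_vcf(cfg$vcf))
    pheno <- stage("read_phenotypes", align_phenotypes(read_phenotypes(cfg$phenotypes), g))
    fams <- stage("read_families", read_families(cfg$families))
    log_lines <- c(log_lines, paste0("input: ", cfg$vcf))
  }
  families <- fams$family[match(individual_ids(g), fams$id)]
  ## --- qc ---
  g <- stage("qc", {
    gq <- filter_markers(g, cfg$qc$maf, cfg$qc$max_missing)
    impute_mode(gq)
  })
  log_lines <- c(log_lines, paste0("markers after QC: ", ncol(g$dosage)))
  ## --- structure ---
  K <- stage("kinship", vanraden_kinship(g))
  utils::write.table(data.frame(id = rownames(K), K, check.names = FALSE),
                     file.path(cfg$out_dir, "kinship.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pca <- stage("pca", genotype_pca(g, n_components = cfg$n_pcs))
  utils::write.table(data.frame(id = rownames(pca$scores), pca$scores,
                                check.names = FALSE),
                     file.path(cfg$out_dir, "pca.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ld <- stage("ld_decay", ld_decay(g))
  utils::write.table(ld, file.path(cfg$out_dir, "ld_decay.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ## --- per-trait GWAS + CV ---
  summary_rows <- list()
  for (tr in cfg$traits) {
    y <- pheno[[tr]]
    if (is.null(y)) stop("trait ", tr, " absent from phenotypes")
    ok <- !is.na(y)
    gk <- g[which(ok), ]
    Kk <- K[ok, ok]
    scan <- stage(paste0("mlm_", tr),
                  mlm_scan(y[ok], gk, covariates = pca$scores[ok, , drop = FALSE],
                           K = Kk))
    fdr <- bh_fdr(scan$p, cfg$fdr)
    scan$significant <- fdr$significant
    utils::write.table(scan, file.path(cfg$out_dir, paste0("mlm_", tr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    vbfit <- stage(paste0("vb_", tr),
                   fit_vbayesb(y[ok], gk, families[ok],
                               vb_hyper(seed = cfg$seed)))
    vbsum <- vb_effect_summary(vbfit, y[ok], gk, cfg$vb_threshold)
    utils::write.table(vbsum, file.path(cfg$out_dir, paste0("vb_", tr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    row <- data.frame(trait = tr, n = sum(ok),
                      mlm_hits = fdr$n_rejected, vb_hits = nrow(vbsum))
    if (isTRUE(cfg$cv)) {
      for (meth in cfg$methods) {
        cv <- stage(paste0("cv_", meth, "_", tr),
                    leave_one_family_out_cv(y, g, families, method = meth,
                                            hyper = vb_hyper(seed = cfg$seed)))
        utils::write.table(cv$per_family,
                           file.path(cfg$out_dir, paste0("cv_", meth, "_", tr, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        row[[paste0("cv_", meth, "_mean_r")]] <- cv$mean_r
        row[[paste0("cv_", meth, "_pooled_r")]] <- cv$pooled_r
      }
    }
    summary_rows[[tr]] <- row
  }
  summary <- do.call(rbind, summary_rows)
  utils::write.table(summary, file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))
  invisible(cfg$out_dir)
}
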