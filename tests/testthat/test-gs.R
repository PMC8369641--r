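test_that("GBLUP fitting validates its inputs", {
  g <- iid_geno(40, 100, seed = 1)
  expect_error(gblup_fit(rep(1, 40), g), "constant")
  expect_error(gblup_fit(rnorm(20), g[1:20, ]), ">= 30")
})

test_that("kinship-form GBLUP equals the marker-ridge formulation", {
  g <- iid_geno(60, 150, seed = 2)
  set.seed(3)
  y <- rnorm(60) + as.numeric(g$dosage[, 1:10] %*% rnorm(10, 0, 0.3))
  model <- gblup_fit(y, g)
  fitted_kin <- gblup_predict(model, g)
  # ridge on centered markers with lambda = delta * 2*sum(p(1-p))
  p <- colMeans(g$dosage) / 2
  poly <- p > 0 & p < 1
  W <- sweep(g$dosage[, poly], 2, 2 * p[poly])
  cc <- 2 * sum(p[poly] * (1 - p[poly]))
  b <- solve(crossprod(W) + model$delta * cc * diag(ncol(W)),
             crossprod(W, y - model$mu))
  fitted_rr <- model$mu + as.numeric(W %*% b)
  expect_equal(unname(fitted_kin), fitted_rr, tolerance = 1e-6)
})

test_that("GBLUP predictions equal an explicit dense mixed-model solve", {
  g <- iid_geno(60, 120, seed = 4)
  set.seed(5)
  y_all <- rnorm(60) + as.numeric(g$dosage[, 1:8] %*% rnorm(8, 0, 0.4))
  train <- 1:40; test <- 41:60
  g_tr <- g[train, ]; g_te <- g[test, ]
  model <- gblup_fit(y_all[train], g_tr)
  pred <- gblup_predict(model, g_te)
  # dense oracle: u_test = sg2 * K_ct V^-1 (y - mu)
  p <- colMeans(g_tr$dosage) / 2
  poly <- p > 0 & p < 1
  W_tr <- sweep(g_tr$dosage[, poly], 2, 2 * p[poly])
  W_te <- sweep(g_te$dosage[, poly], 2, 2 * p[poly])
  cc <- 2 * sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(W_tr) / cc; diag(K) <- diag(K) + 1e-8
  K_ct <- tcrossprod(W_te, W_tr) / cc
  V <- model$sigma2_g * K + model$sigma2_e * diag(length(train))
  u <- model$sigma2_g * K_ct %*% solve(V, y_all[train] - model$mu)
  expect_equal(unname(pred), model$mu + as.numeric(u), tolerance = 1e-8)
  # marker mismatch is rejected
  expect_error(gblup_predict(model, g_te[, 1:50]), "markers")
})

test_that("a test clone of a training individual gets its fitted value", {
  g <- iid_geno(50, 200, seed = 6)
  u_true <- as.numeric(scale(g$dosage) %*% rnorm(200, 0, 0.2))
  y <- 10 + u_true                          # noiseless genetic phenotype
  model <- gblup_fit(y, g)
  fitted <- gblup_predict(model, g)
  clone_dos <- g$dosage[c(7, 7), ]
  rownames(clone_dos) <- c("clone1", "clone2")
  clone <- genotype_matrix(clone_dos, g$map)
  pred <- gblup_predict(model, clone)
  expect_equal(unname(pred), rep(unname(fitted[7]), 2), tolerance = 1e-6)
})

test_that("a vanishing genetic variance makes every prediction the mean", {
  g <- iid_geno(40, 80, seed = 7)
  set.seed(8)
  model <- structure(list(mu = 5, sigma2_g = 1e-12, sigma2_e = 1,
                          delta = 1e12, K = vanraden_kinship(g),
                          y = rnorm(40, 5), g_train = g, map = g$map),
                     class = "gblup_model")
  pred <- gblup_predict(model, g)
  expect_equal(unname(pred), rep(5, 40), tolerance = 1e-6)
})

test_that("vBayesB predictions are weight-averaged marker sums", {
  g <- iid_geno(30, 5, seed = 9)
  fit <- structure(list(mu = 7, gamma = rep(0, 5), atilde = rnorm(5),
                        map = g$map, centers = colMeans(g$dosage)),
                   class = "vb_fit")
  expect_equal(unname(vb_predict(fit, g)), rep(7, 30))
  fit$gamma <- c(1, 0, 0, 0, 0)
  fit$atilde <- c(3, 0, 0, 0, 0)
  pred <- vb_predict(fit, g)
  expect_equal(unname(pred), 7 + 3 * (g$dosage[, 1] - mean(g$dosage[, 1])),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(vb_predict(fit, g[, 1:3]), "markers")
})

test_that("the CV accuracy rule truncates and handles degenerate folds", {
  acc <- pearGS:::.cv_accuracy
  obs <- c(1, 2, 3, 4)
  expect_equal(acc(obs, obs), 1)
  expect_equal(acc(-obs, obs), 0)            # negative r recorded as 0
  expect_equal(acc(rep(1, 4), obs), 0)       # constant predictions
  expect_equal(acc(obs[1:2], obs[1:2]), 0)   # too short to correlate
})

test_that("leave-one-family-out CV trains without the test family and adds a constant-shift invariance", {
  pop <- small_pop()
  ph <- pop$phenotypes
  g <- pop$genotypes
  cv <- leave_one_family_out_cv(ph$SUC, g, pop$families, method = "gblup")
  expect_equal(sort(cv$per_family$family), paste0("F0", 1:4))
  expect_true(all(cv$per_family$r >= 0 & cv$per_family$r <= 1))
  expect_gt(cv$pooled_r, 0)
  # adding a constant to y shifts mu only: identical accuracies
  cv2 <- leave_one_family_out_cv(ph$SUC + 100, g, pop$families, method = "gblup")
  expect_equal(cv2$per_family$r, cv$per_family$r, tolerance = 1e-6)
  # fewer than 2 F1 families is rejected
  expect_error(leave_one_family_out_cv(ph$SUC, g,
                                       rep("collection", nrow(g$dosage)),
                                       method = "gblup"), "families")
})

test_that("families with too few phenotyped members are skipped with a warning", {
  pop <- small_pop()
  ph <- pop$phenotypes$SUC
  fams <- pop$families
  ph[fams$family == "F03"] <- NA
  ph[which(fams$family == "F03")[1:2]] <- pop$phenotypes$SUC[which(fams$family == "F03")[1:2]]
  expect_warning(cv <- leave_one_family_out_cv(ph, pop$genotypes, fams,
                                               method = "gblup"),
                 "F03")
  expect_true(is.na(cv$per_family$r[cv$per_family$family == "F03"]))
})

test_that("vBayesB beats GBLUP when one QTL carries most of the genetic variance", {
  cfg <- sim_config(n_founders = 60, n_cultivars = 40,
                    family_sizes = c(60, 60, 60), n_chromosomes = 3,
                    chrom_length_bp = 3e7, n_markers_per_chrom = 70,
                    ld_range_bp = 250000, seed = 31)
  pop <- build_population(cfg, simulate_founders(cfg))
  g <- pop$genotypes
  fams <- pop$families$family
  test_idx <- which(fams == "F03")
  train_idx <- which(fams != "F03")
  maf <- marker_maf(g)
  wins <- 0
  for (r in 1:20) {
    set.seed(400 + r)
    j <- sample(which(maf > 0.2), 1)
    # one QTL carrying ~80% of the genetic variance (h2 = 0.6, QTL pve 0.5)
    y <- qtl_trait(g, j, pve = 0.5, h2 = 0.6, n_poly = 80, seed = 500 + r)
    gb <- gblup_predict(gblup_fit(y[train_idx], g[train_idx, ]), g[test_idx, ])
    vb <- vb_predict(fit_vbayesb(y[train_idx], g[train_idx, ],
                                 fams[train_idx], vb_hyper(seed = r)),
                     g[test_idx, ])
    acc <- pearGS:::.cv_accuracy
    wins <- wins + (acc(vb, y[test_idx]) >= acc(gb, y[test_idx]))
  }
  expect_gte(wins, 13)                      # one-sided sign test, 20 pairs
})

test_that("the pipeline runs end to end, deterministically, on a small preset", {
  out1 <- file.path(tempdir(), "pipe1")
  out2 <- file.path(tempdir(), "pipe2")
  cfg <- list(out_dir = out1, seed = 5, sim = TRUE,
              sim_args = list(n_founders = 40, n_cultivars = 40,
                              family_sizes = c(60, 60, 70, 70),
                              n_chromosomes = 3, chrom_length_bp = 3e7,
                              n_markers_per_chrom = 60),
              traits = c("SUC", "HarT"), methods = "gblup", cv = TRUE)
  # QTLs of the default trait model live on a 17-chromosome genome; the
  # 3-chromosome test genome must fail loudly at the simulate stage
  expect_error(run_pipeline(cfg), "stage")
  cfg$sim_args$n_chromosomes <- 17
  cfg$sim_args$n_markers_per_chrom <- 30
  run_pipeline(cfg)
  expect_true(file.exists(file.path(out1, "summary.tsv")))
  expect_true(file.exists(file.path(out1, "mlm_SUC.tsv")))
  expect_true(file.exists(file.path(out1, "vb_HarT.tsv")))
  expect_true(file.exists(file.path(out1, "cv_gblup_SUC.tsv")))
  smry <- read.delim(file.path(out1, "summary.tsv"))
  expect_equal(smry$trait, c("SUC", "HarT"))
  expect_true(all(smry$cv_gblup_pooled_r >= 0))
  # bit-identical rerun
  cfg$out_dir <- out2
  run_pipeline(cfg)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)),
                     label = f)
  }
  # unknown trait is rejected by name
  expect_error(run_pipeline(list(out_dir = out1, sim = TRUE, traits = "BRIX")),
               "BRIX")
  unlink(c(out1, out2), recursive = TRUE)
})
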