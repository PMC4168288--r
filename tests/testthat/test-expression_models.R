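# Linear and additive models: exact OLS recovery, cross-validation fold
# mechanics, GAM nesting/limit behaviour, residual association and
# stratification.

test_that("OLS recovers a noiseless linear truth and matches the normal equations", {
  ft <- rand_features(200, beta = c(2, -1), sd_noise = 0, seed = 41)
  fit <- fit_delta_lm(ft)
  expect_equal(unname(fit$coefficients), c(2, -1), tolerance = 1e-8)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(fit$r2_train, 1, tolerance = 1e-10)

  ft2 <- rand_features(200, beta = rnorm(10), sd_noise = 1, seed = 42)
  fit2 <- fit_delta_lm(ft2)
  X <- cbind(1, as.matrix(ft2[, paste0("dtf_TF", 1:10)]))
  beta_hat <- solve(t(X) %*% X, t(X) %*% ft2$delta_ge)  # normal-equations oracle
  expect_equal(unname(c(fit2$intercept, fit2$coefficients)), unname(drop(beta_hat)),
               tolerance = 1e-8)
  # residual orthogonality to every design column
  expect_lt(max(abs(t(X) %*% fit2$residuals)), 1e-8 * nrow(X))
})

test_that("constant responses give zero slopes, and collinear designs are refused by name", {
  ft <- rand_features(100, beta = c(1, 1), seed = 43)
  ft$delta_ge <- 5
  fit <- fit_delta_lm(ft)
  expect_equal(unname(fit$coefficients), c(0, 0), tolerance = 1e-10)
  expect_equal(fit$intercept, 5, tolerance = 1e-10)

  ft2 <- rand_features(100, beta = c(1, 1, 1), seed = 44)
  ft2$dtf_TF3 <- ft2$dtf_TF1 + ft2$dtf_TF2
  expect_error(fit_delta_lm(ft2), "collinear")
  expect_error(fit_delta_lm(rand_features(8, beta = rep(1, 10), seed = 1),
                            min_genes_per_tf = 0), "too few")
})

test_that("degenerate predictors (TFs binding too few genes) are dropped with a warning", {
  ft <- rand_features(100, beta = c(1, 1), seed = 45)
  ft$dtf_TF2[6:100] <- 0  # TF2 bound in 5 genes only
  expect_warning(fit <- fit_delta_lm(ft), "TF2")
  expect_equal(names(fit$coefficients), "TF1")
})

test_that("CV folds partition the rows at 10% each and results are seed-deterministic", {
  ft <- rand_features(1000, beta = rep(0.5, 10), sd_noise = 1, seed = 46)
  cv <- cv_r2(ft, "linear", k = 10, seed = 7)
  expect_length(cv$folds, 10L)
  expect_true(all(lengths(cv$folds) == 100L))
  expect_setequal(unlist(cv$folds), 1:1000)
  expect_true(all(cv$r2_fold >= 0 & cv$r2_fold <= 1))
  cv2 <- cv_r2(ft, "linear", k = 10, seed = 7)
  expect_identical(cv$r2_fold, cv2$r2_fold)
  # remainder rows spread one per fold from the first
  cv3 <- cv_r2(rand_features(103, beta = c(1, 1), seed = 47), "linear", k = 10, seed = 1)
  expect_equal(sort(unname(lengths(cv3$folds)), decreasing = TRUE),
               c(11, 11, 11, rep(10, 7)))
})

test_that("perfect linear data give per-fold R-squared of 1; constant folds are an error", {
  ft <- rand_features(200, beta = c(1.5, -0.5), sd_noise = 0, seed = 48)
  cv <- cv_r2(ft, "linear", k = 10, seed = 1)
  expect_equal(cv$r2_fold, rep(1, 10), tolerance = 1e-9)
  expect_equal(cv$r2_holdout_fold, rep(1, 10), tolerance = 1e-9)

  ftc <- rand_features(100, beta = c(1, 1), seed = 49)
  ftc$delta_ge <- 2
  expect_error(cv_r2(ftc, "linear", k = 5, seed = 1), "fold 1")
  expect_error(cv_r2(ft, "linear", k = 1), "k must be")
})

test_that("a GAM on linear truth is no worse than OLS (splines nest the linear fit)", {
  ft <- rand_features(800, beta = c(0.8, -0.6, 0.4), sd_noise = 1, seed = 50)
  lm_fit <- fit_delta_lm(ft, min_tfs = 0)
  gam_fit <- fit_delta_gam(ft, min_tfs = 0)
  expect_gte(gam_fit$adjusted_r2, lm_fit$r2_train - 0.02)
})

test_that("heavy smoothing collapses the GAM onto the linear fit", {
  ft <- rand_features(400, beta = c(0.7, -0.7), sd_noise = 1, seed = 51)
  lm_fit <- fit_delta_lm(ft, min_tfs = 0)
  gam_fit <- fit_delta_gam(ft, min_tfs = 0, sp = 1e10)
  expect_lt(max(abs(gam_fit$fitted - lm_fit$fitted)), 1e-3)
})

test_that("interaction smooths capture planted product terms the additive GAM misses", {
  tr <- synthetic_truth(seed = 52, n_genes = 1200, n_tfs = 3,
                        linear_coefficients = 0.4,
                        interaction_effects = data.frame(i = 1, j = 2, gamma = 0.8),
                        noise_sd = 0.6)
  ft <- simulate_feature_table(tr)$features
  g0 <- fit_delta_gam(ft, min_tfs = 0, interactions = FALSE)
  g1 <- fit_delta_gam(ft, min_tfs = 0, interactions = TRUE)
  expect_gt(g1$adjusted_r2, g0$adjusted_r2 + 0.03)
  expect_equal(sum(grepl("^ti\\(", names(g1$term_pvalues))), 3L)  # 3 TF pairs
  # the informative pair is flagged by its term p-value
  p_ti <- g1$term_pvalues[grepl("^ti\\(", names(g1$term_pvalues))]
  expect_equal(unname(which.min(p_ti)), which(grepl("TF01.*TF02", names(p_ti))))
})

test_that("predict() on new data matches the training fit for both model classes", {
  ft <- rand_features(300, beta = c(1, -1), sd_noise = 0.5, seed = 53)
  lm_fit <- fit_delta_lm(ft, min_tfs = 0)
  expect_equal(unname(predict(lm_fit, newdata = ft)), unname(lm_fit$fitted),
               tolerance = 1e-10)
  gam_fit <- fit_delta_gam(ft, min_tfs = 0)
  expect_equal(unname(predict(gam_fit, newdata = ft)), unname(gam_fit$fitted),
               tolerance = 1e-6)
})

test_that("residual association reproduces the closed-form 2x2 chi-square", {
  # fixed table [[30,10],[10,30]] -> chi2 = 20
  res <- c(rep(0, 40), rep(9, 40))                    # 40 well-predicted, 40 not
  mark <- c(rep(c(TRUE, FALSE), c(30, 10)), rep(c(TRUE, FALSE), c(10, 30)))
  ra <- residual_association(res, mark, residual_cut = 1.5)
  expect_equal(ra$chi2, 20, tolerance = 1e-12)
  expect_equal(ra$chi2, oracle_chi2(ra$table), tolerance = 1e-12)

  set.seed(54)
  for (rep in 1:20) {
    r <- rnorm(300); m <- runif(300) < 0.4
    ra <- residual_association(r, m)
    expect_equal(ra$chi2, oracle_chi2(ra$table), tolerance = 1e-10)
  }
  expect_error(residual_association(rep(0, 50), runif(50) < 0.5), "margin")
})

test_that("residual stratification by extra-TF peak count summarises each bin", {
  res <- c(1, 1, 0, 0, -2)
  counts <- c(3, 5, 0, 0, 2)
  s <- stratify_residuals(res, counts)
  expect_equal(s$bin, c("0", "1-2", ">2"))
  expect_equal(s$n, c(2L, 1L, 2L))
  expect_equal(s$mean_residual, c(0, -2, 1))
  empty <- stratify_residuals(c(1, 2), c(5, 6))
  expect_equal(empty$n[empty$bin == "0"], 0L)
  expect_true(is.na(empty$mean_residual[empty$bin == "0"]))

  # a planted mean shift in the >2 bin is recovered within 3 SEM
  set.seed(55)
  cnt <- sample(0:5, 2000, TRUE)
  r <- rnorm(2000) + ifelse(cnt > 2, 1, 0)
  s2 <- stratify_residuals(r, cnt)
  sem <- 1 / sqrt(s2$n[s2$bin == ">2"])
  expect_lt(abs(s2$mean_residual[s2$bin == ">2"] - 1), 3 * sem)
})
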