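# Predictive models of delta-GE from per-TF delta-TF features: multiple
# linear regression (OLS) with tenfold cross-validation, and Gaussian
# generalised additive models with per-TF smooths and optional pairwise
# tensor-product interaction smooths, penalties selected by REML (mgcv).

# Design preparation shared by both fitters: filter by bound-TF count,
# sanitise column names for formula use, drop degenerate predictors (TFs
# bound in fewer than min_genes_per_tf of the retained genes).
.prepare_design <- function(features, min_tfs, min_genes_per_tf = 10) {
  stopifnot(inherits(features, "gene_features"))
  tfs <- attr(features, "tfs")
  ff <- features[features$n_tfs_bound >= min_tfs, , drop = FALSE]
  if (nrow(ff) == 0L) stop(sprintf("no genes bound by >= %d TFs", min_tfs))
  cols <- paste0("dtf_", tfs)
  safe <- make.names(cols, unique = TRUE)
  x <- as.matrix(ff[, cols, drop = FALSE])
  colnames(x) <- safe
  n_bound <- colSums(x != 0)
  keep <- n_bound >= min_genes_per_tf
  if (!all(keep)) {
    warning(sprintf("dropping degenerate predictor(s) bound in < %d genes: %s",
                    min_genes_per_tf, paste(tfs[!keep], collapse = ", ")))
  }
  if (!any(keep)) stop("all predictors degenerate after filtering")
  list(gene_id = ff$gene_id, x = x[, keep, drop = FALSE],
       y = ff$delta_ge, tfs = tfs[keep], safe = safe[keep])
}

#' Fit the multiple linear regression of delta-GE on per-TF delta-TF
#'
#' Ordinary least squares of `delta_ge ~ intercept + dtf_TF1 + ... + dtf_TFT`
#' over the genes bound by at least `min_tfs` TFs.
#'
#' @param features `gene_features` table from [build_feature_table()] or
#'   [simulate_feature_table()].
#' @param min_tfs minimum bound-TF count of the genes entering the fit.
#' @param min_genes_per_tf TFs bound in fewer retained genes than this are
#'   dropped from the design with a warning.
#' @return object of class `delta_lm`: coefficients, per-gene fitted values
#'   and residuals, training R-squared, and the underlying [stats::lm] fit.
#' @export
fit_delta_lm <- function(features, min_tfs = 1, min_genes_per_tf = 10) {
  d <- .prepare_design(features, min_tfs, min_genes_per_tf)
  if (nrow(d$x) <= ncol(d$x) + 1L) {
    stop(sprintf("too few genes (%d) for %d predictors", nrow(d$x), ncol(d$x)))
  }
  X <- cbind(`(Intercept)` = 1, d$x)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  df <- data.frame(delta_ge = d$y, d$x, check.names = FALSE)
  fit <- stats::lm(delta_ge ~ ., data = df)
  tss <- sum((d$y - mean(d$y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(list(
    call = match.call(),
    lm = fit,
    intercept = unname(stats::coef(fit)[1L]),
    coefficients = stats::setNames(stats::coef(fit)[-1L], d$tfs),
    fitted = stats::setNames(unname(stats::fitted(fit)), d$gene_id),
    residuals = stats::setNames(unname(stats::residuals(fit)), d$gene_id),
    r2_train = r2,
    sigma = suppressWarnings(summary(fit)$sigma),
    gene_id = d$gene_id, tfs = d$tfs, safe = d$safe,
    min_tfs = min_tfs, n = nrow(d$x)
  ), class = "delta_lm")
}

#' @export
print.delta_lm <- function(x, ...) {
  cat(sprintf("delta_lm: delta-GE ~ %d TF delta-TF predictors, %d genes (>= %d TFs bound)\n",
              length(x$coefficients), x$n, x$min_tfs))
  cat(sprintf("training R-squared: %.3f\n", x$r2_train))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' @export
summary.delta_lm <- function(object, ...) summary(object$lm, ...)

#' @export
coef.delta_lm <- function(object, ...) c(`(Intercept)` = object$intercept, object$coefficients)

#' @export
residuals.delta_lm <- function(object, ...) object$residuals

#' @export
fitted.delta_lm <- function(object, ...) object$fitted

#' @export
predict.delta_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x <- as.matrix(newdata[, paste0("dtf_", object$tfs), drop = FALSE])
  drop(object$intercept + x %*% object$coefficients)
}

#' @export
plot.delta_lm <- function(x, ...) {
  obs <- x$fitted + x$residuals
  plot(obs, x$fitted, xlab = "observed delta-GE", ylab = "predicted delta-GE",
       main = sprintf("linear model, R2 = %.3f", x$r2_train), pch = 16,
       cex = 0.4, ...)
  abline(0, 1, col = "red")
  invisible(x)
}

#' @export
simulate.delta_lm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  out <- as.data.frame(replicate(nsim, object$fitted + stats::rnorm(n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$gene_id
  out
}

# Build the GAM formula over sanitised predictor names.
.gam_formula <- function(safe, interactions, k_main, k_int) {
  mains <- sprintf("s(%s, bs = 'cr', k = %d)", safe, k_main)
  terms <- mains
  if (interactions && length(safe) >= 2L) {
    pairs <- utils::combn(safe, 2L)
    ints <- sprintf("ti(%s, %s, k = %d)", pairs[1L, ], pairs[2L, ], k_int)
    terms <- c(terms, ints)
  }
  stats::as.formula(paste("delta_ge ~", paste(terms, collapse = " + ")))
}

#' Fit the generalised additive model of delta-GE on delta-TF smooths
#'
#' Gaussian GAM (identity link) with one cubic-regression-spline smooth per
#' TF and, optionally, one interaction-only tensor-product smooth per
#' unordered TF pair (45 pairs for 10 TFs). Smoothing parameters are selected
#' by restricted maximum likelihood. Only genes bound by at least `min_tfs`
#' TFs enter the fit (default 2: genes bound by a single TF cannot inform
#' interactions).
#'
#' @inheritParams fit_delta_lm
#' @param interactions include pairwise interaction smooths?
#' @param k_main basis dimension of each univariate smooth.
#' @param k_int marginal basis dimension of each tensor-product interaction
#'   smooth.
#' @param method smoothing-parameter selection criterion (`"REML"` default,
#'   `"GCV.Cp"` as fallback).
#' @param sp optional fixed smoothing parameters (scalar recycled to every
#'   penalty); mainly for studying the heavy-smoothing limit, where the fit
#'   collapses onto the linear model.
#' @return object of class `delta_gam`: the [mgcv::gam] fit, adjusted
#'   R-squared, per-term effective degrees of freedom and approximate
#'   p-values, fitted values and residuals.
#' @export
fit_delta_gam <- function(features, min_tfs = 2, interactions = FALSE,
                          k_main = 10, k_int = 4, method = "REML", sp = NULL,
                          min_genes_per_tf = 10) {
  d <- .prepare_design(features, min_tfs, min_genes_per_tf)
  fml <- .gam_formula(d$safe, interactions, k_main, k_int)
  df <- data.frame(delta_ge = d$y, d$x, check.names = FALSE)
  if (!is.null(sp) && length(sp) == 1L) {
    n_sp <- length(d$safe) +
      if (interactions && length(d$safe) >= 2L) 2L * ncol(utils::combn(d$safe, 2L)) else 0L
    sp <- rep(sp, n_sp)
  }
  fit <- mgcv::gam(fml, data = df, family = stats::gaussian(), method = method,
                   sp = sp)
  smry <- summary(fit)
  structure(list(
    call = match.call(),
    gam = fit,
    adjusted_r2 = unname(smry$r.sq),
    edf = stats::setNames(smry$edf, rownames(smry$s.table)),
    term_pvalues = stats::setNames(smry$s.table[, "p-value"], rownames(smry$s.table)),
    fitted = stats::setNames(unname(stats::fitted(fit)), d$gene_id),
    residuals = stats::setNames(unname(stats::residuals(fit)), d$gene_id),
    smoothing_params = fit$sp,
    interactions = interactions,
    gene_id = d$gene_id, tfs = d$tfs, safe = d$safe,
    min_tfs = min_tfs, n = nrow(d$x)
  ), class = "delta_gam")
}

#' @export
print.delta_gam <- function(x, ...) {
  cat(sprintf("delta_gam: %d TF smooths%s, %d genes (>= %d TFs bound)\n",
              length(x$tfs),
              if (x$interactions) sprintf(" + %d pairwise interaction smooths",
                                          sum(grepl("^ti\\(", names(x$term_pvalues)))) else "",
              x$n, x$min_tfs))
  cat(sprintf("adjusted R-squared: %.3f\n", x$adjusted_r2))
  invisible(x)
}

#' @export
summary.delta_gam <- function(object, ...) summary(object$gam, ...)

#' @export
coef.delta_gam <- function(object, ...) stats::coef(object$gam)

#' @export
residuals.delta_gam <- function(object, ...) object$residuals

#' @export
fitted.delta_gam <- function(object, ...) object$fitted

#' @export
predict.delta_gam <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  nd <- as.data.frame(newdata[, paste0("dtf_", object$tfs), drop = FALSE])
  names(nd) <- object$safe
  as.numeric(mgcv::predict.gam(object$gam, newdata = nd))
}

#' @export
plot.delta_gam <- function(x, ...) {
  mgcv::plot.gam(x$gam, pages = 1, ...)
  invisible(x)
}

#' k-fold cross-validated prediction accuracy
#'
#' Rows of the filtered feature table are shuffled once under `seed` and
#' split into `k` disjoint folds covering all rows (remainder rows spread one
#' per fold from the first). Each fold is predicted from a model trained on
#' its complement; the per-fold accuracy is the squared Pearson correlation
#' between held-out observed and predicted delta-GE, and the reported
#' accuracy is the mean over folds. The holdout `1 - RSS/TSS` variant is
#' reported alongside.
#'
#' @inheritParams fit_delta_gam
#' @param method `"linear"` or `"gam"`.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the single shuffle.
#' @param ... passed to the underlying fitter.
#' @return object of class `cv_r2`: `r2_mean`, `r2_fold`, `r2_holdout_mean`,
#'   `r2_holdout_fold`, `folds` (list of row indices into the filtered
#'   table).
#' @export
cv_r2 <- function(features, method = c("linear", "gam"), k = 10, seed = 1,
                  min_tfs = 1, interactions = FALSE, min_genes_per_tf = 10, ...) {
  method <- match.arg(method)
  if (k < 2L) stop("k must be >= 2")
  d <- .prepare_design(features, min_tfs, min_genes_per_tf)
  ff <- features[match(d$gene_id, features$gene_id), , drop = FALSE]
  ff <- structure(ff, class = class(features), tfs = d$tfs)
  n <- nrow(ff)
  if (n < 2L * k) stop(sprintf("need >= %d rows for %d-fold CV, have %d", 2L * k, k, n))
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
  folds <- split(perm, rep(seq_len(k), times = sizes))
  r2 <- r2h <- numeric(k)
  for (i in seq_len(k)) {
    test <- folds[[i]]
    train <- ff[-test, , drop = FALSE]
    train <- structure(train, class = class(ff), tfs = d$tfs)
    fit <- if (method == "linear") {
      fit_delta_lm(train, min_tfs = 0, min_genes_per_tf = 0)
    } else {
      fit_delta_gam(train, min_tfs = 0, interactions = interactions,
                    min_genes_per_tf = 0, ...)
    }
    pred <- predict(fit, newdata = ff[test, , drop = FALSE])
    obs <- ff$delta_ge[test]
    if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
      stop(sprintf("fold %d has constant observed or predicted values; R-squared undefined", i))
    }
    r2[i] <- stats::cor(obs, pred)^2
    r2h[i] <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
  structure(list(r2_mean = mean(r2), r2_fold = r2,
                 r2_holdout_mean = mean(r2h), r2_holdout_fold = r2h,
                 folds = folds, k = k, method = method, seed = seed),
            class = "cv_r2")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_r2 <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s model): mean R-squared %.3f (per fold: %s)\n",
              x$k, x$method, x$r2_mean,
              paste(sprintf("%.3f", x$r2_fold), collapse = ", ")))
  invisible(x)
}

#' Chi-square association between model predictability and a gene mark
#'
#' Genes are called well-predicted when their absolute model residual is at
#' most `residual_cut`; the 2x2 table of well-predicted against the supplied
#' binary mark (e.g. high H3K27ac in at least one cell type) is tested with
#' Pearson's chi-square (df = 1, no continuity correction).
#'
#' @param fit `delta_lm` or `delta_gam` (or any object with a
#'   [stats::residuals()] method), or a bare residual vector.
#' @param mark_high per-gene logical mark, aligned with the fit's genes.
#' @param residual_cut absolute-residual threshold for "well predicted".
#' @return object of class `residual_association`: `table` (2x2), `chi2`,
#'   `pvalue`.
#' @export
residual_association <- function(fit, mark_high, residual_cut = 1.5) {
  res <- if (is.numeric(fit)) fit else stats::residuals(fit)
  stopifnot(length(mark_high) == length(res), is.logical(mark_high))
  well <- abs(res) <= residual_cut
  tab <- table(well_predicted = factor(well, c(FALSE, TRUE)),
               mark_high = factor(mark_high, c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in the 2x2 table; chi-square test undefined")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  structure(list(table = tab, chi2 = unname(ct$statistic),
                 pvalue = unname(ct$p.value), residual_cut = residual_cut),
            class = "residual_association")
}

#' @export
print.residual_association <- function(x, ...) {
  cat(sprintf("residual_association (|residual| <= %g): chi2 = %.3f, p = %.3g\n",
              x$residual_cut, x$chi2, x$pvalue))
  print(x$table)
  invisible(x)
}

#' Residual summaries stratified by extra-TF binding-peak count
#'
#' Genes are binned by the number of binding peaks of an additional TF
#' (e.g. MITF or c-FOS) in their loci — `0`, `1-2`, `>2` — and per-bin
#' residual summaries are reported, suitable for overlaying extra-TF binding
#' on model residuals.
#'
#' @param fit `delta_lm`/`delta_gam` or residual vector.
#' @param peak_counts per-gene non-negative integer peak counts, aligned with
#'   the fit's genes.
#' @return data frame with one row per bin: `bin`, `n`, `mean_residual`,
#'   `median_residual` (NA summaries for empty bins).
#' @export
stratify_residuals <- function(fit, peak_counts) {
  res <- if (is.numeric(fit)) fit else stats::residuals(fit)
  stopifnot(length(peak_counts) == length(res), all(peak_counts >= 0))
  bin <- cut(peak_counts, breaks = c(-Inf, 0, 2, Inf), labels = c("0", "1-2", ">2"))
  out <- data.frame(bin = levels(bin),
                    n = as.integer(table(bin)),
                    mean_residual = as.numeric(tapply(res, bin, mean)),
                    median_residual = as.numeric(tapply(res, bin, stats::median)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
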