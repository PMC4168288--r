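# Differential scores and the modelling feature table. Both contrasts are
# pseudocounted log2 ratios with cell type B in the numerator, so positive
# values mean "higher in B" for expression and binding alike; swapping the
# cell-type labels negates every score.

#' Differential gene expression (delta-GE)
#'
#' `log2((fpkm_b + pseudocount) / (fpkm_a + pseudocount))`; positive values
#' mean higher expression in cell type B.
#'
#' @param fpkm_a,fpkm_b non-negative fpkm vectors.
#' @param pseudocount non-negative stabiliser added to both sides.
#' @return numeric vector of delta-GE values.
#' @export
delta_expression <- function(fpkm_a, fpkm_b, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(fpkm_a < 0) || any(fpkm_b < 0)) stop("fpkm values must be >= 0")
  log2((fpkm_b + pseudocount) / (fpkm_a + pseudocount))
}

#' Per-region differential binding (delta-TF) for one TF
#'
#' `log2((cov_B + pseudocount) / (cov_A + pseudocount))` on the atlas's
#' normalised coverage, where A and B are the TF's two cell-type samples.
#'
#' @param atlas `coverage_atlas` containing both cell-type columns of the TF.
#' @param tf TF name.
#' @param cell_types length-2 character vector naming cell types (A, B); the
#'   contrast is B over A. Defaults to the order of first appearance in the
#'   atlas samples.
#' @param pseudocount non-negative stabiliser.
#' @return numeric vector with one delta-TF score per atlas region.
#' @export
delta_binding_region <- function(atlas, tf, cell_types = NULL, pseudocount = 1) {
  stopifnot(inherits(atlas, "coverage_atlas"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  s <- atlas$samples
  if (is.null(cell_types)) cell_types <- unique(s$cell_type)
  if (length(cell_types) != 2L) stop("exactly 2 cell types required")
  ia <- which(s$tf == tf & s$cell_type == cell_types[1L])
  ib <- which(s$tf == tf & s$cell_type == cell_types[2L])
  if (length(ia) != 1L || length(ib) != 1L) {
    stop(sprintf("atlas lacks a unique sample column for TF '%s' in each cell type", tf))
  }
  unname(log2((atlas$matrix[, ib] + pseudocount) / (atlas$matrix[, ia] + pseudocount)))
}

#' Gene-level delta-TF by averaging over the gene's TF-bound regions
#'
#' The per-gene score is the arithmetic mean of per-region delta-TF over the
#' regions assigned to the gene in which the TF has a called peak in at least
#' one cell type. Genes with no such region score exactly 0 and are flagged
#' unbound.
#'
#' @param region_scores per-region delta-TF vector (atlas region order).
#' @param map `region_gene_map` on the same atlas.
#' @param tf_bound per-region logical: TF has a called peak in the region.
#' @return data frame `gene_id`, `score`, `bound`.
#' @export
delta_binding_gene <- function(region_scores, map, tf_bound) {
  stopifnot(inherits(map, "region_gene_map"),
            length(region_scores) == attr(map, "n_regions"),
            length(tf_bound) == length(region_scores))
  genes <- sort(unique(map$entries$gene_id))
  e <- map$entries[tf_bound[map$entries$region], , drop = FALSE]
  means <- tapply(region_scores[e$region], e$gene_id, mean)
  out <- data.frame(gene_id = genes,
                    score = ifelse(genes %in% names(means), unname(means[genes]), 0),
                    bound = genes %in% names(means),
                    stringsAsFactors = FALSE)
  out$score[!out$bound] <- 0
  out
}

#' Classify expression into the four cell-type-specificity categories
#'
#' Category IV: not expressed (both fpkm below `min_fpkm`). Categories II and
#' III: cell-type-specific — significant with fold change >= `min_fold`
#' (II higher in cell type A, III higher in B); this takes precedence over
#' category I when both apply. Category I: comparable expression in both cell
#' types (everything else).
#'
#' @param fpkm_a,fpkm_b non-negative fpkm vectors.
#' @param significant logical differential-expression flags (pre-computed).
#' @param min_fpkm expression floor.
#' @param min_fold minimal fold change (ratio of larger to smaller fpkm) for
#'   cell-type-specific calls.
#' @return character vector in `{"I","II","III","IV"}`.
#' @export
categorize_expression <- function(fpkm_a, fpkm_b, significant,
                                  min_fpkm = 2, min_fold = 4) {
  if (any(fpkm_a < 0) || any(fpkm_b < 0)) stop("fpkm values must be >= 0")
  n <- length(fpkm_a)
  stopifnot(length(fpkm_b) == n, length(significant) == n)
  hi <- pmax(fpkm_a, fpkm_b); lo <- pmin(fpkm_a, fpkm_b)
  fold <- ifelse(lo == 0, ifelse(hi > 0, Inf, 1), hi / lo)
  out <- rep("I", n)
  specific <- significant & fold >= min_fold
  out[specific & fpkm_a >= fpkm_b] <- "II"
  out[specific & fpkm_b > fpkm_a] <- "III"
  out[hi < min_fpkm] <- "IV"
  out
}

#' Collapse transcript-level expression records to one per gene
#'
#' @param expr expression data frame (possibly several rows per gene).
#' @param method `"max"` keeps the transcript with the largest summed fpkm;
#'   `"mean"` averages fpkm over transcripts. Significance is OR-ed under
#'   `"mean"`.
#' @return one row per gene.
#' @export
collapse_expression <- function(expr, method = c("max", "mean")) {
  method <- match.arg(method)
  if (!anyDuplicated(expr$gene_id)) return(expr)
  parts <- split(expr, expr$gene_id)
  rows <- lapply(parts, function(p) {
    if (method == "max") {
      p[which.max(p$fpkm_a + p$fpkm_b), , drop = FALSE]
    } else {
      data.frame(gene_id = p$gene_id[1L], fpkm_a = mean(p$fpkm_a),
                 fpkm_b = mean(p$fpkm_b), significant = any(p$significant),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the gene feature table for modelling
#'
#' One row per gene: the per-TF delta-TF vector (exact 0 for unbound TFs),
#' bound-TF count, delta-GE response, and expression category. The table can
#' be filtered by `n_tfs_bound >= k`; tables at successive thresholds nest.
#'
#' @param gene_scores named list (by TF) of data frames from
#'   [delta_binding_gene()].
#' @param delta_ge data frame `gene_id`, `delta_ge`.
#' @param categories data frame `gene_id`, `category` (optional).
#' @return data frame of class `gene_features` with columns `gene_id`,
#'   `dtf_<TF>` ..., `n_tfs_bound`, `delta_ge`, `category`; TF names kept in
#'   `attr(, "tfs")`.
#' @export
build_feature_table <- function(gene_scores, delta_ge, categories = NULL) {
  stopifnot(is.list(gene_scores), !is.null(names(gene_scores)))
  tfs <- names(gene_scores)
  genes <- sort(unique(gene_scores[[1L]]$gene_id))
  for (tf in tfs) {
    if (!setequal(gene_scores[[tf]]$gene_id, genes)) {
      stop(sprintf("gene universe mismatch for TF '%s'", tf))
    }
  }
  miss <- setdiff(genes, delta_ge$gene_id)
  if (length(miss) > 0L) {
    stop(sprintf("no delta-GE for gene(s): %s", paste(utils::head(miss, 5L), collapse = ", ")))
  }
  dtf <- sapply(tfs, function(tf) {
    s <- gene_scores[[tf]]
    s$score[match(genes, s$gene_id)]
  })
  bound <- sapply(tfs, function(tf) {
    s <- gene_scores[[tf]]
    s$bound[match(genes, s$gene_id)]
  })
  dtf <- matrix(dtf, nrow = length(genes),
                dimnames = list(NULL, paste0("dtf_", tfs)))
  out <- data.frame(gene_id = genes, dtf, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out$n_tfs_bound <- as.integer(rowSums(matrix(bound, nrow = length(genes))))
  out$delta_ge <- delta_ge$delta_ge[match(genes, delta_ge$gene_id)]
  out$category <- if (is.null(categories)) NA_character_ else
    categories$category[match(genes, categories$gene_id)]
  structure(out, class = c("gene_features", "data.frame"), tfs = tfs)
}

#' Filter a feature table by minimum bound-TF count
#'
#' @param features `gene_features` table.
#' @param min_tfs threshold on `n_tfs_bound`.
#' @return filtered `gene_features` table (warns when empty).
#' @export
filter_features <- function(features, min_tfs) {
  out <- features[features$n_tfs_bound >= min_tfs, , drop = FALSE]
  if (nrow(out) == 0L) warning(sprintf("no genes bound by >= %d TFs", min_tfs))
  structure(out, class = class(features), tfs = attr(features, "tfs"))
}

#' @export
print.gene_features <- function(x, ...) {
  cat(sprintf("gene_features: %d genes x %d TFs; bound-TF counts: %s\n",
              nrow(x), length(attr(x, "tfs")),
              paste(names(table(x$n_tfs_bound)), table(x$n_tfs_bound),
                    sep = ":", collapse = " ")))
  invisible(x)
}
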