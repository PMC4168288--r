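# Peak-to-gene assignment: promoter window, intragenic, then nearest gene on
# each side within 50 kb; remaining regions stay unassigned. Derived from the
# assignments: per-gene bound-TF incidence and bound-gene sets.

#' Assign atlas regions to genes
#'
#' Rule precedence per region: (1) overlap (>= 1 bp) with the closed TSS
#' window `[tss - tss_window, tss + tss_window]` or with a gene body assigns
#' the region to that gene (all such genes; rule recorded as `tss_window` or
#' `intragenic`, the TSS window taking precedence when both hold for the same
#' gene); (2) otherwise the region is assigned to the nearest gene on each
#' side whose body edge is within `max_distance` bp of the region edge
#' (`nearest_5p` for the lower-coordinate side, `nearest_3p` for the higher;
#' equidistant ties broken by smaller gene_id); (3) otherwise unassigned.
#'
#' @param regions merged region data frame (ordered; `region_id` optional).
#' @param genes gene model data frame from [read_genes()].
#' @param tss_window half-width of the promoter window in bp.
#' @param max_distance maximal region-edge-to-gene-edge gap in bp for the
#'   nearest-gene rule.
#' @return object of class `region_gene_map`: `entries` data frame
#'   (`region` index, `region_id`, `gene_id`, `rule`) and `unassigned`
#'   integer vector of region indices; `n_regions` kept as an attribute.
#' @export
assign_regions <- function(regions, genes, tss_window = 1000, max_distance = 50000) {
  validate_intervals(regions, what = "region")
  n <- nrow(regions)
  region_id <- if (!is.null(regions$region_id)) regions$region_id else
    sprintf("region_%d", seq_len(n))
  empty <- data.frame(region = integer(), region_id = character(),
                      gene_id = character(), rule = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(entries = empty, unassigned = integer()),
                     class = "region_gene_map", n_regions = 0L))
  }
  if (nrow(genes) == 0L) {
    return(structure(list(entries = empty, unassigned = seq_len(n)),
                     class = "region_gene_map", n_regions = n))
  }
  stopifnot(all(c("gene_id", "chrom", "start", "end", "tss") %in% names(genes)))
  lv <- union(unique(as.character(regions$chrom)), unique(as.character(genes$chrom)))
  rg <- .as_granges(regions, lv)

  # Rule 1a: closed TSS window [tss - w, tss + w] -> half-open [tss-w, tss+w+1)
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0L, genes$tss - as.integer(tss_window)),
                    end = genes$tss + as.integer(tss_window) + 1L)
  h_win <- GenomicRanges::findOverlaps(rg, .as_granges(win, lv))
  # Rule 1b: gene body overlap
  h_body <- GenomicRanges::findOverlaps(rg, .as_granges(genes, lv))
  e1 <- data.frame(region = S4Vectors::queryHits(h_win),
                   gene_id = genes$gene_id[S4Vectors::subjectHits(h_win)],
                   rule = rep("tss_window", length(h_win)), stringsAsFactors = FALSE)
  e2 <- data.frame(region = S4Vectors::queryHits(h_body),
                   gene_id = genes$gene_id[S4Vectors::subjectHits(h_body)],
                   rule = rep("intragenic", length(h_body)), stringsAsFactors = FALSE)
  rule1 <- rbind(e1, e2)
  # tss_window takes precedence for the same (region, gene)
  rule1 <- rule1[!duplicated(paste(rule1$region, rule1$gene_id, sep = "\r")), , drop = FALSE]

  assigned1 <- unique(rule1$region)
  rest <- setdiff(seq_len(n), assigned1)

  # Rule 2: nearest gene per side within max_distance, per chromosome.
  rule2 <- empty[, c("region", "gene_id", "rule")]
  if (length(rest) > 0L) {
    pieces <- list()
    for (chr in unique(regions$chrom[rest])) {
      ridx <- rest[regions$chrom[rest] == chr]
      g <- genes[genes$chrom == chr, , drop = FALSE]
      if (nrow(g) == 0L) next
      rs <- regions$start[ridx]; re <- regions$end[ridx]
      # left side: gene bodies ending at or before the region start
      ord_e <- order(g$end, g$gene_id)
      ends <- g$end[ord_e]
      pos <- findInterval(rs, ends)           # last gene with end <= rs
      for (k in seq_along(ridx)) {
        if (pos[k] >= 1L) {
          e_star <- ends[pos[k]]
          gap <- rs[k] - e_star
          if (gap <= max_distance) {
            cand <- g$gene_id[ord_e][ends == e_star]
            pieces[[length(pieces) + 1L]] <- data.frame(
              region = ridx[k], gene_id = min(cand), rule = "nearest_5p",
              stringsAsFactors = FALSE)
          }
        }
      }
      # right side: gene bodies starting at or after the region end
      ord_s <- order(g$start, g$gene_id)
      starts <- g$start[ord_s]
      for (k in seq_along(ridx)) {
        j <- findInterval(re[k] - 0.5, starts) + 1L  # first gene with start >= re
        if (j <= length(starts)) {
          s_star <- starts[j]
          gap <- s_star - re[k]
          if (gap <= max_distance) {
            cand <- g$gene_id[ord_s][starts == s_star]
            pieces[[length(pieces) + 1L]] <- data.frame(
              region = ridx[k], gene_id = min(cand), rule = "nearest_3p",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(pieces) > 0L) rule2 <- do.call(rbind, pieces)
  }

  entries <- rbind(rule1, rule2)
  entries <- entries[order(entries$region, entries$gene_id), , drop = FALSE]
  entries$region_id <- region_id[entries$region]
  entries <- entries[, c("region", "region_id", "gene_id", "rule")]
  rownames(entries) <- NULL
  unassigned <- setdiff(seq_len(n), unique(entries$region))
  structure(list(entries = entries, unassigned = sort(unassigned)),
            class = "region_gene_map", n_regions = n)
}

#' @export
print.region_gene_map <- function(x, ...) {
  cat(sprintf("region_gene_map: %d regions -> %d genes via %d assignments; %d unassigned\n",
              attr(x, "n_regions"), length(unique(x$entries$gene_id)),
              nrow(x$entries), length(x$unassigned)))
  if (nrow(x$entries) > 0L) print(table(x$entries$rule))
  invisible(x)
}

#' Gene x TF binding incidence matrix
#'
#' A TF binds a gene iff at least one region assigned to that gene overlaps
#' (>= 1 bp) a called peak of the TF in either cell type.
#'
#' @param map `region_gene_map` from [assign_regions()].
#' @param peaks peak data frame for all samples with a `tf` column.
#' @param regions the region data frame the map was built from.
#' @return logical matrix, rows = genes, columns = TFs.
#' @export
tf_binding_matrix <- function(map, peaks, regions) {
  stopifnot(inherits(map, "region_gene_map"), "tf" %in% names(peaks))
  tfs <- sort(unique(peaks$tf))
  genes <- sort(unique(map$entries$gene_id))
  out <- matrix(FALSE, nrow = length(genes), ncol = length(tfs),
                dimnames = list(genes, tfs))
  if (nrow(map$entries) == 0L) return(out)
  for (tf in tfs) {
    region_bound <- .overlaps_any(regions, peaks[peaks$tf == tf, , drop = FALSE])
    hit_genes <- unique(map$entries$gene_id[region_bound[map$entries$region]])
    out[hit_genes, tf] <- TRUE
  }
  out
}

#' Genes bound by at least `min_tfs` transcription factors
#'
#' @param map `region_gene_map`.
#' @param peaks peak data frame with `tf` column.
#' @param regions region data frame the map refers to.
#' @param min_tfs minimum bound-TF count (>= 1).
#' @return character vector of gene ids; per-threshold gene counts for
#'   thresholds `1..n_tfs` in `attr(, "threshold_counts")`.
#' @export
bound_gene_sets <- function(map, peaks, regions, min_tfs = 1) {
  if (min_tfs < 1) stop("min_tfs must be >= 1")
  bm <- tf_binding_matrix(map, peaks, regions)
  n_bound <- rowSums(bm)
  thresholds <- seq_len(ncol(bm))
  counts <- stats::setNames(vapply(thresholds, function(k) sum(n_bound >= k), integer(1)),
                            thresholds)
  structure(rownames(bm)[n_bound >= min_tfs], threshold_counts = counts)
}

#' Fraction of differentially expressed genes bound by a TF
#'
#' @param de_genes non-empty character vector of DE gene ids.
#' @param map `region_gene_map`.
#' @param peaks peak data frame with `tf` column.
#' @param regions region data frame.
#' @param tf TF name.
#' @return fraction in `[0, 1]`.
#' @export
bound_fraction <- function(de_genes, map, peaks, regions, tf) {
  if (length(de_genes) == 0L) stop("de_genes is empty")
  bm <- tf_binding_matrix(map, peaks, regions)
  if (!tf %in% colnames(bm)) stop(sprintf("no peaks for TF '%s'", tf))
  bound <- rownames(bm)[bm[, tf]]
  mean(de_genes %in% bound)
}
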