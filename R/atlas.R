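# Merged peak atlas: union of all samples' peak calls, a normalised
# region x sample coverage matrix, sample correlation/clustering, and the
# cell-type-specific vs common partition of each TF's peaks.

#' Merge peak calls from all samples into a single region list
#'
#' Peaks from every (TF, cell type) sample are combined and intervals
#' overlapping by at least 1 bp are merged transitively. Half-open
#' book-ended intervals (`[10,20)` and `[20,30)`) share no base and are NOT
#' merged. Output is sorted by (chrom, start) and covers exactly the union
#' of input bases.
#'
#' @param peaks interval data frame (any extra columns ignored).
#' @return data frame of disjoint merged regions with a `region_id` column.
#' @export
merge_peaks <- function(peaks) {
  validate_intervals(peaks, what = "peak")
  if (nrow(peaks) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      region_id = character(), stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::reduce(.as_granges(peaks), min.gapwidth = 0L)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  out <- .from_granges(gr)
  o <- order(out$chrom, out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out$region_id <- sprintf("region_%d", seq_len(nrow(out)))
  out
}

#' Build the normalised coverage atlas over merged regions
#'
#' Counts, for every (region, sample) pair, the reads overlapping the region
#' by at least 1 bp, and normalises per 10 million reads:
#' `normalised = raw * 1e7 / library_size`. Reads on chromosomes absent from
#' the region list are excluded with a warning.
#'
#' @param regions merged region data frame from [merge_peaks()].
#' @param reads named list (one element per sample label) of read interval
#'   data frames.
#' @param library_sizes named numeric vector of per-sample total read counts;
#'   names must match `reads`.
#' @param samples data frame with columns `tf`, `cell_type` and optionally
#'   `label`; defaults to labels split on the last `"."`.
#' @return object of class `coverage_atlas`: `regions`, `samples`, `matrix`
#'   (n_regions x n_samples normalised coverage), `counts` (raw), and
#'   `library_sizes`.
#' @export
compute_coverage <- function(regions, reads, library_sizes, samples = NULL) {
  validate_intervals(regions, what = "region")
  stopifnot(is.list(reads), !is.null(names(reads)), all(nzchar(names(reads))))
  labels <- names(reads)
  if (is.null(names(library_sizes))) names(library_sizes) <- labels
  miss <- setdiff(labels, names(library_sizes))
  if (length(miss) > 0L) stop(sprintf("no library size for sample(s): %s",
                                      paste(miss, collapse = ", ")))
  if (any(library_sizes[labels] <= 0)) {
    bad <- labels[which(library_sizes[labels] <= 0)[1L]]
    stop(sprintf("sample '%s' has library size 0", bad))
  }
  if (is.null(samples)) {
    parts <- regmatches(labels, regexpr("\\.[^.]*$", labels))
    samples <- data.frame(tf = sub("\\.[^.]*$", "", labels),
                          cell_type = sub("^\\.", "", parts),
                          label = labels, stringsAsFactors = FALSE)
  } else {
    if (is.null(samples$label)) samples$label <- paste(samples$tf, samples$cell_type, sep = ".")
    stopifnot(setequal(samples$label, labels))
    samples <- samples[match(labels, samples$label), , drop = FALSE]
  }
  rg <- .as_granges(regions)
  n <- nrow(regions)
  counts <- matrix(0L, nrow = n, ncol = length(labels),
                   dimnames = list(regions$region_id, labels))
  for (j in seq_along(labels)) {
    rd <- validate_intervals(reads[[j]], what = "read")
    if (library_sizes[labels[j]] < nrow(rd)) {
      stop(sprintf("sample '%s': library size smaller than number of reads", labels[j]))
    }
    if (nrow(rd) == 0L) next
    unknown <- !rd$chrom %in% regions$chrom
    if (any(unknown)) {
      warning(sprintf("sample '%s': %d read(s) on chromosomes absent from the atlas excluded",
                      labels[j], sum(unknown)))
      rd <- rd[!unknown, , drop = FALSE]
    }
    if (nrow(rd) == 0L) next
    counts[, j] <- GenomicRanges::countOverlaps(rg, .as_granges(rd, unique(regions$chrom)))
  }
  norm <- sweep(counts, 2L, as.numeric(library_sizes[labels]), function(c, l) c * 1e7 / l)
  structure(list(regions = regions, samples = samples, matrix = norm,
                 counts = counts,
                 library_sizes = as.numeric(library_sizes[labels])),
            class = "coverage_atlas")
}

#' @export
print.coverage_atlas <- function(x, ...) {
  cat(sprintf("coverage_atlas: %d regions x %d samples (%d TFs, %d cell types)\n",
              nrow(x$regions), nrow(x$samples),
              length(unique(x$samples$tf)), length(unique(x$samples$cell_type))))
  cat(sprintf("library sizes: %s\n",
              paste(format(x$library_sizes, big.mark = ","), collapse = ", ")))
  invisible(x)
}

#' Pairwise sample correlation and hierarchical clustering
#'
#' Pearson correlation between the coverage columns of every sample pair,
#' plus hierarchical clustering on distance `1 - r` for a heatmap-style leaf
#' ordering. No linkage is canonical for this summary; average linkage is the
#' default and the choice is exposed.
#'
#' @param atlas `coverage_atlas`.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list of class `sample_correlation`: `correlation` (symmetric, unit
#'   diagonal), `hclust`, and `order` (leaf ordering).
#' @export
sample_correlation <- function(atlas, linkage = "average") {
  stopifnot(inherits(atlas, "coverage_atlas"))
  m <- atlas$matrix
  if (ncol(m) < 2L || nrow(m) < 2L) stop("need >= 2 samples and >= 2 regions")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("sample '%s' has constant coverage; correlation undefined",
                 colnames(m)[which(sds == 0)[1L]]))
  }
  r <- stats::cor(m)
  diag(r) <- 1
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  structure(list(correlation = r, hclust = hc, order = hc$order),
            class = "sample_correlation")
}

#' @export
print.sample_correlation <- function(x, ...) {
  cat(sprintf("sample_correlation: %d samples, leaf order: %s\n",
              ncol(x$correlation),
              paste(colnames(x$correlation)[x$order], collapse = ", ")))
  invisible(x)
}

#' Partition one TF's peaks into cell-type-specific and common regions
#'
#' A peak in cell type A overlapping (>= 1 bp) any peak of the same TF in
#' cell type B is labelled `common`, and vice versa; peaks with no
#' cross-cell-type overlap are labelled `A_specific` / `B_specific`.
#'
#' @param peaks_a,peaks_b the TF's peak data frames in cell types A and B.
#' @param tf TF name recorded on the result.
#' @return data frame of class `region_partition` with the peaks of both cell
#'   types, their `cell_type` (`"A"`/`"B"`) and `label`; label counts are in
#'   `attr(, "counts")`.
#' @export
partition_regions <- function(peaks_a, peaks_b, tf = NA_character_) {
  validate_intervals(peaks_a, what = "peak")
  validate_intervals(peaks_b, what = "peak")
  base_cols <- c("chrom", "start", "end")
  a <- peaks_a[, base_cols, drop = FALSE]
  b <- peaks_b[, base_cols, drop = FALSE]
  a$cell_type <- "A"; b$cell_type <- "B"
  a$label <- ifelse(.overlaps_any(a, b), "common", "A_specific")
  b$label <- ifelse(.overlaps_any(b, a), "common", "B_specific")
  out <- rbind(a, b)
  rownames(out) <- NULL
  counts <- c(A_specific = sum(out$label == "A_specific"),
              common = sum(out$label == "common"),
              B_specific = sum(out$label == "B_specific"))
  structure(out, class = c("region_partition", "data.frame"),
            tf = tf, counts = counts)
}

#' @export
print.region_partition <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf("region_partition for TF '%s': %d A-specific, %d common, %d B-specific\n",
              attr(x, "tf"), counts[["A_specific"]], counts[["common"]],
              counts[["B_specific"]]))
  invisible(x)
}
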