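# Motif-content matrices over cell-type-specific/common peak regions via
# log-odds PWM scanning of central peak windows, and co-occupancy between
# extra TFs and the categories of a shared TF's peaks.

#' Central window of a peak region
#'
#' Window of `width` bp centred on `floor((start + end) / 2)`; regions
#' shorter than `width` are returned unchanged (clipping).
#'
#' @param regions interval data frame.
#' @param width window width in bp.
#' @return interval data frame of the same rows.
#' @export
central_window <- function(regions, width = 100) {
  stopifnot(width >= 1)
  validate_intervals(regions, what = "region")
  centre <- (regions$start + regions$end) %/% 2L
  ws <- centre - width %/% 2L
  out <- regions
  short <- (regions$end - regions$start) < width
  out$start <- ifelse(short, regions$start, ws)
  out$end <- ifelse(short, regions$end, ws + as.integer(width))
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out
}

.REV_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Score one strand of a sequence against a log2-odds matrix. Returns the
# per-offset score vector (NA where the window contains N).
.scan_strand <- function(idx, lo) {
  L <- ncol(lo)
  n <- length(idx)
  n_win <- n - L + 1L
  if (n_win < 1L) return(numeric(0))
  scores <- numeric(n_win)
  for (j in seq_len(L)) {
    b <- idx[j:(j + n_win - 1L)]
    scores <- scores + ifelse(is.na(b), NA_real_, lo[cbind(b, j)])
  }
  scores
}

#' Scan a DNA sequence with a position weight matrix
#'
#' Computes the log2-odds score against the background at every offset on
#' both strands (the reverse strand via the reverse-complement of the PWM)
#' and reports the positions scoring at least `threshold`. Windows containing
#' `N` are skipped.
#'
#' @param sequence DNA string over `A/C/G/T/N`.
#' @param pwm `pwm` object from [read_pwms()].
#' @param threshold log2-odds score threshold; defaults to
#'   [pwm_score_threshold()] at 80% of the motif's maximum achievable score.
#' @return data frame `offset` (0-based window start), `strand` (`"+"`/`"-"`),
#'   `score`, sorted by offset.
#' @export
scan_pwm <- function(sequence, pwm, threshold = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.null(threshold)) threshold <- pwm_score_threshold(pwm)
  s <- strsplit(toupper(as.character(sequence)), "")[[1L]]
  if (length(s) > 0 && !all(s %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence contains characters outside A/C/G/T/N")
  }
  lo <- log2(pwm$matrix / pwm$background)
  empty <- data.frame(offset = integer(), strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(s) < ncol(lo)) return(empty)
  idx <- match(s, c("A", "C", "G", "T"))  # N -> NA
  fwd <- .scan_strand(idx, lo)
  # reverse strand: score of the reverse complement of each window equals
  # scanning with the reverse-complemented matrix at the same offset
  lo_rc <- lo[4:1, ncol(lo):1, drop = FALSE]
  rownames(lo_rc) <- c("A", "C", "G", "T")
  rev_ <- .scan_strand(idx, lo_rc)
  keep_f <- which(!is.na(fwd) & fwd >= threshold)
  keep_r <- which(!is.na(rev_) & rev_ >= threshold)
  hits <- rbind(
    data.frame(offset = keep_f - 1L, strand = rep("+", length(keep_f)),
               score = fwd[keep_f], stringsAsFactors = FALSE),
    data.frame(offset = keep_r - 1L, strand = rep("-", length(keep_r)),
               score = rev_[keep_r], stringsAsFactors = FALSE)
  )
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

#' Default log-odds threshold for a PWM
#'
#' A configurable fraction (default 80%) of the motif's maximum achievable
#' log2-odds score (sum of per-column maxima).
#'
#' @param pwm `pwm` object.
#' @param fraction fraction of the maximum score.
#' @return numeric threshold.
#' @export
pwm_score_threshold <- function(pwm, fraction = 0.8) {
  lo <- log2(pwm$matrix / pwm$background)
  fraction * sum(apply(lo, 2L, max))
}

.extract_window_seq <- function(sequences, windows) {
  seqs <- character(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    chr <- windows$chrom[i]
    if (!chr %in% names(sequences)) stop(sprintf("chromosome '%s' absent from FASTA", chr))
    full <- sequences[[chr]]
    if (windows$end[i] > nchar(full)) {
      stop(sprintf("region %s:[%d,%d) extends beyond chromosome end (%d bp)",
                   chr, windows$start[i], windows$end[i], nchar(full)))
    }
    seqs[i] <- substr(full, windows$start[i] + 1L, windows$end[i])
  }
  seqs
}

#' Motif-content matrix over partitioned peak regions
#'
#' For every TF, peak category (`A_specific`/`common`/`B_specific`) and
#' motif: the fraction of central peak windows containing at least one PWM
#' hit. Fractions below `min_fraction` are floored to 0 (the matrix's
#' "x or 0" convention).
#'
#' @param partitions named list (by TF) of `region_partition` objects.
#' @param sequences named character vector (or `Biostrings::DNAStringSet`) of
#'   chromosome sequences.
#' @param pwms list of `pwm` objects.
#' @param threshold log2-odds threshold; `NULL` for the per-motif default.
#' @param min_fraction fractions below this report as 0.
#' @param width central-window width in bp.
#' @return numeric matrix, rows = motifs, columns = `TF.category`.
#' @export
motif_content <- function(partitions, sequences, pwms, threshold = NULL,
                          min_fraction = 0, width = 100) {
  stopifnot(is.list(partitions), !is.null(names(partitions)))
  if (methods::is(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  categories <- c("A_specific", "common", "B_specific")
  cols <- as.vector(outer(names(partitions), categories, paste, sep = "."))
  out <- matrix(0, nrow = length(pwms), ncol = length(cols),
                dimnames = list(vapply(pwms, `[[`, "", "motif_id"), cols))
  for (tf in names(partitions)) {
    part <- partitions[[tf]]
    for (cat in categories) {
      regs <- part[part$label == cat, , drop = FALSE]
      col <- paste(tf, cat, sep = ".")
      if (nrow(regs) == 0L) { out[, col] <- NA_real_; next }
      win_seqs <- .extract_window_seq(sequences, central_window(regs, width))
      for (m in seq_along(pwms)) {
        th <- if (is.null(threshold)) pwm_score_threshold(pwms[[m]]) else threshold
        has_hit <- vapply(win_seqs, function(ss) nrow(scan_pwm(ss, pwms[[m]], th)) > 0L,
                          logical(1), USE.NAMES = FALSE)
        frac <- mean(has_hit)
        out[m, col] <- if (frac < min_fraction) 0 else frac
      }
    }
  }
  out
}

#' Co-occupancy of extra TFs over a shared TF's peak categories
#'
#' For each category of the shared TF's partitioned peaks, the percentage of
#' peaks overlapped (>= 1 bp) by any peak of each extra TF; the category's
#' total peak count is the 100% denominator. Empty categories report `NA`.
#'
#' @param partition `region_partition` of the shared TF.
#' @param extra_peaks named list (by extra-TF name) of peak data frames.
#' @return numeric matrix of percentages in `[0, 100]`, rows = categories,
#'   columns = extra TFs.
#' @export
co_occupancy <- function(partition, extra_peaks) {
  stopifnot(inherits(partition, "region_partition"),
            is.list(extra_peaks), !is.null(names(extra_peaks)))
  categories <- c("A_specific", "common", "B_specific")
  out <- matrix(NA_real_, nrow = length(categories), ncol = length(extra_peaks),
                dimnames = list(categories, names(extra_peaks)))
  for (cat in categories) {
    regs <- partition[partition$label == cat, , drop = FALSE]
    if (nrow(regs) == 0L) {
      message(sprintf("co_occupancy: no '%s' peaks; percentage undefined", cat))
      next
    }
    for (xt in names(extra_peaks)) {
      xp <- extra_peaks[[xt]]
      out[cat, xt] <- if (nrow(xp) == 0L) 0 else 100 * mean(.overlaps_any(regs, xp))
    }
  }
  out
}
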