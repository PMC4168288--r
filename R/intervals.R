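# Interval primitives. All coordinates are 0-based half-open (BED convention):
# an interval [start, end) covers bases start .. end-1, and two intervals
# overlap iff they share >= 1 base. GRanges (1-based closed) is used internally
# for the heavy set operations; conversion is confined to the two helpers below.

#' Validate a data frame of genomic intervals
#'
#' Checks the 0-based half-open interval contract: non-empty chromosome names,
#' integer coordinates with `start >= 0` and `end > start`, and (when present)
#' strand in `+`, `-` or `.` and non-negative scores.
#'
#' @param x data frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param what label used in error messages.
#' @return `x`, invisibly, with `start`/`end` coerced to integer.
#' @export
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0L) {
    stop(sprintf("%s table lacks column(s): %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
    stop(sprintf("%s with empty chromosome name", what))
  }
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    stop(sprintf("%s with missing coordinate", what))
  }
  if (any(x$start != floor(x$start)) || any(x$end != floor(x$end))) {
    stop(sprintf("%s with non-integer coordinate", what))
  }
  bad <- which(x$start < 0 | x$end <= x$start)
  if (length(bad) > 0L) {
    stop(sprintf("%s %d violates 0-based half-open contract (start=%s, end=%s)",
                 what, bad[1L], x$start[bad[1L]], x$end[bad[1L]]))
  }
  if ("strand" %in% names(x)) {
    ok <- x$strand %in% c("+", "-", ".")
    if (!all(ok)) stop(sprintf("unknown strand symbol '%s'", x$strand[which(!ok)[1L]]))
  }
  if ("score" %in% names(x) && any(!is.na(x$score) & x$score < 0)) {
    stop(sprintf("%s with negative score", what))
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  invisible(x)
}

# BED half-open -> GRanges (1-based closed). Strand deliberately dropped:
# every overlap operation in the pipeline is strand-blind. `levels` fixes a
# common seqlevel set so cross-object overlap calls compare cleanly even when
# one side lacks a chromosome.
.as_granges <- function(x, levels = NULL) {
  sq <- as.character(x$chrom)
  if (is.null(levels)) levels <- unique(sq)
  GenomicRanges::GRanges(
    seqnames = factor(sq, levels = levels),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

.from_granges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Overlap-by->=1bp indicator of each row of x against any row of y.
.overlaps_any <- function(x, y) {
  if (nrow(y) == 0L || nrow(x) == 0L) return(rep(FALSE, nrow(x)))
  lv <- union(unique(as.character(x$chrom)), unique(as.character(y$chrom)))
  IRanges::overlapsAny(.as_granges(x, lv), .as_granges(y, lv))
}

#' Interval widths
#'
#' @param x interval data frame.
#' @return integer vector of widths in bp (`end - start`).
#' @export
interval_width <- function(x) {
  as.integer(x$end - x$start)
}
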