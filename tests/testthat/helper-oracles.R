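# Brute-force oracles, independent of the package's interval engine: per-base
# occupancy arrays and all-pairs overlap scans, plus the closed-form 2x2
# chi-square. Deliberately O(n*m) / O(L) so they share no code path with the
# implementation they check.

# Merge via a boolean occupancy array at doubled resolution (one per
# chromosome): interval [s, e) marks scaled cells 2s+1 .. 2e-1, so intervals
# sharing >= 1 base produce one contiguous run while book-ended intervals
# keep a one-cell gap and stay separate.
oracle_merge <- function(x) {
  out <- list()
  for (chr in sort(unique(x$chrom))) {
    xi <- x[x$chrom == chr, , drop = FALSE]
    occ <- logical(2L * max(xi$end))
    for (i in seq_len(nrow(xi))) occ[(2L * xi$start[i] + 1L):(2L * xi$end[i] - 1L)] <- TRUE
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep) > 0L) {
      out[[chr]] <- data.frame(chrom = chr, start = (starts[keep] - 1L) %/% 2L,
                               end = (ends[keep] + 1L) %/% 2L, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

overlap_1bp <- function(s1, e1, s2, e2) (s1 < e2) & (s2 < e1)

# All-pairs overlap counting of reads against regions.
oracle_count <- function(regions, reads) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(reads$chrom == regions$chrom[i] &
          overlap_1bp(regions$start[i], regions$end[i], reads$start, reads$end))
  }, numeric(1))
}

# Per-peak specific/common labels by all-pairs scan.
oracle_partition <- function(a, b) {
  la <- vapply(seq_len(nrow(a)), function(i) {
    if (any(b$chrom == a$chrom[i] &
            overlap_1bp(a$start[i], a$end[i], b$start, b$end))) "common" else "A_specific"
  }, character(1))
  lb <- vapply(seq_len(nrow(b)), function(i) {
    if (any(a$chrom == b$chrom[i] &
            overlap_1bp(b$start[i], b$end[i], a$start, a$end))) "common" else "B_specific"
  }, character(1))
  c(la, lb)
}

# Percentage of x peaks overlapped by any y peak.
oracle_cooccupancy <- function(x, y) {
  if (nrow(x) == 0L) return(NA_real_)
  hit <- vapply(seq_len(nrow(x)), function(i) {
    any(y$chrom == x$chrom[i] & overlap_1bp(x$start[i], x$end[i], y$start, y$end))
  }, logical(1))
  100 * mean(hit)
}

# Closed-form Pearson chi-square for a 2x2 table: n(ad - bc)^2 / (r1 r2 c1 c2).
oracle_chi2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# Exhaustive PWM scan: every strand-offset enumerated, windows with N skipped.
oracle_scan <- function(seq, pwm, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  revcomp <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  lo <- log2(pwm$matrix / pwm$background)
  L <- ncol(lo)
  chars <- strsplit(toupper(seq), "")[[1]]
  hits <- list()
  for (off in seq_len(length(chars) - L + 1)) {
    win <- paste(chars[off:(off + L - 1)], collapse = "")
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else revcomp(win)
      ws <- strsplit(w, "")[[1]]
      if (any(ws == "N")) next
      sc <- sum(lo[cbind(match(ws, c("A", "C", "G", "T")), seq_len(L))])
      if (sc >= threshold) {
        hits[[length(hits) + 1]] <- data.frame(offset = off - 1L, strand = strand,
                                               score = sc, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(offset = integer(), strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# Random interval sets on small coordinates (per-base oracle friendly).
rand_intervals <- function(n, max_pos = 20000, max_len = 300, chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

# Random dense feature table with known linear coefficients (local, trivial
# generator independent of the package's synthetic module).
rand_features <- function(n, beta, sd_noise = 1, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), nrow = n, dimnames = list(NULL, paste0("dtf_TF", seq_len(p))))
  y <- drop(X %*% beta) + rnorm(n, 0, sd_noise)
  df <- data.frame(gene_id = sprintf("g%05d", seq_len(n)), X,
                   n_tfs_bound = p, delta_ge = y, category = "I",
                   stringsAsFactors = FALSE, check.names = FALSE)
  structure(df, class = c("gene_features", "data.frame"), tfs = paste0("TF", seq_len(p)))
}
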