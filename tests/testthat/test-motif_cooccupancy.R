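# Central windows, PWM scanning against exhaustive enumeration, motif-content
# fractions on planted sequences, and co-occupancy percentages.

make_pwm <- function(mat, id = "M") {
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(motif_id = id, matrix = mat,
                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
            class = "pwm")
}

test_that("central windows are centred with floor rounding and clipped to short regions", {
  w <- central_window(data.frame(chrom = "chr1", start = 100L, end = 300L))
  expect_equal(c(w$start, w$end), c(150L, 250L))
  w2 <- central_window(data.frame(chrom = "chr1", start = 100L, end = 160L))
  expect_equal(c(w2$start, w2$end), c(100L, 160L))
  w3 <- central_window(data.frame(chrom = "chr1", start = 100L, end = 301L))
  expect_equal(w3$end - w3$start, 100L)
  expect_equal(w3$start, (100L + 301L) %/% 2L - 50L)
})

test_that("a background-equal PWM scores 0 everywhere and N windows are skipped", {
  pwm <- make_pwm(matrix(0.25, 4, 3))
  hits <- scan_pwm("ACGTACGT", pwm, threshold = -1)
  expect_equal(nrow(hits), 12L)  # 6 offsets x 2 strands
  expect_true(all(hits$score == 0))
  expect_equal(nrow(scan_pwm("ACGTACGT", pwm, threshold = 1e-9)), 0L)

  hits_n <- scan_pwm("ACNTACGT", pwm, threshold = -1)
  expect_true(all(hits_n$offset > 2))  # windows covering the N are skipped
  expect_equal(nrow(scan_pwm("AC", pwm, threshold = -1)), 0L)  # shorter than motif
})

test_that("scanning equals exhaustive strand-offset enumeration on random short sequences", {
  set.seed(61)
  for (rep in 1:20) {
    L <- sample(2:5, 1)
    counts <- matrix(rexp(4 * L), 4, L)
    pwm <- make_pwm(sweep(counts, 2, colSums(counts), "/"))
    n <- sample(6:30, 1)
    seq_ <- paste(sample(c("A", "C", "G", "T", "N"), n, TRUE,
                         prob = c(rep(0.24, 4), 0.04)), collapse = "")
    th <- runif(1, -2, 2)
    got <- scan_pwm(seq_, pwm, th)
    want <- oracle_scan(seq_, pwm, th)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("palindromic PWMs score both strands identically at mirrored offsets", {
  # ACGT-palindrome: complement of reversed columns equals the matrix
  m <- cbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.4, 0.4, 0.1),
             c(0.1, 0.4, 0.4, 0.1), c(0.1, 0.1, 0.1, 0.7))
  pwm <- make_pwm(m)
  hits <- scan_pwm("AGGCATGCATT", pwm, threshold = -50)
  fwd <- hits[hits$strand == "+", ]
  rev_ <- hits[hits$strand == "-", ]
  expect_equal(fwd$score, rev_$score[match(fwd$offset, rev_$offset)], tolerance = 1e-12)
})

test_that("motif content recovers a planted motif fraction and applies the x-or-0 floor", {
  set.seed(62)
  motif <- "ACGTACGTAC"
  chrom_seq <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  # plant the motif at the centre of 60% of category-A windows
  n_pk <- 50
  starts <- seq(100L, by = 350L, length.out = n_pk)
  planted <- seq_len(n_pk) <= 30
  for (i in which(planted)) {
    centre <- starts[i] + 100L
    substr(chrom_seq, centre, centre + nchar(motif) - 1L) <- motif
  }
  peaks_a <- data.frame(chrom = "chr1", start = starts, end = starts + 200L)
  peaks_b <- data.frame(chrom = "chr1", start = 18000L, end = 18200L)
  part <- partition_regions(peaks_a, peaks_b)
  counts <- matrix(0.01, 4, nchar(motif))
  for (j in seq_len(nchar(motif))) {
    counts[match(substr(motif, j, j), c("A", "C", "G", "T")), j] <- 0.97
  }
  pwm <- make_pwm(counts)
  mc <- motif_content(list(TFX = part), c(chr1 = chrom_seq), list(pwm))
  expect_equal(mc["M", "TFX.A_specific"], 0.6, tolerance = 0.05 + 1e-9)
  expect_lte(mc["M", "TFX.B_specific"], 0.05)
  # floor: fractions below min_fraction report as 0
  mc_floor <- motif_content(list(TFX = part), c(chr1 = chrom_seq), list(pwm),
                            min_fraction = 0.9)
  expect_equal(mc_floor["M", "TFX.A_specific"], 0)
  # invariance under region order permutation
  part_perm <- part[sample(nrow(part)), ]
  attr(part_perm, "tf") <- attr(part, "tf")
  class(part_perm) <- class(part)
  mc_perm <- motif_content(list(TFX = part_perm), c(chr1 = chrom_seq), list(pwm))
  expect_equal(mc_perm, mc)
})

test_that("windows beyond the chromosome end are an error naming the region", {
  part <- partition_regions(data.frame(chrom = "chr1", start = 90L, end = 290L),
                            data.frame(chrom = "chr1", start = 1L, end = 2L))
  pwm <- make_pwm(matrix(0.25, 4, 2))
  expect_error(motif_content(list(TFX = part), c(chr1 = "ACGT"), list(pwm)),
               "beyond chromosome end")
})

test_that("co-occupancy percentages use the category count as denominator and match the oracle", {
  set.seed(63)
  a <- rand_intervals(100, max_pos = 5000)
  b <- rand_intervals(100, max_pos = 5000)
  part <- partition_regions(a, b)
  extra <- rand_intervals(80, max_pos = 5000)
  co <- co_occupancy(part, list(MITF = extra))
  for (cat in rownames(co)) {
    regs <- part[part$label == cat, , drop = FALSE]
    expect_equal(unname(co[cat, "MITF"]), oracle_cooccupancy(regs, extra))
  }
  # no extra peaks -> 0 everywhere (populated categories)
  co0 <- co_occupancy(part, list(
    NONE = data.frame(chrom = character(), start = integer(), end = integer())))
  expect_true(all(co0[!is.na(co0)] == 0))
  # adding extra peaks never decreases a percentage
  more <- rbind(extra, rand_intervals(40, max_pos = 5000))
  co2 <- co_occupancy(part, list(MITF = more))
  expect_true(all(co2 >= co, na.rm = TRUE))
})

test_that("worked co-occupancy percentage: 30 of 100 B-specific peaks overlapped -> 30%", {
  b <- data.frame(chrom = "chr1", start = seq(0L, by = 1000L, length.out = 100L))
  b$end <- b$start + 200L
  a <- data.frame(chrom = "chr2", start = 1L, end = 2L)  # no overlap with B
  part <- partition_regions(a, b)
  extra <- data.frame(chrom = "chr1", start = b$start[1:30] + 50L, end = b$start[1:30] + 80L)
  co <- suppressMessages(co_occupancy(part, list(X = extra)))
  expect_equal(unname(co["B_specific", "X"]), 30)
})
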