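# The synthetic-data generator: determinism, contract round-trips, shared
# peak fraction construction, delta-TF self-consistency, and noiseless
# identifiability through the whole pipeline.

test_that("identical seeds give identical genomes, peaks and expression", {
  g1 <- simulate_genome(seed = 71, n_genes = 50, chrom_length = 4e5)
  g2 <- simulate_genome(seed = 71, n_genes = 50, chrom_length = 4e5)
  expect_identical(g1, g2)
  g3 <- simulate_genome(seed = 72, n_genes = 50, chrom_length = 4e5)
  expect_false(identical(g1$sequences, g3$sequences))

  tr <- synthetic_truth(seed = 71, n_genes = 50, n_tfs = 2, peaks_per_tf = 40)
  p1 <- simulate_peaks(tr, g1$genes)
  p2 <- simulate_peaks(tr, g2$genes)
  expect_identical(p1, p2)
  X <- matrix(rnorm(100), 50, 2, dimnames = list(sprintf("g%02d", 1:50), tr$tfs))
  e1 <- simulate_expression(tr, X)
  e2 <- simulate_expression(tr, X)
  expect_identical(e1, e2)
})

test_that("simulated genes satisfy the gene-model contract and round-trip the reader", {
  g <- simulate_genome(seed = 73, n_genes = 60, chrom_length = 5e5)
  expect_true(all(g$genes$tss >= g$genes$start & g$genes$tss < g$genes$end))
  expect_false(anyDuplicated(g$genes$gene_id) > 0)
  # bodies are non-overlapping within each chromosome
  for (chr in unique(g$genes$chrom)) {
    gg <- g$genes[g$genes$chrom == chr, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(utils::head(gg$end, -1) <= utils::tail(gg$start, -1)))
  }
  f <- tempfile()
  writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%s", g$genes$gene_id, g$genes$chrom,
                     g$genes$strand, g$genes$start, g$genes$end,
                     g$genes$transcript_id), f)
  back <- read_genes(f)
  expect_equal(back$tss, g$genes$tss)
  expect_equal(nchar(g$sequences[["chr1"]]), 5e5)

  g0 <- simulate_genome(seed = 74, n_genes = 0)
  expect_equal(nrow(g0$genes), 0L)
  expect_equal(length(g0$sequences), 2L)
  expect_error(simulate_genome(seed = 1, n_genes = 500, chrom_length = 1e5),
               "cannot place")
})

test_that("shared peak fraction 1 gives only common labels, 0 gives none", {
  g <- simulate_genome(seed = 75, n_genes = 40, chrom_length = 5e5)
  for (frac in c(0, 1)) {
    tr <- synthetic_truth(seed = 75, n_tfs = 2, peaks_per_tf = 50,
                          shared_peak_fraction = frac)
    sp <- simulate_peaks(tr, g$genes)
    for (tf in tr$tfs) {
      part <- partition_regions(
        sp$peaks[sp$peaks$tf == tf & sp$peaks$cell_type == "A", ],
        sp$peaks[sp$peaks$tf == tf & sp$peaks$cell_type == "B", ])
      n_common <- sum(part$label == "common")
      if (frac == 1) expect_equal(n_common, nrow(part))
      if (frac == 0) expect_equal(n_common, 0L)
    }
  }
})

test_that("the pipeline recovers the generator's shared peak fraction within 0.05", {
  g <- simulate_genome(seed = 76, n_genes = 150, chrom_length = 2e6)
  tr <- synthetic_truth(seed = 76, n_tfs = 3, peaks_per_tf = 400,
                        shared_peak_fraction = 0.3)
  sp <- simulate_peaks(tr, g$genes)
  for (tf in tr$tfs) {
    part <- partition_regions(
      sp$peaks[sp$peaks$tf == tf & sp$peaks$cell_type == "A", ],
      sp$peaks[sp$peaks$tf == tf & sp$peaks$cell_type == "B", ])
    n_common_loc <- sum(part$label == "common") / 2
    n_loc <- nrow(part) - n_common_loc
    expect_lt(abs(n_common_loc / n_loc - 0.3), 0.05)
  }
})

test_that("realised per-region delta-TF tracks the generator's targets (r >= 0.9)", {
  g <- simulate_genome(seed = 77, n_genes = 200, chrom_length = 3e6)
  tr <- synthetic_truth(seed = 77, n_tfs = 1, peaks_per_tf = 1000,
                        shared_peak_fraction = 1)  # all locations in both cells
  sp <- simulate_peaks(tr, g$genes)
  regions <- merge_peaks(sp$peaks)
  atlas <- compute_coverage(regions, sp$reads, sp$library_sizes, sp$samples)
  realised <- delta_binding_region(atlas, tr$tfs[1])
  tgt <- sp$target_dtf
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end)),
    GenomicRanges::GRanges(tgt$chrom, IRanges::IRanges(tgt$start + 1L, tgt$end)))
  q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
  expect_gte(length(q), 900)
  expect_gte(cor(realised[q], tgt$target_dtf[s]), 0.9)
})

test_that("with zero noise and linear truth the pipeline-fitted OLS recovers the coefficients", {
  tr <- synthetic_truth(seed = 78, n_genes = 400, n_tfs = 3,
                        linear_coefficients = c(1.5, -0.5, 0.25), noise_sd = 0)
  sim <- simulate_feature_table(tr)
  fit <- fit_delta_lm(sim$features, min_tfs = 0)
  expect_equal(unname(fit$coefficients), c(1.5, -0.5, 0.25), tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
})

test_that("the population R-squared recorded in the truth matches its defining identity", {
  tr <- synthetic_truth(n_tfs = 4, linear_coefficients = 0.5, noise_sd = 1)
  expect_equal(tr$population_r2, 1 / (1 + 1))  # signal var 4 * 0.25 = 1
  tr2 <- synthetic_truth(n_tfs = 4, linear_coefficients = 0.5, population_r2 = 0.5)
  expect_equal(tr2$noise_sd, 1)
  tr3 <- synthetic_truth(n_tfs = 2, linear_coefficients = c(0, 0.5),
                         smooth_effects = list(list(tf = 1, f = function(x) sin(2 * x),
                                                    var = (1 - exp(-8)) / 2)),
                         noise_sd = 0.5)
  expect_equal(tr3$population_r2,
               (0.25 + (1 - exp(-8)) / 2) / (0.25 + (1 - exp(-8)) / 2 + 0.25))
})

test_that("H3K27ac flags associate with small-noise genes at the configured odds ratio", {
  tr <- synthetic_truth(seed = 79, n_genes = 4000, n_tfs = 2,
                        h3k27ac_odds_ratio = 4, noise_sd = 1)
  sim <- simulate_feature_table(tr)
  predictable <- abs(sim$noise) <= tr$noise_sd
  tab <- table(predictable, sim$h3k27ac)
  or_hat <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_gt(or_hat, 2.5)
  expect_lt(or_hat, 6.5)
})

test_that("an end-to-end simulated study supports the full model stack", {
  tr <- synthetic_truth(seed = 80, n_genes = 250, n_tfs = 4, peaks_per_tf = 150)
  st <- simulate_study(tr)
  expect_equal(ncol(st$atlas$matrix), 8L)
  expect_s3_class(st$features, "gene_features")
  fit <- fit_delta_lm(st$features, min_tfs = 1)
  expect_gt(fit$r2_train, 0.5)
  # fpkm back-solving reproduces delta-GE at pseudocount 0
  dge0 <- delta_expression(st$expression$fpkm_a, st$expression$fpkm_b, pseudocount = 0)
  key <- match(st$features$gene_id, st$expression$gene_id)
  expect_equal(dge0[key], st$features$delta_ge, tolerance = 1e-9)
})
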