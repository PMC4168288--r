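# Synthetic-data generator with recorded ground truth: genome and gene
# models, two-cell-type multi-TF peak sets with a controllable shared
# fraction, per-sample read coverage realising target per-region delta-TF
# values, expression tables whose delta-GE is a known (linear / smooth /
# interaction) function of gene-level delta-TF plus Gaussian noise, and
# H3K27ac flags associated with model predictability. Generator functions
# call set.seed() with their seed argument, so identical seeds give
# byte-identical outputs.

#' Ground-truth parameter set for the synthetic study
#'
#' Bundles every generator parameter together with the analytically implied
#' population R-squared, so parameter-recovery tests can compare estimates
#' against the quantities the data were generated from. Predictor delta-TF
#' values are standard normal by construction, so the population signal
#' variance is `sum(linear_coefficients^2) + sum(var_f) +
#' sum(interaction_effects^2)`, where `var_f` are the analytic variances of
#' any smooth effects, and `population_r2 = signal / (signal + noise_sd^2)`.
#' When `population_r2` is supplied instead of `noise_sd`, the noise SD is
#' back-solved from that identity.
#'
#' @param seed integer seed.
#' @param n_genes,n_tfs study size.
#' @param shared_peak_fraction fraction of each TF's peak locations common to
#'   both cell types.
#' @param linear_coefficients per-TF linear effect sizes (recycled).
#' @param smooth_effects optional named list of per-TF nonlinear functions;
#'   each element is `list(tf = <index>, f = <function>, var = <analytic
#'   variance under N(0,1)>)`.
#' @param interaction_effects optional data frame `i`, `j`, `gamma` of
#'   pairwise product effects.
#' @param noise_sd Gaussian noise SD on delta-GE; mutually exclusive with
#'   `population_r2`.
#' @param population_r2 target fraction of delta-GE variance explained by the
#'   signal.
#' @param peaks_per_tf,peak_width,read_length,library_size ChIP-Seq layer
#'   dimensions.
#' @param dtf_sd SD of the target per-region delta-TF values.
#' @param sig_threshold `|delta-GE|` above which the simulated significance
#'   flag is TRUE (stands in for an external differential test).
#' @param h3k27ac_odds_ratio odds ratio linking high-H3K27ac flags to small
#'   noise terms (1 = no association).
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed = 1, n_genes = 500, n_tfs = 10,
                            shared_peak_fraction = 0.3,
                            linear_coefficients = 0.5,
                            smooth_effects = NULL,
                            interaction_effects = NULL,
                            noise_sd = NULL, population_r2 = NULL,
                            peaks_per_tf = 300, peak_width = 400,
                            read_length = 50, library_size = 2e6,
                            dtf_sd = 1, sig_threshold = 0.5,
                            h3k27ac_odds_ratio = 1) {
  stopifnot(shared_peak_fraction >= 0, shared_peak_fraction <= 1)
  beta <- rep_len(linear_coefficients, n_tfs)
  var_signal <- sum(beta^2)
  if (!is.null(smooth_effects)) {
    for (se in smooth_effects) {
      stopifnot(is.function(se$f), is.numeric(se$var))
      var_signal <- var_signal + se$var
    }
  }
  if (!is.null(interaction_effects)) {
    stopifnot(all(c("i", "j", "gamma") %in% names(interaction_effects)))
    var_signal <- var_signal + sum(interaction_effects$gamma^2)
  }
  if (is.null(noise_sd)) {
    if (is.null(population_r2)) population_r2 <- 0.5
    stopifnot(population_r2 > 0, population_r2 < 1)
    noise_sd <- sqrt(var_signal * (1 - population_r2) / population_r2)
  } else {
    stopifnot(noise_sd >= 0)
    population_r2 <- var_signal / (var_signal + noise_sd^2)
  }
  structure(list(
    seed = seed, n_genes = n_genes, n_tfs = n_tfs,
    tfs = sprintf("TF%02d", seq_len(n_tfs)),
    shared_peak_fraction = shared_peak_fraction,
    linear_coefficients = stats::setNames(beta, sprintf("TF%02d", seq_len(n_tfs))),
    smooth_effects = smooth_effects,
    interaction_effects = interaction_effects,
    noise_sd = noise_sd, population_r2 = population_r2,
    peaks_per_tf = peaks_per_tf, peak_width = peak_width,
    read_length = read_length, library_size = library_size,
    dtf_sd = dtf_sd, sig_threshold = sig_threshold,
    h3k27ac_odds_ratio = h3k27ac_odds_ratio
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic_truth: %d genes, %d TFs, shared peak fraction %.2f,\n",
                     "  noise SD %.3f -> population R2 %.3f\n"),
              x$n_genes, x$n_tfs, x$shared_peak_fraction, x$noise_sd, x$population_r2))
  invisible(x)
}

#' Simulate a genome: gene models and chromosome sequence
#'
#' Places non-overlapping gene bodies (uniform strands) on `n_chroms`
#' chromosomes of i.i.d. uniform-base sequence. Deterministic under `seed`.
#'
#' @param seed integer seed.
#' @param n_chroms,chrom_length genome dimensions.
#' @param n_genes number of genes across the genome.
#' @param gene_length_range min/max gene body length in bp.
#' @return list: `genes` (data frame accepted by the gene reader contract)
#'   and `sequences` (named character vector per chromosome).
#' @export
simulate_genome <- function(seed = 1, n_chroms = 2, chrom_length = 1e6,
                            n_genes = 200, gene_length_range = c(2000, 10000)) {
  set.seed(seed)
  per_chrom <- diff(c(0, round(seq_len(n_chroms) * n_genes / n_chroms)))
  max_len <- gene_length_range[2L]
  rows <- list()
  gid <- 0L
  for (c_ in seq_len(n_chroms)) {
    ng <- per_chrom[c_]
    if (ng == 0L) next
    slot <- chrom_length %/% ng
    if (slot <= max_len + 1L) {
      stop(sprintf("cannot place %d non-overlapping genes of <= %d bp on a %d bp chromosome",
                   ng, max_len, chrom_length))
    }
    len <- sample(gene_length_range[1L]:gene_length_range[2L], ng, replace = TRUE)
    offset <- vapply(slot - len, function(m) sample.int(m, 1L), integer(1))
    start <- (seq_len(ng) - 1L) * slot + offset
    rows[[c_]] <- data.frame(
      gene_id = sprintf("gene_%04d", gid + seq_len(ng)),
      transcript_id = sprintf("tx_%04d", gid + seq_len(ng)),
      chrom = sprintf("chr%d", c_),
      strand = sample(c("+", "-"), ng, replace = TRUE),
      start = as.integer(start), end = as.integer(start + len),
      stringsAsFactors = FALSE)
    gid <- gid + ng
  }
  genes <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene_id = character(), transcript_id = character(),
               chrom = character(), strand = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  if (nrow(genes) > 0L) {
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    rownames(genes) <- NULL
  } else genes$tss <- integer()
  sequences <- stats::setNames(
    vapply(seq_len(n_chroms),
           function(i) paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
                             collapse = ""),
           character(1)),
    sprintf("chr%d", seq_len(n_chroms)))
  list(genes = genes, sequences = sequences)
}

#' Simulate two-cell-type peak sets and read coverage for every TF
#'
#' Per TF, `peaks_per_tf` candidate locations are placed preferentially near
#' gene TSSs (Gaussian offset) on non-overlapping slots; a fraction
#' `shared_peak_fraction` of locations is common to both cell types (same
#' coordinates) and the remainder split evenly into A-only and B-only peaks.
#' Every location carries a target delta-TF drawn from
#' `N(0, dtf_sd^2)` (cell-type-specific locations get one-sided coverage
#' instead); reads of fixed length are placed uniformly within each peak so
#' that normalised coverage ratios realise the targets.
#'
#' @param truth `synthetic_truth`.
#' @param genes gene table from [simulate_genome()].
#' @param chrom_lengths named chromosome lengths (defaults from gene extent).
#' @return list: `peaks` (all samples, with `tf`, `cell_type`), `reads`
#'   (named list per sample label `TF.cell`), `library_sizes`, `samples`,
#'   `target_dtf` (per peak location), `cell_types = c("A", "B")`.
#' @export
simulate_peaks <- function(truth, genes, chrom_lengths = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed + 1L)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end + 50000L, genes$chrom, max)
  }
  chroms <- names(chrom_lengths)
  w <- truth$peak_width
  rl <- truth$read_length
  peaks <- list(); reads <- list(); targets <- list()
  cell_types <- c("A", "B")
  for (tf in truth$tfs) {
    n <- truth$peaks_per_tf
    # non-overlapping slots across the genome, biased towards TSSs
    slots <- list()
    for (chr in chroms) {
      L <- chrom_lengths[[chr]]
      starts <- seq.int(0L, L - w - 1L, by = 2L * w)
      slots[[chr]] <- data.frame(chrom = chr, start = starts, stringsAsFactors = FALSE)
    }
    slots <- do.call(rbind, slots)
    # weight slots by proximity to the nearest TSS (decay scale 10 kb)
    wts <- rep(1, nrow(slots))
    if (nrow(genes) > 0L) {
      for (chr in unique(slots$chrom)) {
        idx <- which(slots$chrom == chr)
        tss <- sort(genes$tss[genes$chrom == chr])
        if (length(tss) == 0L) next
        pos <- slots$start[idx] + w / 2
        lo <- findInterval(pos, tss)
        d_lo <- ifelse(lo >= 1L, pos - tss[pmax(lo, 1L)], Inf)
        d_hi <- ifelse(lo < length(tss), tss[pmin(lo + 1L, length(tss))] - pos, Inf)
        d <- pmin(abs(d_lo), abs(d_hi))
        wts[idx] <- 1 + 9 * exp(-d / 10000)
      }
    }
    pick <- sample.int(nrow(slots), min(n, nrow(slots)), prob = wts)
    loc <- slots[pick, , drop = FALSE]
    n <- nrow(loc)
    n_shared <- round(truth$shared_peak_fraction * n)
    lab <- rep(c("common", "A_only", "B_only"),
               c(n_shared, ceiling((n - n_shared) / 2), floor((n - n_shared) / 2)))
    dtf <- stats::rnorm(n, 0, truth$dtf_sd)
    base_cov <- stats::rlnorm(n, meanlog = log(50), sdlog = 0.4)
    cov_a <- ifelse(lab == "B_only", 0, base_cov * 2^(-dtf / 2))
    cov_b <- ifelse(lab == "A_only", 0, base_cov * 2^(+dtf / 2))
    for (ct in cell_types) {
      covs <- if (ct == "A") cov_a else cov_b
      has_peak <- if (ct == "A") lab != "B_only" else lab != "A_only"
      pk <- data.frame(chrom = loc$chrom, start = loc$start, end = loc$start + w,
                       name = sprintf("%s_%s_pk%d", tf, ct, seq_len(n)),
                       score = round(covs, 3), strand = ".",
                       tf = tf, cell_type = ct,
                       stringsAsFactors = FALSE)[has_peak, , drop = FALSE]
      counts <- round(covs * truth$library_size / 1e7)
      rd <- list()
      for (i in which(counts > 0)) {
        st <- loc$start[i] + sample.int(w - 1L, counts[i], replace = TRUE) - rl %/% 2L
        st <- pmax(st, 0L)
        rd[[length(rd) + 1L]] <- data.frame(chrom = loc$chrom[i], start = st,
                                            end = st + rl, stringsAsFactors = FALSE)
      }
      label <- paste(tf, ct, sep = ".")
      reads[[label]] <- if (length(rd) > 0L) do.call(rbind, rd) else
        data.frame(chrom = character(), start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
      peaks[[label]] <- pk
    }
    targets[[tf]] <- data.frame(chrom = loc$chrom, start = loc$start,
                                end = loc$start + w, tf = tf, label = lab,
                                target_dtf = dtf, stringsAsFactors = FALSE)
  }
  all_peaks <- do.call(rbind, peaks)
  rownames(all_peaks) <- NULL
  samples <- data.frame(tf = rep(truth$tfs, each = 2L),
                        cell_type = rep(cell_types, length(truth$tfs)),
                        stringsAsFactors = FALSE)
  samples$label <- paste(samples$tf, samples$cell_type, sep = ".")
  list(peaks = all_peaks, reads = reads[samples$label],
       library_sizes = stats::setNames(rep(truth$library_size, nrow(samples)),
                                       samples$label),
       samples = samples, target_dtf = do.call(rbind, targets),
       cell_types = cell_types)
}

#' Simulate expression and H3K27ac flags from gene-level delta-TF
#'
#' The ground-truth response is
#' `delta_ge = sum_i f_i(dtf_i) + sum_(i<j) gamma_ij dtf_i dtf_j + eps`,
#' `eps ~ N(0, noise_sd^2)`, with `f_i` linear (`beta_i x`) unless a smooth
#' effect replaces it. fpkm pairs are back-solved as
#' `fpkm_a = base * 2^(-delta_ge/2)`, `fpkm_b = base * 2^(+delta_ge/2)` with
#' log-normal base expression (exact for pseudocount 0, approximate
#' otherwise). Significance flags are TRUE when `|delta_ge|` exceeds the
#' truth's threshold; H3K27ac flags are sampled with odds multiplied by
#' `h3k27ac_odds_ratio` for genes whose `|eps| <= noise_sd` (the
#' "predictable" genes).
#'
#' @param truth `synthetic_truth`.
#' @param gene_dtf numeric matrix of gene-level delta-TF values (genes x
#'   TFs), e.g. from the pipeline run on simulated peaks.
#' @return list: `expression` data frame (`gene_id`, `fpkm_a`, `fpkm_b`,
#'   `significant`), `h3k27ac` logical vector, `delta_ge`, `noise` (the
#'   epsilon draws).
#' @export
simulate_expression <- function(truth, gene_dtf) {
  stopifnot(inherits(truth, "synthetic_truth"), is.matrix(gene_dtf))
  set.seed(truth$seed + 2L)
  n <- nrow(gene_dtf)
  beta <- rep_len(truth$linear_coefficients, ncol(gene_dtf))
  f_mat <- sweep(gene_dtf, 2L, beta, "*")
  if (!is.null(truth$smooth_effects)) {
    for (se in truth$smooth_effects) {
      f_mat[, se$tf] <- se$f(gene_dtf[, se$tf])
    }
  }
  signal <- rowSums(f_mat)
  if (!is.null(truth$interaction_effects)) {
    ie <- truth$interaction_effects
    for (r in seq_len(nrow(ie))) {
      signal <- signal + ie$gamma[r] * gene_dtf[, ie$i[r]] * gene_dtf[, ie$j[r]]
    }
  }
  eps <- stats::rnorm(n, 0, truth$noise_sd)
  delta_ge <- signal + eps
  base <- stats::rlnorm(n, meanlog = log(10), sdlog = 1)
  fpkm_a <- base * 2^(-delta_ge / 2)
  fpkm_b <- base * 2^(+delta_ge / 2)
  gene_id <- rownames(gene_dtf)
  if (is.null(gene_id)) gene_id <- sprintf("gene_%04d", seq_len(n))
  predictable <- abs(eps) <= truth$noise_sd
  p0 <- 0.3
  odds <- p0 / (1 - p0) * ifelse(predictable, truth$h3k27ac_odds_ratio, 1)
  h3k27ac <- stats::runif(n) < odds / (1 + odds)
  list(expression = data.frame(gene_id = gene_id, fpkm_a = fpkm_a,
                               fpkm_b = fpkm_b,
                               significant = abs(delta_ge) > truth$sig_threshold,
                               stringsAsFactors = FALSE),
       h3k27ac = stats::setNames(h3k27ac, gene_id),
       delta_ge = stats::setNames(delta_ge, gene_id),
       noise = stats::setNames(eps, gene_id))
}

#' Simulate a feature table directly at the modelling layer
#'
#' Draws standard-normal delta-TF predictors for every (gene, TF), builds the
#' ground-truth response of [simulate_expression()], and returns a ready
#' `gene_features` table (all genes bound by all TFs). This is the substrate
#' for parameter-recovery and model-class-separation studies where the
#' ChIP-Seq layer is irrelevant.
#'
#' @param truth `synthetic_truth`.
#' @param n_genes optional override of the truth's gene count.
#' @return list: `features` (`gene_features`), `truth`, `h3k27ac`, `noise`.
#' @export
simulate_feature_table <- function(truth, n_genes = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- if (is.null(n_genes)) truth$n_genes else n_genes
  set.seed(truth$seed)
  X <- matrix(stats::rnorm(n * truth$n_tfs), nrow = n,
              dimnames = list(sprintf("gene_%05d", seq_len(n)), truth$tfs))
  sim <- simulate_expression(truth, X)
  gene_scores <- lapply(stats::setNames(truth$tfs, truth$tfs), function(tf) {
    data.frame(gene_id = rownames(X), score = X[, tf], bound = TRUE,
               stringsAsFactors = FALSE)
  })
  dge <- data.frame(gene_id = rownames(X),
                    delta_ge = unname(sim$delta_ge), stringsAsFactors = FALSE)
  cats <- data.frame(gene_id = sim$expression$gene_id,
                     category = categorize_expression(sim$expression$fpkm_a,
                                                      sim$expression$fpkm_b,
                                                      sim$expression$significant),
                     stringsAsFactors = FALSE)
  features <- build_feature_table(gene_scores, dge, cats)
  list(features = features, truth = truth, h3k27ac = sim$h3k27ac, noise = sim$noise)
}

#' Simulate a complete study and run the pipeline over it
#'
#' Generates genome, peaks and reads; builds the merged atlas and coverage
#' matrix; assigns regions to genes; computes gene-level delta-TF with the
#' pipeline; then simulates expression *from those pipeline scores* (closing
#' the loop) and assembles the feature table.
#'
#' @param truth `synthetic_truth`.
#' @param preset `"small"` (default dimensions of `truth`) or
#'   `"paper_shaped"` (10 TFs, larger genome; heavier).
#' @return list with all intermediate artefacts: `genome`, `sim_peaks`,
#'   `atlas`, `map`, `features`, `expression`, `h3k27ac`, `truth`.
#' @export
simulate_study <- function(truth = synthetic_truth(),
                           preset = c("small", "paper_shaped")) {
  preset <- match.arg(preset)
  if (preset == "paper_shaped") {
    truth <- synthetic_truth(seed = truth$seed, n_genes = 5000, n_tfs = 10,
                             shared_peak_fraction = truth$shared_peak_fraction,
                             linear_coefficients = truth$linear_coefficients,
                             noise_sd = truth$noise_sd,
                             peaks_per_tf = 3000)
  }
  genome <- simulate_genome(seed = truth$seed, n_genes = truth$n_genes,
                            chrom_length = max(1e6, truth$n_genes * 12000L / 2L))
  sp <- simulate_peaks(truth, genome$genes)
  regions <- merge_peaks(sp$peaks)
  atlas <- compute_coverage(regions, sp$reads, sp$library_sizes, sp$samples)
  map <- assign_regions(regions, genome$genes)
  gene_scores <- list()
  for (tf in truth$tfs) {
    rs <- delta_binding_region(atlas, tf, cell_types = sp$cell_types)
    tf_bound <- .overlaps_any(regions, sp$peaks[sp$peaks$tf == tf, , drop = FALSE])
    gene_scores[[tf]] <- delta_binding_gene(rs, map, tf_bound)
  }
  genes_in_map <- gene_scores[[1L]]$gene_id
  gene_dtf <- sapply(truth$tfs, function(tf) {
    gene_scores[[tf]]$score[match(genes_in_map, gene_scores[[tf]]$gene_id)]
  })
  gene_dtf <- matrix(gene_dtf, nrow = length(genes_in_map),
                     dimnames = list(genes_in_map, truth$tfs))
  sim_expr <- simulate_expression(truth, gene_dtf)
  dge <- data.frame(gene_id = genes_in_map,
                    delta_ge = unname(sim_expr$delta_ge), stringsAsFactors = FALSE)
  cats <- data.frame(gene_id = sim_expr$expression$gene_id,
                     category = categorize_expression(sim_expr$expression$fpkm_a,
                                                      sim_expr$expression$fpkm_b,
                                                      sim_expr$expression$significant),
                     stringsAsFactors = FALSE)
  features <- build_feature_table(gene_scores, dge, cats)
  list(genome = genome, sim_peaks = sp, atlas = atlas, map = map,
       features = features, expression = sim_expr$expression,
       h3k27ac = sim_expr$h3k27ac, truth = truth)
}
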