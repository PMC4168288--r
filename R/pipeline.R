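# End-to-end glue: from peak calls, reads and expression to the modelling
# feature table. Each stage logs its record counts so filter attrition is
# visible.

#' Run the full feature-construction pipeline
#'
#' Merges all samples' peaks into atlas regions, builds the normalised
#' coverage matrix, assigns regions to genes, computes per-TF gene-level
#' delta-TF and per-gene delta-GE, classifies expression, and assembles the
#' `gene_features` table ready for [fit_delta_lm()] / [fit_delta_gam()].
#'
#' @param peaks peak data frame for all samples (`chrom`, `start`, `end`,
#'   `tf`, `cell_type`).
#' @param reads named list of read interval data frames, one per sample
#'   label `TF.cell_type`.
#' @param library_sizes named per-sample total read counts.
#' @param genes gene table from [read_genes()] or [simulate_genome()].
#' @param expression expression table from [read_expression()]
#'   (transcript-level rows are collapsed per gene).
#' @param cell_types length-2 vector naming cell types (A, B); contrasts are
#'   B over A.
#' @param tss_window,max_distance assignment rule parameters (bp).
#' @param pseudocount log-ratio stabiliser for delta-GE and delta-TF.
#' @param min_fpkm,min_fold expression category thresholds.
#' @param collapse transcript collapsing rule for the expression table.
#' @param verbose log per-stage record counts?
#' @return list: `regions`, `atlas`, `map`, `features`.
#' @export
pipeline_features <- function(peaks, reads, library_sizes, genes, expression,
                              cell_types = c("A", "B"),
                              tss_window = 1000, max_distance = 50000,
                              pseudocount = 1, min_fpkm = 2, min_fold = 4,
                              collapse = c("max", "mean"), verbose = TRUE) {
  collapse <- match.arg(collapse)
  say <- function(...) if (verbose) message(sprintf(...))
  say("pipeline: %d peaks across %d samples", nrow(peaks),
      length(unique(paste(peaks$tf, peaks$cell_type))))
  regions <- merge_peaks(peaks)
  say("pipeline: %d merged regions", nrow(regions))
  samples <- unique(peaks[, c("tf", "cell_type")])
  samples$label <- paste(samples$tf, samples$cell_type, sep = ".")
  atlas <- compute_coverage(regions, reads, library_sizes, samples)
  map <- assign_regions(regions, genes, tss_window = tss_window,
                        max_distance = max_distance)
  say("pipeline: %d regions assigned to %d genes, %d unassigned",
      attr(map, "n_regions") - length(map$unassigned),
      length(unique(map$entries$gene_id)), length(map$unassigned))
  tfs <- sort(unique(peaks$tf))
  gene_scores <- list()
  for (tf in tfs) {
    rs <- delta_binding_region(atlas, tf, cell_types = cell_types,
                               pseudocount = pseudocount)
    tf_bound <- .overlaps_any(regions, peaks[peaks$tf == tf, , drop = FALSE])
    gene_scores[[tf]] <- delta_binding_gene(rs, map, tf_bound)
  }
  expr <- collapse_expression(expression, method = collapse)
  genes_in_map <- gene_scores[[1L]]$gene_id
  expr <- expr[expr$gene_id %in% genes_in_map, , drop = FALSE]
  missing <- setdiff(genes_in_map, expr$gene_id)
  if (length(missing) > 0L) {
    say("pipeline: dropping %d mapped genes with no expression record", length(missing))
    gene_scores <- lapply(gene_scores, function(s)
      s[!s$gene_id %in% missing, , drop = FALSE])
  }
  dge <- data.frame(gene_id = expr$gene_id,
                    delta_ge = delta_expression(expr$fpkm_a, expr$fpkm_b,
                                                pseudocount = pseudocount),
                    stringsAsFactors = FALSE)
  cats <- data.frame(gene_id = expr$gene_id,
                     category = categorize_expression(expr$fpkm_a, expr$fpkm_b,
                                                      expr$significant,
                                                      min_fpkm = min_fpkm,
                                                      min_fold = min_fold),
                     stringsAsFactors = FALSE)
  features <- build_feature_table(gene_scores, dge, cats)
  say("pipeline: feature table with %d genes x %d TFs", nrow(features), length(tfs))
  list(regions = regions, atlas = atlas, map = map, features = features)
}
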