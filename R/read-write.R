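# Readers and writers for the plain-text formats the pipeline touches:
# BED3+ intervals, 5-column gene tables / BED12, expression TSVs, JASPAR PFM
# motif files, and generic TSV/JSON result tables. Parsers are line-level so
# that malformed input is reported with its file line number.

.is_skip_line <- function(line) {
  grepl("^\\s*$", line) || grepl("^#", line) ||
    grepl("^track\\b", line) || grepl("^browser\\b", line)
}

.parse_int <- function(s, line_no, field) {
  v <- suppressWarnings(as.integer(s))
  if (is.na(v) || as.character(v) != sub("^\\+", "", s)) {
    stop(sprintf("line %d: non-integer %s '%s'", line_no, field, s))
  }
  v
}

#' Read genomic intervals from a BED3+ file
#'
#' Reads tab-separated BED records (chrom, start, end, and optionally name,
#' score, strand). Comment, `track` and `browser` lines are skipped. With
#' `kind = "peak"` the TF and cell-type identity of the sample are attached as
#' columns; identity is supplied by the caller, never parsed from file names.
#'
#' @param path file path.
#' @param kind `"peak"` for peak calls, `"read"` for read intervals.
#' @param tf,cell_type sample identity attached when `kind = "peak"`.
#' @return data frame of validated intervals in input order; for peaks with
#'   columns `tf`, `cell_type` and `score`.
#' @export
read_intervals <- function(path, kind = c("peak", "read"), tf = NULL, cell_type = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  keep <- which(!vapply(lines, .is_skip_line, logical(1)))
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop(sprintf("line %d: fewer than 3 BED fields", ln))
    start <- .parse_int(f[2L], ln, "start")
    end <- .parse_int(f[3L], ln, "end")
    if (start < 0 || end <= start) {
      stop(sprintf("line %d: invalid interval [%d, %d) (need 0 <= start < end)", ln, start, end))
    }
    strand <- if (length(f) >= 6L) f[6L] else "."
    if (!strand %in% c("+", "-", ".")) {
      stop(sprintf("line %d: unknown strand symbol '%s'", ln, strand))
    }
    score <- NA_real_
    if (length(f) >= 5L && nzchar(f[5L]) && f[5L] != ".") {
      score <- suppressWarnings(as.numeric(f[5L]))
      if (is.na(score)) stop(sprintf("line %d: non-numeric score '%s'", ln, f[5L]))
      if (score < 0) stop(sprintf("line %d: negative score %s", ln, f[5L]))
    }
    out[[i]] <- data.frame(
      chrom = f[1L], start = start, end = end,
      name = if (length(f) >= 4L) f[4L] else NA_character_,
      score = score, strand = strand, stringsAsFactors = FALSE
    )
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = numeric(), strand = character(),
               stringsAsFactors = FALSE)
  if (kind == "peak") {
    res$tf <- if (is.null(tf)) NA_character_ else tf
    res$cell_type <- if (is.null(cell_type)) NA_character_ else cell_type
  }
  validate_intervals(res, what = kind)
  res
}

#' Read gene models with strand-derived TSS
#'
#' Accepts a 5/6-column tab-separated gene table (`gene_id`, `chrom`,
#' `strand`, `txStart`, `txEnd`[, `transcript_id`]; header optional) or BED12.
#' The transcription start site is `txStart` on the plus strand and
#' `txEnd - 1` on the minus strand (last covered base, half-open convention).
#'
#' @param path file path.
#' @return data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss`.
#' @export
read_genes <- function(path) {
  lines <- readLines(path)
  keep <- which(!vapply(lines, .is_skip_line, logical(1)))
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (i == 1L && identical(f[1L], "gene_id")) { rows[[i]] <- NULL; next }
    if (length(f) == 12L) { # BED12: chrom start end name score strand ...
      start <- .parse_int(f[2L], ln, "start"); end <- .parse_int(f[3L], ln, "end")
      rec <- data.frame(gene_id = f[4L], transcript_id = NA_character_,
                        chrom = f[1L], strand = f[6L],
                        start = start, end = end, stringsAsFactors = FALSE)
    } else if (length(f) >= 5L) {
      start <- .parse_int(f[4L], ln, "txStart"); end <- .parse_int(f[5L], ln, "txEnd")
      rec <- data.frame(gene_id = f[1L],
                        transcript_id = if (length(f) >= 6L) f[6L] else NA_character_,
                        chrom = f[2L], strand = f[3L],
                        start = start, end = end, stringsAsFactors = FALSE)
    } else stop(sprintf("line %d: expected 5+ gene-table or 12 BED12 fields", ln))
    if (!rec$strand %in% c("+", "-")) {
      stop(sprintf("line %d: strand '%s' (TSS undefined without +/- strand)", ln, rec$strand))
    }
    if (rec$end <= rec$start) stop(sprintf("line %d: txEnd <= txStart", ln))
    rows[[i]] <- rec
  }
  rows <- Filter(Negate(is.null), rows)
  genes <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene_id = character(), transcript_id = character(),
               chrom = character(), strand = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  key <- paste(genes$gene_id, genes$transcript_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- genes$gene_id[duplicated(key)][1L]
    stop(sprintf("duplicate gene/transcript key for '%s'", d))
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  validate_intervals(genes, what = "gene")
  genes
}

#' Read a gene expression table
#'
#' TSV with header `gene_id`, `fpkm_a`, `fpkm_b`, `significant`. Significance
#' flags are consumed as pre-computed (e.g. Cuffdiff q <= 0.05), never
#' inferred here.
#'
#' @param path file path.
#' @return data frame with non-negative fpkm columns and a logical
#'   `significant` column.
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("gene_id", "fpkm_a", "fpkm_b", "significant")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0L) stop(sprintf("expression table lacks column(s): %s",
                                      paste(miss, collapse = ", ")))
  x <- x[, req]
  if (nrow(x) == 0L) return(x)
  for (cc in c("fpkm_a", "fpkm_b")) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    if (any(is.na(v))) stop(sprintf("non-numeric %s value", cc))
    if (any(v < 0)) stop(sprintf("negative %s value (fpkm must be >= 0)", cc))
    x[[cc]] <- v
  }
  s <- x$significant
  if (!is.logical(s)) {
    s <- tolower(as.character(s))
    map <- c("true" = TRUE, "false" = FALSE, "1" = TRUE, "0" = FALSE,
             "yes" = TRUE, "no" = FALSE)
    if (any(!s %in% names(map))) stop("unparseable 'significant' flag")
    s <- unname(map[s])
  }
  x$significant <- s
  x
}

#' Read position weight matrices from JASPAR-style PFM text
#'
#' Each motif is a `>` header line followed by four count rows (A, C, G, T;
#' bracketed JASPAR 2016 style or plain numbers). Counts are regularised with
#' a pseudocount per cell and column-normalised to probabilities.
#'
#' @param path file path.
#' @param pseudocount added to every count cell before normalisation.
#' @param background length-4 background base probability vector (A, C, G, T).
#' @return list of `pwm` objects: `motif_id`, `matrix` (4 x L column-stochastic,
#'   rows A/C/G/T), `background`.
#' @export
read_pwms <- function(path, pseudocount = 0.5, background = rep(0.25, 4)) {
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no '>' motif header found")
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (m in seq_along(heads)) {
    id <- sub("^>\\s*", "", lines[heads[m]])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    body <- lines[(bounds[m] + 1L):(bounds[m + 1L] - 1L)]
    if (length(body) != 4L) {
      stop(sprintf("motif '%s': expected 4 count rows (A/C/G/T), got %d", id, length(body)))
    }
    rows <- lapply(body, function(b) {
      b <- gsub("^[ACGTacgt]\\s*", "", b)
      b <- gsub("[\\[\\]]", "", b, perl = TRUE)
      v <- suppressWarnings(as.numeric(strsplit(trimws(b), "\\s+")[[1L]]))
      if (any(is.na(v))) stop(sprintf("motif '%s': non-numeric count", id))
      if (any(v < 0)) stop(sprintf("motif '%s': negative count", id))
      v
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop(sprintf("motif '%s': count rows of unequal length", id))
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    prob <- counts + pseudocount
    prob <- sweep(prob, 2L, colSums(prob), "/")
    out[[m]] <- structure(
      list(motif_id = id, matrix = prob,
           background = stats::setNames(as.numeric(background), c("A", "C", "G", "T"))),
      class = "pwm")
  }
  out
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%d bp)\n", x$motif_id, ncol(x$matrix)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Write a result table to TSV or JSON
#'
#' TSV output round-trips through [utils::read.delim()] bit-exactly at 6+
#' significant digits; JSON output is records-oriented.
#'
#' @param records data frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  if (format == "tsv") {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}
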