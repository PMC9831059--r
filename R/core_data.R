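#' tcis: time-course isoform switch analysis
#'
#' Detection, scoring and downstream analysis of isoform-switch (IS)
#' events in time-course transcriptomics data, together with a
#' ground-truthed count simulator and a precision/recall benchmark
#' harness. See `vignette("tcis-methods")` for the underlying model.
#'
#' @keywords internal
"_PACKAGE"

## ---------------------------------------------------------------------------
## TimeCourseMatrix
## ---------------------------------------------------------------------------

#' Construct a time-course expression matrix
#'
#' A `TimeCourseMatrix` holds isoform-level expression (TPM or counts) over
#' an ordered series of time points with a fixed number of replicates per
#' time point. Columns are ordered time-major, replicate-minor: all
#' replicates of the first time point, then all replicates of the second,
#' and so on.
#'
#' @param values Non-negative numeric matrix, transcripts x samples, with
#'   row names giving transcript identifiers. Column count must equal
#'   `length(time_points) * n_replicates`.
#' @param time_points Character or numeric vector of ordered time-point
#'   labels (length T >= 2).
#' @param n_replicates Positive integer, replicates per time point.
#' @param gene_map Named character vector mapping transcript id (names) to
#'   gene id (values). Every transcript in `values` must be present.
#' @return An object of class `TimeCourseMatrix`: a list with elements
#'   `values`, `transcript_ids`, `time_points`, `n_replicates`, `gene_map`.
#' @examples
#' vals <- matrix(c(5, 1, 1, 5, 2, 2, 2, 2), nrow = 2, byrow = TRUE,
#'                dimnames = list(c("tx1", "tx2"), NULL))
#' m <- time_course_matrix(vals, time_points = c("0h", "6h"),
#'                         n_replicates = 2,
#'                         gene_map = c(tx1 = "g1", tx2 = "g1"))
#' m
#' @export
time_course_matrix <- function(values, time_points, n_replicates, gene_map) {
  values <- as.matrix(values)
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("'values' must have transcript ids as row names")
  time_points <- as.character(time_points)
  n_replicates <- as.integer(n_replicates)
  if (length(time_points) < 2L)
    stop("at least two time points are required")
  if (n_replicates < 1L)
    stop("'n_replicates' must be >= 1")
  if (ncol(values) != length(time_points) * n_replicates)
    stop(sprintf("expected %d sample columns (T=%d x R=%d), found %d",
                 length(time_points) * n_replicates, length(time_points),
                 n_replicates, ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate transcript ids")
  if (any(!is.finite(values)))
    stop("non-finite expression values")
  if (any(values < 0))
    stop("negative expression values")
  gene_map <- unlist(gene_map)
  missing <- setdiff(rownames(values), names(gene_map))
  if (length(missing))
    stop("transcripts missing from gene_map: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  gene_map <- gene_map[rownames(values)]
  colnames(values) <- sample_labels(time_points, n_replicates)
  structure(list(values = values,
                 transcript_ids = if (is.null(rownames(values)))
                   character(0) else rownames(values),
                 time_points = time_points,
                 n_replicates = n_replicates,
                 gene_map = gene_map),
            class = "TimeCourseMatrix")
}

sample_labels <- function(time_points, n_replicates) {
  paste0(rep(time_points, each = n_replicates), "_r",
         rep(seq_len(n_replicates), times = length(time_points)))
}

#' @export
print.TimeCourseMatrix <- function(x, ...) {
  cat(sprintf("%s: %d transcripts, %d genes, %d time points x %d replicates\n",
              class(x)[1], nrow(x$values), length(unique(x$gene_map)),
              length(x$time_points), x$n_replicates))
  cat("time points:", paste(x$time_points, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.TimeCourseMatrix <- function(x) dim(x$values)

n_timepoints <- function(m) length(m$time_points)

## columns belonging to time point t (1-based)
time_columns <- function(m, t) {
  (t - 1L) * m$n_replicates + seq_len(m$n_replicates)
}

## transcripts x T x R array for one gene
gene_array <- function(values, n_timepoints, n_replicates) {
  array(values, dim = c(nrow(values), n_replicates, n_timepoints),
        dimnames = list(rownames(values), NULL, NULL))
}

## ---------------------------------------------------------------------------
## Readers / writers
## ---------------------------------------------------------------------------

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an isoform expression matrix from delimited text
#'
#' The file must have a header row, transcript ids in the first column and
#' `length(time_points) * n_replicates` numeric sample columns ordered
#' time-major, replicate-minor (the order written by [write_expression()]).
#'
#' @inheritParams time_course_matrix
#' @param path TSV (or CSV) file path.
#' @param gene_map Named character vector, or path to a two-column
#'   (transcript_id, gene_id) mapping file.
#' @return A [time_course_matrix()].
#' @export
read_expression <- function(path, time_points, n_replicates, gene_map) {
  df <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file has no sample columns")
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric entries in sample columns")
  rownames(vals) <- ids
  if (is.character(gene_map) && length(gene_map) == 1L && file.exists(gene_map))
    gene_map <- read_gene_map(gene_map)
  time_course_matrix(vals, time_points, n_replicates, gene_map)
}

#' Write an expression matrix as TSV
#'
#' Values are written at full precision (, so that a write/read round trip
#' reproduces the matrix exactly).
#'
#' @param m A `TimeCourseMatrix`.
#' @param path Output file path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(transcript_id = m$transcript_ids, m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a transcript-to-gene mapping
#'
#' @param path Two-column delimited file (transcript_id, gene_id), with or
#'   without a header line named `transcript_id`.
#' @return Named character vector: transcript id -> gene id.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, sep = delim_for(path), header = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) && identical(tolower(df[1, 1]), "transcript_id"))
    df <- df[-1L, , drop = FALSE]
  if (ncol(df) < 2L) stop("gene map must have two columns")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Extract a transcript-to-gene mapping from a GTF file
#'
#' Convenience wrapper; only the `transcript_id` and `gene_id` attributes of
#' transcript (or exon) features are used. Requires the rtracklayer package.
#'
#' @param path GTF/GFF2 file.
#' @return Named character vector: transcript id -> gene id.
#' @export
read_gene_map_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_map_gtf requires the 'rtracklayer' package")
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- !is.na(gr$transcript_id)
  tx <- as.character(gr$transcript_id[keep])
  gn <- as.character(gr$gene_id[keep])
  dup <- duplicated(tx)
  stats::setNames(gn[!dup], tx[!dup])
}

#' Read a transcript-to-protein-domain mapping
#'
#' One row per (transcript, domain) pair. Transcripts absent from the file
#' are treated as *unknown* by [domain_gain_loss()], not as domain-free.
#'
#' @param path Two-column delimited file (transcript_id, domain_id).
#' @return A named list of character vectors (domain sets per transcript)
#'   with class `DomainMap`.
#' @export
read_domain_map <- function(path) {
  df <- utils::read.delim(path, sep = delim_for(path), header = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) && identical(tolower(df[1, 1]), "transcript_id"))
    df <- df[-1L, , drop = FALSE]
  if (ncol(df) < 2L) stop("domain map must have two columns")
  domain_map(split(as.character(df[[2L]]), as.character(df[[1L]])))
}

#' Construct a domain map from a named list
#'
#' @param x Named list: transcript id -> character vector of domain ids.
#' @return The list with class `DomainMap`.
#' @export
domain_map <- function(x) {
  stopifnot(is.list(x), !is.null(names(x)))
  structure(lapply(x, function(d) unique(as.character(d))),
            class = "DomainMap")
}

## ---------------------------------------------------------------------------
## Filtering and relative abundance
## ---------------------------------------------------------------------------

#' Remove lowly expressed transcripts
#'
#' Drops transcripts whose mean expression over *all* samples (pooled
#' across time points and replicates) is below `min_mean_tpm`. A transcript
#' with mean exactly equal to the cutoff is retained. The gene map is
#' restricted to the surviving transcripts.
#'
#' @param m A `TimeCourseMatrix` in TPM units.
#' @param min_mean_tpm Cutoff on the per-transcript mean (default 1).
#' @return Filtered `TimeCourseMatrix`.
#' @export
filter_low_expression <- function(m, min_mean_tpm = 1) {
  stopifnot(inherits(m, "TimeCourseMatrix"))
  keep <- rowMeans(m$values) >= min_mean_tpm
  if (!any(keep))
    warning("no transcripts pass the expression filter")
  time_course_matrix(m$values[keep, , drop = FALSE], m$time_points,
                     m$n_replicates, m$gene_map[keep])
}

#' Compute relative isoform abundance
#'
#' For every gene and sample, each isoform's expression is divided by the
#' total expression of the gene in that sample, yielding isoform fractions
#' that sum to one. Samples where a gene is entirely unexpressed get
#' fractions of 0 (not NaN); such genes are skipped by switch detection at
#' the affected time points.
#'
#' @param m A `TimeCourseMatrix`.
#' @return A `RelativeAbundance` object (same shape and metadata, values in
#'   \[0, 1\]).
#' @export
relative_abundance <- function(m) {
  stopifnot(inherits(m, "TimeCourseMatrix"))
  gene <- m$gene_map[rownames(m$values)]
  totals <- rowsum(m$values, group = gene, reorder = FALSE)
  denom <- totals[match(gene, rownames(totals)), , drop = FALSE]
  frac <- m$values / denom
  frac[denom == 0] <- 0
  out <- time_course_matrix(frac, m$time_points, m$n_replicates, m$gene_map)
  class(out) <- c("RelativeAbundance", class(out))
  out
}
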