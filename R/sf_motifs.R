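## ---------------------------------------------------------------------------
## Splicing-factor co-expression and PSSM motif enrichment
## ---------------------------------------------------------------------------

BASES <- c("A", "C", "G", "T")

#' Construct a PSSM motif
#'
#' Builds a log2-odds position-specific scoring matrix from nucleotide
#' probabilities (or counts) and a background distribution. U is treated
#' as T. The score threshold is unset until [calibrate_threshold()] is
#' applied.
#'
#' @param name Motif name.
#' @param prob_matrix 4 x L matrix (rows A, C, G, T/U) of per-position
#'   probabilities or counts; columns are normalized to sum to 1.
#' @param background Length-4 nucleotide background frequencies (must sum
#'   to 1); default uniform.
#' @param pseudocount Added to each cell before normalization to avoid
#'   -Inf log-odds (default 0.01).
#' @return List of class `PSSMMotif`: `name`, `matrix` (log2-odds),
#'   `background`, `threshold` (NA until calibrated).
#' @export
pssm_motif <- function(name, prob_matrix, background = rep(0.25, 4),
                       pseudocount = 0.01) {
  prob_matrix <- as.matrix(prob_matrix)
  if (nrow(prob_matrix) != 4L)
    stop("'prob_matrix' must have 4 rows (A, C, G, T)")
  if (any(prob_matrix < 0)) stop("negative motif probabilities")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6)
    stop("'background' must be 4 positive frequencies summing to 1")
  p <- sweep(prob_matrix + pseudocount, 2L,
             colSums(prob_matrix + pseudocount), "/")
  lo <- log2(p / background)
  dimnames(lo) <- list(BASES, NULL)
  structure(list(name = name, matrix = lo,
                 background = stats::setNames(background, BASES),
                 threshold = NA_real_),
            class = "PSSMMotif")
}

#' @export
print.PSSMMotif <- function(x, ...) {
  cat(sprintf("PSSMMotif '%s': length %d, threshold %s\n", x$name,
              ncol(x$matrix),
              if (is.na(x$threshold)) "uncalibrated"
              else signif(x$threshold, 4)))
  invisible(x)
}

#' Read a position weight matrix
#'
#' Accepts either a tab-delimited PWM (4 columns A/C/G/T, one row per
#' position, optional header) or MEME minimal format (the first
#' letter-probability matrix in the file).
#'
#' @param path PWM file.
#' @param name Motif name (default: file base name, or the MEME MOTIF id).
#' @param background Background frequencies for the log-odds.
#' @return A [pssm_motif()].
#' @export
read_pwm <- function(path, name = NULL, background = rep(0.25, 4)) {
  lines <- readLines(path)
  if (any(grepl("^MEME version", lines))) {
    mi <- grep("^MOTIF", lines)[1L]
    if (is.na(mi)) stop("no MOTIF block in MEME file")
    if (is.null(name))
      name <- strsplit(trimws(lines[mi]), "\\s+")[[1L]][2L]
    li <- grep("^letter-probability matrix", lines)[1L]
    rows <- list()
    for (ln in lines[-seq_len(li)]) {
      if (!grepl("^\\s*[0-9.eE+-]", ln)) break
      rows[[length(rows) + 1L]] <-
        as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
    }
    mat <- t(do.call(rbind, rows))
  } else {
    df <- utils::read.delim(path, header = any(grepl("[ACGTUacgtu]",
                                                     lines[1L])),
                            sep = "", stringsAsFactors = FALSE)
    mat <- t(as.matrix(df[, 1:4]))
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  pssm_motif(name, mat, background)
}

seq_to_codes <- function(seq) {
  chars <- strsplit(toupper(chartr("U", "T", seq)), "")[[1L]]
  match(chars, BASES)                    # NA for ambiguous bases
}

#' Scan a sequence with a PSSM
#'
#' Computes the log2-odds score at every offset of the sequence. Ambiguous
#' bases (anything outside A/C/G/T/U) contribute 0 to the score, i.e.
#' they are scored as background.
#'
#' @param seq Nucleotide string (DNA or RNA alphabet), at least as long as
#'   the motif.
#' @param motif A [pssm_motif()].
#' @return Numeric vector of scores, one per start offset
#'   (length `nchar(seq) - L + 1`).
#' @export
pssm_scan <- function(seq, motif) {
  stopifnot(inherits(motif, "PSSMMotif"))
  L <- ncol(motif$matrix)
  codes <- seq_to_codes(seq)
  n <- length(codes) - L + 1L
  if (n < 1L) stop("sequence shorter than the motif")
  scores <- numeric(n)
  for (pos in seq_len(L)) {
    v <- motif$matrix[, pos]
    contrib <- v[codes[pos:(pos + n - 1L)]]
    contrib[is.na(contrib)] <- 0
    scores <- scores + contrib
  }
  unname(scores)
}

#' Calibrate a score threshold at a target false-positive rate
#'
#' Computes the exact distribution of the motif score under the background
#' model by dynamic programming over a discretized score lattice and
#' returns the smallest threshold whose background tail mass is below
#' `fpr`. The returned value is shifted up by the maximal discretization
#' error, so `P(score >= threshold | background) < fpr` holds for the
#' exact (undiscretized) scores as well.
#'
#' @param motif A [pssm_motif()].
#' @param fpr Target false-positive rate (default 0.01). `fpr >= 1`
#'   returns the minimum achievable score.
#' @param granularity Score lattice step (default 1e-3).
#' @return Score threshold (numeric scalar).
#' @export
calibrate_threshold <- function(motif, fpr = 0.01, granularity = 1e-3) {
  stopifnot(inherits(motif, "PSSMMotif"))
  if (fpr <= 0) stop("'fpr' must be positive")
  lat <- round(motif$matrix / granularity)
  if (fpr >= 1) return(sum(apply(motif$matrix, 2L, min)))
  cur <- c(1)                            # P(score = origin), origin = 0
  origin <- 0L
  bg <- motif$background
  for (pos in seq_len(ncol(lat))) {
    col <- lat[, pos]
    cmin <- min(col); cmax <- max(col)
    new <- numeric(length(cur) + cmax - cmin)
    for (b in 1:4) {
      off <- col[b] - cmin
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + bg[b] * cur
    }
    cur <- new
    origin <- origin + cmin
  }
  tail_mass <- rev(cumsum(rev(cur)))
  q <- which(tail_mass < fpr)
  if (!length(q)) return(Inf)            # degenerate: fpr below min tail
  thr_lat <- origin + q[1L] - 1L
  thr_lat * granularity + ncol(lat) * granularity / 2
}

#' Calibrate a list of motifs in place
#'
#' @param motifs List of [pssm_motif()] objects.
#' @inheritParams calibrate_threshold
#' @return The list with each motif's `threshold` set.
#' @export
calibrate_motifs <- function(motifs, fpr = 0.01, granularity = 1e-3) {
  lapply(motifs, function(m) {
    m$threshold <- calibrate_threshold(m, fpr, granularity)
    m
  })
}

## ---------------------------------------------------------------------------
## Exon flanks
## ---------------------------------------------------------------------------

#' Construct a set of exon-boundary flank sequences
#'
#' @param category One of "lost", "gained", "unregulated".
#' @param five_prime,three_prime Character vectors of flank sequences
#'   around the 5' and 3' exon boundaries.
#' @param flank_width Flank half-width in nt.
#' @return List of class `ExonFlankSet`.
#' @export
exon_flank_set <- function(category = c("lost", "gained", "unregulated"),
                           five_prime, three_prime, flank_width) {
  category <- match.arg(category)
  chk <- function(x) {
    x <- toupper(x)
    if (length(x) && any(grepl("[^ACGTUN]", x)))
      stop("flank sequences must be over the ACGTU(N) alphabet")
    x
  }
  structure(list(category = category, five_prime = chk(five_prime),
                 three_prime = chk(three_prime),
                 flank_width = as.integer(flank_width)),
            class = "ExonFlankSet")
}

## ordered exon table for one transcript; structure columns:
## transcript_id, chrom, start, end, strand (1-based inclusive coordinates)
tx_exons <- function(structure, tx) {
  e <- structure[structure$transcript_id == tx, , drop = FALSE]
  e <- e[order(e$start), , drop = FALSE]
  if (nrow(e) && e$strand[1L] == "-") e <- e[rev(seq_len(nrow(e))), ,
                                             drop = FALSE]
  e
}

exon_key <- function(e) paste0(e$chrom, ":", e$start, "-", e$end, "(",
                               e$strand, ")")

#' Categorize exons of switching isoform pairs
#'
#' Given detected events and a transcript exon structure table, classifies
#' the *internal* exons (first and last exons of each isoform are
#' excluded) into: `lost` (in the pre-switch dominant isoform only),
#' `gained` (in the post-switch dominant isoform only) and `unregulated`
#' (shared by both isoforms, plus internal exons of the gene's non-switch
#' isoforms). Exons are identified by genomic coordinates.
#'
#' @param events An `ISEvents` data frame.
#' @param structure Data frame with columns `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` (1-based inclusive, one row per exon).
#' @param gene_map Named transcript -> gene vector (to collect the
#'   non-switch isoforms of the events' genes).
#' @return List of data frames `lost`, `gained`, `unregulated` (exon rows,
#'   deduplicated by coordinates).
#' @export
classify_event_exons <- function(events, structure, gene_map = NULL) {
  internal <- function(tx) {
    e <- tx_exons(structure, tx)
    if (nrow(e) <= 2L) e[0L, , drop = FALSE]
    else e[2:(nrow(e) - 1L), , drop = FALSE]
  }
  lost <- gained <- unreg <- list()
  for (i in seq_len(nrow(events))) {
    ea <- internal(events$isoform_a[i])
    eb <- internal(events$isoform_b[i])
    ka <- exon_key(ea); kb <- exon_key(eb)
    lost[[i]] <- ea[!ka %in% kb, , drop = FALSE]
    gained[[i]] <- eb[!kb %in% ka, , drop = FALSE]
    unreg[[i]] <- ea[ka %in% kb, , drop = FALSE]
    if (!is.null(gene_map)) {
      gene <- gene_map[events$isoform_a[i]]
      others <- setdiff(names(gene_map)[gene_map == gene],
                        c(events$isoform_a[i], events$isoform_b[i]))
      for (tx in others)
        unreg[[length(unreg) + 1L]] <- internal(tx)
    }
  }
  dedup <- function(lst) {
    d <- do.call(rbind, lst)
    if (is.null(d) || !nrow(d)) return(structure[0L, , drop = FALSE])
    d[!duplicated(exon_key(d)), , drop = FALSE]
  }
  lost <- dedup(lost); gained <- dedup(gained); unreg <- dedup(unreg)
  reg_keys <- c(exon_key(lost), exon_key(gained))
  list(lost = lost, gained = gained,
       unregulated = unreg[!exon_key(unreg) %in% reg_keys, , drop = FALSE])
}

#' Extract exon-boundary flank sequences
#'
#' For each exon, takes `flank_width` nt on each side of the 5' and 3'
#' boundaries (2 * flank_width nt per boundary). Minus-strand flanks are
#' reverse-complemented so that all returned sequences read 5' to 3' on
#' the transcript; the 5'/3' roles follow the transcript orientation.
#' Flanks extending beyond the chromosome are truncated.
#'
#' @param exons Data frame with columns `chrom`, `start`, `end`, `strand`.
#' @param genome A `Biostrings::DNAStringSet` named by chromosome (e.g.
#'   from `Biostrings::readDNAStringSet`).
#' @param category Category label for the resulting [exon_flank_set()].
#' @param flank_width Half-width in nt (default 50).
#' @return An [exon_flank_set()].
#' @export
exon_flanks <- function(exons, genome, category = "unregulated",
                        flank_width = 50L) {
  five <- character(0); three <- character(0)
  for (i in seq_len(nrow(exons))) {
    chrom <- exons$chrom[i]
    if (!chrom %in% names(genome)) next
    chr <- genome[[chrom]]
    len <- length(chr)
    cut <- function(pos) {
      a <- max(1L, pos - flank_width)
      b <- min(len, pos + flank_width - 1L)
      as.character(Biostrings::subseq(chr, a, b))
    }
    left <- cut(exons$start[i])          # genomic-left boundary
    right <- cut(exons$end[i] + 1L)      # genomic-right boundary
    if (identical(exons$strand[i], "-")) {
      rc <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
      five <- c(five, rc(right))
      three <- c(three, rc(left))
    } else {
      five <- c(five, left)
      three <- c(three, right)
    }
  }
  exon_flank_set(category, five, three, flank_width)
}

## ---------------------------------------------------------------------------
## Enrichment
## ---------------------------------------------------------------------------

above_threshold_scores <- function(seqs, motif) {
  L <- ncol(motif$matrix)
  out <- lapply(seqs[nchar(seqs) >= L], pssm_scan, motif = motif)
  s <- unlist(out)
  s[s >= motif$threshold]
}

#' Motif enrichment in regulated versus unregulated exon flanks
#'
#' For each motif and exon boundary (5', 3'), collects the above-threshold
#' log-odds scores in each category's flank sequences and tests whether
#' regulated (lost, resp. gained) exons carry higher scores than
#' unregulated ones with a one-sided Mann-Whitney U test.
#'
#' @param lost,gained,unregulated [exon_flank_set()] objects.
#' @param motifs List of calibrated [pssm_motif()] objects (see
#'   [calibrate_motifs()]); uncalibrated motifs are calibrated at `fpr`.
#' @param fpr False-positive rate used to calibrate missing thresholds.
#' @return Data frame: `motif`, `boundary`, `comparison`, `n_regulated`,
#'   `n_unregulated` (numbers of above-threshold scores) and `p_value`
#'   (NA when either side has no scores).
#' @export
motif_enrichment <- function(lost, gained, unregulated, motifs,
                             fpr = 0.01) {
  stopifnot(inherits(unregulated, "ExonFlankSet"))
  if (inherits(motifs, "PSSMMotif")) motifs <- list(motifs)
  rows <- list()
  for (motif in motifs) {
    if (is.na(motif$threshold))
      motif$threshold <- calibrate_threshold(motif, fpr)
    for (boundary in c("five_prime", "three_prime")) {
      bg_scores <- above_threshold_scores(unregulated[[boundary]], motif)
      for (cmp in list(lost = lost, gained = gained)) {
        if (is.null(cmp)) next
        reg_scores <- above_threshold_scores(cmp[[boundary]], motif)
        p <- if (length(reg_scores) && length(bg_scores))
          suppressWarnings(stats::wilcox.test(
            reg_scores, bg_scores, alternative = "greater")$p.value)
        else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motif$name,
          boundary = if (boundary == "five_prime") "5p" else "3p",
          comparison = paste0(cmp$category, "_vs_unregulated"),
          n_regulated = length(reg_scores),
          n_unregulated = length(bg_scores),
          p_value = p, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

## ---------------------------------------------------------------------------
## Splicing-factor co-expression
## ---------------------------------------------------------------------------

#' Correlate splicing-factor expression with isoform abundance
#'
#' Pearson correlation between each splicing factor's replicate-mean
#' expression course and each isoform's replicate-mean relative-abundance
#' course. Splicing factors must be expressed (mean TPM > 1) at every time
#' point; correlation-test p-values are BH-adjusted over all tested pairs
#' and pairs with `|r| > r_cut` and adjusted p < `alpha` are returned.
#'
#' @param I A `RelativeAbundance` object.
#' @param sf_expression A `TimeCourseMatrix` of splicing-factor expression
#'   (TPM) on the same time axis.
#' @param r_cut Absolute correlation cutoff (default 0.7).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param isoforms Optional transcript ids to test (e.g. the switching
#'   isoforms of detected events); default all.
#' @return Data frame: `splicing_factor`, `isoform`, `r`, `p_value`,
#'   `adj_p_value`, filtered to the significant correlated pairs.
#' @export
sf_coexpression <- function(I, sf_expression, r_cut = 0.7, alpha = 0.05,
                            isoforms = NULL) {
  stopifnot(inherits(I, "RelativeAbundance"),
            inherits(sf_expression, "TimeCourseMatrix"))
  if (!identical(I$time_points, sf_expression$time_points))
    stop("time axes of isoform and splicing-factor data differ")
  tp_means <- function(m) {
    grp <- rep(seq_len(n_timepoints(m)), each = m$n_replicates)
    t(apply(m$values, 1L, function(v) tapply(v, grp, mean)))
  }
  sfm <- tp_means(sf_expression)
  sfm <- sfm[matrixStats::rowMins(sfm) > 1, , drop = FALSE]
  im <- tp_means(I)
  if (!is.null(isoforms)) im <- im[intersect(isoforms, rownames(im)), ,
                                   drop = FALSE]
  rows <- list()
  for (sf in rownames(sfm)) {
    x <- sfm[sf, ]
    if (stats::sd(x) == 0) next
    for (iso in rownames(im)) {
      y <- im[iso, ]
      if (stats::sd(y) == 0) next
      ct <- stats::cor.test(x, y, method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        splicing_factor = sf, isoform = iso,
        r = unname(ct$estimate), p_value = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(splicing_factor = character(0),
                      isoform = character(0), r = numeric(0),
                      p_value = numeric(0), adj_p_value = numeric(0)))
  df <- do.call(rbind, rows)
  df$adj_p_value <- adjust_pvalues(df$p_value, "BH")
  df <- df[abs(df$r) > r_cut & df$adj_p_value < alpha, , drop = FALSE]
  rownames(df) <- NULL
  df
}
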