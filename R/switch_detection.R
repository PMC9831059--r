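## ---------------------------------------------------------------------------
## Isoform switch detection and scoring
## ---------------------------------------------------------------------------

#' Detection configuration
#'
#' Thresholds and testing options for [detect_isoform_switches()]. All
#' `min_*` thresholds are inclusive minimums: an event is reported when
#' every metric is at least its threshold and the adjusted p-value is below
#' `alpha`.
#'
#' @param min_support Minimum fraction of replicates whose abundance curves
#'   must cross in an interval for it to count as a switch point
#'   (default 0.6).
#' @param min_switch_prob Minimum switching probability (default 0.5).
#' @param min_diff Minimum difference of relative abundance across the
#'   switch point (default 0.2).
#' @param min_event_importance Minimum event importance (default 0.3).
#' @param min_dissimilarity Minimum dissimilarity coefficient
#'   (default 0.5). Note that with the default `d = 1 - r^2` measure,
#'   strongly anti-correlated isoform pairs (the signature of a clean
#'   switch) have *low* d; set this to 0 to disable the filter, or use
#'   `dissimilarity_method = "half_one_minus_r"` which maps r = -1 to 1.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param correction Multiple-testing correction: "BH" (default), "holm" or
#'   "bonferroni".
#' @param dissimilarity_method "one_minus_r2" (default, `d = 1 - r^2`) or
#'   "half_one_minus_r" (`d = (1 - r)/2`).
#' @param n_permutations Permutations for the single-replicate test
#'   (default 999).
#' @param seed Seed for the permutation test.
#' @return A list of class `DetectionConfig`.
#' @export
detection_config <- function(min_support = 0.6, min_switch_prob = 0.5,
                             min_diff = 0.2, min_event_importance = 0.3,
                             min_dissimilarity = 0.5, alpha = 0.05,
                             correction = c("BH", "holm", "bonferroni"),
                             dissimilarity_method = c("one_minus_r2",
                                                      "half_one_minus_r"),
                             n_permutations = 999L, seed = 1L) {
  correction <- match.arg(correction)
  dissimilarity_method <- match.arg(dissimilarity_method)
  for (v in c(min_support, min_switch_prob, min_dissimilarity))
    if (v < 0 || v > 1) stop("thresholds on [0,1] metrics must lie in [0,1]")
  if (min_diff < 0 || min_event_importance < 0)
    stop("metric thresholds must be non-negative")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  structure(list(min_support = min_support,
                 min_switch_prob = min_switch_prob,
                 min_diff = min_diff,
                 min_event_importance = min_event_importance,
                 min_dissimilarity = min_dissimilarity,
                 alpha = alpha, correction = correction,
                 dissimilarity_method = dissimilarity_method,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "DetectionConfig")
}

## reshape one transcript row (time-major sample vector) to R x T
iso_mat <- function(v, n_timepoints, n_replicates) {
  matrix(v, nrow = n_replicates, ncol = n_timepoints)
}

## per-replicate crossing indicator for interval t (between t and t+1):
## strict sign change of D = A - B, with an exact tie at time t+1 assigned
## to the earlier interval t.
crossing_matrix <- function(A, B) {
  D <- A - B
  s <- sign(D)
  tt <- ncol(D)
  left <- s[, seq_len(tt - 1L), drop = FALSE]
  right <- s[, 2:tt, drop = FALSE]
  (left * right < 0) | (right == 0 & left != 0)
}

#' Find switch points for an isoform pair
#'
#' A switch point is a time interval (s, s+1) in which the two isoforms'
#' relative-abundance curves cross in at least `min_support` of the
#' replicates. A crossing in a replicate is a strict sign change of
#' `I_a - I_b` between the two time points; an exact tie at a time point is
#' assigned to the earlier interval. With a single replicate any sign
#' change qualifies.
#'
#' @param I A `RelativeAbundance` object (see [relative_abundance()]).
#' @param gene_id Gene to which both isoforms belong.
#' @param iso_a,iso_b Transcript ids of the pair.
#' @param min_support Minimum crossing fraction over replicates.
#' @return Data frame with columns `gene_id`, `isoform_a`, `isoform_b`,
#'   `switch_interval` (1-based index s: crossing between time points s and
#'   s+1) and `support`.
#' @export
find_switch_points <- function(I, gene_id, iso_a, iso_b, min_support = 0.6) {
  stopifnot(inherits(I, "RelativeAbundance"))
  if (!identical(unname(I$gene_map[iso_a]), unname(I$gene_map[iso_b])) ||
      !identical(unname(I$gene_map[iso_a]), gene_id))
    stop("isoforms must belong to the given gene")
  A <- iso_mat(I$values[iso_a, ], n_timepoints(I), I$n_replicates)
  B <- iso_mat(I$values[iso_b, ], n_timepoints(I), I$n_replicates)
  supp <- colMeans(crossing_matrix(A, B))
  s <- which(supp >= min_support)
  data.frame(gene_id = rep(gene_id, length(s)),
             isoform_a = rep(iso_a, length(s)),
             isoform_b = rep(iso_b, length(s)),
             switch_interval = s, support = supp[s],
             stringsAsFactors = FALSE)
}

#' Switching probability of an event
#'
#' The average of (i) the frequency of samples in the pre-switch interval
#' T1 where isoform i is more abundant than isoform j, and (ii) the
#' frequency of samples in the post-switch interval T2 where it is less
#' abundant. Frequencies are over all (time point, replicate) samples
#' within each interval; i is the pre-switch dominant isoform.
#'
#' @param A,B Replicate-by-time matrices of relative abundance for the two
#'   isoforms (i = A, j = B).
#' @param s Switch interval index (switch between time points s and s+1).
#' @param t1_start First time point of the pre-switch interval
#'   (default 1).
#' @param t2_end Last time point of the post-switch interval (default T).
#' @return Switching probability in \[0, 1\].
#' @export
switch_probability <- function(A, B, s, t1_start = 1L, t2_end = ncol(A)) {
  if (t1_start > s || t2_end < s + 1L) stop("empty interval around 's'")
  pre <- t1_start:s
  post <- (s + 1L):t2_end
  p1 <- mean(A[, pre, drop = FALSE] > B[, pre, drop = FALSE])
  p2 <- mean(A[, post, drop = FALSE] < B[, post, drop = FALSE])
  (p1 + p2) / 2
}

#' Difference of relative abundance across a switch point
#'
#' The replicate-mean change of each isoform's relative abundance between
#' time points s and s+1, taken in absolute value per isoform and averaged
#' over the pair. Quantifies the magnitude of the switch as a fraction of
#' total gene expression.
#'
#' @inheritParams switch_probability
#' @return Non-negative difference.
#' @export
diff_abundance <- function(A, B, s) {
  da <- mean(A[, s + 1L]) - mean(A[, s])
  db <- mean(B[, s + 1L]) - mean(B[, s])
  (abs(da) + abs(db)) / 2
}

#' Event importance
#'
#' Average, over replicates, of the two switching isoforms' relative
#' abundances at the two flanking time points, each normalized to the
#' highest relative abundance among all isoforms of the gene at the
#' corresponding time point and replicate. Near 1 when the switch involves
#' the gene's dominant isoforms; near 0 for switches between minor
#' isoforms.
#'
#' @param A,B Replicate-by-time abundance matrices of the switching pair.
#' @param M Replicate-by-time matrix of the per-sample maximum relative
#'   abundance over *all* isoforms of the gene.
#' @param s Switch interval index.
#' @return Importance in (0, 1\], or `NA` if the gene is entirely
#'   unexpressed at either flanking time point in some replicate.
#' @export
event_importance <- function(A, B, M, s) {
  m0 <- M[, s]; m1 <- M[, s + 1L]
  if (any(m0 == 0) || any(m1 == 0)) return(NA_real_)
  mean((A[, s] / m0 + A[, s + 1L] / m1 + B[, s] / m0 + B[, s + 1L] / m1) / 4)
}

#' Dissimilarity coefficient of two isoform time courses
#'
#' Based on the Pearson correlation r of the replicate-averaged time
#' courses: `d = 1 - r^2` (default) or `d = (1 - r)/2`. The default maps
#' both perfectly correlated and perfectly anti-correlated courses to 0;
#' the alternative maps anti-correlation to 1.
#'
#' @inheritParams switch_probability
#' @param method "one_minus_r2" or "half_one_minus_r".
#' @return Dissimilarity in \[0, 1\], or `NA` if either replicate-averaged
#'   course has zero variance.
#' @export
dissimilarity <- function(A, B, method = c("one_minus_r2",
                                           "half_one_minus_r")) {
  method <- match.arg(method)
  a <- colMeans(A); b <- colMeans(B)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  r <- stats::cor(a, b)
  if (method == "one_minus_r2") 1 - r^2 else (1 - r) / 2
}

#' Rank-based significance of a switch point (replicated data)
#'
#' Two-sided Mann-Whitney U test comparing the pooled per-sample
#' differences of the two isoforms' relative abundances (`I_i - I_j`)
#' before versus after the switch point, within the event's pre/post
#' intervals. A genuine switch flips the sign of the difference, which
#' this statistic detects directly. Requires at least two samples per
#' side, otherwise returns 1 with a warning.
#'
#' @inheritParams switch_probability
#' @return p-value in \[0, 1\].
#' @export
test_switch_replicated <- function(A, B, s, t1_start = 1L,
                                   t2_end = ncol(A)) {
  pre <- t1_start:s
  post <- (s + 1L):t2_end
  n_pre <- length(pre) * nrow(A)
  n_post <- length(post) * nrow(A)
  if (n_pre < 2L || n_post < 2L) {
    warning("fewer than 2 samples on one side of the switch point; p = 1")
    return(1)
  }
  D <- A - B
  suppressWarnings(
    stats::wilcox.test(as.vector(D[, pre, drop = FALSE]),
                       as.vector(D[, post, drop = FALSE]),
                       alternative = "two.sided")$p.value)
}

## sustained difference of relative abundance around interval s: per course,
## |mean after - mean before| over the whole series, averaged over the pair
interval_mean_diff <- function(a, b, s) {
  tt <- length(a)
  (abs(mean(a[(s + 1L):tt]) - mean(a[1:s])) +
   abs(mean(b[(s + 1L):tt]) - mean(b[1:s]))) / 2
}

## best crossing of a single-replicate pair: the crossing interval with the
## largest sustained diff; returns that diff (0 if no crossing)
best_crossing_diff <- function(a, b) {
  cr <- which(crossing_matrix(rbind(a), rbind(b))[1L, ])
  if (!length(cr)) return(0)
  max(vapply(cr, function(s) interval_mean_diff(a, b, s), 0))
}

#' Permutation significance of a switch point (single replicate)
#'
#' For data without replicates: the time-point order of the pair's
#' courses is permuted (the same permutation applied to both courses,
#' preserving their cross-dependence, which makes the p-value a valid
#' exchangeability test), and the empirical p-value is the fraction of
#' permutations in which *both* the dissimilarity coefficient and the
#' sustained difference of relative abundance (the mean abundance change
#' of the pair across the best crossing of the permuted courses) reach
#' the observed values, with add-one correction `(b + 1)/(n + 1)`. The
#' dissimilarity clause is an exact tie under a joint permutation
#' (Pearson correlation is order-invariant), so the sustained difference
#' is the binding statistic; a genuine switch concentrates low and high
#' abundances on opposite sides of the switch point, which scrambling
#' destroys.
#'
#' @param a,b Numeric time courses (length T) of the two isoforms.
#' @param s Observed switch interval index.
#' @param n_permutations Number of permutations (default 999).
#' @param dissimilarity_method Passed to [dissimilarity()].
#' @return Empirical p-value.
#' @export
test_switch_single_replicate <- function(a, b, s, n_permutations = 999L,
                                         dissimilarity_method =
                                           "one_minus_r2") {
  d_obs <- dissimilarity(rbind(a), rbind(b), dissimilarity_method)
  diff_obs <- interval_mean_diff(a, b, s)
  if (is.na(d_obs)) return(1)            # constant course: never significant
  tt <- length(a)
  hits <- 0L
  for (i in seq_len(n_permutations)) {
    perm <- sample.int(tt)
    ap <- a[perm]
    bp <- b[perm]
    dp <- dissimilarity(rbind(ap), rbind(bp), dissimilarity_method)
    if (is.na(dp)) next
    if (dp >= d_obs - 1e-12 && best_crossing_diff(ap, bp) >= diff_obs)
      hits <- hits + 1L
  }
  (hits + 1) / (n_permutations + 1)
}

#' Adjust p-values for multiple testing
#'
#' Step-up Benjamini-Hochberg (default), step-down Holm, or Bonferroni.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method "BH", "holm" or "bonferroni".
#' @return Adjusted p-values, clipped at 1.
#' @export
adjust_pvalues <- function(p, method = c("BH", "holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Protein-domain gain and loss between switching isoforms
#'
#' Compares the domain sets of the pre-switch dominant isoform (`iso_old`)
#' and the post-switch dominant isoform (`iso_new`). Gained domains are
#' those of the new dominant isoform absent from the old one; lost domains
#' the reverse. If either isoform is absent from the map, the comparison is
#' unknown and both sets are empty.
#'
#' @param iso_old,iso_new Transcript ids.
#' @param dmap A [domain_map()].
#' @return List with `gained`, `lost` (character vectors) and `unknown`
#'   (logical).
#' @export
domain_gain_loss <- function(iso_old, iso_new, dmap) {
  stopifnot(inherits(dmap, "DomainMap"))
  if (!iso_old %in% names(dmap) || !iso_new %in% names(dmap))
    return(list(gained = character(0), lost = character(0), unknown = TRUE))
  old <- dmap[[iso_old]]; new <- dmap[[iso_new]]
  list(gained = setdiff(new, old), lost = setdiff(old, new),
       unknown = FALSE)
}

## ---------------------------------------------------------------------------
## Orchestration
## ---------------------------------------------------------------------------

#' Detect isoform switch events
#'
#' For every gene with at least two isoforms and every isoform pair,
#' enumerates switch points (intervals where the relative-abundance curves
#' cross in at least `min_support` of the replicates), scores each with
#' switching probability, difference of relative abundance, event
#' importance and dissimilarity, and tests significance (Mann-Whitney U
#' test across replicates, or a permutation test when only one replicate
#' is available). The switch point with the smallest p-value (ties: larger
#' difference, then earlier interval) represents the pair; the
#' representative p-values are corrected for multiple testing over all
#' pairs, and events passing all configured thresholds are reported.
#'
#' @param m A `TimeCourseMatrix` (TPM; apply [filter_low_expression()]
#'   first) or a precomputed `RelativeAbundance`.
#' @param cfg A [detection_config()].
#' @param dmap Optional [domain_map()] for gain/loss annotation.
#' @return A data frame of class `ISEvents`, one row per reported event,
#'   with columns `gene_id`, `isoform_a` (pre-switch dominant),
#'   `isoform_b`, `switch_interval`, `switch_time`, `support`,
#'   `switch_prob`, `diff`, `importance`, `dissimilarity`, `p_value`,
#'   `adj_p_value`, `secondary_switch_points`, `domains_gained`,
#'   `domains_lost`, `domain_unknown`. The full table of scored candidate
#'   pairs (before threshold filtering) is attached as
#'   `attr(x, "candidates")`.
#' @export
detect_isoform_switches <- function(m, cfg = detection_config(),
                                    dmap = NULL) {
  stopifnot(inherits(cfg, "DetectionConfig"))
  I <- if (inherits(m, "RelativeAbundance")) m else relative_abundance(m)
  tt <- n_timepoints(I); rr <- I$n_replicates
  genes <- split(seq_len(nrow(I$values)), I$gene_map)
  genes <- genes[lengths(genes) >= 2L]
  if (rr == 1L) set.seed(cfg$seed)

  rows <- list()
  n_skipped <- 0L
  for (gene in names(genes)) {
    idx <- genes[[gene]]
    mats <- lapply(idx, function(i) iso_mat(I$values[i, ], tt, rr))
    names(mats) <- I$transcript_ids[idx]
    M <- Reduce(pmax, mats)              # per-sample max over isoforms
    iso <- names(mats)
    k <- length(iso)
    if (k > 30L)
      warning(sprintf("gene %s has %d isoforms; enumerating all %d pairs",
                      gene, k, choose(k, 2)))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      A <- mats[[i]]; B <- mats[[j]]
      supp <- colMeans(crossing_matrix(A, B))
      sps <- which(supp >= cfg$min_support)
      if (!length(sps)) next
      sp_rows <- lapply(seq_along(sps), function(q) {
        s <- sps[q]
        t1_start <- if (q > 1L) sps[q - 1L] + 1L else 1L
        t2_end <- if (q < length(sps)) sps[q + 1L] else tt
        ## orient the pair: "a" dominates before the switch
        a_first <- mean(A[, t1_start:s]) >= mean(B[, t1_start:s])
        Ai <- if (a_first) A else B
        Bj <- if (a_first) B else A
        imp <- event_importance(Ai, Bj, M, s)
        if (is.na(imp)) return(NULL)
        d <- dissimilarity(Ai, Bj, cfg$dissimilarity_method)
        if (is.na(d)) return(NULL)
        p <- if (rr >= 2L)
          test_switch_replicated(Ai, Bj, s, t1_start, t2_end)
        else
          test_switch_single_replicate(Ai[1L, ], Bj[1L, ], s,
                                       cfg$n_permutations,
                                       cfg$dissimilarity_method)
        list(a = iso[if (a_first) i else j], b = iso[if (a_first) j else i],
             s = s, support = supp[s],
             prob = switch_probability(Ai, Bj, s, t1_start, t2_end),
             diff = diff_abundance(Ai, Bj, s), importance = imp,
             dissim = d, p = p)
      })
      sp_rows <- Filter(Negate(is.null), sp_rows)
      if (!length(sp_rows)) { n_skipped <- n_skipped + 1L; next }
      ps <- vapply(sp_rows, `[[`, 0, "p")
      ds <- vapply(sp_rows, `[[`, 0, "diff")
      ss <- vapply(sp_rows, `[[`, 0L, "s")
      best <- order(ps, -ds, ss)[1L]
      b <- sp_rows[[best]]
      secondary <- vapply(sp_rows[-best], function(x)
        if (x$p < cfg$alpha) I$time_points[x$s] else NA_character_,
        NA_character_)
      secondary <- secondary[!is.na(secondary)]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene, isoform_a = b$a, isoform_b = b$b,
        switch_interval = b$s, switch_time = I$time_points[b$s],
        support = b$support, switch_prob = b$prob, diff = b$diff,
        importance = b$importance, dissimilarity = b$dissim,
        p_value = b$p,
        secondary_switch_points = paste(secondary, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0L)
    warning(sprintf(
      "%d isoform pair(s) skipped (unexpressed gene or zero-variance course at the switch point)",
      n_skipped))
  empty_cols <- list(
    gene_id = character(0), isoform_a = character(0),
    isoform_b = character(0), switch_interval = integer(0),
    switch_time = character(0), support = numeric(0),
    switch_prob = numeric(0), diff = numeric(0), importance = numeric(0),
    dissimilarity = numeric(0), p_value = numeric(0),
    secondary_switch_points = character(0), adj_p_value = numeric(0))
  if (!length(rows)) {
    out <- do.call(data.frame,
                   c(empty_cols, list(stringsAsFactors = FALSE)))
    return(annotate_events(out, out, dmap))
  }
  cand <- do.call(rbind, rows)
  cand$adj_p_value <- adjust_pvalues(cand$p_value, cfg$correction)
  cand <- cand[, names(empty_cols)]
  keep <- cand$support >= cfg$min_support &
    cand$switch_prob >= cfg$min_switch_prob &
    cand$diff >= cfg$min_diff &
    cand$importance >= cfg$min_event_importance &
    cand$dissimilarity >= cfg$min_dissimilarity &
    cand$adj_p_value < cfg$alpha
  annotate_events(cand[keep, , drop = FALSE], cand, dmap)
}

annotate_events <- function(events, candidates, dmap) {
  n <- nrow(events)
  gained <- lost <- character(n)
  unknown <- rep(TRUE, n)
  if (!is.null(dmap) && n) {
    for (i in seq_len(n)) {
      gl <- domain_gain_loss(events$isoform_a[i], events$isoform_b[i], dmap)
      gained[i] <- paste(gl$gained, collapse = ";")
      lost[i] <- paste(gl$lost, collapse = ";")
      unknown[i] <- gl$unknown
    }
  }
  events$domains_gained <- gained
  events$domains_lost <- lost
  events$domain_unknown <- unknown
  rownames(events) <- NULL
  rownames(candidates) <- NULL
  attr(events, "candidates") <- candidates
  class(events) <- c("ISEvents", "data.frame")
  events
}

#' Write detected events as TSV
#'
#' @param events An `ISEvents` data frame.
#' @param path Output file path.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
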