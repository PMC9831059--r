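## ---------------------------------------------------------------------------
## Benchmark harness: precision/recall against simulated ground truth
## ---------------------------------------------------------------------------

#' Gene-level precision and recall
#'
#' A ground-truth switching gene counts as recovered if at least one of
#' its events is reported. With no predictions, precision is 1 by the
#' 0/0 convention.
#'
#' @param predicted_genes Character vector (or set) of reported gene ids.
#' @param truth_genes Character vector of ground-truth switching genes
#'   (must be non-empty).
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn`,
#'   `n_predicted`, `n_truth`.
#' @export
precision_recall <- function(predicted_genes, truth_genes) {
  truth_genes <- unique(as.character(truth_genes))
  if (!length(truth_genes)) stop("empty truth set: recall is undefined")
  predicted_genes <- unique(as.character(predicted_genes))
  tp <- length(intersect(predicted_genes, truth_genes))
  fp <- length(setdiff(predicted_genes, truth_genes))
  fn <- length(setdiff(truth_genes, predicted_genes))
  list(precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
       recall = tp / (tp + fn),
       tp = tp, fp = fp, fn = fn,
       n_predicted = length(predicted_genes),
       n_truth = length(truth_genes))
}

#' Sweep the difference-of-relative-abundance threshold
#'
#' Runs detection once at the loosest difference threshold and re-filters
#' the scored candidate events at each requested cutoff, computing
#' gene-level precision and recall against the simulated ground truth for
#' each. All other thresholds come from `cfg`.
#'
#' @param sim A `SimulatedDataset` (see [simulate_timecourse()]).
#' @param cfg A [detection_config()].
#' @param thresholds Ascending numeric vector of difference cutoffs.
#' @return Data frame with one row per threshold: `threshold`,
#'   `precision`, `recall`, `n_predicted`, `n_truth`.
#' @export
pr_sweep <- function(sim, cfg = detection_config(),
                     thresholds = c(0.05, 0.1, 0.2, 0.3)) {
  stopifnot(inherits(sim, "SimulatedDataset"))
  if (is.unsorted(thresholds)) stop("'thresholds' must be ascending")
  base_cfg <- cfg
  base_cfg$min_diff <- 0
  events <- detect_isoform_switches(sim$matrix, base_cfg)
  cand <- attr(events, "candidates")
  pass_other <- cand$support >= cfg$min_support &
    cand$switch_prob >= cfg$min_switch_prob &
    cand$importance >= cfg$min_event_importance &
    cand$dissimilarity >= cfg$min_dissimilarity &
    cand$adj_p_value < cfg$alpha
  out <- lapply(thresholds, function(thr) {
    genes <- unique(cand$gene_id[pass_other & cand$diff >= thr])
    pr <- precision_recall(genes, sim$truth_genes)
    data.frame(threshold = thr, precision = pr$precision,
               recall = pr$recall, n_predicted = pr$n_predicted,
               n_truth = pr$n_truth)
  })
  do.call(rbind, out)
}
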