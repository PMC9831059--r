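## ---------------------------------------------------------------------------
## Ground-truthed time-course isoform expression simulator
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the benchmark simulator. Each gene carries a number of
#' isoforms drawn from a Poisson distribution, a hidden two-state
#' (unswitched/switched) first-order Markov chain over time points, and a
#' Dirichlet-distributed vector of relative isoform abundances per state.
#' A state flip swaps the abundances of a designated isoform pair, which
#' defines the ground-truth switch events. Expression values are normal
#' replicates around `abundance * gene_mean` with gamma-distributed
#' variance that grows with both the mean and the `noise` level.
#'
#' @param n_genes Number of genes.
#' @param n_timepoints Number of time points T (>= 2).
#' @param n_replicates Replicates per time point.
#' @param noise Positive noise level; the benchmark uses 1, 5 and 10.
#' @param model Abundance model: `1` (switches occur between the two
#'   highest-expected-abundance isoforms) or `2` (switches occur between a
#'   random pair of isoforms with drawn abundance > 0.3).
#' @param isoform_count_lambda Poisson rate for the isoforms-per-gene draw;
#'   draws of 0 are clamped to 1. Single-isoform genes are kept as
#'   non-switching background.
#' @param n_switching_isoforms Number of designated high-abundance
#'   ("switching") isoforms under Model 1 (clamped to at most the isoform
#'   count).
#' @param gene_mean_source Either a numeric vector of candidate gene-level
#'   expression means (sampled with replacement) or a function `n ->
#'   numeric(n)`. Default: log-normal with median 500 counts, sdlog 1 --
#'   the scale of moderately-to-well-expressed genes in a typical bulk
#'   RNA-seq library, standing in for the negative-binomial fit to real
#'   data that the benchmark design calls for.
#' @param transition_matrix 2x2 row-stochastic matrix over states
#'   (unswitched, switched); rows must sum to 1. Default: flip probability
#'   0.1 per step in both directions.
#' @param seed Integer seed. Per-gene RNG substreams are derived from it so
#'   that increasing `n_genes` leaves earlier genes unchanged.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 1000L, n_timepoints = 10L,
                              n_replicates = 3L, noise = 1, model = 1L,
                              isoform_count_lambda = 3,
                              n_switching_isoforms = 2L,
                              gene_mean_source = NULL,
                              transition_matrix = NULL,
                              seed = 1L) {
  if (is.null(transition_matrix))
    transition_matrix <- matrix(c(0.9, 0.1, 0.1, 0.9), 2L, 2L, byrow = TRUE)
  transition_matrix <- as.matrix(transition_matrix)
  if (!identical(dim(transition_matrix), c(2L, 2L)) ||
      any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-8))
    stop("'transition_matrix' must be a 2x2 row-stochastic matrix")
  if (n_timepoints < 2L) stop("'n_timepoints' must be >= 2")
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1")
  if (noise <= 0) stop("'noise' must be positive")
  if (!model %in% c(1L, 2L)) stop("'model' must be 1 or 2")
  if (is.null(gene_mean_source))
    gene_mean_source <- function(n) stats::rlnorm(n, meanlog = log(500),
                                                  sdlog = 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_timepoints = as.integer(n_timepoints),
                 n_replicates = as.integer(n_replicates),
                 noise = noise, model = as.integer(model),
                 isoform_count_lambda = isoform_count_lambda,
                 n_switching_isoforms = as.integer(n_switching_isoforms),
                 gene_mean_source = gene_mean_source,
                 transition_matrix = transition_matrix,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

gene_substream_seeds <- function(seed, n) {
  ## first k seeds are invariant to increasing n
  set.seed(seed)
  sample.int(2147483646L, n)
}

markov_path <- function(n_timepoints, transition_matrix) {
  path <- integer(n_timepoints)          # 0 = unswitched, 1 = switched
  for (t in 2:n_timepoints) {
    p_flip <- transition_matrix[path[t - 1L] + 1L, 2L - path[t - 1L]]
    path[t] <- if (stats::runif(1) < p_flip) 1L - path[t - 1L] else path[t - 1L]
  }
  path
}

#' Sample hidden gene state paths
#'
#' Draws, for every gene, a length-T sequence over the states
#' {unswitched, switched} from a first-order Markov chain starting in the
#' unswitched state. State flips define the ground-truth switch times.
#'
#' @param cfg A [simulation_config()].
#' @return Integer matrix `n_genes x T` (0 = unswitched, 1 = switched) with
#'   gene ids as row names.
#' @export
sample_state_paths <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  seeds <- gene_substream_seeds(cfg$seed, cfg$n_genes)
  out <- matrix(0L, cfg$n_genes, cfg$n_timepoints,
                dimnames = list(paste0("g", seq_len(cfg$n_genes)), NULL))
  for (g in seq_len(cfg$n_genes)) {
    set.seed(seeds[g])
    out[g, ] <- markov_path(cfg$n_timepoints, cfg$transition_matrix)
  }
  out
}

#' Apply the switch-introduction rule to an abundance vector
#'
#' Produces the switched-state abundance vector from the unswitched one by
#' swapping one isoform pair. If `pair` is not given, the two
#' largest-abundance isoforms are swapped (the Model 1 rule; ties broken by
#' position).
#'
#' @param probs Numeric probability vector (isoform relative abundances,
#'   summing to 1).
#' @param pair Optional integer vector of length 2: the positions to swap.
#' @return List with `probs` (the switched vector) and `pair` (the swapped
#'   positions, sorted).
#' @examples
#' introduce_switch(c(0.03, 0.07, 0.1, 0.3, 0.5))$probs
#' @export
introduce_switch <- function(probs, pair = NULL) {
  if (length(probs) < 2L) stop("need at least two isoforms to switch")
  if (is.null(pair))
    pair <- order(probs, decreasing = TRUE)[1:2]
  pair <- sort(as.integer(pair))
  out <- probs
  out[pair] <- out[rev(pair)]
  list(probs = out, pair = pair)
}

#' Sample per-state isoform abundance vectors
#'
#' Draws one Dirichlet abundance vector for the unswitched state and
#' derives the switched state by swapping a designated isoform pair.
#' Under Model 1 the Dirichlet concentration is 1 for background isoforms
#' and `10 * (1:s)` for the `s` designated switching isoforms, and the two
#' highest-concentration isoforms are swapped. Under Model 2 the
#' concentration is `10 * (1:k)` over all `k` isoforms and a uniformly
#' random pair among isoforms with drawn abundance > 0.3 is swapped
#' (falling back to the two largest-abundance isoforms when fewer than two
#' exceed 0.3).
#'
#' @param n_isoforms Number of isoforms k (>= 2).
#' @param n_switching Number of designated switching isoforms under Model 1.
#' @param model 1 or 2.
#' @return List: `unswitched`, `switched` (probability vectors), `pair`
#'   (swapped positions) and `alpha` (concentration vector).
#' @export
sample_isoform_probabilities <- function(n_isoforms, n_switching = 2L,
                                         model = 1L) {
  k <- as.integer(n_isoforms)
  if (k < 2L) stop("'n_isoforms' must be >= 2")
  if (model == 1L) {
    s <- max(2L, min(as.integer(n_switching), k))
    alpha <- c(rep(1, k - s), 10 * seq_len(s))
    p <- rdirichlet1(alpha)
    pair <- c(k - 1L, k)                 # two highest-concentration isoforms
  } else {
    alpha <- 10 * seq_len(k)
    p <- rdirichlet1(alpha)
    eligible <- which(p > 0.3)
    pair <- if (length(eligible) >= 2L) sort(sample(eligible, 2L))
            else sort(order(p, decreasing = TRUE)[1:2])
  }
  sw <- introduce_switch(p, pair)
  list(unswitched = p, switched = sw$probs, pair = sw$pair, alpha = alpha)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  ## all-zero draw is essentially impossible for alpha >= 1
  x / sum(x)
}

#' Sample noisy replicate expression around state-dependent means
#'
#' Transcript means are `abundance * gene_mean` per time point. For each
#' (isoform, time point) a variance is drawn from a gamma distribution with
#' shape `mu + noise` and scale `noise` (expectation `(mu + noise) * noise`),
#' so variance grows with both abundance and the noise level; replicates are
#' then normal draws around the mean, truncated at zero.
#'
#' @param probs k x T matrix of per-time-point isoform abundances.
#' @param gene_mean Positive gene-level expression mean.
#' @param noise Positive noise level.
#' @param n_replicates Replicates per time point.
#' @return k x (T * n_replicates) matrix, columns time-major.
#' @export
sample_counts <- function(probs, gene_mean, noise, n_replicates) {
  if (gene_mean <= 0) stop("'gene_mean' must be positive")
  if (noise <= 0) stop("'noise' must be positive")
  probs <- as.matrix(probs)
  k <- nrow(probs); tt <- ncol(probs)
  mu <- probs * gene_mean
  theta <- matrix(stats::rgamma(k * tt, shape = mu + noise, scale = noise),
                  k, tt)
  out <- matrix(0, k, tt * n_replicates)
  for (t in seq_len(tt)) {
    cols <- (t - 1L) * n_replicates + seq_len(n_replicates)
    out[, cols] <- stats::rnorm(k * n_replicates, mean = mu[, t],
                                sd = sqrt(theta[, t]))
  }
  pmax(out, 0)
}

#' Simulate a ground-truthed time-course dataset
#'
#' Assembles per-gene isoform counts from the hidden Markov state paths,
#' per-state Dirichlet abundance vectors and the noise model, and records
#' the ground truth: which genes switch, when, and between which isoform
#' pair. Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `SimulatedDataset`:
#'   \describe{
#'     \item{matrix}{`TimeCourseMatrix` of simulated expression.}
#'     \item{truth_genes}{character vector of genes whose state flips.}
#'     \item{truth_switch_times}{named list: gene -> 1-based interval
#'       indices s (flip between time points s and s+1).}
#'     \item{truth_isoform_pairs}{named list: gene -> the two swapped
#'       transcript ids.}
#'     \item{state_paths}{integer matrix of hidden states.}
#'     \item{params}{named list of per-gene parameters (`alpha`,
#'       `unswitched`, `switched`, `pair`, `gene_mean`).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  seeds <- gene_substream_seeds(cfg$seed, cfg$n_genes)
  tt <- cfg$n_timepoints; rr <- cfg$n_replicates
  gene_ids <- paste0("g", seq_len(cfg$n_genes))
  state_paths <- matrix(0L, cfg$n_genes, tt, dimnames = list(gene_ids, NULL))
  vals <- vector("list", cfg$n_genes)
  gmap <- vector("list", cfg$n_genes)
  params <- vector("list", cfg$n_genes)
  truth_times <- list(); truth_pairs <- list()

  mean_pool <- cfg$gene_mean_source
  for (g in seq_len(cfg$n_genes)) {
    set.seed(seeds[g])
    k <- max(1L, stats::rpois(1L, cfg$isoform_count_lambda))
    gene_mean <- if (is.function(mean_pool)) mean_pool(1L)
                 else sample(mean_pool, 1L, replace = TRUE)
    tx <- paste0(gene_ids[g], ".t", seq_len(k))
    if (k >= 2L) {
      path <- markov_path(tt, cfg$transition_matrix)
      pr <- sample_isoform_probabilities(k, cfg$n_switching_isoforms,
                                         cfg$model)
      probs_t <- sapply(path, function(st)
        if (st == 0L) pr$unswitched else pr$switched)   # k x T
      flips <- which(diff(path) != 0L)
      if (length(flips)) {
        truth_times[[gene_ids[g]]] <- flips
        truth_pairs[[gene_ids[g]]] <- tx[pr$pair]
      }
    } else {
      path <- integer(tt)
      pr <- list(unswitched = 1, switched = 1, pair = NULL, alpha = 1)
      probs_t <- matrix(1, 1L, tt)
    }
    state_paths[g, ] <- path
    vals[[g]] <- sample_counts(probs_t, gene_mean, cfg$noise, rr)
    rownames(vals[[g]]) <- tx
    gmap[[g]] <- stats::setNames(rep(gene_ids[g], k), tx)
    params[[g]] <- list(alpha = pr$alpha, unswitched = pr$unswitched,
                        switched = pr$switched, pair = pr$pair,
                        gene_mean = gene_mean)
  }
  values <- do.call(rbind, vals)
  gene_map <- do.call(c, gmap)
  names(params) <- gene_ids
  m <- time_course_matrix(values, paste0("t", seq_len(tt)), rr, gene_map)
  structure(list(matrix = m,
                 truth_genes = names(truth_times),
                 truth_switch_times = truth_times,
                 truth_isoform_pairs = truth_pairs,
                 state_paths = state_paths,
                 params = params,
                 config = cfg),
            class = "SimulatedDataset")
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat(sprintf(
    "SimulatedDataset: %d genes (%d switching), %d transcripts, T=%d, R=%d, noise=%g, model=%d\n",
    x$config$n_genes, length(x$truth_genes), nrow(x$matrix$values),
    x$config$n_timepoints, x$config$n_replicates, x$config$noise,
    x$config$model))
  invisible(x)
}

#' Write a simulated dataset and its truth tables to a directory
#'
#' Writes `expression.tsv`, `gene_map.tsv`, `truth_genes.tsv`,
#' `switch_times.tsv` and `truth_pairs.tsv`.
#'
#' @param sim A `SimulatedDataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "SimulatedDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$matrix, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(transcript_id = names(sim$matrix$gene_map),
               gene_id = unname(sim$matrix$gene_map)),
    file.path(dir, "gene_map.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = sim$truth_genes),
                     file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  st <- data.frame(
    gene_id = rep(names(sim$truth_switch_times),
                  lengths(sim$truth_switch_times)),
    switch_interval = unlist(sim$truth_switch_times, use.names = FALSE))
  utils::write.table(st, file.path(dir, "switch_times.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tp <- data.frame(gene_id = names(sim$truth_isoform_pairs),
                   isoform_a = vapply(sim$truth_isoform_pairs, `[`, "", 1L),
                   isoform_b = vapply(sim$truth_isoform_pairs, `[`, "", 2L))
  utils::write.table(tp, file.path(dir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
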