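## ---------------------------------------------------------------------------
## Change of total isoform usage and gene clustering
## ---------------------------------------------------------------------------

#' Change of total isoform usage per gene
#'
#' For each gene and each pair of consecutive time points, the L1 distance
#' between the gene's isoform-fraction vectors:
#' `delta_t = sum_A | I_A(t+1) - I_A(t) |`, with `I` the within-gene
#' isoform fraction averaged over replicates. Values lie in \[0, 2\]; a
#' complete two-isoform flip attains 2. Single-isoform genes yield
#' all-zero profiles.
#'
#' @param m A `TimeCourseMatrix` or `RelativeAbundance`.
#' @param genes Optional character vector restricting the genes profiled
#'   (e.g. the IS genes from [detect_isoform_switches()]).
#' @return Numeric matrix of class `UsageChangeProfiles`, genes x (T-1),
#'   with gene ids as row names and `"t->t+1"` interval labels as column
#'   names.
#' @export
total_usage_change <- function(m, genes = NULL) {
  I <- if (inherits(m, "RelativeAbundance")) m else relative_abundance(m)
  tt <- n_timepoints(I); rr <- I$n_replicates
  ## replicate-mean fraction per time point
  grp <- rep(seq_len(tt), each = rr)
  means <- t(apply(I$values, 1L, function(v) tapply(v, grp, mean)))
  if (tt == 2L) means <- matrix(means, ncol = 2L,
                                dimnames = list(rownames(I$values), NULL))
  d <- abs(means[, -1L, drop = FALSE] - means[, -tt, drop = FALSE])
  prof <- rowsum(d, group = I$gene_map[rownames(I$values)], reorder = TRUE)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(prof))
    if (length(missing)) stop("unknown genes: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    prof <- prof[genes, , drop = FALSE]
  }
  colnames(prof) <- paste0(I$time_points[-tt], "->", I$time_points[-1L])
  class(prof) <- c("UsageChangeProfiles", "matrix", "array")
  prof
}

## ---------------------------------------------------------------------------
## Distances
## ---------------------------------------------------------------------------

## classic dynamic-time-warping distance with absolute local cost
dtw_distance <- function(x, y) {
  n <- length(x); m <- length(y)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    D[i + 1L, j + 1L] <- abs(x[i] - y[j]) +
      min(D[i, j + 1L], D[i + 1L, j], D[i, j])
  }
  D[n + 1L, m + 1L]
}

profile_dist <- function(x, metric = c("euclidean", "pearson", "dtw")) {
  metric <- match.arg(metric)
  switch(metric,
    euclidean = stats::dist(x),
    pearson = stats::as.dist(1 - stats::cor(t(x))),
    dtw = {
      n <- nrow(x)
      d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        d[i, j] <- d[j, i] <- dtw_distance(x[i, ], x[j, ])
      stats::as.dist(d)
    })
}

## ---------------------------------------------------------------------------
## Minimal density-based clustering on a distance matrix
## ---------------------------------------------------------------------------

dbscan_dist <- function(d, eps, min_pts) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- integer(n)                   # 0 = noise/unvisited
  core <- rowSums(d <= eps) >= min_pts   # neighborhood includes the point
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      nb <- which(d[p, ] <= eps)
      for (q in nb) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

optics_dist <- function(d, eps, min_pts) {
  d <- as.matrix(d)
  n <- nrow(d)
  core_dist <- apply(d, 1L, function(row) {
    s <- sort(row)
    if (length(s) >= min_pts && s[min_pts] <= eps) s[min_pts] else Inf
  })
  reach <- rep(Inf, n)
  processed <- logical(n)
  order_out <- integer(0)
  seeds <- numeric(0)                    # named vector: index -> reach
  for (start in seq_len(n)) {
    if (processed[start]) next
    queue <- stats::setNames(Inf, start)
    while (length(queue)) {
      p <- as.integer(names(queue)[which.min(queue)])
      queue <- queue[names(queue) != as.character(p)]
      if (processed[p]) next
      processed[p] <- TRUE
      order_out <- c(order_out, p)
      if (is.finite(core_dist[p])) {
        nb <- which(d[p, ] <= eps & !processed)
        newreach <- pmax(core_dist[p], d[p, nb])
        for (k in seq_along(nb)) {
          q <- nb[k]
          if (newreach[k] < reach[q]) {
            reach[q] <- newreach[k]
            queue[as.character(q)] <- newreach[k]
          }
        }
      }
    }
  }
  ## DBSCAN-equivalent cluster extraction at threshold eps
  labels <- integer(n)
  cl <- 0L
  for (p in order_out) {
    if (reach[p] > eps) {
      if (is.finite(core_dist[p])) { cl <- cl + 1L; labels[p] <- cl }
      else labels[p] <- 0L
    } else labels[p] <- cl
  }
  labels
}

## ---------------------------------------------------------------------------
## Clustering front end
## ---------------------------------------------------------------------------

#' Cluster genes by their usage-change profiles
#'
#' Groups genes with similar temporal patterns of total isoform-usage
#' change. Partitional methods (`kmeans`, `kmedoids`) and agglomerative
#' Ward clustering require `k`; the density-based methods (`dbscan`,
#' `optics`) instead take `eps` and `min_pts` and may label genes as noise
#' (cluster 0). Each cluster is summarized by a prototype: the
#' coordinate-wise median of its members' profiles.
#'
#' @param profiles A `UsageChangeProfiles` matrix (see
#'   [total_usage_change()]).
#' @param method One of "agglomerative-ward", "kmeans", "kmedoids",
#'   "dbscan", "optics".
#' @param k Number of clusters (required for ward/kmeans/kmedoids).
#' @param metric Distance: "euclidean" (default), "pearson" (1 - r) or
#'   "dtw" (dynamic time warping). `kmeans` supports euclidean only.
#' @param eps,min_pts Density parameters for dbscan/optics.
#' @param seed Seed for the stochastic initializations.
#' @return List of class `ClusterResult`: `assignments` (named integer
#'   vector), `prototypes` (clusters x (T-1) matrix), `method`, `params`.
#' @export
cluster_profiles <- function(profiles,
                             method = c("agglomerative-ward", "kmeans",
                                        "kmedoids", "dbscan", "optics"),
                             k = NULL,
                             metric = c("euclidean", "pearson", "dtw"),
                             eps = 0.5, min_pts = 5L, seed = 1L) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  x <- unclass(profiles)
  if (!nrow(x)) stop("no profiles to cluster")
  needs_k <- method %in% c("agglomerative-ward", "kmeans", "kmedoids")
  if (needs_k) {
    if (is.null(k)) stop(sprintf("method '%s' requires 'k'", method))
    if (k > nrow(x)) stop("'k' exceeds the number of profiles")
  }
  set.seed(seed)
  assignments <- switch(method,
    "agglomerative-ward" = {
      stats::cutree(stats::hclust(profile_dist(x, metric),
                                  method = "ward.D2"), k = k)
    },
    kmeans = {
      if (metric != "euclidean")
        stop("kmeans supports the euclidean metric only")
      stats::kmeans(x, centers = k, nstart = 10L)$cluster
    },
    kmedoids = cluster::pam(profile_dist(x, metric), k = k,
                            cluster.only = TRUE),
    dbscan = dbscan_dist(profile_dist(x, metric), eps, min_pts),
    optics = optics_dist(profile_dist(x, metric), eps, min_pts))
  assignments <- stats::setNames(as.integer(assignments), rownames(x))
  labs <- sort(unique(assignments[assignments > 0L]))
  prototypes <- do.call(rbind, lapply(labs, function(l)
    matrixStats::colMedians(x[assignments == l, , drop = FALSE])))
  if (length(labs)) {
    rownames(prototypes) <- labs
    colnames(prototypes) <- colnames(x)
  }
  structure(list(assignments = assignments, prototypes = prototypes,
                 method = method,
                 params = list(k = k, metric = metric, eps = eps,
                               min_pts = min_pts, seed = seed)),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  tab <- table(x$assignments)
  cat(sprintf("ClusterResult (%s, %s): %d genes in %d cluster(s)\n",
              x$method, x$params$metric, length(x$assignments),
              nrow(x$prototypes)))
  print(tab)
  invisible(x)
}

#' Ward merge heights to support the manual choice of k
#'
#' Returns the heights of the last `n_last` agglomerative (Ward linkage)
#' merges, largest first. Large gaps between consecutive heights suggest a
#' natural number of clusters.
#'
#' @inheritParams cluster_profiles
#' @param n_last Number of merges to report (default 10).
#' @return Numeric vector of merge heights.
#' @export
ward_merge_heights <- function(profiles, metric = "euclidean",
                               n_last = 10L) {
  h <- stats::hclust(profile_dist(unclass(profiles), metric),
                     method = "ward.D2")
  rev(utils::tail(h$height, n_last))
}

#' Write cluster assignments and prototypes as TSV
#'
#' @param cl A `ClusterResult`.
#' @param path Assignments file; prototypes go to
#'   `<path-without-extension>_prototypes.tsv`.
#' @export
write_clusters <- function(cl, path) {
  utils::write.table(
    data.frame(gene_id = names(cl$assignments),
               cluster = unname(cl$assignments)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  proto_path <- paste0(tools::file_path_sans_ext(path), "_prototypes.tsv")
  pr <- data.frame(cluster = rownames(cl$prototypes),
                   signif(cl$prototypes, 6), check.names = FALSE)
  utils::write.table(pr, proto_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
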