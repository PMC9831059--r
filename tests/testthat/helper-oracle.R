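# Independent brute-force oracles, written as plain loops/explicit formulas
# and kept free of the package's internal code paths.

# crossing indicators per replicate and interval (strict sign change; a tie
# at the later time point is assigned to the earlier interval)
oracle_crossings <- function(A, B) {
  R <- nrow(A); TT <- ncol(A)
  out <- matrix(FALSE, R, TT - 1L)
  for (r in seq_len(R)) {
    for (t in seq_len(TT - 1L)) {
      s1 <- sign(A[r, t] - B[r, t])
      s2 <- sign(A[r, t + 1L] - B[r, t + 1L])
      out[r, t] <- (s1 * s2 < 0) || (s2 == 0 && s1 != 0)
    }
  }
  out
}

oracle_switch_points <- function(A, B, min_support) {
  cr <- oracle_crossings(A, B)
  supp <- numeric(ncol(cr))
  for (t in seq_len(ncol(cr))) supp[t] <- sum(cr[, t]) / nrow(cr)
  which(supp >= min_support)
}

# interval bounds for switch point number q among qualifying points sps
oracle_bounds <- function(sps, q, TT) {
  t1 <- if (q > 1L) sps[q - 1L] + 1L else 1L
  t2 <- if (q < length(sps)) sps[q + 1L] else TT
  c(t1, t2)
}

oracle_switch_prob <- function(A, B, s, t1, t2) {
  n1 <- 0L; c1 <- 0L; n2 <- 0L; c2 <- 0L
  for (r in seq_len(nrow(A))) {
    for (t in t1:s) { n1 <- n1 + 1L; if (A[r, t] > B[r, t]) c1 <- c1 + 1L }
    for (t in (s + 1L):t2) { n2 <- n2 + 1L
      if (A[r, t] < B[r, t]) c2 <- c2 + 1L }
  }
  (c1 / n1 + c2 / n2) / 2
}

oracle_diff <- function(A, B, s) {
  R <- nrow(A)
  da <- 0; db <- 0
  for (r in seq_len(R)) {
    da <- da + (A[r, s + 1L] - A[r, s]) / R
    db <- db + (B[r, s + 1L] - B[r, s]) / R
  }
  (abs(da) + abs(db)) / 2
}

# mats: list of R x T matrices, one per isoform of the gene; a, b: indices
oracle_importance <- function(mats, a, b, s) {
  R <- nrow(mats[[1L]])
  tot <- 0
  for (r in seq_len(R)) {
    m0 <- max(vapply(mats, function(m) m[r, s], 0))
    m1 <- max(vapply(mats, function(m) m[r, s + 1L], 0))
    if (m0 == 0 || m1 == 0) return(NA_real_)
    tot <- tot + (mats[[a]][r, s] / m0 + mats[[a]][r, s + 1L] / m1 +
                  mats[[b]][r, s] / m0 + mats[[b]][r, s + 1L] / m1) / 4
  }
  tot / R
}

oracle_dissimilarity <- function(A, B, method = "one_minus_r2") {
  n <- ncol(A)
  x <- numeric(n); y <- numeric(n)
  for (t in seq_len(n)) { x[t] <- sum(A[, t]) / nrow(A)
                          y[t] <- sum(B[, t]) / nrow(B) }
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  vx <- n * sxx - sx^2; vy <- n * syy - sy^2
  if (vx <= 0 || vy <= 0) return(NA_real_)
  r <- (n * sxy - sx * sy) / sqrt(vx * vy)
  if (method == "one_minus_r2") 1 - r^2 else (1 - r) / 2
}

# exact two-sided Mann-Whitney p from explicit pair counting (untied data)
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  U <- 0
  for (xi in x) for (yj in y) U <- U + (xi > yj) + 0.5 * (xi == yj)
  if (U > n * m / 2) p <- 2 * (1 - stats::pwilcox(U - 1, n, m))
  else p <- 2 * stats::pwilcox(U, n, m)
  min(1, p)
}

oracle_usage_change <- function(frac_mats) {
  # frac_mats: list of R x T fraction matrices (isoforms of one gene)
  TT <- ncol(frac_mats[[1L]])
  out <- numeric(TT - 1L)
  for (t in seq_len(TT - 1L)) {
    acc <- 0
    for (m in frac_mats) acc <- acc + abs(mean(m[, t + 1L]) - mean(m[, t]))
    out[t] <- acc
  }
  out
}

# adjusted Rand index
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
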