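# Builders for small in-code fixtures.

# TimeCourseMatrix for one 2-isoform gene from an R x T fraction matrix A
# (isoform b gets 1 - A); returns the RelativeAbundance object.
ra_two_isoforms <- function(A, scale = 10) {
  B <- 1 - A
  vals <- rbind(tx1 = as.vector(A) * scale, tx2 = as.vector(B) * scale)
  m <- time_course_matrix(vals, time_points = seq_len(ncol(A)),
                          n_replicates = nrow(A),
                          gene_map = c(tx1 = "g1", tx2 = "g1"))
  relative_abundance(m)
}

# TimeCourseMatrix from a list of R x T matrices (isoforms of one gene)
tcm_from_mats <- function(mats, gene = "g1") {
  vals <- do.call(rbind, lapply(mats, as.vector))
  rownames(vals) <- paste0(gene, ".t", seq_along(mats))
  time_course_matrix(vals, time_points = seq_len(ncol(mats[[1L]])),
                     n_replicates = nrow(mats[[1L]]),
                     gene_map = stats::setNames(rep(gene, length(mats)),
                                                rownames(vals)))
}

# write a small expression TSV; returns the path
write_expr_fixture <- function(vals, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(transcript_id = rownames(vals), vals,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# random PWM probability matrix (4 x L)
random_pwm <- function(L, sharp = 1) {
  m <- matrix(stats::rgamma(4 * L, shape = sharp), 4, L)
  sweep(m, 2, colSums(m), "/")
}

random_seq <- function(n, background = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = background), collapse = "")
}

rdirichlet_test <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}
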