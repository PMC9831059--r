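test_that("PSSM construction and scanning follow the log-odds definition", {
  # probabilities equal to the background give 0 log-odds everywhere
  flat <- pssm_motif("flat", matrix(0.25, 4, 5))
  expect_true(all(flat$matrix == 0))
  expect_equal(pssm_scan("ACGTACGTAC", flat), rep(0, 6))

  # consensus placement is the maximal score
  pwm <- matrix(0.02, 4, 4); rownames(pwm) <- c("A", "C", "G", "T")
  pwm["A", 1] <- 0.94; pwm["C", 2] <- 0.94
  pwm["G", 3] <- 0.94; pwm["T", 4] <- 0.94
  motif <- pssm_motif("acgt", pwm, pseudocount = 0)
  seq <- "GGGACGTGGG"                     # consensus at offset 4
  sc <- pssm_scan(seq, motif)
  expect_identical(which.max(sc), 4L)
  expect_equal(max(sc), 4 * log2(0.94 / 0.25))

  # hand-summed oracle on a 6-mer, including U = T and ambiguous N = 0
  set.seed(30)
  p6 <- random_pwm(6)
  m6 <- pssm_motif("m6", p6, background = c(0.3, 0.2, 0.2, 0.3),
                   pseudocount = 0)
  s <- "CAUGNTAC"
  codes <- c(2, 1, 4, 3, NA, 4, 1, 2)    # C A U G N T A C
  for (off in 1:3) {
    expected <- 0
    for (pos in 1:6) {
      code <- codes[off + pos - 1]
      if (!is.na(code)) expected <- expected + m6$matrix[code, pos]
    }
    expect_equal(pssm_scan(s, m6)[off], unname(expected),
                 tolerance = 1e-12)
  }
  expect_error(pssm_scan("ACG", m6), "shorter")
  expect_error(pssm_motif("x", matrix(0.2, 3, 4)), "4 rows")
})

test_that("threshold calibration bounds the exact background tail mass", {
  set.seed(31)
  for (L in c(4, 6, 8)) {
    bg <- as.vector(rdirichlet_test(c(4, 4, 4, 4)))
    motif <- pssm_motif(paste0("m", L), random_pwm(L, sharp = 0.6),
                        background = bg)
    for (fpr in c(0.01, 0.05)) {
      thr <- calibrate_threshold(motif, fpr = fpr)
      # exhaustive enumeration of all 4^L words
      words <- as.matrix(expand.grid(rep(list(1:4), L)))
      scores <- numeric(nrow(words))
      probs <- numeric(nrow(words))
      for (pos in 1:L) {
        scores <- scores + motif$matrix[cbind(words[, pos], pos)]
        probs <- probs + log(bg[words[, pos]])
      }
      tail_mass <- sum(exp(probs)[scores >= thr])
      expect_lt(tail_mass, fpr)
      # threshold is not vacuous: some words can still exceed it
      expect_gt(sum(scores >= thr), 0)
    }
  }
  # fpr = 1 returns the minimum achievable score
  m <- pssm_motif("u", random_pwm(3), pseudocount = 0)
  expect_equal(calibrate_threshold(m, fpr = 1),
               sum(apply(m$matrix, 2, min)))
})

test_that("motif enrichment detects planted sites and respects order invariance", {
  set.seed(33)
  pwm <- matrix(0.04, 4, 6); rownames(pwm) <- c("A", "C", "G", "T")
  consensus <- c("T", "G", "C", "A", "T", "G")
  for (i in seq_along(consensus)) pwm[consensus[i], i] <- 0.88
  motif <- calibrate_motifs(list(pssm_motif("planted", pwm)))[[1]]

  plant <- function(n, with_site) vapply(seq_len(n), function(i) {
    s <- random_seq(60)
    if (with_site) {
      at <- sample(1:54, 1)
      substr(s, at, at + 5) <- paste(consensus, collapse = "")
    }
    s
  }, "")
  lost <- exon_flank_set("lost", plant(25, TRUE), plant(25, FALSE), 30)
  gained <- exon_flank_set("gained", plant(25, FALSE), plant(25, FALSE), 30)
  unreg <- exon_flank_set("unregulated", plant(40, FALSE),
                          plant(40, FALSE), 30)
  res <- motif_enrichment(lost, gained, unreg, list(motif))
  expect_identical(nrow(res), 4L)
  p_lost_5p <- res$p_value[res$comparison == "lost_vs_unregulated" &
                           res$boundary == "5p"]
  expect_lt(p_lost_5p, 0.05)

  # identical sequence sets: no enrichment
  same <- exon_flank_set("lost", unreg$five_prime, unreg$three_prime, 30)
  res2 <- motif_enrichment(same, NULL, unreg, list(motif))
  expect_true(all(res2$p_value[!is.na(res2$p_value)] > 0.4))

  # order of sequences within a set does not matter
  shuf <- exon_flank_set("lost", sample(lost$five_prime),
                         sample(lost$three_prime), 30)
  res3 <- motif_enrichment(shuf, NULL, unreg, list(motif))
  expect_equal(res3$p_value[res3$boundary == "5p"], p_lost_5p)

  expect_error(exon_flank_set("lost", "ACGJ", "ACGT", 2), "alphabet")
})

test_that("exon classification and flank extraction honour strand and terminal exons", {
  # toy genome: one chromosome of known sequence
  chr <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")  # 100 nt
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))

  structure_df <- data.frame(
    transcript_id = c(rep("tx1", 3), rep("tx2", 3), rep("tx3", 3)),
    chrom = "chr1",
    start = c(1, 21, 61,   1, 41, 61,   1, 21, 61),
    end   = c(10, 30, 70,  10, 50, 70,  10, 30, 70),
    strand = c(rep("+", 6), rep("-", 3)),
    stringsAsFactors = FALSE)

  ev <- data.frame(gene_id = "g1", isoform_a = "tx1", isoform_b = "tx2",
                   stringsAsFactors = FALSE)
  gm <- c(tx1 = "g1", tx2 = "g1", tx3 = "g1")
  cats <- classify_event_exons(ev, structure_df, gm)
  # internal exon of tx1 is 21-30 (lost), of tx2 is 41-50 (gained);
  # tx3's internal exon (21-30, minus strand) is unregulated but shares
  # coordinates with a lost exon only per (start, end, strand)
  expect_identical(cats$lost$start, 21)
  expect_identical(cats$gained$start, 41)
  expect_identical(nrow(cats$unregulated), 1L)
  expect_identical(cats$unregulated$strand, "-")

  # plus-strand flanks read straight off the genome
  fl <- exon_flanks(cats$lost, genome, "lost", flank_width = 5)
  expect_identical(fl$five_prime,
                   as.character(Biostrings::subseq(genome[[1]], 16, 25)))
  expect_identical(fl$three_prime,
                   as.character(Biostrings::subseq(genome[[1]], 26, 35)))
  # minus-strand flanks are reverse complemented and role-swapped
  fm <- exon_flanks(cats$unregulated, genome, "unregulated",
                    flank_width = 5)
  rc <- function(a, b) as.character(Biostrings::reverseComplement(
    Biostrings::subseq(genome[[1]], a, b)))
  expect_identical(fm$five_prime, rc(26, 35))
  expect_identical(fm$three_prime, rc(16, 25))
})

test_that("splicing-factor co-expression filters by correlation and significance", {
  set.seed(35)
  tt <- 8; rr <- 2
  # isoform fractions: one rising, one falling
  a <- matrix(rep(seq(0.2, 0.8, length.out = tt), each = rr), rr, tt,
              byrow = FALSE)
  a <- matrix(rep(seq(0.2, 0.8, length.out = tt), each = rr), rr, tt)
  ra <- ra_two_isoforms(a + matrix(stats::rnorm(tt * rr, sd = 0.01),
                                   rr, tt), scale = 100)
  # sf1 tracks isoform tx1; sf2 is noise; sf3 fails the TPM > 1 filter
  sf_vals <- rbind(
    sf1 = rep(seq(5, 50, length.out = tt), each = rr) +
      stats::rnorm(tt * rr, sd = 0.3),
    sf2 = stats::runif(tt * rr, 10, 12),
    sf3 = rep(0.5, tt * rr))
  sf <- time_course_matrix(sf_vals, ra$time_points, rr,
                           c(sf1 = "SF1", sf2 = "SF2", sf3 = "SF3"))
  res <- sf_coexpression(ra, sf, r_cut = 0.7, alpha = 0.05)
  expect_true("sf1" %in% res$splicing_factor)
  expect_false("sf3" %in% res$splicing_factor)
  hit <- res[res$splicing_factor == "sf1" & res$isoform == "tx1", ]
  expect_gt(hit$r, 0.9)

  # r matches a brute-force covariance computation
  grp <- rep(seq_len(tt), each = rr)
  x <- tapply(sf_vals["sf1", ], grp, mean)
  y <- tapply(ra$values["tx1", ], grp, mean)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(hit$r, unname(r_brute), tolerance = 1e-12)

  # independent random courses do not pass |r| > 0.7 (checked over many)
  set.seed(36)
  sf_rand <- time_course_matrix(
    matrix(stats::runif(20 * tt * rr, 10, 20), 20,
           dimnames = list(paste0("r", 1:20), NULL)),
    ra$time_points, rr,
    stats::setNames(paste0("R", 1:20), paste0("r", 1:20)))
  res_rand <- sf_coexpression(ra, sf_rand)
  expect_lt(nrow(res_rand), 3)
})
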