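test_that("switch points require crossings in enough replicates", {
  # clean crossing in all replicates at interval 1
  A <- matrix(c(0.7, 0.3), 3, 2, byrow = TRUE)   # R = 3, T = 2
  ra <- ra_two_isoforms(A)
  sp <- find_switch_points(ra, "g1", "tx1", "tx2")
  expect_identical(sp$switch_interval, 1L)
  expect_identical(sp$support, 1)

  # parallel non-crossing curves
  A2 <- matrix(c(0.8, 0.7, 0.75, 0.9), 1, 4)
  expect_identical(nrow(find_switch_points(ra_two_isoforms(A2), "g1",
                                           "tx1", "tx2")), 0L)

  # crossing in 2 of 4 replicates: support 0.5 < 0.6 is not reported
  A3 <- rbind(c(0.7, 0.3), c(0.6, 0.4), c(0.7, 0.6), c(0.8, 0.7))
  sp3 <- find_switch_points(ra_two_isoforms(A3), "g1", "tx1", "tx2")
  expect_identical(nrow(sp3), 0L)
  sp3b <- find_switch_points(ra_two_isoforms(A3), "g1", "tx1", "tx2",
                             min_support = 0.5)
  expect_identical(sp3b$support, 0.5)

  # ties are assigned to the earlier interval
  A4 <- matrix(c(0.7, 0.5, 0.2), 1, 3)           # hits 0.5 at t = 2
  sp4 <- find_switch_points(ra_two_isoforms(A4), "g1", "tx1", "tx2")
  expect_identical(sp4$switch_interval, 1L)

  expect_error(find_switch_points(ra_two_isoforms(A), "g2", "tx1", "tx2"),
               "belong")
})

test_that("switching probability counts sample orderings on both sides", {
  # clean switch: 1.0
  A <- matrix(rep(c(0.8, 0.8, 0.2, 0.2), each = 2), 2, 4)
  B <- 1 - A
  expect_identical(switch_probability(A, B, 2L), 1)

  # hand-enumerated: 1 time point each side, 3 replicates, i higher in
  # 2/3 before and lower in 3/3 after -> (2/3 + 1)/2 = 5/6
  A2 <- rbind(c(0.6, 0.1), c(0.7, 0.2), c(0.4, 0.3))
  B2 <- rbind(c(0.4, 0.9), c(0.3, 0.8), c(0.6, 0.7))
  expect_equal(switch_probability(A2, B2, 1L), 5 / 6)

  # random orderings: ~0.5 over many samples
  set.seed(3)
  A3 <- matrix(stats::runif(2 * 2000), 2)
  B3 <- matrix(stats::runif(2 * 2000), 2)
  p <- switch_probability(A3, B3, 1000L)
  expect_lt(abs(p - 0.5), 0.03)

  expect_error(switch_probability(A, B, 2L, t1_start = 3L), "empty")
})

test_that("difference of relative abundance averages the two flank changes", {
  A <- matrix(rep(c(0.3, 0.5), each = 3), 3, 2)
  B <- matrix(rep(c(0.5, 0.3), each = 3), 3, 2)
  expect_equal(diff_abundance(A, B, 1L), 0.2)
  # no change across the switch point
  C <- matrix(0.4, 3, 2)
  expect_equal(diff_abundance(C, C, 1L), 0)
})

test_that("event importance normalizes to the per-sample maximum isoform", {
  # switch between the top two isoforms, each at 0.5 -> importance 1
  A <- matrix(0.5, 2, 2); B <- matrix(0.5, 2, 2)
  expect_equal(event_importance(A, B, pmax(A, B), 1L), 1)
  # both switching isoforms at <= 10% of the max -> importance <= 0.1
  M <- matrix(1, 2, 2)
  A2 <- matrix(0.08, 2, 2); B2 <- matrix(0.05, 2, 2)
  expect_lte(event_importance(A2, B2, M, 1L), 0.1)
  # two-isoform genes: importance >= 0.5 over an abundance grid, since one
  # of the pair is always the gene maximum
  for (a1 in seq(0, 1, 0.1)) for (a2 in seq(0, 1, 0.1)) {
    A3 <- matrix(c(a1, a2), 1, 2); B3 <- 1 - A3
    imp <- event_importance(A3, B3, pmax(A3, B3), 1L)
    if (!is.na(imp)) expect_gte(imp, 0.5)
  }
  # all-zero gene at a flank -> NA
  expect_true(is.na(event_importance(matrix(0, 1, 2), matrix(0, 1, 2),
                                     matrix(0, 1, 2), 1L)))
})

test_that("dissimilarity follows 1 - r^2 with the documented alternative", {
  x <- matrix(c(0.1, 0.4, 0.9), 1, 3)
  expect_equal(dissimilarity(x, x), 0)
  expect_equal(dissimilarity(x, 1 - x), 0)               # anti-correlated
  expect_equal(dissimilarity(x, 1 - x, "half_one_minus_r"), 1)
  expect_equal(dissimilarity(x, x, "half_one_minus_r"), 0)
  # zero-variance course is undefined
  expect_true(is.na(dissimilarity(matrix(0.5, 1, 3), x)))
  # long uncorrelated courses: d near 1
  set.seed(5)
  a <- matrix(stats::runif(300), 1); b <- matrix(stats::runif(300), 1)
  expect_gt(dissimilarity(a, b), 0.9)
})

test_that("replicated significance test matches an independent U-statistic oracle", {
  # identical distributions on both sides: large p
  set.seed(6)
  A <- matrix(0.5 + stats::rnorm(24, sd = 0.01), 3, 8)
  B <- 1 - A
  expect_gt(test_switch_replicated(A, B, 4L), 0.2)

  # complete separation, 12 samples per side
  A2 <- cbind(matrix(0.8, 3, 4), matrix(0.2, 3, 4))
  B2 <- 1 - A2
  expect_lt(test_switch_replicated(A2, B2, 4L), 0.001)

  # oracle comparison on random untied input
  for (i in 1:20) {
    A3 <- matrix(stats::runif(18), 3, 6)
    B3 <- matrix(stats::runif(18), 3, 6)
    D <- A3 - B3
    p_or <- oracle_mw_p(as.vector(D[, 1:3]), as.vector(D[, 4:6]))
    expect_equal(test_switch_replicated(A3, B3, 3L), p_or,
                 tolerance = 1e-12)
  }

  expect_warning(p1 <- test_switch_replicated(matrix(0.6, 1, 2),
                                              matrix(0.4, 1, 2), 1L),
                 "fewer than 2 samples")
  expect_identical(p1, 1)
})

test_that("single-replicate permutation test behaves at its extremes", {
  # constant courses: never significant
  expect_identical(test_switch_single_replicate(rep(0.5, 8), rep(0.5, 8),
                                                4L, 99L), 1)
  # strong clean switch: p at the add-one floor for most permutations
  set.seed(10)
  a <- c(0.9, 0.85, 0.9, 0.88, 0.1, 0.12, 0.1, 0.15)
  b <- 1 - a
  p <- test_switch_single_replicate(a, b, 4L, n_permutations = 999L)
  expect_lt(p, 0.05)
  expect_gte(p, 1 / 1000)
})

test_that("p-value adjustment matches hand computations and dominates raw p", {
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "holm"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(0.04, 0.5, 0.9), "bonferroni")[1], 0.12)
  set.seed(2)
  p <- stats::runif(50)
  for (m in c("BH", "holm", "bonferroni")) {
    adj <- adjust_pvalues(p, m)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(adjust_pvalues(1.2), "0, 1")
})

test_that("domain gain/loss is a set difference with an unknown flag", {
  dm <- domain_map(list(a = c("A", "B"), b = c("A", "C"), c = c("A", "B")))
  gl <- domain_gain_loss("a", "b", dm)
  expect_identical(gl, list(gained = "C", lost = "B", unknown = FALSE))
  same <- domain_gain_loss("a", "c", dm)
  expect_length(same$gained, 0)
  expect_length(same$lost, 0)
  unk <- domain_gain_loss("a", "zzz", dm)
  expect_true(unk$unknown)
  expect_length(unk$gained, 0)
})

test_that("detection reports oriented, thresholded, annotated events", {
  # two genes: one clean switch, one constant
  A <- matrix(rep(c(0.75, 0.7, 0.72, 0.25, 0.3, 0.28), each = 3), 3, 6)
  mats_switch <- list(A * 400, (1 - A) * 400)
  mats_const <- list(matrix(300, 3, 6), matrix(100, 3, 6))
  m <- tcm_from_mats(c(mats_switch, mats_const))
  m$gene_map[] <- c("g1", "g1", "g2", "g2")
  dm <- domain_map(list(g1.t1 = c("A", "B"), g1.t2 = c("A", "C")))

  cfg <- detection_config(min_dissimilarity = 0)
  ev <- detect_isoform_switches(m, cfg, dm)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$gene_id, "g1")
  expect_identical(ev$isoform_a, "g1.t1")    # dominant before the switch
  expect_identical(ev$isoform_b, "g1.t2")
  expect_identical(ev$switch_interval, 3L)
  expect_identical(ev$domains_lost, "B")
  expect_identical(ev$domains_gained, "C")
  expect_false(ev$domain_unknown)

  # symmetry: feeding the pair in the opposite row order yields the same
  # oriented event
  m2 <- tcm_from_mats(c(rev(mats_switch), mats_const))
  m2$gene_map[] <- c("g1", "g1", "g2", "g2")
  rownames(m2$values)[1:2] <- c("g1.t2", "g1.t1")
  names(m2$gene_map)[1:2] <- c("g1.t2", "g1.t1")
  ev2 <- detect_isoform_switches(m2, cfg)
  expect_identical(ev2$isoform_a, "g1.t1")
  expect_identical(ev2$switch_interval, ev$switch_interval)
  expect_equal(ev2$p_value, ev$p_value)

  # no crossings anywhere -> empty result with the full schema
  ev0 <- detect_isoform_switches(tcm_from_mats(mats_const), cfg)
  expect_identical(nrow(ev0), 0L)
  expect_true(all(c("gene_id", "adj_p_value", "domains_gained") %in%
                  names(ev0)))
})

test_that("reported events satisfy every configured threshold", {
  sim <- simulate_timecourse(simulation_config(n_genes = 150, noise = 5,
                                               seed = 31))
  cfg <- detection_config(min_dissimilarity = 0)
  ev <- suppressWarnings(detect_isoform_switches(sim$matrix, cfg))
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$support >= cfg$min_support))
  expect_true(all(ev$switch_prob >= cfg$min_switch_prob))
  expect_true(all(ev$diff >= cfg$min_diff))
  expect_true(all(ev$importance >= cfg$min_event_importance))
  expect_true(all(ev$dissimilarity >= cfg$min_dissimilarity))
  expect_true(all(ev$adj_p_value < cfg$alpha))
  expect_true(all(ev$adj_p_value >= ev$p_value))

  # threshold monotonicity: raising any threshold never adds events
  stricter <- list(
    detection_config(min_dissimilarity = 0, min_diff = 0.35),
    detection_config(min_dissimilarity = 0, min_event_importance = 0.6),
    detection_config(min_dissimilarity = 0, min_switch_prob = 0.9),
    detection_config(min_dissimilarity = 0, min_support = 1),
    detection_config(min_dissimilarity = 0.2),
    detection_config(min_dissimilarity = 0, alpha = 0.001))
  key <- function(e) paste(e$gene_id, e$isoform_a, e$isoform_b)
  for (c2 in stricter) {
    e2 <- suppressWarnings(detect_isoform_switches(sim$matrix, c2))
    expect_true(all(key(e2) %in% key(ev)))
  }
})
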