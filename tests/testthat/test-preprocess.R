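test_that("track filter removes bins for the stated single reason", {
  bg <- test_grid(6)
  bg$gc <- c(0.5, 0.05, 0.95, 0.5, 0.5, 0.5)
  bg$mappability <- c(1, 1, 1, 0.5, 1, 1)
  cm <- count_matrix(matrix(1L, 2, 6), c("a", "b"), bg)
  r <- filter_bins_by_tracks(cm)
  expect_equal(ncol(r$cm$counts), 3L)
  expect_equal(r$qc$removed_bins$reason, c("gc_low", "gc_high", "mappability"))

  # all passing -> untouched
  r2 <- filter_bins_by_tracks(test_counts(matrix(1L, 2, 6)))
  expect_equal(ncol(r2$cm$counts), 6L)
  expect_equal(nrow(r2$qc$removed_bins), 0L)

  bg_bad <- test_grid(3, gc = 0.05)
  expect_error(filter_bins_by_tracks(
    count_matrix(matrix(1L, 1, 3), "a", bg_bad)), "no bins survive")
})

test_that("library-size normalization forces unit row means", {
  r <- library_size_normalize(rbind(c(2, 2, 2), c(1, 2, 3)))
  expect_equal(r$norm[1, ], c(1, 1, 1))
  expect_equal(r$norm[2, ], c(0.5, 1, 1.5))
  set.seed(1)
  m <- matrix(rpois(200, 30), 10, 20)
  expect_equal(rowMeans(library_size_normalize(m)$norm), rep(1, 10))
  expect_error(library_size_normalize(rbind(c(0, 0), c(1, 1)),
                                      c("dead", "ok")), "dead")
})

test_that("extreme-bin filter cuts strict quantile tails only", {
  bg <- test_grid(100)
  norm <- matrix(rep(1:100, each = 2), 2, 100) / 1  # means 1..100
  r <- filter_extreme_bins(norm, bg, q = 0.01)
  dropped <- setdiff(seq_len(100), r$keep)
  expect_equal(dropped, c(1L, 100L))

  # identical means: no bin is strictly outside the quantiles
  r2 <- filter_extreme_bins(matrix(1, 2, 100), bg, q = 0.01)
  expect_equal(length(r2$keep), 100L)

  # q = 0 disables the filter
  r3 <- filter_extreme_bins(norm, bg, q = 0)
  expect_equal(length(r3$keep), 100L)
})

test_that("gini coefficient matches the brute-force pairwise oracle", {
  brute <- function(x) {
    n <- length(x)
    sum(outer(x, x, function(a, b) abs(a - b))) / (2 * n^2 * mean(x))
  }
  expect_equal(gini_coefficient(c(1, 1, 1, 1)), 0)
  expect_equal(gini_coefficient(c(0, 0, 0, 4)), 0.75)  # pairwise sum 24 / 32
  expect_equal(gini_coefficient(c(0, 4)), 0.5)         # pairwise sum 8 / 16
  set.seed(42)
  for (i in 1:50) {
    x <- rpois(sample(5:50, 1), sample(3:50, 1))
    if (sum(x) == 0) x[1] <- 1
    expect_equal(gini_coefficient(x), brute(x), tolerance = 1e-12)
    expect_equal(gini_coefficient(3.7 * x), gini_coefficient(x),
                 tolerance = 1e-12)  # scale invariance
  }
  expect_error(gini_coefficient(c(0, 0)), "all-zero")
})

test_that("gini cell filter removes exactly the uneven cells", {
  m <- rbind(rep(2, 8), c(0, 0, 0, 4, 0, 0, 0, 4))  # G = 0 and 0.75
  r <- filter_cells_by_gini(m, c("flat", "spiky"), threshold = 0.3)
  expect_equal(r$keep, c(TRUE, FALSE))
  expect_equal(r$qc$removed_cells$cell_id, "spiky")
  r2 <- filter_cells_by_gini(m, c("flat", "spiky"), threshold = 1.0)
  expect_true(all(r2$keep))
  expect_error(filter_cells_by_gini(m[2, , drop = FALSE], "x",
                                    threshold = 0.1), "no cells survive")
})

test_that("median normalization applies r_hat = r * m / m_k per stratum", {
  # single stratum: identity
  bg1 <- test_grid(6, gc = 0.5)
  norm <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6)
  r1 <- median_normalize(norm, bg1)
  expect_equal(r1$norm, norm)

  # two GC strata with medians 0.5 and 2.0, cell median 1.0:
  # stratum-A bins scaled x2, stratum-B bins x0.5
  bg2 <- test_grid(8, gc = 0.5)
  bg2$gc <- rep(c(0.30, 0.70), each = 4)
  x <- c(0.4, 0.5, 0.5, 0.9, 1.9, 2.0, 2.0, 2.2)  # medians 0.5 / 2, all 1.0
  r2 <- median_normalize(matrix(x, 1, 8), bg2)
  m <- median(x)
  expect_equal(r2$norm[1, 1:4], x[1:4] * m / 0.5)
  expect_equal(r2$norm[1, 5:8], x[5:8] * m / 2.0)
})

test_that("LRC transform floors at eps and log2-transforms", {
  expect_equal(to_lrc(matrix(1)), matrix(0))
  expect_equal(to_lrc(matrix(2)), matrix(1))
  expect_equal(to_lrc(matrix(0)), matrix(log2(0.125)))
  expect_equal(to_lrc(matrix(0), eps = 1e-4), matrix(log2(1e-4)))
})

test_that("preprocessing pipeline keeps dimensions consistent with the log", {
  set.seed(11)
  sim <- simulate_cna_dataset(ploidy = 2, n_cells = 20, n_clones = 2,
                              chrom_lengths = c(chrA = 40e6), seed = 3)
  lrc <- preprocess_counts(sim$counts)
  qc <- lrc$qc
  expect_equal(ncol(lrc$lrc),
               nrow(sim$bins) - nrow(qc$removed_bins))
  expect_equal(nrow(lrc$lrc), 20 - nrow(qc$removed_cells))
  expect_true(all(is.finite(lrc$lrc)))
  expect_equal(lrc$bin_index,
               setdiff(seq_len(nrow(sim$bins)), qc$removed_bins$bin))
})

test_that("LRC level tracks log2 copy-number ratios on unbiased data", {
  # high depth, Poisson noise, no GC/mappability bias: the log-transform
  # bias vanishes and LRC levels recover log2 ratios. Library-size
  # normalization anchors the overall mean, so the absolute level is checked
  # on a CNA-free genome and the CN contrast on an altered one.
  set.seed(5)
  bg <- test_grid(200)
  flat <- simulate_counts(simulate_clonal_tree(1, 2, bg,
                                               n_events_range = c(0L, 0L)),
                          bg, n_cells = 40, depth_mean = 4000,
                          dispersion = Inf, normal_frac = 0)
  lrc0 <- preprocess_counts(flat$counts, quantile_q = 0, gini_max = 1)
  expect_equal(mean(lrc0$lrc), 0, tolerance = 0.02)

  tree <- simulate_clonal_tree(1, 2, bg, cna_size_range = c(3e6, 4e6),
                               n_events_range = c(1L, 1L),
                               copy_changes = 2L, odd_change_per_edge = FALSE)
  sim <- simulate_counts(tree, bg, n_cells = 60, depth_mean = 4000,
                         dispersion = Inf, normal_frac = 0)
  lrc <- preprocess_counts(sim$counts, quantile_q = 0, gini_max = 1)
  cn <- sim$truth$cn[lrc$cell_index, lrc$bin_index]
  contrast <- mean(lrc$lrc[cn == 4]) - mean(lrc$lrc[cn == 2])
  expect_equal(contrast, 1, tolerance = 0.02)
})
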