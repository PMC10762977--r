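test_that("CBS finds the exact change point of a clean step", {
  x <- c(rep(0, 50), rep(1, 50))
  expect_equal(cbs_segment(x, alpha = 0.1, n_permutations = 200, seed = 1),
               50L)
  # location invariance: adding a constant changes nothing
  expect_equal(cbs_segment(x + 7.3, alpha = 0.1, n_permutations = 200,
                           seed = 1), 50L)
  # two steps
  y <- c(rep(0, 40), rep(1.5, 30), rep(0.2, 30))
  bp <- cbs_segment(y, alpha = 0.1, n_permutations = 200, seed = 2)
  expect_true(all(c(40L, 70L) %in% bp))
})

test_that("CBS calls nothing on constants or at vanishing alpha", {
  expect_equal(cbs_segment(rep(3.2, 80), n_permutations = 100, seed = 1),
               integer(0))
  x <- c(rep(0, 50), rep(1, 50))
  expect_equal(cbs_segment(x, alpha = 1e-4, n_permutations = 100, seed = 1),
               integer(0))  # p-value can never fall below 1/(nperm+1)
  expect_equal(cbs_segment(numeric(1)), integer(0))
})

test_that("CBS on pure noise rarely over-segments at alpha 0.1", {
  set.seed(123)
  calls <- replicate(20, length(cbs_segment(rnorm(300), alpha = 0.1,
                                            n_permutations = 100)))
  # regression statistic: small on average, not asserted to be zero
  expect_lt(mean(calls), 2)
})

test_that("breakpoint sets merge as sorted unions", {
  expect_equal(merge_breakpoints(list(c(10L, 20L), c(20L, 30L))),
               c(10L, 20L, 30L))
  expect_equal(merge_breakpoints(list(c(5L, 9L))), c(5L, 9L))
  expect_equal(merge_breakpoints(list()), integer(0))
})

test_that("segmentations satisfy the length bookkeeping invariants", {
  s1 <- segmentation_from_breakpoints(integer(0), 10)
  expect_equal(s1$K, 1L)
  expect_equal(s1$lengths, 10L)

  s2 <- segmentation_from_breakpoints(4L, 10)
  expect_equal(s2$K, 2L)
  expect_equal(s2$lengths, c(4L, 6L))

  s3 <- segmentation_from_breakpoints(integer(0), 10, chrom_bounds = 5L)
  expect_equal(s3$K, 2L)
  expect_equal(s3$lengths, c(5L, 5L))

  expect_error(segmentation_from_breakpoints(10L, 10), "breakpoints")
  for (i in 1:10) {
    set.seed(i)
    M <- sample(20:200, 1)
    bps <- sort(sample(seq_len(M - 1), sample(0:8, 1)))
    s <- segmentation_from_breakpoints(bps, M)
    expect_equal(sum(s$lengths), M)
    expect_equal(s$K, length(s$breakpoints) + 1L)
    expect_true(all(s$lengths >= 1L))
  }
})

test_that("latent segmentation respects chromosome boundaries", {
  bg <- test_grid(100, two_chrom = TRUE)
  z <- c(rep(0, 30), rep(1, 20), rep(1, 25), rep(0, 25))  # steps at 30, 75
  seg <- segment_latent(rbind(z), bg, alpha = 0.1, n_permutations = 200,
                        seed = 3)
  expect_true(50L %in% seg$breakpoints)  # forced chromosome bound
  expect_true(30L %in% seg$breakpoints)
  expect_true(75L %in% seg$breakpoints)
  expect_equal(sum(seg$lengths), 100L)
})

test_that("noiseless piecewise-constant LRC recovers true breakpoints end to end", {
  # joint property of the encoder and CBS: noiseless two-level input
  set.seed(21)
  n_cells <- 15
  lev <- c(rep(0, 40), rep(0.8, 30), rep(-0.4, 30))
  X <- outer(rep(1, n_cells), lev)
  m <- train_bin_autoencoder(X, epochs = 200, seed = 5, batch_size = 64)
  z <- encode_bins(X, m)
  bg <- test_grid(100)
  seg <- segment_latent(z, bg, alpha = 0.1, n_permutations = 200, seed = 6)
  expect_true(all(c(40L, 70L) %in% seg$breakpoints))
})
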