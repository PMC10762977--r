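test_that("reconstruction loss matches its closed form", {
  expect_equal(reconstruction_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(reconstruction_loss(c(1, 0), c(0, 0)), 0.25)  # (1/4)*1
  y <- matrix(rnorm(20), 4, 5)
  expect_equal(reconstruction_loss(y, y * 0),
               mean(colSums(y^2)) / 8)
})

test_that("training reduces loss on low-rank structured input", {
  set.seed(2)
  n_cells <- 12
  signal <- outer(rnorm(n_cells), rep(c(-0.5, 0.5), each = 100))
  X <- signal + matrix(rnorm(n_cells * 200, sd = 0.05), n_cells)
  m <- train_bin_autoencoder(X, latent_dim = 1, epochs = 60, seed = 9,
                             batch_size = 64)
  expect_length(m$loss_trace, 60)
  expect_true(all(is.finite(m$loss_trace)))
  expect_lt(m$loss_trace[60], m$loss_trace[1])
})

test_that("encoding is deterministic and respects input structure", {
  set.seed(3)
  X <- matrix(rnorm(10 * 50), 10, 50)
  X[, 30] <- X[, 10]  # duplicate bin
  m <- train_bin_autoencoder(X, epochs = 10, seed = 4, batch_size = 32)
  z1 <- encode_bins(X, m)
  z2 <- encode_bins(X, m)
  expect_identical(z1, z2)
  expect_equal(z1[, 10], z1[, 30])  # identical bins -> identical codes
  expect_equal(dim(z1), c(1L, 50L))
  expect_error(encode_bins(matrix(0, 9, 50), m), "cells")
})

test_that("training is reproducible under a seed", {
  set.seed(99)
  X <- matrix(rnorm(8 * 40), 8, 40)
  m1 <- train_bin_autoencoder(X, epochs = 5, seed = 123)
  m2 <- train_bin_autoencoder(X, epochs = 5, seed = 123)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$weights, m2$weights)
})

test_that("step-structured input separates linearly in the latent space", {
  set.seed(6)
  n_cells <- 20
  block <- rep(c(0, 0.8), each = 75)  # two blocks of bins
  X <- outer(rep(1, n_cells), block) +
    matrix(rnorm(n_cells * 150, sd = 0.1), n_cells)
  m <- train_bin_autoencoder(X, latent_dim = 1, epochs = 150, seed = 10,
                             batch_size = 64)
  z <- encode_bins(X, m)[1, ]
  lab <- rep(c(0, 1), each = 75)
  # the two blocks separate along the latent dimension: thresholding at the
  # median classifies almost every bin (sign of the code is arbitrary)
  cl <- z > median(z)
  expect_gt(max(mean(cl == lab), mean(cl != lab)), 0.95)
  expect_gt(abs(mean(z[lab == 1]) - mean(z[lab == 0])),
            2 * max(sd(z[lab == 0]), sd(z[lab == 1])))
})

test_that("model state survives a text round-trip", {
  set.seed(7)
  X <- matrix(rnorm(6 * 30), 6, 30)
  m <- train_bin_autoencoder(X, epochs = 3, seed = 11)
  td <- withr::local_tempdir()
  p <- file.path(td, "model.txt")
  write_autoencoder(m, p)
  back <- read_autoencoder(p)
  expect_equal(back$weights, m$weights)
  expect_equal(encode_bins(X, back), encode_bins(X, m))
})

test_that("architecture is the mirrored 256/128/64 funnel", {
  set.seed(8)
  X <- matrix(rnorm(5 * 20), 5, 20)
  m <- train_bin_autoencoder(X, latent_dim = 2, epochs = 1, seed = 1)
  dims <- vapply(m$weights, dim, integer(2))
  expect_equal(dims[1, ], c(5L, 256L, 128L, 64L, 2L, 64L, 128L, 256L))
  expect_equal(dims[2, ], c(256L, 128L, 64L, 2L, 64L, 128L, 256L, 5L))
})
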