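test_that("clonal trees respect the event design", {
  set.seed(1)
  bg <- make_bin_grid(c(chr1 = 120e6, chr2 = 100e6), 200000L)
  tree <- simulate_clonal_tree(4, 2, bg)
  expect_equal(dim(tree$profiles), c(4L, nrow(bg)))
  expect_true(all(tree$profiles >= 0))
  # event lengths within 3-20 Mb
  len <- tree$events$end - tree$events$start
  expect_true(all(len >= 3e6 & len <= 20e6))
  # each clone's edge carries at least one odd copy change
  odd_per_clone <- tapply(tree$events$change %% 2 != 0, tree$events$clone,
                          any)
  expect_true(all(odd_per_clone))
  # child - parent difference is nonzero exactly on the edge's footprints
  for (j in seq_len(4)) {
    parent_prof <- if (tree$parent[j] == 0) rep(2L, nrow(bg)) else
      tree$profiles[tree$parent[j], ]
    d <- tree$profiles[j, ] - parent_prof
    ev <- tree$events[tree$events$clone == j, , drop = FALSE]
    foot <- unlist(mapply(seq, ev$start_bin, ev$end_bin, SIMPLIFY = FALSE))
    expect_true(all(d[-foot] == 0))
    expect_true(all(d[foot] != 0))
  }
})

test_that("degenerate one-clone tree with no events is uniform", {
  bg <- test_grid(50)
  set.seed(2)
  tree <- simulate_clonal_tree(1, 3, bg, n_events_range = c(0L, 0L))
  expect_true(all(tree$profiles == 3L))
  expect_equal(nrow(tree$events), 0L)
})

test_that("count means follow depth * CN / ploidy", {
  set.seed(3)
  bg <- test_grid(300)
  tree <- simulate_clonal_tree(1, 2, bg, cna_size_range = c(10e6, 20e6),
                               n_events_range = c(1L, 1L),
                               copy_changes = 2L,
                               odd_change_per_edge = FALSE)
  # Poisson limit, no normals: law-of-large-numbers check within 3 SE
  sim <- simulate_counts(tree, bg, n_cells = 50, depth_mean = 40,
                         dispersion = Inf, normal_frac = 0)
  cn <- sim$truth$cn
  base <- sim$counts$counts[cn == 2]
  amp <- sim$counts$counts[cn == 4]
  se_base <- sqrt(40 / length(base))
  expect_lt(abs(mean(base) - 40), 3 * se_base)
  se_amp <- sqrt(80 / length(amp))
  expect_lt(abs(mean(amp) - 80), 3 * se_amp)  # CN = 2x ploidy doubles it
})

test_that("negative binomial dispersion widens counts beyond Poisson", {
  set.seed(4)
  bg <- test_grid(400)
  tree <- simulate_clonal_tree(1, 2, bg, n_events_range = c(0L, 0L))
  nb <- simulate_counts(tree, bg, n_cells = 30, depth_mean = 40,
                        dispersion = 8, normal_frac = 0)
  v <- var(as.numeric(nb$counts$counts))
  expect_gt(v, 150)  # theoretical 40 + 40^2/8 = 240 vs 40 for Poisson
  expect_lt(v, 350)
})

test_that("datasets are bitwise reproducible under a fixed seed", {
  a <- simulate_cna_dataset(ploidy = 3, n_cells = 15, n_clones = 3,
                            chrom_lengths = c(chrA = 30e6), seed = 77)
  b <- simulate_cna_dataset(ploidy = 3, n_cells = 15, n_clones = 3,
                            chrom_lengths = c(chrA = 30e6), seed = 77)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$cn, b$truth$cn)
  expect_identical(a$bins$gc, b$bins$gc)
})

test_that("ground-truth breakpoints are the CN matrix change points", {
  sim <- simulate_cna_dataset(ploidy = 2, n_cells = 25, n_clones = 4,
                              chrom_lengths = c(chrA = 50e6, chrB = 40e6),
                              seed = 5)
  cb <- chrom_boundaries(sim$bins)
  expect_equal(sim$truth$breakpoints,
               consensus_breakpoints(sim$truth$cn, cb))
  expect_true(all(sim$truth$clone %in% 0:4))
  expect_equal(sum(sim$truth$clone == 0), round(0.1 * 25))
  # normal cells are diploid
  expect_true(all(sim$truth$cn[sim$truth$clone == 0, ] == 2L))
})

test_that("ground truth tables serialize to plain text", {
  sim <- simulate_cna_dataset(ploidy = 2, n_cells = 6, n_clones = 2,
                              chrom_lengths = c(chrA = 60e6), seed = 6)
  td <- withr::local_tempdir()
  write_ground_truth(sim, td)
  cn <- utils::read.table(file.path(td, "true_cn.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  expect_equal(as.matrix(cn[, -1]), sim$truth$cn, ignore_attr = TRUE)
  bp <- utils::read.table(file.path(td, "true_breakpoints.tsv"),
                          header = TRUE)
  expect_equal(bp$breakpoint, sim$truth$breakpoints)
})
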