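#' Simulate GC and mappability tracks for a bin grid
#'
#' Draws bland, realistic tracks: GC uniform in `[0.35, 0.55]` (the bulk of
#' mammalian 200 kb bins) and mappability uniform in `[0.92, 1]`, so that by
#' default no bin fails the track filters and every GC stratum is well
#' populated. Tails can be injected for filter testing via the `*_outlier`
#' fractions.
#'
#' @param bg a [bin_grid()].
#' @param gc_range,map_range uniform ranges for the tracks.
#' @param gc_outlier_frac,map_outlier_frac fraction of bins given extreme
#'   values (GC drawn from `[0, 0.08] U [0.92, 1]`, mappability from
#'   `[0, 0.5]`).
#' @return the grid with `gc` and `mappability` overwritten.
#' @export
simulate_bin_tracks <- function(bg, gc_range = c(0.35, 0.55),
                                map_range = c(0.92, 1.0),
                                gc_outlier_frac = 0, map_outlier_frac = 0) {
  M <- nrow(bg)
  bg$gc <- stats::runif(M, gc_range[1L], gc_range[2L])
  bg$mappability <- stats::runif(M, map_range[1L], map_range[2L])
  if (gc_outlier_frac > 0) {
    n <- max(1L, round(gc_outlier_frac * M))
    i <- sample.int(M, n)
    lo <- stats::runif(n) < 0.5
    bg$gc[i] <- ifelse(lo, stats::runif(n, 0, 0.08),
                       stats::runif(n, 0.92, 1))
  }
  if (map_outlier_frac > 0) {
    n <- max(1L, round(map_outlier_frac * M))
    bg$mappability[sample.int(M, n)] <- stats::runif(n, 0, 0.5)
  }
  bg
}

#' Simulate a clonal tree of copy number profiles
#'
#' The ancestral cell state (the tree root) is homogeneous at the given
#' ploidy; each of the `n_clones` sampled tumor clones attaches to the
#' ancestor or to a uniformly chosen earlier clone, and its edge carries CNA
#' events. Event lengths are uniform in `cna_size_range` bp (footprint =
#' bins fully contained in the event), copy changes are drawn from
#' `copy_changes` and applied to the parent profile with clipping at 0.
#' Events whose footprint would overlap an earlier event on the same edge,
#' or would leave some footprint bin unchanged after clipping, are re-drawn,
#' so the child-minus-parent difference is nonzero exactly on each edge's
#' event footprint.
#'
#' When `odd_change_per_edge = TRUE` (default) each edge with at least one
#' event carries at least one odd copy change. Single-copy gains and losses
#' are the most common CNAs in tumors, and an odd-copy-number segment in
#' every lineage makes each clone's absolute ploidy identifiable from read
#' depth alone (a genome whose copy numbers are all even is
#' indistinguishable from its halved version).
#'
#' @param n_clones number of sampled clones (>= 1, ancestor not included).
#' @param ploidy ancestral ploidy (2, 3 or 4 in the benchmark designs).
#' @param bg the [bin_grid()] events are placed on.
#' @param cna_size_range event length range in bp (default 3-20 Mb).
#' @param n_events_range events per edge, uniform integer range (default
#'   `c(1, 3)`).
#' @param copy_changes candidate per-event copy changes.
#' @param odd_change_per_edge require at least one odd change per edge.
#' @param max_tries re-draws allowed per event before giving up.
#' @return An object of class `"clonal_tree"`: list with `profiles` (clones
#'   x bins integer matrix), `parent` (per-clone parent index, 0 = the
#'   ancestor), `events` (data.frame: clone, chrom, start, end, change,
#'   start_bin, end_bin), `ploidy`.
#' @export
simulate_clonal_tree <- function(n_clones, ploidy, bg,
                                 cna_size_range = c(3e6, 20e6),
                                 n_events_range = c(1L, 3L),
                                 copy_changes = c(-2L, -1L, 1L, 2L),
                                 odd_change_per_edge = TRUE,
                                 max_tries = 200L) {
  stopifnot(n_clones >= 1L, ploidy >= 1L)
  M <- nrow(bg)
  chroms <- unique(bg$chrom)
  chrom_len <- vapply(chroms, function(ch) max(bg$end[bg$chrom == ch]),
                      numeric(1))
  profiles <- matrix(as.integer(ploidy), n_clones, M)
  parent <- rep(0L, n_clones)
  odd <- copy_changes[copy_changes %% 2L != 0L]
  events <- list()
  for (j in seq_len(n_clones)) {
    parent[j] <- if (j == 1L) 0L else sample.int(j, 1L) - 1L
    prof <- if (parent[j] == 0L) rep(as.integer(ploidy), M) else
      profiles[parent[j], ]
    n_ev <- sample(seq(n_events_range[1L], n_events_range[2L]), 1L)
    used <- rep(FALSE, M)
    force_odd <- odd_change_per_edge && n_ev > 0L && length(odd) > 0L
    for (e in seq_len(n_ev)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        len <- stats::runif(1, cna_size_range[1L], cna_size_range[2L])
        ch <- sample(chroms, 1L, prob = chrom_len)
        if (len >= chrom_len[ch]) next
        start <- floor(stats::runif(1, 0, chrom_len[ch] - len))
        end <- start + len
        foot <- which(bg$chrom == ch & bg$start >= start & bg$end <= end)
        if (length(foot) == 0L || any(used[foot])) next
        # the last event of an edge carries the odd-change requirement if no
        # earlier event satisfied it
        pool <- if (force_odd && e == n_ev) odd else copy_changes
        delta <- if (length(pool) == 1L) pool else sample(pool, 1L)
        new <- pmax(prof[foot] + delta, 0L)
        if (any(new == prof[foot])) next  # clipped to no-op somewhere
        prof[foot] <- new
        used[foot] <- TRUE
        if (delta %% 2L != 0L) force_odd <- FALSE
        events[[length(events) + 1L]] <- data.frame(
          clone = j, chrom = ch, start = start, end = end, change = delta,
          start_bin = min(foot), end_bin = max(foot))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place CNA event (genome exhausted) for clone ", j)
    }
    profiles[j, ] <- prof
  }
  structure(list(profiles = profiles, parent = parent,
                 events = if (length(events)) do.call(rbind, events) else
                   data.frame(),
                 ploidy = as.integer(ploidy)),
            class = "clonal_tree")
}

#' @export
print.clonal_tree <- function(x, ...) {
  cat(sprintf("clonal_tree: %d clones at ploidy %d, %d CNA events\n",
              nrow(x$profiles), x$ploidy, nrow(x$events)))
  invisible(x)
}

#' Simulate bin read counts from a clonal tree
#'
#' Cells are split between the tumor clones in (near-)equal numbers, with an
#' optional fraction of diploid normal cells appended, then per-cell per-bin
#' counts are drawn from a negative binomial with mean
#' `depth_mean * c_ik / ploidy * g(gc_k)` and the given dispersion (size)
#' parameter; `dispersion = Inf` gives the Poisson limit. `depth_mean` is the
#' expected reads per bin at copy number equal to the ancestral ploidy
#' (about 40 for 0.02x coverage, 200 kb bins and ~100 bp reads — the regime
#' whole-genome-amplified single-cell data is sequenced at).
#'
#' @param tree a [simulate_clonal_tree()] result.
#' @param bg the matching [bin_grid()].
#' @param n_cells total number of cells (default 100).
#' @param depth_mean expected reads/bin at CN = ploidy (default 40).
#' @param dispersion negative binomial size parameter (default 8, matching
#'   the overdispersion of amplified single-cell libraries).
#' @param gc_bias optional function `g(gc)` multiplying the mean, for
#'   simulating residual GC bias (default none).
#' @param normal_frac fraction of diploid normal cells mixed in (default
#'   0.1; use 0 for tumor-only datasets).
#' @return list with `counts` (a [count_matrix()]) and `truth` (class
#'   `"cna_ground_truth"`: `cn` cells x bins integer matrix, `breakpoints`
#'   in package convention excluding chromosome boundaries, `clone` per-cell
#'   labels, 0 = normal, `ploidy`, `acn` per-cell true average copy number,
#'   and the simulation parameters).
#' @export
simulate_counts <- function(tree, bg, n_cells = 100L, depth_mean = 40,
                            dispersion = 8, gc_bias = NULL,
                            normal_frac = 0.1) {
  stopifnot(inherits(tree, "clonal_tree"), depth_mean > 0)
  M <- nrow(bg)
  n_clones <- nrow(tree$profiles)
  n_normal <- round(normal_frac * n_cells)
  n_tumor <- n_cells - n_normal
  base <- rep(seq_len(n_clones), length.out = n_tumor)  # near-equal fractions
  clone <- c(sample(base), rep(0L, n_normal))
  cn <- matrix(2L, n_cells, M)
  for (i in seq_len(n_cells))
    if (clone[i] > 0L) cn[i, ] <- tree$profiles[clone[i], ]
  g <- if (is.null(gc_bias)) rep(1, M) else gc_bias(bg$gc)
  mu <- (cn / tree$ploidy * depth_mean) * rep(g, each = n_cells)
  counts <- if (is.infinite(dispersion))
    matrix(stats::rpois(n_cells * M, mu), n_cells, M)
  else
    matrix(stats::rnbinom(n_cells * M, size = dispersion, mu = mu),
           n_cells, M)
  cell_ids <- sprintf("cell_%03d", seq_len(n_cells))
  truth <- structure(list(
    cn = cn, clone = clone,
    breakpoints = consensus_breakpoints(cn, chrom_boundaries(bg)),
    ploidy = tree$ploidy, acn = rowMeans(cn),
    params = list(n_cells = n_cells, depth_mean = depth_mean,
                  dispersion = dispersion, normal_frac = normal_frac)),
    class = "cna_ground_truth")
  list(counts = count_matrix(counts, cell_ids, bg), truth = truth)
}

#' Simulate a complete benchmark dataset
#'
#' One call reproducing the benchmark designs: a bin grid over hg19-scale
#' chromosomes 1-3 at 200 kb (~3450 bins) with simulated tracks, a clonal
#' tree (default 4 clones) at the chosen ploidy with 3-20 Mb CNAs, and
#' negative-binomial counts at ~0.02x-equivalent depth for 100 cells
#' including 10% normal cells. All randomness is governed by `seed`, so a
#' fixed seed gives bitwise-identical output.
#'
#' @param ploidy ancestral tumor ploidy (2, 3 or 4).
#' @param n_cells,n_clones,depth_mean,dispersion,normal_frac,gc_bias see
#'   [simulate_counts()] / [simulate_clonal_tree()].
#' @param chrom_lengths named chromosome lengths (default
#'   [default_sim_chromosomes()]).
#' @param bin_size bin width (default 200 kb).
#' @param cna_size_range,n_events_range,copy_changes event design, see
#'   [simulate_clonal_tree()].
#' @param seed integer seed (required, for reproducibility).
#' @return list `counts`, `truth`, `tree`, `bins`.
#' @export
simulate_cna_dataset <- function(ploidy = 2L, n_cells = 100L, n_clones = 4L,
                                 depth_mean = 40, dispersion = 8,
                                 normal_frac = 0.1, gc_bias = NULL,
                                 chrom_lengths = default_sim_chromosomes(),
                                 bin_size = 200000L,
                                 cna_size_range = c(3e6, 20e6),
                                 n_events_range = c(1L, 3L),
                                 copy_changes = c(-2L, -1L, 1L, 2L),
                                 seed = 1L) {
  set.seed(seed)
  bg <- make_bin_grid(chrom_lengths, bin_size)
  bg <- simulate_bin_tracks(bg)
  tree <- simulate_clonal_tree(n_clones, ploidy, bg, cna_size_range,
                               n_events_range, copy_changes)
  sim <- simulate_counts(tree, bg, n_cells, depth_mean, dispersion, gc_bias,
                         normal_frac)
  list(counts = sim$counts, truth = sim$truth, tree = tree, bins = bg)
}

#' Write ground truth tables
#'
#' Writes the true copy number matrix (TSV, same dialect as counts), the
#' breakpoint list, clone labels, and a JSON manifest of the simulation
#' parameters (requires jsonlite).
#'
#' @param sim a [simulate_cna_dataset()] result.
#' @param dir output directory (created if needed).
#' @export
write_ground_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- sim$truth
  df <- data.frame(cell_id = sim$counts$cell_ids, tr$cn, check.names = FALSE)
  names(df) <- c("cell_id", bin_labels(sim$bins))
  utils::write.table(df, file.path(dir, "true_cn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(breakpoint = tr$breakpoints),
                     file.path(dir, "true_breakpoints.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell_id = sim$counts$cell_ids,
                                clone = tr$clone, acn = tr$acn),
                     file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(c(tr$params, list(ploidy = tr$ploidy)),
                         file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(NULL)
}
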