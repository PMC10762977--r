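#' Circular binary segmentation of one sequence
#'
#' Recursive circular binary segmentation: at each stage the pair of circular
#' split points maximizing the between-segment t-like contrast is found by
#' exhaustive scan, the split is accepted if its permutation p-value is below
#' `alpha`, and accepted subsegments are segmented recursively. The statistic
#' is location-invariant, so adding a constant to the sequence does not
#' change the result.
#'
#' Breakpoint convention (used throughout the package): a breakpoint value
#' `b` counts the bins before the cut, i.e. it separates bins `1..b` from
#' `b+1..M` (equivalently, in 0-based coordinates the new segment starts at
#' bin `b`). Values lie strictly inside `(0, M)`.
#'
#' @param sequence numeric vector (one latent dimension over bins).
#' @param alpha significance level for a split (default 0.1, deliberately
#'   permissive to minimize false-negative breakpoints; over-segmentation is
#'   recalibrated downstream by merging equal-copy-number segments).
#' @param n_permutations permutations per split test (default 1000).
#' @param seed optional integer seed for the permutation stream.
#' @return sorted integer vector of breakpoints in `1..M-1` (empty when no
#'   split is accepted).
#' @export
cbs_segment <- function(sequence, alpha = 0.1, n_permutations = 1000L,
                        seed = NULL) {
  stopifnot(length(sequence) >= 1L, alpha > 0, alpha < 1)
  if (length(sequence) < 2L) return(integer(0))
  if (!is.null(seed)) set.seed(seed)
  bp <- .cbs_segment_cpp(as.numeric(sequence), alpha,
                         as.integer(n_permutations))
  sort(bp)
}

#' Merge breakpoint sets from several latent dimensions
#'
#' @param sets list of integer breakpoint vectors over the same M bins.
#' @return sorted union.
#' @export
merge_breakpoints <- function(sets) {
  if (length(sets) == 0L) return(integer(0))
  sort(unique(as.integer(unlist(sets))))
}

#' Build a segmentation from breakpoints
#'
#' Chromosome boundary indices are mandatory breakpoints: segments never span
#' chromosomes.
#'
#' @param bps integer breakpoints (see [cbs_segment()] for the convention),
#'   strictly inside `(0, M)`.
#' @param M number of bins.
#' @param chrom_bounds integer vector of chromosome boundary breakpoints
#'   (see [chrom_boundaries()]).
#' @return An object of class `"segmentation"`: list with `breakpoints`
#'   (including forced chromosome bounds), `K`, `lengths` (L_k, summing to
#'   M), and `M`.
#' @export
segmentation_from_breakpoints <- function(bps, M, chrom_bounds = integer(0)) {
  bps <- sort(unique(as.integer(c(bps, chrom_bounds))))
  if (length(bps) > 0L && (min(bps) < 1L || max(bps) >= M))
    stop("breakpoints must lie in 1..M-1")
  edges <- c(0L, bps, as.integer(M))
  lengths <- diff(edges)
  structure(list(breakpoints = bps, K = length(lengths), lengths = lengths,
                 M = as.integer(M)),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d segments over %d bins (lengths %s%s)\n",
              x$K, x$M,
              paste(utils::head(x$lengths, 10L), collapse = ", "),
              if (x$K > 10L) ", ..." else ""))
  invisible(x)
}

#' Segment index of every bin
#'
#' @param seg a [segmentation()].
#' @return integer vector of length M mapping each bin to its segment.
#' @export
segment_of_bin <- function(seg) {
  rep(seq_len(seg$K), seg$lengths)
}

#' Segment a latent matrix per chromosome
#'
#' Applies [cbs_segment()] to each latent dimension within each chromosome
#' independently and merges all detected breakpoints (plus the forced
#' chromosome boundaries) into one cross-cell segmentation.
#'
#' @param z numeric matrix d x M of latent bin representations.
#' @param bins the matching [bin_grid()].
#' @param alpha,n_permutations,seed passed to [cbs_segment()].
#' @return A [segmentation_from_breakpoints()] object.
#' @export
segment_latent <- function(z, bins, alpha = 0.1, n_permutations = 1000L,
                           seed = NULL) {
  z <- rbind(z)  # tolerate a bare vector
  M <- ncol(z)
  stopifnot(M == nrow(bins))
  if (!is.null(seed)) set.seed(seed)
  bounds <- chrom_boundaries(bins)
  first <- c(1L, bounds + 1L)
  last <- c(bounds, M)
  sets <- list()
  for (d in seq_len(nrow(z))) {
    for (e in seq_along(first)) {
      a <- first[e]; b <- last[e]
      if (b - a + 1L < 2L) next
      local_bp <- cbs_segment(z[d, a:b], alpha, n_permutations)
      sets[[length(sets) + 1L]] <- local_bp + a - 1L
    }
  }
  segmentation_from_breakpoints(merge_breakpoints(sets), M, bounds)
}
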