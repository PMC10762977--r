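#' Breakpoint distance
#'
#' Sum, over the real breakpoints, of the distance (in bins) to the nearest
#' inferred breakpoint. 0 iff every real breakpoint is also inferred; adding
#' an inferred breakpoint far from all real ones does not change the value
#' (that precision loss is captured by [breakpoint_ratio()]). When the
#' inferred set is empty the distance per real breakpoint is taken as `M`.
#'
#' @param real_bps non-empty integer vector of true breakpoints.
#' @param inferred_bps integer vector of inferred breakpoints (possibly
#'   empty).
#' @param M number of bins (used only for the empty-inferred convention).
#' @return non-negative total distance in bin units.
#' @export
breakpoint_distance <- function(real_bps, inferred_bps, M = NULL) {
  if (length(real_bps) == 0L)
    stop("breakpoint distance is undefined for an empty real set")
  if (length(inferred_bps) == 0L) {
    if (is.null(M)) stop("M is required when the inferred set is empty")
    return(length(real_bps) * M)
  }
  sum(vapply(real_bps, function(b) min(abs(b - inferred_bps)), numeric(1)))
}

#' Breakpoint count ratio w
#'
#' `w = |inferred| / |real|`; values near 1 indicate neither missed
#' breakpoints nor over-segmentation.
#'
#' @inheritParams breakpoint_distance
#' @return positive real (0 when nothing was inferred).
#' @export
breakpoint_ratio <- function(real_bps, inferred_bps) {
  if (length(real_bps) == 0L) stop("w is undefined for an empty real set")
  length(inferred_bps) / length(real_bps)
}

#' Per-cell mean absolute difference of copy numbers
#'
#' @param true_cn,inferred_cn integer vectors of per-bin copy numbers for
#'   one cell.
#' @param common_bins index set over which to compare (default all).
#' @return mean |true - inferred| over the common bins.
#' @export
mad_per_cell <- function(true_cn, inferred_cn,
                         common_bins = seq_along(true_cn)) {
  if (length(common_bins) == 0L) stop("common bin set is empty")
  mean(abs(true_cn[common_bins] - inferred_cn[common_bins]))
}

#' Average copy number and its error
#'
#' ACN is the mean per-bin copy number of a cell; the error is reported as
#' truth minus inferred, so overestimated ploidy gives a negative value.
#'
#' @param true_cn,inferred_cn per-bin copy numbers over the same bin set.
#' @return named numeric: `acn_true`, `acn_inferred`, `delta_acn`.
#' @export
acn_delta <- function(true_cn, inferred_cn) {
  stopifnot(length(true_cn) == length(inferred_cn))
  at <- mean(true_cn); ai <- mean(inferred_cn)
  c(acn_true = at, acn_inferred = ai, delta_acn = at - ai)
}

#' Evaluate an inferred profile set against ground truth
#'
#' Computes the four benchmark metrics on the common bins: breakpoint
#' distance, breakpoint ratio w, per-cell MAD (and its mean), and per-cell
#' ACN error (and its median).
#'
#' @param true_cn integer matrix, cells x bins (ground truth).
#' @param inferred_cn integer matrix, same cells x bins.
#' @param real_bps,inferred_bps breakpoint sets in the same (common-bin)
#'   coordinate space.
#' @param common_bins index set of bins to compare (default all columns).
#' @param cells optional subset/reordering of cell indices.
#' @return An object of class `"eval_report"`: list with `breakpoint_distance`,
#'   `w`, `mad` (per cell), `mean_mad`, `acn` (per-cell matrix), and
#'   `median_delta_acn`.
#' @export
evaluate_calls <- function(true_cn, inferred_cn, real_bps, inferred_bps,
                           common_bins = seq_len(ncol(true_cn)),
                           cells = seq_len(nrow(true_cn))) {
  true_cn <- rbind(true_cn)[cells, common_bins, drop = FALSE]
  inferred_cn <- rbind(inferred_cn)[cells, common_bins, drop = FALSE]
  stopifnot(identical(dim(true_cn), dim(inferred_cn)))
  mad <- vapply(seq_len(nrow(true_cn)), function(i)
    mad_per_cell(true_cn[i, ], inferred_cn[i, ]), numeric(1))
  acn <- t(vapply(seq_len(nrow(true_cn)), function(i)
    acn_delta(true_cn[i, ], inferred_cn[i, ]), numeric(3)))
  structure(list(
    breakpoint_distance = breakpoint_distance(real_bps, inferred_bps,
                                              M = length(common_bins)),
    w = breakpoint_ratio(real_bps, inferred_bps),
    mad = mad, mean_mad = mean(mad),
    acn = acn, median_delta_acn = stats::median(acn[, "delta_acn"]),
    n_real = length(real_bps), n_inferred = length(inferred_bps)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report:\n")
  cat(sprintf("  breakpoint distance: %g (over %d real, %d inferred)\n",
              x$breakpoint_distance, x$n_real, x$n_inferred))
  cat(sprintf("  w:                   %.3f\n", x$w))
  cat(sprintf("  mean MAD:            %.4f\n", x$mean_mad))
  cat(sprintf("  median delta-ACN:    %+.4f\n", x$median_delta_acn))
  invisible(x)
}

#' Evaluate a pipeline fit against simulation ground truth
#'
#' Restricts the ground truth to the cells and bins retained by
#' preprocessing (the common set) and computes the [evaluate_calls()]
#' metrics for a [cna_fit()] on a [simulate_cna_dataset()] result.
#'
#' @param fit a [cna_fit()].
#' @param sim the matching [simulate_cna_dataset()] output.
#' @return An `eval_report` (see [evaluate_calls()]).
#' @export
evaluate_fit <- function(fit, sim) {
  stopifnot(inherits(fit, "cna_fit"))
  tr <- sim$truth$cn[fit$lrc$cell_index, fit$lrc$bin_index, drop = FALSE]
  tb <- consensus_breakpoints(tr, chrom_boundaries(fit$lrc$bins))
  evaluate_calls(tr, fit$cn, tb, fit$breakpoints)
}
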