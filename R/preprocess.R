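#' Quality-control report accumulated across preprocessing
#'
#' Records every bin and cell removed during preprocessing together with the
#' single rule that triggered the removal, plus the per-cell library-size
#' factors used for normalization.
#'
#' @return An object of class `"qc_report"`: list with `removed_bins`
#'   (data.frame: `bin`, original bin index; `label`; `reason` in
#'   `gc_low`, `gc_high`, `mappability`, `quantile`), `removed_cells`
#'   (data.frame: `cell_id`, `gini`), `lib_size` (named numeric), and
#'   `warnings` (character).
#' @keywords internal
new_qc_report <- function() {
  structure(list(
    removed_bins = data.frame(bin = integer(), label = character(),
                              reason = character(), stringsAsFactors = FALSE),
    removed_cells = data.frame(cell_id = character(), gini = numeric(),
                               stringsAsFactors = FALSE),
    lib_size = numeric(0),
    warnings = character(0)),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:\n")
  cat("  bins removed: ", nrow(x$removed_bins), sep = "")
  if (nrow(x$removed_bins) > 0L) {
    tab <- table(x$removed_bins$reason)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n  cells removed: ", nrow(x$removed_cells), "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Remove bins with extreme GC content or low mappability
#'
#' Bins with GC fraction below `gc_low`, above `gc_high`, or mappability on
#' the failing side of `map_min` are outliers of the counting model and are
#' removed before any normalization. High mappability is desirable, so the
#' default removes bins with mappability *below* 0.9; the comparator is
#' configurable via `map_keep_high = FALSE` for tracks with inverted
#' conventions.
#'
#' @param cm a [count_matrix()].
#' @param gc_low,gc_high GC fraction bounds (defaults 0.10 / 0.90).
#' @param map_min mappability threshold (default 0.90).
#' @param map_keep_high if `TRUE` (default), bins with mappability <
#'   `map_min` are removed; if `FALSE` the comparison is reversed.
#' @param qc an existing [new_qc_report()] to append to.
#' @return list with elements `cm` (filtered [count_matrix()]) and `qc`.
#' @export
filter_bins_by_tracks <- function(cm, gc_low = 0.10, gc_high = 0.90,
                                  map_min = 0.90, map_keep_high = TRUE,
                                  qc = new_qc_report()) {
  stopifnot(inherits(cm, "count_matrix"))
  bg <- cm$bins
  reason <- rep(NA_character_, nrow(bg))
  reason[bg$gc < gc_low] <- "gc_low"
  reason[is.na(reason) & bg$gc > gc_high] <- "gc_high"
  map_bad <- if (map_keep_high) bg$mappability < map_min else
    bg$mappability > map_min
  reason[is.na(reason) & map_bad] <- "mappability"
  drop <- which(!is.na(reason))
  if (length(drop) == nrow(bg)) stop("no bins survive track filters")
  if (length(drop) > 0L) {
    qc$removed_bins <- rbind(qc$removed_bins, data.frame(
      bin = drop, label = bin_labels(bg)[drop], reason = reason[drop],
      stringsAsFactors = FALSE))
    keep <- setdiff(seq_len(nrow(bg)), drop)
    bg2 <- bg[keep, , drop = FALSE]
    rownames(bg2) <- NULL
    attr(bg2, "bin_size") <- attr(bg, "bin_size")
    class(bg2) <- class(bg)
    cm <- count_matrix(cm$counts[, keep, drop = FALSE], cm$cell_ids, bg2)
  }
  list(cm = cm, qc = qc)
}

#' Library-size normalization
#'
#' Divides each cell's counts by that cell's mean count, making rows
#' comparable between cells (each output row has mean 1).
#'
#' @param counts numeric matrix, cells x bins (raw counts).
#' @param cell_ids optional cell ids used in error messages.
#' @return list with `norm` (numeric matrix) and `factors` (the per-cell
#'   means divided out).
#' @export
library_size_normalize <- function(counts, cell_ids = rownames(counts)) {
  m <- rowMeans(counts)
  if (any(m <= 0)) {
    bad <- if (is.null(cell_ids)) which(m <= 0)[1L] else
      cell_ids[which(m <= 0)[1L]]
    stop("cell '", bad, "' has zero mean count; remove it before normalizing")
  }
  list(norm = counts / m, factors = stats::setNames(m, cell_ids))
}

#' Remove bins in the extreme quantiles of mean normalized count
#'
#' Bins whose across-cell mean normalized count lies strictly below the `q`
#' quantile or strictly above the `1 - q` quantile (linear-interpolation
#' quantiles) are removed; boundary ties are kept, so the rule is
#' deterministic and conservative.
#'
#' @param norm numeric matrix of library-size-normalized counts.
#' @param bins the matching [bin_grid()].
#' @param q tail fraction (default 0.01).
#' @param qc report to append to.
#' @return list `norm`, `bins`, `qc`, `keep` (surviving original columns).
#' @export
filter_extreme_bins <- function(norm, bins, q = 0.01, qc = new_qc_report()) {
  if (ncol(norm) < 3L) stop("need at least 3 bins")
  keep <- seq_len(ncol(norm))
  if (q > 0) {
    mu <- colMeans(norm)
    lo <- stats::quantile(mu, q, names = FALSE)
    hi <- stats::quantile(mu, 1 - q, names = FALSE)
    drop <- which(mu < lo | mu > hi)
    if (length(drop) > 0L) {
      qc$removed_bins <- rbind(qc$removed_bins, data.frame(
        bin = drop, label = bin_labels(bins)[drop], reason = "quantile",
        stringsAsFactors = FALSE))
      keep <- setdiff(keep, drop)
      norm <- norm[, keep, drop = FALSE]
      bs <- attr(bins, "bin_size")
      bins <- bins[keep, , drop = FALSE]
      rownames(bins) <- NULL
      attr(bins, "bin_size") <- bs
      class(bins) <- c("bin_grid", "data.frame")
    }
  }
  list(norm = norm, bins = bins, qc = qc, keep = keep)
}

#' Gini coefficient of a cell's bin counts
#'
#' Mean-absolute-difference form
#' \deqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x),}
#' computed in O(n log n) via the sorted identity. G is 0 for perfectly even
#' coverage and approaches 1 as coverage concentrates in few bins; it is
#' scale-invariant, so raw and library-normalized counts give the same value.
#'
#' @param row non-negative numeric vector (a cell's counts), length >= 2,
#'   not all zero.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_coefficient <- function(row) {
  if (length(row) < 2L) stop("need at least 2 bins")
  if (any(row < 0)) stop("counts must be non-negative")
  s <- sum(row)
  if (s == 0) stop("all-zero row has undefined Gini coefficient")
  n <- length(row)
  x <- sort(row)
  # sum_{i<j} (x_j - x_i) = sum_i (2i - n - 1) x_(i)
  g <- sum((2 * seq_len(n) - n - 1) * x) / (n * s)
  g
}

#' Remove cells with uneven coverage by Gini coefficient
#'
#' Cells whose Gini coefficient is at or above `threshold` show extensively
#' fluctuating read counts (typically degraded amplification) and are
#' excluded.
#'
#' @param counts numeric matrix (cells x bins) on which to compute Gini;
#'   conventionally the raw counts.
#' @param cell_ids cell identifiers.
#' @param threshold exclusion threshold (default 0.3).
#' @param qc report to append to.
#' @return list `keep` (logical per cell), `gini` (per-cell values), `qc`.
#' @export
filter_cells_by_gini <- function(counts, cell_ids = rownames(counts),
                                 threshold = 0.3, qc = new_qc_report()) {
  g <- apply(counts, 1L, gini_coefficient)
  bad <- g >= threshold
  if (all(bad)) stop("no cells survive Gini filter")
  if (any(bad)) {
    qc$removed_cells <- rbind(qc$removed_cells, data.frame(
      cell_id = cell_ids[bad], gini = g[bad], stringsAsFactors = FALSE))
  }
  list(keep = !bad, gini = stats::setNames(g, cell_ids), qc = qc)
}

.stratum_ids <- function(values, width) {
  pmin(as.integer(floor(values / width)), as.integer(floor(1 / width)))
}

.median_normalize_track <- function(norm, strata, qc) {
  out <- norm
  sl <- split(seq_along(strata), strata)
  for (i in seq_len(nrow(norm))) {
    r <- norm[i, ]
    m <- stats::median(r)
    for (bins_in in sl) {
      mk <- stats::median(r[bins_in])
      if (mk <= 0) {
        qc$warnings <- c(qc$warnings, sprintf(
          "cell %d: stratum with zero median (%d bins); using global median",
          i, length(bins_in)))
        mk <- m
      }
      out[i, bins_in] <- r[bins_in] * m / mk
    }
  }
  list(norm = out, qc = qc)
}

#' Median normalization of GC-content and mappability bias
#'
#' For each cell, corrects each bin's (library-normalized) count as
#' \deqn{\hat r_k = r_k \cdot m / m_k,}
#' where `m` is the cell's median count over all bins and `m_k` the median
#' over bins sharing bin `k`'s stratum. Strata are equal-width intervals of
#' the track value ("same GC-content" operationally); the correction is
#' applied once with GC strata and then once with mappability strata.
#' A stratum with zero median falls back to the global median with a logged
#' warning.
#'
#' @param norm numeric matrix (cells x bins), library-size normalized.
#' @param bins the matching [bin_grid()].
#' @param gc_width width of GC strata (default 0.01).
#' @param map_width width of mappability strata (default 0.02).
#' @param qc report to append to.
#' @return list `norm` (corrected matrix), `qc`.
#' @export
median_normalize <- function(norm, bins, gc_width = 0.01, map_width = 0.02,
                             qc = new_qc_report()) {
  stopifnot(ncol(norm) == nrow(bins))
  r <- .median_normalize_track(norm, .stratum_ids(bins$gc, gc_width), qc)
  r <- .median_normalize_track(r$norm, .stratum_ids(bins$mappability,
                                                    map_width), r$qc)
  r
}

#' Log2 read counts
#'
#' `lrc = log2(max(corrected, eps))`. The floor keeps zero-count bins finite
#' and is chosen to coincide with the copy-number-0 state mean of the
#' downstream mixture (`log2(0.5 * 0.25) = -3`), so bins in homozygously
#' deleted regions land at the value the model expects for them instead of
#' acting as extreme outliers that destabilize the shared variance.
#'
#' @param corrected numeric matrix of corrected, normalized counts.
#' @param eps floor applied before the log (default 0.125).
#' @return numeric matrix of the same shape.
#' @export
to_lrc <- function(corrected, eps = 0.125) {
  log2(pmax(corrected, eps))
}

#' Preprocess a count matrix into the LRC matrix
#'
#' Runs the fixed pipeline: track-based bin filter, library-size
#' normalization, extreme-bin (quantile) filter, Gini cell filter, per-cell
#' median normalization of GC then mappability bias, and the log2 transform.
#' Each step's removals are logged in the QC report.
#'
#' @param cm a [count_matrix()].
#' @param gc_low,gc_high,map_min,map_keep_high see [filter_bins_by_tracks()].
#' @param quantile_q see [filter_extreme_bins()].
#' @param gini_max see [filter_cells_by_gini()] (`threshold`).
#' @param gini_on compute Gini on `"raw"` (default) or `"norm"` counts.
#' @param gc_width,map_width see [median_normalize()].
#' @param eps see [to_lrc()].
#' @return An object of class `"lrc_matrix"`: list with `lrc` (numeric
#'   matrix, retained cells x retained bins), `cell_ids`, `bins` (filtered
#'   [bin_grid()]), `bin_index` (original indices of retained bins, relative
#'   to `cm$bins`), `cell_index`, and `qc`.
#' @export
preprocess_counts <- function(cm, gc_low = 0.10, gc_high = 0.90,
                              map_min = 0.90, map_keep_high = TRUE,
                              quantile_q = 0.01, gini_max = 0.3,
                              gini_on = c("raw", "norm"),
                              gc_width = 0.01, map_width = 0.02, eps = 0.125) {
  stopifnot(inherits(cm, "count_matrix"))
  gini_on <- match.arg(gini_on)
  qc <- new_qc_report()
  orig_labels <- bin_labels(cm$bins)
  st <- filter_bins_by_tracks(cm, gc_low, gc_high, map_min, map_keep_high, qc)
  cm1 <- st$cm; qc <- st$qc
  ls <- library_size_normalize(cm1$counts, cm1$cell_ids)
  qc$lib_size <- ls$factors
  fx <- filter_extreme_bins(ls$norm, cm1$bins, quantile_q, qc)
  qc <- fx$qc
  gsrc <- if (gini_on == "raw") cm1$counts[, fx$keep, drop = FALSE] else
    fx$norm
  gf <- filter_cells_by_gini(gsrc, cm1$cell_ids, gini_max, qc)
  qc <- gf$qc
  norm <- fx$norm[gf$keep, , drop = FALSE]
  mn <- median_normalize(norm, fx$bins, gc_width, map_width, qc)
  qc <- mn$qc
  lrc <- to_lrc(mn$norm, eps)
  if (ncol(lrc) < 2L) stop("fewer than 2 bins remain after preprocessing")
  # map retained bins back to original column indices of the input matrix
  bin_index <- match(bin_labels(fx$bins), orig_labels)
  structure(list(lrc = lrc,
                 cell_ids = cm1$cell_ids[gf$keep],
                 bins = fx$bins,
                 bin_index = bin_index,
                 cell_index = which(gf$keep),
                 gini = gf$gini,
                 qc = qc),
            class = "lrc_matrix")
}

#' @export
print.lrc_matrix <- function(x, ...) {
  cat(sprintf("lrc_matrix: %d cells x %d bins (LRC range %.2f..%.2f)\n",
              nrow(x$lrc), ncol(x$lrc), min(x$lrc), max(x$lrc)))
  print(x$qc)
  invisible(x)
}

#' Read/write an LRC matrix as TSV
#'
#' Same dialect as [write_count_matrix()] with real-valued entries; values
#' are written with enough digits for lossless round-trips at >= 6
#' significant digits.
#'
#' @param x an `lrc_matrix` (or any list with `lrc`, `cell_ids`).
#' @param path TSV path.
#' @export
write_lrc_matrix <- function(x, path) {
  df <- data.frame(cell_id = x$cell_ids,
                   signif(x$lrc, 10), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("cell_id", bin_labels(x$bins))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_lrc_matrix
#' @param path TSV path.
#' @return `read_lrc_matrix` returns a list with `lrc` (numeric matrix),
#'   `cell_ids` and `bin_labels`.
#' @export
read_lrc_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "cell_id") stop("first column must be 'cell_id'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$cell_id
  list(lrc = m, cell_ids = df$cell_id, bin_labels = colnames(m))
}
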