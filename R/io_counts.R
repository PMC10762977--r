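#' Per-cell bin read-count matrix
#'
#' Container for raw read counts of N cells in M genomic bins, tied to the
#' [bin_grid()] that defines the bins. Counts are non-negative integers;
#' cell ids are unique.
#'
#' @param counts integer matrix, N cells x M bins.
#' @param cell_ids character vector of N unique cell identifiers.
#' @param bins the [bin_grid()] the columns refer to (M rows).
#' @return An object of class `"count_matrix"`: a list with elements
#'   `counts` (matrix with cell ids as rownames and bin labels as colnames),
#'   `cell_ids` and `bins`.
#' @export
count_matrix <- function(counts, cell_ids, bins) {
  counts <- as.matrix(counts)
  if (!inherits(bins, "bin_grid")) stop("bins must be a bin_grid")
  if (nrow(counts) != length(cell_ids))
    stop("cell_ids length (", length(cell_ids),
         ") does not match number of rows (", nrow(counts), ")")
  if (ncol(counts) != nrow(bins))
    stop("count matrix has ", ncol(counts), " columns but bin grid has ",
         nrow(bins), " bins")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell id: ", cell_ids[anyDuplicated(cell_ids)])
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("negative count at cell '", cell_ids[bad[1L, 1L]], "', bin ",
         bad[1L, 2L])
  if (any(!is.finite(counts))) stop("non-finite entries in count matrix")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cell_ids, bin_labels(bins))
  structure(list(counts = counts, cell_ids = as.character(cell_ids),
                 bins = bins),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d bins, total %.3g reads\n",
              nrow(x$counts), ncol(x$counts), sum(as.numeric(x$counts))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read/write a count matrix as TSV
#'
#' Dialect: one header row of bin labels `chrom:start-end`, first column
#' `cell_id`, integer counts. The bin grid is stored separately
#' ([write_bin_grid()]); on load the header labels are checked against it
#' column by column.
#'
#' @param cm a [count_matrix()].
#' @param path TSV path for the counts.
#' @param bingrid_path TSV path of the matching bin table.
#' @return `load_count_matrix` returns a validated [count_matrix()].
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(cell_id = cm$cell_ids, cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_count_matrix
#' @export
load_count_matrix <- function(path, bingrid_path) {
  bins <- read_bin_grid(bingrid_path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "cell_id") stop("first column must be 'cell_id'")
  labs <- names(df)[-1L]
  want <- bin_labels(bins)
  if (length(labs) != length(want))
    stop("count table has ", length(labs), " bins but bin table declares ",
         length(want))
  mism <- which(labs != want)
  if (length(mism) > 0L)
    stop("bin label mismatch at column ", mism[1L], ": '", labs[mism[1L]],
         "' vs '", want[mism[1L]], "'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (any(m != round(m))) stop("counts must be integers")
  count_matrix(m, df$cell_id, bins)
}

#' Extract per-cell bin counts from BAM alignments
#'
#' Counts the alignments of each cell whose leftmost mapped position falls in
#' each bin (each read is assigned to exactly one bin). Two input layouts are
#' supported: one indexed BAM per cell, or a single barcoded merged BAM (as
#' produced by droplet platforms) from which cells are demultiplexed by a
#' barcode tag. Unmapped, secondary, supplementary and duplicate-flagged
#' records are excluded; no mapping-quality threshold is applied by default.
#' Cells with zero passing reads are retained (they are removed later by
#' quality control).
#'
#' Requires the Rsamtools package.
#'
#' @param alignment_paths character vector of indexed BAM paths (per-cell
#'   mode, one per cell) or a single merged BAM path (merged mode).
#' @param bingrid the [bin_grid()] to count in.
#' @param barcodes in merged mode, the non-empty character vector of cell
#'   barcodes to extract; reads whose tag value is not listed are dropped.
#' @param barcode_tag BAM tag holding the cell barcode (default `"CB"`).
#' @param cell_ids cell ids for per-cell mode; defaults to basenames.
#' @param min_mapq minimum mapping quality; `NA` (default) disables the
#'   filter.
#' @return A [count_matrix()].
#' @export
extract_counts_from_alignments <- function(alignment_paths, bingrid,
                                           barcodes = NULL,
                                           barcode_tag = "CB",
                                           cell_ids = NULL,
                                           min_mapq = NA) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("extract_counts_from_alignments requires the Rsamtools package")
  stopifnot(inherits(bingrid, "bin_grid"))
  merged <- !is.null(barcodes)
  if (merged && length(barcodes) == 0L)
    stop("merged mode requires a non-empty barcode list")
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  mapq <- if (is.na(min_mapq)) NA_integer_ else as.integer(min_mapq)
  scan1 <- function(path, with_tag) {
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path)))
      stop("missing index for ", path)
    param <- Rsamtools::ScanBamParam(
      flag = flag, what = c("rname", "pos"),
      tag = if (with_tag) barcode_tag else character(0),
      mapqFilter = mapq)
    Rsamtools::scanBam(path, param = param)[[1L]]
  }
  assign_bins <- function(rname, pos) {
    # leftmost aligned position, converted to 0-based, matched into the grid
    p0 <- pos - 1L
    idx <- rep(NA_integer_, length(p0))
    for (ch in unique(bingrid$chrom)) {
      rows <- which(bingrid$chrom == ch)
      sel <- which(as.character(rname) == ch)
      if (length(sel) == 0L) next
      j <- findInterval(p0[sel], bingrid$start[rows])
      ok <- j >= 1L & p0[sel] < bingrid$end[rows][pmax(j, 1L)]
      idx[sel[ok]] <- rows[j[ok]]
    }
    idx
  }
  M <- nrow(bingrid)
  if (merged) {
    rec <- scan1(alignment_paths[1L], with_tag = TRUE)
    bc <- rec$tag[[barcode_tag]]
    if (is.null(bc)) stop("tag '", barcode_tag, "' absent from ",
                          alignment_paths[1L])
    keep <- !is.na(bc) & bc %in% barcodes
    bin <- assign_bins(rec$rname[keep], rec$pos[keep])
    cellf <- factor(bc[keep], levels = barcodes)
    counts <- matrix(0L, length(barcodes), M)
    inb <- !is.na(bin)
    if (any(inb)) {
      tab <- table(cellf[inb], factor(bin[inb], levels = seq_len(M)))
      counts <- matrix(as.integer(tab), nrow = length(barcodes))
    }
    count_matrix(counts, barcodes, bingrid)
  } else {
    if (is.null(cell_ids)) cell_ids <- basename(alignment_paths)
    counts <- matrix(0L, length(alignment_paths), M)
    for (i in seq_along(alignment_paths)) {
      rec <- scan1(alignment_paths[i], with_tag = FALSE)
      bin <- assign_bins(rec$rname, rec$pos)
      bin <- bin[!is.na(bin)]
      if (length(bin) > 0L)
        counts[i, ] <- as.integer(tabulate(bin, nbins = M))
    }
    count_matrix(counts, cell_ids, bingrid)
  }
}

#' Write a segmentation as a BED-like table
#'
#' One row per segment: chrom, start (0-based), end (exclusive), segment
#' index. Segments never span chromosomes.
#'
#' @param seg a [segmentation()].
#' @param bingrid the [bin_grid()] the segmentation refers to.
#' @param path output path.
#' @export
write_segments <- function(seg, bingrid, path) {
  stopifnot(inherits(seg, "segmentation"))
  if (seg$M != nrow(bingrid))
    stop("segmentation covers ", seg$M, " bins but grid has ", nrow(bingrid))
  first <- cumsum(c(1L, seg$lengths[-length(seg$lengths)]))
  last <- cumsum(seg$lengths)
  df <- data.frame(chrom = bingrid$chrom[first],
                   start = bingrid$start[first],
                   end = bingrid$end[last],
                   segment = seq_along(seg$lengths) - 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(NULL)
}

#' @rdname write_segments
#' @return `read_segments` returns the BED-like `data.frame`.
#' @export
read_segments <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
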