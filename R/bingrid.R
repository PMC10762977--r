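#' Genomic bin grid
#'
#' Construct the table of consecutive, equal-sized genomic bins in which reads
#' are counted, together with the per-bin GC fraction and mappability tracks
#' used for quality filtering and bias correction. Coordinates are 0-based,
#' half-open (`start` inclusive, `end` exclusive); bins are sorted by
#' (chromosome, start), non-overlapping, and all non-terminal bins of a
#' chromosome have width `bin_size` (the last bin of a chromosome may be
#' shorter).
#'
#' @param chrom character vector of chromosome names, one per bin.
#' @param start,end integer vectors of 0-based half-open bin coordinates.
#' @param gc numeric vector of per-bin GC fractions in `[0, 1]`.
#' @param mappability numeric vector of per-bin mappability scores in `[0, 1]`.
#' @param bin_size the nominal bin width in bp.
#'
#' @return A `data.frame` of class `"bin_grid"` with columns `chrom`, `start`,
#'   `end`, `gc`, `mappability` and attribute `bin_size`.
#' @seealso [make_bin_grid()] to tile chromosomes, [read_bin_grid()] /
#'   [write_bin_grid()] for TSV interchange.
#' @export
bin_grid <- function(chrom, start, end, gc, mappability, bin_size) {
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stop("chrom/start/end must have equal length")
  if (length(gc) != n || length(mappability) != n)
    stop("gc and mappability tracks must have one value per bin")
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("bins must satisfy end > start")
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("gc fractions must lie in [0, 1]")
  if (any(mappability < 0 | mappability > 1, na.rm = TRUE))
    stop("mappability scores must lie in [0, 1]")
  bg <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   gc = as.numeric(gc), mappability = as.numeric(mappability),
                   stringsAsFactors = FALSE)
  ord <- order(factor(bg$chrom, levels = unique(bg$chrom)), bg$start)
  bg <- bg[ord, , drop = FALSE]
  rownames(bg) <- NULL
  # non-overlap + fixed width for non-terminal bins, per chromosome
  for (ch in unique(bg$chrom)) {
    b <- bg[bg$chrom == ch, , drop = FALSE]
    if (nrow(b) > 1L) {
      if (any(b$start[-1L] < b$end[-nrow(b)]))
        stop("overlapping bins on ", ch)
      w <- b$end - b$start
      if (any(w[-length(w)] != bin_size))
        stop("non-terminal bin on ", ch, " does not have width bin_size")
    }
  }
  attr(bg, "bin_size") <- as.integer(bin_size)
  class(bg) <- c("bin_grid", "data.frame")
  bg
}

#' Tile chromosomes into a bin grid
#'
#' Convenience constructor: tiles each chromosome with consecutive bins of
#' `bin_size` bp. GC and mappability default to bland values (0.45 / 1.0) and
#' are normally overwritten by real tracks or by the simulator.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 200 kb, the working resolution for
#'   ~0.02x single-cell whole-genome data).
#' @param gc,mappability either a single value recycled across bins or a
#'   vector with one value per bin.
#' @return A [bin_grid()] object.
#' @export
make_bin_grid <- function(chrom_lengths, bin_size = 200000L, gc = 0.45,
                          mappability = 1.0) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  starts <- lapply(chrom_lengths, function(len) seq(0L, len - 1L, by = bin_size))
  chrom <- rep(names(chrom_lengths), lengths(starts))
  start <- unlist(starts, use.names = FALSE)
  end <- pmin(start + bin_size, rep(unname(chrom_lengths), lengths(starts)))
  n <- length(start)
  bin_grid(chrom, start, end,
           gc = rep_len(gc, n), mappability = rep_len(mappability, n),
           bin_size = bin_size)
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d bins on %d chromosome(s), bin size %d bp\n",
              nrow(x), length(unique(x$chrom)), attr(x, "bin_size")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Bin labels of the form "chrom:start-end"
#'
#' @param bg a [bin_grid()].
#' @return character vector of unambiguous bin labels (0-based half-open).
#' @export
bin_labels <- function(bg) sprintf("%s:%d-%d", bg$chrom, bg$start, bg$end)

#' Chromosome boundary breakpoints
#'
#' Segments never span chromosomes, so these positions are forced breakpoints
#' during segmentation. The package breakpoint convention is used: a value
#' `b` counts the bins before the cut, so `b` is the number of bins on all
#' chromosomes up to and including the one ending there.
#'
#' @param bg a [bin_grid()].
#' @return integer vector (possibly empty) of boundary breakpoints.
#' @export
chrom_boundaries <- function(bg) {
  r <- rle(bg$chrom)
  idx <- cumsum(r$lengths)
  idx[-length(idx)]
}

#' Read/write a bin grid as TSV
#'
#' Plain TSV with columns chrom, start, end, gc, mappability, bin_size;
#' 0-based half-open coordinates.
#'
#' @param bg a [bin_grid()].
#' @param path TSV file path.
#' @return `read_bin_grid` returns a [bin_grid()]; `write_bin_grid` is called
#'   for its side effect.
#' @export
write_bin_grid <- function(bg, path) {
  stopifnot(inherits(bg, "bin_grid"))
  df <- as.data.frame(bg)
  df$bin_size <- attr(bg, "bin_size")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_bin_grid
#' @export
read_bin_grid <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc", "mappability", "bin_size")
  if (!all(need %in% names(df)))
    stop("bin table must have columns: ", paste(need, collapse = ", "))
  bin_grid(df$chrom, df$start, df$end, df$gc, df$mappability,
           bin_size = df$bin_size[1L])
}

#' hg19-scale chromosome lengths used by the bundled simulator
#'
#' Lengths (bp) of human chromosomes 1-3; together they tile into ~3450 bins
#' of 200 kb, the regime the pipeline is designed for.
#'
#' @return named integer vector of lengths.
#' @export
default_sim_chromosomes <- function() {
  c(chr1 = 249250621L, chr2 = 243199373L, chr3 = 198022430L)
}
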