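# Shared fixtures, built in code at test time.

# small bin grid: `nbins` bins of 200 kb on one or two chromosomes
test_grid <- function(nbins = 10, bin_size = 200000L, two_chrom = FALSE,
                      gc = 0.45, mappability = 1.0) {
  if (two_chrom) {
    half <- nbins %/% 2L
    make_bin_grid(c(chrA = half * bin_size,
                    chrB = (nbins - half) * bin_size),
                  bin_size, gc = gc, mappability = mappability)
  } else {
    make_bin_grid(c(chrA = nbins * bin_size), bin_size, gc = gc,
                  mappability = mappability)
  }
}

# count matrix with given integer matrix on a matching grid
test_counts <- function(m, bg = NULL) {
  m <- as.matrix(m)
  if (is.null(bg)) bg <- test_grid(ncol(m))
  count_matrix(m, sprintf("c%02d", seq_len(nrow(m))), bg)
}

# model-generated LRC for one cell: Gaussian segment data under the mixture
model_lrc <- function(seg_cn, seg_len, o, sigma) {
  unlist(mapply(function(c, L)
    stats::rnorm(L, state_mean(c, o), sigma), seg_cn, seg_len,
    SIMPLIFY = FALSE))
}

# minimal SAM text for alignment-extraction tests; reads is a data.frame
# with qname, flag, rname, pos (1-based) and optional barcode (CB tag)
write_test_sam <- function(path, reads, chrom_lengths = c(chrA = 2000000L)) {
  hd <- c("@HD\tVN:1.6\tSO:coordinate",
          sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), chrom_lengths))
  body <- character(0)
  if (nrow(reads) > 0) {
    reads <- reads[order(match(reads$rname, names(chrom_lengths)),
                         reads$pos), , drop = FALSE]
    body <- sprintf("%s\t%d\t%s\t%d\t60\t10M\t*\t0\t0\tACGTACGTAC\t**********",
                    reads$qname, reads$flag, reads$rname, reads$pos)
    if (!is.null(reads$barcode))
      body <- paste0(body, "\tCB:Z:", reads$barcode)
  }
  writeLines(c(hd, body), path)
  invisible(path)
}

# SAM -> sorted, indexed BAM (requires Rsamtools)
sam_to_bam <- function(sam_path) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = sub("\\.sam$", "", sam_path),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}
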