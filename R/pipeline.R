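#' Fit single-cell copy number profiles from bin read counts
#'
#' The full calling pipeline in one fitting function. The count matrix is
#' quality-filtered and normalized into log2 read counts
#' ([preprocess_counts()]); an autoencoder embeds each bin's cross-cell LRC
#' vector into a `latent_dim`-dimensional code ([train_bin_autoencoder()]);
#' circular binary segmentation along each latent dimension, per chromosome,
#' yields one cross-cell breakpoint set ([segment_latent()]); each cell's
#' segment LRC is then fit with the Gaussian mixture model over copy number
#' states by EM with a grid search over the baseline shift `o`
#' ([fit_cell_mixture()]); highly amplified segments are re-estimated
#' ([postprocess_amplified()]); and equal-copy-number neighbors are merged
#' into the final per-cell segment tables whose union of copy-number changes
#' forms the consensus breakpoints.
#'
#' @param cm a [count_matrix()].
#' @param latent_dim latent dimension d (default 1; 1-2 suffice to capture
#'   shared breakpoints).
#' @param epochs,lr,batch_size autoencoder training schedule (defaults 500,
#'   1e-4, 256).
#' @param plateau_window,plateau_tol,min_epochs optional loss-plateau early
#'   stop (disabled when `plateau_window = 0`).
#' @param alpha CBS per-split significance level (default 0.1).
#' @param n_permutations CBS permutations per split (default 1000).
#' @param max_cn maximum modeled copy number (default 10).
#' @param o_grid,tol,max_iter EM grid search and convergence controls, see
#'   [fit_cell_mixture()].
#' @param gc_low,gc_high,map_min,quantile_q,gini_max preprocessing
#'   thresholds, see [preprocess_counts()].
#' @param sel_window,bias_floor branch-selection controls, see
#'   [fit_cell_mixture()].
#' @param anchor_candidates,anchor_slack dataset-level ploidy anchoring, see
#'   [ploidy_anchor()].
#' @param normal_window a cell is treated as normal-like (kept at the
#'   diploid preference instead of the anchor) when some flat branch of its
#'   mixture has excess within this window of the best branch (default 5).
#' @param seed optional integer seed covering training, segmentation
#'   permutations, and any other randomness.
#' @param verbose print progress messages.
#' @return An object of class `"cna_fit"` with components `lrc` (the
#'   `lrc_matrix`), `model` (the autoencoder), `z` (latent matrix),
#'   `segmentation`, `cn` (cells x retained-bins integer copy numbers),
#'   `params` (per-cell data.frame: cell_id, o, sigma, loglik, acn, ploidy),
#'   `segments` (per-cell merged segment tables), `breakpoints` (consensus),
#'   `mixtures` (per-cell `cn_mixture` fits), and the call.
#' @seealso [simulate_cna_dataset()] to generate ground-truthed input,
#'   [evaluate_calls()] to score a fit.
#' @export
cna_fit <- function(cm, latent_dim = 1L, epochs = 500L, lr = 1e-4,
                    batch_size = 256L, plateau_window = 0L,
                    plateau_tol = 1e-4, min_epochs = 50L, alpha = 0.1,
                    n_permutations = 1000L, max_cn = 10L,
                    o_grid = seq(-2, 1, by = 0.05), tol = 1e-6,
                    max_iter = 200L, gc_low = 0.10, gc_high = 0.90,
                    map_min = 0.90, quantile_q = 0.01, gini_max = 0.3,
                    sel_window = 15, bias_floor = 0.04,
                    anchor_candidates = 2:5, anchor_slack = 2,
                    normal_window = 5, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is.null(seed)) set.seed(seed)
  say <- function(...) if (verbose) message(...)

  lrc <- preprocess_counts(cm, gc_low = gc_low, gc_high = gc_high,
                           map_min = map_min, quantile_q = quantile_q,
                           gini_max = gini_max)
  say(sprintf("preprocessed: %d cells x %d bins retained", nrow(lrc$lrc),
              ncol(lrc$lrc)))

  model <- train_bin_autoencoder(lrc, latent_dim = latent_dim,
                                 epochs = epochs, lr = lr,
                                 batch_size = batch_size,
                                 plateau_tol = plateau_tol,
                                 plateau_window = plateau_window,
                                 min_epochs = min_epochs)
  say(sprintf("autoencoder: %d epochs, final loss %.5g", model$epochs_run,
              model$loss_trace[length(model$loss_trace)]))
  z <- encode_bins(lrc, model)

  seg <- segment_latent(z, lrc$bins, alpha = alpha,
                        n_permutations = n_permutations)
  say(sprintf("segmentation: %d segments (%d breakpoints incl. chromosome bounds)",
              seg$K, length(seg$breakpoints)))

  N <- nrow(lrc$lrc)
  M <- ncol(lrc$lrc)
  cn <- matrix(0L, N, M, dimnames = list(lrc$cell_ids, NULL))
  mixtures <- vector("list", N)
  params <- data.frame(cell_id = lrc$cell_ids, o = NA_real_,
                       sigma = NA_real_, loglik = NA_real_, acn = NA_real_,
                       ploidy = NA_real_, modal_cn = NA_real_,
                       normal_like = NA, stringsAsFactors = FALSE)
  seg_tables <- vector("list", N)
  # pass 1: fit every cell with the diploid preference
  for (i in seq_len(N)) {
    mixtures[[i]] <- fit_cell_mixture(lrc$lrc[i, ], seg, max_cn = max_cn,
                                      o_grid = o_grid, tol = tol,
                                      max_iter = max_iter,
                                      sel_window = sel_window,
                                      bias_floor = bias_floor)
  }
  # dataset-level ploidy anchor from cells that are not normal-like
  normal_like <- vapply(mixtures, function(f)
    any(f$branches$flat &
          f$branches$excess <= min(f$branches$excess) + normal_window),
    logical(1))
  anchor <- ploidy_anchor(mixtures, normal_like,
                          candidates = anchor_candidates,
                          slack = anchor_slack)
  say(sprintf("ploidy anchor: %g (%d of %d cells normal-like)", anchor,
              sum(normal_like), N))
  # pass 2: re-select branches of tumor-like cells against the anchor
  for (i in seq_len(N)) {
    fit <- if (normal_like[i]) mixtures[[i]] else
      reselect_branch(mixtures[[i]], anchor)
    mixtures[[i]] <- fit
    seg_cn <- postprocess_amplified(fit$seg_states, lrc$lrc[i, ], fit$o,
                                    max_cn = max_cn, seg = seg)
    cn[i, ] <- expand_to_bins(seg_cn, seg)
    seg_tables[[i]] <- merge_equal_cn(seg_cn, seg, lrc$bins)
    params$o[i] <- fit$o
    params$sigma[i] <- fit$sigma
    params$loglik[i] <- fit$loglik
    params$acn[i] <- mean(cn[i, ])
    params$ploidy[i] <- fit$ploidy
    params$modal_cn[i] <- fit$modal_cn
    params$normal_like[i] <- normal_like[i]
  }
  names(seg_tables) <- names(mixtures) <- lrc$cell_ids

  bps <- consensus_breakpoints(cn, chrom_boundaries(lrc$bins))
  say(sprintf("consensus: %d breakpoints after equal-CN merging",
              length(bps)))

  structure(list(lrc = lrc, model = model, z = z, segmentation = seg,
                 cn = cn, params = params, segments = seg_tables,
                 breakpoints = bps, mixtures = mixtures, anchor = anchor,
                 max_cn = as.integer(max_cn), call = match.call()),
            class = "cna_fit")
}

#' @export
print.cna_fit <- function(x, ...) {
  cat("Single-cell CNA fit\n")
  cat(sprintf("  cells: %d (of %d input), bins: %d retained\n",
              nrow(x$cn), nrow(x$cn) + nrow(x$lrc$qc$removed_cells),
              ncol(x$cn)))
  cat(sprintf("  segments: %d, consensus breakpoints: %d\n",
              x$segmentation$K, length(x$breakpoints)))
  pl <- round(x$params$acn)
  tab <- table(pl)
  cat(sprintf("  ploidy (rounded ACN): %s\n",
              paste(sprintf("%s: %d cells", names(tab), tab),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.cna_fit <- function(object, ...) {
  s <- list(
    n_cells = nrow(object$cn), n_bins = ncol(object$cn),
    n_segments = object$segmentation$K,
    n_breakpoints = length(object$breakpoints),
    removed_bins = nrow(object$lrc$qc$removed_bins),
    removed_cells = nrow(object$lrc$qc$removed_cells),
    o = stats::quantile(object$params$o, c(0, 0.25, 0.5, 0.75, 1)),
    sigma = stats::quantile(object$params$sigma, c(0, 0.5, 1)),
    acn = stats::quantile(object$params$acn, c(0, 0.25, 0.5, 0.75, 1)),
    ae_loss = object$model$loss_trace[length(object$model$loss_trace)],
    ae_epochs = object$model$epochs_run)
  class(s) <- "summary.cna_fit"
  s
}

#' @export
print.summary.cna_fit <- function(x, ...) {
  cat("Single-cell CNA fit summary\n")
  cat(sprintf("  %d cells x %d bins (%d bins, %d cells removed by QC)\n",
              x$n_cells, x$n_bins, x$removed_bins, x$removed_cells))
  cat(sprintf("  %d segments; %d consensus breakpoints\n", x$n_segments,
              x$n_breakpoints))
  cat(sprintf("  autoencoder: %d epochs, final reconstruction loss %.5g\n",
              x$ae_epochs, x$ae_loss))
  cat("  baseline shift o quartiles: ",
      paste(sprintf("%.3f", x$o[2:4]), collapse = " / "), "\n", sep = "")
  cat("  ACN quartiles:              ",
      paste(sprintf("%.3f", x$acn[2:4]), collapse = " / "), "\n", sep = "")
  cat(sprintf("  sigma median: %.4f\n", x$sigma[2L]))
  invisible(x)
}

#' @export
coef.cna_fit <- function(object, ...) {
  m <- as.matrix(object$params[, c("o", "sigma", "loglik", "acn", "ploidy")])
  rownames(m) <- object$params$cell_id
  m
}

#' @export
fitted.cna_fit <- function(object, ...) {
  # expected LRC per bin: mu of the assigned state under each cell's fit
  o <- object$params$o
  f <- state_mean(object$cn, rep(o, ncol(object$cn)))
  dimnames(f) <- dimnames(object$cn)
  f
}

#' @export
residuals.cna_fit <- function(object, ...) {
  object$lrc$lrc - fitted(object)
}

#' @importFrom stats simulate
#' @export
simulate.cna_fit <- function(object, nsim = 1, seed = NULL, ...) {
  # draws LRC matrices from the fitted per-cell mixtures (assigned states)
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sig <- object$params$sigma
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    e <- matrix(stats::rnorm(length(mu), 0, rep(sig, ncol(mu))), nrow(mu))
    out[[r]] <- mu + e
  }
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a CNA fit
#'
#' Two panels: the first latent dimension along the genome with the
#' consensus breakpoints, and the per-cell copy number heatmap (cells x
#' bins, capped at `max_cn` for display).
#'
#' @param x a [cna_fit()].
#' @param cap display cap for copy numbers (default `max_cn`).
#' @param ... ignored.
#' @export
plot.cna_fit <- function(x, cap = x$max_cn, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  M <- ncol(x$cn)
  graphics::plot(seq_len(M), x$z[1L, ], type = "p", pch = 16, cex = 0.3,
                 xlab = "", ylab = "latent z[1]", main = "latent sequence")
  graphics::abline(v = x$breakpoints + 0.5, col = "red", lwd = 0.5)
  bounds <- chrom_boundaries(x$lrc$bins)
  graphics::abline(v = bounds + 0.5, col = "grey40", lty = 2)
  cnview <- pmin(x$cn, cap)
  graphics::image(seq_len(M), seq_len(nrow(cnview)), t(cnview),
                  col = grDevices::hcl.colors(cap + 1L, "RdBu", rev = TRUE),
                  xlab = "bin", ylab = "cell", main = "copy number",
                  useRaster = TRUE)
  invisible(x)
}
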