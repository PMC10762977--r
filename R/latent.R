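#' Train a bin autoencoder on an LRC matrix
#'
#' Learns a `latent_dim`-dimensional representation of each genomic bin from
#' its cross-cell LRC vector. The sample unit is the bin: each column of the
#' N x M LRC matrix is a feature vector of length N. The encoder consists of
#' three fully-connected hidden layers (256, 128, 64 neurons) followed by a
#' linear latent code; the decoder mirrors the encoder. Hidden layers use a
#' leaky-ReLU nonlinearity and the reconstruction head is linear, so code and
#' reconstruction remain unbounded like LRC itself. The network minimizes the
#' reconstruction loss
#' \deqn{L(y, \hat y) = \frac{1}{2N} \lVert y - \hat y \rVert_2^2}
#' averaged over each mini-batch, using Adam at the configured learning rate.
#' Bins are reshuffled every epoch with R's RNG, so training is reproducible
#' under `set.seed()`; the final partial batch is kept.
#'
#' An optional loss-plateau stop ends training early once the epoch-mean loss
#' has improved by less than a relative `plateau_tol` over the last
#' `plateau_window` epochs (disabled by default: `plateau_window = 0`).
#'
#' @param X an `lrc_matrix` from [preprocess_counts()], or a bare numeric
#'   matrix (cells x bins).
#' @param latent_dim dimension d of the latent code (default 1).
#' @param hidden hidden layer widths (default `c(256, 128, 64)`).
#' @param epochs maximum training epochs (default 500).
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size mini-batch size in bins (default 256).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   initialization and shuffling are reproducible.
#' @param plateau_tol,plateau_window,min_epochs loss-plateau stopping rule.
#' @return An object of class `"bin_autoencoder"`: list with `weights`,
#'   `biases`, `loss_trace` (per-epoch mean loss), `epochs_run`, `n_cells`,
#'   `latent_dim`, and the configuration.
#' @export
train_bin_autoencoder <- function(X, latent_dim = 1L,
                                  hidden = c(256L, 128L, 64L),
                                  epochs = 500L, lr = 1e-4,
                                  batch_size = 256L, seed = NULL,
                                  plateau_tol = 1e-4, plateau_window = 0L,
                                  min_epochs = 50L) {
  mat <- if (inherits(X, "lrc_matrix")) X$lrc else as.matrix(X)
  if (nrow(mat) < 2L) stop("need at least 2 cells")
  stopifnot(latent_dim >= 1L, epochs >= 1L, lr > 0)
  if (!is.null(seed)) set.seed(seed)
  fit <- .ae_train_cpp(mat, as.integer(latent_dim), as.integer(hidden),
                       as.integer(epochs), lr, as.integer(batch_size),
                       plateau_tol, as.integer(plateau_window),
                       as.integer(min_epochs))
  structure(list(weights = fit$weights, biases = fit$biases,
                 loss_trace = fit$loss_trace, epochs_run = fit$epochs_run,
                 latent_layer = fit$latent_layer,
                 n_cells = nrow(mat), latent_dim = as.integer(latent_dim),
                 hidden = as.integer(hidden), lr = lr,
                 batch_size = as.integer(batch_size)),
            class = "bin_autoencoder")
}

#' @export
print.bin_autoencoder <- function(x, ...) {
  cat(sprintf(paste0("bin_autoencoder: %d -> %s -> %d (leaky ReLU, linear",
                     " code/output)\n"),
              x$n_cells, paste(x$hidden, collapse = " -> "), x$latent_dim))
  cat(sprintf("  trained %d epochs, final loss %.6g\n", x$epochs_run,
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Encode bins into the latent space
#'
#' Deterministically maps each bin's cross-cell LRC vector through the
#' trained encoder.
#'
#' @param X an `lrc_matrix` or numeric matrix with the same number of cells
#'   the model was trained on.
#' @param model a [train_bin_autoencoder()] fit.
#' @return numeric matrix `z`, `latent_dim` x M (one column per bin).
#' @export
encode_bins <- function(X, model) {
  stopifnot(inherits(model, "bin_autoencoder"))
  mat <- if (inherits(X, "lrc_matrix")) X$lrc else as.matrix(X)
  if (nrow(mat) != model$n_cells)
    stop("model was trained on ", model$n_cells, " cells but input has ",
         nrow(mat))
  out <- .ae_forward_cpp(mat, model$weights, model$biases,
                         model$latent_layer)
  out$z
}

#' Reconstruct LRC from the trained autoencoder
#'
#' @inheritParams encode_bins
#' @return numeric matrix of reconstructions, same shape as the input LRC.
#' @export
reconstruct_bins <- function(X, model) {
  stopifnot(inherits(model, "bin_autoencoder"))
  mat <- if (inherits(X, "lrc_matrix")) X$lrc else as.matrix(X)
  out <- .ae_forward_cpp(mat, model$weights, model$biases,
                         model$latent_layer)
  out$reconstruction
}

#' Reconstruction loss of the autoencoder
#'
#' Per-sample loss `(1 / 2N) * sum((y - yhat)^2)`, averaged over samples when
#' matrices are given.
#'
#' @param y,yhat numeric vectors (one bin) or matrices (cells x bins).
#' @return mean reconstruction loss.
#' @export
reconstruction_loss <- function(y, yhat) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  stopifnot(identical(dim(y), dim(yhat)))
  n_feat <- nrow(y)
  mean(colSums((y - yhat)^2) / (2 * n_feat))
}

#' Save/load a trained bin autoencoder as plain text (JSON-free TSV bundle)
#'
#' Weights are serialized with full precision into a single RDS-free text
#' file so model state can be archived alongside results.
#'
#' @param model a [train_bin_autoencoder()] fit.
#' @param path file path.
#' @export
write_autoencoder <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(model$n_cells, model$latent_dim, model$latent_layer,
            length(model$hidden), model$hidden)
  writeLines(paste(meta, collapse = "\t"), con)
  for (l in seq_along(model$weights)) {
    w <- model$weights[[l]]
    writeLines(paste(dim(w), collapse = "\t"), con)
    writeLines(paste(sprintf("%.17g", w), collapse = "\t"), con)
    writeLines(paste(sprintf("%.17g", model$biases[[l]]), collapse = "\t"),
               con)
  }
  writeLines(paste(sprintf("%.17g", model$loss_trace), collapse = "\t"), con)
  invisible(NULL)
}

#' @rdname write_autoencoder
#' @export
read_autoencoder <- function(path) {
  ln <- readLines(path)
  meta <- as.integer(strsplit(ln[1L], "\t")[[1L]])
  n_layers <- 2L * meta[4L] + 2L
  weights <- vector("list", n_layers)
  biases <- vector("list", n_layers)
  row <- 2L
  for (l in seq_len(n_layers)) {
    d <- as.integer(strsplit(ln[row], "\t")[[1L]])
    weights[[l]] <- matrix(as.numeric(strsplit(ln[row + 1L], "\t")[[1L]]),
                           d[1L], d[2L])
    biases[[l]] <- as.numeric(strsplit(ln[row + 2L], "\t")[[1L]])
    row <- row + 3L
  }
  structure(list(weights = weights, biases = biases,
                 loss_trace = as.numeric(strsplit(ln[row], "\t")[[1L]]),
                 epochs_run = length(strsplit(ln[row], "\t")[[1L]]),
                 latent_layer = meta[3L], n_cells = meta[1L],
                 latent_dim = meta[2L],
                 hidden = meta[5L:(4L + meta[4L])],
                 lr = NA_real_, batch_size = NA_integer_),
            class = "bin_autoencoder")
}
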