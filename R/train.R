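#' Training configuration
#'
#' Defaults follow the method's stated settings: mini-batches of 2000 spots,
#' 100 epochs of plain SGD, learning rate 0.2 dropping to 0.1 for the last 20
#' epochs, and quantile parameters tau_e = tau_p = 0.07 for both adjacency
#' views.
#'
#' @param batch_size mini-batch size n (>= 2).
#' @param epochs number of training epochs.
#' @param lr_initial,lr_final step sizes before/after the drop.
#' @param lr_drop_epoch first epoch trained at `lr_final`; default
#'   `epochs - 20 + 1` so exactly the last 20 epochs use the final rate.
#' @param tau_e,tau_p adjacency nonzero fractions.
#' @param seed integer seed governing initialisation and batch shuffling.
#' @param precision `"double"` or `"single"` working precision for the
#'   adjacency underflow rule.
#' @param variant `"full"`, `"exp_only"` or `"spa_only"`.
#' @param normalization adjacency mode: `"none"` (the literal smoothing
#'   operator) or `"sym_degree"` (degree-normalized stability preset).
#' @param output_activation final decoder activation, `"elu"` or `"linear"`.
#' @param momentum SGD momentum (default 0, plain SGD).
#' @param shuffle reshuffle batch composition each epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 2000L, epochs = 100L,
                         lr_initial = 0.2, lr_final = 0.1,
                         lr_drop_epoch = max(1L, epochs - 20L + 1L),
                         tau_e = 0.07, tau_p = 0.07, seed = 1L,
                         precision = c("double", "single"),
                         variant = c("full", "exp_only", "spa_only"),
                         normalization = c("none", "sym_degree"),
                         output_activation = c("elu", "linear"),
                         momentum = 0, shuffle = TRUE) {
  precision <- match.arg(precision)
  variant <- match.arg(variant)
  normalization <- match.arg(normalization)
  output_activation <- match.arg(output_activation)
  stopifnot(batch_size >= 2, epochs >= 1,
            lr_final > 0, lr_final <= lr_initial,
            lr_drop_epoch >= 1, lr_drop_epoch <= epochs + 1L,
            tau_e > 0, tau_e < 1, tau_p > 0, tau_p < 1,
            momentum >= 0, momentum < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_initial = lr_initial, lr_final = lr_final,
                 lr_drop_epoch = as.integer(lr_drop_epoch),
                 tau_e = tau_e, tau_p = tau_p, seed = as.integer(seed),
                 precision = precision, variant = variant,
                 normalization = normalization,
                 output_activation = output_activation,
                 momentum = momentum, shuffle = shuffle),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf(paste0("<train_config> n = %d, epochs = %d, lr %.3g -> %.3g ",
                     "(from epoch %d), tau = (%.3g, %.3g), variant = %s, ",
                     "normalization = %s, seed = %d\n"),
              x$batch_size, x$epochs, x$lr_initial, x$lr_final,
              x$lr_drop_epoch, x$tau_e, x$tau_p, x$variant,
              x$normalization, x$seed))
  invisible(x)
}

#' Learning rate at an epoch
#'
#' Step schedule: `lr_initial` for epochs before `lr_drop_epoch`, `lr_final`
#' from `lr_drop_epoch` onward (with defaults, 0.2 for epochs 1-80 and 0.1
#' for the last 20 epochs of 100).
#'
#' @param epoch epoch index in `1..cfg$epochs`.
#' @param cfg a [train_config()].
#' @return Positive step size.
#' @export
lr_at <- function(epoch, cfg) {
  if (epoch < 1 || epoch > cfg$epochs) stop("epoch out of range")
  ifelse(epoch >= cfg$lr_drop_epoch, cfg$lr_final, cfg$lr_initial)
}

#' Split spot indices into mini-batches
#'
#' Produces `ceiling(N / n)` disjoint batches covering `1..N` exactly once
#' (the last may be smaller). A trailing batch of size 1 is merged into the
#' previous batch because a graph needs at least 2 spots; the pre-merge batch
#' count is kept in the `"n_pre_merge"` attribute. With `shuffle = TRUE`
#' indices are permuted first, using `seed` if given, otherwise the current
#' RNG stream.
#'
#' @param N total number of spots (>= 2).
#' @param n batch size (>= 2).
#' @param seed optional integer seed for the permutation.
#' @param shuffle permute indices before splitting.
#' @return List of integer index vectors.
#' @export
make_batches <- function(N, n, seed = NULL, shuffle = TRUE) {
  if (N < 2) stop("need at least 2 spots")
  if (n < 2) stop("batch size must be >= 2")
  idx <- seq_len(N)
  if (shuffle) {
    if (!is.null(seed)) set.seed(seed)
    idx <- sample(idx)
  }
  k <- ceiling(N / n)
  batches <- split(idx, ceiling(seq_len(N) / n))
  names(batches) <- NULL
  if (k > 1L && length(batches[[k]]) == 1L) {
    batches[[k - 1L]] <- c(batches[[k - 1L]], batches[[k]])
    batches[[k]] <- NULL
  }
  attr(batches, "n_pre_merge") <- as.integer(k)
  batches
}

# Flush subnormal-range kernel entries to zero for compute. Entries in
# (5e-324, 1e-300) contribute < 1e-290 relative to any matrix product but make
# BLAS hit denormal traps, slowing sparse products by an order of magnitude.
.flush_tiny <- function(W, eps = 1e-300) {
  if (inherits(W, "sparseMatrix")) {
    W@x[W@x < eps] <- 0
    Matrix::drop0(W)
  } else {
    W[W > 0 & W < eps] <- 0
    W
  }
}

# build + optionally degree-normalize the graph for one batch
.batch_graph <- function(X, P, members, cfg) {
  g <- make_batch_graph(X[members, , drop = FALSE], P[members, , drop = FALSE],
                        tau_e = cfg$tau_e, tau_p = cfg$tau_p,
                        precision = cfg$precision, member_indices = members)
  g$W_e <- .flush_tiny(g$W_e)
  g$W_p <- .flush_tiny(g$W_p)
  if (cfg$normalization != "none") {
    g$W_e <- normalize_adjacency(g$W_e, cfg$normalization)
    g$W_p <- normalize_adjacency(g$W_p, cfg$normalization)
  }
  g
}

#' Fit the symmetric graph convolutional auto-encoder
#'
#' Mini-batch SGD: each epoch the spots are split into `ceiling(N/n)` batches
#' (reshuffled per epoch by default); for each batch the two Gaussian-kernel
#' adjacencies are built with quantile-calibrated bandwidths, the tied-weight
#' encoder/decoder is run forward, and the projection matrices take one SGD
#' step on the mean-squared reconstruction error of the PCs. The recorded
#' per-batch loss is the Frobenius norm of the reconstruction residual. The
#' whole trajectory is reproducible from `cfg$seed`.
#'
#' @param pcs a [pc_matrix()] (or plain spot x D matrix).
#' @param coords a [spot_coordinates()] (or plain spot x 2 matrix),
#'   row-aligned with `pcs`.
#' @param cfg a [train_config()].
#' @return An object of class `sgcae_fit` with elements `params`
#'   (`model_params`), `history` (data.frame: epoch, lr, n_batches,
#'   mean_loss, mean_mse) and `config`.
#' @export
fit_sgcae <- function(pcs, coords, cfg = train_config()) {
  X <- if (inherits(pcs, "pc_matrix")) pcs$scores else as.matrix(pcs)
  P <- if (inherits(coords, "spot_coordinates")) coords$positions else as.matrix(coords)
  if (nrow(X) != nrow(P)) stop("pcs and coords must be row-aligned")
  N <- nrow(X); D <- ncol(X)

  set.seed(cfg$seed)
  params <- .init_params_rng(D, cfg$variant)
  vel <- lapply(params[c("B1", "B2")], function(b) if (is.null(b)) NULL else b * 0)

  hist <- data.frame(epoch = integer(), lr = double(), n_batches = integer(),
                     mean_loss = double(), mean_mse = double())
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at(epoch, cfg)
    batches <- make_batches(N, cfg$batch_size, shuffle = cfg$shuffle)
    losses <- mses <- double(length(batches))
    for (b in seq_along(batches)) {
      members <- batches[[b]]
      g <- .batch_graph(X, P, members, cfg)
      fb <- .forward_backward(X[members, , drop = FALSE], g, params,
                              output = cfg$output_activation)
      if (!is.finite(fb$loss_mse)) {
        stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, b))
      }
      for (nm in names(fb$grads)) {
        if (cfg$momentum > 0) {
          vel[[nm]] <- cfg$momentum * vel[[nm]] - lr * fb$grads[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        } else {
          params[[nm]] <- params[[nm]] - lr * fb$grads[[nm]]
        }
      }
      losses[b] <- fb$loss_fro
      mses[b] <- fb$loss_mse
      # memory-profiling hook: collect at batch boundaries so the gc
      # high-water mark reflects a single batch's transient allocations
      if (isTRUE(getOption("sgcae.gc_per_batch"))) gc(verbose = FALSE)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   n_batches = length(batches),
                                   mean_loss = mean(losses),
                                   mean_mse = mean(mses)))
  }
  structure(list(params = params, history = hist, config = cfg,
                 D = D, N = N),
            class = "sgcae_fit")
}

#' @export
print.sgcae_fit <- function(x, ...) {
  cat(sprintf("<sgcae_fit> %d spots, D = %d, %d epochs; final mean loss %.4g\n",
              x$N, x$D, nrow(x$history), utils::tail(x$history$mean_loss, 1)))
  invisible(x)
}

#' Extract latent embeddings for all spots
#'
#' Inference pass: spots are processed in deterministic sequential batches
#' (no shuffling) of the configured size; each batch gets its own adjacency
#' pair and is encoded with the trained parameters, and rows are reassembled
#' in dataset order. Repeated calls are bit-identical. Because the graph is
#' built per batch, an individual spot's embedding depends (weakly) on its
#' batch's composition; sequential batching fixes that composition.
#'
#' @param pcs a [pc_matrix()] or spot x D matrix.
#' @param coords a [spot_coordinates()] or spot x 2 matrix.
#' @param params trained `model_params` (or an `sgcae_fit`).
#' @param cfg a [train_config()]; batch size, tau, precision and
#'   normalization are honoured.
#' @return An [embedding_matrix()].
#' @export
extract_embeddings <- function(pcs, coords, params, cfg = train_config()) {
  if (inherits(params, "sgcae_fit")) {
    cfg <- params$config
    params <- params$params
  }
  X <- if (inherits(pcs, "pc_matrix")) pcs$scores else as.matrix(pcs)
  P <- if (inherits(coords, "spot_coordinates")) coords$positions else as.matrix(coords)
  ids <- if (inherits(pcs, "pc_matrix")) pcs$spot_ids else rownames(X)
  N <- nrow(X)
  E <- matrix(NA_real_, N, params$D)
  batches <- make_batches(N, cfg$batch_size, shuffle = FALSE)
  for (members in batches) {
    g <- .batch_graph(X, P, members, cfg)
    E[members, ] <- encode(X[members, , drop = FALSE], g, params)
  }
  embedding_matrix(E, spot_ids = ids)
}
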