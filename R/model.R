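#' Exponential linear unit
#'
#' `elu(x) = x` for `x > 0` and `expm1(x)` otherwise; the activation used in
#' every layer of the auto-encoder.
#'
#' @param x numeric vector or matrix.
#' @return Same shape as `x`.
#' @keywords internal
elu <- function(x) {
  neg <- x <= 0
  x[neg] <- expm1(x[neg])
  x
}

# derivative of ELU given the *pre-activation* a: 1 where a > 0, exp(a) else
elu_grad <- function(a) {
  g <- a
  pos <- a > 0
  g[pos] <- 1
  g[!pos] <- exp(a[!pos])
  g
}

#' Initialise auto-encoder parameters
#'
#' Two trainable D x D projection matrices: `B1` for the expression-smoothing
#' layer and `B2` for the spatial-smoothing layer. The decoder reuses their
#' transposes, so the full model carries exactly `2 * D^2` trainable scalars;
#' single-view variants carry `D^2`. Entries are drawn uniformly from
#' `±sqrt(1/D)` (fan-in scaled).
#'
#' @param D embedding dimension (default 50).
#' @param variant `"full"`, `"exp_only"` (expression layer only) or
#'   `"spa_only"` (spatial layer only).
#' @param seed integer seed; if `NULL` the current RNG stream is used.
#' @return An object of class `model_params` with fields `B1` and/or `B2`.
#' @export
init_params <- function(D = 50L, variant = c("full", "exp_only", "spa_only"),
                        seed = NULL) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  .init_params_rng(D, variant)
}

# draws from the current RNG stream (fit() manages seeding around this)
.init_params_rng <- function(D, variant) {
  if (D < 1) stop("D must be >= 1")
  r <- sqrt(1 / D)
  draw <- function() matrix(stats::runif(D * D, -r, r), D, D)
  p <- list(D = as.integer(D), variant = variant)
  if (variant %in% c("full", "exp_only")) p$B1 <- draw()
  if (variant %in% c("full", "spa_only")) p$B2 <- draw()
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> D = %d, variant = %s, %d trainable scalars\n",
              x$D, x$variant, n_trainable(x)))
  invisible(x)
}

#' Number of trainable scalars in a parameter set
#'
#' @param params a `model_params` object.
#' @return Integer count (`2 D^2` for the full tied-weight model, `D^2` for
#'   single-view variants; the decoder adds none).
#' @export
n_trainable <- function(params) {
  sum(vapply(params[c("B1", "B2")], function(b) if (is.null(b)) 0L else length(b),
             integer(1)))
}

# encoder/decoder layer lists for a variant: each element (W-name, B-name)
.layer_plan <- function(variant) {
  switch(variant,
         full     = list(list(W = "W_e", B = "B1"), list(W = "W_p", B = "B2")),
         exp_only = list(list(W = "W_e", B = "B1")),
         spa_only = list(list(W = "W_p", B = "B2")))
}

.as_dense <- function(x) if (inherits(x, "Matrix")) as.matrix(x) else x

#' Encoder forward pass
#'
#' Two Laplacian-smoothing graph-convolution layers with ELU activation:
#' `H1 = elu(W_e X B1)` aggregates over gene-expression similarity, then
#' `H2 = elu(W_p H1 B2)` aggregates over spatial proximity. Single-view
#' variants apply only their one layer.
#'
#' @param X n x D matrix of PC scores for the batch, row-aligned with the
#'   graph's members.
#' @param graph a `minibatch_graph` (optionally degree-normalized adjacencies).
#' @param params a `model_params` object.
#' @return n x D embedding matrix `H2`.
#' @export
encode <- function(X, graph, params) {
  X <- as.matrix(X)
  if (ncol(X) != params$D) stop("dimension mismatch: ncol(X) != params$D")
  if (nrow(X) != nrow(graph$W_e %||% graph$W_p)) {
    stop("dimension mismatch: X rows != graph size")
  }
  H <- X
  for (ly in .layer_plan(params$variant)) {
    H <- elu(.as_dense(graph[[ly$W]] %*% H %*% params[[ly$B]]))
  }
  H
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decoder forward pass
#'
#' Mirrors the encoder with Laplacian sharpening and tied weights: each layer
#' applies `elu((3I - W) H t(B))` in reverse layer order, reconstructing the
#' input PCs. The final layer's activation is ELU by default; `output =
#' "linear"` leaves it linear (PC targets can fall below ELU's lower bound of
#' -1).
#'
#' @param H2 n x D encoder output.
#' @param graph a `minibatch_graph`.
#' @param params a `model_params` object.
#' @param output `"elu"` or `"linear"` final-layer activation.
#' @return n x D reconstructed input.
#' @export
decode <- function(H2, graph, params, output = c("elu", "linear")) {
  output <- match.arg(output)
  H <- as.matrix(H2)
  if (ncol(H) != params$D) stop("dimension mismatch: ncol(H2) != params$D")
  plan <- rev(.layer_plan(params$variant))
  for (i in seq_along(plan)) {
    ly <- plan[[i]]
    A <- .as_dense(sharpen_adjacency(graph[[ly$W]]) %*% H %*% t(params[[ly$B]]))
    H <- if (i == length(plan) && output == "linear") A else elu(A)
  }
  H
}

#' Reconstruction loss
#'
#' Frobenius norm `||X - Xhat||_2` (the reported training loss) or its
#' mean-squared-error monotone transform (`sum((X-Xhat)^2)/length`, the
#' quantity the optimizer actually descends for step-size stability).
#'
#' @param X,Xhat matrices of identical shape.
#' @param reduction `"frobenius"` or `"mse"`.
#' @return Nonnegative scalar.
#' @export
reconstruction_loss <- function(X, Xhat, reduction = c("frobenius", "mse")) {
  reduction <- match.arg(reduction)
  if (!identical(dim(X), dim(Xhat))) stop("shape mismatch")
  ss <- sum((X - Xhat)^2)
  if (reduction == "frobenius") sqrt(ss) else ss / length(X)
}

# Forward + backward through the tied-weight auto-encoder.
# Returns loss (frobenius and mse) and gradients of the MSE wrt B1/B2.
# Layout per layer k (encoder): A_k = W_k H_{k-1} B_k, H_k = elu(A_k);
# decoder step for layer k:     Ah  = (3I - W_k) Hh_k t(B_k), Hh_{k-1} = act(Ah).
# Tied weights mean each B_k accumulates gradient from both passes.
.forward_backward <- function(X, graph, params, output = "elu") {
  plan <- .layer_plan(params$variant)
  K <- length(plan)
  Ws <- lapply(plan, function(ly) graph[[ly$W]])
  Whs <- lapply(Ws, sharpen_adjacency)   # symmetric, reused in both passes
  Bs <- lapply(plan, function(ly) params[[ly$B]])

  # encoder
  H_in <- vector("list", K)   # layer inputs H_{k-1}
  V <- vector("list", K)      # V_k = W_k H_{k-1}
  A <- vector("list", K)      # pre-activations
  H <- X
  for (k in seq_len(K)) {
    H_in[[k]] <- H
    V[[k]] <- .as_dense(Ws[[k]] %*% H)
    A[[k]] <- V[[k]] %*% Bs[[k]]
    H <- elu(A[[k]])
  }
  H2 <- H

  # decoder (reverse layer order)
  U <- vector("list", K)      # U_k = (3I - W_k) Hh_k
  Ah <- vector("list", K)     # decoder pre-activations
  lin_last <- identical(output, "linear")
  Hh <- H2
  for (k in rev(seq_len(K))) {
    U[[k]] <- .as_dense(Whs[[k]] %*% Hh)
    Ah[[k]] <- U[[k]] %*% t(Bs[[k]])
    Hh <- if (k == 1L && lin_last) Ah[[k]] else elu(Ah[[k]])
  }
  Xhat <- Hh

  ss <- sum((X - Xhat)^2)
  loss_mse <- ss / length(X)
  loss_fro <- sqrt(ss)

  # backward
  dB <- lapply(Bs, function(b) matrix(0, nrow(b), ncol(b)))
  G <- 2 * (Xhat - X) / length(X)          # dL/dXhat (MSE)
  # decoder layers in forward-application reverse order: k = 1 .. K
  for (k in seq_len(K)) {
    Gk <- if (k == 1L && lin_last) G else G * elu_grad(Ah[[k]])
    dB[[k]] <- dB[[k]] + crossprod(Gk, U[[k]])             # d/dB from A = U t(B)
    G <- .as_dense(Whs[[k]] %*% Gk) %*% Bs[[k]]            # Wh symmetric
  }
  # G now holds dL/dH2 (encoder output); encoder layers k = K .. 1
  for (k in rev(seq_len(K))) {
    Gk <- G * elu_grad(A[[k]])
    dB[[k]] <- dB[[k]] + crossprod(V[[k]], Gk)             # d/dB from A = V B
    if (k > 1L) G <- .as_dense(Ws[[k]] %*% Gk) %*% t(Bs[[k]])  # W symmetric
  }

  names(dB) <- vapply(plan, `[[`, "", "B")
  list(loss_fro = loss_fro, loss_mse = loss_mse, Xhat = Xhat, H2 = H2,
       grads = dB)
}
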