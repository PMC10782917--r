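# Independent oracles used across test files.

# scalar triple-loop graph-convolution layer: act(W %*% X %*% B) elementwise
oracle_layer <- function(X, W, B, act = c("elu", "linear")) {
  act <- match.arg(act)
  W <- as.matrix(W)
  n <- nrow(X); p <- ncol(X); q <- ncol(B)
  out <- matrix(0, n, q)
  for (u in seq_len(n)) {
    for (j in seq_len(q)) {
      s <- 0
      for (v in seq_len(n)) {
        for (r in seq_len(p)) s <- s + W[u, v] * X[v, r] * B[r, j]
      }
      out[u, j] <- if (act == "elu" && s <= 0) exp(s) - 1 else s
    }
  }
  out
}

oracle_encode <- function(X, graph, params) {
  H <- X
  if (!is.null(params$B1)) H <- oracle_layer(H, graph$W_e, params$B1)
  if (!is.null(params$B2)) H <- oracle_layer(H, graph$W_p, params$B2)
  H
}

oracle_decode <- function(H2, graph, params, output = "elu") {
  n <- nrow(H2)
  layers <- list()
  if (!is.null(params$B2)) {
    layers <- c(layers, list(list(W = 3 * diag(n) - as.matrix(graph$W_p),
                                  B = t(params$B2))))
  }
  if (!is.null(params$B1)) {
    layers <- c(layers, list(list(W = 3 * diag(n) - as.matrix(graph$W_e),
                                  B = t(params$B1))))
  }
  H <- H2
  for (i in seq_along(layers)) {
    act <- if (i == length(layers)) output else "elu"
    H <- oracle_layer(H, layers[[i]]$W, layers[[i]]$B, act)
  }
  H
}

# full-batch gradient descent without any of the mini-batch machinery:
# one graph over all spots, one step per epoch using the gradient kernel
full_batch_gd <- function(X, P, cfg) {
  g <- make_batch_graph(X, P, tau_e = cfg$tau_e, tau_p = cfg$tau_p,
                        precision = cfg$precision)
  g$W_e <- normalize_adjacency(g$W_e, cfg$normalization)
  g$W_p <- normalize_adjacency(g$W_p, cfg$normalization)
  params <- init_params(ncol(X), cfg$variant, seed = cfg$seed)
  losses <- double(cfg$epochs)
  for (e in seq_len(cfg$epochs)) {
    lr <- lr_at(e, cfg)
    fb <- sgcae:::.forward_backward(X, g, params, output = cfg$output_activation)
    for (nm in names(fb$grads)) params[[nm]] <- params[[nm]] - lr * fb$grads[[nm]]
    losses[e] <- fb$loss_fro
  }
  list(params = params, losses = losses)
}

# finite-difference gradient of the MSE loss wrt one parameter matrix
numerical_grad <- function(X, graph, params, name, output = "elu", h = 1e-6) {
  B <- params[[name]]
  G <- B * 0
  for (i in seq_along(B)) {
    p1 <- params; p1[[name]][i] <- B[i] + h
    p2 <- params; p2[[name]][i] <- B[i] - h
    G[i] <- (sgcae:::.forward_backward(X, graph, p1, output)$loss_mse -
             sgcae:::.forward_backward(X, graph, p2, output)$loss_mse) / (2 * h)
  }
  G
}

# small aligned random dataset for model-level tests
toy_graph <- function(n, D, seed, tau = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * D), n, D)
  P <- matrix(runif(n * 2), n, 2)
  list(X = X, P = P, graph = make_batch_graph(X, P, tau_e = tau, tau_p = tau))
}
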