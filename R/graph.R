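#' Pairwise Euclidean distance matrix
#'
#' Dense n x n Euclidean distance matrix computed via the Gram-matrix
#' identity `d(u,v)^2 = |x_u|^2 + |x_v|^2 - 2 x_u . x_v`, which is much faster
#' than a double loop for the batch sizes used in training. The diagonal is
#' exactly zero and the result is exactly symmetric.
#'
#' @param points numeric n x d matrix (n >= 2).
#' @return n x n symmetric matrix of distances.
#' @export
pairwise_distance <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("batch too small")
  if (any(!is.finite(points))) stop("points must be finite")
  g <- tcrossprod(points)            # symmetric by construction (BLAS syrk)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0                    # clamp negative rounding noise
  d <- sqrt(d2)
  diag(d) <- 0
  d
}

#' Exponential underflow constant of the working precision
#'
#' The largest (i.e. least negative) integer m such that `exp(m)` evaluates to
#' exactly zero in the requested floating-point precision. Determined by a
#' runtime probe rather than hard-coded, so the exact-sparsity guarantee of
#' the adjacency construction holds on any compliant platform. Single
#' precision is emulated by rounding the double result through IEEE binary32.
#'
#' @param precision `"double"` (default) or `"single"`.
#' @return A negative integer m with `exp(m) == 0` and `exp(m + 1) > 0` in the
#'   stated precision.
#' @export
underflow_constant <- function(precision = c("double", "single")) {
  precision <- match.arg(precision)
  cached <- .sgcae_cache$m[[precision]]
  if (!is.null(cached)) return(cached)
  expf <- if (precision == "double") exp else function(x) float32(exp(x))
  m <- -1L
  while (expf(m) > 0) m <- m - 1L
  .sgcae_cache$m[[precision]] <- m
  m
}

.sgcae_cache <- new.env(parent = emptyenv())
.sgcae_cache$m <- list()

#' Round doubles through IEEE binary32
#'
#' @param x numeric vector.
#' @return `x` after a round trip through 4-byte floats.
#' @keywords internal
float32 <- function(x) {
  readBin(writeBin(as.double(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}

#' Quantile of the off-diagonal distance population
#'
#' Linear-interpolation (type 7) quantile of the pairwise distances of a
#' batch. By default the diagonal's structural zeros are excluded so that the
#' fraction of entries below the threshold matches `tau` exactly up to
#' interpolation granularity; `include_diagonal = TRUE` reproduces the
#' quantile over the full matrix.
#'
#' @param D n x n distance matrix.
#' @param tau fraction in (0, 1).
#' @param include_diagonal include the n diagonal zeros in the population.
#' @return The tau-quantile distance.
#' @export
quantile_threshold <- function(D, tau, include_diagonal = FALSE) {
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  n <- nrow(D)
  pop <- if (include_diagonal) as.vector(D) else as.vector(D)[-(0:(n - 1L) * (n + 1L) + 1L)]
  if (all(pop == 0)) stop("degenerate batch: all off-diagonal distances are zero")
  unname(stats::quantile(pop, probs = tau, type = 7, names = FALSE))
}

#' Gaussian-kernel bandwidth from the underflow rule
#'
#' Solves `-d_tau^2 / (2 l^2) = m` for the bandwidth l, so that a kernel entry
#' at distance `d_tau` has exponent m and therefore underflows to exactly zero
#' in the working precision, while closer pairs stay positive. This calibrates
#' every mini-batch to the same expected neighbour fraction.
#'
#' @param d_tau positive distance threshold (a quantile of the batch).
#' @param m negative integer from [underflow_constant()].
#' @return The bandwidth `l = sqrt(d_tau^2 / (-2 m))`.
#' @export
solve_bandwidth <- function(d_tau, m) {
  if (d_tau <= 0) stop("degenerate batch: nonpositive distance threshold")
  if (m >= 0) stop("m must be negative")
  sqrt(d_tau^2 / (-2 * m))
}

#' Gaussian-kernel adjacency matrix
#'
#' Builds `W[u,v] = exp(-D[u,v]^2 / (2 l^2))`. When the distance threshold
#' `d_max` that produced the bandwidth is supplied, the kernel is truncated at
#' it: entries at `D >= d_max` are exactly zero and entries strictly below are
#' guaranteed positive (values whose exponent underflows just inside the
#' boundary are clamped to the smallest positive double). The diagonal is
#' exactly 1. Matrices larger than `dense_limit` are stored sparse with
#' structural zeros dropped.
#'
#' @param D n x n distance matrix.
#' @param l positive bandwidth.
#' @param d_max optional truncation distance (the quantile threshold).
#' @param precision working precision; `"single"` rounds kernel values through
#'   binary32 before truncation.
#' @param dense_limit matrices with `n <= dense_limit` stay base-dense.
#' @return n x n symmetric adjacency matrix (base matrix or `Matrix::dgCMatrix`).
#' @export
build_adjacency <- function(D, l, d_max = NULL,
                            precision = c("double", "single"),
                            dense_limit = 64L) {
  precision <- match.arg(precision)
  if (l <= 0) stop("bandwidth must be positive")
  n <- nrow(D)
  if (!is.null(d_max) && n > dense_limit) {
    # sparse fast path: only sub-threshold entries are ever nonzero
    keep <- which(D < d_max)
    x <- exp(-(D[keep]^2) / (2 * l * l))
    if (precision == "single") x <- float32(x)
    x[x == 0] <- 5e-324              # underflow just inside the boundary
    i <- (keep - 1L) %% n + 1L
    j <- (keep - 1L) %/% n + 1L
    x[i == j] <- 1
    return(Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n)))
  }
  W <- exp(-(D * D) / (2 * l * l))
  if (precision == "single") W <- matrix(float32(W), nrow = n)
  if (!is.null(d_max)) {
    W[D >= d_max] <- 0
    inside <- D < d_max & W == 0    # underflow just inside the boundary
    W[inside] <- 5e-324
  }
  diag(W) <- 1
  if (n > dense_limit) W <- methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix")
  W
}

#' Mini-batch graph pair
#'
#' Composes [pairwise_distance()], [quantile_threshold()], [solve_bandwidth()]
#' and [build_adjacency()] independently for the expression view (PC scores)
#' and the spatial view (tissue coordinates) of one mini-batch of spots. The
#' quantile calibration makes the expected fraction of nonzero off-diagonal
#' entries equal `tau_e` / `tau_p` in each view, so every batch has the same
#' average neighbour count regardless of its composition.
#'
#' @param pcs numeric n x D matrix of PC scores for the batch.
#' @param coords numeric n x 2 matrix of spot positions for the batch.
#' @param tau_e,tau_p target nonzero fractions (defaults 0.07).
#' @param precision working precision for the underflow constant.
#' @param member_indices optional global indices of the batch members.
#' @param include_diagonal passed to [quantile_threshold()].
#' @return An object of class `minibatch_graph` with fields `W_e`, `W_p`,
#'   `l_e`, `l_p`, `d_tau_e`, `d_tau_p`, `tau_e`, `tau_p`, `m`,
#'   `member_indices`.
#' @export
make_batch_graph <- function(pcs, coords, tau_e = 0.07, tau_p = 0.07,
                             precision = c("double", "single"),
                             member_indices = seq_len(nrow(as.matrix(pcs))),
                             include_diagonal = FALSE) {
  precision <- match.arg(precision)
  pcs <- as.matrix(pcs); coords <- as.matrix(coords)
  if (nrow(pcs) != nrow(coords)) stop("pcs and coords must be row-aligned")
  if (nrow(pcs) < 2L) stop("batch too small")
  m <- underflow_constant(precision)
  view <- function(points, tau) {
    D <- pairwise_distance(points)
    d_tau <- quantile_threshold(D, tau, include_diagonal = include_diagonal)
    if (d_tau <= 0) stop("degenerate batch: nonpositive distance threshold")
    l <- solve_bandwidth(d_tau, m)
    list(W = build_adjacency(D, l, d_max = d_tau, precision = precision),
         l = l, d_tau = d_tau)
  }
  e <- view(pcs, tau_e)
  p <- view(coords, tau_p)
  structure(list(member_indices = member_indices,
                 W_e = e$W, W_p = p$W, l_e = e$l, l_p = p$l,
                 d_tau_e = e$d_tau, d_tau_p = p$d_tau,
                 tau_e = tau_e, tau_p = tau_p, m = m,
                 precision = precision),
            class = "minibatch_graph")
}

#' @export
print.minibatch_graph <- function(x, ...) {
  cat(sprintf(
    "<minibatch_graph> n = %d, l_e = %.4g, l_p = %.4g, tau = (%.3g, %.3g), m = %d\n",
    length(x$member_indices), x$l_e, x$l_p, x$tau_e, x$tau_p, x$m))
  invisible(x)
}

#' Fraction of strictly positive off-diagonal entries
#'
#' @param W adjacency matrix (dense or sparse).
#' @return Fraction in \[0, 1\].
#' @export
offdiag_nonzero_fraction <- function(W) {
  n <- nrow(W)
  nnz <- Matrix::nnzero(W) - sum(Matrix::diag(W) > 0)
  nnz / (n * (n - 1))
}

#' Degree normalization of an adjacency matrix
#'
#' `mode = "none"` returns W unchanged (the literal smoothing operator);
#' `mode = "sym_degree"` returns `Deg^(-1/2) W Deg^(-1/2)` with
#' `Deg = diag(rowSums(W))`, the symmetric normalization whose spectral radius
#' is at most 1 — used by the training stability preset.
#'
#' @param W nonnegative symmetric matrix with positive diagonal.
#' @param mode `"none"` or `"sym_degree"`.
#' @return Matrix of the same shape (and storage class family).
#' @export
normalize_adjacency <- function(W, mode = c("none", "sym_degree")) {
  mode <- match.arg(mode)
  if (mode == "none") return(W)
  deg <- Matrix::rowSums(W)
  if (any(deg <= 0)) stop("zero row sum: adjacency must have positive diagonal")
  s <- 1 / sqrt(deg)
  if (inherits(W, "Matrix")) {
    Matrix::Diagonal(x = s) %*% W %*% Matrix::Diagonal(x = s)
  } else {
    W * tcrossprod(s)
  }
}

#' Laplacian-sharpening operator
#'
#' The decoder counterpart of the smoothing adjacency: `3 I - W`, which
#' accentuates each spot's deviation from its neighbours. The map is an
#' involution: applying it twice returns W.
#'
#' @param W square matrix.
#' @return `3 * I - W`, same storage family.
#' @export
sharpen_adjacency <- function(W) {
  n <- nrow(W)
  if (n != ncol(W)) stop("W must be square")
  if (inherits(W, "Matrix")) 3 * Matrix::Diagonal(n) - W else 3 * diag(n) - W
}
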