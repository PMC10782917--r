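test_that("pairwise distances satisfy the metric axioms and match brute force", {
  d <- pairwise_distance(rbind(c(0, 0), c(3, 4)))
  expect_equal(d[1, 2], 5)
  set.seed(3)
  x <- matrix(rnorm(50), 10, 5)
  D <- pairwise_distance(x)
  expect_true(all(diag(D) == 0))
  expect_identical(D, t(D))
  brute <- matrix(0, 10, 10)
  for (u in 1:10) for (v in 1:10) brute[u, v] <- sqrt(sum((x[u, ] - x[v, ])^2))
  expect_equal(D, brute, tolerance = 1e-12)
  expect_error(pairwise_distance(matrix(1, 1, 3)), "batch too small")
})

test_that("the underflow constant is found by probe in both precisions", {
  m_d <- underflow_constant("double")
  expect_identical(m_d, -746L)
  expect_identical(exp(m_d), 0)
  expect_gt(exp(m_d + 1), 0)
  m_s <- underflow_constant("single")
  expect_identical(m_s, -104L)
  expect_identical(sgcae:::float32(exp(m_s)), 0)
  expect_gt(sgcae:::float32(exp(m_s + 1)), 0)
})

test_that("quantile threshold matches a sorting oracle on the off-diagonal", {
  set.seed(7)
  x <- matrix(rnorm(100), 50, 2)
  D <- pairwise_distance(x)
  pop <- sort(D[row(D) != col(D)])
  for (tau in c(0.07, 0.25, 0.5)) {
    # type-7 linear interpolation, written out directly
    h <- (length(pop) - 1) * tau + 1
    lo <- floor(h)
    oracle <- pop[lo] + (h - lo) * (pop[lo + 1] - pop[lo])
    expect_equal(quantile_threshold(D, tau), oracle, tolerance = 1e-12)
  }
  # tau -> 0 approaches the minimum off-diagonal distance
  expect_equal(quantile_threshold(D, 1e-9), min(pop), tolerance = 1e-6)
  dup <- matrix(0, 4, 4)
  expect_error(quantile_threshold(dup, 0.07), "degenerate batch")
})

test_that("bandwidths solve the underflow equation", {
  expect_equal(solve_bandwidth(2, -104L), sqrt(4 / 208))
  l <- solve_bandwidth(2, -104L)
  expect_equal(-2^2 / (2 * l^2), -104)
  expect_equal(solve_bandwidth(sqrt(208), -104L), 1)
  expect_equal(solve_bandwidth(4, -104L), 2 * solve_bandwidth(2, -104L))
  expect_error(solve_bandwidth(0, -104L), "degenerate")
})

test_that("adjacency kernel has unit diagonal, truncation, and monotone decay", {
  set.seed(5)
  x <- matrix(rnorm(400), 200, 2)
  D <- pairwise_distance(x)
  m <- underflow_constant()
  d_tau <- quantile_threshold(D, 0.07)
  W <- build_adjacency(D, solve_bandwidth(d_tau, m), d_max = d_tau)
  expect_s4_class(W, "dgCMatrix")   # sparse above the dense fixture limit
  Wd <- as.matrix(W)
  expect_true(all(diag(Wd) == 1))
  expect_true(all(Wd[D >= d_tau] == 0))
  fr <- offdiag_nonzero_fraction(W)
  expect_gte(fr, 0.06); expect_lte(fr, 0.08)
  # kernel monotonicity within a row
  for (u in c(1, 50)) {
    ord <- order(D[u, -u])
    expect_true(all(diff(Wd[u, -u][ord]) <= 0))
  }
  # small matrices stay base-dense
  expect_true(is.matrix(build_adjacency(D[1:10, 1:10], 1)))
  # distance zero gives weight one
  expect_equal(build_adjacency(matrix(0, 2, 2), 1)[1, 2], 1)
})

test_that("mini-batch graphs obey symmetry, view identity, and degeneracy checks", {
  set.seed(9)
  x <- matrix(rnorm(200), 50, 4)
  g <- make_batch_graph(x, x[, 1:2], tau_e = 0.2, tau_p = 0.2)
  expect_true(Matrix::isSymmetric(g$W_e))
  expect_true(Matrix::isSymmetric(g$W_p))
  # identical inputs to both views give identical adjacencies
  g2 <- make_batch_graph(x, x, tau_e = 0.2, tau_p = 0.2)
  expect_equal(as.matrix(g2$W_e), as.matrix(g2$W_p))
  # all spots at one location: spatial view is degenerate
  expect_error(make_batch_graph(x, matrix(1, 50, 2)), "degenerate batch")
})

test_that("coordinate rescaling scales the bandwidth but not the weights", {
  set.seed(13)
  x <- matrix(rnorm(300), 75, 4)
  p <- matrix(runif(150), 75, 2)
  g1 <- make_batch_graph(x, p)
  g2 <- make_batch_graph(x, 10 * p)
  expect_equal(g2$l_p, 10 * g1$l_p, tolerance = 1e-12)
  expect_equal(as.matrix(g2$W_p), as.matrix(g1$W_p), tolerance = 1e-10)
})

test_that("degree normalization and sharpening behave as operators", {
  expect_identical(normalize_adjacency(diag(4), "sym_degree"), diag(4))
  expect_equal(normalize_adjacency(matrix(1, 2, 2), "sym_degree"),
               matrix(0.5, 2, 2))
  W <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_identical(normalize_adjacency(W, "none"), W)
  ns <- normalize_adjacency(W, "sym_degree")
  expect_lte(max(abs(eigen(ns)$values)), 1 + 1e-12)

  expect_equal(sharpen_adjacency(diag(3)), 2 * diag(3))
  set.seed(1)
  S <- crossprod(matrix(rnorm(25), 5, 5))
  expect_true(all(sharpen_adjacency(S) + S == 3 * diag(5)))
  expect_identical(sharpen_adjacency(sharpen_adjacency(S)), S)
})
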