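test_that("library-size normalization matches hand-computed scale factors", {
  raw <- expression_matrix(rbind(a = c(10, 0), b = c(5, 5)),
                           gene_ids = c("g1", "g2"), layer = "raw")
  # libraries are 10 and 10, so scale factors to a target of 10 are both 1
  out <- normalize_log(raw, target_size = 10)
  expect_equal(unname(out$values),
               rbind(c(log(11), 0), c(log(6), log(6))))
  expect_identical(out$layer, "normalized")
  # a spot at half the target library is scaled up by 2 before log1p
  raw2 <- expression_matrix(rbind(a = c(10, 0), b = c(5, 0)), layer = "raw")
  out2 <- normalize_log(raw2, target_size = 10)
  expect_equal(unname(out2$values), rbind(c(log(11), 0), c(log(11), 0)))
})

test_that("zero-count spots are dropped with a warning", {
  raw <- expression_matrix(rbind(a = c(1, 2), b = c(0, 0), c = c(3, 1)),
                           layer = "raw")
  expect_warning(out <- normalize_log(raw), "zero total count")
  expect_identical(out$spot_ids, c("a", "c"))
})

test_that("an all-equal count matrix normalizes to a constant matrix", {
  raw <- expression_matrix(matrix(4, 5, 3), layer = "raw")
  out <- normalize_log(raw)
  expect_equal(max(out$values) - min(out$values), 0)
})

test_that("high-dispersion genes are selected, constants never", {
  set.seed(51)
  n <- 80; G <- 100
  # same mean (10) on the back-transformed scale, 50x the variance for the
  # ten designated genes, so selection must come from dispersion alone
  y <- matrix(rgamma(n * G, shape = 100, scale = 0.1), n, G)
  hi <- 4 + seq(1, 100, by = 10)                # 10 designated genes
  y[, hi] <- rgamma(n * 10, shape = 2, scale = 5)
  v <- log1p(y)
  norm <- expression_matrix(v, layer = "normalized")
  sel <- select_hvg(norm, n_top = 10, flavor = "variance")
  expect_setequal(sel$gene_ids, norm$gene_ids[hi])
  # with a single mean bin the seurat flavour reduces to dispersion ranking
  sel_s <- select_hvg(norm, n_top = 10, flavor = "seurat", n_bins = 1)
  expect_setequal(sel_s$gene_ids, norm$gene_ids[hi])
  # brute-force dispersion ranking oracle for the variance flavour
  sel_v <- select_hvg(norm, n_top = 10, flavor = "variance")
  oracle <- norm$gene_ids[order(apply(v, 2, var), decreasing = TRUE)[1:10]]
  expect_setequal(sel_v$gene_ids, oracle)

  v2 <- v; v2[, 7] <- 1                          # constant gene
  norm2 <- expression_matrix(v2, layer = "normalized")
  sel2 <- select_hvg(norm2, n_top = 50, flavor = "seurat")
  expect_false("gene7" %in% sel2$gene_ids)
})

test_that("HVG selection keeps all genes when n_top exceeds the gene count", {
  norm <- expression_matrix(matrix(runif(12), 3, 4), layer = "normalized")
  expect_identical(select_hvg(norm, n_top = 3000)$gene_ids, norm$gene_ids)
})

test_that("HVG selection is permutation-equivariant in the genes", {
  set.seed(53)
  v <- matrix(rexp(60 * 40), 60, 40)
  norm <- expression_matrix(v, layer = "normalized")
  perm <- sample(40)
  normp <- expression_matrix(v[, perm], gene_ids = norm$gene_ids[perm],
                             layer = "normalized")
  # n_bins chosen so bins hold several genes and bin z-scores are tie-free
  s1 <- select_hvg(norm, n_top = 12, flavor = "seurat", n_bins = 5)
  s2 <- select_hvg(normp, n_top = 12, flavor = "seurat", n_bins = 5)
  expect_setequal(s1$gene_ids, s2$gene_ids)
  s3 <- select_hvg(norm, n_top = 12, flavor = "variance")
  s4 <- select_hvg(normp, n_top = 12, flavor = "variance")
  expect_setequal(s3$gene_ids, s4$gene_ids)
})

test_that("PCA scores reproduce a rank-2 matrix and match a dense SVD oracle", {
  set.seed(57)
  base <- matrix(rnorm(20), 10, 2) %*% matrix(rnorm(8), 2, 4)
  norm <- expression_matrix(base, layer = "normalized")
  p <- compute_pcs(norm, n_pcs = 2)
  centred <- scale(base, scale = FALSE)
  # reconstruction from 2 PCs is exact for a rank-2 matrix
  rot <- stats::prcomp(base, rank. = 2)$rotation
  expect_equal(unname(p$scores %*% t(rot)), unname(centred),
               tolerance = 1e-9, ignore_attr = TRUE)

  x <- matrix(rnorm(200), 20, 10)
  px <- compute_pcs(expression_matrix(x, layer = "normalized"), n_pcs = 5)
  sv <- svd(scale(x, scale = FALSE))
  oracle <- sv$u[, 1:5] %*% diag(sv$d[1:5])
  flip <- sign(colSums(px$scores * oracle))
  expect_equal(unname(px$scores), oracle %*% diag(flip), tolerance = 1e-9)
  # column covariance is diagonal with decreasing entries
  cv <- cov(px$scores)
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(diag(cv)) <= 1e-9))
  expect_error(compute_pcs(expression_matrix(x, layer = "normalized"),
                           n_pcs = 11), "exceeds")
})

test_that("the preprocessing pipeline is deterministic and drops bad spots coherently", {
  ds <- generate_layered_dataset(synth_config(n_spots = 120, n_genes = 40,
                                              n_markers_per_domain = 4,
                                              seed = 5))
  v <- ds$counts$values
  v[7, ] <- 0                                    # force one zero-count spot
  counts <- expression_matrix(v, layer = "raw")
  pp1 <- suppressWarnings(preprocess(counts, ds$coords, n_hvg = 30, n_pcs = 10))
  pp2 <- suppressWarnings(preprocess(counts, ds$coords, n_hvg = 30, n_pcs = 10))
  expect_identical(pp1$pcs$scores, pp2$pcs$scores)
  expect_identical(pp1$pcs$spot_ids, pp1$coords$spot_ids)
  expect_length(pp1$pcs$spot_ids, 119)
})
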