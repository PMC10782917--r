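test_that("the generator is deterministic and marker means obey the design", {
  cfg <- synth_config()
  d1 <- generate_layered_dataset(cfg)
  d2 <- generate_layered_dataset(cfg)
  expect_identical(d1$counts$values, d2$counts$values)
  expect_identical(d1$truth$labels, d2$truth$labels)

  # law of large numbers: in-domain marker mean ~= baseline * exp(effect)
  target <- 5 * exp(1.5)
  for (d in 1:5) {
    inside <- d1$truth$labels == d
    expect_gt(sum(inside), 500)
    mm <- mean(d1$counts$values[inside, d1$marker_genes[[d]]])
    expect_lt(abs(mm - target) / target, 0.05)
    outside <- mean(d1$counts$values[!inside, d1$marker_genes[[d]]])
    expect_lt(abs(outside - 5) / 5, 0.05)
  }
})

test_that("bands are spatially contiguous and depend only on the y coordinate", {
  ds <- generate_layered_dataset(synth_config(n_spots = 900, seed = 2))
  y <- ds$coords$positions[, "y"]
  expect_true(all(tapply(ds$truth$labels, y, function(l) length(unique(l))) == 1))
  # band index is non-decreasing in y
  ord <- order(y)
  expect_true(all(diff(ds$truth$labels[ord]) >= 0))
  expect_identical(sort(unique(ds$truth$labels)), 1:5)
})

test_that("ring geometry produces K concentric domains", {
  ds <- generate_layered_dataset(synth_config(n_spots = 800, n_domains = 4,
                                              geometry = "rings", seed = 3))
  r <- sqrt(rowSums(sweep(ds$coords$positions, 2,
                          colMeans(ds$coords$positions))^2))
  expect_identical(sort(unique(ds$truth$labels)), 1:4)
  # mean radius is strictly increasing across ring labels
  expect_true(all(diff(tapply(r, ds$truth$labels, mean)) > 0))
})

test_that("count marginals match the requested noise model", {
  # non-marker genes are iid with mean = baseline under both models
  cfg <- synth_config(n_spots = 2500, n_genes = 60, n_markers_per_domain = 2,
                      seed = 7)
  ds <- generate_layered_dataset(cfg)
  draws <- as.vector(ds$counts$values[, 31:34])   # 10^4 non-marker draws
  brk <- c(-0.5, seq(0.5, 11.5), Inf)
  obs <- table(cut(draws, brk))
  pr <- diff(c(0, ppois(0:11, 5), 1))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.01)

  cfgnb <- synth_config(n_spots = 2500, n_genes = 60, n_markers_per_domain = 2,
                        noise = "nb", theta = 2, seed = 8)
  dsnb <- generate_layered_dataset(cfgnb)
  drawsnb <- as.vector(dsnb$counts$values[, 31:34])
  expect_gt(var(drawsnb) / mean(drawsnb), 2)      # overdispersed
  obs2 <- table(cut(drawsnb, brk))
  pr2 <- diff(c(0, pnbinom(0:11, mu = 5, size = 2), 1))
  gof2 <- suppressWarnings(chisq.test(as.vector(obs2), p = pr2))
  expect_gt(gof2$p.value, 0.01)
})

test_that("a zero effect size carries no domain signal", {
  ds <- generate_layered_dataset(synth_config(n_spots = 600, n_genes = 80,
                                              effect = 0, seed = 9))
  pp <- preprocess(ds$counts, ds$coords, n_hvg = 80, n_pcs = 20)
  lab <- gmm_cluster(pp$pcs$scores, k = 5, seed = 1)
  truth <- ds$truth$labels[match(pp$pcs$spot_ids, ds$truth$spot_ids)]
  expect_lt(abs(score_ari(lab$labels, truth)), 0.1)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(n_domains = 1), "n_domains")
  expect_error(synth_config(n_genes = 10, n_domains = 5,
                            n_markers_per_domain = 3))
  expect_error(generate_layered_dataset(
    synth_config(n_spots = 16, n_domains = 5)), "bands")
})

test_that("the adjusted Rand index matches its reference implementation", {
  expect_equal(score_ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(score_ari(1:4, rep(1L, 4)), 0)
  set.seed(15)
  a <- sample(1:4, 200, replace = TRUE)
  b <- sample(1:3, 200, replace = TRUE)
  expect_equal(score_ari(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(score_ari(perm[a], b), score_ari(a, b))
  expect_error(score_ari(1:3, 1:4), "length mismatch")
})
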