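# Memoized end-to-end runs on the default synthetic layered dataset
# (3000 spots, K = 5 bands, 200 genes, effect 1.5, Poisson), trained for 30
# epochs with the sym_degree stability preset. Several test files share them.

.run_cache <- new.env(parent = emptyenv())

default_run <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.run_cache[[key]])) {
    ds <- generate_layered_dataset(synth_config(seed = seed))
    run <- run_pipeline(ds$counts, ds$coords, n_domains = 5, epochs = 30,
                        batch_size = 2000, seed = seed,
                        normalization = "sym_degree", run_deg = FALSE)
    .run_cache[[key]] <- list(ds = ds, run = run)
  }
  .run_cache[[key]]
}

# peak R heap use of fit() above the post-input baseline, in Mb; the
# per-batch gc hook makes the high-water mark reflect one batch's transients
peak_fit_mb <- function(N, n, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(N * 50), N, 50)
  P <- cbind(runif(N, 0, 100), runif(N, 0, 100))
  cfg <- train_config(batch_size = n, epochs = 1, seed = 1,
                      normalization = "sym_degree")
  old <- options(sgcae.gc_per_batch = TRUE)
  on.exit(options(old))
  invisible(gc(reset = TRUE, full = TRUE))
  base <- sum(gc()[, 2])
  invisible(fit_sgcae(X, P, cfg))
  sum(gc()[, 6]) - base
}
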