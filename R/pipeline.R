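#' End-to-end spatial-domain pipeline
#'
#' Chains the full method on an in-memory dataset: preprocessing (normalize,
#' log1p, HVG, PCA), mini-batch training of the symmetric graph convolutional
#' auto-encoder, embedding extraction, clustering (Gaussian mixture when
#' `n_domains` is given, Louvain otherwise), spatial label refinement, and
#' optional one-vs-rest Wilcoxon marker detection.
#'
#' The pipeline trains with the degree-normalized smoothing operator
#' (`normalization = "sym_degree"`), the stability preset; pass
#' `normalization = "none"` for the literal un-normalized operator.
#'
#' @param counts an [expression_matrix()] with raw counts.
#' @param coords a [spot_coordinates()] aligned with `counts`.
#' @param n_domains known number of domains (Gaussian mixture), or `NULL`
#'   to infer via Louvain.
#' @param epochs,batch_size,seed,variant,normalization training settings; see
#'   [train_config()].
#' @param n_hvg,n_pcs preprocessing sizes (defaults 3000 and 50).
#' @param resolution,n_neighbors Louvain settings.
#' @param refine apply [refine_labels()] (default TRUE).
#' @param k_neighbors refinement neighbourhood size.
#' @param run_deg compute the marker table (default TRUE).
#' @param ... further arguments passed to [train_config()].
#' @return List of class `sgcae_run`: `pcs`, `coords`, `fit`, `embeddings`,
#'   `labels` (pre-refinement), `labels_refined` (or `NULL`), `deg` (or
#'   `NULL`), `norm`.
#' @export
run_pipeline <- function(counts, coords, n_domains = NULL,
                         epochs = 100L, batch_size = 2000L, seed = 1L,
                         variant = "full", normalization = "sym_degree",
                         n_hvg = 3000L, n_pcs = 50L,
                         resolution = 1.2, n_neighbors = 15L,
                         refine = TRUE, k_neighbors = 6L,
                         run_deg = TRUE, ...) {
  pp <- preprocess(counts, coords, n_hvg = n_hvg, n_pcs = n_pcs)
  cfg <- train_config(batch_size = batch_size, epochs = epochs, seed = seed,
                      variant = variant, normalization = normalization, ...)
  fit <- fit_sgcae(pp$pcs, pp$coords, cfg)
  emb <- extract_embeddings(pp$pcs, pp$coords, fit)
  labels <- if (is.null(n_domains)) {
    louvain_cluster(emb, resolution = resolution, n_neighbors = n_neighbors,
                    seed = seed)
  } else {
    gmm_cluster(emb, k = n_domains, seed = seed)
  }
  refined <- if (refine) refine_labels(labels, pp$coords, k_neighbors) else NULL
  final <- refined %||% labels
  deg <- if (run_deg) wilcoxon_deg(pp$norm, final) else NULL
  structure(list(pcs = pp$pcs, coords = pp$coords, fit = fit,
                 embeddings = emb, labels = labels, labels_refined = refined,
                 deg = deg, norm = pp$norm),
            class = "sgcae_run")
}

#' @export
print.sgcae_run <- function(x, ...) {
  lab <- x$labels_refined %||% x$labels
  cat(sprintf("<sgcae_run> %d spots, %d domains%s, %d training epochs\n",
              length(lab$labels), lab$K,
              if (lab$refined) " (refined)" else "",
              nrow(x$fit$history)))
  invisible(x)
}

#' Plot spatial domains
#'
#' Scatter of spot positions coloured by domain label (requires ggplot2).
#'
#' @param labels a [domain_labels()].
#' @param coords a [spot_coordinates()] aligned with `labels`.
#' @param point_size point size passed to `geom_point`.
#' @return A ggplot object.
#' @export
plot_domains <- function(labels, coords, point_size = 1) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_domains requires ggplot2")
  }
  df <- data.frame(x = coords$positions[, 1], y = coords$positions[, 2],
                   domain = factor(labels$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$domain)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(colour = "domain")
}

#' Write pipeline outputs and a run manifest
#'
#' Writes embeddings, labels, the DEG table and the training history as
#' plain-text tables, plus a JSON manifest recording the configuration,
#' seed, package version, per-file md5 hashes and timestamps (requires
#' jsonlite).
#'
#' @param run an `sgcae_run` from [run_pipeline()].
#' @param output_dir output directory (created if needed).
#' @param seed the seed the run used (recorded in the manifest).
#' @return Path to the manifest, invisibly.
#' @export
write_run_outputs <- function(run, output_dir, seed = run$fit$config$seed) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  lab <- run$labels_refined %||% run$labels
  utils::write.csv(data.frame(spot_id = run$embeddings$spot_ids,
                              run$embeddings$values),
                   file.path(output_dir, "embeddings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(spot_id = run$embeddings$spot_ids,
                              domain = run$labels$labels,
                              domain_refined = lab$labels),
                   file.path(output_dir, "labels.csv"), row.names = FALSE)
  utils::write.table(run$fit$history, file.path(output_dir, "history.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(run$deg)) {
    utils::write.table(run$deg, file.path(output_dir, "deg.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest_path <- file.path(output_dir, "manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    files <- setdiff(list.files(output_dir, full.names = TRUE), manifest_path)
    manifest <- list(
      package_version = as.character(utils::packageVersion("sgcae")),
      seed = seed,
      config = unclass(run$fit$config),
      files = stats::setNames(as.list(unname(tools::md5sum(files))),
                              basename(files)),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    tmp <- paste0(manifest_path, ".tmp")
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
    file.rename(tmp, manifest_path)   # atomic finalisation
  }
  invisible(manifest_path)
}
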