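#' Library-size normalization and log transform
#'
#' Scales each spot's counts so library sizes equal a common target (the
#' median library size by default), then applies `log1p`. Spots with zero
#' total count are dropped with a warning — downstream coordinate tables
#' should be realigned by spot id (the pipeline does this).
#'
#' @param raw an [expression_matrix()] with `layer = "raw"`.
#' @param target_size library-size target; default median of per-spot totals.
#' @return An [expression_matrix()] with `layer = "normalized"`.
#' @export
normalize_log <- function(raw, target_size = NULL) {
  stopifnot(inherits(raw, "expression_matrix"))
  if (raw$layer != "raw") stop("normalize_log expects layer = 'raw'")
  v <- raw$values
  lib <- rowSums(v)
  zero <- lib == 0
  if (any(zero)) {
    warning(sprintf("dropping %d spot(s) with zero total count: %s",
                    sum(zero), paste(utils::head(raw$spot_ids[zero], 5),
                                     collapse = ", ")))
    v <- v[!zero, , drop = FALSE]
    lib <- lib[!zero]
  }
  if (is.null(target_size)) target_size <- stats::median(lib)
  out <- log1p(v * (target_size / lib))
  expression_matrix(out, spot_ids = rownames(v), gene_ids = raw$gene_ids,
                    layer = "normalized")
}

#' Select highly variable genes
#'
#' Dispersion-based ranking on the log-normalized matrix. The default
#' `"seurat"` flavour works on the back-transformed (`expm1`) values: per-gene
#' dispersion = variance/mean, genes grouped into 20 equal-occupancy mean
#' bins, dispersions z-scored within bin, top `n_top` by normalized
#' dispersion.
#' `"variance"` is plain variance ranking (useful for small fixtures).
#' Constant genes are never selected. The original gene order is preserved
#' among the survivors.
#'
#' @param norm an [expression_matrix()] with `layer = "normalized"`.
#' @param n_top number of genes to keep (default 3000).
#' @param flavor `"seurat"` or `"variance"`.
#' @param n_bins mean bins for the seurat flavour.
#' @return An [expression_matrix()] restricted to the selected genes.
#' @export
select_hvg <- function(norm, n_top = 3000L, flavor = c("seurat", "variance"),
                       n_bins = 20L) {
  stopifnot(inherits(norm, "expression_matrix"))
  flavor <- match.arg(flavor)
  if (norm$layer != "normalized") stop("select_hvg expects layer = 'normalized'")
  if (n_top < 1) stop("n_top must be >= 1")
  G <- ncol(norm$values)
  if (G < 2) stop("need at least 2 genes")
  if (n_top >= G) return(norm)

  v <- norm$values
  if (flavor == "variance") {
    score <- apply(v, 2, stats::var)
    score[score == 0] <- -Inf
  } else {
    x <- expm1(v)
    mu <- colMeans(x)
    va <- apply(x, 2, stats::var)
    disp <- ifelse(mu > 0, va / mu, 0)
    # equal-occupancy bins: no empty or singleton bins to distort the z-scores
    brk <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- if (length(brk) > 2) cut(mu, breaks = brk, include.lowest = TRUE)
            else factor(rep(1, G))
    bm <- stats::ave(disp, bins, FUN = mean)
    bs <- stats::ave(disp, bins, FUN = stats::sd)
    score <- ifelse(is.na(bs) | bs == 0, 0, (disp - bm) / bs)
    score[va == 0] <- -Inf
  }
  keep <- sort(utils::head(order(score, decreasing = TRUE), n_top))
  expression_matrix(v[, keep, drop = FALSE], spot_ids = norm$spot_ids,
                    gene_ids = norm$gene_ids[keep], layer = "normalized")
}

#' Principal-component scores
#'
#' Gene-wise centered (optionally unit-scaled) PCA of the normalized HVG
#' matrix via [stats::prcomp()] (exact SVD — deterministic). The top `n_pcs`
#' score columns, ordered by decreasing explained variance, form the
#' auto-encoder input.
#'
#' @param hvg an [expression_matrix()] with `layer = "normalized"`.
#' @param n_pcs number of components (default 50).
#' @param scale. unit-scale genes before SVD (default FALSE: center only).
#' @return A [pc_matrix()].
#' @export
compute_pcs <- function(hvg, n_pcs = 50L, scale. = FALSE) {
  stopifnot(inherits(hvg, "expression_matrix"))
  if (hvg$layer != "normalized") stop("compute_pcs expects layer = 'normalized'")
  v <- hvg$values
  max_d <- min(nrow(v) - 1L, ncol(v))
  if (n_pcs > max_d) {
    stop(sprintf("n_pcs = %d exceeds min(n_spots - 1, n_genes) = %d",
                 n_pcs, max_d))
  }
  if (scale.) {
    sdv <- apply(v, 2, stats::sd)
    if (any(sdv == 0)) v <- v[, sdv > 0, drop = FALSE]
  }
  p <- stats::prcomp(v, center = TRUE, scale. = scale., rank. = n_pcs)
  pc_matrix(p$x[, seq_len(n_pcs), drop = FALSE],
            explained_variance = p$sdev[seq_len(n_pcs)]^2,
            spot_ids = hvg$spot_ids,
            center = p$center, scale = if (scale.) p$scale else NULL)
}

#' Preprocessing pipeline
#'
#' Fixed order: library-size normalize, log1p, highly-variable-gene
#' selection, PCA. Coordinates are realigned if zero-count spots were
#' dropped.
#'
#' @param counts an [expression_matrix()] with raw counts.
#' @param coords a [spot_coordinates()] aligned with `counts`.
#' @param n_hvg,n_pcs,hvg_flavor,scale_pcs,target_size stage parameters; see
#'   [normalize_log()], [select_hvg()], [compute_pcs()].
#' @return List with `pcs` ([pc_matrix()]), `coords` (realigned
#'   [spot_coordinates()]), `norm` (normalized [expression_matrix()], all
#'   genes) and `hvg` (selected genes).
#' @export
preprocess <- function(counts, coords, n_hvg = 3000L, n_pcs = 50L,
                       hvg_flavor = "seurat", scale_pcs = FALSE,
                       target_size = NULL) {
  stopifnot(inherits(counts, "expression_matrix"),
            inherits(coords, "spot_coordinates"))
  if (!identical(counts$spot_ids, coords$spot_ids)) {
    stop("counts and coords must share the same spot order")
  }
  norm <- normalize_log(counts, target_size = target_size)
  if (length(norm$spot_ids) < length(counts$spot_ids)) {
    keep <- match(norm$spot_ids, coords$spot_ids)
    coords <- spot_coordinates(coords$positions[keep, , drop = FALSE],
                               spot_ids = coords$spot_ids[keep])
  }
  hvg <- select_hvg(norm, n_top = n_hvg, flavor = hvg_flavor)
  n_pcs <- min(n_pcs, nrow(hvg$values) - 1L, ncol(hvg$values))
  pcs <- compute_pcs(hvg, n_pcs = n_pcs, scale. = scale_pcs)
  list(pcs = pcs, coords = coords, norm = norm, hvg = hvg)
}
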