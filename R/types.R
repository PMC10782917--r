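#' Spot-by-gene expression matrix
#'
#' Light container for a spot x gene expression matrix with aligned spot and
#' gene identifiers. `layer = "raw"` holds nonnegative counts; after
#' [normalize_log()] the layer is `"normalized"` (library-size scaled,
#' log1p-transformed values).
#'
#' @param values numeric matrix, spots in rows, genes in columns.
#' @param spot_ids character vector of unique spot identifiers (one per row).
#' @param gene_ids character vector of unique gene identifiers (one per column).
#' @param layer either `"raw"` or `"normalized"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, spot_ids = rownames(values),
                              gene_ids = colnames(values),
                              layer = c("raw", "normalized")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  stopifnot(length(spot_ids) == nrow(values), length(gene_ids) == ncol(values))
  if (anyDuplicated(spot_ids)) stop("spot_ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (layer == "raw" && any(values < 0)) stop("raw counts must be nonnegative")
  rownames(values) <- spot_ids
  colnames(values) <- gene_ids
  structure(list(values = values, spot_ids = spot_ids, gene_ids = gene_ids,
                 layer = layer),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d spots x %d genes, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Planar spot coordinates
#'
#' Spot x 2 table of tissue positions, row-aligned with an
#' [expression_matrix()].
#'
#' @param positions numeric matrix or data frame with two columns (x, y).
#' @param spot_ids character vector of spot identifiers.
#' @return An object of class `spot_coordinates`.
#' @export
spot_coordinates <- function(positions, spot_ids = rownames(positions)) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 2L) stop("positions must have exactly 2 columns")
  if (any(!is.finite(positions))) stop("positions must be finite")
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(positions)))
  spot_ids <- as.character(spot_ids)
  stopifnot(length(spot_ids) == nrow(positions))
  rownames(positions) <- spot_ids
  colnames(positions) <- c("x", "y")
  structure(list(positions = positions, spot_ids = spot_ids),
            class = "spot_coordinates")
}

#' @export
print.spot_coordinates <- function(x, ...) {
  cat(sprintf("<spot_coordinates> %d spots\n", nrow(x$positions)))
  invisible(x)
}

#' Principal-component score matrix
#'
#' Spot x D matrix of PC scores (the auto-encoder input), columns ordered by
#' decreasing explained variance.
#'
#' @param scores numeric spot x D matrix.
#' @param explained_variance length-D vector of component variances.
#' @param spot_ids character vector of spot identifiers.
#' @param center,scale centering/scaling metadata from the PCA.
#' @return An object of class `pc_matrix`.
#' @export
pc_matrix <- function(scores, explained_variance, spot_ids = rownames(scores),
                      center = NULL, scale = NULL) {
  scores <- as.matrix(scores)
  stopifnot(length(explained_variance) == ncol(scores))
  if (is.unsorted(rev(explained_variance))) {
    stop("explained_variance must be non-increasing")
  }
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(scores)))
  rownames(scores) <- spot_ids
  structure(list(scores = scores, explained_variance = explained_variance,
                 spot_ids = as.character(spot_ids),
                 center = center, scale = scale),
            class = "pc_matrix")
}

#' @export
print.pc_matrix <- function(x, ...) {
  cat(sprintf("<pc_matrix> %d spots x %d PCs\n", nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Per-spot spatial-domain labels
#'
#' Integer cluster assignments in `1..K` (R's 1-based convention) with a flag
#' recording whether the spatial majority-vote refinement has been applied.
#'
#' @param labels integer vector of domain assignments.
#' @param K number of domains; defaults to the number of distinct labels.
#' @param refined logical, whether [refine_labels()] has been applied.
#' @param spot_ids optional spot identifiers.
#' @return An object of class `domain_labels`.
#' @export
domain_labels <- function(labels, K = length(unique(labels)), refined = FALSE,
                          spot_ids = names(labels)) {
  labels <- as.integer(labels)
  if (any(is.na(labels))) stop("labels must not contain NA")
  if (any(labels < 1L) || any(labels > K)) stop("labels must lie in 1..K")
  structure(list(labels = labels, K = as.integer(K), refined = refined,
                 spot_ids = spot_ids),
            class = "domain_labels")
}

#' @export
print.domain_labels <- function(x, ...) {
  cat(sprintf("<domain_labels> %d spots, K = %d, refined = %s\n",
              length(x$labels), x$K, x$refined))
  invisible(x)
}

#' Latent embedding matrix
#'
#' Spot x D matrix of encoder outputs used for clustering and visualisation.
#'
#' @param values numeric spot x D matrix.
#' @param spot_ids character vector of spot identifiers.
#' @return An object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(values, spot_ids = rownames(values)) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("embeddings must be finite")
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(values)))
  rownames(values) <- spot_ids
  structure(list(values = values, spot_ids = as.character(spot_ids)),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d spots x %d dims\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
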