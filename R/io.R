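#' Load a spatial expression dataset
#'
#' Reads counts plus spot coordinates from one of three containers and
#' returns them with a common, aligned spot order (the count matrix's order;
#' coordinates are joined by spot id).
#'
#' * `"csv"`: `counts.csv` (first column `spot_id`, remaining columns genes)
#'   and `coords.csv` (`spot_id`, `x`, `y`).
#' * `"mtx_dir"`: MatrixMarket `matrix.mtx` (genes x spots, 10x convention),
#'   `barcodes.tsv`, `genes.tsv` (or `features.tsv`), and a positions table
#'   `positions.csv` with columns `spot_id`, `x`, `y`.
#' * `"h5"`: an AnnData-layout HDF5 file — `X` (dense, or CSR group with
#'   `data`/`indices`/`indptr` and a `shape` attribute), `obs` spot index,
#'   `var` gene index, and coordinates in `obsm/spatial` (requires the
#'   `rhdf5` package).
#'
#' @param path file (csv stem/h5 file) or directory (mtx_dir).
#' @param format `"csv"`, `"mtx_dir"` or `"h5"`.
#' @return List with `counts` ([expression_matrix()], `layer = "raw"`) and
#'   `coords` ([spot_coordinates()]), spot-aligned.
#' @export
load_dataset <- function(path, format = c("csv", "mtx_dir", "h5")) {
  format <- match.arg(format)
  switch(format,
         csv = .load_csv(path),
         mtx_dir = .load_mtx_dir(path),
         h5 = .load_h5(path))
}

.align_coords <- function(counts, coord_df) {
  miss <- setdiff(counts$spot_ids, coord_df$spot_id)
  extra <- setdiff(coord_df$spot_id, counts$spot_ids)
  if (length(miss) || length(extra)) {
    stop(sprintf("spot-ID mismatch between counts and coordinates; missing: [%s], unmatched: [%s]",
                 paste(utils::head(miss, 5), collapse = ", "),
                 paste(utils::head(extra, 5), collapse = ", ")))
  }
  ord <- match(counts$spot_ids, coord_df$spot_id)
  spot_coordinates(as.matrix(coord_df[ord, c("x", "y")]),
                   spot_ids = coord_df$spot_id[ord])
}

.load_csv <- function(path) {
  cf <- file.path(path, "counts.csv")
  xf <- file.path(path, "coords.csv")
  if (!file.exists(cf) || !file.exists(xf)) {
    stop("csv dataset needs counts.csv and coords.csv in ", path)
  }
  ct <- utils::read.csv(cf, check.names = FALSE)
  m <- as.matrix(ct[, -1, drop = FALSE])
  rownames(m) <- as.character(ct[[1]])
  counts <- expression_matrix(m, layer = "raw")
  co <- utils::read.csv(xf)
  co$spot_id <- as.character(co$spot_id)
  list(counts = counts, coords = .align_coords(counts, co))
}

.load_mtx_dir <- function(path) {
  mf <- file.path(path, "matrix.mtx")
  if (!file.exists(mf)) stop("mtx_dir dataset needs matrix.mtx in ", path)
  bc <- readLines(file.path(path, "barcodes.tsv"))
  gf <- file.path(path, "genes.tsv")
  if (!file.exists(gf)) gf <- file.path(path, "features.tsv")
  genes <- utils::read.delim(gf, header = FALSE)[[1]]
  m <- Matrix::readMM(mf)              # genes x spots (10x convention)
  m <- t(as.matrix(m))                 # -> spots x genes
  rownames(m) <- bc
  colnames(m) <- genes
  counts <- expression_matrix(m, layer = "raw")
  pf <- file.path(path, "positions.csv")
  if (!file.exists(pf)) stop("no spatial coordinates: positions.csv missing in ", path)
  co <- utils::read.csv(pf)
  co$spot_id <- as.character(co$spot_id)
  list(counts = counts, coords = .align_coords(counts, co))
}

.load_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("h5 input requires the rhdf5 package")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)
  paths <- file.path(contents$group, contents$name)
  paths <- sub("^/", "", sub("^//", "/", paths))
  has <- function(p) p %in% paths || sub("^/", "", p) %in% paths
  if (!has("obsm/spatial")) stop("no spatial coordinates")
  read <- function(p) rhdf5::h5read(path, p)
  spot_ids <- as.character(read(if (has("obs/_index")) "obs/_index" else "obs/index"))
  gene_ids <- as.character(read(if (has("var/_index")) "var/_index" else "var/index"))
  if (has("X/data")) {                 # CSR sparse: h5ad convention
    data <- as.numeric(read("X/data"))
    indices <- as.integer(read("X/indices"))
    indptr <- as.integer(read("X/indptr"))
    n <- length(spot_ids); g <- length(gene_ids)
    m <- as.matrix(Matrix::sparseMatrix(
      j = indices + 1L, p = indptr, x = data, dims = c(n, g), index1 = TRUE))
  } else {
    m <- read("X")
    # h5ad stores X as genes x spots on disk (column-major transposition)
    if (nrow(m) == length(gene_ids) && ncol(m) == length(spot_ids)) m <- t(m)
  }
  rownames(m) <- spot_ids
  colnames(m) <- gene_ids
  counts <- expression_matrix(m, layer = "raw")
  sp <- read("obsm/spatial")
  if (nrow(sp) == 2 && ncol(sp) == length(spot_ids)) sp <- t(sp)
  co <- data.frame(spot_id = spot_ids, x = sp[, 1], y = sp[, 2])
  list(counts = counts, coords = .align_coords(counts, co))
}

#' Write a dataset to disk
#'
#' Writes the same containers [load_dataset()] reads, so simulated data can
#' round-trip through the real readers.
#'
#' @param counts an [expression_matrix()] (raw counts).
#' @param coords a [spot_coordinates()] aligned with `counts`.
#' @param path output directory (csv, mtx_dir) or `.h5` file path.
#' @param format `"csv"`, `"mtx_dir"` or `"h5"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(counts, coords, path,
                          format = c("csv", "mtx_dir", "h5")) {
  format <- match.arg(format)
  stopifnot(inherits(counts, "expression_matrix"),
            inherits(coords, "spot_coordinates"))
  co <- data.frame(spot_id = coords$spot_ids,
                   x = coords$positions[, 1], y = coords$positions[, 2])
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    ct <- data.frame(spot_id = counts$spot_ids, counts$values,
                     check.names = FALSE)
    utils::write.csv(ct, file.path(path, "counts.csv"), row.names = FALSE)
    utils::write.csv(co, file.path(path, "coords.csv"), row.names = FALSE)
  } else if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- Matrix::Matrix(t(counts$values), sparse = TRUE)  # genes x spots
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(counts$spot_ids, file.path(path, "barcodes.tsv"))
    utils::write.table(data.frame(counts$gene_ids, counts$gene_ids),
                       file.path(path, "genes.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.csv(co, file.path(path, "positions.csv"), row.names = FALSE)
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("h5 output requires the rhdf5 package")
    }
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(t(counts$values), path, "X")   # genes x spots on disk
    rhdf5::h5createGroup(path, "obs")
    rhdf5::h5write(counts$spot_ids, path, "obs/_index")
    rhdf5::h5createGroup(path, "var")
    rhdf5::h5write(counts$gene_ids, path, "var/_index")
    rhdf5::h5createGroup(path, "obsm")
    rhdf5::h5write(coords$positions, path, "obsm/spatial")
    rhdf5::h5closeAll()
  }
  invisible(path)
}
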