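#' Synthetic layered-tissue configuration
#'
#' Defaults emulate a laminar tissue section (cortical-layer-like bands):
#' 3000 spots on a grid, 5 horizontal bands, 200 genes with 10 markers per
#' domain, marker mean shift of 1.5 on the log scale over a baseline mean of
#' 5, Poisson counts.
#'
#' @param n_spots total number of spots.
#' @param n_domains number of spatial domains K (>= 2).
#' @param n_genes total genes G.
#' @param n_markers_per_domain marker genes per domain
#'   (`K * n_markers_per_domain <= G`).
#' @param effect marker log-scale mean shift (> 0; marker mean inside its
#'   domain is `baseline * exp(effect)`). `effect = 0` gives the null model.
#' @param baseline baseline count mean.
#' @param noise `"poisson"` or `"nb"` (negative binomial).
#' @param theta NB size (inverse overdispersion), used when `noise = "nb"`.
#' @param dropout probability of zeroing each count independently.
#' @param geometry `"bands"` (horizontal layers) or `"rings"` (concentric).
#' @param seed integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_spots = 3000L, n_domains = 5L, n_genes = 200L,
                         n_markers_per_domain = 10L, effect = 1.5,
                         baseline = 5, noise = c("poisson", "nb"), theta = 10,
                         dropout = 0, geometry = c("bands", "rings"),
                         seed = 1L) {
  noise <- match.arg(noise)
  geometry <- match.arg(geometry)
  stopifnot(n_spots >= 4, n_domains >= 2, n_genes >= 2,
            n_markers_per_domain >= 1,
            n_domains * n_markers_per_domain <= n_genes,
            effect >= 0, baseline > 0, theta > 0,
            dropout >= 0, dropout < 1)
  structure(list(n_spots = as.integer(n_spots),
                 n_domains = as.integer(n_domains),
                 n_genes = as.integer(n_genes),
                 n_markers_per_domain = as.integer(n_markers_per_domain),
                 effect = effect, baseline = baseline, noise = noise,
                 theta = theta, dropout = dropout, geometry = geometry,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic layered spatial dataset
#'
#' Spots are placed on a near-square integer grid. With `geometry = "bands"`
#' the domain is the horizontal band index (K contiguous layers); with
#' `"rings"` it is a concentric ring index around the grid centre, binned so
#' rings hold roughly equal numbers of spots. Gene g in domain d's marker set
#' has count mean `baseline * exp(effect)` inside d and `baseline` outside;
#' all other genes have mean `baseline` everywhere. Counts are Poisson or
#' negative binomial, with optional independent dropout. Fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return List with `counts` ([expression_matrix()], raw), `coords`
#'   ([spot_coordinates()]), `truth` ([domain_labels()]) and `marker_genes`
#'   (list of gene-id vectors per domain).
#' @export
generate_layered_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_spots; K <- cfg$n_domains; G <- cfg$n_genes

  nrow_g <- ceiling(sqrt(n))
  ncol_g <- ceiling(n / nrow_g)
  if (cfg$geometry == "bands" && nrow_g < K) {
    stop(sprintf("grid height %d cannot hold %d bands", nrow_g, K))
  }
  cells <- seq_len(n) - 1L
  xs <- cells %% ncol_g + 1L
  ys <- cells %/% ncol_g + 1L

  if (cfg$geometry == "bands") {
    dom <- pmin(K, ceiling(ys / (nrow_g / K)))
  } else {
    r <- sqrt((xs - mean(xs))^2 + (ys - mean(ys))^2)
    br <- stats::quantile(r, probs = seq(0, 1, length.out = K + 1))
    dom <- as.integer(cut(r, breaks = unique(br), include.lowest = TRUE))
    dom <- pmin(dom, K)
  }

  markers <- split(seq_len(K * cfg$n_markers_per_domain),
                   rep(seq_len(K), each = cfg$n_markers_per_domain))
  mu <- matrix(cfg$baseline, n, G)
  for (d in seq_len(K)) {
    mu[dom == d, markers[[d]]] <- cfg$baseline * exp(cfg$effect)
  }

  counts <- if (cfg$noise == "poisson") {
    matrix(stats::rpois(n * G, mu), n, G)
  } else {
    matrix(stats::rnbinom(n * G, mu = mu, size = cfg$theta), n, G)
  }
  if (cfg$dropout > 0) {
    counts <- counts * matrix(stats::rbinom(n * G, 1, 1 - cfg$dropout), n, G)
  }

  spot_ids <- sprintf("spot%04d", seq_len(n))
  gene_ids <- sprintf("gene%03d", seq_len(G))
  rownames(counts) <- spot_ids
  colnames(counts) <- gene_ids
  list(counts = expression_matrix(counts, layer = "raw"),
       coords = spot_coordinates(cbind(x = as.numeric(xs), y = as.numeric(ys)),
                                 spot_ids = spot_ids),
       truth = domain_labels(dom, K = K, refined = FALSE, spot_ids = spot_ids),
       marker_genes = lapply(markers, function(i) gene_ids[i]))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions via the standard
#' pair-counting formula: `(Index - E[Index]) / (MaxIndex - E[Index])` over
#' the contingency table of the two labelings. 1 for identical partitions,
#' about 0 for independent ones.
#'
#' @param labels,truth [domain_labels()] objects or integer vectors of equal
#'   length.
#' @return A real number in \[-1, 1\].
#' @export
score_ari <- function(labels, truth) {
  a <- if (inherits(labels, "domain_labels")) labels$labels else as.integer(labels)
  b <- if (inherits(truth, "domain_labels")) truth$labels else as.integer(truth)
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
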