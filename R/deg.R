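#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction: with the p-values sorted
#' ascending, `adj_i = min_{j >= i} (p_j * m / j)` clipped at 1, returned in
#' the input order (delegates to [stats::p.adjust()] after validating the
#' input range).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' One-vs-rest Wilcoxon marker detection
#'
#' For each spatial domain and each gene, a two-sided Wilcoxon rank-sum test
#' of the spots in the domain against all other spots. For combined sample
#' sizes below 20 (and tie-free data) the exact null distribution is used via
#' [stats::wilcox.test()]; otherwise a vectorised tie-corrected normal
#' approximation of the rank-sum statistic. P-values are BH-adjusted per
#' domain (each domain's gene family is corrected separately). The reported
#' log2 fold change is computed on `expm1`-backtransformed means with a small
#' pseudocount.
#'
#' @param norm an [expression_matrix()] with `layer = "normalized"`.
#' @param labels a [domain_labels()] aligned with `norm`.
#' @param min_cells domains with fewer spots are skipped with a warning.
#' @return A `data.frame` (class `deg_table`) with columns `gene_id`,
#'   `domain`, `log2_fc`, `statistic` (z score, positive = up in domain),
#'   `p_value`, `p_adj`, sorted within domain by adjusted then raw p.
#' @export
wilcoxon_deg <- function(norm, labels, min_cells = 3L) {
  stopifnot(inherits(norm, "expression_matrix"))
  if (norm$layer != "normalized") stop("wilcoxon_deg expects layer = 'normalized'")
  lab <- if (inherits(labels, "domain_labels")) labels$labels else as.integer(labels)
  v <- norm$values
  if (length(lab) != nrow(v)) stop("labels and expression matrix must be aligned")
  n <- nrow(v); G <- ncol(v)
  doms <- sort(unique(lab))
  counts <- table(factor(lab, levels = doms))
  skip <- doms[counts < min_cells]
  if (length(skip)) {
    warning(sprintf("skipping domain(s) below min_cells = %d: %s",
                    min_cells, paste(skip, collapse = ", ")))
    doms <- setdiff(doms, skip)
  }
  if (!length(doms)) stop("no domain has at least min_cells spots")

  # rank once per gene; reuse across the one-vs-rest comparisons
  ranks <- apply(v, 2, rank)
  tie_term <- apply(ranks, 2, function(r) {
    t <- table(r); sum(t^3 - t)
  })

  out <- vector("list", length(doms))
  for (di in seq_along(doms)) {
    d <- doms[di]
    in_d <- lab == d
    n1 <- sum(in_d); n2 <- n - n1
    if (n < 20) {
      res <- apply(v, 2, function(x) {
        wt <- suppressWarnings(
          stats::wilcox.test(x[in_d], x[!in_d], exact = TRUE, correct = FALSE))
        c(p = wt$p.value, U = unname(wt$statistic))
      })
      p <- res["p", ]
      U <- res["U", ]
      mu <- n1 * n2 / 2
      sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
      z <- ifelse(sigma > 0, (U - mu) / sigma, 0)
    } else {
      W <- colSums(ranks[in_d, , drop = FALSE])
      U <- W - n1 * (n1 + 1) / 2
      mu <- n1 * n2 / 2
      sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
      z <- ifelse(sigma > 0, (U - mu) / sigma, 0)
      p <- 2 * stats::pnorm(-abs(z))
    }
    # expm1 back-transform; clamp at zero so the ratio stays in log2's domain
    m1 <- pmax(colMeans(expm1(v[in_d, , drop = FALSE])), 0)
    m0 <- pmax(colMeans(expm1(v[!in_d, , drop = FALSE])), 0)
    lfc <- log2((m1 + 1e-9) / (m0 + 1e-9))
    tab <- data.frame(gene_id = norm$gene_ids, domain = d, log2_fc = lfc,
                      statistic = z, p_value = pmin(p, 1),
                      p_adj = bh_adjust(pmin(p, 1)), row.names = NULL)
    out[[di]] <- tab[order(tab$p_adj, tab$p_value), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("deg_table", "data.frame")
  res
}
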