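# Single-cell co-expression screen: detection filters, dot-plot statistics,
# pairwise Pearson correlation of log2(count+1) values with a cell-level
# bootstrap, and a genome-wide percentile rank of a candidate pair against
# all other detected transcripts.

.as_counts <- function(m) {
  if (is.list(m) && !is.null(m$counts)) m$counts else as.matrix(m)
}

.check_gene <- function(counts, gene) {
  if (!gene %in% rownames(counts)) stop("gene '", gene, "' absent from matrix")
}

#' Restrict to cell types expressing an anchor gene
#'
#' Returns the cells belonging to clusters in which the anchor gene is
#' detected (count > 0) in at least `min_pct` percent of cells. The 10%
#' boundary is inclusive: a cluster at exactly 10% detection is retained.
#'
#' @param m Count matrix (genes x cells, dimnames set) or the list returned
#'   by [gen_count_matrix()].
#' @param labels Per-cell cluster labels (same order as columns).
#' @param anchor_gene Gene whose expressing cell types define the subset.
#' @param min_pct Detection threshold in percent (default 10).
#' @return Character vector of retained cell ids (possibly empty).
#' @export
filter_expressing_celltypes <- function(m, labels, anchor_gene, min_pct = 10) {
  counts <- .as_counts(m)
  if (is.list(m) && is.null(labels)) labels <- m$clusters
  stopifnot(length(labels) == ncol(counts))
  .check_gene(counts, anchor_gene)
  det <- counts[anchor_gene, ] > 0
  pct <- tapply(det, labels, function(x) 100 * mean(x))
  keep_clusters <- names(pct)[pct >= min_pct]
  colnames(counts)[labels %in% keep_clusters]
}

#' Dot-plot statistics per gene and cluster
#'
#' For each requested gene and cluster: the percentage of cells with a
#' nonzero count (dot radius) and the mean centred/scaled log-normalised
#' expression (dot colour; library-size normalisation to 10^4, `log1p`,
#' then per-gene z-scaling across all cells). Genes detected in fewer than
#' `hide_below_pct` percent of the cells of every cluster are flagged hidden.
#'
#' @inheritParams filter_expressing_celltypes
#' @param genes Genes to tabulate.
#' @param hide_below_pct Visualisation threshold in percent.
#' @return `data.frame` with `gene`, `cluster`, `pct_expressing`,
#'   `mean_scaled`, `hidden`.
#' @export
dotplot_stats <- function(m, labels, genes, hide_below_pct = 10) {
  counts <- .as_counts(m)
  if (is.list(m) && is.null(labels)) labels <- m$clusters
  stopifnot(length(labels) == ncol(counts))
  for (g in genes) .check_gene(counts, g)
  libsize <- pmax(colSums(counts), 1)
  out <- list()
  for (g in genes) {
    x <- counts[g, ]
    lognorm <- log1p(x / libsize * 1e4)
    s <- stats::sd(lognorm)
    scaled <- if (s > 0) (lognorm - mean(lognorm)) / s else lognorm * 0
    pct <- tapply(x > 0, labels, function(v) 100 * mean(v))
    msc <- tapply(scaled, labels, mean)
    out[[g]] <- data.frame(gene = g, cluster = names(pct),
                           pct_expressing = as.numeric(pct),
                           mean_scaled = as.numeric(msc[names(pct)]),
                           hidden = all(pct < hide_below_pct),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.log2p1 <- function(x) log2(x + 1)

#' Pearson correlation of two genes with a cell-level bootstrap
#'
#' The point estimate is the Pearson correlation of `log2(count + 1)` values
#' across the selected cells. Cells (the individual observations) are then
#' resampled with replacement `n_boot` times; the bootstrap distribution is
#' summarised box-plot style with quartile hinges and whiskers extending to
#' the last resample within 1.5 interquartile ranges of the hinges.
#'
#' @inheritParams filter_expressing_celltypes
#' @param cells Cell ids (or indices) to use; `NULL` for all.
#' @param geneA,geneB Gene pair.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Optional integer seed (same seed, same result).
#' @return List of class `"kv_coexpr"`: `pcc`, `boot` (resampled PCCs),
#'   `hinges` (25/50/75% quantiles), `whiskers`, `n_cells`,
#'   `percentile = NA` (see [pcc_percentile()]).
#' @export
pcc_with_bootstrap <- function(m, cells = NULL, geneA, geneB, n_boot = 100,
                               seed = NULL) {
  counts <- .as_counts(m)
  .check_gene(counts, geneA); .check_gene(counts, geneB)
  if (is.null(cells)) cells <- colnames(counts)
  if (length(cells) < 3L) stop("need at least 3 cells")
  x <- .log2p1(counts[geneA, cells])
  y <- .log2p1(counts[geneB, cells])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: a gene is constant on the selected cells")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
    stats::cor(x[idx], y[idx])
  }, numeric(1L))
  boot_ok <- boot[!is.na(boot)]
  hinges <- stats::quantile(boot_ok, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- hinges[3L] - hinges[1L]
  lo_lim <- hinges[1L] - 1.5 * iqr
  hi_lim <- hinges[3L] + 1.5 * iqr
  whiskers <- c(min(boot_ok[boot_ok >= lo_lim]), max(boot_ok[boot_ok <= hi_lim]))
  structure(list(pcc = stats::cor(x, y), boot = boot, hinges = hinges,
                 whiskers = whiskers, n_cells = n, n_boot = n_boot,
                 geneA = geneA, geneB = geneB, percentile = NA_real_),
            class = "kv_coexpr")
}

#' @export
print.kv_coexpr <- function(x, ...) {
  cat(sprintf("PCC(%s, %s) = %.3f on %d cells", x$geneA, x$geneB, x$pcc,
              x$n_cells))
  if (!is.na(x$percentile)) {
    cat(sprintf("; above %.1f%% of %d other transcripts", x$percentile,
                x$n_genes_compared))
  }
  cat("\n")
  invisible(x)
}

#' Genome-wide percentile rank of a gene pair's correlation
#'
#' Computes the Pearson correlation (on `log2(count + 1)` values) of the
#' anchor gene with every other gene detected in at least
#' `min_cells_detected` cells and with nonzero variance on the selected
#' cells, and ranks the candidate partner within that set: the percentile is
#' `100 x (# genes with PCC strictly below PCC(geneA, geneB)) / (# genes
#' compared)`; ties count as not below. The partner itself is part of the
#' comparison set, so a perfect duplicate tops out at `100 (n-1)/n`.
#'
#' @inheritParams pcc_with_bootstrap
#' @param min_cells_detected Detection floor for genes entering the null set.
#' @return As [pcc_with_bootstrap()] without bootstrap fields, plus
#'   `percentile`, `n_genes_compared`, and `null_pcc` (named vector).
#' @export
pcc_percentile <- function(m, cells = NULL, geneA, geneB,
                           min_cells_detected = 3) {
  counts <- .as_counts(m)
  .check_gene(counts, geneA); .check_gene(counts, geneB)
  if (is.null(cells)) cells <- colnames(counts)
  if (length(cells) < 3L) stop("need at least 3 cells")
  sub <- counts[, cells, drop = FALSE]
  x <- .log2p1(sub[geneA, ])
  if (stats::sd(x) == 0) stop("anchor gene is constant on the selected cells")
  others <- setdiff(rownames(sub), geneA)
  detected <- rowSums(sub[others, , drop = FALSE] > 0) >= min_cells_detected
  lm2 <- .log2p1(t(sub[others[detected], , drop = FALSE]))
  vars <- apply(lm2, 2L, stats::var)
  comparable <- colnames(lm2)[vars > 0]
  if (length(comparable) < 10L) {
    stop("fewer than 10 comparable genes for the percentile null")
  }
  if (!geneB %in% comparable) {
    stop("gene '", geneB, "' is not comparable (undetected or constant)")
  }
  r <- as.numeric(stats::cor(x, lm2[, comparable, drop = FALSE]))
  names(r) <- comparable
  pcc_ab <- r[[geneB]]
  structure(list(pcc = pcc_ab,
                 percentile = 100 * sum(r < pcc_ab) / length(r),
                 n_genes_compared = length(r), null_pcc = r,
                 n_cells = length(cells), geneA = geneA, geneB = geneB),
            class = "kv_coexpr")
}
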