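# Synthetic single-cell gene-count matrices with cluster structure and
# planted gene-gene correlation. Counts are negative binomial around
# cluster-specific mean profiles; a planted pair shares a bivariate-Gaussian
# latent log-mean with a stated correlation, every other gene carries an
# independent latent, so decoys form a genuine null for the percentile screen.

#' Generate a clustered count matrix with planted correlated gene pairs
#'
#' @param n_genes Total number of genes (planted genes included).
#' @param cells_per_cluster Integer vector, cells in each cluster (all >= 1).
#' @param planted_pairs List of `list(geneA =, geneB =, corr =)` entries;
#'   genes may be referenced by index or by name (`"gene0001"` style names are
#'   assigned). `corr` is the latent log-mean correlation in `[-1, 1]`.
#' @param dispersion Negative-binomial dispersion (counts have
#'   `size = 1/dispersion`); 0 gives Poisson.
#' @param latent_sd SD of the per-cell latent log-mean fluctuation shared
#'   structure (natural-log scale).
#' @param mean_log_range Range of cluster-level mean expression drawn per gene
#'   per cluster, on the log scale (natural log of expected counts).
#' @param zero_genes Optional gene indices/names given an all-zero mean
#'   profile (never detected; useful as hidden-gene fixtures).
#' @param seed Optional integer seed.
#' @return List with `counts` (integer matrix genes x cells, dimnames set),
#'   `gene_ids`, `cell_ids`, `clusters` (character vector per cell), and
#'   `truth` (planted pairs plus generator parameters).
#' @examples
#' sim <- gen_count_matrix(50, c(30, 30),
#'                         planted_pairs = list(list(geneA = 1, geneB = 2,
#'                                                   corr = 0.9)),
#'                         seed = 1)
#' dim(sim$counts)
#' @export
gen_count_matrix <- function(n_genes, cells_per_cluster,
                             planted_pairs = list(), dispersion = 0.5,
                             latent_sd = 1, mean_log_range = log(c(0.5, 20)),
                             zero_genes = NULL, seed = NULL) {
  stopifnot(n_genes >= 1, length(cells_per_cluster) >= 1)
  if (any(cells_per_cluster < 1)) stop("empty clusters are not allowed")
  if (!is.null(seed)) set.seed(seed)

  n_cells <- sum(cells_per_cluster)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  clusters <- rep(sprintf("cluster%d", seq_along(cells_per_cluster)),
                  cells_per_cluster)

  resolve <- function(g) {
    if (is.numeric(g)) return(gene_ids[g])
    i <- match(g, gene_ids)
    if (is.na(i)) stop("unknown gene: ", g)
    gene_ids[i]
  }
  pairs <- lapply(planted_pairs, function(p) {
    if (abs(p$corr) > 1) stop("latent_corr must lie in [-1, 1]")
    list(geneA = resolve(p$geneA), geneB = resolve(p$geneB), corr = p$corr)
  })
  planted_genes <- unlist(lapply(pairs, function(p) c(p$geneA, p$geneB)))
  if (anyDuplicated(planted_genes)) stop("a gene may appear in one planted pair only")

  # cluster-level baseline log-means; planted genes get the upper half of the
  # range in every cluster so detection filters retain them
  log_mu <- matrix(runif(n_genes * length(cells_per_cluster),
                         mean_log_range[1L], mean_log_range[2L]),
                   nrow = n_genes)
  log_mu[gene_ids %in% planted_genes, ] <-
    runif(sum(gene_ids %in% planted_genes) * length(cells_per_cluster),
          mean(mean_log_range), mean_log_range[2L])

  # per-cell latent fluctuations: independent for all genes, then overwritten
  # with correlated draws for planted pairs
  z <- matrix(rnorm(n_genes * n_cells), nrow = n_genes,
              dimnames = list(gene_ids, cell_ids))
  for (p in pairs) {
    z1 <- rnorm(n_cells)
    z2 <- p$corr * z1 + sqrt(1 - p$corr^2) * rnorm(n_cells)
    z[p$geneA, ] <- z1
    z[p$geneB, ] <- z2
  }

  cl_idx <- rep(seq_along(cells_per_cluster), cells_per_cluster)
  mu <- exp(log_mu[, cl_idx, drop = FALSE] + latent_sd * z)
  if (!is.null(zero_genes)) {
    zg <- vapply(as.list(zero_genes), resolve, character(1L))
    mu[match(zg, gene_ids), ] <- 0
  }
  counts <- if (dispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), nrow = n_genes)
  } else {
    matrix(rpois(length(mu), lambda = mu), nrow = n_genes)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, cell_ids)

  list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
       clusters = clusters,
       truth = list(planted_pairs = pairs, dispersion = dispersion,
                    latent_sd = latent_sd, log_mu = log_mu))
}
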