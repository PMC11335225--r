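# Synthetic plate-assay tables: RT-qPCR Cq values (one doubling per cycle,
# technical duplicates, per-sample loading offsets that reference-gene
# normalization must cancel) and oocyte surface-expression luminescence
# (per-experiment multiplicative batch factors that per-experiment
# normalization must cancel).

#' Generate a synthetic Cq table
#'
#' Cq values follow `Cq = cq_const - log2(abundance) + sample_shift + noise`
#' (one cycle per doubling of template). Reference genes share the same
#' per-sample shift, so reference normalization recovers the planted
#' abundance ratios exactly at zero noise. Genes with `NA` abundance are
#' emitted as non-detects (missing Cq).
#'
#' @param true_rel_abundance Named numeric vector of relative template
#'   abundances (> 0, or `NA` for non-detect genes). Reference genes must be
#'   included and detected.
#' @param ref_genes Character vector of reference-gene names.
#' @param n_samples Biological samples per tissue (each run in technical
#'   duplicate: two rows per gene and sample).
#' @param noise_sd_cycles Gaussian noise SD on Cq, in cycles.
#' @param sample_shift_sd SD of the per-sample loading offset (cycles),
#'   applied to every gene of a sample.
#' @param cq_const Cq of a gene at abundance 1 in an unshifted sample.
#' @param tissue Tissue label for the output rows.
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `tissue`, `gene`, `sample`, `replicate`,
#'   `cq` (NA for non-detects), plus attribute `"truth"`.
#' @export
gen_cq_table <- function(true_rel_abundance, ref_genes, n_samples = 8,
                         noise_sd_cycles = 0.2, sample_shift_sd = 1,
                         cq_const = 28, tissue = "tissue", seed = NULL) {
  stopifnot(!is.null(names(true_rel_abundance)), n_samples >= 1)
  if (!all(ref_genes %in% names(true_rel_abundance))) {
    stop("all reference genes must appear in true_rel_abundance")
  }
  if (anyNA(true_rel_abundance[ref_genes])) {
    stop("reference genes must not be non-detect")
  }
  detected <- !is.na(true_rel_abundance)
  if (any(true_rel_abundance[detected] <= 0)) {
    stop("abundances must be > 0 (or NA to flag non-detect)")
  }
  if (!is.null(seed)) set.seed(seed)

  genes <- names(true_rel_abundance)
  shifts <- rnorm(n_samples, sd = sample_shift_sd)
  rows <- expand.grid(replicate = 1:2, sample = seq_len(n_samples),
                      gene = genes, stringsAsFactors = FALSE)
  rows <- rows[, c("gene", "sample", "replicate")]
  ab <- true_rel_abundance[rows$gene]
  cq <- cq_const - log2(ab) + shifts[rows$sample] +
    rnorm(nrow(rows), sd = noise_sd_cycles)
  out <- data.frame(tissue = tissue, gene = rows$gene,
                    sample = sprintf("s%02d", rows$sample),
                    replicate = rows$replicate, cq = as.numeric(cq),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(true_rel_abundance = true_rel_abundance,
                             sample_shifts = shifts, cq_const = cq_const)
  out
}

#' Generate a synthetic oocyte luminescence (RLU) table
#'
#' Group means are absolute expected luminescence; the background
#' (`background_group`, by default added as `"uninjected"` with mean
#' `background_mean`) represents non-specific signal present in every group.
#' Each experiment carries a multiplicative batch factor (lognormal,
#' `batch_sd`); per-oocyte Gaussian noise is added on top. With
#' `batch_sd = 0` and `noise_sd = 0` measured values equal the group means
#' exactly.
#'
#' @param group_means Named numeric vector of expected RLU per group,
#'   including the Kv7-alone control group.
#' @param n_oocytes_per_group Oocytes per group per experiment (>= 2).
#' @param background_mean Expected RLU of uninjected oocytes.
#' @param noise_sd Per-oocyte Gaussian noise SD (RLU).
#' @param n_experiments Number of independent experiments.
#' @param batch_sd Lognormal sdlog of the per-experiment batch factor.
#' @param background_group Name for the uninjected group.
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `experiment`, `group`, `oocyte`, `rlu`,
#'   plus attribute `"truth"` (group means, background, batch factors).
#' @export
gen_rlu_table <- function(group_means, n_oocytes_per_group = 20,
                          background_mean = 50, noise_sd = 0,
                          n_experiments = 3, batch_sd = 0.25,
                          background_group = "uninjected", seed = NULL) {
  stopifnot(!is.null(names(group_means)), n_experiments >= 1)
  if (n_oocytes_per_group < 2) stop("need at least 2 oocytes per group")
  if (!is.null(seed)) set.seed(seed)
  all_means <- c(group_means,
                 stats::setNames(background_mean, background_group))
  if (anyDuplicated(names(all_means))) stop("duplicate group names")
  batch <- exp(rnorm(n_experiments, sd = batch_sd))
  rows <- expand.grid(oocyte = seq_len(n_oocytes_per_group),
                      group = names(all_means),
                      experiment = seq_len(n_experiments),
                      stringsAsFactors = FALSE)
  rlu <- batch[rows$experiment] * all_means[rows$group] +
    rnorm(nrow(rows), sd = noise_sd)
  out <- data.frame(experiment = sprintf("exp%d", rows$experiment),
                    group = rows$group,
                    oocyte = sprintf("exp%d_%s_oo%02d", rows$experiment,
                                     rows$group, rows$oocyte),
                    rlu = pmax(as.numeric(rlu), 0), stringsAsFactors = FALSE)
  attr(out, "truth") <- list(group_means = all_means,
                             background_group = background_group,
                             batch_factors = batch)
  out
}
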