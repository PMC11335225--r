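# Stage orchestration: JSON run configs, a stage dispatcher, and a run
# manifest for provenance. All randomness flows from the config seed; every
# stochastic stage refuses to run without one.

#' Read a JSON run configuration
#'
#' A config has `stage`, `seed` (required for stochastic stages), `out_dir`,
#' and a free-form `params` list; it round-trips losslessly through JSON.
#'
#' @param path JSON file.
#' @return The config list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$stage)) stop("config is missing the 'stage' field")
  cfg
}

.write_manifest <- function(out_dir, cfg, outputs) {
  manifest <- list(
    stage = cfg$stage, seed = cfg$seed, params = cfg$params,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("silentkv")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run a pipeline stage from a configuration
#'
#' Stages: `"synth_recordings"` (generate recordings, write CSV + sidecar),
#' `"ephys"` (QC filter, tail extraction, Boltzmann fits, density table from
#' a recordings CSV), `"synth_counts"` (count matrix to MTX + TSV),
#' `"coexpr"` (percentile screen on an MTX input), `"assembly_predict"`,
#' `"assembly_fit"`, `"assembly_modes"` (co-assembly model tables), and
#' `"demo"` (synthetic recordings -> ephys -> preference fit, end to end).
#' Outputs and a machine-readable `run_manifest.json` (parameters, seed,
#' versions) are written to `out_dir`; identical config and seed give
#' identical numeric outputs.
#'
#' @param cfg Config list or path to a JSON config (see [read_run_config()]).
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(cfg) {
  # species specs arrive as a list of lists or (from simplified JSON) a
  # data.frame; normalise to a kv_mix either way
  mix_from <- function(spec) {
    if (is.data.frame(spec)) {
      rows <- lapply(seq_len(nrow(spec)), function(i) as.list(spec[i, ]))
    } else {
      rows <- spec
    }
    do.call(kv_mix, lapply(rows, function(sp) do.call(kv_species, sp)))
  }
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(cfg$stage)) stop("config is missing the 'stage' field")
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params %||% list()
  stochastic <- c("synth_recordings", "synth_counts", "demo")
  if (cfg$stage %in% stochastic && is.null(cfg$seed)) {
    stop("stage '", cfg$stage, "' is stochastic and requires an explicit seed")
  }

  outputs <- switch(
    cfg$stage,
    synth_recordings = {
      gating <- do.call(gating_params, p$gating %||% list())
      protocol <- do.call(voltage_protocol, p$protocol %||% list())
      recs <- gen_recordings(gating, protocol,
                             n_cells = p$n_cells %||% 10L,
                             noise_sd = p$noise_sd %||% 10,
                             group = p$group %||% "group1",
                             seed = cfg$seed)
      write_recordings_csv(recs, file.path(out_dir, "recordings.csv"))
    },
    ephys = {
      recs <- read_recordings_csv(p$recordings_csv)
      qc <- qc_filter(recs)
      fits <- lapply(qc$kept, function(r) {
        ta <- extract_tail_amplitudes(r)
        ft <- fit_boltzmann(ta$voltage, ta$amplitude)
        data.frame(cell = r$meta$id, group = r$meta$group, Vh = ft$Vh,
                   s = ft$s, I_min = ft$I_min, I_max = ft$I_max,
                   density_20mV = steady_state_density(r, p$at %||% 20))
      })
      fits <- do.call(rbind, fits)
      fit_path <- file.path(out_dir, "boltzmann_fits.tsv")
      utils::write.table(fits, fit_path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      qc_path <- file.path(out_dir, "qc_exclusions.tsv")
      utils::write.table(qc$log, qc_path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      c(fits = fit_path, qc = qc_path)
    },
    synth_counts = {
      sim <- gen_count_matrix(
        n_genes = p$n_genes %||% 200L,
        cells_per_cluster = p$cells_per_cluster %||% c(100L, 100L),
        planted_pairs = p$planted_pairs %||% list(),
        seed = cfg$seed)
      unlist(write_counts_mtx(sim, out_dir))
    },
    coexpr = {
      sim <- read_counts_mtx(p$mtx, p$genes, p$cells, p$clusters)
      cells <- if (!is.null(sim$clusters)) {
        filter_expressing_celltypes(sim$counts, sim$clusters, p$anchor,
                                    min_pct = p$min_pct %||% 10)
      } else colnames(sim$counts)
      res <- pcc_percentile(sim$counts, cells, p$anchor, p$partner)
      boot <- pcc_with_bootstrap(sim$counts, cells, p$anchor, p$partner,
                                 seed = cfg$seed %||% 1L)
      out <- file.path(out_dir, "coexpr_summary.json")
      jsonlite::write_json(
        list(anchor = p$anchor, partner = p$partner, pcc = res$pcc,
             percentile = res$percentile,
             n_genes_compared = res$n_genes_compared,
             boot_hinges = boot$hinges, boot_whiskers = boot$whiskers,
             n_cells = res$n_cells),
        out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(summary = out)
    },
    assembly_predict = {
      mix <- mix_from(p$mix)
      rule <- assembly_rule(p$variant %||% "stochastic", p$f %||% 1)
      cond <- conductance_rule(p$mode %||% "single_pore_heteromer",
                               standalone_kvs_conductance = p$kvs_g %||% 0)
      pred <- predict_relative_current(mix, rule, cond,
                                       p$baseline %||% "wt_mix")
      out <- file.path(out_dir, "prediction.json")
      jsonlite::write_json(unclass(pred), out, auto_unbox = TRUE, digits = NA)
      c(prediction = out)
    },
    assembly_modes = {
      mix <- mix_from(p$mix)
      rule <- assembly_rule(p$variant %||% "stochastic", p$f %||% 1)
      tab <- compare_modes(mix, rule,
                           conductance_rule(
                             standalone_kvs_conductance = p$kvs_g %||% 0),
                           baseline = p$baseline %||% "wt_mix")
      out <- file.path(out_dir, "modes.tsv")
      utils::write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
      c(modes = out)
    },
    assembly_fit = {
      mix <- mix_from(p$mix)
      res <- fit_preference(p$observed, mix, p$variant,
                            baseline = p$baseline %||% "wt_mix")
      out <- file.path(out_dir, "preference_fit.json")
      jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
      c(fit = out)
    },
    demo = {
      # end-to-end: simulate two cohorts, analyse, fit a preference factor
      # from the recovered relative density
      seed <- cfg$seed
      proto <- voltage_protocol()
      wt <- gen_recordings(gating_params(g_max = 4), proto, n_cells = 8L,
                           noise_sd = 5, group = "wt_pair", seed = seed)
      dn <- gen_recordings(gating_params(g_max = 2), proto, n_cells = 8L,
                           noise_sd = 5, group = "kvs_pore_dead",
                           seed = seed + 1L)
      recs <- qc_filter(c(wt, dn))$kept
      dens <- do.call(rbind, lapply(recs, function(r) {
        data.frame(cell = r$meta$id, group = r$meta$group,
                   value = steady_state_density(r, 20))
      }))
      gs <- group_summary(dens, reference_group = "wt_pair")
      observed <- gs$summary$norm_mean[gs$summary$group == "kvs_pore_dead"]
      mix <- kv_mix(kv_species("Kv7.2", "KV7"),
                    kv_species("Kv8.1dn", "KVS", pore_functional = FALSE),
                    equalize = TRUE)
      fit <- tryCatch(
        fit_preference(observed, mix, "per_site"),
        error = function(e) list(error = conditionMessage(e)))
      out <- file.path(out_dir, "demo_summary.json")
      jsonlite::write_json(list(group_summary = gs$summary,
                                observed_ratio = observed,
                                preference_fit = fit),
                           out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(demo = out)
    },
    stop("unknown stage: ", cfg$stage)
  )
  .write_manifest(out_dir, cfg, as.list(outputs))
  invisible(outputs)
}
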