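# Format readers/writers: Matrix Market count matrices with gene/cell/cluster
# TSV sidecars, long-format recording CSVs with a JSON truth sidecar, and
# two-channel TIFF image pairs. MTX coordinates are 1-based on disk and
# converted at the boundary.

#' Read a count matrix from Matrix Market + TSV sidecars
#'
#' @param mtx_path Path to the MTX file (genes x cells, integer counts).
#' @param genes_path,cells_path One-column TSV files (no header) with gene /
#'   cell identifiers.
#' @param clusters_path Optional TSV with per-cell cluster labels (one per
#'   cell, same order).
#' @return List with `counts` (integer matrix with dimnames), `gene_ids`,
#'   `cell_ids`, and `clusters` (or `NULL`).
#' @export
read_counts_mtx <- function(mtx_path, genes_path, cells_path,
                            clusters_path = NULL) {
  m <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop(sprintf("dimension mismatch: matrix %d x %d vs %d genes, %d cells",
                 nrow(m), ncol(m), length(genes), length(cells)))
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  dense <- as.matrix(m)
  if (any(dense != round(dense)) || any(dense < 0)) {
    stop("counts must be nonnegative integers")
  }
  storage.mode(dense) <- "integer"
  dimnames(dense) <- list(genes, cells)
  clusters <- NULL
  if (!is.null(clusters_path)) {
    clusters <- readLines(clusters_path)
    if (length(clusters) != length(cells)) {
      stop("cluster labels do not match number of cells")
    }
  }
  list(counts = dense, gene_ids = genes, cell_ids = cells,
       clusters = clusters)
}

#' Write a count matrix as Matrix Market + TSV sidecars
#'
#' @param sim A list with `counts`, `gene_ids`, `cell_ids`, optionally
#'   `clusters` (as from [gen_count_matrix()]).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_counts_mtx <- function(sim, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    mtx = file.path(dir, paste0(prefix, ".mtx")),
    genes = file.path(dir, paste0(prefix, "_genes.tsv")),
    cells = file.path(dir, paste0(prefix, "_cells.tsv")))
  Matrix::writeMM(Matrix::Matrix(sim$counts, sparse = TRUE), paths$mtx)
  writeLines(sim$gene_ids, paths$genes)
  writeLines(sim$cell_ids, paths$cells)
  if (!is.null(sim$clusters)) {
    paths$clusters <- file.path(dir, paste0(prefix, "_clusters.tsv"))
    writeLines(sim$clusters, paths$clusters)
  }
  invisible(paths)
}

#' Write recordings as long-format CSV with a JSON truth sidecar
#'
#' Columns: `cell`, `step_mV`, `time_ms`, `pA`. The sidecar stores the
#' protocol, per-cell metadata, and the ground-truth gating parameters.
#'
#' @param recordings List from [gen_recordings()].
#' @param csv_path Output CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return Invisibly, the two paths.
#' @export
write_recordings_csv <- function(recordings, csv_path) {
  long <- do.call(rbind, lapply(recordings, function(rec) {
    data.frame(cell = rec$meta$id,
               step_mV = rep(rec$protocol$step_levels,
                             each = nrow(rec$sweeps)),
               time_ms = rep(rec$time_ms, ncol(rec$sweeps)),
               pA = as.numeric(rec$sweeps))
  }))
  utils::write.csv(long, csv_path, row.names = FALSE)
  sidecar <- paste0(csv_path, ".json")
  meta <- list(
    protocol = unclass(recordings[[1L]]$protocol),
    truth = unclass(recordings[[1L]]$truth),
    cells = lapply(recordings, function(r) r$meta))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = sidecar))
}

#' Read recordings written by [write_recordings_csv()]
#' @param csv_path Path to the CSV (expects `<path>.json` sidecar).
#' @return List of recordings in the in-memory format of [gen_recordings()].
#' @export
read_recordings_csv <- function(csv_path) {
  long <- utils::read.csv(csv_path)
  meta <- jsonlite::read_json(paste0(csv_path, ".json"),
                              simplifyVector = FALSE)
  protocol <- do.call(voltage_protocol,
                      lapply(meta$protocol, function(x) unlist(x)))
  truth <- do.call(gating_params, meta$truth)
  cells_meta <- meta$cells
  lapply(split(long, long$cell), function(d) {
    sweeps <- matrix(d$pA, ncol = length(protocol$step_levels))
    colnames(sweeps) <- protocol$step_levels
    id <- d$cell[1L]
    cm <- Filter(function(m) identical(m$id, id), cells_meta)[[1L]]
    structure(list(sweeps = sweeps,
                   time_ms = d$time_ms[seq_len(nrow(sweeps))],
                   protocol = protocol,
                   meta = list(id = cm$id, Cm = cm$Cm, Rs = cm$Rs,
                               group = cm$group),
                   truth = truth),
              class = "kv_recording")
  })
}

#' Write a PLA image pair as two TIFF files
#'
#' Intensities are scaled into `[0, 1]` by `scale` (stored nowhere in the
#' TIFF; pass the same value when reading).
#'
#' @param pair A `"kv_pla_stack"`.
#' @param cells_path,dots_path Output TIFF paths.
#' @param scale Intensity divisor before writing.
#' @return Invisibly, the paths.
#' @export
write_pla_tiff <- function(pair, cells_path, dots_path, scale = NULL) {
  if (is.null(scale)) {
    scale <- max(pair$channel_cells, pair$channel_dots, 1e-9)
  }
  clip01 <- function(m) pmin(pmax(m / scale, 0), 1)
  tiff::writeTIFF(clip01(pair$channel_cells), cells_path, bits.per.sample = 16L)
  tiff::writeTIFF(clip01(pair$channel_dots), dots_path, bits.per.sample = 16L)
  invisible(c(cells = cells_path, dots = dots_path, scale = scale))
}

#' Read a PLA image pair from two TIFF files
#' @param cells_path,dots_path TIFF paths.
#' @param pixel_size Pixel size in micrometres.
#' @param scale Intensity multiplier applied after reading.
#' @return List with `channel_cells`, `channel_dots`, `pixel_size`.
#' @export
read_pla_tiff <- function(cells_path, dots_path, pixel_size = 0.2,
                          scale = 1) {
  structure(list(channel_cells = tiff::readTIFF(cells_path) * scale,
                 channel_dots = tiff::readTIFF(dots_path) * scale,
                 pixel_size = pixel_size),
            class = "kv_pla_stack")
}
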