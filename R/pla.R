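# PLA image quantification: segment immunopositive cells from the
# immunofluorescence channel by auto-thresholding, detect diffraction-limited
# PLA dots in the second channel, and count dots inside vs outside the cell
# boundaries. All steps are deterministic (no RNG).

#' Segment immunopositive cells by auto-thresholding
#'
#' Gaussian smoothing (sigma 2 px) -> Otsu threshold on the smoothed
#' histogram -> hole filling -> connected components -> discard components
#' below `min_area`. The Otsu threshold is computed over the image's own
#' intensity range, so adding a uniform offset leaves the masks unchanged.
#'
#' An image with no immunopositive cells has a unimodal intensity histogram,
#' which Otsu would still split down the middle; a separability guard
#' (Otsu's between-class variance as a fraction of total variance, which is
#' ~0.64 for pure Gaussian noise and ~1 for a well-separated foreground)
#' returns an empty mask set instead.
#'
#' @param pair A `"kv_pla_stack"` (or list with `channel_cells` matrix and
#'   `pixel_size`).
#' @param min_area Minimum cell area in square micrometres.
#' @param sigma Smoothing sigma in pixels.
#' @param min_separability Minimal between-class variance fraction for the
#'   threshold to count as foreground detection.
#' @return List of class `"kv_cell_masks"`: `mask` (integer label matrix,
#'   labels 1..n contiguous), `areas_um2`, `n_cells`, `threshold`.
#' @export
segment_cells <- function(pair, min_area = 50, sigma = 2,
                          min_separability = 0.8) {
  img <- pair$channel_cells
  stopifnot(is.matrix(img), length(img) > 0)
  px <- pair$pixel_size %||% 1
  sm <- EBImage::gblur(img, sigma = sigma)
  rng <- range(sm)
  if (diff(rng) == 0) {
    return(structure(list(mask = matrix(0L, nrow(img), ncol(img)),
                          areas_um2 = numeric(0), n_cells = 0L,
                          threshold = rng[1L]),
                     class = "kv_cell_masks"))
  }
  thr <- EBImage::otsu(EBImage::Image(sm), range = rng, levels = 256L)
  bin <- sm > thr
  w1 <- mean(bin)
  sep <- if (w1 %in% c(0, 1)) 0 else
    w1 * (1 - w1) * (mean(sm[bin]) - mean(sm[!bin]))^2 / stats::var(c(sm))
  if (sep < min_separability) {
    return(structure(list(mask = matrix(0L, nrow(img), ncol(img)),
                          areas_um2 = numeric(0), n_cells = 0L,
                          threshold = thr),
                     class = "kv_cell_masks"))
  }
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  lab <- EBImage::imageData(lab)
  min_px <- min_area / px^2
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(img), ncol(img))
  nz <- lab > 0
  out[nz] <- relabel[lab[nz]]
  structure(list(mask = out, areas_um2 = sizes[keep] * px^2,
                 n_cells = length(keep), threshold = thr),
            class = "kv_cell_masks")
}

#' @export
print.kv_cell_masks <- function(x, ...) {
  cat(sprintf("%d segmented cell(s); areas (um^2): %s\n", x$n_cells,
              paste(round(x$areas_um2, 1), collapse = ", ")))
  invisible(x)
}

#' Detect PLA dots
#'
#' Matched smoothing (Gaussian, `smooth_sigma`, matched to the punctum PSF)
#' -> white top-hat with a disc of radius `tophat_radius` (removes
#' background structure much larger than a punctum while barely attenuating
#' the smoothed spot peak) -> threshold at the top-hat image's mean + `k_sd`
#' standard deviations -> local maxima with a minimum separation. Returns
#' integer pixel coordinates. The default threshold (`k_sd = 5`) keeps
#' featureless images free of false detections (a max-statistics requirement
#' over ~10^4 candidate maxima); lower it for higher recall on dim spots at
#' the cost of false positives.
#'
#' @param pair A `"kv_pla_stack"` (or list with `channel_dots` matrix).
#' @param smooth_sigma Pre-smoothing sigma (px), matched to the punctum PSF.
#' @param tophat_radius Disc radius of the top-hat opening (px).
#' @param k_sd Threshold in SD units above the top-hat image mean.
#' @param min_sep Minimum separation between detected maxima (px).
#' @return `data.frame` with integer columns `x`, `y` (possibly 0 rows).
#' @export
detect_dots <- function(pair, smooth_sigma = 1.5, tophat_radius = 8,
                        k_sd = 5, min_sep = 2) {
  img <- pair$channel_dots
  stopifnot(is.matrix(img), length(img) > 0)
  sm <- if (smooth_sigma > 0) EBImage::gblur(img, sigma = smooth_sigma) else img
  brush <- EBImage::makeBrush(2L * tophat_radius + 1L, shape = "disc")
  th <- EBImage::imageData(EBImage::whiteTopHat(EBImage::Image(sm), brush))
  cut <- mean(th) + k_sd * stats::sd(th)
  sep_brush <- EBImage::makeBrush(2L * min_sep + 1L, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(th), sep_brush))
  maxima <- (th >= dil - 1e-12) & (th > cut)
  if (!any(maxima)) return(data.frame(x = integer(0), y = integer(0)))
  # plateaus of equal maxima collapse to their centroid
  lab <- EBImage::imageData(EBImage::bwlabel(maxima))
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  cx <- round(tapply(idx[, 1L], labs, mean))
  cy <- round(tapply(idx[, 2L], labs, mean))
  data.frame(x = as.integer(cx), y = as.integer(cy))
}

#' Count dots inside and outside segmented cells
#'
#' A dot belongs to cell k iff its integer coordinate lies on label k of the
#' mask (centre-pixel membership; PLA puncta are subcellular-scale).
#'
#' @param masks A `"kv_cell_masks"` from [segment_cells()].
#' @param dots `data.frame` with columns `x`, `y` from [detect_dots()].
#' @return List of class `"kv_pla_counts"`: `per_cell` (integer vector, one
#'   entry per cell label), `outside`, `total`.
#' @export
count_inside_outside <- function(masks, dots) {
  mask <- masks$mask
  if (nrow(dots)) {
    if (any(dots$x < 1 | dots$x > nrow(mask) |
            dots$y < 1 | dots$y > ncol(mask))) {
      stop("dot coordinate outside image bounds")
    }
  }
  labels_at <- if (nrow(dots)) mask[cbind(dots$x, dots$y)] else integer(0)
  per_cell <- tabulate(labels_at[labels_at > 0], nbins = masks$n_cells)
  structure(list(per_cell = per_cell, outside = sum(labels_at == 0L),
                 total = nrow(dots)),
            class = "kv_pla_counts")
}

#' Full PLA quantification pipeline
#'
#' [segment_cells()] then [detect_dots()] then [count_inside_outside()].
#'
#' @inheritParams segment_cells
#' @param ... Passed to [detect_dots()].
#' @return List with `masks`, `dots`, `counts`.
#' @export
pla_quantify <- function(pair, min_area = 50, ...) {
  masks <- segment_cells(pair, min_area = min_area)
  dots <- detect_dots(pair, ...)
  list(masks = masks, dots = dots,
       counts = count_inside_outside(masks, dots))
}
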