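# Synthetic two-channel PLA micrograph pairs with exact ground truth.
# Channel A emulates flag immunofluorescence: smooth elliptical cell bodies
# on a noisy background. Channel B emulates the PLA channel: diffraction-
# limited Gaussian puncta (sigma ~ 1.5 px) at recorded integer coordinates,
# some inside cells and some outside, under Poisson-Gaussian noise. The
# generator enforces non-overlapping cells and a minimum dot separation so a
# correct detector can recover the truth exactly on clean fixtures.

#' Generate a synthetic PLA image pair with ground truth
#'
#' @param n_cells Number of elliptical cells (0 allowed: blank cell channel).
#' @param dots_inside_per_cell PLA dots planted inside each cell.
#' @param dots_outside PLA dots planted on background.
#' @param image_size Image side length in pixels (square images).
#' @param pixel_size Pixel size in micrometres.
#' @param cell_radius Range (px) of ellipse semi-axes.
#' @param noise List of intensity parameters: `background` (baseline level),
#'   `noise_sd` (Gaussian read-noise SD, both channels), `cell_amplitude`
#'   (cell-body intensity), `dot_amplitude` (peak amplitude of a planted dot;
#'   SNR = dot_amplitude / noise_sd), `dot_sigma` (PSF sigma, px),
#'   `poisson_scale` (photons per intensity unit for Poisson shot noise;
#'   `NULL` disables).
#' @param min_dot_sep Minimum centre-to-centre dot distance (px).
#' @param seed Optional integer seed.
#' @return List of class `"kv_pla_stack"`: `channel_cells`, `channel_dots`
#'   (matrices, arbitrary intensity units), `pixel_size`, and `truth` with
#'   `mask` (integer label matrix), `dots` (data.frame `x`, `y`, `cell`;
#'   cell 0 = outside), and `counts` (`inside` per cell, `outside`, `total`).
#' @export
gen_pla_stack <- function(n_cells, dots_inside_per_cell, dots_outside,
                          image_size = 256, pixel_size = 0.2,
                          cell_radius = c(18, 30),
                          noise = list(), min_dot_sep = 3, seed = NULL) {
  stopifnot(n_cells >= 0, dots_inside_per_cell >= 0, dots_outside >= 0,
            image_size >= 16)
  if (!is.null(seed)) set.seed(seed)
  nz <- utils::modifyList(
    list(background = 0.1, noise_sd = 0.02, cell_amplitude = 0.5,
         dot_amplitude = 0.5, dot_sigma = 1.5, poisson_scale = 200),
    noise)

  sz <- as.integer(image_size)
  xs <- matrix(seq_len(sz), nrow = sz, ncol = sz)
  ys <- matrix(seq_len(sz), nrow = sz, ncol = sz, byrow = TRUE)

  # --- cells: rejection-sample non-overlapping ellipses ------------------
  cells <- list()
  margin <- 4
  tries <- 0L
  while (length(cells) < n_cells) {
    tries <- tries + 1L
    if (tries > 5000L) stop("requested cell geometry is infeasible for this image size")
    a <- runif(1, cell_radius[1L], cell_radius[2L])
    b <- runif(1, cell_radius[1L], cell_radius[2L])
    r_out <- max(a, b)
    cx <- runif(1, r_out + margin, sz - r_out - margin)
    cy <- runif(1, r_out + margin, sz - r_out - margin)
    ok <- all(vapply(cells, function(cl) {
      (cx - cl$cx)^2 + (cy - cl$cy)^2 >
        (r_out + max(cl$a, cl$b) + margin)^2
    }, logical(1L)))
    if (ok) {
      cells[[length(cells) + 1L]] <-
        list(cx = cx, cy = cy, a = a, b = b, theta = runif(1, 0, pi))
    }
  }

  mask <- matrix(0L, sz, sz)
  chan_cells <- matrix(nz$background, sz, sz)
  r_ell <- function(cl) {
    dx <- xs - cl$cx; dy <- ys - cl$cy
    u <- dx * cos(cl$theta) + dy * sin(cl$theta)
    v <- -dx * sin(cl$theta) + dy * cos(cl$theta)
    sqrt((u / cl$a)^2 + (v / cl$b)^2)
  }
  for (k in seq_along(cells)) {
    r <- r_ell(cells[[k]])
    mask[r <= 1] <- k
    # soft-edged body (sigmoid falloff) so segmentation sees a realistic rim
    chan_cells <- chan_cells + nz$cell_amplitude / (1 + exp((r - 1) / 0.04))
  }

  # --- dots: inside each cell and on background, min separation enforced --
  dots <- data.frame(x = integer(0), y = integer(0), cell = integer(0))
  far_enough <- function(x, y) {
    !nrow(dots) ||
      all((dots$x - x)^2 + (dots$y - y)^2 >= min_dot_sep^2)
  }
  place <- function(n, target_cell) {
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 20000L) stop("requested dot geometry is infeasible")
      x <- sample.int(sz - 8L, 1L) + 4L
      y <- sample.int(sz - 8L, 1L) + 4L
      in_cell <- mask[x, y]
      if (target_cell == 0L) {
        # keep background dots clear of cell rims
        near_rim <- any(vapply(cells, function(cl) {
          dx <- x - cl$cx; dy <- y - cl$cy
          u <- dx * cos(cl$theta) + dy * sin(cl$theta)
          v <- -dx * sin(cl$theta) + dy * cos(cl$theta)
          sqrt((u / cl$a)^2 + (v / cl$b)^2) < 1.15
        }, logical(1L)))
        if (in_cell != 0L || near_rim) next
      } else if (in_cell != target_cell) next
      if (!far_enough(x, y)) next
      dots[nrow(dots) + 1L, ] <<- list(x, y, target_cell)
      placed <- placed + 1L
    }
  }
  for (k in seq_along(cells)) place(dots_inside_per_cell, k)
  place(dots_outside, 0L)

  chan_dots <- matrix(nz$background, sz, sz)
  if (nrow(dots)) {
    half <- ceiling(4 * nz$dot_sigma)
    stamp_off <- seq(-half, half)
    g1 <- dnorm(stamp_off, sd = nz$dot_sigma)
    stamp <- outer(g1, g1) / dnorm(0, sd = nz$dot_sigma)^2  # peak = 1
    for (d in seq_len(nrow(dots))) {
      ix <- dots$x[d] + stamp_off
      iy <- dots$y[d] + stamp_off
      okx <- ix >= 1 & ix <= sz; oky <- iy >= 1 & iy <= sz
      chan_dots[ix[okx], iy[oky]] <- chan_dots[ix[okx], iy[oky]] +
        nz$dot_amplitude * stamp[okx, oky]
    }
  }

  if (!is.null(nz$poisson_scale)) {
    chan_dots <- rpois(length(chan_dots), chan_dots * nz$poisson_scale) /
      nz$poisson_scale
    dim(chan_dots) <- c(sz, sz)
  }
  chan_dots <- chan_dots + rnorm(length(chan_dots), sd = nz$noise_sd)
  chan_cells <- chan_cells + rnorm(length(chan_cells), sd = nz$noise_sd)

  counts_inside <- if (n_cells > 0) {
    vapply(seq_len(n_cells), function(k) sum(dots$cell == k), integer(1L))
  } else integer(0)
  structure(list(channel_cells = chan_cells, channel_dots = chan_dots,
                 pixel_size = pixel_size,
                 truth = list(mask = mask, dots = dots,
                              counts = list(inside = counts_inside,
                                            outside = sum(dots$cell == 0L),
                                            total = nrow(dots)),
                              cells = cells, noise = nz)),
            class = "kv_pla_stack")
}
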