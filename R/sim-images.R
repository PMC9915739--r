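#' Configuration for simulated two-channel section images
#'
#' Emulates confocal maximum projections of labelled mesofrontal tissue:
#' the red channel carries curvilinear axons drawn as cubic-smoothed random
#' walks, the green channel carries Gaussian synaptic-bouton puncta placed
#' on the axons at a set linear density; a midbrain variant places labelled
#' somata instead. Ground truth (exact polyline lengths, bouton and cell
#' coordinates) is recorded as drawn.
#'
#' @param image_shape Image size in pixels, `c(rows, cols)`; default 256 x 256.
#' @param pixel_size Microns per pixel; default 0.5.
#' @param n_axons Number of axons; default 3.
#' @param axon_length_um Target length per axon, microns; default 120.
#' @param axon_length_jitter Relative half-range of per-axon length
#'   variation (lengths drawn uniformly in `length * (1 +/- jitter)`);
#'   default 0.2.
#' @param axon_intensity Peak axon intensity, a.u.; default 1.
#' @param axon_sigma_um Gaussian cross-section width of the drawn axon,
#'   microns; default 0.4.
#' @param curvature Heading change SD per 5 microns of path, radians;
#'   default 0.25 (curved enough that ridge detection is nontrivial).
#' @param boutons_per_100um Bouton density per 100 microns of axon;
#'   default 5.
#' @param bouton_amplitude Peak bouton intensity, a.u.; default 1.
#' @param bouton_sigma Bouton Gaussian width, microns; default 0.5.
#' @param n_cells Number of somata (midbrain variant); default 0.
#' @param cell_sigma_um Soma Gaussian width, microns; default 4.
#' @param cell_amplitude Peak soma intensity; default 1.
#' @param background_sd Gaussian background noise SD, a.u.; default 0.05.
#' @param seed Integer seed.
#' @return A list of class `mf_image_cfg`.
#' @export
image_sim_config <- function(image_shape = c(256, 256), pixel_size = 0.5,
                             n_axons = 3, axon_length_um = 120,
                             axon_length_jitter = 0.2,
                             axon_intensity = 1, axon_sigma_um = 0.4,
                             curvature = 0.25, boutons_per_100um = 5,
                             bouton_amplitude = 1, bouton_sigma = 0.5,
                             n_cells = 0, cell_sigma_um = 4,
                             cell_amplitude = 1, background_sd = 0.05,
                             seed = 1L) {
  check_positive(pixel_size, "pixel_size")
  for (v in c(n_axons, boutons_per_100um, bouton_amplitude, axon_intensity,
              background_sd, n_cells))
    if (!is_scalar_number(v) || v < 0)
      stop("densities, counts and intensities must be >= 0", call. = FALSE)
  if (boutons_per_100um > 0 && n_axons == 0)
    stop("bouton placement requested with n_axons = 0", call. = FALSE)
  structure(list(image_shape = image_shape, pixel_size = pixel_size,
                 n_axons = n_axons, axon_length_um = axon_length_um,
                 axon_length_jitter = axon_length_jitter,
                 axon_intensity = axon_intensity, axon_sigma_um = axon_sigma_um,
                 curvature = curvature, boutons_per_100um = boutons_per_100um,
                 bouton_amplitude = bouton_amplitude, bouton_sigma = bouton_sigma,
                 n_cells = n_cells, cell_sigma_um = cell_sigma_um,
                 cell_amplitude = cell_amplitude, background_sd = background_sd,
                 seed = as.integer(seed)),
            class = "mf_image_cfg")
}

# Fraction of path samples that revisit a pixel neighbourhood first
# touched more than ~15 px of arc earlier (self-crossing/folding measure).
path_self_overlap <- function(iy, ix, sh) {
  first <- matrix(NA_integer_, sh[1], sh[2])
  hits <- 0L
  lag <- 30L  # dense samples are ~0.5 px apart
  for (j in seq_along(iy)) {
    ys <- max(1, iy[j] - 1):min(sh[1], iy[j] + 1)
    xs <- max(1, ix[j] - 1):min(sh[2], ix[j] + 1)
    blk <- first[ys, xs]
    if (any(!is.na(blk) & blk < j - lag)) hits <- hits + 1L
    blk[is.na(blk)] <- j
    first[ys, xs] <- blk
  }
  hits / length(iy)
}

# Max-composite a Gaussian spot into an image (rows = y, cols = x).
stamp_gaussian <- function(img, cy, cx, sigma_px, amplitude) {
  r <- max(2L, ceiling(3 * sigma_px))
  ys <- max(1, floor(cy - r)):min(nrow(img), ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(img)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  img[ys, xs] <- pmax(img[ys, xs], amplitude * exp(-d2 / (2 * sigma_px^2)))
  img
}

# One cubic-smoothed random-walk polyline inside the image, returned as
# densely sampled points (px) plus its exact arc length (px).
random_axon_path <- function(shape, length_px, curvature, margin = 6) {
  step <- 10  # control-point spacing, px
  n_cp <- max(3L, ceiling(length_px / step) + 1L)
  cy <- stats::runif(1, margin, shape[1] - margin)
  cx <- stats::runif(1, margin, shape[2] - margin)
  theta <- stats::runif(1, 0, 2 * pi)
  py <- numeric(n_cp); px <- numeric(n_cp)
  py[1] <- cy; px[1] <- cx
  for (k in 2:n_cp) {
    theta <- theta + stats::rnorm(1, 0, curvature)
    ny <- py[k - 1] + step * sin(theta)
    nx <- px[k - 1] + step * cos(theta)
    if (ny < margin || ny > shape[1] - margin ||
        nx < margin || nx > shape[2] - margin) {
      # steer back toward the image centre
      theta <- atan2(shape[1] / 2 - py[k - 1], shape[2] / 2 - px[k - 1]) +
        stats::rnorm(1, 0, 0.2)
      ny <- py[k - 1] + step * sin(theta)
      nx <- px[k - 1] + step * cos(theta)
    }
    py[k] <- ny; px[k] <- nx
  }
  s <- seq_len(n_cp)
  dense <- seq(1, n_cp, by = 0.05)  # ~0.5 px sample spacing
  sy <- stats::spline(s, py, xout = dense)$y
  sx <- stats::spline(s, px, xout = dense)$y
  seglen <- sqrt(diff(sy)^2 + diff(sx)^2)
  # trim the dense samples to the requested arc length
  cum <- cumsum(seglen)
  keep <- which(cum <= length_px)
  if (length(keep) < 2) keep <- seq_len(2)
  idx <- c(1, keep + 1)
  list(y = sy[idx], x = sx[idx], length_px = sum(seglen[keep]),
       cum_px = c(0, cum[keep]))
}

#' Simulate a two-channel section image with known ground truth
#'
#' @param cfg An [image_sim_config()].
#' @return A list of class `mf_section_image`: `channels` (list `red`,
#'   `green` matrices), `pixel_size`, `roi_mask` (all-TRUE by default) and
#'   `ground_truth` (per-axon lengths in microns, bouton and cell
#'   coordinates in pixels).
#' @export
simulate_morphology_image <- function(cfg) {
  stopifnot(inherits(cfg, "mf_image_cfg"))
  sh <- cfg$image_shape
  red <- matrix(0, sh[1], sh[2])
  green <- matrix(0, sh[1], sh[2])
  axon_lengths <- numeric(0)
  boutons <- cells <- data.frame(y = numeric(0), x = numeric(0))
  with_seed(cfg$seed, {
    if (cfg$n_axons > 0) {
      sig_px <- cfg$axon_sigma_um / cfg$pixel_size
      occupied <- matrix(FALSE, sh[1], sh[2])
      for (a in seq_len(cfg$n_axons)) {
        len_px <- cfg$axon_length_um / cfg$pixel_size *
          stats::runif(1, 1 - cfg$axon_length_jitter, 1 + cfg$axon_length_jitter)
        # brief crossings are fine, but redraw paths that run along an
        # existing axon or fold back onto themselves: merged ribbons make
        # length unrecoverable for any centerline method
        for (try in 1:20) {
          path <- random_axon_path(sh, len_px, cfg$curvature)
          iy <- pmin(pmax(round(path$y), 1), sh[1])
          ix <- pmin(pmax(round(path$x), 1), sh[2])
          if (mean(occupied[cbind(iy, ix)]) > 0.05) next
          if (path_self_overlap(iy, ix, sh) <= 0.02) break
        }
        for (dy in -2:2) for (dx in -2:2)
          occupied[cbind(pmin(pmax(iy + dy, 1), sh[1]),
                         pmin(pmax(ix + dx, 1), sh[2]))] <- TRUE
        for (j in seq_along(path$y))
          red <- stamp_gaussian(red, path$y[j], path$x[j], sig_px,
                                cfg$axon_intensity)
        len_um <- path$length_px * cfg$pixel_size
        axon_lengths <- c(axon_lengths, len_um)
        n_b <- round(len_um * cfg$boutons_per_100um / 100)
        if (n_b > 0) {
          # arc-length-stratified placement keeps puncta resolvable
          targets <- (seq_len(n_b) - 0.5) / n_b * path$length_px
          bidx <- vapply(targets, function(tt) which.min(abs(path$cum_px - tt)),
                         integer(1))
          for (j in bidx) {
            green <- stamp_gaussian(green, path$y[j], path$x[j],
                                    cfg$bouton_sigma / cfg$pixel_size,
                                    cfg$bouton_amplitude)
            boutons <- rbind(boutons, data.frame(y = path$y[j], x = path$x[j]))
          }
        }
      }
    }
    if (cfg$n_cells > 0) {
      sig <- cfg$cell_sigma_um / cfg$pixel_size
      min_sep <- 4 * sig
      tries <- 0
      while (nrow(cells) < cfg$n_cells && tries < 10000) {
        tries <- tries + 1
        cy <- stats::runif(1, 3 * sig, sh[1] - 3 * sig)
        cx <- stats::runif(1, 3 * sig, sh[2] - 3 * sig)
        if (nrow(cells) == 0 ||
            min(sqrt((cells$y - cy)^2 + (cells$x - cx)^2)) > min_sep) {
          cells <- rbind(cells, data.frame(y = cy, x = cx))
          red <- stamp_gaussian(red, cy, cx, sig, cfg$cell_amplitude)
        }
      }
      if (nrow(cells) < cfg$n_cells)
        stop("could not place requested somata without overlap", call. = FALSE)
    }
    if (cfg$background_sd > 0) {
      red <- red + matrix(stats::rnorm(length(red), 0, cfg$background_sd), sh[1])
      green <- green + matrix(stats::rnorm(length(green), 0, cfg$background_sd), sh[1])
    }
  })
  section_image(red, green, cfg$pixel_size,
                ground_truth = list(axon_lengths_um = axon_lengths,
                                    total_axon_um = sum(axon_lengths),
                                    boutons = boutons, n_boutons = nrow(boutons),
                                    cells = cells, n_cells = nrow(cells),
                                    seed = cfg$seed))
}
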