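#' Construct a two-channel section image
#'
#' @param red,green 2-D numeric matrices of the same shape (axon / tdTomato
#'   signal in red, bouton / SypGFP signal in green; either may be NULL if
#'   only one channel was imaged).
#' @param pixel_size Microns per pixel.
#' @param roi_mask Logical matrix marking the region of interest; default
#'   the whole image.
#' @param ground_truth Optional list attached by simulators.
#' @return An object of class `mf_section_image`.
#' @export
section_image <- function(red = NULL, green = NULL, pixel_size,
                          roi_mask = NULL, ground_truth = NULL) {
  check_positive(pixel_size, "pixel_size")
  ref <- if (!is.null(red)) red else green
  if (is.null(ref)) stop("at least one channel is required", call. = FALSE)
  if (!is.null(red) && !is.null(green) && !all(dim(red) == dim(green)))
    stop("channels must have the same shape", call. = FALSE)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(ref), ncol(ref))
  structure(list(channels = list(red = red, green = green),
                 pixel_size = pixel_size, roi_mask = roi_mask,
                 ground_truth = ground_truth),
            class = "mf_section_image")
}

#' @export
print.mf_section_image <- function(x, ...) {
  ref <- if (!is.null(x$channels$red)) x$channels$red else x$channels$green
  cat(sprintf("SectionImage: %d x %d px @ %.2f um/px (%s)\n", nrow(ref),
              ncol(ref), x$pixel_size,
              paste(names(Filter(Negate(is.null), x$channels)), collapse = "+")))
  invisible(x)
}

# --- filters -----------------------------------------------------------

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Scale-normalized Laplacian-of-Gaussian kernel; negated so that bright
# blobs give positive responses.
log_kernel <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  d2 <- outer((-r:r)^2, (-r:r)^2, "+")
  k <- (d2 / sigma^2 - 2) * exp(-d2 / (2 * sigma^2))
  k <- k - mean(k)            # zero-DC: flat regions give zero response
  -k / (2 * pi * sigma^2)     # sigma^2 * laplacian(G), G = gaussian(sigma)
}

conv2d <- function(img, kernel) {
  as.matrix(EBImage::filter2(img, kernel, boundary = "replicate"))
}

shift_mat <- function(m, dr, dc, fill = 0) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- seq_len(n) - dr; cs <- seq_len(p) - dc
  ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= p
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Shift with edge replication: derivative stencils stay valid (zero on
# constant images) at the borders.
shift_rep <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  m[pmin(pmax(seq_len(n) - dr, 1L), n), pmin(pmax(seq_len(p) - dc, 1L), p)]
}

# Background pixels: inside the ROI but outside the dilated signal mask.
# The signal mask is a robust threshold on the raw channel (median + 2 MAD)
# dilated by `dilate_px`. All detector thresholds are expressed in SDs of
# the raw background intensity ("k SD above background"), applied to the
# filter response above its own background mean.
background_mask <- function(channel, roi, dilate_px) {
  thr <- stats::median(channel[roi]) + 2 * stats::mad(channel[roi])
  sig <- channel > thr & roi
  size <- 2L * as.integer(max(1, dilate_px)) + 1L
  dil <- as.matrix(EBImage::dilate(EBImage::Image(sig * 1),
                                   EBImage::makeBrush(size, "disc"))) > 0
  bg <- roi & !dil
  if (!any(bg)) bg <- roi  # degenerate: whole ROI is signal
  bg
}

local_maxima <- function(resp, mask) {
  is_max <- matrix(TRUE, nrow(resp), ncol(resp))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & resp >= shift_mat(resp, dr, dc, fill = -Inf)
  }
  which(is_max & mask, arr.ind = TRUE)
}

#' Detect synaptic boutons with a Laplacian-of-Gaussian filter
#'
#' The green channel is filtered with a scale-normalized
#' Laplacian-of-Gaussian at the bouton scale; local maxima of the response
#' inside the ROI that exceed the background response mean by `k` background
#' SDs are counted as boutons. Background is estimated from ROI pixels
#' outside the dilated signal mask.
#'
#' @param img An `mf_section_image` with a green channel and nonempty ROI.
#' @param sigma_um LoG scale in microns; default 0.8.
#' @param k Threshold in background SDs; default 5.
#' @return A list of class `mf_boutons`: `count`, `coords` (row `y`, col
#'   `x`, response), `threshold`.
#' @export
detect_boutons <- function(img, sigma_um = 0.8, k = 5) {
  stopifnot(inherits(img, "mf_section_image"))
  ch <- img$channels$green
  if (is.null(ch)) stop("green channel required for bouton detection", call. = FALSE)
  roi <- img$roi_mask
  if (!any(roi)) stop("ROI mask is empty", call. = FALSE)
  sigma <- sigma_um / img$pixel_size
  resp <- conv2d(ch, log_kernel(sigma))
  bg <- background_mask(ch, roi, dilate_px = 3 * sigma)
  thr <- mean(resp[bg]) + k * stats::sd(ch[bg])
  mx <- local_maxima(resp, resp > thr & roi)
  coords <- data.frame(y = mx[, 1], x = mx[, 2],
                       response = resp[mx])
  structure(list(count = nrow(coords), coords = coords, threshold = thr),
            class = "mf_boutons")
}

#' Detect axons with a multiscale Hessian ridge filter and measure length
#'
#' At each scale the red channel is Gaussian-smoothed and the most negative
#' Hessian eigenvalue computed; the scale-normalized ridge (tubeness)
#' response is its rectified negation, maximized over scales. The response
#' is thresholded at `k` background SDs above the background mean,
#' skeletonized by Zhang-Suen thinning, and the skeleton length summed with
#' the 1 / sqrt(2) step convention (1 px for 4-neighbour steps, sqrt(2) px
#' for diagonal steps), which is unbiased for diagonal segments.
#'
#' @param img An `mf_section_image` with a red channel.
#' @param scales_um Hessian scales in microns; default `c(0.5, 1, 1.5)`.
#' @param k Threshold in background SDs; default 2.
#' @param min_fragment_um Binary fragments whose area corresponds to less
#'   than this many microns of ribbon are discarded as speckle before
#'   skeletonization; default 5.
#' @param prune_px Skeleton spur-pruning depth in pixels; default 4.
#' @param smooth_px Gaussian regularization of the ridge response before
#'   thresholding, pixels; keeps the medial axis tracking the ridge centre
#'   rather than boundary noise (which would bias lengths upward).
#'   Default 2.
#' @return A list of class `mf_axons`: `length_um`, `skeleton` (logical
#'   matrix), `binary`, `threshold`.
#' @export
detect_axons <- function(img, scales_um = c(0.5, 1, 1.5), k = 2,
                         min_fragment_um = 5, prune_px = 4, smooth_px = 2) {
  stopifnot(inherits(img, "mf_section_image"))
  ch <- img$channels$red
  if (is.null(ch)) stop("red channel required for axon detection", call. = FALSE)
  roi <- img$roi_mask
  resp <- matrix(0, nrow(ch), ncol(ch))
  for (s_um in scales_um) {
    s <- s_um / img$pixel_size
    sm <- conv2d(ch, gaussian_kernel(s))
    hxx <- shift_rep(sm, 0, 1) - 2 * sm + shift_rep(sm, 0, -1)
    hyy <- shift_rep(sm, 1, 0) - 2 * sm + shift_rep(sm, -1, 0)
    hxy <- (shift_rep(sm, 1, 1) - shift_rep(sm, 1, -1) -
            shift_rep(sm, -1, 1) + shift_rep(sm, -1, -1)) / 4
    lam_min <- ((hxx + hyy) - sqrt((hxx - hyy)^2 + 4 * hxy^2)) / 2
    resp <- pmax(resp, s^2 * pmax(0, -lam_min))
  }
  if (smooth_px > 0) resp <- conv2d(resp, gaussian_kernel(smooth_px))
  bg <- background_mask(ch, roi, dilate_px = 3 * max(scales_um) / img$pixel_size)
  thr <- mean(resp[bg]) + k * stats::sd(ch[bg])
  binary <- resp > thr & roi
  # despeckle: drop components smaller than a ~4 px wide ribbon fragment
  min_area <- 4 * min_fragment_um / img$pixel_size
  if (min_area > 0 && any(binary)) {
    lbl <- EBImage::bwlabel(EBImage::Image(binary * 1))
    sz <- tabulate(as.vector(lbl)[as.vector(lbl) > 0])
    small <- which(sz < min_area)
    if (length(small)) binary[matrix(as.vector(lbl) %in% small, nrow(binary))] <- FALSE
  }
  skel <- prune_spurs(zhang_suen_thin(binary), prune_px)
  # pruning retracts every surviving terminal by prune_px steps; add that
  # length back per remaining endpoint so true axon ends are not shortened
  # (fully removed side spurs leave no endpoint and get no credit)
  nb <- matrix(0, nrow(skel), ncol(skel))
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) nb <- nb + shift_mat(skel, dr, dc)
  n_ends <- sum(skel & nb == 1)
  len_px <- skeleton_length(skel) + n_ends * prune_px
  structure(list(length_um = len_px * img$pixel_size,
                 skeleton = skel, binary = binary, threshold = thr),
            class = "mf_axons")
}

# Iteratively strip skeleton end points to remove short side spurs left by
# thinning a noisy ribbon.
prune_spurs <- function(skel, n) {
  s <- skel != 0
  for (i in seq_len(n)) {
    nb <- matrix(0, nrow(s), ncol(s))
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) nb <- nb + shift_mat(s, dr, dc)
    ends <- s & nb <= 1
    if (!any(ends)) break
    s[ends] <- FALSE
  }
  s
}

#' Count labelled somata with a Laplacian-of-Gaussian filter
#'
#' LoG blob detection at the soma scale, thresholded at `k` background SDs;
#' response maxima closer than one soma radius are merged (two touching
#' somata count as one — documented behaviour).
#'
#' @param img An `mf_section_image` (midbrain section); the red channel is
#'   used unless `channel = "green"`.
#' @param sigma_um LoG scale in microns; default 8 (soma scale).
#' @param k Threshold in background SDs; default 2.
#' @param channel Which channel carries the label; default `"red"`.
#' @return A list of class `mf_cells`: `count`, `coords`, `threshold`.
#' @export
count_cells <- function(img, sigma_um = 8, k = 2, channel = "red") {
  stopifnot(inherits(img, "mf_section_image"))
  ch <- img$channels[[channel]]
  if (is.null(ch)) stop(sprintf("%s channel required", channel), call. = FALSE)
  roi <- img$roi_mask
  sigma <- sigma_um / img$pixel_size
  resp <- conv2d(ch, log_kernel(sigma))
  bg <- background_mask(ch, roi, dilate_px = 2 * sigma)
  thr <- mean(resp[bg]) + k * stats::sd(ch[bg])
  mx <- local_maxima(resp, resp > thr & roi)
  if (nrow(mx) == 0)
    return(structure(list(count = 0L,
                          coords = data.frame(y = numeric(0), x = numeric(0)),
                          threshold = thr), class = "mf_cells"))
  ord <- order(resp[mx], decreasing = TRUE)
  mx <- mx[ord, , drop = FALSE]
  min_sep <- sigma  # one soma radius (sigma ~ radius at the LoG match scale)
  keep <- integer(0)
  for (i in seq_len(nrow(mx))) {
    if (!length(keep) ||
        min(sqrt((mx[keep, 1] - mx[i, 1])^2 + (mx[keep, 2] - mx[i, 2])^2)) > min_sep)
      keep <- c(keep, i)
  }
  structure(list(count = length(keep),
                 coords = data.frame(y = mx[keep, 1], x = mx[keep, 2]),
                 threshold = thr),
            class = "mf_cells")
}

# --- skeletonization ---------------------------------------------------

# Zhang-Suen two-subiteration thinning of a logical mask, vectorized over
# the image with matrix shifts.
zhang_suen_thin <- function(mask) {
  m <- mask != 0
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(m, -1, 0);  p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);   p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);   p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1);  p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 < p3) + (p3 < p4) + (p4 < p5) + (p5 < p6) +
           (p6 < p7) + (p7 < p8) + (p8 < p9) + (p9 < p2)
      if (step == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Skeleton length in pixels: 4-neighbour steps count 1, diagonal steps
# sqrt(2); a diagonal is skipped when a 4-connected shortcut through a
# shared neighbour exists (avoids double counting at corners).
skeleton_length <- function(skel) {
  s <- skel != 0
  n_h <- sum(s[, -ncol(s)] & s[, -1])
  n_v <- sum(s[-nrow(s), ] & s[-1, ])
  se <- shift_mat(s, 1, 1); e <- shift_mat(s, 0, 1); so <- shift_mat(s, 1, 0)
  n_d1 <- sum(s & se & !e & !so)                       # down-right diagonals
  ne <- shift_mat(s, -1, 1); no <- shift_mat(s, -1, 0)
  n_d2 <- sum(s & ne & !e & !no)                       # up-right diagonals
  n_h + n_v + sqrt(2) * (n_d1 + n_d2)
}

#' Aggregate per-section morphology into per-animal normalized metrics
#'
#' Counts and lengths are summed per animal before taking ratios (ratio of
#' sums, not mean of ratios): bouton density = total boutons / total axon
#' length; axon per cell = total axon length / total labelled cells. Each
#' metric is additionally expressed as a percentage of the control-group
#' mean, so the control group averages 100% by construction. Animals with
#' zero axon length or zero cells are flagged and excluded.
#'
#' @param per_section A data.frame with columns `animal`, `group`, and any
#'   of `bouton_count`, `axon_length_um`, `cell_count` (NA where a section
#'   lacks that measure).
#' @param control_group Name of the control group (the normalization
#'   reference); defaults to the first group level.
#' @return A list of class `mf_morph_summary`: `per_animal`,
#'   `group_summary`, `excluded` (animal ids), `control_group`.
#' @export
normalize_metrics <- function(per_section, control_group = NULL) {
  stopifnot(all(c("animal", "group") %in% names(per_section)))
  for (col in c("bouton_count", "axon_length_um", "cell_count"))
    if (is.null(per_section[[col]])) per_section[[col]] <- NA_real_
  agg <- stats::aggregate(
    per_section[, c("bouton_count", "axon_length_um", "cell_count")],
    by = list(animal = per_section$animal, group = per_section$group),
    FUN = function(v) if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE))
  if (is.null(control_group)) control_group <- as.character(agg$group[1])
  if (!control_group %in% agg$group)
    stop("control group not present in data", call. = FALSE)
  bad <- (!is.na(agg$axon_length_um) & agg$axon_length_um <= 0) |
         (!is.na(agg$cell_count) & agg$cell_count <= 0)
  excluded <- agg$animal[bad]
  agg <- agg[!bad, , drop = FALSE]
  agg$bouton_density <- agg$bouton_count / agg$axon_length_um
  agg$axon_per_cell <- agg$axon_length_um / agg$cell_count
  ctrl <- agg$group == control_group
  for (metric in c("bouton_density", "axon_per_cell")) {
    ref <- mean(agg[[metric]][ctrl], na.rm = TRUE)
    agg[[paste0(metric, "_pct")]] <-
      if (is.finite(ref) && ref > 0) 100 * agg[[metric]] / ref else NA_real_
  }
  summ <- do.call(rbind, lapply(split(agg, agg$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               bouton_density = mean(g$bouton_density, na.rm = TRUE),
               bouton_density_pct = mean(g$bouton_density_pct, na.rm = TRUE),
               axon_per_cell = mean(g$axon_per_cell, na.rm = TRUE),
               axon_per_cell_pct = mean(g$axon_per_cell_pct, na.rm = TRUE))
  }))
  rownames(summ) <- NULL
  structure(list(per_animal = agg, group_summary = summ,
                 excluded = excluded, control_group = control_group),
            class = "mf_morph_summary")
}
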