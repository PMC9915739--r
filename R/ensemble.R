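#' Construct a spatial activity map from a per-trial tensor
#'
#' Wraps a trials x neurons x bins activity tensor with its alternation
#' labels and computes trial-averaged maps over all, alternating and
#' non-alternating trials. Empty (NA) bins are linearly interpolated from
#' neighbouring bins within each trial and flagged.
#'
#' @param per_trial Numeric array, trials x neurons x bins.
#' @param trial_labels Logical vector per trial: alternating (`TRUE`),
#'   non-alternating (`FALSE`), or `NA` (unlabelled, e.g. first trial).
#' @return An object of class `mf_spatial_map`: `per_trial`,
#'   `trial_labels`, `mean_map`, `mean_alt`, `mean_nonalt`, and
#'   `empty_bins` (trials x bins logical).
#' @export
spatial_activity_map <- function(per_trial, trial_labels) {
  stopifnot(length(dim(per_trial)) == 3,
            dim(per_trial)[1] == length(trial_labels))
  n_tr <- dim(per_trial)[1]; n_bins <- dim(per_trial)[3]
  empty <- matrix(FALSE, n_tr, n_bins)
  for (tr in seq_len(n_tr)) {
    slice <- per_trial[tr, , , drop = FALSE]
    na_bins <- apply(is.na(slice[1, , , drop = FALSE]), 3, any)
    if (any(na_bins)) {
      empty[tr, ] <- na_bins
      for (i in seq_len(dim(per_trial)[2])) {
        v <- per_trial[tr, i, ]
        if (anyNA(v)) {
          ok <- which(!is.na(v))
          if (length(ok) == 0) v[] <- 0
          else v <- stats::approx(ok, v[ok], xout = seq_len(n_bins), rule = 2)$y
          per_trial[tr, i, ] <- v
        }
      }
    }
  }
  mean_over <- function(sel) {
    if (!any(sel)) return(matrix(NA_real_, dim(per_trial)[2], n_bins))
    apply(per_trial[sel, , , drop = FALSE], c(2, 3), mean)
  }
  structure(list(per_trial = per_trial,
                 trial_labels = trial_labels,
                 mean_map = mean_over(rep(TRUE, n_tr)),
                 mean_alt = mean_over(trial_labels %in% TRUE),
                 mean_nonalt = mean_over(trial_labels %in% FALSE),
                 empty_bins = empty),
            class = "mf_spatial_map")
}

#' @export
print.mf_spatial_map <- function(x, ...) {
  cat(sprintf("SpatialActivityMap: %d trials (%d alt / %d non-alt) x %d neurons x %d bins\n",
              dim(x$per_trial)[1], sum(x$trial_labels %in% TRUE),
              sum(x$trial_labels %in% FALSE), dim(x$per_trial)[2],
              dim(x$per_trial)[3]))
  invisible(x)
}

#' Build a position-binned spatial activity map from traces
#'
#' For each trial and neuron, activity in a bin is the mean ΔF/F0 over the
#' trial frames assigned to that bin; bin values are then averaged across
#' trials (all, alternating, non-alternating).
#'
#' @param traces An `mf_traces`.
#' @param trials An `mf_trials` data.frame.
#' @param bins Per-trial frame/bin tables from [bin_trials()].
#' @param n_bins Number of bins; default 20.
#' @return An `mf_spatial_map`.
#' @export
build_spatial_map <- function(traces, trials, bins, n_bins = 20) {
  stopifnot(inherits(traces, "mf_traces"), nrow(trials) == length(bins))
  if (nrow(trials) == 0) stop("no trials", call. = FALSE)
  n_neur <- nrow(traces$dff)
  per_trial <- array(NA_real_, c(nrow(trials), n_neur, n_bins))
  for (k in seq_along(bins)) {
    fb <- bins[[k]]
    for (b in unique(fb$bin)) {
      fr <- fb$frame[fb$bin == b]
      per_trial[k, , b] <- rowMeans(traces$dff[, fr, drop = FALSE])
    }
  }
  spatial_activity_map(per_trial, trials$is_alternation)
}

#' Distribution of peak-activity positions across neurons
#'
#' Each neuron's peak bin is the argmax of its trial-averaged activity
#' (ties broken to the lowest bin and counted); the proportion of neurons
#' peaking in each bin is reported with a Wilson score confidence interval.
#' Neurons with constant (all-equal) mean activity are excluded and counted.
#'
#' @param map An `mf_spatial_map`.
#' @param conf.level Confidence level for the Wilson intervals; default 0.95.
#' @return A list of class `mf_peak_dist`: `table` (bin, count, proportion,
#'   ci_low, ci_high), `peak_bin` per neuron, `n_neurons`, `n_ties`,
#'   `n_excluded`.
#' @export
peak_position_distribution <- function(map, conf.level = 0.95) {
  stopifnot(inherits(map, "mf_spatial_map"))
  m <- map$mean_map
  n_bins <- ncol(m)
  rng <- apply(m, 1, function(v) diff(range(v)))
  keep <- rng > 0
  peaks <- rep(NA_integer_, nrow(m))
  ties <- 0L
  for (i in which(keep)) {
    w <- which(m[i, ] == max(m[i, ]))
    if (length(w) > 1) ties <- ties + 1L
    peaks[i] <- w[1]
  }
  counts <- tabulate(peaks[keep], nbins = n_bins)
  n <- sum(keep)
  ci <- wilson_ci(counts, n, conf.level)
  structure(list(table = data.frame(bin = seq_len(n_bins), count = counts,
                                    proportion = counts / n,
                                    ci_low = ci$lower, ci_high = ci$upper),
                 peak_bin = peaks, n_neurons = n, n_ties = ties,
                 n_excluded = sum(!keep)),
            class = "mf_peak_dist")
}

#' @export
print.mf_peak_dist <- function(x, ...) {
  cat(sprintf("Peak-position distribution: %d neurons (%d excluded, %d ties)\n",
              x$n_neurons, x$n_excluded, x$n_ties))
  cat(sprintf("  modal bin %d (proportion %.3f)\n",
              which.max(x$table$proportion), max(x$table$proportion)))
  invisible(x)
}

#' Alternation selectivity of binned neuronal activity
#'
#' For each neuron the activity difference between alternating and
#' non-alternating trials, `d(b) = mean_alt(b) - mean_nonalt(b)`, is
#' computed per bin; the neuron is selective at bin `b` if `|d(b)|`
#' exceeds `k` standard deviations of its differences at all other
#' positions. The absolute value makes the rule two-sided (selectivity in
#' either direction). Bins where the SD of the other positions is zero are
#' flagged degenerate (selective there only if `|d(b)| > 0`). A
#' neuron-level summary flag, `selective_at_peak`, marks neurons selective
#' at their own peak mean-activity bin.
#'
#' @param map An `mf_spatial_map` with at least 2 alternating and 2
#'   non-alternating trials.
#' @param k Threshold in SDs of the other positions' differences; default 2.
#' @param conf.level Confidence level for Wilson intervals; default 0.95.
#' @return A list of class `mf_selectivity`: `selective` (neurons x bins
#'   logical), `difference` (the d matrix), `table` (per-bin count,
#'   proportion and Wilson CI of selective neurons), `selective_at_peak`,
#'   `peak_bin`, `degenerate` (neurons x bins logical), `n_neurons`.
#' @export
alternation_selectivity <- function(map, k = 2, conf.level = 0.95) {
  stopifnot(inherits(map, "mf_spatial_map"))
  if (sum(map$trial_labels %in% TRUE) < 2 || sum(map$trial_labels %in% FALSE) < 2)
    stop("need at least 2 alternating and 2 non-alternating trials", call. = FALSE)
  d <- map$mean_alt - map$mean_nonalt
  n_bins <- ncol(d); n <- nrow(d)
  selective <- degenerate <- matrix(FALSE, n, n_bins)
  for (b in seq_len(n_bins)) {
    sd_others <- apply(d[, -b, drop = FALSE], 1, stats::sd)
    zero <- sd_others == 0
    selective[, b] <- abs(d[, b]) > k * sd_others
    degenerate[, b] <- zero
    selective[zero, b] <- abs(d[zero, b]) > 0
  }
  peaks <- peak_position_distribution(map)$peak_bin
  at_peak <- rep(FALSE, n)
  ok <- !is.na(peaks)
  at_peak[ok] <- selective[cbind(which(ok), peaks[ok])]
  counts <- colSums(selective)
  ci <- wilson_ci(counts, n, conf.level)
  structure(list(selective = selective, difference = d,
                 table = data.frame(bin = seq_len(n_bins), count = counts,
                                    proportion = counts / n,
                                    ci_low = ci$lower, ci_high = ci$upper),
                 selective_at_peak = at_peak, peak_bin = peaks,
                 degenerate = degenerate, n_neurons = n),
            class = "mf_selectivity")
}

#' Simulate a cohort of per-trial spatial activity maps
#'
#' Map-level counterpart of the trace simulator, generating binned
#' activity directly at the interface [alternation_selectivity()] and
#' [peak_position_distribution()] consume: each neuron has a Gaussian
#' tuning profile over bins (baseline + bump), a `frac_selective` subset
#' has all activity multiplied by `gain` on alternating trials, and i.i.d.
#' Gaussian trial-to-trial noise of SD `noise_sd` is added per bin. Used
#' to calibrate the selectivity rule under a homoscedastic null
#' (`frac_selective = 0`, `amp = 0` gives pure noise maps).
#'
#' @param n_neurons Number of neurons.
#' @param n_alt,n_nonalt Number of alternating / non-alternating trials.
#' @param n_bins Number of bins; default 20.
#' @param tuning_center Bin per neuron (scalar, vector, or `NULL` for
#'   uniform random).
#' @param tuning_width Gaussian width in bins; default 3.
#' @param base,amp Baseline and bump amplitude of mean activity; defaults
#'   0.1 and 0.3.
#' @param gain Alternating-trial multiplier for selective neurons;
#'   default 2.
#' @param frac_selective Proportion of selective neurons; default 0.
#' @param noise_sd Trial-to-trial noise SD per bin; default 0.15.
#' @param seed Integer seed.
#' @return A list: `map` (an `mf_spatial_map`) and `ground_truth`
#'   (`selective_ids`, `tuning_center`).
#' @export
simulate_spatial_map_cohort <- function(n_neurons, n_alt = 20, n_nonalt = 20,
                                        n_bins = 20, tuning_center = NULL,
                                        tuning_width = 3, base = 0.1,
                                        amp = 0.3, gain = 2,
                                        frac_selective = 0, noise_sd = 0.15,
                                        seed = 1L) {
  with_seed(seed, {
    centers <- tuning_center
    if (is.null(centers)) centers <- sample.int(n_bins, n_neurons, replace = TRUE)
    if (length(centers) == 1) centers <- rep(centers, n_neurons)
    n_sel <- round(frac_selective * n_neurons)
    selective <- sort(sample.int(n_neurons, n_sel))
    mu <- base + amp * exp(-outer(centers, seq_len(n_bins), function(c, b)
      (b - c)^2) / (2 * tuning_width^2))
    n_tr <- n_alt + n_nonalt
    labels <- rep(c(TRUE, FALSE), c(n_alt, n_nonalt))
    per_trial <- array(0, c(n_tr, n_neurons, n_bins))
    for (tr in seq_len(n_tr)) {
      m <- mu
      if (labels[tr] && length(selective)) m[selective, ] <- gain * m[selective, ]
      per_trial[tr, , ] <- m + matrix(stats::rnorm(n_neurons * n_bins, 0, noise_sd),
                                      n_neurons, n_bins)
    }
  })
  list(map = spatial_activity_map(per_trial, labels),
       ground_truth = list(selective_ids = selective, tuning_center = centers))
}

#' Expected per-bin selectivity rate under a homoscedastic null
#'
#' If the per-bin differences are i.i.d. normal, `|d(b)| / sd(d(-b))`
#' follows a t distribution with `n_bins - 2` degrees of freedom, so the
#' chance rate of the selectivity rule is `2 * pt(-k, n_bins - 2)` per bin
#' (about 6.1% for k = 2 over 20 bins). Used to calibrate null cohorts.
#'
#' @param n_bins Number of position bins; default 20.
#' @param k Threshold in SDs; default 2.
#' @return Scalar chance rate.
#' @export
selectivity_chance_rate <- function(n_bins = 20, k = 2) {
  2 * stats::pt(-k, df = n_bins - 2)
}

#' Compare peak (or selectivity) proportions between two groups
#'
#' Pearson chi-square (no continuity correction) on the 2 x 2 table of
#' neurons peaking (or selective) within `center_bins` versus elsewhere,
#' group A versus group B. A 2 x n_bins distribution chi-square over all
#' bins is also reported. Which bins count as "near the centre" must be
#' given explicitly.
#'
#' @param a,b `mf_peak_dist` or `mf_selectivity` objects (both the same
#'   kind).
#' @param center_bins Integer bin indices defining the centre window.
#' @return A list of class `mf_prop_test`: `statistic`, `df`, `p`, `table`,
#'   `warning_low_count`, and `full_table_test` (statistic, df, p over all
#'   bins).
#' @export
compare_peak_proportions <- function(a, b, center_bins) {
  stopifnot(length(center_bins) >= 1)
  counts <- function(x) {
    if (inherits(x, "mf_peak_dist")) {
      inb <- sum(x$table$count[center_bins]); tot <- x$n_neurons
      percount <- x$table$count
    } else if (inherits(x, "mf_selectivity")) {
      inb <- sum(rowSums(x$selective[, center_bins, drop = FALSE]) > 0)
      tot <- x$n_neurons
      percount <- x$table$count
    } else stop("unsupported group object", call. = FALSE)
    list(inb = inb, tot = tot, percount = percount)
  }
  ca <- counts(a); cb <- counts(b)
  tab <- matrix(c(ca$inb, ca$tot - ca$inb, cb$inb, cb$tot - cb$inb),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("center", "elsewhere")))
  test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- any(test$expected < 5)
  full <- suppressWarnings(stats::chisq.test(rbind(ca$percount, cb$percount),
                                             correct = FALSE))
  structure(list(statistic = unname(test$statistic), df = unname(test$parameter),
                 p = test$p.value, table = tab, warning_low_count = low,
                 full_table_test = list(statistic = unname(full$statistic),
                                        df = unname(full$parameter),
                                        p = full$p.value)),
            class = "mf_prop_test")
}

#' @export
print.mf_prop_test <- function(x, ...) {
  cat(sprintf("2x2 chi-square: X2 = %.3f, df = %d, p = %.3g%s\n",
              x$statistic, x$df, x$p,
              if (x$warning_low_count) " (low expected counts)" else ""))
  invisible(x)
}

#' Normalize each neuron's mean map to its own maximum (display only)
#'
#' Raster-panel convention: rows scaled to peak 1. Statistics always use
#' unnormalized values.
#'
#' @param map An `mf_spatial_map`.
#' @return Matrix neurons x bins, rows sorted by peak position.
#' @export
raster_matrix <- function(map) {
  stopifnot(inherits(map, "mf_spatial_map"))
  m <- map$mean_map
  mx <- apply(m, 1, max)
  mn <- apply(m, 1, min)
  scaled <- (m - mn) / ifelse(mx > mn, mx - mn, 1)
  peaks <- apply(scaled, 1, which.max)
  scaled[order(peaks), , drop = FALSE]
}
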