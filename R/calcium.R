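#' Construct a trace set
#'
#' Container for a neurons x frames ΔF/F0 matrix with its sampling rate.
#'
#' @param dff Numeric matrix, neurons in rows, frames in columns.
#' @param frame_rate Sampling rate in Hz.
#' @param frame_times Optional frame timestamps in seconds; defaults to
#'   `(0:(nframes-1)) / frame_rate`.
#' @return An object of class `mf_traces`.
#' @export
trace_set <- function(dff, frame_rate = 30, frame_times = NULL) {
  dff <- as.matrix(dff)
  check_positive(frame_rate, "frame_rate")
  if (!all(is.finite(dff))) stop("dff matrix contains non-finite values", call. = FALSE)
  if (is.null(frame_times)) frame_times <- (seq_len(ncol(dff)) - 1) / frame_rate
  stopifnot(length(frame_times) == ncol(dff))
  structure(list(dff = dff, frame_rate = frame_rate,
                 frame_times = as.numeric(frame_times)),
            class = "mf_traces")
}

#' @export
print.mf_traces <- function(x, ...) {
  cat(sprintf("TraceSet: %d neurons x %d frames @ %g Hz (%.1f s)\n",
              nrow(x$dff), ncol(x$dff), x$frame_rate,
              ncol(x$dff) / x$frame_rate))
  invisible(x)
}

#' Compute ΔF/F0 from raw fluorescence
#'
#' F0 is either the session mean of each trace (`"session_mean"`, the
#' convention for full navigation sessions) or the mean over the first 15 s
#' (`"first_15s"`, the convention for stimulation time series).
#'
#' @param raw Numeric matrix (neurons x frames) or vector of raw
#'   fluorescence, all finite.
#' @param f0_mode `"session_mean"` or `"first_15s"`.
#' @param frame_rate Hz; required for `"first_15s"`.
#' @return An `mf_traces` with `dff = (F - F0) / F0`.
#' @examples
#' compute_dff(matrix(c(10, 10, 20, 10), 1), "session_mean")$dff
#' @export
compute_dff <- function(raw, f0_mode = c("session_mean", "first_15s"),
                        frame_rate = 30) {
  f0_mode <- match.arg(f0_mode)
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  raw <- as.matrix(raw)
  if (!all(is.finite(raw))) stop("raw fluorescence must be finite", call. = FALSE)
  f0 <- switch(f0_mode,
    session_mean = rowMeans(raw),
    first_15s = {
      k <- min(ncol(raw), max(1L, floor(15 * frame_rate)))
      rowMeans(raw[, seq_len(k), drop = FALSE])
    })
  bad <- which(f0 <= 0)
  if (length(bad))
    stop(sprintf("F0 <= 0 for trace(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  trace_set(sweep(sweep(raw, 1, f0), 1, f0, "/"), frame_rate)
}

#' Extract a soma trace with annulus background subtraction
#'
#' Per-frame value is the mean over the soma mask minus the median over a
#' surrounding doughnut-shaped background annulus.
#'
#' @param movie Array h x w x frames, or a frames x pixels matrix.
#' @param soma_mask,annulus_mask Logical masks (h x w, or pixel vectors
#'   matching the matrix layout). Must be nonempty and disjoint.
#' @return Numeric vector, one value per frame.
#' @export
extract_trace_with_annulus <- function(movie, soma_mask, annulus_mask) {
  if (length(dim(movie)) == 3) {
    nf <- dim(movie)[3]
    movie <- matrix(movie, ncol = nf)  # pixels x frames
    movie <- t(movie)
  }
  soma <- as.logical(soma_mask); ann <- as.logical(annulus_mask)
  if (!any(soma) || !any(ann)) stop("masks must be nonempty", call. = FALSE)
  if (any(soma & ann)) stop("soma and annulus masks overlap", call. = FALSE)
  stopifnot(ncol(movie) == length(soma))
  rowMeans(movie[, soma, drop = FALSE]) -
    apply(movie[, ann, drop = FALSE], 1, stats::median)
}

#' Select neuronal components by temporal skewness and vessel overlap
#'
#' Calcium signals rise fast and decay slowly, so genuine neuronal time
#' courses are positively skewed; components with sample skewness below
#' `skew_min` are rejected. Components whose brightest spatial-filter
#' pixels lie mostly inside the blood-vessel shadow mask are rejected as
#' blood-flow artifacts. Spatial filters are rectified at zero before the
#' overlap computation.
#'
#' @param time_courses Components x frames matrix of component signals.
#' @param spatial_filters Components x pixels matrix.
#' @param vessel_mask Logical pixel mask of vessel shadows (optional).
#' @param skew_min Minimum sample skewness; default 1.
#' @param max_vessel_overlap Reject if at least this fraction of the
#'   brightest filter pixels falls inside the vessel mask; default 0.5.
#' @param top_frac Fraction of brightest filter pixels used for the overlap
#'   measure; default 0.05.
#' @return Integer indices of accepted components, with per-component
#'   diagnostics in the `"details"` attribute.
#' @export
select_components <- function(time_courses, spatial_filters = NULL,
                              vessel_mask = NULL, skew_min = 1,
                              max_vessel_overlap = 0.5, top_frac = 0.05) {
  time_courses <- as.matrix(time_courses)
  skew <- apply(time_courses, 1, e1071::skewness)
  overlap <- rep(0, nrow(time_courses))
  if (!is.null(spatial_filters) && !is.null(vessel_mask)) {
    spatial_filters <- pmax(as.matrix(spatial_filters), 0)
    vm <- as.logical(vessel_mask)
    for (i in seq_len(nrow(spatial_filters))) {
      f <- spatial_filters[i, ]
      ntop <- max(1L, ceiling(top_frac * sum(f > 0)))
      top <- order(f, decreasing = TRUE)[seq_len(ntop)]
      overlap[i] <- mean(vm[top])
    }
  }
  keep <- which(skew >= skew_min & overlap < max_vessel_overlap)
  attr(keep, "details") <- data.frame(component = seq_along(skew),
                                      skewness = skew, vessel_overlap = overlap)
  keep
}

# Least-squares slope of a trace over a centred moving window (frames per
# frame units). Window length is forced odd; edges use zero (no events are
# scored at the very edges of a recording).
ls_derivative <- function(trace, window_frames) {
  w <- as.integer(window_frames)
  if (w < 2) stop("derivative window shorter than 2 frames", call. = FALSE)
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) %/% 2L
  i <- seq(-half, half)
  coefs <- i / sum(i^2)  # slope of LS line fit
  d <- stats::filter(trace, rev(coefs), sides = 2)
  d[is.na(d)] <- 0
  as.numeric(d)
}

#' Baseline fluctuation statistics of a ΔF/F0 trace
#'
#' Robust estimates of the baseline SD of the trace and of its first
#' derivative, computed as 1.4826 x median absolute deviation over the full
#' trace (events are sparse, so the MAD tracks the event-free baseline).
#' Both SDs are needed by the event detector: the 3-SD acceptance rule uses
#' the trace SD, the 5-SD rise rule uses the derivative SD.
#'
#' @param trace Numeric ΔF/F0 vector.
#' @param fs Sampling rate, Hz.
#' @param deriv_window Derivative window in seconds; default 0.2.
#' @return A list of class `mf_baseline`: `sd_baseline`, `sd_derivative`
#'   (per-frame units), `method`.
#' @export
baseline_stats <- function(trace, fs, deriv_window = 0.2) {
  check_positive(fs, "fs")
  d <- ls_derivative(trace, round(deriv_window * fs))
  structure(list(sd_baseline = stats::mad(trace),
                 sd_derivative = stats::mad(d),
                 method = "mad"),
            class = "mf_baseline")
}

#' Detect rising-phase calcium events in one trace
#'
#' The first derivative of ΔF/F0 is taken as the least-squares slope over a
#' `deriv_window` (200 ms) centred moving window. A candidate event starts
#' at an upward zero-crossing of the derivative (ties at zero resolved to
#' the earlier frame) and ends at the frame before the next downward
#' zero-crossing (the local maximum of the trace); the candidate is kept if
#' the derivative exceeds `deriv_k` x the baseline derivative SD somewhere
#' in between, and if the trace at the event end exceeds `peak_k` x the
#' baseline SD (measured relative to the trace median, so detection is
#' invariant to adding a constant). Event magnitude is the ΔF/F0 difference
#' between end and start. Events separated by fewer than 2 frames are
#' merged; output events are ordered and non-overlapping.
#'
#' @param trace Numeric ΔF/F0 vector.
#' @param fs Sampling rate, Hz.
#' @param stats A [baseline_stats()] object, or `NULL` to compute one.
#' @param deriv_window Derivative window, seconds; default 0.2 (must span
#'   at least 2 frames).
#' @param peak_k Peak acceptance threshold in baseline SDs; default 3.
#' @param deriv_k Rise threshold in derivative SDs; default 5.
#' @return A data.frame of class `mf_events`: `start_frame`, `end_frame`,
#'   `magnitude`, `peak_value`.
#' @export
detect_events <- function(trace, fs, stats = NULL, deriv_window = 0.2,
                          peak_k = 3, deriv_k = 5) {
  check_positive(fs, "fs")
  if (round(deriv_window * fs) < 2)
    stop("derivative window shorter than 2 frames", call. = FALSE)
  if (is.null(stats)) stats <- baseline_stats(trace, fs, deriv_window)
  d <- ls_derivative(trace, round(deriv_window * fs))
  base <- stats::median(trace)
  n <- length(trace)

  pos <- d > 0
  up <- which(pos & !c(FALSE, pos[-n]))          # first positive frame
  down <- which(d < 0 & c(TRUE, d[-n] >= 0))     # first negative frame
  # next downward crossing after each upward crossing
  nxt <- findInterval(up, down) + 1L
  ends <- ifelse(nxt <= length(down), down[pmin(nxt, length(down))] - 1L, n)
  events <- list()
  for (i in seq_along(up)) {
    u <- up[i]; e <- ends[i]
    if (e <= u) next
    if (max(d[u:e]) <= deriv_k * stats$sd_derivative) next
    if ((trace[e] - base) <= peak_k * stats$sd_baseline) next
    events[[length(events) + 1]] <- c(start = u, end = e)
  }
  if (!length(events)) {
    out <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      magnitude = numeric(0), peak_value = numeric(0))
    class(out) <- c("mf_events", "data.frame")
    return(out)
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev[, "start"]), , drop = FALSE]
  merged <- list(ev[1, ])
  if (nrow(ev) > 1) for (i in 2:nrow(ev)) {
    last <- merged[[length(merged)]]
    if (ev[i, "start"] - last["end"] < 2) {
      last["end"] <- ev[i, "end"]
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1]] <- ev[i, ]
  }
  mv <- do.call(rbind, merged)
  out <- data.frame(start_frame = as.integer(mv[, "start"]),
                    end_frame = as.integer(mv[, "end"]),
                    magnitude = trace[mv[, "end"]] - trace[mv[, "start"]],
                    peak_value = trace[mv[, "end"]] - base)
  class(out) <- c("mf_events", "data.frame")
  out
}

#' Detect events for every neuron of a trace set
#'
#' @param traces An `mf_traces`.
#' @param ... Passed to [detect_events()].
#' @return A data.frame with a `neuron` column prepended.
#' @export
detect_events_all <- function(traces, ...) {
  stopifnot(inherits(traces, "mf_traces"))
  res <- lapply(seq_len(nrow(traces$dff)), function(i) {
    ev <- detect_events(traces$dff[i, ], traces$frame_rate, ...)
    if (nrow(ev)) cbind(neuron = i, ev) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(neuron = integer(0), start_frame = integer(0),
                                      end_frame = integer(0), magnitude = numeric(0),
                                      peak_value = numeric(0))
  out
}

#' Overall activity of a trace
#'
#' The sample standard deviation of a ΔF/F trace, used as the summary
#' measure of overall cortical activity in validation imaging.
#'
#' @param trace Numeric vector.
#' @return Scalar SD.
#' @export
activity_sd <- function(trace) stats::sd(trace)

#' Relative activity change between two conditions
#'
#' `(sd2 - sd1) / sd1`, where `sd1` summarizes activity before and `sd2`
#' after a treatment. Multiply by 100 for display as a percentage.
#'
#' @param sd1,sd2 Activity SDs before and after.
#' @return Scalar relative change.
#' @export
activity_change <- function(sd1, sd2) {
  if (!is_scalar_number(sd1) || sd1 <= 0) stop("`sd1` must be > 0", call. = FALSE)
  (sd2 - sd1) / sd1
}

#' Onset frame of a stimulation time series
#'
#' @param onset_s Stimulus time after imaging start, seconds (default 20).
#' @param frame_dt Frame interval, seconds (default 0.351).
#' @return 1-based index of the frame nearest the onset time
#'   (`round(onset_s / frame_dt) + 1`).
#' @export
stim_onset_frame <- function(onset_s = 20, frame_dt = 0.351) {
  as.integer(round(onset_s / frame_dt)) + 1L
}

#' Baseline-referenced stimulation time course
#'
#' Converts raw stimulation-response series to ΔF/F against the mean of the
#' first `baseline_s` seconds and summarizes across animals as mean and SEM
#' per frame.
#'
#' @param series Matrix animals x frames of raw fluorescence (or a single
#'   series as a vector), one stimulation condition.
#' @param frame_dt Frame interval, seconds; default 0.351.
#' @param baseline_s Baseline window, seconds; default 15.
#' @param onset_s Stimulus onset, seconds; default 20. Must lie within the
#'   series.
#' @return A data.frame of class `mf_stim_tc`: `time_s`, `mean_dff`,
#'   `sem_dff`; attributes `onset_frame`, `n`.
#' @export
stim_timecourse <- function(series, frame_dt = 0.351, baseline_s = 15,
                            onset_s = 20) {
  if (is.null(dim(series))) series <- matrix(series, nrow = 1)
  series <- as.matrix(series)
  nb <- max(1L, floor(baseline_s / frame_dt))
  if (nb > ncol(series)) stop("baseline window longer than series", call. = FALSE)
  if (stim_onset_frame(onset_s, frame_dt) > ncol(series))
    stop("onset beyond end of series", call. = FALSE)
  f0 <- rowMeans(series[, seq_len(nb), drop = FALSE])
  if (any(f0 <= 0)) stop("baseline F0 <= 0", call. = FALSE)
  dff <- sweep(sweep(series, 1, f0), 1, f0, "/")
  out <- data.frame(time_s = (seq_len(ncol(series)) - 1) * frame_dt,
                    mean_dff = colMeans(dff),
                    sem_dff = if (nrow(dff) > 1) apply(dff, 2, sem) else 0)
  attr(out, "onset_frame") <- stim_onset_frame(onset_s, frame_dt)
  attr(out, "n") <- nrow(series)
  class(out) <- c("mf_stim_tc", "data.frame")
  out
}
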