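#' Configuration for simulated calcium traces
#'
#' Neurons fire position-tuned events while the simulated animal runs
#' trials: the event rate is a Gaussian bump over track bins centred on
#' each neuron's tuning bin, on top of a uniform baseline rate. Events are
#' unit impulses of `event_amplitude` convolved with a
#' difference-of-exponentials calcium kernel (GCaMP6s-like: 0.1 s rise,
#' 1 s decay), and i.i.d. Gaussian noise is added. A `frac_selective`
#' subset of neurons has all event amplitudes multiplied by
#' `selective_gain` on alternating trials.
#'
#' Defaults emulate a miniscope recording: 30 Hz, transients of ~0.5 ΔF/F0
#' against ~0.05 noise SD, broad frontal-cortex tuning (width 3 bins) with
#' substantial out-of-field baseline firing.
#'
#' @param n_neurons Number of neurons.
#' @param frame_rate Hz; default 30.
#' @param tuning_center Tuning bin per neuron (1..n_bins): a scalar, a
#'   vector of length `n_neurons`, or `NULL` to draw uniformly at random.
#' @param tuning_width Gaussian tuning width in bins; default 3.
#' @param peak_rate Event rate at the tuning bin, Hz; default 1.5.
#' @param baseline_rate Event rate far from the tuning bin, Hz; default 0.3.
#' @param event_amplitude ΔF/F0 amplitude of one event; default 0.5.
#' @param kernel_rise,kernel_decay Calcium kernel time constants, seconds
#'   (defaults 0.1 and 1.0); `kernel_decay` must exceed `kernel_rise`.
#' @param noise_sd SD of additive Gaussian noise, ΔF/F0 units; default 0.05.
#' @param frac_selective Proportion of neurons with alternation-dependent
#'   gain; default 0.
#' @param selective_gain Amplitude multiplier on alternating trials for
#'   selective neurons; default 2.
#' @param n_bins Number of track bins; default 20.
#' @param seed Integer seed.
#' @return A list of class `mf_trace_cfg`.
#' @export
trace_sim_config <- function(n_neurons = 50, frame_rate = 30,
                             tuning_center = NULL, tuning_width = 3,
                             peak_rate = 1.5, baseline_rate = 0.3,
                             event_amplitude = 0.5,
                             kernel_rise = 0.1, kernel_decay = 1.0,
                             noise_sd = 0.05, frac_selective = 0,
                             selective_gain = 2, n_bins = 20, seed = 1L) {
  check_positive(frame_rate, "frame_rate")
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is_scalar_number(frac_selective) || frac_selective < 0 || frac_selective > 1)
    stop("`frac_selective` must be in [0, 1]", call. = FALSE)
  if (kernel_decay <= kernel_rise)
    stop("`kernel_decay` must exceed `kernel_rise`", call. = FALSE)
  structure(list(n_neurons = n_neurons, frame_rate = frame_rate,
                 tuning_center = tuning_center, tuning_width = tuning_width,
                 peak_rate = peak_rate, baseline_rate = baseline_rate,
                 event_amplitude = event_amplitude,
                 kernel_rise = kernel_rise, kernel_decay = kernel_decay,
                 noise_sd = noise_sd, frac_selective = frac_selective,
                 selective_gain = selective_gain, n_bins = n_bins,
                 seed = as.integer(seed)),
            class = "mf_trace_cfg")
}

# Difference-of-exponentials calcium kernel, peak-normalized to 1 so that
# an isolated event of amplitude a produces a trace peak of a.
calcium_kernel <- function(rise, decay, fs, len_s = NULL) {
  if (decay <= rise) stop("`kernel_decay` must exceed `kernel_rise`", call. = FALSE)
  if (is.null(len_s)) len_s <- 6 * decay
  t <- seq(0, len_s, by = 1 / fs)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

# Forward shift (in frames) that convolution with the calcium kernel
# imposes on the mode of a Gaussian rate bump of SD `sigma_s` seconds:
# the smear the slow indicator adds to position-binned activity.
kernel_mode_shift_frames <- function(kern, sigma_s, fs) {
  dt <- 1 / fs
  bump <- stats::dnorm(seq(-4 * sigma_s, 4 * sigma_s, by = dt), 0, sigma_s)
  sm <- stats::convolve(c(bump, numeric(length(kern))), rev(kern), type = "open")
  max(0L, which.max(sm) - which.max(bump))
}

#' Simulate a position-tuned calcium trace set over a trajectory
#'
#' @param traj An `mf_trajectory`, typically from [simulate_trajectory()].
#' @param cfg A [trace_sim_config()].
#' @param trials Optional `mf_trials`; segmented from `traj` if omitted.
#' @return A list of class `mf_sim_traces`: `traces` (an `mf_traces`),
#'   `trials`, `bins` (per-trial frame/bin tables) and `ground_truth` with
#'   per-neuron event frames and amplitudes, tuning centres and the
#'   selective neuron ids.
#' @export
simulate_trace_set <- function(traj, cfg, trials = NULL) {
  stopifnot(inherits(traj, "mf_trajectory"), inherits(cfg, "mf_trace_cfg"))
  if (is.null(trials)) {
    entries <- detect_arm_entries(traj)
    trials <- segment_trials(traj, entries)
  }
  if (nrow(trials) < 1) stop("trajectory covers no trials", call. = FALSE)
  bins <- bin_trials(trials, traj, cfg$n_bins)
  nf <- length(traj$time_s)

  # per-frame bin index (NA outside trials) and trial id
  frame_bin <- rep(NA_integer_, nf)
  frame_trial <- rep(NA_integer_, nf)
  for (k in seq_along(bins)) {
    frame_bin[bins[[k]]$frame] <- bins[[k]]$bin
    frame_trial[bins[[k]]$frame] <- k
  }

  with_seed(cfg$seed, {
    centers <- cfg$tuning_center
    if (is.null(centers)) centers <- sample.int(cfg$n_bins, cfg$n_neurons, replace = TRUE)
    if (length(centers) == 1) centers <- rep(centers, cfg$n_neurons)
    stopifnot(length(centers) == cfg$n_neurons)
    n_sel <- round(cfg$frac_selective * cfg$n_neurons)
    selective <- sort(sample.int(cfg$n_neurons, n_sel))
    kern <- calcium_kernel(cfg$kernel_rise, cfg$kernel_decay, cfg$frame_rate)
    # Tuning is defined on the measured calcium signal: the slow indicator
    # smears binned activity forward, so the event rate is driven by the
    # bin the animal occupies `lag` frames later (anticipatory firing,
    # consistent with premotor position coding), where `lag` is the mode
    # shift the kernel imposes on a bump of this tuning width.
    med_dur <- stats::median(trials$end_s - trials$start_s)
    sigma_s <- cfg$tuning_width * med_dur / cfg$n_bins
    lag <- kernel_mode_shift_frames(kern, sigma_s, cfg$frame_rate)
    if (lag > 0) frame_bin <- c(frame_bin[(lag + 1):nf], rep(NA_integer_, lag))
    alt_frame <- !is.na(frame_trial) &
      !is.na(trials$is_alternation[pmax(frame_trial, 1L)]) &
      trials$is_alternation[pmax(frame_trial, 1L)] %in% TRUE

    dff <- matrix(0, cfg$n_neurons, nf)
    events <- vector("list", cfg$n_neurons)
    for (i in seq_len(cfg$n_neurons)) {
      dist2 <- (frame_bin - centers[i])^2
      rate <- ifelse(is.na(frame_bin), cfg$baseline_rate,
                     cfg$baseline_rate +
                       (cfg$peak_rate - cfg$baseline_rate) *
                       exp(-dist2 / (2 * cfg$tuning_width^2)))
      fire <- stats::runif(nf) < rate / cfg$frame_rate
      frames <- which(fire)
      amp <- rep(cfg$event_amplitude, length(frames))
      if (i %in% selective && length(frames))
        amp[alt_frame[frames]] <- amp[alt_frame[frames]] * cfg$selective_gain
      sig <- numeric(nf + length(kern))
      for (j in seq_along(frames)) {  # events are sparse: add kernels directly
        idx <- frames[j]:(frames[j] + length(kern) - 1L)
        sig[idx] <- sig[idx] + amp[j] * kern
      }
      sig <- sig[seq_len(nf)]
      dff[i, ] <- sig + stats::rnorm(nf, 0, cfg$noise_sd)
      events[[i]] <- data.frame(frame = frames, amplitude = amp)
    }
  })
  structure(list(
    traces = trace_set(dff, cfg$frame_rate, traj$time_s),
    trials = trials, bins = bins,
    ground_truth = list(events = events, tuning_center = centers,
                        selective_ids = selective, seed = cfg$seed)),
    class = "mf_sim_traces")
}

#' Simulate a VTA-stimulation response series
#'
#' A 115-frame fluorescence series at 0.351 s/frame with the stimulus at
#' 20 s after imaging start. The response is an instant-rise exponential
#' decay whose peak scales linearly with the pulse count
#' (`amplitude` is the ΔF/F peak at `n_ref` pulses). The returned series is
#' raw fluorescence around a baseline level, ready for [stim_timecourse()].
#'
#' @param n_pulses Number of stimulation pulses (>= 0).
#' @param amplitude ΔF/F response peak at `n_ref` pulses; default 0.5.
#' @param decay Response decay constant, seconds; default 8.
#' @param noise_sd SD of Gaussian noise in ΔF/F units; default 0.
#' @param n_frames,frame_dt Series length and frame interval (defaults 115
#'   and 0.351 s).
#' @param onset_s Stimulus time, seconds; default 20.
#' @param n_ref Reference pulse count at which the peak equals `amplitude`;
#'   default 10.
#' @param f_baseline Baseline fluorescence level; default 100.
#' @param seed Optional seed for the noise.
#' @return A list of class `mf_sim_stim`: `raw` (fluorescence vector),
#'   `time_s`, `onset_frame` (1-based), and `ground_truth` with the
#'   noiseless ΔF/F response.
#' @export
simulate_stim_response <- function(n_pulses, amplitude = 0.5, decay = 8,
                                   noise_sd = 0, n_frames = 115,
                                   frame_dt = 0.351, onset_s = 20,
                                   n_ref = 10, f_baseline = 100, seed = NULL) {
  if (!is_scalar_number(n_pulses) || n_pulses < 0)
    stop("`n_pulses` must be >= 0", call. = FALSE)
  t <- (seq_len(n_frames) - 1) * frame_dt
  onset <- stim_onset_frame(onset_s, frame_dt)
  peak <- amplitude * n_pulses / n_ref
  resp <- numeric(n_frames)
  post <- seq(onset, n_frames)
  resp[post] <- peak * exp(-(t[post] - t[onset]) / decay)
  noise <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(n_frames, 0, noise_sd)) else 0
  structure(list(raw = f_baseline * (1 + resp + noise), time_s = t,
                 onset_frame = onset,
                 ground_truth = list(response_dff = resp, peak = peak,
                                     n_pulses = n_pulses)),
            class = "mf_sim_stim")
}
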