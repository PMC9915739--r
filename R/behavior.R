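#' Detect arm entries from a maze trajectory
#'
#' An entry is recorded when the tracked point penetrates beyond
#' `entry_fraction` of an arm's length from the centre, for an arm different
#' from the current one. This operationalizes the "all four paws entered"
#' convention at centroid level; the fraction is configurable. The returned
#' sequence never contains an immediate repeat.
#'
#' @param traj An `mf_trajectory`.
#' @param entry_fraction Fraction of arm length that must be penetrated to
#'   count as an entry; default 0.2.
#' @return A data.frame of class `mf_entries` with columns `arm`, `time_s`,
#'   `frame`. Empty (zero-row) if the trajectory never leaves the centre.
#' @export
detect_arm_entries <- function(traj, entry_fraction = 0.2) {
  stopifnot(inherits(traj, "mf_trajectory"))
  if (!is_scalar_number(entry_fraction) || entry_fraction <= 0 || entry_fraction >= 1)
    stop("`entry_fraction` must be in (0, 1)", call. = FALSE)
  cf <- classify_frames(traj)
  thr <- entry_fraction * traj$geometry$arm_length
  inside <- cf$r > thr
  arm <- ifelse(inside, cf$arm, NA_integer_)
  entries <- integer(0); frames <- integer(0)
  current <- NA_integer_
  for (i in which(inside)) {
    if (is.na(current) || arm[i] != current) {
      current <- arm[i]
      entries <- c(entries, current)
      frames <- c(frames, i)
    }
  }
  out <- data.frame(arm = traj$geometry$arm_labels[entries],
                    time_s = traj$time_s[frames], frame = frames,
                    stringsAsFactors = FALSE)
  class(out) <- c("mf_entries", "data.frame")
  out
}

#' Score spontaneous alternation
#'
#' Counts consecutive entry triplets whose three arms are all distinct
#' (e.g. ABC) and reports the alternation percentage,
#' 100 x alternating triplets / (total entries - 2), together with the
#' total entry count. With fewer than three entries the percentage is
#' undefined and flagged as insufficient data.
#'
#' @param entries An `mf_entries` data.frame, an `mf_sim_entries` object,
#'   or a character vector of arm labels.
#' @return A list of class `mf_alternation`: `percent`, `n_alternating`,
#'   `n_entries`, `insufficient`.
#' @examples
#' score_alternation(c("A", "B", "C", "A", "B", "C"))$percent  # 100
#' score_alternation(c("A", "B", "A", "B"))$percent            # 0
#' @export
score_alternation <- function(entries) {
  arms <- entry_arms(entries)
  n <- length(arms)
  if (n < 3) {
    return(structure(list(percent = NA_real_, n_alternating = NA_integer_,
                          n_entries = n, insufficient = TRUE),
                     class = "mf_alternation"))
  }
  alt <- arms[3:n] != arms[1:(n - 2)]  # third arm differs from first;
  # consecutive entries never repeat, so distinct-from-two-back is the
  # full non-repeating-triplet condition
  structure(list(percent = 100 * sum(alt) / (n - 2),
                 n_alternating = sum(alt), n_entries = n,
                 insufficient = FALSE),
            class = "mf_alternation")
}

entry_arms <- function(entries) {
  arms <- if (inherits(entries, "mf_sim_entries")) entries$arms
  else if (is.data.frame(entries)) entries$arm
  else as.character(entries)
  if (length(arms) > 1 && any(arms[-1] == arms[-length(arms)]))
    stop("entry sequence contains an immediate repeat", call. = FALSE)
  arms
}

#' @export
print.mf_alternation <- function(x, ...) {
  if (x$insufficient) {
    cat(sprintf("Alternation: undefined (%d entries, need >= 3)\n", x$n_entries))
  } else {
    cat(sprintf("Alternation: %.1f%% (%d/%d triplets, %d entries)\n",
                x$percent, x$n_alternating, x$n_entries - 2, x$n_entries))
  }
  invisible(x)
}

#' Segment a session into terminal-to-terminal trials
#'
#' One trial per consecutive entry pair. A trial begins at the last frame at
#' the origin terminal before the animal moves away (speed rising above
#' `stop_speed`) and ends at the first frame at the destination terminal
#' where speed stays below `stop_speed` for `stop_window` seconds. Each
#' trial is labelled `is_alternation` if its destination differs from the
#' arm visited two entries before (it completes a non-repeating triplet);
#' the first trial of a session is unlabelled. Traversals that never reach
#' the destination terminal are flagged in `aborted` and excluded.
#'
#' @param traj An `mf_trajectory`.
#' @param entries Entries detected from `traj` with [detect_arm_entries()].
#' @param stop_speed Speed threshold in cm/s below which the animal counts
#'   as stopped; default 2.
#' @param terminal_fraction Fraction of arm length beyond which a position
#'   counts as "at the terminal"; default 0.85.
#' @param stop_window Time the speed must stay low to count as stopped,
#'   seconds; default 0.5.
#' @return A data.frame of class `mf_trials` with columns `origin`,
#'   `destination`, `start_s`, `end_s`, `start_frame`, `end_frame`,
#'   `is_alternation`; attribute `n_aborted` counts excluded traversals.
#' @export
segment_trials <- function(traj, entries, stop_speed = 2,
                           terminal_fraction = 0.85, stop_window = 0.5) {
  stopifnot(inherits(traj, "mf_trajectory"), is.data.frame(entries))
  n <- nrow(entries)
  if (n < 2) {
    out <- data.frame(origin = character(0), destination = character(0),
                      start_s = numeric(0), end_s = numeric(0),
                      start_frame = integer(0), end_frame = integer(0),
                      is_alternation = logical(0))
    class(out) <- c("mf_trials", "data.frame")
    attr(out, "n_aborted") <- 0L
    return(out)
  }
  cf <- classify_frames(traj)
  speed <- frame_speed(traj)
  dt <- stats::median(diff(traj$time_s))
  wk <- max(1L, round(stop_window / dt))
  nf <- length(traj$time_s)
  at_term <- cf$r >= terminal_fraction * traj$geometry$arm_length
  labels <- traj$geometry$arm_labels

  # stopped[i]: speed stays below stop_speed for the next stop_window
  below <- speed < stop_speed
  cs <- cumsum(c(0, below))
  stopped <- logical(nf)
  last <- pmin(nf, seq_len(nf) + wk - 1L)
  stopped <- (cs[last + 1L] - cs[seq_len(nf)]) == (last - seq_len(nf) + 1L)

  rows <- vector("list", n - 1)
  aborted <- 0L
  for (k in seq_len(n - 1)) {
    o <- match(entries$arm[k], labels)
    d <- match(entries$arm[k + 1], labels)
    f0 <- entries$frame[k]
    f1 <- entries$frame[k + 1]
    f2 <- if (k + 2 <= n) entries$frame[k + 2] else nf
    # last frame at the origin terminal before the destination entry
    origin_term <- which(at_term[f0:f1] & cf$arm[f0:f1] == o) + f0 - 1L
    # first stopped frame at the destination terminal
    dest_term <- which(at_term[f1:f2] & cf$arm[f1:f2] == d & stopped[f1:f2]) + f1 - 1L
    if (length(origin_term) == 0 || length(dest_term) == 0) {
      aborted <- aborted + 1L
      next
    }
    start <- origin_term[length(origin_term)]
    end <- dest_term[1]
    rows[[k]] <- data.frame(
      origin = labels[o], destination = labels[d],
      start_s = traj$time_s[start], end_s = traj$time_s[end],
      start_frame = start, end_frame = end,
      is_alternation = if (k == 1) NA else entries$arm[k + 1] != entries$arm[k - 1],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(origin = character(0), destination = character(0),
                                      start_s = numeric(0), end_s = numeric(0),
                                      start_frame = integer(0), end_frame = integer(0),
                                      is_alternation = logical(0))
  if (nrow(out) > 1 && any(out$start_frame[-1] < out$end_frame[-nrow(out)]))
    stop("internal error: overlapping trials", call. = FALSE)
  class(out) <- c("mf_trials", "data.frame")
  attr(out, "n_aborted") <- aborted
  out
}

#' Map trial frames to track-position bins
#'
#' The path-length coordinate from the origin terminal (0) to the
#' destination terminal (1) is divided into `n_bins` half-open equal
#' intervals `[k/n, (k+1)/n)`, the top bin closed. Bins are 1-based and run
#' in the direction of travel, so with equal arm lengths the maze centre
#' lies exactly at the bin n/2 | n/2+1 boundary and a frame at the centre
#' falls in bin n/2 + 1 (bin 11 of 20).
#'
#' @param trial One row of an `mf_trials` data.frame.
#' @param traj The trajectory the trials were segmented from.
#' @param n_bins Number of bins; default 20.
#' @return Integer vector of bin indices, one per frame in
#'   `trial$start_frame:trial$end_frame`.
#' @export
bin_position <- function(trial, traj, n_bins = 20) {
  stopifnot(inherits(traj, "mf_trajectory"), nrow(trial) == 1)
  frames <- trial$start_frame:trial$end_frame
  if (length(frames) < 2) stop("zero-length trial", call. = FALSE)
  cf <- classify_frames(traj)
  L <- traj$geometry$arm_length
  o <- match(trial$origin, traj$geometry$arm_labels)
  r <- cf$r[frames]
  in_origin <- cf$arm[frames] == o
  u <- ifelse(in_origin, (L - r) / (2 * L), (L + r) / (2 * L))
  u <- pmin(pmax(u, 0), 1)
  pmin(floor(u * n_bins) + 1L, n_bins)
}

#' Bin every trial of a session
#'
#' @inheritParams bin_position
#' @param trials An `mf_trials` data.frame.
#' @return A list with one data.frame per trial (`frame`, `bin`).
#' @export
bin_trials <- function(trials, traj, n_bins = 20) {
  lapply(seq_len(nrow(trials)), function(k) {
    tr <- trials[k, ]
    data.frame(frame = tr$start_frame:tr$end_frame,
               bin = bin_position(tr, traj, n_bins))
  })
}
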