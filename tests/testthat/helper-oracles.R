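# Shared fixtures and independent brute-force oracles used across tests.

# A small simulated session reused by several files.
make_session <- function(seed = 3, p_alternate = 0.6, duration = 480) {
  cfg <- behavior_sim_config(p_alternate = p_alternate,
                             session_duration = duration, seed = seed)
  entries <- simulate_arm_entries(cfg)
  traj <- simulate_trajectory(entries, cfg)
  list(cfg = cfg, entries = entries, traj = traj)
}

# Independent triplet scorer: literal enumeration of all consecutive
# triplets, checking that the three arms are pairwise distinct.
oracle_alternation_percent <- function(arms) {
  n <- length(arms)
  if (n < 3) return(NA_real_)
  hits <- 0
  for (k in 1:(n - 2)) {
    tri <- arms[k:(k + 2)]
    if (length(unique(tri)) == 3) hits <- hits + 1
  }
  100 * hits / (n - 2)
}

# Brute-force event scanner: enumerate every (upward, downward)
# zero-crossing pair of the derivative with no crossing in between, apply
# the rise / peak rules literally, then merge events separated by < 2
# frames. Independent of the streaming implementation's bookkeeping.
oracle_detect_events <- function(trace, fs, deriv_window = 0.2,
                                 peak_k = 3, deriv_k = 5) {
  st <- baseline_stats(trace, fs, deriv_window)
  d <- mesoframe:::ls_derivative(trace, round(deriv_window * fs))
  n <- length(trace)
  base <- stats::median(trace)
  up <- which(d > 0 & c(-1, d[-n]) <= 0)
  down <- which(d < 0 & c(1, d[-n]) >= 0)
  found <- list()
  for (u in up) for (e in c(down, n + 1L)) {
    if (e <= u) next
    between <- c(up, down)
    between <- between[between > u & between < e]
    if (length(between)) next           # not the *next* crossing
    end <- min(e - 1L, n)
    if (end <= u) next
    if (max(d[u:end]) <= deriv_k * st$sd_derivative) next
    if ((trace[end] - base) <= peak_k * st$sd_baseline) next
    found[[length(found) + 1]] <- c(u, end)
    break
  }
  if (!length(found)) return(data.frame(start_frame = integer(0),
                                        end_frame = integer(0)))
  m <- do.call(rbind, found)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- list(m[1, ])
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    last <- out[[length(out)]]
    if (m[i, 1] - last[2] < 2) {
      last[2] <- m[i, 2]; out[[length(out)]] <- last
    } else out[[length(out) + 1]] <- m[i, ]
  }
  m <- do.call(rbind, out)
  data.frame(start_frame = m[, 1], end_frame = m[, 2])
}

# Direct per-neuron enumeration of the selectivity rule.
oracle_selectivity <- function(d, k = 2) {
  n <- nrow(d); nb <- ncol(d)
  out <- matrix(FALSE, n, nb)
  for (i in 1:n) for (b in 1:nb) {
    others <- d[i, -b]
    s <- stats::sd(others)
    out[i, b] <- if (s == 0) abs(d[i, b]) > 0 else abs(d[i, b]) > k * s
  }
  out
}

# Flood-fill component count of a thresholded image (4-connectivity),
# independent of EBImage.
oracle_count_blobs <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[2] < 1 || p[1] > nrow(mask) || p[2] > ncol(mask)) next
      if (!mask[p[1], p[2]] || lab[p[1], p[2]] > 0) next
      lab[p[1], p[2]] <- cur
      stack <- c(stack, list(p + c(1, 0)), list(p - c(1, 0)),
                 list(p + c(0, 1)), list(p - c(0, 1)))
    }
  }
  cur
}

# Greedy matching of detected event starts to ground-truth frames.
match_events <- function(detected_starts, truth_frames, tol = 10) {
  used <- rep(FALSE, length(detected_starts))
  tp <- 0L
  for (g in truth_frames) {
    j <- which(!used & abs(detected_starts - g) <= tol)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = sum(!used), fn = length(truth_frames) - tp)
}

# Collapse ground-truth impulses closer than `gap` frames: impulses inside
# one derivative window form a single rising phase (one event).
merge_truth <- function(frames, gap = 10) frames[c(TRUE, diff(frames) >= gap)]
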