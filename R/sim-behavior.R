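#' Configuration for simulated Y-maze behaviour
#'
#' The entry process is first-order Markov on (previous arm, current arm):
#' at each arm exit the agent takes the "new" arm (the one visited least
#' recently) with probability `p_alternate`, otherwise returns to the
#' previously visited arm; it never re-enters the arm it is in. A uniform
#' random agent corresponds to `p_alternate = 0.5` (two available arms, one
#' of which is new), which is the chance level of the alternation score.
#'
#' @param n_sessions Number of sessions to simulate.
#' @param session_duration Session length in seconds (default 480, an 8-min
#'   session).
#' @param arm_length,arm_width Maze geometry in cm (defaults 45 and 8).
#' @param p_alternate Probability of choosing the new arm at each exit.
#' @param mean_dwell Mean pause at an arm terminal, seconds.
#' @param speed Running speed along the maze, cm/s.
#' @param pos_noise SD of Gaussian tracking jitter added to positions, cm.
#' @param sample_rate Position sampling rate, Hz (default 30, matched to the
#'   imaging frame rate).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `mf_behavior_cfg`.
#' @export
behavior_sim_config <- function(n_sessions = 1, session_duration = 480,
                                arm_length = 45, arm_width = 8,
                                p_alternate = 0.67, mean_dwell = 1.5,
                                speed = 10, pos_noise = 0.1,
                                sample_rate = 30, seed = 1L) {
  if (!is_scalar_number(p_alternate) || p_alternate < 0 || p_alternate > 1)
    stop("`p_alternate` must be a probability in [0, 1]", call. = FALSE)
  check_positive(session_duration, "session_duration")
  check_positive(speed, "speed")
  check_positive(sample_rate, "sample_rate")
  structure(list(n_sessions = n_sessions, session_duration = session_duration,
                 arm_length = arm_length, arm_width = arm_width,
                 p_alternate = p_alternate, mean_dwell = mean_dwell,
                 speed = speed, pos_noise = pos_noise,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "mf_behavior_cfg")
}

#' Simulate a sequence of Y-maze arm entries
#'
#' First two entries are drawn uniformly without an immediate repeat. Each
#' later entry is the new arm with probability `p_alternate`, otherwise the
#' previously visited arm, and never the current arm.
#'
#' @param cfg A [behavior_sim_config()].
#' @param n_entries Number of entries; if `NULL`, derived from the session
#'   duration, speed and dwell (one traversal is two arm lengths).
#' @return A list of class `mf_sim_entries`: `arms` (character vector),
#'   `is_alternation` (logical per entry; `NA` for the first two), and the
#'   seed used. The alternation flags are the ground truth for triplet
#'   scoring: entry k alternates iff it differs from entry k-2.
#' @export
simulate_arm_entries <- function(cfg, n_entries = NULL) {
  stopifnot(inherits(cfg, "mf_behavior_cfg"))
  if (is.null(n_entries)) {
    per_trial <- 2 * cfg$arm_length / cfg$speed + cfg$mean_dwell
    n_entries <- max(3L, 1L + floor(cfg$session_duration / per_trial))
  }
  arms <- c("A", "B", "C")
  seq <- character(n_entries)
  with_seed(cfg$seed, {
    seq[1] <- sample(arms, 1)
    seq[2] <- sample(setdiff(arms, seq[1]), 1)
    if (n_entries > 2) {
      u <- stats::runif(n_entries - 2)
      for (k in 3:n_entries) {
        new_arm <- setdiff(arms, seq[c(k - 1, k - 2)])
        seq[k] <- if (u[k - 2] < cfg$p_alternate) new_arm else seq[k - 2]
      }
    }
  })
  flags <- rep(NA, n_entries)
  if (n_entries > 2) flags[3:n_entries] <- seq[3:n_entries] != seq[1:(n_entries - 2)]
  structure(list(arms = seq, is_alternation = flags,
                 p_alternate = cfg$p_alternate, seed = cfg$seed),
            class = "mf_sim_entries")
}

#' @export
print.mf_sim_entries <- function(x, ...) {
  cat(sprintf("Simulated entries: n = %d, p_alternate = %.2f\n",
              length(x$arms), x$p_alternate))
  cat(" ", paste(utils::head(x$arms, 30), collapse = ""),
      if (length(x$arms) > 30) "..." else "", "\n")
  invisible(x)
}

#' Simulate a continuous maze trajectory from an entry sequence
#'
#' Produces a centre-of-mass position series that visits the arm terminals
#' in the given order, always passing through the maze centre between arms,
#' at constant running speed with a pause at each terminal. Gaussian
#' tracking jitter (`cfg$pos_noise`) is added to the sampled positions.
#'
#' @param entries An [simulate_arm_entries()] result or a character vector
#'   of arm labels.
#' @param cfg A [behavior_sim_config()].
#' @return An `mf_trajectory` whose `"ground_truth"` attribute records the
#'   entry sequence, per-visit terminal arrival/departure times and the
#'   alternation flags.
#' @export
simulate_trajectory <- function(entries, cfg) {
  stopifnot(inherits(cfg, "mf_behavior_cfg"))
  arms <- if (inherits(entries, "mf_sim_entries")) entries$arms else as.character(entries)
  if (length(arms) < 1) stop("`entries` must be nonempty", call. = FALSE)
  geom <- maze_geometry(cfg$arm_length, cfg$arm_width)
  idx <- match(arms, geom$arm_labels)
  if (anyNA(idx)) stop("unknown arm label in `entries`", call. = FALSE)
  L <- cfg$arm_length
  term_x <- geom$unit_x * L
  term_y <- geom$unit_y * L

  # key points: terminal_1, (centre, terminal_k, ...) with dwell at terminals
  with_seed(child_seed(cfg$seed, "trajectory"), {
    n <- length(idx)
    dwell <- cfg$mean_dwell * stats::runif(n, 0.8, 1.2)
    dwell <- pmax(dwell, 0.6)  # long enough for the stop rule to latch
    kx <- ky <- kt <- numeric(0)
    t_now <- 0
    arrive <- depart <- numeric(n)
    add <- function(x, y, t) { kx <<- c(kx, x); ky <<- c(ky, y); kt <<- c(kt, t) }
    add(term_x[idx[1]], term_y[idx[1]], t_now)
    arrive[1] <- 0
    t_now <- t_now + dwell[1]
    depart[1] <- t_now
    add(term_x[idx[1]], term_y[idx[1]], t_now)
    if (n > 1) for (k in 2:n) {
      t_now <- t_now + L / cfg$speed
      add(0, 0, t_now)
      t_now <- t_now + L / cfg$speed
      add(term_x[idx[k]], term_y[idx[k]], t_now)
      arrive[k] <- t_now
      t_now <- t_now + dwell[k]
      depart[k] <- t_now
      add(term_x[idx[k]], term_y[idx[k]], t_now)
    }
    dt <- 1 / cfg$sample_rate
    ts <- seq(0, t_now, by = dt)
    px <- stats::approx(kt, kx, xout = ts)$y + stats::rnorm(length(ts), 0, cfg$pos_noise)
    py <- stats::approx(kt, ky, xout = ts)$y + stats::rnorm(length(ts), 0, cfg$pos_noise)
  })
  traj <- trajectory(ts, px, py, geom)
  flags <- rep(NA, length(arms))
  if (length(arms) > 2) flags[3:length(arms)] <- arms[3:length(arms)] != arms[1:(length(arms) - 2)]
  attr(traj, "ground_truth") <- list(arms = arms, arrive_s = arrive,
                                     depart_s = depart, is_alternation = flags)
  traj
}
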