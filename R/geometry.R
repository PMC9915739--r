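#' Y-maze geometry
#'
#' Describes a symmetric three-arm maze: arm axes at 120 degrees around a
#' common centre, with a length and width per arm. All behavioural analyses
#' take positions in centimetres in the maze frame, centre at the origin.
#'
#' @param arm_length Arm length from centre to terminal, cm (default 45).
#' @param arm_width Arm width, cm (default 8).
#' @param arm_labels Arm identifiers, default `c("A", "B", "C")`.
#' @param angles_deg Direction of each arm axis in degrees; default
#'   `c(90, 210, 330)` (one arm pointing "up").
#' @return An object of class `mf_geometry` with the arm unit vectors.
#' @export
maze_geometry <- function(arm_length = 45, arm_width = 8,
                          arm_labels = c("A", "B", "C"),
                          angles_deg = c(90, 210, 330)) {
  check_positive(arm_length, "arm_length")
  check_positive(arm_width, "arm_width")
  stopifnot(length(arm_labels) == 3L, length(angles_deg) == 3L,
            !anyDuplicated(arm_labels))
  theta <- angles_deg * pi / 180
  structure(list(
    arm_length = arm_length,
    arm_width = arm_width,
    arm_labels = as.character(arm_labels),
    angles_deg = angles_deg,
    unit_x = cos(theta),
    unit_y = sin(theta)
  ), class = "mf_geometry")
}

#' @export
print.mf_geometry <- function(x, ...) {
  cat(sprintf("Y-maze geometry: arms %s, length %.1f cm, width %.1f cm\n",
              paste(x$arm_labels, collapse = "/"), x$arm_length, x$arm_width))
  invisible(x)
}

#' Position trajectory in the maze
#'
#' @param time_s Strictly increasing timestamps in seconds.
#' @param x_cm,y_cm Tracked centre-of-mass coordinates in the maze frame, cm.
#' @param geometry A [maze_geometry()] object.
#' @return An object of class `mf_trajectory`.
#' @export
trajectory <- function(time_s, x_cm, y_cm, geometry = maze_geometry()) {
  stopifnot(inherits(geometry, "mf_geometry"),
            length(time_s) == length(x_cm), length(x_cm) == length(y_cm))
  if (!all(is.finite(time_s)) || !all(is.finite(x_cm)) || !all(is.finite(y_cm)))
    stop("trajectory coordinates and timestamps must be finite", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("trajectory timestamps must be strictly increasing", call. = FALSE)
  structure(list(time_s = as.numeric(time_s), x_cm = as.numeric(x_cm),
                 y_cm = as.numeric(y_cm), geometry = geometry),
            class = "mf_trajectory")
}

#' @export
print.mf_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %.1f s, %s\n", length(x$time_s),
              diff(range(x$time_s)),
              paste(x$geometry$arm_labels, collapse = "/")))
  invisible(x)
}

# For each frame: index of the nearest arm axis (by angular sector) and the
# radial distance from the centre. The maze is partitioned into three 120
# degree sectors so every point maps to exactly one arm.
classify_frames <- function(traj) {
  g <- traj$geometry
  proj <- outer(traj$x_cm, g$unit_x) + outer(traj$y_cm, g$unit_y)
  arm <- max.col(proj, ties.method = "first")
  r <- sqrt(traj$x_cm^2 + traj$y_cm^2)
  list(arm = arm, r = r)
}

# Frame-to-frame speed (cm/s) over a short centred window, robust to
# small tracking jitter. Window in seconds.
frame_speed <- function(traj, window_s = 0.2) {
  dt <- stats::median(diff(traj$time_s))
  k <- max(1L, round(window_s / dt))
  n <- length(traj$time_s)
  i0 <- pmax(1L, seq_len(n) - k)
  i1 <- pmin(n, seq_len(n) + k)
  d <- sqrt((traj$x_cm[i1] - traj$x_cm[i0])^2 + (traj$y_cm[i1] - traj$y_cm[i0])^2)
  d / (traj$time_s[i1] - traj$time_s[i0])
}
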