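# Tabular writers use UTF-8 CSV with a header row; floats are serialized
# at 9 significant digits so reruns are byte-identical.

fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) format(v, digits = 9), character(1)))
}

write_csv_stable <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a trajectory as CSV
#'
#' Columns `time_s`, `x_cm`, `y_cm`; maze geometry goes to a YAML sidecar
#' (or is supplied on read).
#'
#' @param traj An `mf_trajectory`.
#' @param path Output CSV path.
#' @param geometry_path Optional YAML path for the geometry (default:
#'   `path` with extension `.geometry.yaml`).
#' @return The CSV path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path,
                                 geometry_path = paste0(path, ".geometry.yaml")) {
  stopifnot(inherits(traj, "mf_trajectory"))
  write_csv_stable(data.frame(time_s = traj$time_s, x_cm = traj$x_cm,
                              y_cm = traj$y_cm), path)
  g <- traj$geometry
  yaml::write_yaml(list(arm_length = g$arm_length, arm_width = g$arm_width,
                        arm_labels = as.list(g$arm_labels),
                        angles_deg = as.list(g$angles_deg)), geometry_path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param geometry A [maze_geometry()]; if NULL, read from `geometry_path`.
#' @export
read_trajectory_csv <- function(path, geometry = NULL,
                                geometry_path = paste0(path, ".geometry.yaml")) {
  df <- utils::read.csv(path)
  if (is.null(geometry)) {
    if (file.exists(geometry_path)) {
      y <- yaml::read_yaml(geometry_path)
      geometry <- maze_geometry(y$arm_length, y$arm_width,
                                unlist(y$arm_labels), unlist(y$angles_deg))
    } else geometry <- maze_geometry()
  }
  trajectory(df$time_s, df$x_cm, df$y_cm, geometry)
}

#' Write / read a trace set as CSV
#'
#' Wide format: first column `time_s`, then one column per neuron
#' (`n1`, `n2`, ...). The frame rate is recovered from the timestamps.
#'
#' @param traces An `mf_traces`.
#' @param path CSV path.
#' @return The path (write) or an `mf_traces` (read).
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "mf_traces"))
  df <- data.frame(time_s = traces$frame_times, t(traces$dff))
  names(df) <- c("time_s", paste0("n", seq_len(nrow(traces$dff))))
  write_csv_stable(df, path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  tm <- df$time_s
  trace_set(t(as.matrix(df[, -1, drop = FALSE])),
            frame_rate = 1 / stats::median(diff(tm)), frame_times = tm)
}

#' Write entries / trials tables as CSV
#' @param x An `mf_entries` or `mf_trials` data.frame.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_table_csv <- function(x, path) write_csv_stable(as.data.frame(x), path)

#' Write a two-channel section image as TIFF
#'
#' Requires the `tiff` package; channels are written as separate pages,
#' intensities rescaled to the unit range per file.
#'
#' @param img An `mf_section_image`.
#' @param path TIFF path.
#' @return The path, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(inherits(img, "mf_section_image"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the `tiff` package is required to write TIFF files", call. = FALSE)
  chs <- Filter(Negate(is.null), img$channels)
  mx <- max(vapply(chs, max, numeric(1)), 1e-12)
  tiff::writeTIFF(lapply(chs, function(ch) pmin(pmax(ch / mx, 0), 1)), path)
  invisible(path)
}
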