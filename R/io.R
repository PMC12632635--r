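# Events table I/O: tab-separated, header row, UTF-8; seconds with 3
# decimals, angles with 2 decimals, 0-based trial indices on disk.

events_required_cols <- c("trial", "run", "state_block", "miniblock",
                          "trial_in_miniblock", "color", "novel", "rotation",
                          "sim_dur", "onset_sim", "onset_resp", "onset_out")

events_second_cols <- c("sim_dur", "onset_sim", "onset_resp", "onset_out")
events_angle_cols <- c("rotation", "theta", "abs_angular_error",
                       "theta_curr_error", "theta_alt_error")

#' Write an events table as TSV
#'
#' One row per trial; onsets and durations in seconds with 3 decimals, angles
#' in degrees with 2 decimals, trial indices 0-based on disk (re-based on
#' read). Unknown extra columns are written as-is.
#'
#' @param events a behavioral dataset / events data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- as.data.frame(events)
  miss <- setdiff(events_required_cols, names(ev))
  if (length(miss)) {
    stop("events table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ev$trial <- ev$trial - 1L                 # 0-based on disk
  for (cl in intersect(events_second_cols, names(ev))) {
    ev[[cl]] <- sprintf("%.3f", ev[[cl]])
  }
  for (cl in intersect(events_angle_cols, names(ev))) {
    ev[[cl]] <- sprintf("%.2f", ev[[cl]])
  }
  num <- vapply(ev, is.numeric, logical(1)) & !names(ev) %in%
    c(events_second_cols, events_angle_cols, "trial", "run", "state_block",
      "miniblock", "trial_in_miniblock", "color")
  for (cl in names(ev)[num]) ev[[cl]] <- sprintf("%.4f", ev[[cl]])
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "n/a")
  invisible(path)
}

#' Read an events TSV
#'
#' Validates required columns (a schema error names any missing column) and
#' malformed numeric fields (the error names the offending row). Extra
#' columns are preserved.
#'
#' @param path file written by \code{\link{write_events}} (or compatible).
#' @return data.frame of events with 1-based trial indices.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", na.strings = "n/a",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(events_required_cols, names(ev))
  if (length(miss)) {
    stop("events file missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cl in c(events_second_cols, "trial")) {
    v <- ev[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad)) {
        stop("malformed value in column '", cl, "' at row ", bad[1],
             call. = FALSE)
      }
      ev[[cl]] <- conv
    }
  }
  ev$trial <- as.integer(ev$trial) + 1L
  if (!is.logical(ev$novel)) ev$novel <- as.logical(ev$novel)
  for (cl in intersect(c("missed", "correct", "transfer", "novel_transfer"),
                       names(ev))) {
    if (!is.logical(ev[[cl]])) ev[[cl]] <- as.logical(ev[[cl]])
  }
  ev
}

#' Read / write a task configuration as YAML
#' @param config a \code{\link{task_config}}.
#' @param path YAML file path.
#' @return \code{write_task_config}: the path; \code{read_task_config}: a
#'   \code{task_config}.
#' @export
write_task_config <- function(config, path) {
  x <- unclass(config)
  x$color_lab <- apply(config$color_lab, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  x <- yaml::read_yaml(path)
  lab <- do.call(rbind, x$color_lab)
  colnames(lab) <- c("L", "a", "b")
  task_config(planet_radius = x$planet_radius, n_colors = x$n_colors,
              attack_sd = x$attack_sd,
              target_radius_bounds = unlist(x$target_radius_bounds),
              sim_period_choices = unlist(x$sim_period_choices),
              response_period = x$response_period,
              outcome_period = x$outcome_period,
              iti_period = x$iti_period,
              correct_threshold = x$correct_threshold,
              missed_threshold = x$missed_threshold,
              color_lab = lab)
}

#' Write a statistic map as NIfTI
#'
#' @param values numeric vector (length prod(dims)) or 3D array.
#' @param dims grid dimensions.
#' @param path output .nii / .nii.gz path.
#' @param voxel_size isotropic voxel size in mm.
#' @return the path, invisibly.
#' @export
write_map_nifti <- function(values, dims, path, voxel_size = 3) {
  img <- RNifti::asNifti(array(values, dim = dims),
                         pixdim = rep(voxel_size, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @param path NIfTI file path.
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  as.numeric(img)
}
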