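#' Readers and writers for the pipeline's tabular formats
#'
#' Plain-CSV schemas bind the stages together: trajectory tables
#' (`particle_id`, `frame`, `x_um`, `y_um`; the frame interval travels as a
#' function argument and tibble attribute), time courses (`time_min`,
#' `intensity`, `condition`/`assay`, `phi`), rate profiles (`phi`, `rate`,
#' `replicate`, `assay`), and key-value fit reports.
#'
#' @name io
NULL

check_columns <- function(data, need, what) {
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  for (col in need) {
    if (col %in% c("particle_id", "frame", "x_um", "y_um", "time_min",
                   "intensity", "phi", "rate", "replicate", "lag_s",
                   "msd_um2", "weight", "D_um2_s")) {
      if (!is.numeric(data[[col]])) {
        abort(sprintf("Column `%s` in %s must be numeric.", col, what))
      }
    }
  }
  invisible(TRUE)
}

#' Read a trajectory CSV
#'
#' @param path CSV with columns `particle_id`, `frame` (0-based), `x_um`,
#'   `y_um` (header mandatory); an optional `phi` column is preserved.
#' @param frame_interval sampling interval in seconds attached to the
#'   result (default 1/3 s).
#' @return a trajectory tibble.
#' @export
read_trajectories <- function(path, frame_interval = 1 / 3) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(data) == 0) abort(paste0("Empty trajectory file: ", path))
  check_columns(data, c("particle_id", "frame", "x_um", "y_um"),
                paste0("trajectory file '", path, "'"))
  new_trajectory_tbl(data, frame_interval)
}

#' Write a trajectory tibble to CSV
#'
#' @param data a trajectory tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(data, path) {
  check_trajectory_cols(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Read a time-course CSV
#'
#' @param path CSV with columns `time_min`, `intensity` and optionally
#'   `assay` (or `condition`), `phi`, `batch`, `background_intensity`.
#' @return a time-course tibble.
#' @export
read_timecourses <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(data) == 0) abort(paste0("Empty time-course file: ", path))
  if ("condition" %in% names(data) && !"assay" %in% names(data)) {
    data <- dplyr::rename(data, assay = "condition")
  }
  check_columns(data, c("time_min", "intensity"),
                paste0("time-course file '", path, "'"))
  tibble::as_tibble(data)
}

#' Read a rate-profile CSV
#'
#' @param path CSV with columns `phi`, `rate` and optionally `replicate`,
#'   `assay`, `batch`.
#' @return a rate-profile tibble.
#' @export
read_rate_profile <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(data) == 0) abort(paste0("Empty rate-profile file: ", path))
  check_columns(data, c("phi", "rate"), paste0("rate-profile file '", path, "'"))
  tibble::as_tibble(data)
}

#' Write an MSD curve to CSV
#'
#' @param msd an MSD tibble (`lag_s`, `msd_um2`, `weight`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msd <- function(msd, path) {
  check_columns(msd, c("lag_s", "msd_um2", "weight"), "MSD curve")
  readr::write_csv(msd, path)
  invisible(path)
}

#' Write a fit report as key-value text
#'
#' Serializes the scalar fields of a fit object (`phillies_fit`,
#' `size_scaling_fit`, `rate_model_fit`, `diffusion_estimate`,
#' `securin_fit`) as `key = value` lines.
#'
#' @param fit a fit object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  fields <- unclass(fit)
  scalars <- fields[vapply(fields, function(x) {
    is.atomic(x) && length(x) == 1 && !is.list(x)
  }, logical(1))]
  lines <- c(
    paste0("# ", class(fit)[1]),
    vapply(names(scalars), function(nm) {
      val <- scalars[[nm]]
      paste0(nm, " = ", if (is.numeric(val)) format(val, digits = 15) else val)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a key-value fit report
#'
#' @param path a file written by [write_fit_report()].
#' @return a named list of parsed values.
#' @export
read_fit_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- lapply(kv, function(p) {
    num <- suppressWarnings(as.numeric(p[2]))
    if (is.na(num) && !identical(p[2], "NA")) p[2] else num
  })
  setNames(out, vapply(kv, `[[`, character(1), 1))
}
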