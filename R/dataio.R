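#' @useDynLib emgimu, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx ar.burg var sd median mad quantile rnorm runif
#' @importFrom utils head tail
NULL

IM_AXES <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")

#' Sensor layout description
#'
#' Describes the physical montage of EMG-IM sensor pods. The default
#' 12-sensor montage follows the NinaPro-style placement: eight pods equally
#' spaced around the forearm (3 cm below the elbow), one over the extensor
#' digitorum communis (EDC), one over the flexor digitorum superficialis
#' (FDS), and one each on biceps and triceps brachii.
#'
#' @param n_sensors number of EMG-IM sensor pods (>= 1).
#' @param placement_labels character vector of unique placement labels, one
#'   per sensor. Defaults to the 12-sensor montage above, or generic
#'   `s01..sNN` labels for other sizes.
#' @return object of class `sensor_layout`.
#' @export
sensor_layout <- function(n_sensors = 12L, placement_labels = NULL) {
  n_sensors <- as.integer(n_sensors)
  if (is.na(n_sensors) || n_sensors < 1L)
    stop("n_sensors must be a positive integer", call. = FALSE)
  if (is.null(placement_labels)) {
    placement_labels <- if (n_sensors == 12L) {
      c(paste0("forearm_", 1:8), "EDC", "FDS", "biceps", "triceps")
    } else {
      sprintf("s%02d", seq_len(n_sensors))
    }
  }
  if (length(placement_labels) != n_sensors)
    stop("placement_labels length must equal n_sensors", call. = FALSE)
  if (anyDuplicated(placement_labels))
    stop("placement_labels must be unique", call. = FALSE)
  structure(list(n_sensors = n_sensors,
                 placement_labels = as.character(placement_labels)),
            class = "sensor_layout")
}

#' Multi-rate EMG + inertial recording container
#'
#' Bundles raw surface EMG (one channel per sensor, sampled at `f_emg`) with
#' the nine inertial channels per sensor (tri-axial accelerometer, gyroscope
#' and magnetometer, sampled at `f_im`), a class-label series on the EMG
#' timeline (0 = rest), and sensor metadata. Inertial columns are ordered
#' per sensor as (ax, ay, az, gx, gy, gz, mx, my, mz), sensors in layout
#' order, so each sensor contributes 10 raw signals in total.
#'
#' @param emg numeric matrix `[n_emg_samples x n_sensors]`.
#' @param im numeric matrix `[n_im_samples x 9 * n_sensors]`.
#' @param f_emg EMG sampling rate in Hz (default 2000).
#' @param f_im inertial sampling rate in Hz (default 128).
#' @param labels integer class per EMG sample; 0 denotes rest.
#' @param class_map named character vector mapping class id (as name) to
#'   class label, e.g. `c("0" = "rest", "1" = "power")`.
#' @param layout a [sensor_layout()].
#' @param meta free-form provenance list.
#' @return object of class `recording`.
#' @export
recording <- function(emg, im, f_emg = 2000, f_im = 128, labels,
                      class_map, layout = sensor_layout(ncol(emg)),
                      meta = list()) {
  rec <- structure(list(emg = as.matrix(emg), im = as.matrix(im),
                        f_emg = f_emg, f_im = f_im,
                        labels = as.integer(labels),
                        class_map = class_map, layout = layout,
                        meta = meta),
                   class = "recording")
  problems <- validate_recording(rec)
  if (length(problems))
    stop("invalid recording: ", paste(problems, collapse = "; "),
         call. = FALSE)
  rec
}

#' Validate a recording against its invariants
#'
#' Never raises: returns a character vector of violations (empty when the
#' recording conforms). Each entry names the field, the expectation and the
#' observed value.
#'
#' @param rec object to validate.
#' @return character vector of violation messages.
#' @export
validate_recording <- function(rec) {
  problems <- character()
  say <- function(...) problems <<- c(problems, sprintf(...))
  if (!is.list(rec) || is.null(rec$emg) || is.null(rec$im))
    return("recording: expected a list with emg and im matrices")
  if (!is.numeric(rec$f_emg) || !is.numeric(rec$f_im) ||
      length(rec$f_emg) != 1L || length(rec$f_im) != 1L ||
      is.na(rec$f_emg) || is.na(rec$f_im) ||
      rec$f_im <= 0 || rec$f_emg <= rec$f_im) {
    say("rates: expected f_emg > f_im > 0, observed f_emg=%s f_im=%s",
        format(rec$f_emg), format(rec$f_im))
    return(problems)
  }
  n_sensors <- ncol(rec$emg)
  if (!inherits(rec$layout, "sensor_layout"))
    say("layout: expected a sensor_layout object")
  else if (rec$layout$n_sensors != n_sensors)
    say("layout: n_sensors %d does not match emg columns %d",
        rec$layout$n_sensors, n_sensors)
  if (ncol(rec$im) != 9L * n_sensors)
    say("im: expected %d columns (9 per sensor), observed %d",
        9L * n_sensors, ncol(rec$im))
  dur_gap <- abs(nrow(rec$emg) / rec$f_emg - nrow(rec$im) / rec$f_im)
  if (dur_gap > 1 / rec$f_im + 1e-9)
    say("durations: EMG (%.4f s) and IM (%.4f s) disagree by more than one IM sample period",
        nrow(rec$emg) / rec$f_emg, nrow(rec$im) / rec$f_im)
  if (length(rec$labels) != nrow(rec$emg))
    say("labels: length %d does not equal n_emg_samples %d",
        length(rec$labels), nrow(rec$emg))
  known <- suppressWarnings(as.integer(names(rec$class_map)))
  bad <- setdiff(unique(rec$labels), known)
  if (length(bad))
    say("labels: values {%s} absent from class_map",
        paste(bad, collapse = ","))
  problems
}

#' Write a recording to a directory of CSV files
#'
#' The on-disk container is a directory holding `meta.json` (rates, layout,
#' class map, provenance), `emg.csv` (`time,s01,...`), `imu.csv`
#' (`time,s01_ax,...,sNN_mz`) and `labels.csv` (`time,class`). Time columns
#' are seconds from recording start, 0-based, samples left-aligned on their
#' timestamps. The format round-trips through [read_recording()] to the
#' stored precision.
#'
#' @param rec a valid [recording()].
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  problems <- validate_recording(rec)
  if (length(problems))
    stop("invalid recording: ", paste(problems, collapse = "; "),
         call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  ns <- rec$layout$n_sensors
  meta <- list(f_emg = rec$f_emg, f_im = rec$f_im, n_sensors = ns,
               placement_labels = rec$layout$placement_labels,
               class_map = as.list(rec$class_map), meta = rec$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  t_emg <- (seq_len(nrow(rec$emg)) - 1L) / rec$f_emg
  t_im <- (seq_len(nrow(rec$im)) - 1L) / rec$f_im
  emg_dt <- data.table::data.table(time = t_emg)
  for (s in seq_len(ns)) emg_dt[[sprintf("s%02d", s)]] <- rec$emg[, s]
  data.table::fwrite(emg_dt, file.path(path, "emg.csv"))
  im_dt <- data.table::data.table(time = t_im)
  for (s in seq_len(ns)) for (a in seq_along(IM_AXES))
    im_dt[[sprintf("s%02d_%s", s, IM_AXES[a])]] <- rec$im[, (s - 1L) * 9L + a]
  data.table::fwrite(im_dt, file.path(path, "imu.csv"))
  data.table::fwrite(
    data.table::data.table(time = t_emg, class = rec$labels),
    file.path(path, "labels.csv"))
  invisible(path)
}

#' Read a recording from its directory container
#'
#' Inverse of [write_recording()]. Inertial columns are normalised to the
#' per-sensor (ax..mz) ordering regardless of their order in `imu.csv`; a
#' missing channel column is a validation error naming the absent column.
#'
#' @param path directory produced by [write_recording()].
#' @return a validated [recording()].
#' @export
read_recording <- function(path) {
  need <- file.path(path, c("meta.json", "emg.csv", "imu.csv", "labels.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing recording file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  ns <- as.integer(meta$n_sensors)
  emg_dt <- data.table::fread(file.path(path, "emg.csv"))
  im_dt <- data.table::fread(file.path(path, "imu.csv"))
  lab_dt <- data.table::fread(file.path(path, "labels.csv"))
  emg_cols <- sprintf("s%02d", seq_len(ns))
  if (!all(emg_cols %in% names(emg_dt)))
    stop("emg.csv missing column(s): ",
         paste(setdiff(emg_cols, names(emg_dt)), collapse = ", "),
         call. = FALSE)
  im_cols <- as.vector(t(outer(sprintf("s%02d", seq_len(ns)), IM_AXES,
                               paste, sep = "_")))
  if (!all(im_cols %in% names(im_dt)))
    stop("imu.csv missing column(s): ",
         paste(setdiff(im_cols, names(im_dt)), collapse = ", "),
         call. = FALSE)
  class_map <- unlist(meta$class_map)
  recording(emg = as.matrix(emg_dt[, emg_cols, with = FALSE]),
            im = as.matrix(im_dt[, im_cols, with = FALSE]),
            f_emg = meta$f_emg, f_im = meta$f_im,
            labels = lab_dt$class, class_map = class_map,
            layout = sensor_layout(ns, meta$placement_labels),
            meta = if (length(meta$meta)) as.list(meta$meta) else list())
}
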