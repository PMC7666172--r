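# Readers and writers for the plain-text interchange formats: epoch-count
# activity CSV, per-minute temperature CSV, pose-track CSV (the three-header
# markerless-pose dialect and a flat dialect) and the YAML study config.

#' Write / read an epoch activity CSV
#'
#' Format: header `zt_hours,count,valid`, one row per 12-s epoch.
#'
#' @param series An [epoch_series()].
#' @param path File path.
#' @return `read_epoch_csv` returns an [epoch_series()].
#' @export
write_epoch_csv <- function(series, path) {
  utils::write.csv(
    data.frame(zt_hours = epoch_zt(series), count = series$counts,
               valid = series$valid),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epoch_csv
#' @export
read_epoch_csv <- function(path) {
  df <- utils::read.csv(path)
  abort_if(!all(c("zt_hours", "count") %in% names(df)),
           "epoch CSV needs columns zt_hours,count[,valid]")
  epoch_series(df$count, start_zt = df$zt_hours[1L],
               valid = if ("valid" %in% names(df)) df$valid else NULL)
}

#' Write / read a body-temperature CSV
#'
#' Format: header `zt_hours,temp_c`, one row per minute.
#'
#' @param series A [temperature_series()].
#' @param path File path.
#' @return `read_temperature_csv` returns a [temperature_series()].
#' @export
write_temperature_csv <- function(series, path) {
  utils::write.csv(
    data.frame(zt_hours = temp_zt(series), temp_c = series$temps_c),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_temperature_csv
#' @export
read_temperature_csv <- function(path) {
  df <- utils::read.csv(path)
  abort_if(!all(c("zt_hours", "temp_c") %in% names(df)),
           "temperature CSV needs columns zt_hours,temp_c")
  temperature_series(df$temp_c, start_zt = df$zt_hours[1L])
}

#' Write / read a pose-track CSV
#'
#' Two dialects: `"dlc"`, the de-facto markerless-pose table with three
#' header rows (scorer / body part / coordinate) and a leading frame-index
#' column; and `"flat"`, with header `frame,part,x,y,likelihood` in long
#' form. Coordinates are written in pixels (`px_per_cm` applied) and
#' converted back to cm on read.
#'
#' @param session A [tracked_session()].
#' @param path File path.
#' @param dialect `"dlc"` or `"flat"` (reader: `"auto"` detects).
#' @param px_per_cm Pixel calibration (default 1).
#' @param fps,kind Session metadata (needed on read; not stored in the CSV).
#' @return `read_pose_csv` returns a [tracked_session()].
#' @export
write_pose_csv <- function(session, path, dialect = c("dlc", "flat"),
                           px_per_cm = 1) {
  dialect <- match.arg(dialect)
  fr <- session$frames
  if (dialect == "dlc") {
    lines <- c(
      paste(c("scorer", rep("model", 6L)), collapse = ","),
      paste(c("bodyparts", rep(c("centroid", "nose"), each = 3L)),
            collapse = ","),
      paste(c("coords", rep(c("x", "y", "likelihood"), 2L)), collapse = ","),
      sprintf("%d,%g,%g,%g,%g,%g,%g", seq_len(nrow(fr)) - 1L,
              fr$x_c * px_per_cm, fr$y_c * px_per_cm, fr$lik_c,
              fr$x_n * px_per_cm, fr$y_n * px_per_cm, fr$lik_n))
    writeLines(lines, path)
  } else {
    long <- rbind(
      data.frame(frame = seq_len(nrow(fr)) - 1L, part = "centroid",
                 x = fr$x_c * px_per_cm, y = fr$y_c * px_per_cm,
                 likelihood = fr$lik_c),
      data.frame(frame = seq_len(nrow(fr)) - 1L, part = "nose",
                 x = fr$x_n * px_per_cm, y = fr$y_n * px_per_cm,
                 likelihood = fr$lik_n))
    utils::write.csv(long[order(long$frame), ], path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_pose_csv
#' @export
read_pose_csv <- function(path, fps, kind = "test", px_per_cm = 1,
                          dialect = "auto") {
  first <- readLines(path, n = 1L)
  if (dialect == "auto") {
    dialect <- if (startsWith(first, "scorer")) "dlc" else "flat"
  }
  if (dialect == "dlc") {
    hdr <- utils::read.csv(path, header = FALSE, nrows = 3L,
                           colClasses = "character")
    parts <- as.character(hdr[2L, -1L])
    coords <- as.character(hdr[3L, -1L])
    df <- utils::read.csv(path, header = FALSE, skip = 3L)
    get <- function(part, coord) df[[1L + which(parts == part & coords == coord)]]
    frames <- tibble::tibble(
      x_c = get("centroid", "x") / px_per_cm,
      y_c = get("centroid", "y") / px_per_cm,
      lik_c = get("centroid", "likelihood"),
      x_n = get("nose", "x") / px_per_cm,
      y_n = get("nose", "y") / px_per_cm,
      lik_n = get("nose", "likelihood"))
  } else {
    long <- utils::read.csv(path)
    wide_part <- function(p) long[long$part == p, ][order(long$frame[long$part == p]), ]
    ct <- wide_part("centroid"); ns <- wide_part("nose")
    frames <- tibble::tibble(
      x_c = ct$x / px_per_cm, y_c = ct$y / px_per_cm, lik_c = ct$likelihood,
      x_n = ns$x / px_per_cm, y_n = ns$y / px_per_cm, lik_n = ns$likelihood)
  }
  tracked_session(frames, fps = fps, kind = kind)
}

#' Read a YAML study configuration
#'
#' Overrides in the file are applied on top of [cohort_config()] defaults.
#'
#' @param path YAML file.
#' @return A `cohort_config`.
#' @export
read_study_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}
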