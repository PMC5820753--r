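# CSV dialects. All readers validate headers and name the offending column
# in their errors; all writers produce files the readers round-trip.

.read_csv_checked <- function(path, required, what,
                              numeric_cols = character(0)) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop("malformed ", what, " CSV '", path, "': ",
                        conditionMessage(e))
                 })
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " CSV '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(what, " CSV '", path, "': non-numeric value in column '", col,
           "', row ", bad[1])
    }
  }
  df
}

#' Read a kinetic trace CSV (`time_s,signal`)
#'
#' @param path CSV path.
#' @param kind trace kind, `"cd_decay"` or `"hd_exchange"`.
#' @return a [kinetic_trace()].
#' @export
read_trace_csv <- function(path, kind = "cd_decay") {
  df <- .read_csv_checked(path, c("time_s", "signal"), "trace",
                          numeric_cols = c("time_s", "signal"))
  kinetic_trace(as.numeric(df$time_s), as.numeric(df$signal), kind)
}

#' Write a kinetic trace CSV
#' @param trace a [kinetic_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  write.csv(data.frame(time_s = trace$times_s, signal = trace$signal),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a buffer-dilution series CSV
#' (`base_concentration_M,k_obs_s,k_obs_se`)
#' @param path CSV path.
#' @return a data.frame for [extract_kgb()].
#' @export
read_buffer_series_csv <- function(path) {
  df <- .read_csv_checked(path, c("base_concentration_M", "k_obs_s"),
                          "buffer series",
                          numeric_cols = c("base_concentration_M",
                                           "k_obs_s"))
  data.frame(
    base_concentration = as.numeric(df$base_concentration_M),
    k_obs = as.numeric(df$k_obs_s),
    k_obs_se = if (!is.null(df$k_obs_se)) as.numeric(df$k_obs_se) else 0
  )
}

#' Write a buffer-dilution series CSV
#' @param series data.frame with `base_concentration`, `k_obs`, optional
#'   `k_obs_se`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_buffer_series_csv <- function(series, path) {
  write.csv(data.frame(
    base_concentration_M = series$base_concentration,
    k_obs_s = series$k_obs,
    k_obs_se = if (!is.null(series$k_obs_se)) series$k_obs_se else 0
  ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration dataset CSV
#' (`x_kcal_mol,log_kgb,class_label,excluded`)
#' @param path CSV path.
#' @return a data.frame for [fit_line()].
#' @export
read_calibration_csv <- function(path) {
  df <- .read_csv_checked(path, c("x_kcal_mol", "log_kgb"), "calibration",
                          numeric_cols = c("x_kcal_mol", "log_kgb"))
  df$x_kcal_mol <- as.numeric(df$x_kcal_mol)
  df$log_kgb <- as.numeric(df$log_kgb)
  if (is.null(df$class_label)) {
    df$class_label <- paste0("p", seq_len(nrow(df)))
  }
  df$excluded <- if (is.null(df$excluded)) FALSE else as.logical(df$excluded)
  df
}

#' Write a calibration dataset CSV
#' @param data calibration data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_csv <- function(data, path) {
  df <- as.data.frame(data)[, c("x_kcal_mol", "log_kgb", "class_label",
                                "excluded")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Hammett series CSV (`substituent,sigma,sigma_minus,log_k`)
#' @param path CSV path.
#' @return a data.frame for [fit_hammett()].
#' @export
read_hammett_csv <- function(path) {
  .read_csv_checked(path, c("substituent", "sigma", "sigma_minus", "log_k"),
                    "Hammett",
                    numeric_cols = c("sigma", "sigma_minus", "log_k"))
}

#' Serialize a fitted calibration line to JSON
#' @param line a [calibration_line()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_line_json <- function(line, path) {
  stopifnot(inherits(line, "calibration_line"))
  jsonlite::write_json(
    list(domain = line$domain, slope = line$slope,
         intercept = line$intercept, rmse = line$rmse, r2 = line$r2),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration line from JSON
#' @param path JSON path written by [write_calibration_line_json()].
#' @return a [calibration_line()].
#' @export
read_calibration_line_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  calibration_line(x$domain, x$slope, x$intercept,
                   rmse = if (is.null(x$rmse)) NA_real_ else x$rmse,
                   r2 = if (is.null(x$r2)) NA_real_ else x$r2)
}

#' Write a prediction report CSV
#'
#' Columns: `identifier,center,sigma_ddg,log_kgb,k_low,k_high,k_obs,
#' half_life_h,frac_racemized,percent_racemized,risk`. Percentages are
#' rounded to one decimal; the raw fraction is kept alongside.
#'
#' @param report prediction report data.frame (see [predict_command()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prediction_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a prediction report CSV
#' @param path CSV written by [write_prediction_report()].
#' @return a data.frame.
#' @export
read_prediction_report <- function(path) {
  .read_csv_checked(path, c("identifier", "center", "log_kgb",
                            "frac_racemized", "risk"), "prediction report",
                    numeric_cols = c("log_kgb", "frac_racemized"))
}

#' Write stereocenter reports to CSV
#' @param table data.frame from [center_report_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_center_report_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
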