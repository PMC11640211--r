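# Log and configuration file formats. CSV is the canonical interchange; a
# versioned PLC-style JSON dialect ("bv-plc-1") carries 10 s records and is
# resampled on read.

LOG_COLUMNS <- c("timestamp_s", "Ti_C", "To_C", "RHo_pct", "Td_C",
                 "age_days", "stage", "n_fans", "pad_on", "actual_vent_m3h")

validate_log <- function(df, where = "log") {
  miss <- setdiff(LOG_COLUMNS, names(df))
  if (length(miss)) stop(where, ": missing columns: ", paste(miss, collapse = ", "))
  df <- df[LOG_COLUMNS]
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop(where, ": non-numeric value in column '", names(df)[j],
           "' at record ", if (is.na(bad)) "?" else bad)
    }
    na <- which(is.na(df[[j]]))
    if (length(na)) stop(where, ": missing value in column '", names(df)[j],
                         "' at record ", na[1])
  }
  if (nrow(df) > 1 && any(diff(df$timestamp_s) <= 0)) {
    stop(where, ": timestamps must be strictly increasing")
  }
  if (any(df$actual_vent_m3h < 0)) stop(where, ": actual_vent_m3h must be >= 0")
  class(df) <- c("bv_log", "data.frame")
  df
}

#' Write an operation log as CSV
#'
#' Fixed ten-column header; plain '.' decimal point regardless of locale.
#' Reading the file back reproduces the values to 1e-6.
#'
#' @param log A `bv_log` / data.frame with the standard columns.
#' @param path Output path.
#' @param iso_time Add an `iso_time` column (UTC, offset from epoch 0) for
#'   human consumption; ignored on read.
#' @return Invisibly, the path.
#' @export
write_log <- function(log, path, iso_time = FALSE) {
  df <- as.data.frame(log)[intersect(LOG_COLUMNS, names(log))]
  miss <- setdiff(LOG_COLUMNS, names(df))
  if (length(miss)) stop("write_log: missing columns: ", paste(miss, collapse = ", "))
  if (iso_time) {
    df$iso_time <- format(as.POSIXct(df$timestamp_s, origin = "1970-01-01",
                                     tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_log: cannot write '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read an operation log
#'
#' Two dialects: `"csv"` (the canonical ten-column schema written by
#' [write_log()]) and `"plc_json"` (schema `bv-plc-1`: a JSON object with
#' `schema`, `interval_s`, and `records`, an array of per-interval objects
#' using the same field names as the CSV columns). PLC logs at a fine
#' cadence can be resampled to an audit cadence on read: temperatures and
#' humidities by interval mean, fan and pad states by time-weighted duty
#' (stage takes the value occupying most of the interval).
#'
#' @param path Input path.
#' @param dialect `"csv"` or `"plc_json"`.
#' @param cadence_s Optional output cadence, s; must be a multiple of the
#'   source interval. `NULL` keeps the source cadence.
#' @return A validated `bv_log` data.frame, time-sorted.
#' @export
read_log <- function(path, dialect = c("csv", "plc_json"), cadence_s = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_log: no such file: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path)
    df <- validate_log(df, where = paste0("read_log(", basename(path), ")"))
  } else {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.null(doc$schema) || doc$schema != "bv-plc-1") {
      stop("read_log: unsupported PLC schema: ",
           if (is.null(doc$schema)) "<missing>" else doc$schema)
    }
    recs <- doc$records
    if (is.null(recs) || NROW(recs) == 0) stop("read_log: PLC log has no records")
    df <- as.data.frame(recs)
    for (col in LOG_COLUMNS) {
      if (!col %in% names(df)) {
        stop("read_log: PLC records missing field '", col, "'")
      }
      na <- which(is.na(df[[col]]))
      if (length(na)) stop("read_log: record ", na[1],
                           " has missing field '", col, "'")
    }
    df <- validate_log(df, where = paste0("read_log(", basename(path), ")"))
    interval <- doc$interval_s %||% (if (nrow(df) > 1) diff(df$timestamp_s)[1] else 10)
    if (!is.null(cadence_s)) df <- resample_log(df, interval, cadence_s)
  }
  df
}

resample_log <- function(df, interval_s, cadence_s) {
  k <- cadence_s / interval_s
  if (k < 1 || abs(k - round(k)) > 1e-9) {
    stop("read_log: cadence_s must be a positive multiple of the source interval")
  }
  k <- as.integer(round(k))
  if (k == 1) return(df)
  grp <- (seq_len(nrow(df)) - 1) %/% k
  agg_mean <- function(x) as.numeric(tapply(x, grp, mean))
  stage_mode <- function(x) {
    as.numeric(tapply(x, grp, function(v) {
      tb <- table(v)
      as.numeric(names(tb)[which.max(tb)])
    }))
  }
  out <- data.frame(
    timestamp_s = as.numeric(tapply(df$timestamp_s, grp, function(v) v[1])),
    Ti_C = agg_mean(df$Ti_C), To_C = agg_mean(df$To_C),
    RHo_pct = agg_mean(df$RHo_pct), Td_C = agg_mean(df$Td_C),
    age_days = as.numeric(tapply(df$age_days, grp, function(v) v[1])),
    stage = stage_mode(df$stage),
    n_fans = agg_mean(df$n_fans),
    pad_on = agg_mean(df$pad_on),
    actual_vent_m3h = agg_mean(df$actual_vent_m3h)
  )
  validate_log(out, where = "resample")
}

#' Write a PLC-style JSON log
#'
#' Companion writer for the `bv-plc-1` dialect accepted by [read_log()].
#'
#' @param log A `bv_log` data.frame at a uniform cadence.
#' @param path Output path.
#' @param interval_s Record cadence, s.
#' @return Invisibly, the path.
#' @export
write_plc_json <- function(log, path, interval_s = 10) {
  df <- as.data.frame(log)[LOG_COLUMNS]
  doc <- list(schema = "bv-plc-1", interval_s = interval_s, records = df)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- configuration documents -----------------------------------------------

CONFIG_KEYS <- c("house", "setpoints", "baseline_table", "scenario",
                 "controller", "seed")

#' Read a structured configuration document
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`) with top-level sections `house`,
#' `setpoints`, `baseline_table`, `scenario`, `controller`, `seed` --- all
#' optional; omitted sections take the package defaults. Unknown keys, at
#' the top level or inside a section, are rejected with the offending name;
#' physically impossible values (non-positive volume, pad efficiency above
#' 1, ...) are rejected by the constructors with field-specific messages.
#'
#' @param path Config file path.
#' @return List: `house` ([house_config()]), `setpoints`
#'   ([setpoint_schedule()]), `baseline_table` ([stage_threshold_table()]),
#'   `scenario` ([weather_scenario()]), `controller`, `seed`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown)) stop("read_config: unknown key(s): ",
                            paste(unknown, collapse = ", "))
  call_checked <- function(fn, args, section) {
    ok <- names(formals(fn))
    bad <- setdiff(names(args), ok)
    if (length(bad)) stop("read_config: unknown key(s) in '", section, "': ",
                          paste(bad, collapse = ", "))
    do.call(fn, args)
  }
  house_args <- raw$house %||% list()
  if (!is.null(house_args$envelope)) {
    house_args$envelope <- call_checked(envelope_spec, house_args$envelope,
                                        "house$envelope")
  }
  if (!is.null(house_args$min_vent)) {
    house_args$min_vent <- call_checked(min_vent_schedule, house_args$min_vent,
                                        "house$min_vent")
  }
  list(
    house = call_checked(house_config, house_args, "house"),
    setpoints = call_checked(setpoint_schedule, raw$setpoints %||% list(),
                             "setpoints"),
    baseline_table = call_checked(stage_threshold_table,
                                  raw$baseline_table %||% list(),
                                  "baseline_table"),
    scenario = call_checked(weather_scenario, raw$scenario %||% list(),
                            "scenario"),
    controller = raw$controller %||% "vrr",
    seed = as.integer(raw$seed %||% 1L)
  )
}
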