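#' Construct a gas-detector log
#'
#' A `gaslog` is one device-person time series of H2S readings at a fixed
#' sampling interval (15 s for the alarm detectors), plus any alarm-only
#' single datapoints: the instrument stores the maximum at alarm in a
#' separate slot, so an alarm maximum can survive even when the
#' surrounding measurement log was lost to the 16-h wraparound.
#'
#' @param ppm numeric vector of concentrations (ppm, 0.1 ppm resolution,
#'   0-100; the instrument ceiling is 100 ppm).
#' @param interval_s sampling interval in seconds (default 15).
#' @param start timestamp of the first reading (`POSIXct`).
#' @param person_id,device_id opaque identifiers.
#' @param alarm_ppm concentrations of alarm-only datapoints (no
#'   surrounding log).
#' @param alarm_time timestamps for `alarm_ppm`; defaults to `start`.
#' @param truncated `TRUE` when part of the log was lost to wraparound.
#' @return an object of class `gaslog` with elements `person_id`,
#'   `device_id`, `interval_s`, `readings` (data frame: `timestamp`,
#'   `ppm`, `overload`), `alarm_points`, `truncated`, `n_segments`.
#' @export
#' @examples
#' g <- gaslog(c(0, 1.6, 0))
#' compute_index(band_profile(g))
gaslog <- function(ppm = numeric(),
                   interval_s = 15,
                   start = as.POSIXct("2019-06-03 08:00:00", tz = "UTC"),
                   person_id = "P01", device_id = "D01",
                   alarm_ppm = numeric(), alarm_time = NULL,
                   truncated = FALSE) {
  stopifnot(is.numeric(ppm), all(ppm >= 0), interval_s > 0)
  n <- length(ppm)
  readings <- data.frame(
    timestamp = if (n) start + (seq_len(n) - 1) * interval_s else as.POSIXct(character(), tz = "UTC"),
    ppm = as.numeric(ppm),
    overload = dppm(ppm) >= 1000L
  )
  if (is.null(alarm_time)) alarm_time <- rep(start, length(alarm_ppm))
  alarm_points <- data.frame(
    timestamp = as.POSIXct(alarm_time, tz = "UTC"),
    ppm = as.numeric(alarm_ppm)
  )
  structure(
    list(person_id = person_id, device_id = device_id,
         interval_s = interval_s, readings = readings,
         alarm_points = alarm_points, truncated = truncated,
         n_segments = 1L),
    class = "gaslog"
  )
}

#' @export
print.gaslog <- function(x, ...) {
  cat(sprintf("<gaslog> person %s device %s: %d readings @ %gs, %d alarm points%s\n",
              x$person_id, x$device_id, nrow(x$readings), x$interval_s,
              nrow(x$alarm_points),
              if (isTRUE(x$truncated)) " (truncated)" else ""))
  invisible(x)
}

.parse_iso_times <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  retry <- is.na(out)
  if (any(retry))
    out[retry] <- as.POSIXct(x[retry], tz = "UTC", format = "%Y-%m-%d %H:%M")
  out
}

#' Parse a gas-detector CSV export into a single log
#'
#' Expected dialect: header `person_id,device_id,timestamp,ppm,flag`,
#' ISO 8601 timestamps, `flag` one of `""`, `"ALARM"`, `"OVERLOAD"`.
#' `ALARM` rows are isolated single datapoints (maximum stored at alarm)
#' and go to `alarm_points`, not the reading series.
#'
#' The docking-station transfer may skip all-zero intervals; gaps that
#' are a multiple of the sampling interval and no longer than
#' `max_gap_s` are reinstated as explicit 0.0 readings. Longer gaps
#' split the log into segments (`n_segments > 1`) since a gap of hours
#' more likely reflects the device being off.
#'
#' @param source path to a CSV file, or a character vector of CSV lines.
#' @param interval_s expected sampling interval in seconds.
#' @param max_gap_s longest gap refilled with zeros (default 4 h).
#' @return a `gaslog`. For files holding several person/device series use
#'   [parse_gas_log_multi()].
#' @export
parse_gas_log <- function(source, interval_s = 15, max_gap_s = 4 * 3600) {
  logs <- parse_gas_log_multi(source, interval_s = interval_s,
                              max_gap_s = max_gap_s, split_days = FALSE)
  if (length(logs) != 1)
    stop("source contains ", length(logs),
         " person/device series; use parse_gas_log_multi()")
  logs[[1]]
}

#' Parse a gas-detector CSV export holding several series
#'
#' Splits rows by person and device (and, optionally, calendar date) and
#' parses each series with the rules of [parse_gas_log()].
#'
#' @inheritParams parse_gas_log
#' @param split_days also split series at calendar-date boundaries.
#' @return a list of `gaslog` objects.
#' @export
parse_gas_log_multi <- function(source, interval_s = 15,
                                max_gap_s = 4 * 3600, split_days = TRUE) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    df <- utils::read.csv(source, colClasses = "character", strip.white = TRUE)
  } else {
    df <- utils::read.csv(text = paste(source, collapse = "\n"),
                          colClasses = "character", strip.white = TRUE)
  }
  need <- c("person_id", "device_id", "timestamp", "ppm", "flag")
  if (!all(need %in% names(df)))
    stop("gas-log CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) return(list())

  ts <- .parse_iso_times(df$timestamp)
  bad <- which(is.na(ts))
  if (length(bad))
    stop("malformed timestamp at data line ", bad[1], ": '",
         df$timestamp[bad[1]], "'")
  ppm <- suppressWarnings(as.numeric(df$ppm))
  if (anyNA(ppm))
    stop("malformed concentration at data line ", which(is.na(ppm))[1])

  key <- paste(df$person_id, df$device_id,
               if (split_days) format(ts, "%Y-%m-%d") else "")
  idx <- split(seq_len(nrow(df)), key)
  logs <- lapply(idx, function(i) {
    .assemble_gaslog(person = df$person_id[i[1]], device = df$device_id[i[1]],
                     ts = ts[i], ppm = ppm[i], flag = df$flag[i],
                     interval_s = interval_s, max_gap_s = max_gap_s)
  })
  unname(logs[order(vapply(logs, function(g)
    format(min(c(g$readings$timestamp, g$alarm_points$timestamp))), ""))])
}

.assemble_gaslog <- function(person, device, ts, ppm, flag,
                             interval_s, max_gap_s) {
  is_alarm <- flag == "ALARM"
  a_ts <- ts[is_alarm]; a_ppm <- ppm[is_alarm]
  ts <- ts[!is_alarm]; ppm <- ppm[!is_alarm]; flag <- flag[!is_alarm]

  if (length(ts) > 1) {
    d <- as.numeric(diff(ts), units = "secs")
    if (any(d <= 0))
      stop("non-monotone timestamps for person ", person,
           " device ", device, " (reading ", which(d <= 0)[1] + 1, ")")
    off <- d %% interval_s
    if (any(off > 1e-6 & off < interval_s - 1e-6))
      stop("timestamp spacing not a multiple of ", interval_s,
           " s for person ", person)
    # refill zero-skipped gaps; longer gaps start a new segment
    seg <- cumsum(c(1, as.integer(d > max_gap_s)))
    out_ts <- list(); out_ppm <- list()
    for (s in unique(seg)) {
      i <- which(seg == s)
      t0 <- ts[i]; p0 <- ppm[i]
      full <- seq(t0[1], t0[length(t0)], by = interval_s)
      p <- numeric(length(full))
      p[match(as.numeric(t0), as.numeric(full))] <- p0
      out_ts[[s]] <- full; out_ppm[[s]] <- p
    }
    ts <- do.call(c, out_ts); ppm <- unlist(out_ppm)
    n_seg <- max(seg)
  } else n_seg <- 1L

  g <- gaslog(ppm = ppm, interval_s = interval_s,
              start = if (length(ts)) ts[1] else as.POSIXct("1970-01-01", tz = "UTC"),
              person_id = person, device_id = device,
              alarm_ppm = a_ppm, alarm_time = a_ts)
  if (length(ts)) g$readings$timestamp <- ts
  g$n_segments <- as.integer(n_seg)
  g
}

#' Detect excursions (peaks) above the detection floor
#'
#' An excursion is a maximal run of consecutive readings at or above
#' `threshold` (default 0.1 ppm, the detection floor). A single
#' qualifying reading is one excursion. Runs never span a gap in the
#' reading grid (log segments separated by more than one sampling
#' interval): what happened during unrecorded time is unknown, so a
#' qualifying run on each side counts separately. Each excursion is
#' tagged with
#' every concentration band its peak crosses: B01 (0.1-1.0 ppm),
#' B1 (1.1-5.0), B5 (5.1-10.0), B10 (above 10.0). A dip within a band
#' (e.g. 12 -> 6 -> 12 ppm) does not create extra peaks; only a drop
#' below the floor ends an excursion.
#'
#' @param log a `gaslog`.
#' @param threshold detection floor in ppm.
#' @return data frame with one row per excursion: `start`, `end`
#'   (1-based reading indices, inclusive), `n_readings`, `peak_ppm`,
#'   and logical band columns `b01`, `b1`, `b5`, `b10`.
#' @export
detect_excursions <- function(log, threshold = 0.1) {
  stopifnot(inherits(log, "gaslog"), threshold > 0)
  x <- dppm(log$readings$ppm)
  thr <- dppm(threshold)
  above <- x >= thr
  if (!any(above))
    return(data.frame(start = integer(), end = integer(),
                      n_readings = integer(), peak_ppm = numeric(),
                      b01 = logical(), b1 = logical(), b5 = logical(),
                      b10 = logical()))
  gap <- c(FALSE, as.numeric(diff(log$readings$timestamp), units = "secs") >
             log$interval_s * 1.5)
  run <- cumsum(c(TRUE, above[-1] != above[-length(above)]) | gap)
  keep_run <- unique(run[above])
  starts <- match(keep_run, run)
  ends <- length(run) - match(keep_run, rev(run)) + 1L
  peak <- mapply(function(s, e) max(x[s:e]), starts, ends)
  data.frame(
    start = starts, end = ends,
    n_readings = ends - starts + 1L,
    peak_ppm = peak / 10,
    b01 = peak >= .band_edges_dppm["b01"],
    b1 = peak >= .band_edges_dppm["b1"],
    b5 = peak >= .band_edges_dppm["b5"],
    b10 = peak >= .band_edges_dppm["b10"],
    row.names = NULL
  )
}

#' Band profile of one worker-day log
#'
#' Computes the seven terms of the H2S exposure index for one log: peak
#' counts per concentration band, minutes spent in the 0.1-5.0 ppm and
#' above-5.0 ppm ranges, and the maximum level detected (readings and
#' alarm-only points).
#'
#' Two peak-count conventions are supported. `"cumulative"` (default)
#' increments the count of every band the excursion's peak crosses, so a
#' single 1.6 ppm reading counts once in the 0.1-1.0 band and once in
#' the 1.1-5.0 band; this convention reproduces the published
#' imputation constant for the alarm detectors (1.927). `"max_band"`
#' increments only the highest band reached.
#'
#' @param log a `gaslog`.
#' @param mode `"cumulative"` or `"max_band"`.
#' @param threshold detection floor in ppm.
#' @return object of class `band_profile`: `h2s01`, `h2s1`, `h2s5`,
#'   `h2s10` (peak counts), `duration01_min`, `duration5_min`,
#'   `max_ppm`, plus the `mode` used.
#' @export
band_profile <- function(log, mode = c("cumulative", "max_band"),
                         threshold = 0.1) {
  mode <- match.arg(mode)
  exc <- detect_excursions(log, threshold = threshold)
  if (mode == "cumulative") {
    counts <- c(h2s01 = sum(exc$b01), h2s1 = sum(exc$b1),
                h2s5 = sum(exc$b5), h2s10 = sum(exc$b10))
  } else {
    top <- with(exc, ifelse(b10, 4L, ifelse(b5, 3L, ifelse(b1, 2L, 1L))))
    counts <- c(h2s01 = sum(top == 1L), h2s1 = sum(top == 2L),
                h2s5 = sum(top == 3L), h2s10 = sum(top == 4L))
  }
  x <- dppm(log$readings$ppm)
  per_min <- log$interval_s / 60
  profile <- structure(
    list(h2s01 = unname(counts["h2s01"]), h2s1 = unname(counts["h2s1"]),
         h2s5 = unname(counts["h2s5"]), h2s10 = unname(counts["h2s10"]),
         duration01_min = sum(x >= 1L & x <= 50L) * per_min,
         duration5_min = sum(x >= 51L) * per_min,
         max_ppm = max(c(log$readings$ppm, log$alarm_points$ppm, 0)),
         mode = mode),
    class = "band_profile"
  )
  profile
}

#' @export
print.band_profile <- function(x, ...) {
  cat(sprintf(
    "<band_profile %s> peaks 0.1-1: %d | 1.1-5: %d | 5.1-10: %d | >10: %d\n",
    x$mode, x$h2s01, x$h2s1, x$h2s5, x$h2s10))
  cat(sprintf("  duration 0.1-5.0: %.3f min | >5.0: %.3f min | max %.1f ppm\n",
              x$duration01_min, x$duration5_min, x$max_ppm))
  invisible(x)
}

#' The H2S exposure index
#'
#' Unitless daily risk score combining peak counts per band, band
#' durations and the maximum level:
#'
#' index = 0.1 * n(0.1-1.0) + 0.1 * minutes(0.1-5.0) + n(1.1-5.0)
#'         + 5 * n(5.1-10.0) + 5 * minutes(>5.0) + 10 * n(>10.0) + max
#'
#' An all-censored profile (no detected reading, max below the floor)
#' scores 0.
#'
#' @param profile a `band_profile`.
#' @return non-negative numeric scalar.
#' @export
#' @examples
#' compute_index(band_profile(gaslog(1.6)))  # 2.725
compute_index <- function(profile) {
  stopifnot(inherits(profile, "band_profile"))
  f <- c(profile$h2s01, profile$h2s1, profile$h2s5, profile$h2s10,
         profile$duration01_min, profile$duration5_min, profile$max_ppm)
  if (any(f < 0)) stop("band profile has negative fields")
  if (dppm(profile$max_ppm) < 1L) return(0)
  0.1 * profile$h2s01 + 0.1 * profile$duration01_min + profile$h2s1 +
    5 * profile$h2s5 + 5 * profile$duration5_min + 10 * profile$h2s10 +
    profile$max_ppm
}

#' Lowest possible index value at the limit of detection
#'
#' Index of a log containing exactly one reading at the LOD -- the
#' smallest value a non-censored day can take. Dividing by sqrt(2)
#' gives the constant imputed for below-LOD days:
#' [imputation_constant()].
#'
#' @param lod_ppm limit of detection in ppm.
#' @param interval_s sampling interval in seconds.
#' @param mode peak-count convention, see [band_profile()].
#' @return numeric scalar.
#' @export
#' @examples
#' lowest_index_at_lod(1.6)          # 2.725
#' imputation_constant(1.6)          # 1.927 to 3 decimals
lowest_index_at_lod <- function(lod_ppm, interval_s = 15,
                                mode = c("cumulative", "max_band")) {
  mode <- match.arg(mode)
  stopifnot(lod_ppm > 0, abs(lod_ppm * 10 - round(lod_ppm * 10)) < 1e-8)
  compute_index(band_profile(gaslog(lod_ppm, interval_s = interval_s),
                             mode = mode))
}

#' @rdname lowest_index_at_lod
#' @export
imputation_constant <- function(lod_ppm, interval_s = 15,
                                mode = c("cumulative", "max_band")) {
  lowest_index_at_lod(lod_ppm, interval_s, mode) / sqrt(2)
}

#' 8-h time-weighted average concentration
#'
#' Sum of concentration x sampling time over the log, divided by the
#' fixed reference shift (480 min by default) regardless of the log's
#' span. Alarm-only points carry no duration and are excluded.
#'
#' @param log a `gaslog`.
#' @param constants an [h2s_constants()] bundle.
#' @return TWA in ppm; `NA` (with a warning) when the log has no
#'   readings, since a TWA of an empty log is undefined, not zero.
#' @export
compute_twa <- function(log, constants = h2s_constants()) {
  stopifnot(inherits(log, "gaslog"))
  if (nrow(log$readings) == 0) {
    warning("TWA undefined: log has no readings")
    return(NA_real_)
  }
  sum(log$readings$ppm) * (log$interval_s / 60) / constants$twa_reference_min
}

#' Ceiling-value exceedance
#'
#' `TRUE` iff the maximum over readings and alarm-only points is
#' strictly above the ceiling value (10 ppm): exceedance is strict, a
#' maximum of exactly 10.0 ppm does not exceed.
#'
#' @inheritParams compute_twa
#' @return logical scalar.
#' @export
exceeds_ceiling <- function(log, constants = h2s_constants()) {
  stopifnot(inherits(log, "gaslog"))
  m <- max(c(log$readings$ppm, log$alarm_points$ppm, 0))
  dppm(m) > dppm(constants$cv_ppm)
}
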