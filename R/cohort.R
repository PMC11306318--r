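#' Aggregate all logs of one person-day into a daily exposure record
#'
#' A worker may produce several log segments (and alarm-only points)
#' within one calendar day; they are merged into a single series
#' (identical timestamps resolved by the maximum) and summarized into
#' the per-day metrics: band profile, H2S index, 8-h TWA,
#' ceiling-value exceedance and censoring status. A day is censored
#' when no reading and no alarm point reaches the LOD.
#'
#' @param logs a `gaslog` or list of `gaslog`s sharing person and date.
#' @param meta optional one-row logbook-day record for this person-date
#'   (see [logbook_days()]); contributes activity covariates.
#' @param seg similar-exposure-group label.
#' @param constants an [h2s_constants()] bundle.
#' @param mode peak-count convention, see [band_profile()].
#' @return one-row data frame (a daily exposure record): identifiers,
#'   `seg`, `season`, band-profile fields, `index`, `twa_ppm`,
#'   `cv_exceeded`, `censored`, `n_positive_readings`, `status`.
#' @export
aggregate_person_day <- function(logs, meta = NULL, seg = NA_character_,
                                 constants = h2s_constants(),
                                 mode = c("cumulative", "max_band")) {
  mode <- match.arg(mode)
  if (inherits(logs, "gaslog")) logs <- list(logs)
  stopifnot(length(logs) >= 1, all(vapply(logs, inherits, TRUE, "gaslog")))

  persons <- unique(vapply(logs, `[[`, "", "person_id"))
  if (length(persons) != 1)
    stop("logs mix persons: ", paste(persons, collapse = ", "))
  all_ts <- do.call(c, lapply(logs, function(g)
    c(g$readings$timestamp, g$alarm_points$timestamp)))
  dates <- unique(format(all_ts, "%Y-%m-%d"))
  if (length(dates) > 1)
    stop("logs mix calendar dates: ", paste(dates, collapse = ", "))

  readings <- do.call(rbind, lapply(logs, `[[`, "readings"))
  alarms <- do.call(rbind, lapply(logs, `[[`, "alarm_points"))
  interval_s <- logs[[1]]$interval_s
  if (nrow(readings)) {
    # overlap between devices/segments: keep the maximum per timestamp
    readings <- readings[order(readings$timestamp, -readings$ppm), ]
    readings <- readings[!duplicated(readings$timestamp), ]
  }
  merged <- gaslog(interval_s = interval_s,
                   person_id = persons, device_id = "merged")
  merged$readings <- readings
  merged$alarm_points <- alarms

  profile <- band_profile(merged, mode = mode)
  twa <- if (nrow(readings)) compute_twa(merged, constants) else NA_real_
  max_all <- profile$max_ppm
  date <- as.Date(dates[1])
  data.frame(
    person_id = persons,
    date = date,
    seg = seg,
    season = season_of(date),
    h2s01 = profile$h2s01, h2s1 = profile$h2s1,
    h2s5 = profile$h2s5, h2s10 = profile$h2s10,
    duration01_min = profile$duration01_min,
    duration5_min = profile$duration5_min,
    max_ppm = max_all,
    index = compute_index(profile),
    twa_ppm = twa,
    cv_exceeded = dppm(max_all) > dppm(constants$cv_ppm),
    censored = dppm(max_all) < dppm(constants$lod_ppm),
    n_positive_readings = if (nrow(readings))
      sum(dppm(readings$ppm) >= dppm(constants$lod_ppm)) else 0L,
    status = "measured",
    n_exposed_tasks = if (!is.null(meta)) meta$n_exposed_tasks[1] else NA_integer_,
    manhole_entries = if (!is.null(meta)) meta$manhole_entries[1] else NA_integer_,
    has_logbook = !is.null(meta),
    stringsAsFactors = FALSE
  )
}

#' Construct a study dataset
#'
#' Container for the daily exposure records collected under one
#' sampling strategy, plus its design descriptors: number of enrolled
#' persons, study duration in months, instrument LOD, and (optionally)
#' the explicit study frame of scheduled person-workdays when it is not
#' simply measurement-days x persons.
#'
#' @param label strategy label (`"A"`, `"B"`, `"C"` or free text).
#' @param days data frame of daily exposure records
#'   ([aggregate_person_day()] rows, possibly with `status` levels
#'   `real_zero`/`missing` appended for unmeasured frame days).
#' @param n_persons number of persons enrolled.
#' @param months study duration in months.
#' @param lod_ppm instrument LOD in ppm.
#' @param interval_s sampling interval in seconds.
#' @param frame_workdays explicit total of scheduled person-workdays in
#'   the study frame; default `NULL` derives measurement-days x
#'   persons.
#' @return object of class `study_dataset`.
#' @export
study_dataset <- function(label, days, n_persons, months, lod_ppm = 1.6,
                          interval_s = 15, frame_workdays = NULL) {
  stopifnot(n_persons >= 1, months > 0)
  measured <- days[days$status == "measured", , drop = FALSE]
  structure(
    list(label = label, days = days, n_persons = as.integer(n_persons),
         n_measurement_days = length(unique(measured$date)),
         months = months, lod_ppm = lod_ppm, interval_s = interval_s,
         frame_workdays = frame_workdays),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset %s> %d person-days (%d measured) | %d persons | %s months | LOD %.1f ppm\n",
              x$label, nrow(x$days),
              sum(x$days$status == "measured"), x$n_persons,
              format(x$months), x$lod_ppm))
  invisible(x)
}

#' Impute left-censored (below-LOD) days
#'
#' Measured days with no reading at or above the LOD cannot be zero --
#' exposure below the floor is unobservable -- so their index is set to
#' the lowest possible index value at the LOD divided by sqrt(2)
#' (1.927 for LOD 1.6 ppm at 15-s sampling, cumulative convention).
#' Confirmed real-zero days are not imputed: they keep their value in
#' descriptives and are excluded from the model frame. Idempotent.
#'
#' @param dataset a [study_dataset()].
#' @param mode peak-count convention used for the constant.
#' @return the dataset with `index_model` (imputed index) and
#'   `in_model` (logical, rows eligible for the mixed model) columns;
#'   the constant used is attached as attribute
#'   `"imputation_constant"` on the dataset.
#' @export
impute_censored <- function(dataset, mode = c("cumulative", "max_band")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "study_dataset"))
  k <- imputation_constant(dataset$lod_ppm, dataset$interval_s, mode)
  d <- dataset$days
  measured <- d$status == "measured"
  d$index_model <- d$index
  d$index_model[measured & d$censored] <- k
  d$in_model <- measured
  dataset$days <- d
  attr(dataset, "imputation_constant") <- k
  attr(dataset, "imputation_mode") <- mode
  dataset
}

#' Descriptive summary of a study dataset
#'
#' The headline counting arithmetic for one sampling strategy: measured
#' workdays, detects above the cross-dataset floor, ceiling-value
#' exceedances, overloads; the study-workday denominators (measurement
#' days x persons unless an explicit frame is given) and the
#' study-duration workdays from months at 220 workdays/year/person.
#'
#' Detection uses the common 1.6-ppm floor for all datasets (the mutual
#' measurement range), even for instruments that resolve to 0.1 ppm, so
#' strategies remain comparable.
#'
#' @param dataset a [study_dataset()].
#' @param detect_floor_ppm cross-dataset detection floor (default 1.6).
#' @return one-row data frame (`summary_row`): counts, percentages
#'   (rounded half away from zero to integers), `study_workdays`,
#'   `duration_workdays`, and the measured fractions of each.
#' @export
summarize_dataset <- function(dataset, detect_floor_ppm = 1.6) {
  stopifnot(inherits(dataset, "study_dataset"))
  m <- dataset$days[dataset$days$status == "measured", , drop = FALSE]
  summary_from_counts(
    label = dataset$label,
    n_measured = nrow(m),
    n_detect = sum(dppm(m$max_ppm) > dppm(detect_floor_ppm)),
    n_cv = sum(m$cv_exceeded),
    n_over100 = sum(dppm(m$max_ppm) > 1000L),
    n_days = dataset$n_measurement_days,
    n_persons = dataset$n_persons,
    months = dataset$months,
    frame_workdays = dataset$frame_workdays
  )
}

#' Summary-row arithmetic from printed counts
#'
#' The same arithmetic as [summarize_dataset()], but starting from
#' counts, so published tables can be recomputed directly.
#'
#' @param label dataset label.
#' @param n_measured workdays with measurement.
#' @param n_detect measured workdays with a recording above the
#'   detection floor.
#' @param n_cv measured workdays exceeding the ceiling value.
#' @param n_over100 measured workdays with recordings above 100 ppm.
#' @param n_days distinct measurement days.
#' @param n_persons persons in the study.
#' @param months study duration in months.
#' @param frame_workdays explicit study frame (person-workdays), or
#'   `NULL` for `n_days * n_persons`.
#' @return one-row data frame.
#' @export
#' @examples
#' # expert campaign: 35 days x 149 persons over 19 months
#' summary_from_counts("A", 93, 25, 8, 1, 35, 149, 19)
summary_from_counts <- function(label, n_measured, n_detect, n_cv,
                                n_over100, n_days, n_persons, months,
                                frame_workdays = NULL) {
  stopifnot(n_cv <= n_detect, n_detect <= n_measured)
  if (months <= 0) stop("study duration must be positive")
  study_workdays <- if (is.null(frame_workdays)) n_days * n_persons
                    else frame_workdays
  duration_workdays <- round_half_up(months * n_persons * 220 / 12)
  data.frame(
    label = label,
    n_measured = n_measured, n_detect = n_detect, n_cv = n_cv,
    n_over100 = n_over100,
    pct_detect_of_measured = round_half_up(100 * n_detect / n_measured),
    pct_cv_of_measured = round_half_up(100 * n_cv / n_measured),
    pct_cv_of_detect = if (n_detect > 0)
      round_half_up(100 * n_cv / n_detect) else NA_real_,
    study_workdays = study_workdays,
    duration_workdays = duration_workdays,
    pct_measured_of_study = round_half_up(100 * n_measured / study_workdays),
    pct_measured_of_duration = round_half_up(100 * n_measured / duration_workdays),
    stringsAsFactors = FALSE
  )
}

#' Histogram bins for daily-maximum concentrations
#'
#' Bins the daily maxima above the common 1.6-ppm floor with the
#' decade-scaled rule: bin width is 1/10 of the upper 10-integer, so
#' bins are 1 ppm wide from 2.1 to 10.0 and 10 ppm wide from 10.1 to
#' 100 (the first bin is 1.7-2.0). 10.0 ends a bin because it is the
#' ceiling value. Values above 100 ppm (instrument overload) form one
#' extra bin; values at or below 1.6 are rejected and counted.
#' Intervals are left-open, right-closed.
#'
#' @param values numeric vector of daily maxima (ppm).
#' @return object of class `histogram_spec`: `bin_edges`, `labels`,
#'   `counts`, `overload` (count above 100), `n_rejected`.
#' @export
histogram_bins <- function(values) {
  edges <- c(1.6, 2:10, seq(20, 100, by = 10))
  v <- dppm(values)
  e <- as.integer(round(edges * 10))
  rejected <- v <= e[1]
  overload <- v > e[length(e)]
  inbin <- !rejected & !overload
  counts <- integer(length(e) - 1)
  if (any(inbin)) {
    bin <- findInterval(v[inbin], e + 1L)  # (lo, hi] on the deci-ppm grid
    counts <- tabulate(bin, nbins = length(e) - 1)
  }
  structure(
    list(bin_edges = edges,
         labels = paste0("(", edges[-length(edges)], ",", edges[-1], "]"),
         counts = counts,
         overload = sum(overload),
         n_rejected = sum(rejected)),
    class = "histogram_spec"
  )
}

#' @export
print.histogram_spec <- function(x, ...) {
  cat("<histogram_spec> daily maxima above 1.6 ppm\n")
  print(stats::setNames(x$counts, x$labels))
  cat("overload (>100 ppm):", x$overload, "| rejected (<=1.6):",
      x$n_rejected, "\n")
  invisible(x)
}

#' Index-versus-TWA table with per-stratum log-log fits
#'
#' Export table for the index-against-TWA scatter, split by
#' ceiling-value exceedance, with least-squares fits of log10(index) on
#' log10(TWA) per stratum and pooled. Rows with zero or missing TWA (or
#' zero index) cannot enter a log fit and are counted.
#'
#' @param days data frame of daily exposure records after imputation
#'   (needs `twa_ppm`, `index_model` or `index`, `cv_exceeded`).
#' @return list with `table` (the plot rows) and `fits` (data frame:
#'   stratum, n, intercept, slope, r_squared) and `n_excluded`.
#' @export
index_twa_table <- function(days) {
  idx <- if ("index_model" %in% names(days)) days$index_model else days$index
  tab <- data.frame(person_id = days$person_id, date = days$date,
                    twa_ppm = days$twa_ppm, index = idx,
                    cv_exceeded = days$cv_exceeded)
  usable <- !is.na(tab$twa_ppm) & tab$twa_ppm > 0 & tab$index > 0
  fit_one <- function(d, stratum) {
    if (nrow(d) < 2 || stats::var(log10(d$twa_ppm)) == 0)
      return(data.frame(stratum = stratum, n = nrow(d),
                        intercept = NA_real_, slope = NA_real_,
                        r_squared = NA_real_))
    f <- stats::lm(log10(index) ~ log10(twa_ppm), data = d)
    data.frame(stratum = stratum, n = nrow(d),
               intercept = unname(stats::coef(f)[1]),
               slope = unname(stats::coef(f)[2]),
               r_squared = summary(f)$r.squared)
  }
  d <- tab[usable, , drop = FALSE]
  fits <- rbind(fit_one(d, "total"),
                fit_one(d[!d$cv_exceeded, , drop = FALSE], "cv_no"),
                fit_one(d[d$cv_exceeded, , drop = FALSE], "cv_yes"))
  list(table = tab, fits = fits, n_excluded = sum(!usable))
}

#' Meteorological season of a date
#'
#' Dec-Feb winter, Mar-May spring, Jun-Aug summer, Sep-Nov autumn by
#' default; the month-to-season mapping is overridable since season
#' partitions differ between study designs.
#'
#' @param date `Date` vector.
#' @param mapping length-12 character vector mapping months 1-12 to
#'   season names.
#' @return factor with levels winter/spring/summer/autumn (or the
#'   distinct values of `mapping`).
#' @export
#' @examples
#' season_of(as.Date("2019-02-15"))  # winter
season_of <- function(date,
                      mapping = c("winter", "winter", "spring", "spring",
                                  "spring", "summer", "summer", "summer",
                                  "autumn", "autumn", "autumn", "winter")) {
  stopifnot(length(mapping) == 12)
  m <- as.POSIXlt(date)$mon + 1
  factor(mapping[m], levels = unique(mapping[c(12, 3, 6, 9)]))
}

#' Export / import a study dataset as CSV + JSON sidecar
#'
#' The daily records go to `<path>.csv`, the design metadata (label,
#' persons, months, LOD, frame, imputation settings) to
#' `<path>.json`.
#'
#' @param dataset a [study_dataset()].
#' @param path file stem (without extension).
#' @return `write_study_dataset` returns `path` invisibly;
#'   `read_study_dataset` returns the reconstructed `study_dataset`.
#' @export
write_study_dataset <- function(dataset, path) {
  utils::write.csv(dataset$days, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(label = dataset$label, n_persons = dataset$n_persons,
               n_measurement_days = dataset$n_measurement_days,
               months = dataset$months, lod_ppm = dataset$lod_ppm,
               interval_s = dataset$interval_s,
               frame_workdays = dataset$frame_workdays,
               imputation_constant = attr(dataset, "imputation_constant"),
               imputation_mode = attr(dataset, "imputation_mode"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_study_dataset
#' @export
read_study_dataset <- function(path) {
  days <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  days$date <- as.Date(days$date)
  if ("season" %in% names(days))
    days$season <- factor(days$season,
                          levels = c("winter", "spring", "summer", "autumn"))
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  ds <- study_dataset(meta$label, days, meta$n_persons, meta$months,
                      lod_ppm = meta$lod_ppm, interval_s = meta$interval_s,
                      frame_workdays = meta$frame_workdays)
  if (!is.null(meta$imputation_constant))
    attr(ds, "imputation_constant") <- meta$imputation_constant
  ds
}
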