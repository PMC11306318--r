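#' Default logbook task vocabulary
#'
#' Controlled vocabulary for the logbook's task categories, editable
#' because workers can give categories different meanings. `exposed`
#' lists the categories counted as exposed tasks when a day is
#' summarized.
#'
#' @return list with `known` and `exposed` character vectors.
#' @export
logbook_categories <- function() {
  known <- c("driving", "office", "break",
             "waternet_unexposed", "manhole_entry", "flushing",
             "sewer_maintenance", "septic_emptying", "plant_operation",
             "plant_cleaning", "pumping_station_check", "other")
  list(known = known,
       exposed = c("manhole_entry", "flushing", "sewer_maintenance",
                   "septic_emptying", "plant_cleaning",
                   "pumping_station_check"))
}

#' Parse a worker logbook
#'
#' Reads the logbook CSV (or electronic-form JSON with identical
#' fields): `person_id,date,workplace,category,start,duration_or_end,`
#' `flushing,manhole_entry,comment`. One row is one task entry; the
#' `date` field may hold an ISO interval `start/end` (expanded later by
#' [split_multiday()]). Unknown categories are kept verbatim and
#' flagged; rows without person or date are rejected with a line-level
#' report.
#'
#' @param source path to a CSV/JSON file or character vector of CSV
#'   lines.
#' @param categories vocabulary list, see [logbook_categories()].
#' @return data frame of task records with columns as in the file plus
#'   `known_category` (logical) and `line` (source line). Rejected rows
#'   are reported via warning and attached as attribute `"rejected"`.
#' @export
parse_logbook <- function(source, categories = logbook_categories()) {
  is_path <- length(source) == 1 && !grepl("\n", source) && file.exists(source)
  if (is_path && grepl("\\.json$", source, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(source)
    df[] <- lapply(df, as.character)
  } else if (is_path) {
    df <- utils::read.csv(source, colClasses = "character", strip.white = TRUE)
  } else {
    df <- utils::read.csv(text = paste(source, collapse = "\n"),
                          colClasses = "character", strip.white = TRUE)
  }
  need <- c("person_id", "date", "workplace", "category", "start",
            "duration_or_end", "flushing", "manhole_entry", "comment")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("logbook missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    df$known_category <- logical(); df$line <- integer()
    return(df)
  }
  df$line <- seq_len(nrow(df)) + 1L   # 1-based file line incl. header
  bad <- df$person_id == "" | is.na(df$person_id) | df$date == "" | is.na(df$date)
  if (any(bad)) {
    warning("rejected ", sum(bad), " logbook row(s) without person/date: line(s) ",
            paste(df$line[bad], collapse = ", "))
  }
  rejected <- df[bad, , drop = FALSE]
  df <- df[!bad, , drop = FALSE]
  df$manhole_entry <- suppressWarnings(as.integer(df$manhole_entry))
  df$manhole_entry[is.na(df$manhole_entry)] <- 0L
  df$flushing[!df$flushing %in% c("none", "some", "much")] <- "none"
  df$known_category <- df$category %in% categories$known
  if (any(!df$known_category))
    warning("unknown task categories kept verbatim: ",
            paste(unique(df$category[!df$known_category]), collapse = ", "))
  attr(df, "rejected") <- rejected
  df
}

.parse_clock_min <- function(x) {
  # "HH:MM", "HHMM" or "HMM" -> minutes since midnight, else NA
  out <- rep(NA_real_, length(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  has_colon <- lengths(m) == 3
  if (any(has_colon)) {
    h <- as.numeric(vapply(m[has_colon], `[`, "", 2))
    mi <- as.numeric(vapply(m[has_colon], `[`, "", 3))
    ok <- h < 24 & mi < 60
    out[has_colon][ok] <- (h * 60 + mi)[ok]
  }
  plain <- grepl("^[0-9]{3,4}$", x) & is.na(out)
  if (any(plain)) {
    v <- x[plain]
    h <- as.numeric(substr(v, 1, nchar(v) - 2))
    mi <- as.numeric(substr(v, nchar(v) - 1, nchar(v)))
    ok <- h < 24 & mi < 60
    out[plain][ok] <- (h * 60 + mi)[ok]
  }
  out
}

#' Normalize task durations ("duration" often recorded as end time)
#'
#' Workers frequently wrote the task's end time in the duration field.
#' For each task the raw field is reinterpreted as an end-of-task clock
#' time when (a) taken as minutes it would push the task past 24:00, or
#' (b) it parses as a clock time later than the start time. Otherwise
#' it is taken as minutes. Irrecoverably ambiguous values (e.g. crossing
#' midnight either way) leave `duration_min` `NA` and are flagged. The
#' decision is recorded per task in `duration_rule`; the operation is
#' idempotent.
#'
#' @param tasks task data frame from [parse_logbook()].
#' @param clock_threshold_min raw minute values above this are treated
#'   as suspect and checked for clock-time reinterpretation
#'   (default 720 = 12 h).
#' @return `tasks` with `duration_min` (numeric minutes or `NA`) and
#'   `duration_rule` in `{"minutes", "end_time", "ambiguous", "empty"}`.
#' @export
normalize_durations <- function(tasks, clock_threshold_min = 720) {
  n <- nrow(tasks)
  dur <- rep(NA_real_, n)
  rule <- rep("empty", n)
  start_min <- .parse_clock_min(tasks$start)
  raw <- tasks$duration_or_end
  raw_num <- suppressWarnings(as.numeric(raw))
  clock <- .parse_clock_min(raw)

  for (i in seq_len(n)) {
    r <- raw[i]
    if (is.na(r) || r == "") next
    as_min <- raw_num[i]
    as_clock <- clock[i]
    s <- start_min[i]
    # already-normalized or plain minute values stay as minutes
    if (!is.na(as_min) && as_min > 0 && as_min <= clock_threshold_min &&
        (is.na(as_clock) || is.na(s) || as_clock <= s)) {
      # plausible minutes; but a clock-parse later than start wins
      dur[i] <- as_min; rule[i] <- "minutes"
      if (!is.na(s) && s + as_min > 1440) { dur[i] <- NA; rule[i] <- "ambiguous" }
      next
    }
    if (!is.na(as_clock) && !is.na(s) && as_clock > s) {
      dur[i] <- as_clock - s; rule[i] <- "end_time"
      next
    }
    if (!is.na(as_min) && as_min > clock_threshold_min) {
      # too long to be minutes, and no valid later clock time
      rule[i] <- "ambiguous"
      next
    }
    if (!is.na(as_min) && as_min > 0 && !is.na(s) && s + as_min <= 1440) {
      dur[i] <- as_min; rule[i] <- "minutes"
      next
    }
    rule[i] <- "ambiguous"
  }
  tasks$duration_min <- dur
  tasks$duration_rule <- rule
  tasks
}

#' Expand multi-day logbook entries
#'
#' Entries recorded for a date range (ISO interval `YYYY-MM-DD/`
#' `YYYY-MM-DD` in the `date` field) are separated to one record per
#' date, tasks duplicated to each date. Total task count per date is
#' conserved times the range length.
#'
#' @param tasks task data frame.
#' @return task data frame with single ISO dates only.
#' @export
split_multiday <- function(tasks) {
  if (nrow(tasks) == 0) return(tasks)
  is_range <- grepl("/", tasks$date, fixed = TRUE)
  if (!any(is_range)) return(tasks)
  singles <- tasks[!is_range, , drop = FALSE]
  parts <- lapply(which(is_range), function(i) {
    ends <- strsplit(tasks$date[i], "/", fixed = TRUE)[[1]]
    if (length(ends) != 2 || any(ends == ""))
      stop("open-ended date range in logbook: '", tasks$date[i], "'")
    d1 <- as.Date(ends[1]); d2 <- as.Date(ends[2])
    if (is.na(d1) || is.na(d2)) stop("unparseable date range: '", tasks$date[i], "'")
    if (d2 < d1) stop("date range ends before it starts: '", tasks$date[i], "'")
    out <- tasks[rep(i, as.numeric(d2 - d1) + 1), , drop = FALSE]
    out$date <- format(seq(d1, d2, by = "day"))
    out
  })
  out <- rbind(singles, do.call(rbind, parts))
  rownames(out) <- NULL
  out
}

#' Summarize task records to one logbook day per person-date
#'
#' Encodes the activity metadata used downstream: workplace, flushing
#' level (ordered `none < some < much`; absence of mention means
#' `none`), count of exposed tasks per the vocabulary, and the number
#' of manhole entries.
#'
#' @param tasks normalized, single-date task data frame.
#' @param categories vocabulary list, see [logbook_categories()].
#' @param source data source label (`"paper_form"`, `"electronic_form"`,
#'   `"worklog"`).
#' @return data frame with one row per person-date: `person_id`, `date`
#'   (`Date`), `workplace`, `flushing` (ordered factor),
#'   `n_exposed_tasks`, `manhole_entries`, `n_tasks`, `source`.
#' @export
logbook_days <- function(tasks, categories = logbook_categories(),
                         source = "paper_form") {
  if (nrow(tasks) == 0)
    return(data.frame(person_id = character(), date = as.Date(character()),
                      workplace = character(),
                      flushing = factor(character(),
                                        levels = c("none", "some", "much"),
                                        ordered = TRUE),
                      n_exposed_tasks = integer(), manhole_entries = integer(),
                      n_tasks = integer(), source = character()))
  if (any(grepl("/", tasks$date, fixed = TRUE)))
    stop("run split_multiday() before logbook_days()")
  lev <- c("none", "some", "much")
  key <- interaction(tasks$person_id, tasks$date, drop = TRUE)
  rows <- lapply(split(tasks, key), function(d) {
    data.frame(
      person_id = d$person_id[1],
      date = as.Date(d$date[1]),
      workplace = d$workplace[1],
      flushing = factor(lev[max(match(d$flushing, lev))], levels = lev,
                        ordered = TRUE),
      n_exposed_tasks = sum(d$category %in% categories$exposed),
      manhole_entries = sum(d$manhole_entry),
      n_tasks = nrow(d),
      source = source
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$person_id, out$date), ]
}

#' Drop weekend and holiday measurement days with only zero exposure
#'
#' Measurement days falling on weekends or configured holidays are
#' removed when every reading is below the LOD, unless the person also
#' has an activity registration (logbook day) for that date. A day with
#' any reading at or above the LOD is never removed.
#'
#' @param daily data frame of worker-day exposure records with columns
#'   `person_id`, `date` (`Date`) and `max_ppm`.
#' @param logbook data frame from [logbook_days()] (may be empty).
#' @param holidays `Date` vector of public holidays.
#' @param lod_ppm limit of detection in ppm.
#' @return `daily` with the qualifying rows removed; the number dropped
#'   is attached as attribute `"n_dropped"`.
#' @export
drop_weekend_zero_days <- function(daily, logbook = NULL,
                                   holidays = as.Date(character()),
                                   lod_ppm = 1.6) {
  if (nrow(daily) == 0) return(daily)
  wd <- as.POSIXlt(daily$date)$wday
  offday <- wd %in% c(0, 6) | daily$date %in% holidays
  zero <- dppm(daily$max_ppm) < dppm(lod_ppm)
  has_log <- if (is.null(logbook) || nrow(logbook) == 0) {
    rep(FALSE, nrow(daily))
  } else {
    paste(daily$person_id, daily$date) %in%
      paste(logbook$person_id, logbook$date)
  }
  drop <- offday & zero & !has_log
  out <- daily[!drop, , drop = FALSE]
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Classify person-days as measured, real-zero or missing
#'
#' Every person-day in the study frame gets exactly one status:
#' `measured` when a measurement exists; otherwise `real_zero` when the
#' work-log roster shows an absence-type reason (sick leave, holiday,
#' education day, union work, compensation day); otherwise `missing`.
#' A person absent from the roster is `missing` with reason
#' `"no roster"`.
#'
#' @param frame data frame of the study frame: `person_id`, `date`.
#' @param measured data frame (or NULL) of person-days that have
#'   measurements: `person_id`, `date`.
#' @param roster data frame `person_id,date,reason` from the work-log
#'   system.
#' @param real_zero_reasons roster reasons counting as real zero.
#' @return `frame` with `status` (factor measured/real_zero/missing)
#'   and `reason` columns.
#' @export
classify_days <- function(frame, measured = NULL, roster = NULL,
                          real_zero_reasons = c("sick leave", "holiday",
                                                "education", "union work",
                                                "compensation day",
                                                "absence")) {
  key <- paste(frame$person_id, frame$date)
  has_meas <- if (is.null(measured) || nrow(measured) == 0) rep(FALSE, nrow(frame))
              else key %in% paste(measured$person_id, measured$date)
  reason <- rep(NA_character_, nrow(frame))
  status <- ifelse(has_meas, "measured", "missing")
  if (!is.null(roster) && nrow(roster) > 0) {
    i <- match(key, paste(roster$person_id, roster$date))
    r <- roster$reason[i]
    rz <- !has_meas & !is.na(r) & r %in% real_zero_reasons
    status[rz] <- "real_zero"
    reason[!has_meas & !is.na(r)] <- r[!has_meas & !is.na(r)]
  }
  reason[status == "missing" & is.na(reason)] <- "no roster"
  frame$status <- factor(status, levels = c("measured", "real_zero", "missing"))
  frame$reason <- reason
  frame
}

#' Manhole-entry rate ratio between two worker groups
#'
#' Contrast of how often two similar-exposure groups enter manholes.
#' Uncorrected: raw count ratio. Corrected for group size: ratio of
#' per-person counts. Printed reports round to integer
#' ([round_half_up()]); the exact ratio is returned.
#'
#' @param count_a,count_b manhole-entry counts in groups a and b.
#' @param n_a,n_b group sizes (persons).
#' @param corrected correct for group sizes (default `TRUE`).
#' @return exact ratio (numeric scalar).
#' @export
#' @examples
#' manhole_entry_ratio(34, 15, 3, 24)                    # about 18
#' manhole_entry_ratio(34, 15, 3, 24, corrected = FALSE) # about 11
manhole_entry_ratio <- function(count_a, n_a, count_b, n_b,
                                corrected = TRUE) {
  stopifnot(count_a >= 0, count_b >= 0, n_a > 0, n_b > 0)
  if (count_b == 0) stop("ratio undefined: comparison group has no entries")
  if (corrected) (count_a / n_a) / (count_b / n_b) else count_a / count_b
}
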