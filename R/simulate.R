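#' Simulation parameters for a synthetic worker cohort
#'
#' Defaults emulate the field situation the pipeline targets: four
#' similar-exposure groups in a municipal water/wastewater department
#' (24 wastewater-network, 15 treatment-plant, 6 pumping-station, 15
#' water-distribution-network workers); sporadic exposure where a
#' majority of workdays carry at least one short excursion during
#' campaign conditions; log-normal excursion peaks whose daily-maximum
#' mode among detects falls between 5 and 8 ppm, with a rare
#' "confined-space incident" tail so readings above the 100-ppm
#' instrument ceiling are possible but exceptional; excursions of 1-15
#' readings at 15-s cadence (at most about 4 min of positive readings
#' per day); 23% real-zero days (leave, training) and 11% missing
#' days; and an 8-h shift of 1920 readings on the 15-s grid.
#'
#' @param n_persons named integer vector: persons per
#'   similar-exposure group.
#' @param study_start first Monday of the study window.
#' @param study_weeks total weeks in the window.
#' @param study_months study duration in months (descriptive).
#' @param campaign_week_starts 1-based week numbers starting each 2-week
#'   intensive campaign period.
#' @param campaign_weeks_each length of each campaign period in weeks.
#' @param p_exposed_day named probability per group that a working day
#'   carries exposure.
#' @param excursions_extra mean of the Poisson count of excursions
#'   beyond the first on an exposed day (most exposed days have a
#'   single excursion).
#' @param peak_meanlog,peak_sdlog log-normal parameters of excursion
#'   peak height (ppm); defaults put the mode at 6 ppm.
#' @param incident_prob,incident_meanlog,incident_sdlog rare heavy-tail
#'   mixture component for confined-space incidents.
#' @param person_sdlog between-worker standard deviation added to
#'   `peak_meanlog` (drives the between/within variance split).
#' @param excursion_len_p geometric parameter of excursion length;
#'   lengths are `1 + Geom(p)` truncated at `excursion_len_max`
#'   readings.
#' @param excursion_len_max longest excursion in readings (default 15,
#'   i.e. just under 4 min at 15 s).
#' @param p_real_zero,p_missing day-level probabilities of a real-zero
#'   day and of a missing (device not worn/lost) working day.
#' @param lod_ppm,interval_s,shift_readings instrument floor, sampling
#'   interval and readings per 8-h shift.
#' @param alarm_ppm alarm set point (ppm); alarms also preserve data
#'   under the routine-docking strategy.
#' @param reporting_rate probability that a workday has logbook
#'   context information.
#' @param manhole_rate named per-day Poisson rate of manhole entries
#'   per group; defaults make water-network workers enter roughly 18x
#'   as often per person as wastewater-network workers.
#' @param seed integer seed used by [simulate_latent_cohort()].
#' @return list of class `sim_params`.
#' @export
sim_params <- function(
    n_persons = c(wastewater_network = 24, treatment_plant = 15,
                  pumping_station = 6, water_network = 15),
    study_start = as.Date("2019-02-04"),
    study_weeks = 34,
    study_months = 7,
    campaign_week_starts = c(4, 18, 31),
    campaign_weeks_each = 2,
    p_exposed_day = c(wastewater_network = 0.60, treatment_plant = 0.55,
                      pumping_station = 0.50, water_network = 0.65),
    excursions_extra = 0.15,
    peak_meanlog = log(6) + 0.45^2,
    peak_sdlog = 0.45,
    incident_prob = 0.005,
    incident_meanlog = log(30),
    incident_sdlog = 0.8,
    person_sdlog = 0.40,
    excursion_len_p = 0.55,
    excursion_len_max = 15,
    p_real_zero = 0.23,
    p_missing = 0.11,
    lod_ppm = 1.6,
    interval_s = 15,
    shift_readings = 1920,
    alarm_ppm = 10,
    reporting_rate = 0.81,
    manhole_rate = c(wastewater_network = 3 / (24 * 30),
                     treatment_plant = 0,
                     pumping_station = 0,
                     water_network = 34 / (15 * 30)),
    seed = 1L) {
  p <- as.list(environment())
  stopifnot(all(p_exposed_day >= 0 & p_exposed_day <= 1),
            p_real_zero >= 0, p_missing >= 0,
            reporting_rate >= 0, reporting_rate <= 1,
            identical(sort(names(n_persons)), sort(names(p_exposed_day))),
            identical(sort(names(n_persons)), sort(names(manhole_rate))))
  if (p_real_zero + p_missing > 1)
    stop("infeasible params: p_real_zero + p_missing > 1")
  structure(p, class = "sim_params")
}

.campaign_weeks <- function(params) {
  unlist(lapply(params$campaign_week_starts,
                function(w) w + seq_len(params$campaign_weeks_each) - 1))
}

#' Simulate the latent exposure process of a worker cohort
#'
#' Generates ground truth: for every person and scheduled workday
#' (Mon-Fri over the study window), a day status (real-zero, missing,
#' or working), and for exposed working days a set of short
#' block-shaped excursions with log-normal peaks placed in
#' non-overlapping slots of an 8-h shift on the 15-s grid. Sampling
#' strategies then *observe* this process; they never alter it.
#' Reproducible from `params$seed`.
#'
#' @param params a [sim_params()] list.
#' @return object of class `latent_cohort`: `params`, `persons`
#'   (person_id, seg, peak_shift), `days` (day_id, person_id, seg,
#'   date, week, campaign, status, missing, exposed, n_exc, max_true,
#'   manholes), `excursions` (day_id, start, len, peak).
#' @export
simulate_latent_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(as.integer(params$seed))

  segs <- names(params$n_persons)
  persons <- data.frame(
    person_id = sprintf("P%03d", seq_len(sum(params$n_persons))),
    seg = rep(segs, params$n_persons),
    stringsAsFactors = FALSE
  )
  persons$peak_shift <- stats::rnorm(nrow(persons), 0, params$person_sdlog)

  # scheduled workdays: Mon-Fri of each study week
  week <- rep(seq_len(params$study_weeks), each = 5)
  dates <- params$study_start + (week - 1) * 7 + rep(0:4, params$study_weeks)
  cw <- .campaign_weeks(params)

  days <- expand.grid(date_i = seq_along(dates),
                      person_i = seq_len(nrow(persons)))
  days <- data.frame(
    day_id = seq_len(nrow(days)),
    person_id = persons$person_id[days$person_i],
    seg = persons$seg[days$person_i],
    date = dates[days$date_i],
    week = week[days$date_i],
    stringsAsFactors = FALSE
  )
  days$campaign <- days$week %in% cw

  u <- stats::runif(nrow(days))
  days$status <- ifelse(u < params$p_real_zero, "real_zero", "work")
  days$missing <- days$status == "work" &
    u < params$p_real_zero + params$p_missing
  days$exposed <- days$status == "work" &
    stats::runif(nrow(days)) < params$p_exposed_day[days$seg]
  days$n_exc <- 0L
  ne <- which(days$exposed)
  days$n_exc[ne] <- pmin(1L + stats::rpois(length(ne), params$excursions_extra), 8L)
  days$manholes <- 0L
  wk <- which(days$status == "work")
  days$manholes[wk] <- stats::rpois(length(wk), params$manhole_rate[days$seg[wk]])

  # excursions, vectorized over all exposed days
  did <- rep(days$day_id[ne], days$n_exc[ne])
  n_tot <- length(did)
  shift <- persons$peak_shift[match(days$person_id[match(did, days$day_id)],
                                    persons$person_id)]
  peak <- stats::rlnorm(n_tot, params$peak_meanlog + shift, params$peak_sdlog)
  inc <- stats::runif(n_tot) < params$incident_prob
  if (any(inc))
    peak[inc] <- stats::rlnorm(sum(inc), params$incident_meanlog + shift[inc],
                               params$incident_sdlog)
  peak <- pmax(round(peak, 1), 0.1)
  len <- pmin(1L + stats::rgeom(n_tot, params$excursion_len_p),
              params$excursion_len_max)
  # non-overlapping placement: one excursion per equal chunk of the shift
  n_per_day <- days$n_exc[match(did, days$day_id)]
  j <- sequence(days$n_exc[ne])
  chunk <- params$shift_readings %/% n_per_day
  offset <- 1L + floor(stats::runif(n_tot) *
                         pmax(chunk - params$excursion_len_max - 1L, 1L))
  start <- (j - 1L) * chunk + offset

  exc <- data.frame(day_id = did, start = as.integer(start),
                    len = as.integer(len), peak = peak)
  mx <- rep(0, nrow(days))
  if (nrow(exc)) {
    agg <- tapply(exc$peak, exc$day_id, max)
    mx[match(as.integer(names(agg)), days$day_id)] <- agg
  }
  days$max_true <- mx

  structure(list(params = params, persons = persons, days = days,
                 excursions = exc),
            class = "latent_cohort")
}

#' @export
print.latent_cohort <- function(x, ...) {
  cat(sprintf("<latent_cohort> %d persons x %d workdays = %d person-days (%d exposed, %d excursions)\n",
              nrow(x$persons), length(unique(x$days$date)), nrow(x$days),
              sum(x$days$exposed), nrow(x$excursions)))
  invisible(x)
}

#' Materialize one latent day as an observed gas-detector log
#'
#' Renders the ground truth of one person-day as the `gaslog` a device
#' with floor `lod_ppm` would record: a full shift of readings on the
#' 15-s grid, zeros outside excursions, concentrations below the LOD
#' recorded as 0, values above 100 ppm clipped to the instrument
#' ceiling (overload).
#'
#' @param cohort a `latent_cohort`.
#' @param day_id day identifier.
#' @param lod_ppm instrument floor.
#' @return a `gaslog`.
#' @export
latent_gaslog <- function(cohort, day_id, lod_ppm = cohort$params$lod_ppm) {
  d <- cohort$days[match(day_id, cohort$days$day_id), ]
  stopifnot(nrow(d) == 1, !is.na(d$day_id))
  p <- cohort$params
  ppm <- numeric(p$shift_readings)
  exc <- cohort$excursions[cohort$excursions$day_id == day_id, ]
  for (i in seq_len(nrow(exc))) {
    v <- if (dppm(exc$peak[i]) >= dppm(lod_ppm)) min(exc$peak[i], 100) else 0
    ppm[exc$start[i]:(exc$start[i] + exc$len[i] - 1)] <- v
  }
  gaslog(ppm, interval_s = p$interval_s,
         start = as.POSIXct(paste(d$date, "08:00:00"), tz = "UTC"),
         person_id = d$person_id, device_id = "SIM")
}

# Vectorized per-day observed metrics for block-pulse latent logs.
# Exact equivalent of materializing each gaslog and running
# band_profile()/compute_index()/compute_twa() (asserted in tests),
# because every reading of an excursion equals its peak.
.observed_daily <- function(cohort, day_ids, lod_ppm, mode = "cumulative",
                            alarm_only = NULL) {
  p <- cohort$params
  days <- cohort$days[match(day_ids, cohort$days$day_id), ]
  if (nrow(days) == 0) {
    out <- cohort$days[0, c("person_id", "date", "seg")]
    out$season <- season_of(as.Date(character()))
    for (col in c("h2s01", "h2s1", "h2s5", "h2s10", "n_positive_readings"))
      out[[col]] <- integer(0)
    for (col in c("duration01_min", "duration5_min", "max_ppm", "twa_ppm",
                  "index"))
      out[[col]] <- numeric(0)
    out$cv_exceeded <- logical(0); out$censored <- logical(0)
    out$status <- character(0); out$day_id <- integer(0)
    return(out)
  }
  f <- factor(days$day_id, levels = days$day_id)
  exc <- cohort$excursions[cohort$excursions$day_id %in% days$day_id, ]
  ef <- factor(exc$day_id, levels = days$day_id)

  pd <- dppm(exc$peak)
  obs <- ifelse(pd >= dppm(lod_ppm), pmin(pd, 1000L), 0L)
  det <- obs >= 1L
  if (mode == "cumulative") {
    cnt <- cbind(h2s01 = det, h2s1 = obs >= 11L, h2s5 = obs >= 51L,
                 h2s10 = obs > 100L)
  } else {
    top <- ifelse(obs > 100L, 4L, ifelse(obs >= 51L, 3L,
                  ifelse(obs >= 11L, 2L, ifelse(det, 1L, 0L))))
    cnt <- cbind(h2s01 = top == 1L, h2s1 = top == 2L, h2s5 = top == 3L,
                 h2s10 = top == 4L)
  }
  per_min <- p$interval_s / 60
  storage.mode(cnt) <- "numeric"
  mat <- cbind(cnt,
               d01 = exc$len * per_min * (obs >= 1L & obs <= 50L),
               d5 = exc$len * per_min * (obs >= 51L),
               ppm_min = (obs / 10) * exc$len * per_min,
               npos = exc$len * (obs >= dppm(lod_ppm)))
  sums_raw <- rowsum(mat, ef)
  sums <- matrix(0, nrow(days), ncol(mat),
                 dimnames = list(NULL, colnames(mat)))
  sums[match(rownames(sums_raw), levels(f)), ] <- sums_raw
  mxo <- rep(0, nrow(days))
  if (nrow(exc)) {
    mx_raw <- tapply(obs, ef, max)
    hit <- !is.na(mx_raw)
    mxo[match(names(mx_raw)[hit], levels(f))] <- mx_raw[hit] / 10
  }

  out <- data.frame(
    person_id = days$person_id, date = days$date, seg = days$seg,
    season = season_of(days$date),
    h2s01 = as.integer(sums[, "h2s01"]), h2s1 = as.integer(sums[, "h2s1"]),
    h2s5 = as.integer(sums[, "h2s5"]), h2s10 = as.integer(sums[, "h2s10"]),
    duration01_min = sums[, "d01"], duration5_min = sums[, "d5"],
    max_ppm = as.numeric(mxo),
    twa_ppm = sums[, "ppm_min"] / 480,
    n_positive_readings = as.integer(sums[, "npos"]),
    stringsAsFactors = FALSE
  )
  out$index <- ifelse(dppm(out$max_ppm) < 1L, 0,
                      0.1 * out$h2s01 + 0.1 * out$duration01_min + out$h2s1 +
                        5 * out$h2s5 + 5 * out$duration5_min +
                        10 * out$h2s10 + out$max_ppm)

  if (!is.null(alarm_only) && any(alarm_only)) {
    # log lost to wraparound, alarm slot kept the maximum only
    mt <- pmin(days$max_true[alarm_only], 100)
    out[alarm_only, c("h2s01", "h2s1", "h2s5", "h2s10")] <- 0L
    out[alarm_only, c("duration01_min", "duration5_min")] <- 0
    out$max_ppm[alarm_only] <- mt
    out$index[alarm_only] <- mt
    out$twa_ppm[alarm_only] <- NA_real_
    out$n_positive_readings[alarm_only] <- 0L
  }
  out$cv_exceeded <- dppm(out$max_ppm) > 100L
  out$censored <- dppm(out$max_ppm) < dppm(lod_ppm)
  out$status <- "measured"
  out$day_id <- days$day_id
  out
}

#' Descriptor of a sampling strategy
#'
#' The three observation regimes: `"A"` expert campaign -- a limited
#' number of person-days chosen with a targeting bias toward days the
#' workers expect exposure, on instruments with a 0.1-ppm floor;
#' `"B"` routine self-assessed collection -- detectors docked about
#' weekly, the 16-h wraparound keeping readings only for days close to
#' a docking, alarms preserved in a separate slot; `"C"` intensive
#' self-assessed campaign -- daily docking through the 2-week campaign
#' periods with logbook metadata. Strategies select and censor latent
#' days; they never alter concentrations.
#'
#' @param label `"A"`, `"B"` or `"C"`.
#' @param ... overrides of the per-strategy defaults: A:
#'   `n_measurements` (93), `targeting_bias` (0.8), `lod_ppm` (0.1);
#'   B: `dock_weekday` (5 = Friday, `0` = never), `dock_after_alarm`
#'   (0.9), `lod_ppm` (1.6); C: `reporting_rate` (taken from the
#'   cohort's params), `lod_ppm` (1.6).
#' @return list of class `strategy_descriptor`.
#' @export
strategy_descriptor <- function(label = c("A", "B", "C"), ...) {
  label <- match.arg(label)
  defaults <- switch(label,
    A = list(n_measurements = 93, targeting_bias = 0.8, lod_ppm = 0.1),
    B = list(dock_weekday = 5, dock_after_alarm = 0.9, lod_ppm = 1.6),
    C = list(reporting_rate = NULL, lod_ppm = 1.6))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown option(s) for strategy ", label, ": ",
         paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(c(list(label = label), defaults), class = "strategy_descriptor")
}

#' Observe a latent cohort under one sampling strategy
#'
#' Applies the observation regime of [strategy_descriptor()] to the
#' ground truth and assembles the resulting [study_dataset()]:
#' which person-days end up with measurements, which readings survive,
#' and at what detection floor. Unmeasured frame days are appended
#' with status `real_zero` or `missing` so day classification stays a
#' partition.
#'
#' @param cohort a `latent_cohort`.
#' @param strategy a `strategy_descriptor` or a label (`"A"`, `"B"`,
#'   `"C"`).
#' @param seed integer seed for the strategy's own randomness
#'   (selection, logbook reporting).
#' @param mode peak-count convention for the index.
#' @return a [study_dataset()].
#' @export
apply_strategy <- function(cohort, strategy, seed = 1L,
                           mode = c("cumulative", "max_band")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "latent_cohort"))
  if (is.character(strategy)) strategy <- strategy_descriptor(strategy)
  stopifnot(inherits(strategy, "strategy_descriptor"))
  set.seed(as.integer(seed))
  p <- cohort$params
  days <- cohort$days

  if (strategy$label == "C") {
    frame <- days[days$campaign, , drop = FALSE]
    meas_id <- frame$day_id[frame$status == "work" & !frame$missing]
    obs <- .observed_daily(cohort, meas_id, strategy$lod_ppm, mode)
    rate <- if (is.null(strategy$reporting_rate)) p$reporting_rate
            else strategy$reporting_rate
    lb <- simulate_logbook(cohort, meas_id, reporting_rate = rate)
    i <- match(obs$day_id, lb$day_id)
    obs$has_logbook <- !is.na(i)
    obs$n_exposed_tasks <- ifelse(obs$has_logbook, lb$n_exposed_tasks[i], NA)
    obs$manhole_entries <- ifelse(obs$has_logbook, lb$manhole_entries[i], NA)
    rest <- frame[!frame$day_id %in% meas_id, , drop = FALSE]
    out <- .bind_frame(obs, rest)
    ds <- study_dataset("C", out, n_persons = nrow(cohort$persons),
                        months = p$study_months, lod_ppm = strategy$lod_ppm,
                        interval_s = p$interval_s,
                        frame_workdays = nrow(frame))
    attr(ds, "logbook") <- lb
    return(ds)
  }

  if (strategy$label == "B") {
    frame <- days
    worked <- frame$status == "work" & !frame$missing
    if (strategy$dock_weekday < 1) {
      # never docked, nothing transferred: only alarm-triggered docking
      alarmed <- worked & dppm(frame$max_true) >= dppm(p$alarm_ppm) &
        stats::runif(nrow(frame)) < strategy$dock_after_alarm
      meas <- alarmed
      retained <- alarmed
    } else {
      wday <- as.POSIXlt(frame$date)$wday
      # 16-h wraparound at 8 h worn/day: dock day and the workday before
      near_dock <- wday %in% c(strategy$dock_weekday - 1, strategy$dock_weekday)
      alarmed <- dppm(frame$max_true) >= dppm(p$alarm_ppm)
      dock_extra <- alarmed & stats::runif(nrow(frame)) < strategy$dock_after_alarm
      meas <- worked
      retained <- worked & (near_dock | dock_extra)
    }
    meas_id <- frame$day_id[meas]
    retained_id <- frame$day_id[retained]
    obs <- .observed_daily(cohort, meas_id, strategy$lod_ppm, mode)
    lost <- !obs$day_id %in% retained_id
    # lost days transfer as all-zero (zero-skip), unless the alarm slot
    # kept the maximum as a single datapoint
    alarm_slot <- lost & dppm(days$max_true[match(obs$day_id, days$day_id)]) >=
      dppm(p$alarm_ppm)
    zero_lost <- lost & !alarm_slot
    obs[zero_lost, c("h2s01", "h2s1", "h2s5", "h2s10")] <- 0L
    obs[zero_lost, c("duration01_min", "duration5_min")] <- 0
    obs$max_ppm[zero_lost] <- 0
    obs$index[zero_lost] <- 0
    obs$twa_ppm[zero_lost] <- 0
    obs$n_positive_readings[zero_lost] <- 0L
    obs$cv_exceeded[zero_lost] <- FALSE
    obs$censored[zero_lost] <- TRUE
    if (any(alarm_slot)) {
      mt <- pmin(days$max_true[match(obs$day_id[alarm_slot], days$day_id)], 100)
      obs[alarm_slot, c("h2s01", "h2s1", "h2s5", "h2s10")] <- 0L
      obs[alarm_slot, c("duration01_min", "duration5_min")] <- 0
      obs$max_ppm[alarm_slot] <- mt
      obs$index[alarm_slot] <- mt
      obs$twa_ppm[alarm_slot] <- NA_real_
      obs$n_positive_readings[alarm_slot] <- 0L
      obs$cv_exceeded[alarm_slot] <- dppm(mt) > 100L
      obs$censored[alarm_slot] <- FALSE
    }
    obs$has_logbook <- rep(FALSE, nrow(obs))
    obs$n_exposed_tasks <- rep(NA_integer_, nrow(obs))
    obs$manhole_entries <- rep(NA_integer_, nrow(obs))
    rest <- frame[!frame$day_id %in% meas_id, , drop = FALSE]
    out <- .bind_frame(obs, rest)
    return(study_dataset("B", out, n_persons = nrow(cohort$persons),
                         months = p$study_months, lod_ppm = strategy$lod_ppm,
                         interval_s = p$interval_s))
  }

  # strategy A: expert campaign with worker-influenced targeting
  cand <- days[days$status == "work" & !days$missing, , drop = FALSE]
  n_pick <- min(strategy$n_measurements, nrow(cand))
  exposed_pool <- which(cand$exposed)
  pick <- integer(0)
  for (k in seq_len(n_pick)) {
    pool <- if (stats::runif(1) < strategy$targeting_bias &&
                length(setdiff(exposed_pool, pick)))
      setdiff(exposed_pool, pick) else setdiff(seq_len(nrow(cand)), pick)
    pick <- c(pick, pool[sample.int(length(pool), 1)])
  }
  meas_id <- cand$day_id[pick]
  obs <- .observed_daily(cohort, meas_id, strategy$lod_ppm, mode)
  obs$has_logbook <- TRUE     # expert collection records activity metadata
  di <- match(obs$day_id, days$day_id)
  obs$n_exposed_tasks <- as.integer(days$exposed[di]) + days$manholes[di]
  obs$manhole_entries <- days$manholes[di]
  study_dataset("A", obs, n_persons = nrow(cohort$persons),
                months = p$study_months, lod_ppm = strategy$lod_ppm,
                interval_s = p$interval_s)
}

.bind_frame <- function(obs, rest) {
  if (nrow(rest) == 0) return(obs)
  extra <- data.frame(
    person_id = rest$person_id, date = rest$date, seg = rest$seg,
    season = season_of(rest$date),
    h2s01 = NA_integer_, h2s1 = NA_integer_, h2s5 = NA_integer_,
    h2s10 = NA_integer_, duration01_min = NA_real_,
    duration5_min = NA_real_, max_ppm = NA_real_, twa_ppm = NA_real_,
    n_positive_readings = NA_integer_, index = NA_real_,
    cv_exceeded = NA, censored = NA,
    status = ifelse(rest$status == "real_zero", "real_zero", "missing"),
    day_id = rest$day_id, has_logbook = FALSE,
    n_exposed_tasks = NA_integer_, manhole_entries = NA_integer_,
    stringsAsFactors = FALSE
  )
  rbind(obs[, names(extra)], extra)
}

#' Simulate logbook context information for workdays
#'
#' Each requested workday yields a logbook-day record with probability
#' `reporting_rate`. Manhole-entry counts come from the latent ground
#' truth (group-specific rates); flushing is mostly unregistered.
#'
#' @param cohort a `latent_cohort`.
#' @param day_ids which days to offer a logbook for.
#' @param reporting_rate probability a day's logbook exists.
#' @return data frame of logbook days (`day_id`, `person_id`, `date`,
#'   `workplace`, `flushing`, `n_exposed_tasks`, `manhole_entries`,
#'   `n_tasks`, `source`).
#' @export
simulate_logbook <- function(cohort, day_ids,
                             reporting_rate = cohort$params$reporting_rate) {
  stopifnot(reporting_rate >= 0, reporting_rate <= 1)
  d <- cohort$days[match(day_ids, cohort$days$day_id), ]
  present <- stats::runif(nrow(d)) < reporting_rate
  d <- d[present, , drop = FALSE]
  flev <- c("none", "some", "much")
  data.frame(
    day_id = d$day_id,
    person_id = d$person_id,
    date = d$date,
    workplace = d$seg,
    flushing = factor(sample(flev, nrow(d), replace = TRUE,
                             prob = c(0.83, 0.12, 0.05)),
                      levels = flev, ordered = TRUE),
    n_exposed_tasks = as.integer(d$exposed) + d$manholes,
    manhole_entries = d$manholes,
    n_tasks = 2L + as.integer(d$exposed) + d$manholes,
    source = "electronic_form",
    stringsAsFactors = FALSE
  )
}

#' Emit simulated data in the parser dialects
#'
#' Writers that produce the same CSV dialects the parsers consume, so
#' the whole pipeline round-trips on synthetic data. The gas-log
#' writer reproduces the device transfer behaviour: interior all-zero
#' runs are skipped (zero-skip) and reinstated by the parser; the
#' first and last reading of the shift anchor the day.
#'
#' @param cohort a `latent_cohort`.
#' @param day_ids days to emit.
#' @param path output file path.
#' @param lod_ppm instrument floor applied at observation.
#' @param zero_skip drop interior all-zero readings as the docking
#'   transfer does.
#' @return `path`, invisibly.
#' @export
emit_gas_log_csv <- function(cohort, day_ids, path,
                             lod_ppm = cohort$params$lod_ppm,
                             zero_skip = TRUE) {
  rows <- lapply(day_ids, function(id) {
    g <- latent_gaslog(cohort, id, lod_ppm)
    r <- g$readings
    keep <- if (zero_skip && nrow(r) > 2)
      c(1L, which(r$ppm > 0), nrow(r)) else seq_len(nrow(r))
    r <- r[sort(unique(keep)), , drop = FALSE]
    data.frame(person_id = g$person_id, device_id = g$device_id,
               timestamp = format(r$timestamp, "%Y-%m-%dT%H:%M:%S"),
               ppm = r$ppm,
               flag = ifelse(r$overload, "OVERLOAD", ""),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname emit_gas_log_csv
#' @param logbook data frame from [simulate_logbook()].
#' @export
emit_logbook_csv <- function(logbook, path) {
  rows <- lapply(seq_len(nrow(logbook)), function(i) {
    d <- logbook[i, ]
    base <- data.frame(person_id = d$person_id, date = format(d$date),
                       workplace = d$workplace, stringsAsFactors = FALSE)
    n_exposed_other <- d$n_exposed_tasks - d$manhole_entries
    task <- function(category, start, dur, manhole = 0L)
      cbind(base, category = category, start = start,
            duration_or_end = dur, flushing = as.character(d$flushing),
            manhole_entry = manhole, comment = "")
    out <- task("driving", "07:00", "60")
    if (d$manhole_entries > 0)
      out <- rbind(out, do.call(rbind, replicate(
        d$manhole_entries, task("manhole_entry", "09:00", "30", 1L),
        simplify = FALSE)))
    if (n_exposed_other > 0)
      out <- rbind(out, do.call(rbind, replicate(
        n_exposed_other, task("sewer_maintenance", "12:00", "90"),
        simplify = FALSE)))
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname emit_gas_log_csv
#' @export
emit_roster_csv <- function(cohort, path) {
  d <- cohort$days
  reason <- ifelse(d$status == "real_zero",
                   sample(c("holiday", "sick leave", "education",
                            "union work", "compensation day"),
                          nrow(d), replace = TRUE),
                   "duty")
  utils::write.csv(
    data.frame(person_id = d$person_id, date = format(d$date),
               reason = reason, stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
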