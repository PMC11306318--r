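mk_dataset <- function(days, label = "C", n_persons = 10, months = 7,
                       lod = 1.6, frame = NULL) {
  study_dataset(label, days, n_persons, months, lod_ppm = lod,
                frame_workdays = frame)
}

day_row <- function(person = "P01", date = "2019-06-03", ppm = 1.6,
                    seg = "water_network") {
  aggregate_person_day(gaslog(ppm, person_id = person,
                              start = as.POSIXct(paste(date, "08:00:00"),
                                                 tz = "UTC")),
                       seg = seg, constants = h2s_constants(1.6))
}

test_that("person-day aggregation computes index, censoring and CV", {
  d <- day_row(ppm = 1.6)
  expect_equal(d$index, 2.725)
  expect_false(d$censored)
  expect_false(d$cv_exceeded)
  expect_equal(d$season, factor("summer",
                                levels = c("winter", "spring", "summer",
                                           "autumn")))

  z <- day_row(ppm = rep(0, 10))
  expect_true(z$censored)
  expect_equal(z$index, 0)

  # an alarm-only point drives the maximum and the ceiling flag
  g1 <- gaslog(rep(0, 10), person_id = "P01")
  g2 <- gaslog(numeric(0), alarm_ppm = 29, person_id = "P01")
  d <- aggregate_person_day(list(g1, g2), constants = h2s_constants(1.6))
  expect_true(d$cv_exceeded)
  expect_equal(d$max_ppm, 29)
  expect_false(d$censored)
})

test_that("aggregation rejects mixed persons or dates", {
  g1 <- gaslog(1.6, person_id = "P01")
  g2 <- gaslog(1.6, person_id = "P02")
  expect_error(aggregate_person_day(list(g1, g2)), "persons")
  g3 <- gaslog(1.6, person_id = "P01",
               start = as.POSIXct("2019-06-04 08:00:00", tz = "UTC"))
  expect_error(aggregate_person_day(list(g1, g3)), "dates")
})

test_that("aggregation is invariant to the order of input logs", {
  g1 <- gaslog(c(0, 5.2, 0), person_id = "P01")
  g2 <- gaslog(c(0, 0, 1.8, 0), person_id = "P01",
               start = as.POSIXct("2019-06-03 10:00:00", tz = "UTC"))
  g3 <- gaslog(numeric(0), alarm_ppm = 12, person_id = "P01")
  a <- aggregate_person_day(list(g1, g2, g3), constants = h2s_constants(1.6))
  b <- aggregate_person_day(list(g3, g2, g1), constants = h2s_constants(1.6))
  expect_equal(a, b)
})

test_that("overlapping timestamps resolve to the maximum reading", {
  g1 <- gaslog(c(1.6, 0), person_id = "P01")
  g2 <- gaslog(c(5.2, 0), person_id = "P01")
  d <- aggregate_person_day(list(g1, g2), constants = h2s_constants(1.6))
  expect_equal(d$max_ppm, 5.2)
  expect_equal(d$n_positive_readings, 1L)
})

test_that("imputation assigns the LOD constant to censored measured days only", {
  days <- rbind(day_row("P01", ppm = 1.6), day_row("P02", ppm = rep(0, 5)),
                day_row("P03", ppm = rep(0, 5)))
  days$status[3] <- "real_zero"
  ds <- impute_censored(mk_dataset(days))
  expect_equal(attr(ds, "imputation_constant"), 2.725 / sqrt(2))
  expect_equal(ds$days$index_model[1], 2.725)          # untouched
  expect_equal(ds$days$index_model[2], 2.725 / sqrt(2)) # imputed
  expect_equal(ds$days$index_model[3], 0)               # real zero untouched
  expect_false(ds$days$in_model[3])                     # and out of the model

  twice <- impute_censored(ds)
  expect_equal(twice$days, ds$days)

  clean <- impute_censored(mk_dataset(day_row(ppm = 1.6)))
  expect_equal(clean$days$index_model, clean$days$index)
})

test_that("summary arithmetic reproduces the published denominators", {
  # expert campaign: 93 measured workdays, 35 days x 149 persons, 19 months
  a <- summary_from_counts("A", 93, 25, 8, 1, 35, 149, 19)
  expect_equal(a$study_workdays, 5215)
  expect_equal(a$duration_workdays, 51902)
  expect_equal(a$pct_detect_of_measured, 27)
  expect_equal(a$pct_cv_of_measured, 9)
  expect_equal(a$pct_cv_of_detect, 32)

  # routine self-assessed: 1559 days x 60 persons over 5.5 years
  b <- summary_from_counts("B", 7083, 1295, 424, 3, 1559, 60, 66)
  expect_equal(b$study_workdays, 93540)
  expect_equal(b$duration_workdays, 72600)
  expect_equal(b$pct_detect_of_measured, 18)

  # intensive campaign: explicit 1807-person-workday frame
  cc <- summary_from_counts("C", 872, 522, 118, 0, 60, 60, 7,
                            frame_workdays = 1807)
  expect_equal(cc$duration_workdays, 7700)
  expect_equal(cc$pct_detect_of_measured, 60)
  expect_equal(cc$pct_cv_of_measured, 14)
  expect_equal(cc$pct_cv_of_detect, 23)
  expect_equal(cc$pct_measured_of_study, 48)

  none <- summary_from_counts("X", 10, 0, 0, 0, 10, 1, 1)
  expect_true(is.na(none$pct_cv_of_detect))
  expect_error(summary_from_counts("X", 10, 1, 0, 0, 10, 1, 0), "positive")
})

test_that("summary percentages stay consistent with their counts", {
  set.seed(9)
  for (r in 1:10) {
    n_meas <- sample(50:500, 1)
    n_det <- sample(0:n_meas, 1)
    n_cv <- sample(0:n_det, 1)
    s <- summary_from_counts("X", n_meas, n_det, n_cv, 0, 30, 20, 6)
    if (n_det > 0)
      expect_lte(abs(s$pct_cv_of_detect * n_det - 100 * n_cv), 0.5 * n_det)
  }
})

test_that("histogram bins follow the decade-scaled rule", {
  h <- histogram_bins(c(7.3, 10.0, 10.1, 100.5, 1.6, 1.7))
  expect_equal(h$counts[h$labels == "(7,8]"], 1)
  expect_equal(h$counts[h$labels == "(9,10]"], 1)
  expect_equal(h$counts[h$labels == "(10,20]"], 1)
  expect_equal(h$counts[h$labels == "(1.6,2]"], 1)
  expect_equal(h$overload, 1)
  expect_equal(h$n_rejected, 1)    # 1.6 itself is below the first bin
})

test_that("histogram conserves its input", {
  set.seed(10)
  for (r in 1:10) {
    v <- round(runif(sample(10:200, 1), 0, 120), 1)
    h <- histogram_bins(v)
    expect_equal(sum(h$counts) + h$overload + h$n_rejected, length(v))
  }
})

test_that("index-TWA table fits log-log lines per ceiling stratum", {
  # perfectly collinear synthetic rows give R^2 = 1
  twa <- c(0.001, 0.01, 0.1, 1)
  days <- data.frame(person_id = "P", date = as.Date("2019-06-03"),
                     twa_ppm = twa, index = 10 * twa^0.8,
                     cv_exceeded = FALSE)
  out <- index_twa_table(days)
  expect_equal(out$fits$r_squared[out$fits$stratum == "total"], 1)
  expect_equal(out$fits$slope[out$fits$stratum == "total"], 0.8)
  expect_equal(nrow(out$fits[out$fits$stratum == "cv_yes", ]), 1)
  expect_true(is.na(out$fits$r_squared[out$fits$stratum == "cv_yes"]))

  single <- index_twa_table(days[1, ])
  expect_true(is.na(single$fits$r_squared[1]))
  expect_equal(nrow(single$table), 1)

  censored_only <- data.frame(person_id = "P", date = as.Date("2019-06-03"),
                              twa_ppm = c(0, 0), index = c(0, 0),
                              cv_exceeded = FALSE)
  out <- index_twa_table(censored_only)
  expect_equal(out$n_excluded, 2)
  expect_equal(nrow(out$table), 2)
})

test_that("season mapping follows meteorological months", {
  expect_equal(as.character(season_of(as.Date("2019-02-15"))), "winter")
  expect_equal(as.character(season_of(as.Date("2019-06-10"))), "summer")
  expect_equal(as.character(season_of(as.Date("2019-09-01"))), "autumn")
  expect_equal(as.character(season_of(as.Date("2019-12-01"))), "winter")
})

test_that("study datasets round-trip through CSV + JSON sidecar", {
  days <- rbind(day_row("P01", ppm = 1.6), day_row("P02", ppm = rep(0, 5)))
  ds <- impute_censored(mk_dataset(days, frame = 100))
  stem <- file.path(tempdir(), "ds_roundtrip")
  write_study_dataset(ds, stem)
  back <- read_study_dataset(stem)
  expect_equal(back$label, ds$label)
  expect_equal(back$frame_workdays, 100)
  expect_equal(back$days$index_model, ds$days$index_model)
  expect_equal(attr(back, "imputation_constant"),
               attr(ds, "imputation_constant"))
})
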