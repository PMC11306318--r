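test_that("the latent cohort is reproducible from its seed", {
  a <- simulate_latent_cohort(small_params(seed = 3))
  b <- simulate_latent_cohort(small_params(seed = 3))
  expect_identical(a$days, b$days)
  expect_identical(a$excursions, b$excursions)
  cc <- simulate_latent_cohort(small_params(seed = 4))
  expect_false(identical(a$excursions, cc$excursions))
})

test_that("infeasible day-status probabilities are rejected", {
  expect_error(small_params(1, p_real_zero = 0.7, p_missing = 0.5),
               "infeasible")
})

test_that("zero exposure probability yields all-zero logs", {
  co <- simulate_latent_cohort(small_params(
    seed = 5,
    p_exposed_day = c(wastewater_network = 0, treatment_plant = 0,
                      pumping_station = 0, water_network = 0)))
  expect_equal(nrow(co$excursions), 0)
  expect_true(all(co$days$max_true == 0))
})

test_that("the exposed-day fraction matches its probability at scale", {
  co <- shared_cohort()   # 10200 person-days
  work <- co$days[co$days$status == "work", ]
  p_hat <- mean(work$exposed)
  p_exp <- weighted.mean(co$params$p_exposed_day,
                         co$params$n_persons[names(co$params$p_exposed_day)])
  expect_lt(abs(p_hat - p_exp), 0.02)
})

test_that("excursions are short, sparse and on the 0.1-ppm grid", {
  co <- shared_cohort()
  expect_true(all(co$excursions$len >= 1 & co$excursions$len <= 15))
  expect_true(all(co$excursions$peak >= 0.1))
  expect_equal(co$excursions$peak, round(co$excursions$peak, 1))
  # block placement never overlaps within a day
  by_day <- split(co$excursions, co$excursions$day_id)
  multi <- by_day[vapply(by_day, nrow, 1L) > 1]
  for (d in multi[seq_len(min(50, length(multi)))]) {
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] > d$start[-nrow(d)] + d$len[-nrow(d)]))
  }
})

test_that("strategies observe but never alter concentrations", {
  co <- simulate_latent_cohort(small_params(seed = 6))
  C <- apply_strategy(co, "C", seed = 1)
  m <- C$days[C$days$status == "measured", ]
  for (i in sample(seq_len(nrow(m)), 25)) {
    g <- latent_gaslog(co, m$day_id[i], lod_ppm = 1.6)
    latent <- co$excursions[co$excursions$day_id == m$day_id[i], ]
    kept <- g$readings$ppm[g$readings$ppm > 0]
    # every retained reading equals a latent excursion value (clipped at 100)
    expect_true(all(kept %in% pmin(latent$peak, 100)))
    expect_equal(m$max_ppm[i],
                 max(c(0, pmin(latent$peak, 100)[latent$peak >= 1.6])))
  }
})

test_that("the vectorized strategy path equals the reading-level pipeline", {
  co <- shared_cohort()
  set.seed(31)
  ids <- sample(co$days$day_id[co$days$exposed], 12)
  fast <- h2sindex:::.observed_daily(co, ids, 1.6)
  for (k in seq_along(ids)) {
    ref <- aggregate_person_day(latent_gaslog(co, ids[k], 1.6),
                                constants = h2s_constants(1.6))
    for (col in c("h2s01", "h2s1", "h2s5", "h2s10", "duration01_min",
                  "duration5_min", "max_ppm", "index", "twa_ppm",
                  "cv_exceeded", "censored"))
      expect_equal(fast[[col]][k], ref[[col]], tolerance = 1e-9,
                   label = paste("fast", col), expected.label = "pipeline")
  }
})

test_that("intensive strategy C observes every non-missing campaign workday", {
  co <- simulate_latent_cohort(small_params(seed = 7))
  C <- apply_strategy(co, "C", seed = 1)
  frame <- co$days[co$days$campaign, ]
  expect_equal(nrow(C$days), nrow(frame))
  expected <- frame$day_id[frame$status == "work" & !frame$missing]
  expect_setequal(C$days$day_id[C$days$status == "measured"], expected)
  # classification stays a partition
  expect_false(any(is.na(C$days$status)))
  expect_equal(sum(table(C$days$status)), nrow(frame))
})

test_that("routine strategy B with no docking and no alarms is empty", {
  co <- simulate_latent_cohort(small_params(
    seed = 8,
    p_exposed_day = c(wastewater_network = 0, treatment_plant = 0,
                      pumping_station = 0, water_network = 0)))
  B <- apply_strategy(co, strategy_descriptor("B", dock_weekday = 0), seed = 1)
  expect_equal(sum(B$days$status == "measured"), 0)
})

test_that("daily collection detects more exposed days than routine docking", {
  wins <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    co <- simulate_latent_cohort(small_params(seed = 100 + r))
    detect <- function(ds) {
      m <- ds$days[ds$days$status == "measured", ]
      mean(m$max_ppm > 1.6, na.rm = TRUE)
    }
    if (detect(apply_strategy(co, "C", seed = r)) >=
        detect(apply_strategy(co, "B", seed = r))) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.95 * n_rep))
})

test_that("expert targeting enriches very high days relative to B and C", {
  prop20 <- c(A = 0, B = 0, C = 0)
  meas <- c(A = 0, B = 0, C = 0)
  for (r in 1:40) {
    co <- simulate_latent_cohort(small_params(seed = 200 + r))
    sets <- list(
      A = apply_strategy(co, strategy_descriptor("A", targeting_bias = 0.9),
                         seed = r),
      B = apply_strategy(co, "B", seed = r),
      C = apply_strategy(co, "C", seed = r))
    for (nm in names(sets)) {
      m <- sets[[nm]]$days[sets[[nm]]$days$status == "measured", ]
      prop20[nm] <- prop20[nm] + sum(m$max_ppm > 20, na.rm = TRUE)
      meas[nm] <- meas[nm] + nrow(m)
    }
  }
  frac <- prop20 / meas
  expect_gt(frac["A"], frac["B"])
  expect_gt(frac["A"], frac["C"])
})

test_that("logbook reporting follows its rate and feeds the manhole contrast", {
  co <- shared_cohort()
  work_ids <- co$days$day_id[co$days$status == "work"]
  set.seed(32)
  lb_all <- simulate_logbook(co, work_ids, reporting_rate = 1)
  expect_equal(nrow(lb_all), length(work_ids))
  lb <- simulate_logbook(co, work_ids, reporting_rate = 0.81)
  expect_lt(abs(nrow(lb) / length(work_ids) - 0.81), 0.015)

  # per-person manhole rates were set 18x higher for water-network workers
  seg <- co$days$seg[match(lb_all$day_id, co$days$day_id)]
  n <- co$params$n_persons
  ratio <- manhole_entry_ratio(
    sum(lb_all$manhole_entries[seg == "water_network"]), n["water_network"],
    sum(lb_all$manhole_entries[seg == "wastewater_network"]),
    n["wastewater_network"])
  expect_gt(ratio, 10)
  expect_lt(ratio, 30)
})

test_that("emitted CSVs round-trip through the parsers", {
  co <- simulate_latent_cohort(small_params(seed = 9))
  set.seed(33)
  ids <- sample(co$days$day_id[co$days$exposed], 6)
  fast <- h2sindex:::.observed_daily(co, ids, 1.6)

  f <- file.path(tempdir(), "sim_gaslog.csv")
  emit_gas_log_csv(co, ids, f)
  logs <- parse_gas_log_multi(f)
  expect_equal(length(logs), length(ids))
  for (g in logs) {
    ref <- aggregate_person_day(g, constants = h2s_constants(1.6))
    k <- which(fast$person_id == ref$person_id & fast$date == ref$date)
    expect_equal(ref$index, fast$index[k])
    expect_equal(ref$twa_ppm, fast$twa_ppm[k])
  }

  lb <- simulate_logbook(co, ids, reporting_rate = 1)
  f2 <- file.path(tempdir(), "sim_logbook.csv")
  emit_logbook_csv(lb, f2)
  days <- logbook_days(normalize_durations(split_multiday(parse_logbook(f2))))
  expect_equal(nrow(days), nrow(lb))
  expect_equal(sum(days$manhole_entries), sum(lb$manhole_entries))
  expect_equal(sum(days$n_exposed_tasks), sum(lb$n_exposed_tasks))

  f3 <- file.path(tempdir(), "sim_roster.csv")
  emit_roster_csv(co, f3)
  roster <- read.csv(f3, stringsAsFactors = FALSE)
  cls <- classify_days(
    data.frame(person_id = co$days$person_id, date = format(co$days$date)),
    measured = NULL, roster = roster)
  expect_equal(sum(cls$status == "real_zero"),
               sum(co$days$status == "real_zero"))
})
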