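csv_lines <- function(rows) {
  c("person_id,device_id,timestamp,ppm,flag", rows)
}

test_that("parser echoes a plain three-reading file", {
  g <- parse_gas_log(csv_lines(c(
    "P01,D01,2019-06-03T08:00:00,0.0,",
    "P01,D01,2019-06-03T08:00:15,1.6,",
    "P01,D01,2019-06-03T08:00:30,0.0,")))
  expect_s3_class(g, "gaslog")
  expect_equal(nrow(g$readings), 3)
  expect_equal(g$readings$ppm, c(0, 1.6, 0))
  expect_equal(g$n_segments, 1L)
})

test_that("zero-skipped gaps are reinstated as explicit zero readings", {
  g <- parse_gas_log(csv_lines(c(
    "P01,D01,2019-06-03T08:00:00,1.6,",
    "P01,D01,2019-06-03T08:02:00,2.0,")))  # 120 s apart at 15 s cadence
  expect_equal(nrow(g$readings), 9)        # 7 zeros refilled
  expect_equal(sum(g$readings$ppm == 0), 7)
  expect_equal(g$readings$ppm[c(1, 9)], c(1.6, 2.0))
})

test_that("gaps beyond the refill limit split the log into segments", {
  g <- parse_gas_log(csv_lines(c(
    "P01,D01,2019-06-03T08:00:00,1.6,",
    "P01,D01,2019-06-03T14:00:00,2.0,")), max_gap_s = 4 * 3600)
  expect_equal(g$n_segments, 2L)
  expect_equal(nrow(g$readings), 2)
  # the two qualifying runs do not merge across the unrecorded gap
  expect_equal(nrow(detect_excursions(g)), 2)
})

test_that("non-monotone timestamps and bad fields are rejected", {
  expect_error(parse_gas_log(csv_lines(c(
    "P01,D01,2019-06-03T08:00:15,0.0,",
    "P01,D01,2019-06-03T08:00:00,0.0,"))), "non-monotone")
  expect_error(parse_gas_log(csv_lines(
    "P01,D01,notatime,0.0,")), "timestamp")
})

test_that("alarm rows become alarm-only datapoints", {
  g <- parse_gas_log(csv_lines(c(
    "P01,D01,2019-06-03T08:00:00,0.0,",
    "P01,D01,2019-06-03T09:12:00,29.0,ALARM",
    "P01,D01,2019-06-03T08:00:15,0.0,")))
  expect_equal(nrow(g$readings), 2)
  expect_equal(g$alarm_points$ppm, 29)
  expect_true(exceeds_ceiling(g))
})

test_that("excursion detection finds maximal runs and their bands", {
  expect_equal(nrow(detect_excursions(gaslog(c(0, 0, 0)))), 0)

  e <- detect_excursions(gaslog(c(0, 1.6, 0)))
  expect_equal(nrow(e), 1)
  expect_equal(e$peak_ppm, 1.6)
  expect_true(e$b01 && e$b1)
  expect_false(e$b5 || e$b10)

  expect_equal(nrow(detect_excursions(gaslog(c(0, 1.6, 0, 0, 1.6, 0)))), 2)

  # a dip within a band does not create extra peaks
  e <- detect_excursions(gaslog(c(0, 12, 6, 12, 0)))
  expect_equal(nrow(e), 1)
  expect_true(e$b10)
  expect_equal(e$peak_ppm, 12)
})

test_that("band membership respects the strict >10 ceiling edge", {
  expect_false(detect_excursions(gaslog(10.0))$b10)
  expect_true(detect_excursions(gaslog(10.1))$b10)
})

test_that("band profile: cumulative vs max-band counting", {
  pc <- band_profile(gaslog(1.6), mode = "cumulative")
  expect_equal(pc$h2s01, 1)
  expect_equal(pc$h2s1, 1)
  expect_equal(pc$duration01_min, 0.25)
  expect_equal(pc$max_ppm, 1.6)

  pm <- band_profile(gaslog(1.6), mode = "max_band")
  expect_equal(pm$h2s01, 0)
  expect_equal(pm$h2s1, 1)

  for (m in c("cumulative", "max_band")) {
    p <- band_profile(gaslog(10.1), mode = m)
    expect_equal(p$duration01_min, 0)
    expect_equal(p$duration5_min, 0.25)
    expect_equal(p$max_ppm, 10.1)
  }
  expect_error(band_profile(gaslog(1.6), mode = "nonsense"))
})

test_that("index formula reproduces hand-computed values", {
  expect_equal(compute_index(band_profile(gaslog(numeric(0)))), 0)
  # one reading at 1.6: 0.1 + 0.025 + 1 + 1.6
  expect_equal(compute_index(band_profile(gaslog(1.6))), 2.725)
  # one reading at 10.1: 0.1 + 1 + 5 + 10 + 5*0.25 + 10.1
  expect_equal(compute_index(band_profile(gaslog(10.1))), 27.45)
  # two separate single readings at 1.6: 0.2 + 0.05 + 2 + 1.6
  expect_equal(compute_index(band_profile(gaslog(c(1.6, 0, 1.6)))), 3.85)
})

test_that("lowest index at the LOD and the imputation constant", {
  expect_equal(lowest_index_at_lod(1.6), 2.725)
  expect_equal(round_half_up(imputation_constant(1.6), 3), 1.927)
  # the max-band convention does not reproduce the published constant
  expect_equal(lowest_index_at_lod(1.6, mode = "max_band"), 2.625)
  expect_equal(round_half_up(imputation_constant(1.6, mode = "max_band"), 3),
               1.856)
  # symbolic form at a 0.1-ppm floor: 0.2 + 0.1 * t/60
  for (t_s in c(15, 60, 120))
    expect_equal(lowest_index_at_lod(0.1, interval_s = t_s),
                 0.2 + 0.1 * t_s / 60)
})

test_that("TWA uses the fixed 480-min reference shift", {
  expect_equal(compute_twa(gaslog(1.6)), 1.6 * 0.25 / 480)
  expect_equal(compute_twa(gaslog(rep(5, 1920))), 5)
  expect_equal(compute_twa(gaslog(rep(0, 100))), 0)
  expect_warning(out <- compute_twa(gaslog(numeric(0))), "undefined")
  expect_true(is.na(out))
})

test_that("ceiling exceedance is strict and counts alarm points", {
  expect_false(exceeds_ceiling(gaslog(c(0, 10.0, 0))))
  expect_true(exceeds_ceiling(gaslog(c(0, 10.1, 0))))
  expect_true(exceeds_ceiling(gaslog(numeric(0), alarm_ppm = 29)))
})

test_that("durations conserve positive reading time exactly", {
  set.seed(41)
  for (r in 1:25) {
    v <- random_ppm(sample(5:50, 1))
    p <- band_profile(gaslog(v))
    expect_equal(p$duration01_min + p$duration5_min,
                 sum(v >= 0.095) * 15 / 60)
  }
})

test_that("index equals the brute-force oracle on random logs", {
  set.seed(42)
  for (r in 1:60) {
    v <- random_ppm(sample(1:50, 1), p_zero = runif(1, 0.2, 0.9),
                    max_ppm = sample(c(2, 8, 30, 110), 1))
    for (m in c("cumulative", "max_band"))
      expect_equal(compute_index(band_profile(gaslog(v), mode = m)),
                   oracle_index(v, mode = m), tolerance = 1e-9)
  }
})

test_that("raising any single reading never lowers the index", {
  set.seed(43)
  for (r in 1:20) {
    v <- random_ppm(20)
    i0 <- compute_index(band_profile(gaslog(v)))
    k <- sample(20, 1)
    v[k] <- min(v[k] + round(runif(1, 0.1, 20), 1), 100)
    expect_gte(compute_index(band_profile(gaslog(v))), i0)
  }
})

test_that("index dominates the daily maximum, cumulative dominates max-band", {
  set.seed(44)
  for (r in 1:20) {
    v <- random_ppm(sample(5:40, 1))
    p <- band_profile(gaslog(v))
    if (p$max_ppm >= 0.1)
      expect_gte(compute_index(p), p$max_ppm)
    expect_gte(compute_index(p),
               compute_index(band_profile(gaslog(v), mode = "max_band")))
  }
})

test_that("ceiling exceedance coincides with a >10 ppm peak count", {
  set.seed(45)
  for (r in 1:20) {
    v <- random_ppm(30, max_ppm = 15)
    g <- gaslog(v)
    expect_identical(exceeds_ceiling(g), band_profile(g)$h2s10 >= 1)
  }
})
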