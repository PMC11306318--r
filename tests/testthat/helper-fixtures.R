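# one shared full-size latent cohort, generated once per test run
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_latent_cohort(sim_params(seed = 73))
    cache
  }
})

# compact cohort for replicate-heavy simulation tests: 16 workers over a
# 6-week window that is campaign throughout
small_params <- function(seed, ...) {
  args <- list(
    n_persons = c(wastewater_network = 6, treatment_plant = 4,
                  pumping_station = 2, water_network = 4),
    study_weeks = 6, campaign_week_starts = c(1, 3, 5),
    study_months = 1.5, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_params, args)
}

# balanced synthetic model frame drawn from the variance-components model
# itself: log-index = mu + seg/season effects + person + noise
lmm_frame <- function(n_person = 20, n_day = 8, mu = log(8),
                      sd_between = 0.5, sd_within = 0.9,
                      segs = c("wastewater_network", "water_network"),
                      seasons = c("winter", "summer")) {
  person <- sprintf("P%02d", seq_len(n_person))
  b <- rnorm(n_person, 0, sd_between)
  d <- expand.grid(person_id = person, day = seq_len(n_day),
                   stringsAsFactors = FALSE)
  d$seg <- segs[(match(d$person_id, person) - 1) %% length(segs) + 1]
  d$season <- seasons[(d$day - 1) %% length(seasons) + 1]
  d$index_model <- exp(mu + b[match(d$person_id, person)] +
                         rnorm(nrow(d), 0, sd_within))
  d
}
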