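# small hand-built ringing-record fixtures

record <- function(ring_id, date, age_code = "adult", sex_code = "unknown") {
  tibble::tibble(ring_id = ring_id, date = as.Date(date),
                 age_code = age_code, sex_code = sex_code)
}

annual_grid_2003_2008 <- function() occasion_grid("2003-01-01", "2008-12-31")

# constant daily weather over a span, two stations
constant_weather <- function(from, to, tmin = 0, tmax = 10, precip = 1) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  dplyr::bind_rows(
    tibble::tibble(date = dates, station_id = "A", tmin = tmin, tmax = tmax, precip = precip),
    tibble::tibble(date = dates, station_id = "B", tmin = tmin, tmax = tmax, precip = precip)
  )
}

# quick simulated study for fitting tests: no covariate effects, no year
# effects, no transience unless asked
quick_sim <- function(n = 120, n_years = 6, phi = c(0.12, 0.50, 0.55),
                      p = 0.5, residency = 1, seed = 1,
                      p_identify = c(nestling = 1, first_year = 1, adult = 1),
                      age_probs = c(nestling = 0.15, fullgrown_first_year = 0.35,
                                    adult = 0.5)) {
  cfg <- sim_config(
    n_individuals = n, n_years = n_years,
    age_at_first_probs = age_probs,
    phi_first_year = phi[1],
    phi_adult = c(male = phi[2], female = phi[3]),
    residency = c(male = residency, female = residency),
    slope_Tsu = c(male = 0, female = 0), slope_Twi = c(male = 0, female = 0),
    slope_Tsu_juv = 0, slope_Twi_juv = 0,
    sigma_year = c(male = 0, female = 0),
    p_year = p,
    p_identify = p_identify,
    identify_year_ramp = c(1, 1)
  )
  years <- 2003:(2003 + n_years - 1)
  w <- simulate_weather(years, seed = seed + 500)
  covs <- seasonal_covariates(daily_weather_index(w), years)
  sim <- simulate_population(cfg, covs, seed = seed)
  sim$covs <- covs
  sim$em <- aggregate_occasions(sim$records, sim$grid)
  sim
}
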