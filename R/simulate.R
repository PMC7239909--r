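#' Configuration for the synthetic ringing-study generator
#'
#' Defaults emulate the conditions of a 15-year high-elevation ringing study
#' of about 671 individuals: summer-biased capture effort, roughly 60% of
#' individuals of unknown sex (identification probability increasing with
#' age and varying across years), transience among adults, sex-specific
#' among-year variation, and a negative association between female survival
#' and summer temperature. All probabilities are on the probability scale;
#' covariate slopes act on the logit scale per SD of the covariate.
#'
#' @param n_individuals Number of individuals ringed.
#' @param n_years Number of study years (>= 3).
#' @param start_year First calendar year.
#' @param granularity `"annual"` or `"seasonal"` occasion structure.
#' @param sex_ratio_male Probability that an individual is male.
#' @param age_at_first_probs Probabilities of entry age class (nestling,
#'   fullgrown first-year, adult).
#' @param monthly_entry_weights Relative first-capture weights for January
#'   to December (defaults reproduce a strong summer bias).
#' @param phi_first_year Annual apparent survival of first-year birds.
#' @param phi_adult Annual apparent survival of resident adults (male,
#'   female), at average weather and zero year effect.
#' @param residency Probability that a newly captured adult is a resident;
#'   transients permanently leave the study area after their first interval,
#'   so first-interval apparent survival is `residency * phi_adult`.
#' @param slope_Tsu,slope_Twi Adult logit-scale slopes (male, female) of
#'   standardized summer/winter temperature.
#' @param slope_Tsu_juv,slope_Twi_juv First-year slopes.
#' @param sigma_year Among-year SD of the sex-specific logit year effects
#'   (male, female).
#' @param p_year Per-year recapture probability: `NULL` draws one value per
#'   year and sex from Uniform(0.1, 0.8); a scalar is recycled; or a
#'   years-by-2 matrix.
#' @param phi_season 3-by-3 matrix of 4-month survivals (rows first-year,
#'   adult male, adult female; columns winter, breeding, summer) for the
#'   seasonal structure.
#' @param p_season Seasonal recapture probability (winter, breeding,
#'   summer), modulated by a yearly logit effect of SD `sigma_p_year`.
#' @param sigma_p_year Among-year SD of the seasonal recapture year effect.
#' @param p_identify Probability that a capture event identifies the
#'   bird's sex, by age at capture (nestling, first_year, adult).
#' @param identify_year_ramp Range of the multiplicative year trend in sex
#'   identification (linear from the first to the last study year),
#'   emulating changing field methods; identification is therefore not
#'   missing at random.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_individuals = 671,
                       n_years = 15,
                       start_year = 2003,
                       granularity = c("annual", "seasonal"),
                       sex_ratio_male = 0.5,
                       age_at_first_probs = c(nestling = 0.15,
                                              fullgrown_first_year = 0.45,
                                              adult = 0.40),
                       monthly_entry_weights = c(21, 13, 14, 14, 67, 165,
                                                 141, 184, 24, 18, 1, 10),
                       phi_first_year = 0.11,
                       phi_adult = c(male = 0.52, female = 0.64),
                       residency = c(male = 0.54, female = 0.59),
                       slope_Tsu = c(male = 0.05, female = -0.85),
                       slope_Twi = c(male = 0, female = 0.99),
                       slope_Tsu_juv = -0.76,
                       slope_Twi_juv = -0.16,
                       sigma_year = c(male = 0.43, female = 1.41),
                       p_year = NULL,
                       phi_season = rbind(first_year = c(0.50, 0.70, 0.35),
                                          adult_male = c(0.85, 0.55, 0.90),
                                          adult_female = c(0.65, 0.70, 0.75)),
                       p_season = c(winter = 0.05, breeding = 0.20, summer = 0.08),
                       sigma_p_year = 0.5,
                       p_identify = c(nestling = 0.02, first_year = 0.20,
                                      adult = 0.75),
                       identify_year_ramp = c(0.6, 1.3)) {
  granularity <- match.arg(granularity)
  stopifnot(n_years >= 3, n_individuals >= 1)
  probs <- c(sex_ratio_male, phi_first_year, phi_adult, residency, p_identify,
             phi_season, p_season)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  stopifnot(length(monthly_entry_weights) == 12, all(monthly_entry_weights >= 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate daily two-station weather records
#'
#' Daily minimum and maximum temperatures are a shared seasonal sinusoid
#' plus a shared AR(1) regional anomaly plus station-specific noise (the
#' shared anomaly makes tmin and tmax highly correlated, target around
#' 0.9). Precipitation is zero-inflated with occurrence and amounts
#' suppressed on anomalously warm days, so that warm summers tend to be dry
#' (negative summer temperature-precipitation correlation across years).
#'
#' @param years Integer vector of calendar years to cover (generated through
#'   March of the year after the last, so the final winter covariate window
#'   is complete).
#' @param seed Integer seed.
#' @param mean_temp,amplitude Annual mean and semi-amplitude of the seasonal
#'   temperature cycle (degrees C).
#' @param anomaly_sd,anomaly_rho SD and lag-1 autocorrelation of the shared
#'   daily anomaly.
#' @param station_noise_sd Independent per-station, per-extreme noise SD.
#'   tmin and tmax share the seasonal cycle and the daily anomaly, so their
#'   correlation is roughly
#'   `(amplitude^2/2 + anomaly_sd^2) / (amplitude^2/2 + anomaly_sd^2 + station_noise_sd^2)`;
#'   the defaults put it near 0.9.
#' @param diurnal_range Average tmax - tmin (degrees C).
#' @param wet_prob Baseline probability of a wet day per station.
#' @return A tibble of daily records for stations `"A"` and `"B"`: `date`,
#'   `station_id`, `tmin`, `tmax`, `precip`.
#' @export
simulate_weather <- function(years, seed = 1, mean_temp = 9, amplitude = 9,
                             anomaly_sd = 3, anomaly_rho = 0.7,
                             station_noise_sd = 2.3, diurnal_range = 8,
                             wet_prob = 0.4) {
  set.seed(seed)
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years) + 1, "-03-31")), by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- mean_temp - amplitude * cos(2 * pi * (doy - 25) / 365.25)
  innov_sd <- anomaly_sd * sqrt(1 - anomaly_rho^2)
  anom <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), anomaly_rho,
                                   method = "recursive"))
  purrr::map_dfr(c(A = 0.8, B = -0.8), function(offset) {
    centre <- seasonal + anom + offset
    tmin <- centre - diurnal_range / 2 + rnorm(n, 0, station_noise_sd)
    tmax <- centre + diurnal_range / 2 + rnorm(n, 0, station_noise_sd)
    bad <- tmin > tmax
    tmax[bad] <- tmin[bad]
    # anomalously warm days are less often wet and rain less
    pw <- plogis(qlogis(wet_prob) - 0.3 * anom)
    wet <- runif(n) < pw
    amount <- stats::rgamma(n, shape = 1.2, rate = 1.2 / pmax(6 - 0.5 * anom, 1))
    tibble::tibble(date = dates, tmin = tmin, tmax = tmax,
                   precip = ifelse(wet, amount, 0))
  }, .id = "station_id") |>
    dplyr::relocate("date")
}

# logit-scale survival for one individual-interval under the generator truth
sim_logit_phi <- function(cfg, age_class, sex_i, t, xsu, xwi, gamma) {
  s_row <- if (sex_i == "male") 1L else 2L
  if (age_class == "first_year") {
    qlogis(cfg$phi_first_year) + cfg$slope_Tsu_juv * xsu[t] +
      cfg$slope_Twi_juv * xwi[t] + gamma[s_row, t]
  } else {
    qlogis(cfg$phi_adult[[sex_i]]) + cfg$slope_Tsu[[sex_i]] * xsu[t] +
      cfg$slope_Twi[[sex_i]] * xwi[t] + gamma[s_row, t]
  }
}

#' Simulate a ringing study
#'
#' Draws entry occasions, age classes and sexes; simulates the latent alive
#' state forward with logit-linear weather effects, sex-specific year
#' effects and transience (a Bernoulli fraction of newly captured adults
#' permanently emigrates after its first interval); draws detections; and
#' masks sex labels through a capture-level identification process whose
#' success increases with age and drifts across years. Returns capture
#' records in the same schema the ingest functions read, plus a truth ledger
#' sufficient to recompute the exact likelihood of the generated data.
#'
#' @param cfg A [sim_config()].
#' @param covs Seasonal covariates covering the study years (required for
#'   the annual structure; ignored for the seasonal structure). Standardized
#'   internally before slopes are applied.
#' @param seed Integer seed.
#' @return A `cjs_simulation`: list with `records` (tibble: `ring_id`,
#'   `date`, `age_code`, `sex_code`), `grid`, and `truth` (per-individual
#'   entry/sex/transience, the latent alive matrix, year effects, recapture
#'   probabilities, standardized covariates and the config).
#' @export
simulate_population <- function(cfg, covs = NULL, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  annual <- cfg$granularity == "annual"
  grid <- if (annual) {
    occasion_grid(paste0(min(years), "-01-01"), paste0(max(years), "-12-31"))
  } else {
    occasion_grid(paste0(min(years), "-04-01"), paste0(max(years), "-11-30"),
                  granularity = "seasonal")
  }
  n_occ <- nrow(grid)
  n <- cfg$n_individuals

  # standardized covariates per interval (annual structure only)
  xsu <- xwi <- rep(0, n_occ)
  covs_std <- NULL
  if (annual) {
    if (is.null(covs)) stop("annual simulation needs seasonal covariates")
    covs_std <- standardize_covariates(covs)
    idx <- match(grid$year[seq_len(n_occ - 1)], covs_std$year)
    if (anyNA(idx)) stop("covariates do not cover the study years")
    xsu[-1] <- covs_std$T_su[idx]
    xwi[-1] <- covs_std$T_wi[idx]
  }

  gamma <- rbind(rnorm(n_occ, 0, cfg$sigma_year[["male"]]),
                 rnorm(n_occ, 0, cfg$sigma_year[["female"]]))
  if (!annual) gamma[] <- 0

  # recapture probability per occasion and sex
  if (annual) {
    p_occ <- if (is.null(cfg$p_year)) {
      matrix(runif(n_occ * 2, 0.1, 0.8), n_occ, 2)
    } else if (is.matrix(cfg$p_year)) {
      stopifnot(nrow(cfg$p_year) == n_occ)
      cfg$p_year
    } else {
      matrix(cfg$p_year, n_occ, 2)
    }
  } else {
    gy <- rnorm(length(unique(grid$year)), 0, cfg$sigma_p_year)
    yidx <- match(grid$year, sort(unique(grid$year)))
    base <- qlogis(cfg$p_season[as.integer(grid$season)])
    p_occ <- matrix(plogis(base + gy[yidx]), n_occ, 2)
  }

  sex <- ifelse(runif(n) < cfg$sex_ratio_male, "male", "female")
  age_first <- sample(names(cfg$age_at_first_probs), n, replace = TRUE,
                      prob = cfg$age_at_first_probs)
  entry <- sample.int(n_occ, n, replace = TRUE,
                      prob = entry_occasion_weights(grid, cfg))
  transient <- (age_first == "adult") &
    (runif(n) >= cfg$residency[match(sex, c("male", "female"))])

  z <- matrix(0L, n, n_occ)        # alive AND present in the study area
  y <- matrix(0L, n, n_occ)
  for (i in seq_len(n)) {
    f <- entry[i]
    z[i, f] <- 1L
    y[i, f] <- 1L
    if (f == n_occ) next
    if (transient[i]) next  # leaves the area right after first capture
    s_i <- sex[i]
    adult_from <- adult_boundary(f, if (age_first[i] == "adult") "adult" else "nestling", grid)
    alive <- TRUE
    for (t in (f + 1):n_occ) {
      if (annual) {
        cls <- if (t <= adult_from) "first_year" else "adult"
        lphi <- sim_logit_phi(cfg, cls, s_i, t, xsu, xwi, gamma)
        phi <- plogis(lphi)
      } else {
        row <- if (t <= adult_from) "first_year" else paste0("adult_", s_i)
        phi <- cfg$phi_season[row, as.integer(grid$season[t])]
      }
      alive <- alive && (runif(1) < phi)
      if (!alive) break
      z[i, t] <- 1L
      s_col <- if (s_i == "male") 1L else 2L
      if (runif(1) < p_occ[t, s_col]) y[i, t] <- 1L
    }
  }

  records <- records_from_detections(y, entry, age_first, sex, grid, cfg)
  structure(
    list(
      records = records$records,
      grid = grid,
      truth = list(
        config = cfg, sex = sex, age_at_first = age_first, entry = entry,
        transient = transient, z = z, y = y, gamma = gamma, p_occ = p_occ,
        covs_std = covs_std, ring_id = records$ring_id,
        sexed = records$sexed
      )
    ),
    class = "cjs_simulation"
  )
}

entry_occasion_weights <- function(grid, cfg) {
  # distribute the monthly first-capture weights over the occasion windows
  w <- vapply(seq_len(nrow(grid)), function(t) {
    days <- seq(grid$start[t], grid$end[t] - 1, by = "day")
    sum(cfg$monthly_entry_weights[as.integer(format(days, "%m"))])
  }, 1.0)
  w / sum(w)
}

records_from_detections <- function(y, entry, age_first, sex, grid, cfg) {
  n <- nrow(y)
  ring_id <- sprintf("SF%04d", seq_len(n))
  ramp <- seq(cfg$identify_year_ramp[1], cfg$identify_year_ramp[2],
              length.out = max(grid$year) - min(grid$year) + 1)
  rows <- vector("list", n)
  sexed_any <- logical(n)
  for (i in seq_len(n)) {
    occs <- which(y[i, ] == 1L)
    adult_from <- adult_boundary(entry[i],
                                 if (age_first[i] == "adult") "adult" else "nestling",
                                 grid)
    sexed <- FALSE
    recs <- lapply(occs, function(t) {
      date <- capture_date_in_window(grid$start[t], grid$end[t], cfg)
      age_at_t <- if (t == entry[i]) {
        c(nestling = "nestling", fullgrown_first_year = "first_year",
          adult = "adult")[[age_first[i]]]
      } else if (t <= adult_from) "first_year" else "adult"
      id_class <- if (age_at_t == "nestling") "nestling" else
        if (age_at_t == "first_year") "first_year" else "adult"
      p_id <- min(1, cfg$p_identify[[id_class]] * ramp[grid$year[t] - min(grid$year) + 1])
      if (!sexed && runif(1) < p_id) sexed <<- TRUE
      tibble::tibble(ring_id = ring_id[i], date = date, age_code = age_at_t,
                     sex_code = if (sexed) sex[i] else "unknown")
    })
    sexed_any[i] <- sexed
    rows[[i]] <- dplyr::bind_rows(recs)
  }
  list(records = dplyr::bind_rows(rows) |> dplyr::arrange(.data$date, .data$ring_id),
       ring_id = ring_id, sexed = sexed_any)
}

capture_date_in_window <- function(start, end, cfg) {
  days <- seq(start, end - 1, by = "day")
  w <- cfg$monthly_entry_weights[as.integer(format(days, "%m"))]
  if (sum(w) == 0) w <- rep(1, length(days))
  days[sample.int(length(days), 1, prob = w)]
}

#' Bundled synthetic study at the published scale
#'
#' Generates the package's reference synthetic dataset: about 671
#' individuals over 15 years with summer-biased captures, transients and a
#' majority of unknown-sex individuals, together with matching daily weather
#' and the derived seasonal covariates. Regenerable bit-identically from the
#' seed; the copies under `inst/extdata/` were written by this function.
#'
#' @param seed Integer master seed; weather and population use offset
#'   substreams so each stage is independently reproducible.
#' @return A list: `records`, `weather_daily`, `covs` (raw scale), `grid`,
#'   `truth`.
#' @export
snowfinch_synthetic_study <- function(seed = 2003) {
  cfg <- sim_config()
  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  weather <- simulate_weather(years, seed = seed + 1L)
  covs <- seasonal_covariates(daily_weather_index(weather), years)
  sim <- simulate_population(cfg, covs, seed = seed + 2L)
  list(records = sim$records, weather_daily = weather, covs = covs,
       grid = sim$grid, truth = sim$truth)
}

#' Log-likelihood of simulated data at a parameter set
#'
#' Evaluates the exact marginal CJS likelihood of a simulation's encounter
#' data at its own generating parameters (or a perturbed copy): the
#' self-consistency check that the truth ledger suffices to reproduce the
#' likelihood.
#'
#' @param sim A `cjs_simulation` (annual structure).
#' @param logit_shift Additive perturbation applied to all logit-scale
#'   survival parameters before evaluating.
#' @return The total log-likelihood of the simulated detection histories.
#' @export
simulation_loglik <- function(sim, logit_shift = 0) {
  tr <- sim$truth
  cfg <- tr$config
  stopifnot(cfg$granularity == "annual")
  grid <- sim$grid
  n_occ <- nrow(grid)
  xsu <- xwi <- rep(0, n_occ)
  idx <- match(grid$year[seq_len(n_occ - 1)], tr$covs_std$year)
  xsu[-1] <- tr$covs_std$T_su[idx]
  xwi[-1] <- tr$covs_std$T_wi[idx]
  total <- 0
  for (i in seq_along(tr$ring_id)) {
    f <- tr$entry[i]
    if (f >= n_occ) next
    s_i <- tr$sex[i]
    s_col <- if (s_i == "male") 1L else 2L
    adult_from <- adult_boundary(f, if (tr$age_at_first[i] == "adult") "adult" else "nestling",
                                 grid)
    phi <- rep(NA_real_, n_occ)
    for (t in (f + 1):n_occ) {
      cls <- if (t <= adult_from) "first_year" else "adult"
      lphi <- sim_logit_phi(cfg, cls, s_i, t, xsu, xwi, tr$gamma) + logit_shift
      phi[t] <- plogis(lphi)
      if (t == f + 1 && tr$age_at_first[i] == "adult") {
        phi[t] <- phi[t] * cfg$residency[[s_i]]  # transience mixture
      }
    }
    total <- total + cjs_loglik(tr$y[i, ], f, phi, tr$p_occ[, s_col])
  }
  total
}
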