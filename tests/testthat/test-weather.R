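test_that("daily temperature index is the mean of four station extremes", {
  day <- tibble::tibble(
    date = as.Date("2005-06-01"),
    station_id = c("A", "B"),
    tmin = c(0, 2), tmax = c(10, 12), precip = c(2, 3)
  )
  idx <- daily_weather_index(day)
  expect_equal(idx$temp, 6.0)
  expect_equal(idx$precip, 5)
  flat <- day |> dplyr::mutate(tmin = 5, tmax = 5, precip = 0)
  idx2 <- daily_weather_index(flat)
  expect_equal(idx2$temp, 5.0)
  expect_equal(idx2$precip, 0)
})

test_that("temperature index matches a naive per-day loop on random data", {
  set.seed(42)
  dates <- seq(as.Date("2005-01-01"), as.Date("2005-03-31"), by = "day")
  daily <- dplyr::bind_rows(lapply(c("A", "B"), function(s) {
    tmin <- rnorm(length(dates), 0, 5)
    tibble::tibble(date = dates, station_id = s, tmin = tmin,
                   tmax = tmin + runif(length(dates), 0, 10),
                   precip = rexp(length(dates)))
  }))
  idx <- daily_weather_index(daily)
  naive_t <- naive_p <- numeric(length(dates))
  for (k in seq_along(dates)) {
    sel <- daily[daily$date == dates[k], ]
    naive_t[k] <- mean(c(sel$tmin, sel$tmax))
    naive_p[k] <- sum(sel$precip)
  }
  expect_equal(idx$temp[match(dates, idx$date)], naive_t, tolerance = 1e-12)
  expect_equal(idx$precip[match(dates, idx$date)], naive_p, tolerance = 1e-12)
})

test_that("missing station-days follow the configured policy", {
  day <- tibble::tibble(
    date = as.Date(c("2005-06-01", "2005-06-02")),
    station_id = c("A", "A"),
    tmin = 1, tmax = 3, precip = 0.5
  )
  dropped <- daily_weather_index(day, missing_policy = "drop")
  expect_equal(nrow(dropped), 0L)
  kept <- daily_weather_index(day, missing_policy = "fallback")
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$n_stations_present == 1L))
})

test_that("seasonal means use the documented windows", {
  w <- constant_weather("2005-01-01", "2006-12-31", tmin = 0, tmax = 10, precip = 1)
  idx <- daily_weather_index(w)
  sc <- seasonal_covariates(idx, 2005)
  expect_equal(sc$T_su, 5)
  expect_equal(sc$T_wi, 5)
  expect_equal(sc$Pr_su, 2)  # mean of the two-station daily sums
  # winter of year t spans Nov(t)..Mar(t+1): make those months distinct
  w2 <- w |>
    dplyr::mutate(tmin = ifelse(format(date, "%Y-%m") %in%
                                  c("2005-11", "2005-12", "2006-01", "2006-02", "2006-03"),
                                10, tmin),
                  tmax = ifelse(format(date, "%Y-%m") %in%
                                  c("2005-11", "2005-12", "2006-01", "2006-02", "2006-03"),
                                20, tmax))
  sc2 <- seasonal_covariates(daily_weather_index(w2), 2005)
  expect_equal(sc2$T_wi, 15)
  expect_equal(sc2$T_su, 5)
  # means agree with a brute-force mean over the explicit date lists
  dates_su <- seq(as.Date("2005-06-01"), as.Date("2005-09-30"), by = "day")
  idx2 <- daily_weather_index(w2)
  expect_equal(sc2$T_su, mean(idx2$temp[idx2$date %in% dates_su]))
  # incomplete seasons error rather than silently averaging a fragment
  expect_error(seasonal_covariates(idx, 2006), "days present")
})

test_that("seasonal means are invariant to record order", {
  set.seed(1)
  w <- constant_weather("2005-01-01", "2006-06-30")
  w$tmin <- rnorm(nrow(w)); w$tmax <- w$tmin + 5; w$precip <- rexp(nrow(w))
  sc1 <- seasonal_covariates(daily_weather_index(w), 2005)
  w_shuffled <- w[sample.int(nrow(w)), ]
  sc2 <- seasonal_covariates(daily_weather_index(w_shuffled), 2005)
  expect_equal(sc1, sc2)
})

test_that("standardization is mean-0 SD-1 and invertible", {
  sc <- tibble::tibble(
    year = 2003:2010,
    T_su = rnorm(8, 15, 2), T_wi = rnorm(8, 1, 1.5),
    Pr_su = rexp(8, 1 / 5), Pr_wi = rexp(8, 1 / 6)
  )
  z <- standardize_covariates(sc)
  for (v in c("T_su", "T_wi", "Pr_su", "Pr_wi")) {
    expect_equal(mean(z[[v]]), 0, tolerance = 1e-12)
    expect_equal(sd(z[[v]]), 1, tolerance = 1e-12)
  }
  expect_true(isTRUE(attr(z, "standardized")))
  back <- unstandardize_covariates(z)
  expect_equal(back$T_su, sc$T_su, tolerance = 1e-12)
  # standardizing twice is a no-op
  expect_equal(standardize_covariates(z), z)
})

test_that("covariate correlations recover exact and null relationships", {
  base <- tibble::tibble(year = 1:20, T_su = rnorm(20))
  sc <- base |> dplyr::mutate(T_wi = -T_su, Pr_su = T_su, Pr_wi = rnorm(20))
  cc <- covariate_correlations(sc)
  get_r <- function(a, b) cc$r[(cc$var1 == a & cc$var2 == b) | (cc$var1 == b & cc$var2 == a)]
  expect_equal(get_r("T_su", "T_wi"), -1)
  expect_equal(get_r("T_su", "Pr_su"), 1)
  # independent covariates at large n have correlation near zero
  set.seed(99)
  big <- tibble::tibble(year = 1:5000, T_su = rnorm(5000), T_wi = rnorm(5000),
                        Pr_su = rnorm(5000), Pr_wi = rnorm(5000))
  cc_big <- covariate_correlations(big)
  expect_lt(max(abs(cc_big$r)), 0.05)
  expect_error(covariate_correlations(sc[1:2, ]), "3 years")
  const <- sc |> dplyr::mutate(Pr_wi = 1)
  expect_warning(covariate_correlations(const), "constant")
})

test_that("correlated AR(1) daily extremes show the expected high correlation", {
  # two daily series sharing an AR(1) anomaly, as the weather generator
  # builds tmin/tmax; shared-variance ratio sets the correlation
  set.seed(7)
  n <- 5000
  rho <- 0.7; sd_shared <- 3; sd_ind <- 1
  innov <- rnorm(n, 0, sd_shared * sqrt(1 - rho^2))
  shared <- as.numeric(stats::filter(innov, rho, method = "recursive"))
  tmin <- shared + rnorm(n, 0, sd_ind)
  tmax <- shared + 8 + rnorm(n, 0, sd_ind)
  target <- sd_shared^2 / (sd_shared^2 + sd_ind^2)  # 0.9
  expect_equal(cor(tmin, tmax), target, tolerance = 0.05)
})
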