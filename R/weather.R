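#' Collapse two-station daily weather records to daily indices
#'
#' The daily temperature index is the mean of the minimum and maximum
#' temperatures of both stations (four values per day), a measure sensitive
#' to extremes; the daily precipitation index is the precipitation summed
#' over the stations.
#'
#' @param daily Data frame with columns `date`, `station_id`, `tmin`, `tmax`
#'   (degrees C) and `precip` (mm/day).
#' @param n_stations Number of stations expected per day.
#' @param missing_policy What to do with days on which fewer than
#'   `n_stations` report: `"drop"` removes the day, `"fallback"` computes the
#'   index from the stations present. Either way the `n_stations_present`
#'   column records provenance.
#' @return A tibble with one row per retained day: `date`, `temp` (degrees C),
#'   `precip` (mm), `n_stations_present`.
#' @export
daily_weather_index <- function(daily, n_stations = 2,
                                missing_policy = c("drop", "fallback")) {
  missing_policy <- match.arg(missing_policy)
  daily <- tibble::as_tibble(daily)
  stopifnot(all(c("date", "station_id", "tmin", "tmax", "precip") %in% names(daily)))
  daily$date <- as.Date(daily$date)
  if (any(daily$tmin > daily$tmax)) stop("tmin > tmax in daily weather records")
  if (any(daily$precip < 0)) stop("negative precipitation in daily weather records")
  idx <- daily |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      temp = mean(c(.data$tmin, .data$tmax)),
      precip = sum(.data$precip),
      n_stations_present = dplyr::n_distinct(.data$station_id),
      .groups = "drop"
    )
  short <- idx$n_stations_present < n_stations
  if (any(short) && missing_policy == "drop") {
    idx <- idx[!short, ]
  }
  idx
}

summer_window <- function(year) {
  seq(as.Date(paste0(year, "-06-01")), as.Date(paste0(year, "-09-30")), by = "day")
}
winter_window <- function(year) {
  seq(as.Date(paste0(year, "-11-01")), as.Date(paste0(year + 1, "-03-31")), by = "day")
}

#' Seasonal weather covariates per study year
#'
#' Averages the daily indices over the summer months (June--September) and
#' the winter months (November--March) of each year. The winter covariate of
#' year `t` spans November of year `t` to March of year `t + 1`, so that both
#' covariates of year `t` fall inside the survival interval from (the summer
#' of) year `t` to year `t + 1` and can be assigned unambiguously.
#'
#' @param daily_index Output of [daily_weather_index()].
#' @param years Integer vector of study years to summarise.
#' @param min_coverage Minimum fraction of season days that must be present;
#'   a season below this is an error (partial weather records would silently
#'   bias the seasonal mean).
#' @return A tibble with columns `year`, `T_su`, `T_wi` (degrees C), `Pr_su`,
#'   `Pr_wi` (mm/day, mean of the daily two-station sums) and the seasonal
#'   precipitation totals `Pr_su_total`, `Pr_wi_total` (mm).
#' @export
seasonal_covariates <- function(daily_index, years, min_coverage = 0.8) {
  one_season <- function(days, what) {
    sel <- daily_index[daily_index$date %in% days, ]
    if (nrow(sel) < min_coverage * length(days)) {
      stop(sprintf("season %s has %d of %d days present (min_coverage = %.2f)",
                   what, nrow(sel), length(days), min_coverage))
    }
    c(temp = mean(sel$temp), precip = mean(sel$precip), total = sum(sel$precip))
  }
  purrr::map_dfr(years, function(yr) {
    su <- one_season(summer_window(yr), paste0("summer-", yr))
    wi <- one_season(winter_window(yr), paste0("winter-", yr))
    tibble::tibble(
      year = yr,
      T_su = su[["temp"]], T_wi = wi[["temp"]],
      Pr_su = su[["precip"]], Pr_wi = wi[["precip"]],
      Pr_su_total = su[["total"]], Pr_wi_total = wi[["total"]]
    )
  })
}

covariate_names <- function() c("T_su", "T_wi", "Pr_su", "Pr_wi")

#' Standardize seasonal covariates across study years
#'
#' Z-scores each covariate (mean 0, SD 1 across the years supplied), storing
#' the constants so the transformation is invertible. Model coefficients on
#' standardized covariates are per-SD effects.
#'
#' @param sc Output of [seasonal_covariates()] (or any data frame with the
#'   four covariate columns `T_su`, `T_wi`, `Pr_su`, `Pr_wi`).
#' @return `sc` with the four covariate columns standardized; attributes
#'   `standardized` (TRUE), `center` and `scale` (named vectors).
#' @export
standardize_covariates <- function(sc) {
  if (isTRUE(attr(sc, "standardized"))) return(sc)
  vars <- covariate_names()
  center <- vapply(sc[vars], mean, 1.0)
  scale <- vapply(sc[vars], sd, 1.0)
  if (any(scale == 0)) stop("constant covariate cannot be standardized: ",
                            paste(vars[scale == 0], collapse = ", "))
  for (v in vars) sc[[v]] <- (sc[[v]] - center[[v]]) / scale[[v]]
  attr(sc, "standardized") <- TRUE
  attr(sc, "center") <- center
  attr(sc, "scale") <- scale
  sc
}

#' Invert [standardize_covariates()]
#' @param sc A standardized covariate tibble.
#' @return The covariates on their original scale.
#' @export
unstandardize_covariates <- function(sc) {
  if (!isTRUE(attr(sc, "standardized"))) return(sc)
  center <- attr(sc, "center"); scale <- attr(sc, "scale")
  for (v in covariate_names()) sc[[v]] <- sc[[v]] * scale[[v]] + center[[v]]
  attr(sc, "standardized") <- FALSE
  sc
}

#' Pairwise Pearson correlations of the seasonal covariates
#'
#' @param sc Output of [seasonal_covariates()]; at least 3 years.
#' @return A tibble with columns `var1`, `var2`, `r` for all pairs (each pair
#'   once). Constant covariates yield `NA` with a warning.
#' @export
covariate_correlations <- function(sc) {
  if (nrow(sc) < 3) stop("need at least 3 years for covariate correlations")
  vars <- covariate_names()
  if (any(vapply(sc[vars], sd, 1.0) == 0)) {
    warning("constant covariate: correlation undefined (NA)")
  }
  cm <- suppressWarnings(cor(as.data.frame(sc[vars])))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  tibble::tibble(
    var1 = vars[pairs[, 1]],
    var2 = vars[pairs[, 2]],
    r = cm[pairs]
  )
}
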