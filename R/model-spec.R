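#' Specify a CJS model variant
#'
#' The annual model family shares one structure for recapture probability
#' (a free probability per year and sex) and varies the linear predictor of
#' apparent survival:
#'
#' * `m1` -- constant survival per age/sex class, on the probability scale
#'   with uniform priors.
#' * `m2a` -- class intercepts plus sex-specific random year effects.
#' * `m2b` -- as `m2a`, with a separate adult intercept for the first
#'   interval after first capture (transience).
#' * `m3a` -- class intercepts plus linear effects of summer and winter
#'   temperature.
#' * `m3b` -- as `m3a`, with both intercepts and temperature slopes split by
#'   first/later interval after first capture.
#' * `m23b` -- transience intercepts, temperature slopes shared between
#'   first and later intervals, and sex-specific random year effects.
#' * `m4` -- as `m3a` plus summer and winter precipitation.
#' * `seasonal` -- 4-month occasions; survival per age/sex class and season
#'   on the probability scale with a Beta(3.6, 1.2) prior; recapture per
#'   season and sex on the logit scale with a year random effect.
#'
#' On the reduced dataset (all individuals adult and of known sex at entry)
#' the first-year class is dropped and the mixture is not used.
#'
#' @param variant One of `"m1"`, `"m2a"`, `"m2b"`, `"m3a"`, `"m3b"`,
#'   `"m23b"`, `"m4"`, `"seasonal"` (the leading `"m"` may be omitted).
#' @param dataset `"full"` (mixture handles unknown sex) or `"reduced"`.
#' @param standardize_covariates Z-score weather covariates across study
#'   years before they enter the linear predictor (slopes are then per-SD
#'   effects).
#' @param priors Optional overrides for the prior settings; see
#'   [default_priors()].
#' @return A `cjs_model_spec` list with the variant, dataset, the covariates
#'   it uses, structure flags and prior settings.
#' @export
cjs_model_spec <- function(variant = "m23b", dataset = c("full", "reduced"),
                           standardize_covariates = TRUE, priors = list()) {
  dataset <- match.arg(dataset)
  variant <- as.character(variant)
  if (variant %in% c("1", "2a", "2b", "3a", "3b", "23b", "4")) {
    variant <- paste0("m", variant)
  }
  all_variants <- c("m1", "m2a", "m2b", "m3a", "m3b", "m23b", "m4", "seasonal")
  if (!variant %in% all_variants) {
    stop("unknown model variant '", variant, "'; available: ",
         paste(all_variants, collapse = ", "))
  }
  covs <- switch(variant,
    m3a = , m3b = , m23b = c("T_su", "T_wi"),
    m4 = c("T_su", "T_wi", "Pr_su", "Pr_wi"),
    character()
  )
  pr <- utils::modifyList(default_priors(), priors)
  structure(
    list(
      variant = variant,
      dataset = dataset,
      covariates = covs,
      seasonal = variant == "seasonal",
      prob_scale = variant %in% c("m1", "seasonal"),
      fo_intercept = variant %in% c("m2b", "m3b", "m23b"),
      fo_slopes = variant == "m3b",
      random_year = variant %in% c("m2a", "m2b", "m23b"),
      standardize_covariates = standardize_covariates,
      priors = pr
    ),
    class = "cjs_model_spec"
  )
}

#' Default prior settings
#'
#' Normal(0, 1.5) for logit-scale survival intercepts, Normal(0, 3) for
#' covariate slopes, Uniform(0, 1) for probability-scale parameters,
#' Beta(3.6, 1.2) for seasonal survival, Normal(0, 1.5) for seasonal
#' recapture intercepts, Beta(1, 1) for the per-individual male probability,
#' and Uniform(0, 5) for random-effect standard deviations.
#'
#' @return A named list of prior settings.
#' @export
default_priors <- function() {
  list(
    sd_a0 = 1.5,
    sd_slope = 3,
    sigma_upper = 5,
    seasonal_phi_shape = c(3.6, 1.2),
    sd_b0_seasonal = 1.5
  )
}

#' @export
print.cjs_model_spec <- function(x, ...) {
  cat(sprintf("CJS model spec: variant %s, %s dataset", x$variant, x$dataset))
  if (length(x$covariates)) cat(", covariates:", paste(x$covariates, collapse = " "))
  cat("\n")
  invisible(x)
}

agesex_levels <- function(spec) {
  if (spec$dataset == "reduced") c("adult_male", "adult_female")
  else c("first_year", "adult_male", "adult_female")
}

# intercept class labels for the variant
intercept_levels <- function(spec) {
  base <- agesex_levels(spec)
  if (spec$seasonal) {
    as.vector(outer(base, season_levels(), paste, sep = "."))
  } else if (spec$fo_intercept) {
    adults <- setdiff(base, "first_year")
    c(setdiff(base, adults), as.vector(t(outer(adults, c("first", "later"), paste, sep = "_"))))
  } else {
    base
  }
}

slope_levels <- function(spec) {
  if (!length(spec$covariates)) return(character())
  if (spec$fo_slopes) intercept_levels(spec) else agesex_levels(spec)
}

# class label for one design row under candidate sex s ("male"/"female")
row_class <- function(age_class, fo, season, s, spec, slopes = FALSE) {
  base <- if (age_class == "first_year") "first_year" else paste0("adult_", s)
  if (spec$seasonal) return(paste0(base, ".", as.character(season)))
  split_fo <- if (slopes) spec$fo_slopes else spec$fo_intercept
  if (split_fo && base != "first_year") {
    paste0(base, c("_first", "_later")[fo])
  } else {
    base
  }
}

# integer class index arrays [ind, interval, candidate sex] for a design
class_maps <- function(design, spec) {
  tbl <- design$tbl
  ilev <- intercept_levels(spec)
  slev <- slope_levels(spec)
  icls <- array(0L, c(design$n_ind, design$n_occ, 2))
  scls <- if (length(slev)) array(0L, c(design$n_ind, design$n_occ, 2)) else NULL
  if (spec$dataset == "reduced" && any(tbl$age_class == "first_year")) {
    stop("reduced-dataset model but design contains first-year intervals")
  }
  sexes <- c("male", "female")
  for (r in seq_len(nrow(tbl))) {
    i <- tbl$ind[r]; t <- tbl$interval[r]
    for (s in 1:2) {
      lab <- row_class(tbl$age_class[r], tbl$firstoccasion[r], tbl$season[r],
                       sexes[s], spec)
      icls[i, t, s] <- match(lab, ilev)
      if (!is.null(scls)) {
        lab_s <- row_class(tbl$age_class[r], tbl$firstoccasion[r], tbl$season[r],
                           sexes[s], spec, slopes = TRUE)
        scls[i, t, s] <- match(lab_s, slev)
      }
    }
  }
  list(icls = icls, scls = scls, intercept_levels = ilev, slope_levels = slev)
}

# covariate matrix by interval: row t = covariates for the transition ending
# at occasion t (the year in which the interval starts)
interval_covariates <- function(design, spec, covs) {
  n_occ <- design$n_occ
  out <- matrix(0, n_occ, length(spec$covariates),
                dimnames = list(NULL, spec$covariates))
  if (!length(spec$covariates)) return(out)
  if (is.null(covs)) stop("model variant ", spec$variant, " needs seasonal covariates")
  if (spec$standardize_covariates) covs <- standardize_covariates(covs)
  cov_year <- c(NA_integer_, design$grid$year[seq_len(n_occ - 1L)])
  idx <- match(cov_year, covs$year)
  if (any(is.na(idx[-1]))) {
    stop("no covariates for interval year(s): ",
         paste(unique(cov_year[-1][is.na(idx[-1])]), collapse = ", "))
  }
  for (v in spec$covariates) out[-1, v] <- covs[[v]][idx[-1]]
  out
}
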