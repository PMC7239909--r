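#' Build per-interval design structures for survival modelling
#'
#' Expands an encounter matrix into the individual-by-interval structures the
#' survival models consume. Interval `t` denotes the transition from occasion
#' `t - 1` to occasion `t`; each individual contributes intervals
#' `first_occ + 1, ..., n_occ`.
#'
#' Age class: a bird first captured as a nestling or in its first year is
#' `first_year` until it becomes adult. On an annual grid that is after one
#' interval; on a seasonal grid the boundary is the start of the first
#' breeding window after first capture, so a juvenile ringed during breeding
#' stays `first_year` through its first winter. Birds first captured as
#' adults are `adult` throughout.
#'
#' The transience indicator `firstoccasion` is 1 for the first interval after
#' first capture and 2 later; it is only set to 1 for birds that entered as
#' adults (first-year birds have a single survival class).
#'
#' @param em An `encounter_matrix`.
#' @param grid The occasion grid (defaults to the grid stored in `em`).
#' @return A `cjs_design`: a list with `tbl` (tibble with one row per
#'   individual-interval: `ind`, `ring_id`, `interval`, `age_class`,
#'   `firstoccasion`, `class_index`, `sex`, `season`, `cov_year`), plus
#'   `n_ind`, `n_occ`, `first_occ`, `last_occ`, `y`, `sex`, `grid`.
#' @export
build_design <- function(em, grid = occasions(em)) {
  n_ind <- nrow(em)
  n_occ <- nrow(grid)
  y <- if (n_ind) encounter_y(em) else matrix(0L, 0, n_occ)
  if (n_ind && ncol(y) != n_occ) stop("encounter matrix inconsistent with grid")
  rows <- purrr::map_dfr(seq_len(n_ind), function(i) {
    f <- em$first_occ[i]
    if (f >= n_occ) return(tibble::tibble())
    ts <- (f + 1L):n_occ
    adult_from <- adult_boundary(f, em$age_at_first[i], grid)
    age_class <- ifelse(ts <= adult_from, "first_year", "adult")
    if (em$age_at_first[i] == "adult" && any(age_class == "first_year")) {
      stop("internal error: adult-at-first-capture individual assigned first_year class")
    }
    fo <- ifelse(em$age_at_first[i] == "adult" & ts == f + 1L, 1L, 2L)
    tibble::tibble(
      ind = i, ring_id = em$ring_id[i], interval = ts,
      age_class = age_class, firstoccasion = fo
    )
  })
  if (nrow(rows)) {
    sex_chr <- as.character(em$sex)[rows$ind]
    rows$sex <- factor(sex_chr, levels = sex_levels())
    rows$class_index <- factor(
      ifelse(rows$age_class == "first_year", "first_year",
             paste0("adult_", ifelse(sex_chr == "unknown", "unknown_sex", sex_chr))),
      levels = c("first_year", "adult_male", "adult_female", "adult_unknown_sex")
    )
    rows$season <- grid$season[rows$interval]
    # covariates of interval t belong to the window in which the interval starts
    rows$cov_year <- grid$year[rows$interval - 1L]
  } else {
    rows <- tibble::tibble(
      ind = integer(), ring_id = character(), interval = integer(),
      age_class = character(), firstoccasion = integer(),
      sex = factor(character(), levels = sex_levels()),
      class_index = factor(character(),
        levels = c("first_year", "adult_male", "adult_female", "adult_unknown_sex")),
      season = factor(character(), levels = season_levels()),
      cov_year = integer()
    )
  }
  structure(
    list(
      tbl = rows,
      n_ind = n_ind, n_occ = n_occ,
      first_occ = em$first_occ,
      last_occ = if (n_ind) apply(y, 1, function(r) max(which(r == 1L))) else integer(),
      y = y,
      sex = em$sex,
      age_at_first = em$age_at_first,
      ring_id = em$ring_id,
      grid = grid
    ),
    class = "cjs_design"
  )
}

# last interval (occasion index) during which the individual is first_year;
# f itself for adults (no first_year intervals).
adult_boundary <- function(f, age_at_first, grid) {
  if (age_at_first == "adult") return(f)
  if ((attr(grid, "granularity") %||% "annual") == "annual") return(f + 1L)
  later_breeding <- which(grid$season == "breeding" & grid$occasion > f)
  if (length(later_breeding)) later_breeding[1] else nrow(grid)
}

#' @export
print.cjs_design <- function(x, ...) {
  cat(sprintf("CJS design: %d individuals, %d occasions, %d individual-intervals\n",
              x$n_ind, x$n_occ, nrow(x$tbl)))
  invisible(x)
}
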