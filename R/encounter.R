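#' Build an occasion grid
#'
#' Constructs the temporal aggregation grid onto which individual capture
#' records are collapsed. Annual grids use calendar years (1 January --
#' 31 December). Seasonal grids use contiguous 4-month windows: winter
#' (December--March, straddling the year boundary), breeding (April--July)
#' and summer (August--November).
#'
#' Windows are half-open `[start, end)`: a capture on the last calendar day of
#' a window belongs to that window.
#'
#' @param start,end `Date` (or coercible) limits of the study window. Every
#'   window that overlaps `[start, end]` is included.
#' @param granularity `"annual"` or `"seasonal"`.
#' @return A tibble with one row per occasion: `occasion` (integer index),
#'   `start`, `end` (Dates, half-open), `label`, `year` (calendar year of the
#'   window start) and `season` (factor, `NA` for annual grids).
#' @export
#' @examples
#' occasion_grid("2003-06-01", "2017-06-30")
#' occasion_grid("2003-06-01", "2005-06-30", granularity = "seasonal")
occasion_grid <- function(start, end, granularity = c("annual", "seasonal")) {
  granularity <- match.arg(granularity)
  start <- as.Date(start)
  end <- as.Date(end)
  stopifnot(!is.na(start), !is.na(end), start <= end)
  if (granularity == "annual") {
    years <- seq(as.integer(format(start, "%Y")), as.integer(format(end, "%Y")))
    grid <- tibble::tibble(
      occasion = seq_along(years),
      start = as.Date(paste0(years, "-01-01")),
      end = as.Date(paste0(years + 1, "-01-01")),
      label = as.character(years),
      year = years,
      season = factor(NA_character_, levels = season_levels())
    )
  } else {
    # season window starts fall on 1 Dec / 1 Apr / 1 Aug
    first_start <- season_window_start(start)
    starts <- first_start
    while (tail(starts, 1) <= end) {
      starts <- c(starts, next_season_start(tail(starts, 1)))
    }
    starts <- starts[-length(starts)]
    ends <- as.Date(vapply(starts, function(s) as.character(next_season_start(s)), ""))
    season <- vapply(starts, season_of_start, "")
    year <- as.integer(format(starts, "%Y"))
    grid <- tibble::tibble(
      occasion = seq_along(starts),
      start = starts, end = ends,
      label = paste0(season, "-", year),
      year = year,
      season = factor(season, levels = season_levels())
    )
  }
  attr(grid, "granularity") <- granularity
  grid
}

season_levels <- function() c("winter", "breeding", "summer")

# latest season-window start at or before a date
season_window_start <- function(date) {
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  if (m == 12) as.Date(paste0(y, "-12-01"))
  else if (m >= 8) as.Date(paste0(y, "-08-01"))
  else if (m >= 4) as.Date(paste0(y, "-04-01"))
  else as.Date(paste0(y - 1, "-12-01"))
}

next_season_start <- function(start) {
  m <- as.integer(format(start, "%m"))
  y <- as.integer(format(start, "%Y"))
  switch(as.character(m),
    "12" = as.Date(paste0(y + 1, "-04-01")),
    "4" = as.Date(paste0(y, "-08-01")),
    "8" = as.Date(paste0(y, "-12-01")),
    stop("not a season window start: ", start)
  )
}

season_of_start <- function(start) {
  switch(format(start, "%m"), "12" = "winter", "04" = "breeding", "08" = "summer",
         stop("not a season window start: ", start))
}

age_code_levels <- function() c("nestling", "first_year", "adult", "unknown_grown")
sex_levels <- function() c("male", "female", "unknown")
age_first_levels <- function() c("nestling", "fullgrown_first_year", "adult")

#' Read ringing records from delimited text
#'
#' Expects columns `ring_id`, `date` (ISO-8601), `age_code` (one of
#' `nestling`, `first_year`, `adult`, `unknown_grown`) and `sex_code` (one of
#' `male`, `female`, `unknown`). One row per physical capture event.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated ringing records.
#' @export
read_ringing_records <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ringing_records(tibble::as_tibble(raw))
}

#' Validate a data frame of ringing records
#'
#' @param records Data frame with columns `ring_id`, `date`, `age_code`,
#'   `sex_code`.
#' @return The records as a tibble with parsed dates and checked factor codes.
#' @export
validate_ringing_records <- function(records) {
  needed <- c("ring_id", "date", "age_code", "sex_code")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("ringing records missing column(s): ", paste(miss, collapse = ", "))
  records <- tibble::as_tibble(records)
  records$date <- as.Date(records$date)
  if (anyNA(records$date)) stop("unparseable capture date(s) in ringing records")
  bad_age <- setdiff(unique(records$age_code), age_code_levels())
  if (length(bad_age)) stop("unknown age_code value(s): ", paste(bad_age, collapse = ", "))
  bad_sex <- setdiff(unique(records$sex_code), sex_levels())
  if (length(bad_sex)) stop("unknown sex_code value(s): ", paste(bad_sex, collapse = ", "))
  # an individual may move from unknown to known sex, never male <-> female
  conf <- records |>
    dplyr::filter(.data$sex_code != "unknown") |>
    dplyr::distinct(.data$ring_id, .data$sex_code) |>
    dplyr::count(.data$ring_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conf)) {
    stop("conflicting sex codes for ring_id(s): ", paste(conf$ring_id, collapse = ", "))
  }
  records
}

#' Aggregate capture records onto an occasion grid
#'
#' Collapses individual capture events to a binary encounter matrix: one row
#' per individual, one column per occasion, with `y[i, t] = 1` if individual
#' `i` was captured at least once during occasion `t`. Multiple captures
#' within one window collapse to a single detection.
#'
#' @param records Ringing records (see [read_ringing_records()]).
#' @param grid An [occasion_grid()].
#' @return An `encounter_matrix`: a tibble with one row per individual and
#'   columns `ring_id`, `ch` (capture-history string), `first_occ`,
#'   `n_captures` (number of occasions with a detection), `age_at_first`
#'   (factor: `nestling`, `fullgrown_first_year`, `adult`) and `sex` (factor:
#'   `male`, `female`, `unknown`), with the grid stored as an attribute.
#' @export
aggregate_occasions <- function(records, grid) {
  records <- validate_ringing_records(records)
  idx <- match_occasion(records$date, grid)
  if (anyNA(idx)) {
    bad <- records[is.na(idx), ]
    stop("capture record(s) outside the occasion grid: ",
         paste(paste0(bad$ring_id, "@", bad$date), collapse = ", "))
  }
  records$occ <- idx
  per_ind <- records |>
    dplyr::group_by(.data$ring_id) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::summarise(
      occs = list(sort(unique(.data$occ))),
      age_at_first = age_at_first_from_code(.data$age_code[1]),
      sex = resolved_sex(.data$sex_code),
      .groups = "drop"
    )
  n_occ <- nrow(grid)
  ch <- vapply(per_ind$occs, function(o) {
    h <- rep.int(0L, n_occ); h[o] <- 1L; paste(h, collapse = "")
  }, "")
  em <- tibble::tibble(
    ring_id = per_ind$ring_id,
    ch = ch,
    first_occ = vapply(per_ind$occs, function(o) o[1], 1L),
    n_captures = lengths(per_ind$occs),
    age_at_first = factor(per_ind$age_at_first, levels = age_first_levels()),
    sex = factor(per_ind$sex, levels = sex_levels())
  )
  new_encounter_matrix(em, grid)
}

match_occasion <- function(dates, grid) {
  i <- findInterval(as.numeric(dates), as.numeric(grid$start))
  i[i == 0L] <- NA_integer_
  out_of <- !is.na(i) & as.numeric(dates) >= as.numeric(grid$end)[pmax(i, 1L)]
  i[out_of] <- NA_integer_
  i
}

age_at_first_from_code <- function(code) {
  switch(code,
    nestling = "nestling",
    first_year = "fullgrown_first_year",
    # birds of unknown age ringed fully grown are treated as adults
    adult = "adult",
    unknown_grown = "adult"
  )
}

resolved_sex <- function(sex_codes) {
  known <- unique(sex_codes[sex_codes != "unknown"])
  if (length(known) == 0L) "unknown" else known
}

new_encounter_matrix <- function(em, grid) {
  stopifnot(all(substr(em$ch, em$first_occ, em$first_occ) == "1"))
  stopifnot(all(em$n_captures >= 1L))
  attr(em, "grid") <- grid
  class(em) <- c("encounter_matrix", class(em))
  em
}

#' @export
print.encounter_matrix <- function(x, ...) {
  grid <- occasions(x)
  cat(sprintf("Encounter matrix: %d individuals x %d %s occasions\n",
              nrow(x), nrow(grid), attr(grid, "granularity") %||% "custom"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Occasion grid of an encounter matrix
#' @param em An `encounter_matrix`.
#' @return The occasion-grid tibble the matrix was aggregated onto.
#' @export
occasions <- function(em) attr(em, "grid")

#' Binary detection matrix of an encounter matrix
#' @param em An `encounter_matrix`.
#' @return Integer matrix, individuals by occasions, with ring ids as row names.
#' @export
encounter_y <- function(em) {
  n_occ <- nchar(em$ch[1])
  y <- matrix(0L, nrow(em), n_occ,
              dimnames = list(em$ring_id, seq_len(n_occ)))
  for (i in seq_len(nrow(em))) {
    y[i, ] <- as.integer(strsplit(em$ch[i], "")[[1]])
  }
  y
}

#' Restrict records to sex-ascertained captures and rebuild the encounter matrix
#'
#' Builds the reduced dataset: individuals whose sex was never identified are
#' dropped, and for each retained individual all captures before the first
#' capture at which its sex was ascertained are discarded, so that the first
#' sexed capture becomes the first occasion. Individuals that were not adult
#' when first sexed are excluded.
#'
#' @inheritParams aggregate_occasions
#' @return An `encounter_matrix` of the reduced dataset (all individuals of
#'   known sex, all adult at their new first occasion).
#' @export
build_reduced_dataset <- function(records, grid) {
  records <- validate_ringing_records(records)
  trimmed <- records |>
    dplyr::group_by(.data$ring_id) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::filter(any(.data$sex_code != "unknown")) |>
    dplyr::filter(dplyr::row_number() >= which(.data$sex_code != "unknown")[1]) |>
    # keep only individuals adult (or unaged fully grown) when first sexed
    dplyr::filter(.data$age_code[1] %in% c("adult", "unknown_grown")) |>
    dplyr::ungroup()
  if (nrow(trimmed) == 0L) {
    warning("reduced dataset is empty: no adult individuals with identified sex")
    em <- tibble::tibble(
      ring_id = character(), ch = character(), first_occ = integer(),
      n_captures = integer(),
      age_at_first = factor(character(), levels = age_first_levels()),
      sex = factor(character(), levels = sex_levels())
    )
    attr(em, "grid") <- grid
    class(em) <- c("encounter_matrix", class(em))
    return(em)
  }
  aggregate_occasions(trimmed, grid)
}

#' Capture-frequency spectrum
#'
#' Tabulates individuals by their number of capture occasions; the number
#' captured exactly once and the number captured at least three times are the
#' two statistics used for posterior-predictive checking.
#'
#' @param em An `encounter_matrix` (or any data frame with an `n_captures`
#'   column; a `sex` column is needed for `by_sex_known = TRUE`).
#' @param by_sex_known Also split the spectrum by whether sex is known.
#' @return A tibble with columns `group` (`"all"`, and `"sex_known"` /
#'   `"sex_unknown"` when split), `n_captures`, `n_individuals`, plus the
#'   scalar statistics as columns `n_once` and `n_ge3` repeated within group.
#' @export
capture_frequency_spectrum <- function(em, by_sex_known = FALSE) {
  groups <- list(all = rep(TRUE, nrow(em)))
  if (by_sex_known) {
    groups$sex_known <- em$sex != "unknown"
    groups$sex_unknown <- em$sex == "unknown"
  }
  purrr::imap_dfr(groups, function(sel, g) {
    nc <- em$n_captures[sel]
    spec <- if (length(nc)) {
      tibble::as_tibble(table(n_captures = nc), n = "n_individuals") |>
        dplyr::mutate(n_captures = as.integer(.data$n_captures))
    } else {
      tibble::tibble(n_captures = integer(), n_individuals = integer())
    }
    spec |>
      dplyr::mutate(
        group = g,
        n_once = sum(nc == 1L),
        n_ge3 = sum(nc >= 3L),
        .before = 1
      )
  })
}

#' Summarize an encounter matrix
#'
#' Counts of individuals by sex and by age at first capture, per-occasion
#' detection totals, and the percentage of unknown-sex individuals.
#'
#' Whether "recaptures" should count capture events or individual-occasion
#' detections is ambiguous in general; this summary reports occasion-level
#' recaptures (`n_recapture_occasions`), while event counts remain available
#' from the raw records.
#'
#' @param em An `encounter_matrix`.
#' @return A list with elements `n_ind`, `by_sex`, `by_age_at_first`,
#'   `per_occasion` (tibbles), `n_recapture_occasions` (detections beyond
#'   first capture) and `pct_unknown_sex` (integer percent).
#' @export
summarize_dataset <- function(em) {
  y <- if (nrow(em)) encounter_y(em) else matrix(0L, 0, 0)
  per_occ <- tibble::tibble(
    occasion = seq_len(ncol(y)),
    n_detected = if (ncol(y)) as.integer(colSums(y)) else integer()
  )
  n_unknown <- sum(em$sex == "unknown")
  list(
    n_ind = nrow(em),
    by_sex = dplyr::count(tibble::as_tibble(em), .data$sex, name = "n_individuals"),
    by_age_at_first = dplyr::count(tibble::as_tibble(em), .data$age_at_first,
                                   name = "n_individuals"),
    per_occasion = per_occ,
    n_recapture_occasions = sum(em$n_captures - 1L),
    pct_unknown_sex = if (nrow(em)) as.integer(round(100 * n_unknown / nrow(em))) else 0L
  )
}

#' Export an encounter matrix as a MARK-style .inp file
#'
#' Writes one line per individual: a `/* ring_id */` comment, the capture
#' history string, and nine group-frequency columns (sex by age at first
#' capture), terminated by `;`.
#'
#' @param em An `encounter_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(em, path) {
  sex_i <- as.integer(em$sex)
  age_i <- as.integer(em$age_at_first)
  lines <- vapply(seq_len(nrow(em)), function(i) {
    freq <- rep.int(0L, 9L)
    freq[(sex_i[i] - 1L) * 3L + age_i[i]] <- 1L
    sprintf("/* %s */ %s %s;", em$ring_id[i], em$ch[i], paste(freq, collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a MARK-style .inp file written by [write_inp()]
#'
#' @param path Input file path.
#' @param grid The [occasion_grid()] the histories refer to.
#' @return An `encounter_matrix`.
#' @export
read_inp <- function(path, grid) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^/\\* (.+) \\*/ ([01]+) ([0-9 ]+);$", lines))
  if (any(lengths(m) != 4L)) stop("malformed .inp line(s)")
  ring_id <- vapply(m, `[[`, "", 2)
  ch <- vapply(m, `[[`, "", 3)
  freq <- lapply(m, function(x) as.integer(strsplit(x[[4]], " +")[[1]]))
  if (any(vapply(freq, sum, 1L) != 1L)) stop("each .inp line must have exactly one group")
  grp <- vapply(freq, which.max, 1L)
  sex <- sex_levels()[(grp - 1L) %/% 3L + 1L]
  age <- age_first_levels()[(grp - 1L) %% 3L + 1L]
  first_occ <- vapply(strsplit(ch, ""), function(h) which(h == "1")[1], 1L)
  em <- tibble::tibble(
    ring_id = ring_id, ch = ch, first_occ = first_occ,
    n_captures = vapply(strsplit(ch, ""), function(h) sum(h == "1"), 1L),
    age_at_first = factor(age, levels = age_first_levels()),
    sex = factor(sex, levels = sex_levels())
  )
  new_encounter_matrix(em, grid)
}
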