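test_that("captures within one window collapse to a single annual detection", {
  recs <- dplyr::bind_rows(
    record("A1", "2005-03-01"),
    record("A1", "2005-08-15"),
    record("B2", "2004-06-10")
  )
  grid <- annual_grid_2003_2008()
  em <- aggregate_occasions(recs, grid)
  a1 <- em[em$ring_id == "A1", ]
  expect_equal(a1$ch, "001000")
  expect_equal(a1$first_occ, 3L)
  expect_equal(a1$n_captures, 1L)
  y <- encounter_y(em)
  expect_equal(unname(y["B2", ]), c(0L, 1L, 0L, 0L, 0L, 0L))
})

test_that("seasonal aggregation assigns captures to the right season window", {
  grid <- occasion_grid("2004-12-01", "2006-11-30", granularity = "seasonal")
  em <- aggregate_occasions(record("A1", "2005-04-10"), grid)
  t <- em$first_occ
  expect_equal(as.character(grid$season[t]), "breeding")
  expect_equal(grid$year[t], 2005L)
  # winter window straddles the year boundary: January belongs to the
  # December-started window
  em2 <- aggregate_occasions(record("B2", "2005-01-20"), grid)
  expect_equal(as.character(grid$season[em2$first_occ]), "winter")
  expect_equal(grid$year[em2$first_occ], 2004L)
})

test_that("records outside the grid and conflicting sexes are rejected", {
  grid <- annual_grid_2003_2008()
  expect_error(aggregate_occasions(record("A1", "2002-05-05"), grid), "outside")
  expect_error(aggregate_occasions(record("A1", "2009-01-01"), grid), "outside")
  conf <- dplyr::bind_rows(
    record("A1", "2004-05-05", sex_code = "male"),
    record("A1", "2006-05-05", sex_code = "female")
  )
  expect_error(aggregate_occasions(conf, grid), "conflicting sex")
  # unknown -> known is fine
  ok <- dplyr::bind_rows(
    record("A1", "2004-05-05", sex_code = "unknown"),
    record("A1", "2006-05-05", sex_code = "female")
  )
  expect_equal(as.character(aggregate_occasions(ok, grid)$sex), "female")
})

test_that("reduced dataset starts histories at the first sexed adult capture", {
  grid <- annual_grid_2003_2008()
  recs <- dplyr::bind_rows(
    record("A1", "2004-06-01", sex_code = "unknown"),   # t=2 unknown
    record("A1", "2006-06-01", sex_code = "male"),      # t=4 sexed
    record("A1", "2008-06-01", sex_code = "unknown"),   # t=6
    record("B2", "2005-06-01", sex_code = "unknown"),   # never sexed
    record("C3", "2003-07-01", sex_code = "female"),    # sexed at first capture
    record("C3", "2007-07-01", sex_code = "unknown"),
    record("D4", "2004-06-01", age_code = "first_year", sex_code = "male") # not adult when sexed
  )
  red <- build_reduced_dataset(recs, grid)
  expect_setequal(red$ring_id, c("A1", "C3"))
  a1 <- red[red$ring_id == "A1", ]
  expect_equal(a1$first_occ, 4L)
  expect_equal(a1$ch, "000101")
  # sexed at first capture: identical in full and reduced data
  full <- aggregate_occasions(recs, grid)
  expect_equal(red[red$ring_id == "C3", ]$ch, full[full$ring_id == "C3", ]$ch)
  # detections are never added, only trimmed
  for (id in red$ring_id) {
    y_red <- as.integer(strsplit(red$ch[red$ring_id == id], "")[[1]])
    y_full <- as.integer(strsplit(full$ch[full$ring_id == id], "")[[1]])
    expect_true(all(y_red <= y_full))
  }
  expect_warning(build_reduced_dataset(record("X", "2004-05-05"), grid), "empty")
})

test_that("design classes follow the juvenile-to-adult transition", {
  grid <- annual_grid_2003_2008()
  recs <- dplyr::bind_rows(
    record("N1", "2005-06-15", age_code = "nestling"),
    record("N1", "2007-06-15"),
    record("M1", "2004-05-01", age_code = "adult", sex_code = "male")
  )
  em <- aggregate_occasions(recs, grid)
  des <- build_design(em)
  n1 <- des$tbl[des$tbl$ring_id == "N1", ]
  expect_equal(n1$age_class, c("first_year", "adult", "adult"))
  expect_equal(as.character(n1$class_index),
               c("first_year", "adult_unknown_sex", "adult_unknown_sex"))
  expect_true(all(n1$firstoccasion == 2L)) # transience indicator is adults-only
  m1 <- des$tbl[des$tbl$ring_id == "M1", ]
  expect_equal(m1$firstoccasion, c(1L, 2L, 2L, 2L))
  expect_true(all(m1$age_class == "adult"))
  # interval t carries the covariate year of the window it starts in
  expect_equal(m1$cov_year, c(2004L, 2005L, 2006L, 2007L))
})

test_that("a juvenile on the seasonal grid stays first-year until the next breeding window", {
  grid <- occasion_grid("2005-04-01", "2006-11-30", granularity = "seasonal")
  em <- aggregate_occasions(
    record("J1", "2005-06-01", age_code = "nestling"), grid)
  des <- build_design(em)
  j <- des$tbl[des$tbl$ring_id == "J1", ]
  # ringed in breeding 2005: first_year through summer, winter, and the
  # transition into breeding 2006; adult afterwards
  expect_equal(j$age_class[1:3], rep("first_year", 3))
  expect_true(all(j$age_class[-(1:3)] == "adult"))
})

test_that("single-occasion studies give an empty design", {
  grid <- occasion_grid("2005-01-01", "2005-12-31")
  em <- aggregate_occasions(record("A1", "2005-06-01"), grid)
  des <- build_design(em)
  expect_equal(nrow(des$tbl), 0L)
})

test_that("capture-frequency spectrum counts once/thrice captures and sums to n", {
  em <- tibble::tibble(
    ring_id = paste0("i", 1:5),
    n_captures = c(1L, 1L, 2L, 3L, 4L),
    sex = factor(c("male", "unknown", "unknown", "female", "male"),
                 levels = c("male", "female", "unknown"))
  )
  sp <- capture_frequency_spectrum(em)
  expect_equal(sp$n_once[1], 2L)
  expect_equal(sp$n_ge3[1], 2L)
  expect_equal(sum(sp$n_individuals), 5L)
  split <- capture_frequency_spectrum(em, by_sex_known = TRUE)
  known <- split[split$group == "sex_known", ]
  expect_equal(known$n_once[1], 1L)
  expect_equal(sum(split$n_individuals[split$group != "all"]), 5L)
  # degenerate spectra
  all_once <- tibble::tibble(n_captures = rep(1L, 7))
  expect_equal(capture_frequency_spectrum(all_once)$n_once[1], 7L)
  expect_equal(capture_frequency_spectrum(all_once)$n_ge3[1], 0L)
  empty <- tibble::tibble(n_captures = integer())
  expect_equal(nrow(capture_frequency_spectrum(empty)), 0L)
})

test_that("dataset summary reports the unknown-sex percentage", {
  mk <- function(m, f, u) {
    tibble::tibble(
      ring_id = sprintf("i%d", seq_len(m + f + u)),
      ch = rep("10", m + f + u), first_occ = 1L, n_captures = 1L,
      age_at_first = factor("adult", levels = c("nestling", "fullgrown_first_year", "adult")),
      sex = factor(rep(c("male", "female", "unknown"), c(m, f, u)),
                   levels = c("male", "female", "unknown"))
    )
  }
  grid2 <- occasion_grid("2003-01-01", "2004-12-31")
  em <- mk(157, 104, 410)
  attr(em, "grid") <- grid2
  class(em) <- c("encounter_matrix", class(em))
  s <- summarize_dataset(em)
  expect_equal(s$pct_unknown_sex, 61L)
  em2 <- mk(3, 2, 0); attr(em2, "grid") <- grid2
  class(em2) <- c("encounter_matrix", class(em2))
  expect_equal(summarize_dataset(em2)$pct_unknown_sex, 0L)
  em3 <- mk(1, 1, 2); attr(em3, "grid") <- grid2
  class(em3) <- c("encounter_matrix", class(em3))
  expect_equal(summarize_dataset(em3)$pct_unknown_sex, 50L)
})

test_that("MARK .inp export round-trips detections, first captures and groups", {
  sim <- quick_sim(n = 60, seed = 11,
                   p_identify = c(nestling = 0.1, first_year = 0.3, adult = 0.7))
  em <- sim$em
  path <- withr::local_tempfile(fileext = ".inp")
  write_inp(em, path)
  em2 <- read_inp(path, sim$grid)
  expect_equal(em2$ch, em$ch)
  expect_equal(em2$first_occ, em$first_occ)
  expect_equal(as.character(em2$sex), as.character(em$sex))
  expect_equal(as.character(em2$age_at_first), as.character(em$age_at_first))
})

test_that("aggregation is idempotent on already-aggregated data", {
  sim <- quick_sim(n = 50, seed = 7)
  em <- sim$em
  # expand the encounter matrix back to one record per detection occasion
  y <- encounter_y(em)
  recs <- purrr::map_dfr(seq_len(nrow(em)), function(i) {
    ts <- which(y[i, ] == 1L)
    tibble::tibble(
      ring_id = em$ring_id[i],
      date = sim$grid$start[ts],
      age_code = c(nestling = "nestling", fullgrown_first_year = "first_year",
                   adult = "adult")[[as.character(em$age_at_first[i])]],
      sex_code = as.character(em$sex[i])
    )
  })
  em2 <- aggregate_occasions(recs, sim$grid)
  em2 <- em2[match(em$ring_id, em2$ring_id), ]
  expect_equal(em2$ch, em$ch)
  expect_equal(em2$first_occ, em$first_occ)
})
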