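test_that("marginalized likelihood matches hand-computed histories", {
  # [1,0,1]: only the all-alive path is consistent
  expect_equal(exp(cjs_loglik(c(1, 0, 1), 1, rep(0.5, 3), rep(0.5, 3))), 0.0625,
               tolerance = 1e-12)
  # [1,0,0]: dead after 1, or alive-unseen combinations
  expect_equal(exp(cjs_loglik(c(1, 0, 0), 1, rep(0.5, 3), rep(0.5, 3))), 0.6875,
               tolerance = 1e-12)
  # first capture at the final occasion carries no information
  expect_equal(cjs_loglik(c(0, 0, 1), 3, rep(0.5, 3), rep(0.5, 3)), 0)
  expect_error(cjs_loglik(c(1, 0), 1, c(0.5, 1.5), c(0.5, 0.5)), "\\[0, 1\\]")
})

test_that("marginalized likelihood equals latent-path enumeration", {
  set.seed(123)
  for (rep in 1:25) {
    n_occ <- sample(2:5, 1)
    phi <- rand_unit(n_occ); p <- rand_unit(n_occ)
    first <- sample.int(n_occ - 1, 1)
    hs <- all_histories_after(n_occ, first)
    for (r in seq_len(nrow(hs))) {
      h <- hs[r, ]
      expect_equal(exp(cjs_loglik(h, first, phi, p)),
                   enum_cjs_lik(h, first, phi, p), tolerance = 1e-10)
    }
  }
})

test_that("history probabilities given first capture sum to one", {
  set.seed(77)
  for (rep in 1:10) {
    n_occ <- sample(3:5, 1)
    phi <- rand_unit(n_occ); p <- rand_unit(n_occ)
    first <- sample.int(n_occ - 1, 1)
    hs <- all_histories_after(n_occ, first)
    total <- sum(apply(hs, 1, function(h) exp(cjs_loglik(h, first, phi, p))))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("likelihood rises with survival when the bird is seen at the end", {
  h <- c(1, 0, 0, 1)
  p <- rep(0.4, 4)
  lls <- vapply(seq(0.1, 0.9, by = 0.1),
                function(s) cjs_loglik(h, 1, rep(s, 4), p), 1.0)
  expect_true(all(diff(lls) > 0))
})

test_that("mixture likelihood is the q-weighted sum with exact endpoints", {
  h <- c(1, 0, 1)
  phi_m <- rep(0.5, 3); p_m <- rep(0.5, 3)
  h2 <- c(1, 0, 0)
  # component likelihoods 0.0625 (male params on h) vs 0.6875-style female set
  phi_f <- c(NA, 0.9, 0.9); p_f <- c(NA, 0.8, 0.8)
  lm <- exp(cjs_loglik(h, 1, phi_m, p_m))
  lf <- exp(cjs_loglik(h, 1, phi_f, p_f))
  for (q in c(0, 0.25, 0.5, 0.9, 1)) {
    expect_equal(exp(mixture_loglik(h, 1, phi_m, p_m, phi_f, p_f, q)),
                 q * lm + (1 - q) * lf, tolerance = 1e-12)
  }
  # 0.5/0.5 mixture of the two worked examples
  expect_equal(0.5 * 0.0625 + 0.5 * 0.6875, 0.375)
  # identical components make the mixture independent of q
  l1 <- mixture_loglik(h2, 1, phi_m, p_m, phi_m, p_m, 0.1)
  l2 <- mixture_loglik(h2, 1, phi_m, p_m, phi_m, p_m, 0.9)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("mixture likelihood is linear in q", {
  set.seed(5)
  h <- c(1, 1, 0, 0)
  phi_m <- rand_unit(4); p_m <- rand_unit(4)
  phi_f <- rand_unit(4); p_f <- rand_unit(4)
  qs <- seq(0, 1, by = 0.1)
  ls <- vapply(qs, function(q) exp(mixture_loglik(h, 1, phi_m, p_m, phi_f, p_f, q)), 1.0)
  fitline <- lm(ls ~ qs)
  expect_equal(unname(residuals(fitline)), rep(0, length(qs)), tolerance = 1e-12)
})

test_that("nested variants collapse onto each other", {
  sim <- quick_sim(n = 40, n_years = 5, seed = 3)
  em <- sim$em
  covs <- sim$covs
  design <- build_design(em)

  # m3a with zero slopes == m2a with zero year effects
  spec3a <- cjs_model_spec("m3a")
  spec2a <- cjs_model_spec("m2a")
  n_occ <- design$n_occ
  b0 <- matrix(0.4, n_occ, 2)
  a0_3 <- c(first_year = -1, adult_male = 0.2, adult_female = 0.3)
  params3a <- list(a0 = a0_3, a1 = c(0, 0, 0), a2 = c(0, 0, 0), b0 = b0)
  params2a <- list(a0 = a0_3, gamma = matrix(0, 2, n_occ), sigma = c(1, 1), b0 = b0)
  lp3 <- linear_predictor(spec3a, params3a, design, covs)
  lp2 <- linear_predictor(spec2a, params2a, design, covs)
  expect_equal(lp3$phi, lp2$phi, tolerance = 1e-12)

  # m23b with zero slopes and zero year effects == m2b
  spec23b <- cjs_model_spec("m23b")
  spec2b <- cjs_model_spec("m2b")
  a0_fo <- c(first_year = -1, adult_male_first = -0.5, adult_male_later = 0.2,
             adult_female_first = -0.4, adult_female_later = 0.3)
  params23b <- list(a0 = a0_fo, a1 = c(0, 0, 0), a2 = c(0, 0, 0),
                    gamma = matrix(0, 2, n_occ), sigma = c(1, 1), b0 = b0)
  params2b <- list(a0 = a0_fo, gamma = matrix(0, 2, n_occ), sigma = c(1, 1), b0 = b0)
  expect_equal(linear_predictor(spec23b, params23b, design, covs)$phi,
               linear_predictor(spec2b, params2b, design, covs)$phi,
               tolerance = 1e-12)

  # m3b with equal first/later slopes matches m3a's response to the covariate
  spec3b <- cjs_model_spec("m3b")
  lev3b <- c(first_year = -1, adult_male_first = 0.2, adult_male_later = 0.2,
             adult_female_first = 0.3, adult_female_later = 0.3)
  s3b <- setNames(c(-0.5, 0.4, 0.4, 0.6, 0.6), names(lev3b))
  params3b <- list(a0 = lev3b, a1 = s3b, a2 = 0 * s3b, b0 = b0)
  params3a2 <- list(a0 = c(first_year = -1, adult_male = 0.2, adult_female = 0.3),
                    a1 = c(first_year = -0.5, adult_male = 0.4, adult_female = 0.6),
                    a2 = c(first_year = 0, adult_male = 0, adult_female = 0),
                    b0 = b0)
  expect_equal(linear_predictor(spec3b, params3b, design, covs)$phi,
               linear_predictor(spec3a, params3a2, design, covs)$phi,
               tolerance = 1e-12)
})

test_that("a standardized covariate shifts the logit by its slope", {
  # +1 SD of summer temperature with slope -0.85 drops the female logit by 0.85
  eta0 <- 0.3
  expect_equal(plogis(eta0 - 0.85 * 1), plogis(eta0 - 0.85), tolerance = 1e-15)
  expect_lt(plogis(eta0 - 0.85), plogis(eta0))
})

test_that("m1's constant survival is a pure class lookup", {
  sim <- quick_sim(n = 30, n_years = 4, seed = 9)
  design <- build_design(sim$em)
  spec <- cjs_model_spec("m1")
  a0 <- c(first_year = 0.12, adult_male = 0.50, adult_female = 0.55)
  params <- list(a0 = a0, b0 = matrix(0.4, design$n_occ, 2))
  lp <- linear_predictor(spec, params, design)
  tbl <- design$tbl
  for (r in sample(nrow(tbl), min(20, nrow(tbl)))) {
    i <- tbl$ind[r]; t <- tbl$interval[r]
    for (s in 1:2) {
      lab <- if (tbl$age_class[r] == "first_year") "first_year"
             else paste0("adult_", c("male", "female")[s])
      expect_equal(lp$phi[i, t, s], a0[[lab]])
    }
  }
})

test_that("log posterior adds likelihood and priors, flags bad terms", {
  grid <- occasion_grid("2003-01-01", "2005-12-31")
  recs <- dplyr::bind_rows(
    record("A1", "2003-06-01", age_code = "adult", sex_code = "male"),
    record("A1", "2005-06-01", age_code = "adult", sex_code = "male")
  )
  em <- aggregate_occasions(recs, grid)
  spec <- cjs_model_spec("m1")
  n_occ <- 3
  params <- list(a0 = c(first_year = 0.2, adult_male = 0.5, adult_female = 0.5),
                 b0 = matrix(0.5, n_occ, 2))
  lp <- total_log_posterior(spec, params, em)
  # single known male, uniform priors contribute 0 on the log scale
  manual <- cjs_loglik(c(1, 0, 1), 1, rep(0.5, 3), rep(0.5, 3))
  expect_equal(as.numeric(lp), manual, tolerance = 1e-12)

  # empty dataset: prior-only density
  em0 <- em[0, ]
  attr(em0, "grid") <- grid
  class(em0) <- c("encounter_matrix", class(em0))
  expect_equal(as.numeric(total_log_posterior(spec, params, em0)), 0, tolerance = 1e-12)

  # out-of-support parameter is flagged by name
  bad <- params
  bad$a0[["adult_male"]] <- 1.4
  expect_error(total_log_posterior(spec, bad, em), "\\[0, 1\\]")
})

test_that("logit-scale and probability-scale densities agree through the Jacobian", {
  # density of a0 ~ Normal(0, 1.5) at a0 = 0 equals the density of
  # phi = plogis(a0) at 0.5 times |d phi / d a0| = 0.25
  d_logit <- dnorm(0, 0, 1.5)
  d_prob_scale <- d_logit / 0.25
  phi_vals <- plogis(rnorm(50000, 0, 1.5))
  dens <- density(phi_vals, from = 0.49, to = 0.51, n = 3)
  expect_equal(dens$y[2], d_prob_scale, tolerance = 0.05)
})

test_that("Beta prior quantiles are exact", {
  q <- beta_prior_quantiles(3.6, 1.2)
  expect_equal(q$quantile[q$prob == 0.5], qbeta(0.5, 3.6, 1.2), tolerance = 1e-12)
  expect_equal(round(q$quantile, 2), c(0.33, 0.79, 0.99))
  expect_equal(beta_prior_quantiles(1, 1, 0.5)$quantile, 0.5)
  expect_error(beta_prior_quantiles(3.6, 1.2, c(0, 0.5)), "strictly")
  expect_error(beta_prior_quantiles(-1, 1), "shape1 > 0")
})
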