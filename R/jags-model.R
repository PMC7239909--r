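# JAGS representation of the marginalized CJS mixture likelihood.
#
# The latent alive state is never sampled: each individual's marginal
# likelihood is computed inside the model (detection terms up to the last
# capture, chi recursion afterwards) and attached to the posterior via the
# zeros trick, `zeros ~ dpois(-loglik)`. Unknown-sex individuals contribute
# a two-component mixture with a per-individual Beta(1, 1) weight.

jags_model_code <- function(spec) {
  pr <- spec$priors
  lines <- c("model {")
  # survival intercepts
  if (spec$prob_scale) {
    prior <- if (spec$seasonal) {
      sprintf("aP[k] ~ dbeta(%g, %g)", pr$seasonal_phi_shape[1], pr$seasonal_phi_shape[2])
    } else {
      "aP[k] ~ dunif(0, 1)"
    }
    lines <- c(lines, sprintf("  for (k in 1:NI) { %s }", prior))
  } else {
    lines <- c(lines, sprintf("  for (k in 1:NI) { a0[k] ~ dnorm(0, %g) }", 1 / pr$sd_a0^2))
  }
  slope_names <- c(T_su = "a1", T_wi = "a2", Pr_su = "a3", Pr_wi = "a4")
  for (v in spec$covariates) {
    lines <- c(lines, sprintf("  for (k in 1:NS) { %s[k] ~ dnorm(0, %g) }",
                              slope_names[[v]], 1 / pr$sd_slope^2))
  }
  if (spec$random_year) {
    lines <- c(lines,
      "  for (s in 1:2) {",
      sprintf("    sigma_g[s] ~ dunif(0, %g)", pr$sigma_upper),
      "    tau_g[s] <- pow(sigma_g[s], -2)",
      "    for (t in 1:(nocc - 1)) { g[s, t] ~ dnorm(0, tau_g[s]) }",
      "  }")
  }
  # recapture probabilities
  if (spec$seasonal) {
    lines <- c(lines,
      sprintf("  for (ss in 1:3) { for (s in 1:2) { b0[ss, s] ~ dnorm(0, %g) } }",
              1 / pr$sd_b0_seasonal^2),
      sprintf("  sigma_p ~ dunif(0, %g)", pr$sigma_upper),
      "  tau_p <- pow(sigma_p, -2)",
      "  for (yy in 1:nyear) { gy[yy] ~ dnorm(0, tau_p) }",
      "  for (t in 2:nocc) { for (s in 1:2) {",
      "    logit(p[t, s]) <- b0[st[t], s] + gy[yidx[t]]",
      "  } }")
  } else {
    lines <- c(lines, "  for (t in 2:nocc) { for (s in 1:2) { p[t, s] ~ dunif(0, 1) } }")
  }
  # linear predictor for survival
  eta <- if (spec$prob_scale) {
    "        phi[i, t, s] <- aP[icls[i, t, s]]"
  } else {
    terms <- "a0[icls[i, t, s]]"
    for (v in spec$covariates) {
      terms <- paste0(terms, sprintf(" + %s[scls[i, t, s]] * %s[t]", slope_names[[v]], v))
    }
    if (spec$random_year) terms <- paste0(terms, " + g[s, t - 1]")
    paste0("        logit(phi[i, t, s]) <- ", terms)
  }
  lines <- c(lines,
    "  for (i in 1:ni) {",
    "    for (s in 1:2) {",
    "      for (t in (f[i] + 1):nocc) {",
    eta,
    "        lp[i, t, s] <- w[i, t] * (log(phi[i, t, s]) + y[i, t] * log(p[t, s]) +",
    "                       (1 - y[i, t]) * log(1 - p[t, s]))",
    "      }",
    "      chi[i, nocc, s] <- 1",
    "      for (j in 1:(nocc - f[i])) {",
    "        chi[i, nocc - j, s] <- (1 - phi[i, nocc - j + 1, s]) +",
    "          phi[i, nocc - j + 1, s] * (1 - p[nocc - j + 1, s]) * chi[i, nocc - j + 1, s]",
    "      }",
    "      ll[i, s] <- sum(lp[i, (f[i] + 1):nocc, s]) + log(chi[i, l[i], s])",
    "    }",
    "  }")
  lines <- c(lines,
    "  for (j in 1:nknown) {",
    "    zeros_k[j] ~ dpois(-ll[known[j], sexk[j]])",
    "  }")
  lines <- c(lines,
    "  for (k in 1:nunk) {",
    "    q[k] ~ dbeta(1, 1)",
    "    mixl[k] <- q[k] * exp(ll[unk[k], 1]) + (1 - q[k]) * exp(ll[unk[k], 2])",
    "    zeros_u[k] ~ dpois(-log(mixl[k]))",
    "  }")
  c(lines, "}")
}

# assemble the data list (informative individuals only: first capture before
# the final occasion)
jags_data <- function(spec, design, covs) {
  maps <- class_maps(design, spec)
  used <- which(design$first_occ < design$n_occ)
  if (!length(used)) stop("no informative capture histories (all first captures at the final occasion)")
  ni <- length(used)
  nocc <- design$n_occ
  y <- design$y[used, , drop = FALSE]
  f <- design$first_occ[used]
  l <- design$last_occ[used]
  w <- matrix(0, ni, nocc)
  for (i in seq_len(ni)) if (l[i] > f[i]) w[i, (f[i] + 1):l[i]] <- 1
  sex <- as.character(design$sex[used])
  known <- which(sex != "unknown")
  unk <- which(sex == "unknown")
  if (spec$dataset == "reduced" && length(unk)) {
    stop("reduced-dataset model but data contain unknown-sex individuals")
  }
  dat <- list(
    ni = ni, nocc = nocc, f = f, l = l, y = y, w = w,
    icls = maps$icls[used, , , drop = FALSE],
    NI = length(maps$intercept_levels),
    nknown = length(known), known = known,
    sexk = ifelse(sex[known] == "male", 1L, 2L),
    zeros_k = rep(0L, length(known)),
    nunk = length(unk), unk = unk,
    zeros_u = rep(0L, length(unk))
  )
  if (length(maps$slope_levels)) {
    dat$NS <- length(maps$slope_levels)
    dat$scls <- maps$scls[used, , , drop = FALSE]
    covmat <- interval_covariates(design, spec, covs)
    for (v in spec$covariates) {
      x <- covmat[, v]
      x[1] <- 0  # occasion 1 starts no interval
      dat[[v]] <- x
    }
  }
  if (spec$seasonal) {
    dat$st <- as.integer(design$grid$season)
    years <- sort(unique(design$grid$year))
    dat$yidx <- match(design$grid$year, years)
    dat$nyear <- length(years)
  }
  # drop empty blocks JAGS cannot loop over
  if (dat$nunk == 0L) { dat$unk <- NULL; dat$zeros_u <- NULL }
  if (dat$nknown == 0L) { dat$known <- NULL; dat$sexk <- NULL; dat$zeros_k <- NULL }
  list(data = dat, maps = maps, used = used,
       unknown_ids = design$ring_id[used][unk])
}

jags_monitors <- function(spec, dat) {
  mon <- if (spec$prob_scale) "aP" else "a0"
  slope_names <- c(T_su = "a1", T_wi = "a2", Pr_su = "a3", Pr_wi = "a4")
  mon <- c(mon, unname(slope_names[spec$covariates]))
  if (spec$random_year) mon <- c(mon, "sigma_g", "g")
  mon <- c(mon, "p")
  if (spec$seasonal) mon <- c(mon, "b0", "gy", "sigma_p")
  if (dat$nunk > 0L) mon <- c(mon, "q")
  mon
}

jags_inits <- function(spec, dat, chain_seed) {
  ini <- list(
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = chain_seed
  )
  if (spec$prob_scale) {
    ini$aP <- runif(dat$NI, 0.3, 0.7)
  } else {
    ini$a0 <- runif(dat$NI, -1, 1)
  }
  slope_names <- c(T_su = "a1", T_wi = "a2", Pr_su = "a3", Pr_wi = "a4")
  for (v in spec$covariates) ini[[slope_names[[v]]]] <- runif(dat$NS, -0.5, 0.5)
  if (spec$random_year) {
    ini$sigma_g <- runif(2, 0.5, 1.5)
    ini$g <- matrix(rnorm(2 * (dat$nocc - 1), 0, 0.1), 2, dat$nocc - 1)
  }
  if (spec$seasonal) {
    ini$b0 <- matrix(runif(6, -1, 1), 3, 2)
    ini$sigma_p <- runif(1, 0.5, 1.5)
  } else {
    p0 <- matrix(runif(dat$nocc * 2, 0.2, 0.6), dat$nocc, 2)
    p0[1, ] <- NA
    ini$p <- p0
  }
  if (dat$nunk > 0L) ini$q <- runif(dat$nunk, 0.3, 0.7)
  ini
}

# map raw JAGS names to labelled terms
parameter_map <- function(spec, dat, maps, design, unknown_ids) {
  grid <- design$grid
  sexes <- c("male", "female")
  rows <- list()
  add <- function(raw, label, block) {
    rows[[length(rows) + 1]] <<- tibble::tibble(raw = raw, label = label, block = block)
  }
  ilev <- maps$intercept_levels
  if (spec$prob_scale) {
    add(sprintf("aP[%d]", seq_along(ilev)), sprintf("phi[%s]", ilev), "a0")
  } else {
    add(sprintf("a0[%d]", seq_along(ilev)), sprintf("a0[%s]", ilev), "a0")
  }
  slope_names <- c(T_su = "a1", T_wi = "a2", Pr_su = "a3", Pr_wi = "a4")
  slev <- maps$slope_levels
  for (v in spec$covariates) {
    nm <- slope_names[[v]]
    add(sprintf("%s[%d]", nm, seq_along(slev)), sprintf("%s[%s]", nm, slev), nm)
  }
  if (spec$random_year) {
    add(sprintf("sigma_g[%d]", 1:2), sprintf("sigma[%s]", sexes), "sigma")
    for (s in 1:2) {
      # g[s, t - 1] is the year effect of the interval ending at occasion t
      add(sprintf("g[%d,%d]", s, seq_len(dat$nocc - 1)),
          sprintf("gamma[%s,%s]", sexes[s], grid$label[2:dat$nocc]), "gamma")
    }
  }
  for (s in 1:2) {
    add(sprintf("p[%d,%d]", 2:dat$nocc, s),
        sprintf("p[%s,%s]", grid$label[2:dat$nocc], sexes[s]), "p")
  }
  if (spec$seasonal) {
    for (s in 1:2) {
      add(sprintf("b0[%d,%d]", 1:3, s),
          sprintf("b0[%s,%s]", season_levels(), sexes[s]), "b0")
    }
    years <- sort(unique(grid$year))
    add(sprintf("gy[%d]", seq_along(years)), sprintf("gy[%d]", years), "gy")
    add("sigma_p", "sigma_p", "sigma_p")
  }
  if (dat$nunk > 0L) {
    add(sprintf("q[%d]", seq_len(dat$nunk)), sprintf("q[%s]", unknown_ids), "q")
  }
  dplyr::bind_rows(rows)
}
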