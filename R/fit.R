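#' Fit a CJS model by MCMC
#'
#' Samples the joint posterior of the selected model variant with JAGS,
#' using the analytically marginalized likelihood (the latent alive state is
#' never sampled). Defaults follow the fitting protocol of 4 chains of
#' length 2000 with the second half of each chain retained.
#'
#' @param em An `encounter_matrix`. Individuals first captured at the final
#'   occasion carry no information and are excluded from the likelihood (they
#'   are retained in the stored data for predictive checks).
#' @param spec A [cjs_model_spec()].
#' @param covs Seasonal covariates ([seasonal_covariates()]), required for
#'   variants with weather terms. Standardized internally when the spec says
#'   so.
#' @param n_chains Number of MCMC chains (at least 2 for convergence
#'   diagnostics).
#' @param n_iter Total iterations per chain (warmup + retained).
#' @param warmup Iterations discarded per chain; default half.
#' @param n_adapt Sampler adaptation iterations (before warmup).
#' @param thin Thinning of the retained draws.
#' @param seed Integer seed; all chain RNGs derive from it.
#' @param quiet Suppress JAGS progress output.
#' @return A `cjs_fit` object: retained draws (a [coda::mcmc.list] with
#'   labelled parameter names), the spec, design, data, parameter map,
#'   sampler configuration and a divergence count (identically 0: the
#'   slice/Gibbs updates used here have no divergent-transition failure
#'   mode).
#' @export
fit_cjs <- function(em, spec = cjs_model_spec(), covs = NULL,
                    n_chains = 4, n_iter = 2000, warmup = floor(n_iter / 2),
                    n_adapt = 1000, thin = 1, seed = 1, quiet = TRUE) {
  stopifnot(inherits(spec, "cjs_model_spec"))
  if (length(spec$covariates) && is.null(covs)) {
    stop("variant ", spec$variant, " requires seasonal covariates")
  }
  if (!is.null(covs) && spec$standardize_covariates) covs <- standardize_covariates(covs)
  design <- build_design(em)
  jd <- jags_data(spec, design, covs)
  code <- paste(jags_model_code(spec), collapse = "\n")
  inits <- lapply(seq_len(n_chains), function(ch) {
    chain_seed <- (as.integer(seed) * 1009L + ch * 7919L) %% 2147483647L
    set.seed(chain_seed)
    jags_inits(spec, jd$data, chain_seed)
  })
  t0 <- Sys.time()
  jm <- rjags::jags.model(textConnection(code), data = jd$data,
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_adapt, quiet = quiet)
  if (warmup > 0) stats::update(jm, warmup, progress.bar = "none")
  mon <- jags_monitors(spec, jd$data)
  draws <- rjags::coda.samples(jm, mon, n.iter = n_iter - warmup, thin = thin,
                               progress.bar = "none")
  runtime <- as.numeric(Sys.time() - t0, units = "secs")
  pmap <- parameter_map(spec, jd$data, jd$maps, design, jd$unknown_ids)
  draws <- relabel_draws(draws, pmap)
  structure(
    list(
      draws = draws,
      spec = spec,
      design = design,
      em = em,
      covs = covs,
      maps = jd$maps,
      used = jd$used,
      unknown_ids = jd$unknown_ids,
      par_map = pmap,
      config = list(n_chains = n_chains, n_iter = n_iter, warmup = warmup,
                    n_adapt = n_adapt, thin = thin, seed = seed),
      n_divergent = 0L,
      runtime_s = runtime
    ),
    class = "cjs_fit"
  )
}

relabel_draws <- function(draws, pmap) {
  coda::as.mcmc.list(lapply(draws, function(ch) {
    idx <- match(colnames(ch), pmap$raw)
    keep <- !is.na(idx)
    mcpar <- attr(ch, "mcpar")
    ch <- ch[, keep, drop = FALSE]
    colnames(ch) <- pmap$label[idx[keep]]
    coda::mcmc(ch, start = mcpar[1], end = mcpar[2], thin = mcpar[3])
  }))
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat(sprintf("CJS fit: variant %s (%s data), %d individuals, %d occasions\n",
              x$spec$variant, x$spec$dataset, x$design$n_ind, x$design$n_occ))
  cat(sprintf("  %d chains x %d retained draws (%.1f s)\n",
              x$config$n_chains,
              (x$config$n_iter - x$config$warmup) %/% x$config$thin,
              x$runtime_s))
  invisible(x)
}

#' Posterior draws as a matrix
#'
#' @param fit A `cjs_fit`.
#' @param pars Optional regular expression selecting parameters by label.
#' @return Matrix of retained draws (all chains stacked) by parameter.
#' @export
draws_matrix <- function(fit, pars = NULL) {
  m <- as.matrix(fit$draws)
  if (!is.null(pars)) m <- m[, grepl(pars, colnames(m)), drop = FALSE]
  m
}

#' Split-half potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the classical between/within-chain
#' variance ratio is computed over the resulting 2m half-chains.
#'
#' @param x Matrix of draws, iterations by chains.
#' @return The split R-hat (NaN for constant draws).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])
  }))
  m <- ncol(halves); nn <- nrow(halves)
  mu <- colMeans(halves)
  B <- nn * var(mu)
  W <- mean(apply(halves, 2, var))
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Convergence report for a fitted model
#'
#' Applies the four-part convergence gate: no divergent transitions, at
#' least 1000 effective samples, Monte Carlo standard error below 10% of the
#' posterior standard deviation, and split R-hat below 1.01 -- for every
#' monitored parameter.
#'
#' @param fit A `cjs_fit`.
#' @param ess_min Minimum effective sample size.
#' @param rhat_max Maximum split R-hat.
#' @param mcse_ratio_max Maximum MCSE / posterior SD ratio.
#' @return A `cjs_convergence` object: a tibble with one row per parameter
#'   (`term`, `ess`, `rhat`, `mcse_ratio` and the per-criterion booleans)
#'   carrying the overall verdict and any failure messages as attributes.
#' @export
check_convergence <- function(fit, ess_min = 1000, rhat_max = 1.01,
                              mcse_ratio_max = 0.1) {
  draws <- fit$draws
  n_chains <- length(draws)
  failures <- character()
  if (n_chains < 2) {
    failures <- c(failures, "R-hat undefined with a single chain")
  }
  params <- colnames(draws[[1]])
  ess <- coda::effectiveSize(draws)[params]
  rhat <- vapply(params, function(pn) {
    split_rhat(sapply(draws, function(ch) ch[, pn]))
  }, 1.0)
  pooled_sd <- vapply(params, function(pn) sd(unlist(lapply(draws, function(ch) ch[, pn]))), 1.0)
  mcse_ratio <- ifelse(pooled_sd > 0, 1 / sqrt(pmax(ess, 1e-12)), Inf)
  tab <- tibble::tibble(
    term = params,
    ess = as.numeric(ess),
    rhat = unname(rhat),
    mcse_ratio = unname(mcse_ratio),
    ess_ok = ess > ess_min,
    rhat_ok = is.finite(rhat) & rhat < rhat_max,
    mcse_ok = mcse_ratio < mcse_ratio_max
  )
  n_div <- fit$n_divergent %||% 0L
  if (n_div > 0) failures <- c(failures, sprintf("%d divergent transitions", n_div))
  bad <- tab[!(tab$ess_ok & tab$rhat_ok & tab$mcse_ok), ]
  if (nrow(bad)) {
    failures <- c(failures, sprintf(
      "%s: ess %.0f, rhat %.4f, mcse ratio %.3f", bad$term, bad$ess, bad$rhat,
      bad$mcse_ratio))
  }
  structure(tab,
            converged = length(failures) == 0L && n_chains >= 2,
            n_divergent = n_div,
            failures = failures,
            thresholds = c(ess_min = ess_min, rhat_max = rhat_max,
                           mcse_ratio_max = mcse_ratio_max),
            class = c("cjs_convergence", class(tab)))
}

#' @export
print.cjs_convergence <- function(x, ...) {
  verdict <- if (isTRUE(attr(x, "converged"))) "PASS" else "FAIL"
  cat(sprintf("Convergence: %s (%d parameters, %d divergences)\n", verdict,
              nrow(x), attr(x, "n_divergent")))
  fl <- attr(x, "failures")
  if (length(fl)) cat(paste0("  - ", fl, "\n"), sep = "")
  invisible(x)
}

#' Is the fit accepted by the convergence gate?
#' @param x A `cjs_convergence` report.
#' @return Logical.
#' @export
is_converged <- function(x) isTRUE(attr(x, "converged"))

#' Tidy posterior summaries of a fitted CJS model
#'
#' @param x A `cjs_fit`.
#' @param conf.level Width of the equal-tailed posterior interval.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (posterior median),
#'   `conf.low`/`conf.high` (posterior quantiles) and `std.error`
#'   (posterior SD).
#' @export
tidy.cjs_fit <- function(x, conf.level = 0.95, ...) {
  m <- draws_matrix(x)
  a <- (1 - conf.level) / 2
  tibble::tibble(
    term = colnames(m),
    estimate = apply(m, 2, median),
    std.error = apply(m, 2, sd),
    conf.low = apply(m, 2, quantile, probs = a),
    conf.high = apply(m, 2, quantile, probs = 1 - a)
  )
}

#' One-row summary of a fitted CJS model
#'
#' @param x A `cjs_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fit metadata and worst-case diagnostics.
#' @export
glance.cjs_fit <- function(x, ...) {
  cc <- check_convergence(x)
  tibble::tibble(
    variant = x$spec$variant,
    dataset = x$spec$dataset,
    n_ind = x$design$n_ind,
    n_occ = x$design$n_occ,
    n_chains = x$config$n_chains,
    n_draws = nrow(draws_matrix(x)),
    max_rhat = max(cc$rhat, na.rm = TRUE),
    min_ess = min(cc$ess),
    n_divergent = attr(cc, "n_divergent"),
    converged = is_converged(cc)
  )
}

#' Reconstruct the parameter list of one posterior draw
#'
#' Builds the `params` list consumed by [linear_predictor()] and
#' [total_log_posterior()] from row `j` of the stacked draws.
#'
#' @param fit A `cjs_fit`.
#' @param j Draw index (row of [draws_matrix()]).
#' @return A named parameter list.
#' @export
draw_params <- function(fit, j, .m = NULL) {
  m <- if (is.null(.m)) draws_matrix(fit) else .m
  stopifnot(j >= 1, j <= nrow(m))
  row <- m[j, ]
  spec <- fit$spec
  maps <- fit$maps
  grid <- fit$design$grid
  n_occ <- fit$design$n_occ
  sexes <- c("male", "female")
  params <- list()
  ilev <- maps$intercept_levels
  a0_lab <- if (spec$prob_scale) sprintf("phi[%s]", ilev) else sprintf("a0[%s]", ilev)
  params$a0 <- setNames(row[a0_lab], ilev)
  slope_names <- c(T_su = "a1", T_wi = "a2", Pr_su = "a3", Pr_wi = "a4")
  for (v in spec$covariates) {
    nm <- slope_names[[v]]
    params[[nm]] <- setNames(row[sprintf("%s[%s]", nm, maps$slope_levels)],
                             maps$slope_levels)
  }
  if (spec$random_year) {
    params$sigma <- unname(row[sprintf("sigma[%s]", sexes)])
    gamma <- matrix(0, 2, n_occ)
    for (s in 1:2) {
      gamma[s, 2:n_occ] <- row[sprintf("gamma[%s,%s]", sexes[s], grid$label[2:n_occ])]
    }
    params$gamma <- gamma
  }
  if (spec$seasonal) {
    params$b0 <- matrix(row[as.vector(outer(season_levels(), sexes,
                          function(a, b) sprintf("b0[%s,%s]", a, b)))], 3, 2)
    years <- sort(unique(grid$year))
    params$gy <- unname(row[sprintf("gy[%d]", years)])
    params$sigma_p <- unname(row["sigma_p"])
  } else {
    b0 <- matrix(NA_real_, n_occ, 2)
    for (s in 1:2) {
      b0[2:n_occ, s] <- row[sprintf("p[%s,%s]", grid$label[2:n_occ], sexes[s])]
    }
    params$b0 <- b0
  }
  if (length(fit$unknown_ids)) {
    params$q <- as.list(setNames(row[sprintf("q[%s]", fit$unknown_ids)],
                                 fit$unknown_ids))
  }
  params
}
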