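#' Marginal log-likelihood of one capture history
#'
#' Exact marginal probability of a detection history under the state-space
#' CJS model, conditioning on the first capture. The latent alive state is
#' marginalized analytically: the probability equals the product of survival
#' and detection terms up to the last detection, times the probability of
#' never being seen after it (the "chi" recursion
#' `chi[t] = (1 - phi[t+1]) + phi[t+1] (1 - p[t+1]) chi[t+1]`, `chi[T] = 1`).
#'
#' @param history 0/1 vector of detections over all occasions (must have a 1
#'   at `first`).
#' @param first Occasion of first capture.
#' @param phi Per-interval apparent survival; `phi[t]` is survival from
#'   occasion `t - 1` to `t`, used for `t > first`.
#' @param p Per-occasion recapture probability, used for `t > first`.
#' @return The log-likelihood (0 for an individual first captured at the
#'   final occasion, whose history carries no information).
#' @export
#' @examples
#' # detected, missed, detected: only the all-alive path is consistent
#' cjs_loglik(c(1, 0, 1), 1, phi = rep(0.5, 3), p = rep(0.5, 3))
#' log(0.5 * 0.5 * 0.5 * 0.5)
cjs_loglik <- function(history, first, phi, p) {
  n_occ <- length(history)
  stopifnot(length(phi) == n_occ, length(p) == n_occ, history[first] == 1)
  if (any(phi < 0 | phi > 1, na.rm = TRUE) || any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("phi and p must lie in [0, 1]")
  }
  if (first >= n_occ) return(0)
  last <- max(which(history == 1))
  chi <- chi_vector(phi, p, first)
  ll <- log(chi[last])
  if (last > first) {
    ts <- (first + 1):last
    ll <- ll + sum(log(phi[ts]) + ifelse(history[ts] == 1, log(p[ts]), log1p(-p[ts])))
  }
  ll
}

# chi[t] = P(never detected after t | alive at t), t = first..n_occ
chi_vector <- function(phi, p, first) {
  n_occ <- length(phi)
  chi <- rep(NA_real_, n_occ)
  chi[n_occ] <- 1
  if (n_occ > first) {
    for (t in (n_occ - 1):first) {
      chi[t] <- (1 - phi[t + 1]) + phi[t + 1] * (1 - p[t + 1]) * chi[t + 1]
    }
  }
  chi
}

#' Mixture log-likelihood for an individual of unknown sex
#'
#' `log(q_male * L_male + (1 - q_male) * L_female)`, where each component is
#' the marginal CJS likelihood under that sex's parameters. Known-sex
#' individuals bypass the mixture (set `q_male` to 0 or 1).
#'
#' @inheritParams cjs_loglik
#' @param phi_m,p_m,phi_f,p_f Per-interval survival/recapture under the male
#'   and female parameters.
#' @param q_male Probability that the individual is male, in `[0, 1]`.
#' @return The mixture log-likelihood.
#' @export
mixture_loglik <- function(history, first, phi_m, p_m, phi_f, p_f, q_male) {
  stopifnot(q_male >= 0, q_male <= 1)
  ll_m <- cjs_loglik(history, first, phi_m, p_m)
  ll_f <- cjs_loglik(history, first, phi_f, p_f)
  log_weighted_sum(c(log(q_male) + ll_m, log(1 - q_male) + ll_f))
}

# reorder a parameter vector by class-level names; unnamed vectors are taken
# to already follow the level order
in_level_order <- function(x, levels, what) {
  if (length(x) != length(levels)) {
    stop(sprintf("parameter %s has length %d, expected %d (%s)",
                 what, length(x), length(levels), paste(levels, collapse = ", ")))
  }
  if (is.null(names(x))) return(unname(x))
  if (!setequal(names(x), levels)) {
    stop(sprintf("parameter %s must be named by: %s", what,
                 paste(levels, collapse = ", ")))
  }
  unname(x[levels])
}

log_weighted_sum <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Survival and recapture probabilities under a model variant
#'
#' Evaluates the variant's linear predictor at one parameter set, for every
#' individual-interval and both candidate sexes (the mixture needs survival
#' under either sex for unknown-sex individuals).
#'
#' @param spec A [cjs_model_spec()].
#' @param params Named list of parameters: `a0` (intercepts, named by the
#'   variant's intercept classes; probability scale for `m1`/seasonal, logit
#'   otherwise), optional slopes `a1`--`a4` (named by slope class), `gamma`
#'   (2 x occasions matrix of year effects, rows male/female), `b0`
#'   (occasions x 2 recapture probabilities for annual variants; 3 x 2
#'   season-by-sex logit intercepts for the seasonal variant), `gy` (per-year
#'   recapture effects, seasonal variant).
#' @param design A [build_design()] result.
#' @param covs Seasonal covariates (needed for variants with weather terms).
#' @return A list: `phi` (array individuals x occasions x sex), `p` (matrix
#'   occasions x sex), and the class maps used.
#' @export
linear_predictor <- function(spec, params, design, covs = NULL, maps = NULL) {
  if (is.null(maps)) maps <- class_maps(design, spec)
  covmat <- interval_covariates(design, spec, covs)
  n_ind <- design$n_ind; n_occ <- design$n_occ
  phi <- array(NA_real_, c(n_ind, n_occ, 2))
  tbl <- design$tbl
  slope_names <- c(T_su = "a1", T_wi = "a2", Pr_su = "a3", Pr_wi = "a4")
  a0v <- in_level_order(params$a0, maps$intercept_levels, "a0")
  for (s in 1:2) {
    idx <- cbind(tbl$ind, tbl$interval)
    ic <- maps$icls[cbind(idx, rep(s, nrow(idx)))]
    if (spec$prob_scale) {
      val <- a0v[ic]
    } else {
      eta <- a0v[ic]
      for (v in spec$covariates) {
        slp <- in_level_order(params[[slope_names[[v]]]], maps$slope_levels,
                              slope_names[[v]])
        sc <- maps$scls[cbind(idx, rep(s, nrow(idx)))]
        eta <- eta + slp[sc] * covmat[tbl$interval, v]
      }
      if (spec$random_year) eta <- eta + params$gamma[s, tbl$interval]
      val <- plogis(eta)
    }
    phi[cbind(idx, rep(s, nrow(idx)))] <- val
  }
  p <- matrix(NA_real_, n_occ, 2)
  if (spec$seasonal) {
    yr_idx <- match(design$grid$year, sort(unique(design$grid$year)))
    for (s in 1:2) {
      p[-1, s] <- plogis(params$b0[as.integer(design$grid$season[-1]), s] +
                           params$gy[yr_idx[-1]])
    }
  } else {
    p[-1, ] <- params$b0[-1, , drop = FALSE]
  }
  list(phi = phi, p = p, maps = maps)
}

#' Joint log-posterior density of a model at one parameter set
#'
#' Sum of the per-individual marginal log-likelihoods (mixture components
#' for unknown-sex individuals) and the log prior densities. This is the
#' same density the MCMC engine samples from; it is exposed for diagnostics,
#' truth-ledger checks and tests.
#'
#' @inheritParams linear_predictor
#' @param em An `encounter_matrix`.
#' @param params As in [linear_predictor()], plus `sigma` (length-2 SD of the
#'   year effects, when used), `sigma_p` (seasonal), and `q` (per-individual
#'   male probabilities, named by `ring_id`, for unknown-sex individuals).
#' @return The scalar log-posterior. If non-finite, the attribute
#'   `"offending_terms"` names the component(s) responsible.
#' @export
total_log_posterior <- function(spec, params, em, covs = NULL) {
  design <- build_design(em)
  terms <- c(
    loglik = data_loglik(spec, params, design, covs),
    log_priors(spec, params, design)
  )
  out <- sum(terms)
  if (!is.finite(out)) {
    attr(out, "offending_terms") <- names(terms)[!is.finite(terms)]
  }
  out
}

data_loglik <- function(spec, params, design, covs) {
  if (design$n_ind == 0L) return(0)
  lp <- linear_predictor(spec, params, design, covs)
  ll <- 0
  for (i in seq_len(design$n_ind)) {
    h <- design$y[i, ]
    f <- design$first_occ[i]
    if (f >= design$n_occ) next
    sx <- as.character(design$sex[i])
    if (sx == "unknown") {
      q_i <- params$q[[design$ring_id[i]]]
      if (is.null(q_i)) stop("missing mixture weight q for ", design$ring_id[i])
      ll <- ll + mixture_loglik(h, f, lp$phi[i, , 1], lp$p[, 1],
                                lp$phi[i, , 2], lp$p[, 2], q_i)
    } else {
      s <- if (sx == "male") 1L else 2L
      ll <- ll + cjs_loglik(h, f, lp$phi[i, , s], lp$p[, s])
    }
  }
  ll
}

log_priors <- function(spec, params, design) {
  pr <- spec$priors
  out <- c()
  if (spec$prob_scale) {
    out["a0"] <- if (spec$seasonal) {
      sum(dbeta(params$a0, pr$seasonal_phi_shape[1], pr$seasonal_phi_shape[2], log = TRUE))
    } else {
      sum(dunif(params$a0, 0, 1, log = TRUE))
    }
  } else {
    out["a0"] <- sum(dnorm(params$a0, 0, pr$sd_a0, log = TRUE))
  }
  for (a in c("a1", "a2", "a3", "a4")) {
    if (!is.null(params[[a]])) {
      out[a] <- sum(dnorm(params[[a]], 0, pr$sd_slope, log = TRUE))
    }
  }
  if (spec$random_year) {
    out["sigma"] <- sum(dunif(params$sigma, 0, pr$sigma_upper, log = TRUE))
    out["gamma"] <- sum(dnorm(params$gamma[1, -1], 0, params$sigma[1], log = TRUE)) +
      sum(dnorm(params$gamma[2, -1], 0, params$sigma[2], log = TRUE))
  }
  if (spec$seasonal) {
    out["b0"] <- sum(dnorm(params$b0, 0, pr$sd_b0_seasonal, log = TRUE))
    out["sigma_p"] <- dunif(params$sigma_p, 0, pr$sigma_upper, log = TRUE)
    out["gy"] <- sum(dnorm(params$gy, 0, params$sigma_p, log = TRUE))
  } else {
    out["b0"] <- sum(dunif(params$b0[-1, ], 0, 1, log = TRUE))
  }
  if (!is.null(params$q) && length(params$q)) {
    out["q"] <- sum(dbeta(unlist(params$q), 1, 1, log = TRUE))
  }
  out
}

#' Quantiles of a Beta prior
#'
#' @param shape1,shape2 Positive Beta shape parameters.
#' @param probs Probabilities in (0, 1); defaults to the median and the
#'   equal-tailed 95% interval.
#' @return A tibble with columns `prob` and `quantile`.
#' @export
#' @examples
#' beta_prior_quantiles(3.6, 1.2)
beta_prior_quantiles <- function(shape1, shape2, probs = c(0.025, 0.5, 0.975)) {
  stopifnot(shape1 > 0, shape2 > 0)
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie strictly in (0, 1)")
  tibble::tibble(prob = probs, quantile = qbeta(probs, shape1, shape2))
}
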