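#' Posterior summaries: median and 95% compatibility interval
#'
#' Summarises draws by the posterior median and the 2.5% / 97.5% quantiles
#' (the equal-tailed 95% compatibility interval). Quantiles use the type-7
#' interpolation convention throughout the package.
#'
#' @param x A `cjs_fit`, a draws matrix (columns = parameters), or a numeric
#'   vector of draws.
#' @param pars Optional regular expression selecting parameters (fit/matrix
#'   input).
#' @param level Interval mass (default 0.95).
#' @return A tibble with columns `term`, `median`, `lower`, `upper`.
#' @export
summarize_draws <- function(x, pars = NULL, level = 0.95) {
  m <- if (inherits(x, "cjs_fit")) {
    draws_matrix(x, pars)
  } else if (is.matrix(x)) {
    if (!is.null(pars)) x[, grepl(pars, colnames(x)), drop = FALSE] else x
  } else {
    matrix(x, ncol = 1, dimnames = list(NULL, "value"))
  }
  if (ncol(m) == 0) {
    stop("no parameters match; available: ",
         paste(utils::head(colnames(draws_matrix(x)), 30), collapse = ", "))
  }
  a <- (1 - level) / 2
  tibble::tibble(
    term = colnames(m) %||% paste0("V", seq_len(ncol(m))),
    median = unname(apply(m, 2, median)),
    lower = unname(apply(m, 2, quantile, probs = a, type = 7)),
    upper = unname(apply(m, 2, quantile, probs = 1 - a, type = 7))
  )
}

#' Class-level apparent survival at average conditions
#'
#' Posterior survival per age/sex (and first/later, or season) class with
#' covariates held at their across-year mean (zero on the standardized
#' scale) and year effects at zero -- the layout used to report survival per
#' model and dataset.
#'
#' @param fit A `cjs_fit`.
#' @return A `cjs_survival_table` tibble: `class`, `median`, `lower`,
#'   `upper`, plus the model/dataset labels.
#' @export
survival_table <- function(fit) {
  ilev <- fit$maps$intercept_levels
  labs <- if (fit$spec$prob_scale) sprintf("phi[%s]", ilev) else sprintf("a0[%s]", ilev)
  m <- draws_matrix(fit)[, labs, drop = FALSE]
  if (!fit$spec$prob_scale) m <- plogis(m)
  out <- summarize_draws(m) |>
    dplyr::mutate(class = ilev, variant = fit$spec$variant,
                  dataset = fit$spec$dataset, .before = 1) |>
    dplyr::select(!"term")
  class(out) <- c("cjs_survival_table", class(out))
  out
}

#' Plot class-level survival estimates
#' @param object A `cjs_survival_table`.
#' @param ... Unused.
#' @return A ggplot of posterior medians with 95% intervals.
#' @export
autoplot.cjs_survival_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$class, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "apparent survival",
                  title = sprintf("Apparent survival (%s, %s data)",
                                  object$variant[1], object$dataset[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Annualize 4-month seasonal survival
#'
#' Annual survival is the product of the three seasonal (4-month) survivals;
#' for a constant seasonal survival `s` it is `s^3`. Applied per draw when
#' given draws, so the interval of the annual value is the interval of the
#' per-draw product.
#'
#' @param phi_seasons Either a length-3 numeric vector (one survival per
#'   season) or a draws matrix with 3 columns.
#' @return A scalar (vector input) or a vector of per-draw annual survivals.
#' @export
#' @examples
#' annualize_seasonal(rep(0.79, 3)) # ~0.49
annualize_seasonal <- function(phi_seasons) {
  if (is.matrix(phi_seasons)) {
    if (ncol(phi_seasons) != 3) stop("need 3 seasonal survivals per draw")
    check_unit_interval(phi_seasons)
    return(apply(phi_seasons, 1, prod))
  }
  if (length(phi_seasons) != 3) stop("need exactly 3 seasonal survivals")
  check_unit_interval(phi_seasons)
  prod(phi_seasons)
}

check_unit_interval <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("survival probabilities must lie in [0, 1]")
  invisible(x)
}

#' Cumulative survival across consecutive segments
#'
#' Running product of per-segment survival, e.g. the proportion of
#' first-year birds ringed during breeding still alive and present by their
#' first winter. Given a draws matrix the product is taken per draw, so
#' posterior intervals of the cumulative proportion are intervals of the
#' per-draw product (never products of interval endpoints).
#'
#' @param phi_segments Numeric vector of ordered segment survivals, or a
#'   draws matrix (draws by segments).
#' @return Running product: a vector (same length as the input) or a draws
#'   matrix of running products.
#' @export
cumulative_survival <- function(phi_segments) {
  check_unit_interval(phi_segments)
  if (is.matrix(phi_segments)) {
    t(apply(phi_segments, 1, cumprod))
  } else {
    cumprod(phi_segments)
  }
}

#' Posterior probability of an ordering hypothesis
#'
#' Mean of the per-draw indicator of `relation(a, b)` over paired draws from
#' one joint posterior -- e.g. the probability that the female summer
#' temperature slope is more negative than the male one.
#'
#' @param draws_a,draws_b Paired numeric draw vectors (same joint posterior,
#'   same length).
#' @param relation Vectorized comparison, default `<`.
#' @return The posterior probability of the relation.
#' @export
#' @examples
#' hypothesis_probability(c(0, 0, 1), c(1, 1, 0)) # 2/3
hypothesis_probability <- function(draws_a, draws_b, relation = `<`) {
  if (length(draws_a) != length(draws_b)) {
    stop("draws must be paired: lengths differ (", length(draws_a), " vs ",
         length(draws_b), ")")
  }
  mean(relation(draws_a, draws_b))
}

#' Survival vs covariate regression bands
#'
#' Posterior median and 95% band of inverse-logit predicted survival along a
#' covariate grid, per class (and first/later level where the model splits
#' them), with the other covariates at their mean and year effects at zero.
#'
#' @param fit A `cjs_fit` of a variant including `covariate`.
#' @param covariate One of the fitted weather covariates (default the first).
#' @param grid_x Covariate grid on the model's scale (standardized if the
#'   spec standardizes); defaults to 50 points over the observed range.
#'   Values beyond the observed covariate range are flagged with a warning.
#' @return A `cjs_effect_curves` tibble: `class`, `x`, `median`, `lower`,
#'   `upper`.
#' @export
effect_curves <- function(fit, covariate = fit$spec$covariates[1], grid_x = NULL) {
  spec <- fit$spec
  if (!length(spec$covariates) || !covariate %in% spec$covariates) {
    stop("variant ", spec$variant, " does not include covariate ", covariate)
  }
  design_cov <- interval_covariates(fit$design, spec, fit$covs)[-1, covariate]
  rng <- range(design_cov)
  if (is.null(grid_x)) {
    grid_x <- seq(rng[1], rng[2], length.out = 50)
  } else if (any(grid_x < rng[1] | grid_x > rng[2])) {
    warning("grid extends beyond the observed covariate range (",
            sprintf("%.2f..%.2f", rng[1], rng[2]), "): extrapolation")
  }
  slope_names <- c(T_su = "a1", T_wi = "a2", Pr_su = "a3", Pr_wi = "a4")
  nm <- slope_names[[covariate]]
  m <- draws_matrix(fit)
  ilev <- fit$maps$intercept_levels
  out <- purrr::map_dfr(ilev, function(lab) {
    slab <- if (lab %in% fit$maps$slope_levels) lab else sub("_(first|later)$", "", lab)
    eta0 <- m[, sprintf("a0[%s]", lab)]
    slope <- m[, sprintf("%s[%s]", nm, slab)]
    purrr::map_dfr(grid_x, function(xv) {
      sv <- plogis(eta0 + slope * xv)
      tibble::tibble(class = lab, x = xv,
                     median = median(sv),
                     lower = quantile(sv, 0.025),
                     upper = quantile(sv, 0.975))
    })
  })
  attr(out, "covariate") <- covariate
  class(out) <- c("cjs_effect_curves", class(out))
  out
}

#' Plot survival-vs-covariate regression bands
#' @param object A `cjs_effect_curves`.
#' @param ... Unused.
#' @return A ggplot with posterior median lines and 95% ribbons per class.
#' @export
autoplot.cjs_effect_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$class)) +
    ggplot2::labs(x = attr(object, "covariate"), y = "apparent survival",
                  title = "Apparent survival vs covariate (posterior band)") +
    ggplot2::theme_minimal()
}
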