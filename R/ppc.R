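#' Simulate one replicate dataset from a posterior draw
#'
#' Conditions on each individual's observed first capture occasion and class,
#' then simulates the latent alive state and detections forward under the
#' survival and recapture probabilities of one posterior draw. Unknown-sex
#' individuals have their sex drawn from that draw's mixture weight `q_i`.
#'
#' @param fit A `cjs_fit`.
#' @param draw Draw index into [draws_matrix()].
#' @return A replicate `encounter_matrix` with the same individuals,
#'   first-capture occasions and grid as the observed data.
#' @export
simulate_replicate <- function(fit, draw) {
  params <- draw_params(fit, draw)
  y <- replicate_y(fit, params)
  replicate_em(fit, y)
}

# forward simulation of y given one parameter list; vectorized over individuals
replicate_y <- function(fit, params) {
  design <- fit$design
  n_ind <- design$n_ind; n_occ <- design$n_occ
  lp <- linear_predictor(fit$spec, params, design, fit$covs, maps = fit$maps)
  sex_i <- as.character(design$sex)
  s_idx <- ifelse(sex_i == "male", 1L, ifelse(sex_i == "female", 2L, NA_integer_))
  if (anyNA(s_idx)) {
    unk <- which(is.na(s_idx))
    q <- vapply(design$ring_id[unk], function(id) {
      qv <- params$q[[id]]
      if (is.null(qv)) 0.5 else qv  # uninformative individuals keep prior weight
    }, 1.0)
    s_idx[unk] <- ifelse(runif(length(unk)) < q, 1L, 2L)
  }
  y <- matrix(0L, n_ind, n_occ)
  y[cbind(seq_len(n_ind), design$first_occ)] <- 1L
  entered <- design$first_occ
  alive <- rep(TRUE, n_ind)
  for (t in 2:n_occ) {
    at_risk <- entered < t
    phi_t <- lp$phi[cbind(seq_len(n_ind), t, s_idx)]
    surv <- runif(n_ind) < phi_t
    alive <- ifelse(at_risk, alive & surv, alive)
    p_t <- lp$p[t, ][s_idx]
    det <- at_risk & alive & (runif(n_ind) < p_t)
    y[det, t] <- 1L
  }
  y
}

replicate_em <- function(fit, y) {
  em <- fit$em
  ch <- apply(y, 1, paste, collapse = "")
  out <- tibble::tibble(
    ring_id = em$ring_id,
    ch = ch,
    first_occ = em$first_occ,
    n_captures = as.integer(rowSums(y)),
    age_at_first = em$age_at_first,
    sex = em$sex
  )
  new_encounter_matrix(out, occasions(em))
}

ppc_groups <- function(em, split_by_sex_known) {
  groups <- list(all = rep(TRUE, nrow(em)))
  if (split_by_sex_known && any(em$sex == "unknown")) {
    groups$sex_known <- em$sex != "unknown"
    groups$sex_unknown <- em$sex == "unknown"
  }
  groups
}

stat_row <- function(n_captures, sel, group) {
  tibble::tibble(
    group = group,
    statistic = c("n_once", "n_ge3"),
    value = c(sum(n_captures[sel] == 1L), sum(n_captures[sel] >= 3L))
  )
}

#' Posterior-predictive check on capture-frequency statistics
#'
#' Simulates replicate capture histories from distinct posterior draws and
#' compares two statistics -- the number of individuals captured exactly once
#' and the number captured at least three times -- between the replicates and
#' the observed data. For full-dataset fits the statistics are also split by
#' whether sex is known.
#'
#' `p_tail` is the one-sided predictive tail probability
#' `P(replicate >= observed)` with ties counted half (0.5 when all
#' replicates equal the observed value); `p_two_sided = 2 * min(P(rep <=
#' obs), P(rep >= obs))`, capped at 1. `adequate` flags an observed value
#' inside the central 95% predictive interval.
#'
#' @param fit A `cjs_fit`.
#' @param n_rep Number of replicate datasets (distinct posterior draws,
#'   evenly spaced through the retained draws).
#' @param seed Seed for the replicate simulations.
#' @return A `cjs_ppc` object: list with `stats` (one row per group and
#'   statistic) and `replicates` (long tibble of replicate values).
#' @export
ppc_check <- function(fit, n_rep = 1000, seed = 1) {
  m <- draws_matrix(fit)
  if (n_rep > nrow(m)) {
    stop(sprintf("n_rep = %d exceeds the %d retained draws", n_rep, nrow(m)))
  }
  if (n_rep < 100) warning("fewer than 100 replicates: predictive intervals will be coarse")
  draws_idx <- unique(round(seq(1, nrow(m), length.out = n_rep)))
  groups <- ppc_groups(fit$em, split_by_sex_known = fit$spec$dataset == "full")
  set.seed(seed)
  rep_stats <- purrr::map_dfr(seq_along(draws_idx), function(r) {
    params <- draw_params(fit, draws_idx[r], .m = m)
    y <- replicate_y(fit, params)
    nc <- as.integer(rowSums(y))
    purrr::imap_dfr(groups, function(sel, g) stat_row(nc, sel, g)) |>
      dplyr::mutate(rep = r)
  })
  obs <- purrr::imap_dfr(groups, function(sel, g) stat_row(fit$em$n_captures, sel, g)) |>
    dplyr::rename(observed = "value")
  structure(list(stats = ppc_summarise(rep_stats, obs), replicates = rep_stats,
                 n_rep = length(draws_idx)),
            class = "cjs_ppc")
}

ppc_summarise <- function(rep_stats, obs) {
  rep_stats |>
    dplyr::group_by(.data$group, .data$statistic) |>
    dplyr::summarise(
      rep_mean = mean(.data$value),
      rep_lower = quantile(.data$value, 0.025),
      rep_upper = quantile(.data$value, 0.975),
      values = list(.data$value),
      .groups = "drop"
    ) |>
    dplyr::left_join(obs, by = c("group", "statistic")) |>
    dplyr::mutate(
      p_tail = purrr::map2_dbl(.data$values, .data$observed, tail_prob_ge),
      p_two_sided = purrr::map2_dbl(.data$values, .data$observed, two_sided_prob),
      adequate = .data$observed >= .data$rep_lower & .data$observed <= .data$rep_upper
    ) |>
    dplyr::select(!"values")
}

tail_prob_ge <- function(rep_values, observed) {
  (sum(rep_values > observed) + 0.5 * sum(rep_values == observed)) / length(rep_values)
}

two_sided_prob <- function(rep_values, observed) {
  p_ge <- tail_prob_ge(rep_values, observed)
  min(1, 2 * min(p_ge, 1 - p_ge))
}

#' @export
print.cjs_ppc <- function(x, ...) {
  cat(sprintf("Posterior-predictive check (%d replicates)\n", x$n_rep))
  print(x$stats)
  invisible(x)
}

#' Plot a posterior-predictive check
#'
#' @param object A `cjs_ppc`.
#' @param ... Unused.
#' @return A ggplot: replicate distributions with the observed value marked.
#' @export
autoplot.cjs_ppc <- function(object, ...) {
  obs <- object$stats
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$observed),
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group, .data$statistic), scales = "free") +
    ggplot2::labs(x = "capture-frequency statistic (replicates)", y = "count",
                  title = "Posterior-predictive check",
                  subtitle = "vertical line: observed value") +
    ggplot2::theme_minimal()
}

#' Capture-frequency PPC statistics from explicit replicate datasets
#'
#' Lower-level interface: computes the predictive summaries from a list of
#' replicate encounter matrices (e.g. produced by [simulate_replicate()]).
#'
#' @param replicates List of replicate `encounter_matrix` objects.
#' @param em The observed `encounter_matrix`.
#' @param split_by_sex_known Split statistics by sex-known vs sex-unknown.
#' @return A `cjs_ppc` object.
#' @export
ppc_statistics <- function(replicates, em, split_by_sex_known = TRUE) {
  if (length(replicates) < 100) warning("fewer than 100 replicates: predictive intervals will be coarse")
  groups <- ppc_groups(em, split_by_sex_known)
  rep_stats <- purrr::map_dfr(seq_along(replicates), function(r) {
    nc <- replicates[[r]]$n_captures
    purrr::imap_dfr(groups, function(sel, g) stat_row(nc, sel, g)) |>
      dplyr::mutate(rep = r)
  })
  obs <- purrr::imap_dfr(groups, function(sel, g) stat_row(em$n_captures, sel, g)) |>
    dplyr::rename(observed = "value")
  structure(list(stats = ppc_summarise(rep_stats, obs), replicates = rep_stats,
                 n_rep = length(replicates)),
            class = "cjs_ppc")
}
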