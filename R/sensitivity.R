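# Deterministic (one-way / tornado) and probabilistic (Monte Carlo)
# sensitivity analysis, with CEAC and CE-plane summaries.

.incremental_outcome <- function(params, instrument, settings) {
  traces <- compare_arms(params, instrument, settings)
  dc <- traces$CABG$total_cost - traces$PCI$total_cost
  dq <- traces$CABG$total_qaly - traces$PCI$total_qaly
  ic <- icer(dc, dq)
  list(delta_cost = dc, delta_qaly = dq,
       inmb = nmb(settings$wtp, dq, dc),
       verdict = threshold_verdict(ic$value, ic$flag,
                                   settings$gdp_per_capita))
}

#' One-way deterministic sensitivity analysis for a single parameter
#'
#' Re-runs both arms with the chosen parameter set to its low and then its
#' high value, everything else at base case, and records the incremental
#' net monetary benefit (CABG minus PCI, at the settings' reference WTP) at
#' each endpoint. Transition-row renormalization is reapplied after each
#' perturbation, and probability endpoints are clamped to `[0, 1]`.
#'
#' @param params A `cea_parameters` object.
#' @param param_id Entry id (see `param_values(params)` for the id set).
#' @param low,high Endpoint values; default to the entry's own range.
#' @param instrument `"SAQ"` or `"SF36"`.
#' @param settings A [cea_settings()] list.
#' @return One-row data frame: `param`, `low`, `high`, `inmb_low`,
#'   `inmb_high`, `swing` (absolute difference of the endpoint outcomes),
#'   `verdict_low`, `verdict_high`.
#' @export
one_way <- function(params, param_id, low = NULL, high = NULL,
                    instrument = CEA_INSTRUMENTS,
                    settings = cea_settings()) {
  instrument <- match.arg(instrument)
  if (!param_id %in% params$entries$id)
    stop("unknown parameter id: ", param_id)
  entry <- params$entries[param_id, ]
  if (is.null(low)) low <- entry$low
  if (is.null(high)) high <- entry$high
  if (low > high) stop("`low` must not exceed `high`")
  at <- function(value) {
    .incremental_outcome(set_param(params, param_id, value), instrument,
                         settings)
  }
  o_low <- at(low); o_high <- at(high)
  data.frame(param = param_id, low = low, high = high,
             inmb_low = o_low$inmb, inmb_high = o_high$inmb,
             swing = abs(o_high$inmb - o_low$inmb),
             verdict_low = o_low$verdict, verdict_high = o_high$verdict,
             row.names = NULL)
}

#' Tornado analysis over every ranged parameter
#'
#' Runs [one_way()] for each parameter whose range has positive width and
#' sorts the entries by outcome swing, largest first — the ordering of a
#' tornado diagram.
#'
#' @inheritParams one_way
#' @return Data frame of one-way rows sorted descending by `swing`, with an
#'   `inmb_base` attribute carrying the base-case incremental NMB.
#' @export
tornado <- function(params, instrument = CEA_INSTRUMENTS,
                    settings = cea_settings()) {
  instrument <- match.arg(instrument)
  ranged <- params$entries$id[params$entries$high > params$entries$low]
  rows <- lapply(ranged, function(id) one_way(params, id,
                                              instrument = instrument,
                                              settings = settings))
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  attr(out, "inmb_base") <-
    .incremental_outcome(params, instrument, settings)$inmb
  out
}

# deterministic per-trial seed, independent of trial count; kept < 2^31
.trial_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Probabilistic sensitivity analysis by Monte Carlo
#'
#' Per trial, every ranged parameter is drawn from its fitted distribution
#' (gamma for costs, beta for probabilities and utilities; see
#' [fit_distribution()]), transition rows are renormalized, both arms are
#' run, and the incremental cost and QALY of CABG over PCI are recorded.
#' Each trial uses its own seed derived deterministically from `seed` and
#' the trial index, so trial `i` is reproducible regardless of `n_trials`.
#'
#' @param params A `cea_parameters` object.
#' @param n_trials Number of Monte Carlo trials (>= 1; 5000 is the
#'   conventional choice).
#' @param seed Integer RNG seed.
#' @param instrument `"SAQ"` or `"SF36"`.
#' @param settings A [cea_settings()] list.
#' @param keep_draws Logical; retain the matrix of sampled parameter values
#'   (one row per trial)?
#' @return A list of class `cea_psa`: `trials` data frame (`trial`,
#'   `delta_cost`, `delta_qaly`), `n_trials`, `seed`, `instrument`,
#'   `settings`, and optionally `draws`.
#' @export
run_psa <- function(params, n_trials = 5000, seed = 1,
                    instrument = CEA_INSTRUMENTS,
                    settings = cea_settings(), keep_draws = FALSE) {
  instrument <- match.arg(instrument)
  if (n_trials < 1) stop("`n_trials` must be at least 1")
  entries <- params$entries
  ranged <- entries$id[entries$high > entries$low]
  dists <- lapply(ranged, function(id) {
    tryCatch(fit_distribution(as.list(entries[id, ])),
             error = function(e) stop("parameter '", id, "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(dists) <- ranged
  dc <- dq <- numeric(n_trials)
  draws <- if (keep_draws)
    matrix(NA_real_, n_trials, length(ranged),
           dimnames = list(NULL, ranged)) else NULL
  for (i in seq_len(n_trials)) {
    set.seed(.trial_seed(seed, i))
    p_i <- params
    vals <- vapply(dists, sample_dist, numeric(1), n = 1)
    p_i$entries[ranged, "mean"] <-
      ifelse(p_i$entries[ranged, "kind"] == "probability",
             pmin(pmax(vals, 0), 1), vals)
    if (keep_draws) draws[i, ] <- p_i$entries[ranged, "mean"]
    out <- .incremental_outcome(p_i, instrument, settings)
    dc[i] <- out$delta_cost
    dq[i] <- out$delta_qaly
  }
  structure(list(trials = data.frame(trial = seq_len(n_trials),
                                     delta_cost = dc, delta_qaly = dq),
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 instrument = instrument, settings = settings,
                 draws = draws),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("PSA: %d trials, seed %d, %s utilities\n",
              x$n_trials, x$seed, x$instrument))
  cat(sprintf("  mean dCost %.1f USD, mean dQALY %.4f; acceptance at WTP %.0f: %.1f%%\n",
              mean(x$trials$delta_cost), mean(x$trials$delta_qaly),
              x$settings$wtp,
              100 * acceptance_fraction(x, x$settings$wtp)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that CABG is
#' cost-effective is the fraction of PSA trials with positive incremental
#' net monetary benefit, `wtp * dQALY - dCost > 0`.
#'
#' @param psa A `cea_psa` from [run_psa()].
#' @param wtp_grid Strictly increasing grid of WTP values (USD/QALY);
#'   default 0 to 100,000 by 1,000.
#' @return Data frame of class `cea_ceac` with columns `wtp`,
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(inherits(psa, "cea_psa"))
  if (length(wtp_grid) == 0) stop("`wtp_grid` must be non-empty")
  if (any(diff(wtp_grid) <= 0)) stop("`wtp_grid` must be strictly increasing")
  prob <- vapply(wtp_grid, function(w) acceptance_fraction(psa, w),
                 numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("cea_ceac", "data.frame"))
}

#' Fraction of PSA trials in the acceptance region
#'
#' The acceptance region of the cost-effectiveness plane is operationalized
#' as positive incremental NMB at the given WTP — the half-plane below the
#' WTP ray, covering both the dominant (south-east) quadrant and the
#' below-threshold part of the north-east quadrant.
#'
#' @param psa A `cea_psa`.
#' @param wtp Willingness to pay per QALY, USD (default 3 x 8329).
#' @return Fraction in `[0, 1]`.
#' @export
acceptance_fraction <- function(psa, wtp = 3 * 8329) {
  stopifnot(inherits(psa, "cea_psa"))
  mean(nmb(wtp, psa$trials$delta_qaly, psa$trials$delta_cost) > 0)
}

# ---- plots ---------------------------------------------------------------

#' Cost-effectiveness plane scatter of PSA trials
#'
#' @param psa A `cea_psa`.
#' @param wtp WTP threshold drawn as a ray through the origin.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = 3 * 8329) {
  df <- psa$trials
  df$accepted <- nmb(wtp, df$delta_qaly, df$delta_cost) > 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_qaly,
                                   y = .data$delta_cost,
                                   colour = .data$accepted)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs (CABG - PCI)",
                  y = "Incremental cost, USD (CABG - PCI)",
                  colour = sprintf("iNMB > 0 at %.0f", wtp)) +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A `cea_ceac` from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay, USD/QALY",
                  y = "P(CABG cost-effective)") +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' @param tornado_df Output of [tornado()].
#' @param top Number of widest bars to show (default 15).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado_df, top = 15) {
  df <- utils::head(tornado_df, top)
  df$param <- factor(df$param, levels = rev(df$param))
  base <- attr(tornado_df, "inmb_base") %||% 0
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$inmb_low,
                                       xend = .data$inmb_high,
                                       y = .data$param, yend = .data$param),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "Incremental NMB, USD (CABG - PCI)", y = NULL) +
    ggplot2::theme_minimal()
}
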