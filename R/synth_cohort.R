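# Synthetic patient-cohort generator: demographics, length of stay, billing
# categories, and pre/post questionnaire scores with the marginal structure
# of the observed study arms, so costing and effectiveness run end-to-end
# without hospital records.

#' Specification of a synthetic study cohort
#'
#' Defaults mirror the observed study arms: 210 CABG / 200 PCI patients;
#' age 60.23 +/- 12.53 vs 58.65 +/- 11.19 years; length of stay
#' 8.05 +/- 5.438 vs 3.19 +/- 2.843 days; per-capita billing targets
#' (hospitalization, medication, travel/hotel) from the observed cost
#' ledgers; and post-minus-pre utility-gain targets per instrument equal to
#' the stable-state per-cycle utilities of each arm. Lost productivity is
#' never a target: it is derived from length of stay through
#' [lost_productivity()].
#'
#' @param n Patients per arm, named `c(CABG = , PCI = )`.
#' @param age_mean,age_sd Age distribution per arm, years.
#' @param los_mean,los_sd Length-of-stay distribution per arm, days.
#' @param bills Per-capita billing targets, USD: a named list per arm with
#'   `hospitalization`, `medication`, `travel_hotel`.
#' @param utility_gain Post-minus-pre utility targets: a named list per
#'   instrument (`SAQ`, `SF36`), each `c(CABG = , PCI = )`.
#' @param female_prop Proportion of female patients per arm (descriptive
#'   payload only).
#' @param pre_score_mean Target pre-intervention summary score, 0-100.
#' @param score_sigma Logit-scale spread of dimension scores (0 gives
#'   degenerate, identical scores).
#' @param bill_cv Coefficient of variation of the gamma billing draws
#'   (0 gives every patient the target exactly).
#' @return A list of class `cea_cohort_spec`.
#' @export
cohort_spec <- function(
    n = c(CABG = 210, PCI = 200),
    age_mean = c(CABG = 60.23, PCI = 58.65),
    age_sd = c(CABG = 12.53, PCI = 11.19),
    los_mean = c(CABG = 8.05, PCI = 3.19),
    los_sd = c(CABG = 5.438, PCI = 2.843),
    bills = list(
      CABG = c(hospitalization = 67567.1 / 210, medication = 7340.18 / 210,
               travel_hotel = 6967.82 / 210),
      PCI = c(hospitalization = 49660.97 / 200, medication = 11588.01 / 200,
              travel_hotel = 2520.12 / 200)),
    utility_gain = list(SAQ = c(CABG = 0.135, PCI = 0.063),
                        SF36 = c(CABG = 0.100, PCI = 0.063)),
    female_prop = c(CABG = 0.365, PCI = 0.374),
    pre_score_mean = 50, score_sigma = 0.5, bill_cv = 0.5) {
  for (arm in CEA_ARMS) {
    if (n[[arm]] < 1) stop("need at least one patient per arm")
    if (age_sd[[arm]] < 0 || los_sd[[arm]] < 0)
      stop("standard deviations must be non-negative")
    if (los_mean[[arm]] <= 0)
      stop("length-of-stay mean must be positive")
    if (los_sd[[arm]] > 0 && los_mean[[arm]] == 0)
      stop("cannot request positive spread around a zero mean")
    if (any(bills[[arm]] < 0)) stop("billing targets must be non-negative")
  }
  if (pre_score_mean < 0 || pre_score_mean > 100)
    stop("pre-intervention score target must lie in [0, 100]")
  structure(list(n = n, age_mean = age_mean, age_sd = age_sd,
                 los_mean = los_mean, los_sd = los_sd, bills = bills,
                 utility_gain = utility_gain, female_prop = female_prop,
                 pre_score_mean = pre_score_mean,
                 score_sigma = score_sigma, bill_cv = bill_cv),
            class = "cea_cohort_spec")
}

# mean of a gamma(shape a, rate r) truncated to x >= c
.trunc_gamma_mean <- function(a, r, c) {
  (a / r) * (1 - stats::pgamma(c, a + 1, r)) /
    (1 - stats::pgamma(c, a, r))
}

# draw n from a gamma truncated at >= trunc whose *truncated* mean equals
# `target`: the shape is fixed by the requested (mean, sd) and the rate is
# calibrated, since the truncated mean is monotone in the scale
.rgamma_trunc <- function(n, target, s, trunc = 0) {
  if (s == 0) return(rep(target, n))
  a <- (target / s)^2
  r <- a / target
  if (trunc > 0) {
    if (target <= trunc)
      stop("target mean must exceed the truncation point")
    r <- stats::uniroot(function(rr) .trunc_gamma_mean(a, rr, trunc) - target,
                        interval = c(r / 10, r * 10), extendInt = "yes",
                        tol = 1e-10)$root
  }
  x <- stats::rgamma(n, a, r)
  while (any(bad <- x < trunc)) x[bad] <- stats::rgamma(sum(bad), a, r)
  x
}

# mean of 100*plogis(N(mu, sigma)) by quadrature
.logitnorm_mean <- function(mu, sigma) {
  if (sigma == 0) return(100 * stats::plogis(mu))
  100 * stats::integrate(function(z) stats::plogis(mu + sigma * z) *
                           stats::dnorm(z),
                         -Inf, Inf, rel.tol = 1e-10)$value
}

# logit-scale location giving a target mean score on [0, 100]
.calibrate_logitnorm <- function(target, sigma) {
  if (target <= 0 || target >= 100)
    stop("score targets must lie strictly inside (0, 100) unless sigma = 0")
  stats::uniroot(function(mu) .logitnorm_mean(mu, sigma) - target,
                 interval = c(-10, 10), extendInt = "yes", tol = 1e-9)$root
}

.rscore <- function(n, target, sigma) {
  if (sigma == 0) return(rep(target, n))
  mu <- .calibrate_logitnorm(target, sigma)
  100 * stats::plogis(stats::rnorm(n, mu, sigma))
}

#' Generate a synthetic patient cohort
#'
#' Ages are normal truncated at 18; length of stay is gamma, truncated at
#' half a day, with the underlying distribution calibrated so the truncated
#' mean equals the spec target; billing categories are gamma around their
#' per-capita targets; lost productivity is computed from length of stay via
#' [lost_productivity()] rather than drawn; and questionnaire dimension
#' scores are logit-normal on `[0, 100]`, calibrated so the post-minus-pre
#' summary difference centres on the arm's utility-gain target. Fully
#' reproducible for a given seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed.
#' @return Data frame of class `cea_cohort`, one row per patient: `id`,
#'   `arm`, `age`, `sex`, `los_days`, the four ledger columns
#'   (`hospitalization`, `medication`, `travel_hotel`, `lost_productivity`,
#'   USD), and dimension-score columns `saq_pre_1..5`, `saq_post_1..5`,
#'   `sf36_pre_1..8`, `sf36_post_1..8`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cea_cohort_spec"))
  set.seed(as.integer(seed))
  arms <- lapply(CEA_ARMS, function(arm) {
    n <- as.integer(spec$n[[arm]])
    age <- stats::rnorm(n, spec$age_mean[[arm]], spec$age_sd[[arm]])
    while (any(bad <- age < 18))
      age[bad] <- stats::rnorm(sum(bad), spec$age_mean[[arm]],
                               spec$age_sd[[arm]])
    los <- .rgamma_trunc(n, spec$los_mean[[arm]], spec$los_sd[[arm]],
                         trunc = 0.5)
    bill <- function(category) {
      target <- spec$bills[[arm]][[category]]
      .rgamma_trunc(n, target, spec$bill_cv * target)
    }
    df <- data.frame(
      arm = arm, age = age,
      sex = ifelse(stats::runif(n) < spec$female_prop[[arm]],
                   "female", "male"),
      los_days = los,
      hospitalization = bill("hospitalization"),
      medication = bill("medication"),
      travel_hotel = bill("travel_hotel"),
      lost_productivity = lost_productivity(los))
    for (instr in CEA_INSTRUMENTS) {
      nd <- .N_DIMENSIONS[[instr]]
      pre_t <- spec$pre_score_mean
      post_t <- pre_t + 100 * spec$utility_gain[[instr]][[arm]]
      for (d in seq_len(nd)) {
        df[[sprintf("%s_pre_%d", tolower(instr), d)]] <-
          .rscore(n, pre_t, spec$score_sigma)
        df[[sprintf("%s_post_%d", tolower(instr), d)]] <-
          .rscore(n, post_t, spec$score_sigma)
      }
    }
    df
  })
  out <- do.call(rbind, arms)
  out <- cbind(id = seq_len(nrow(out)), out)
  class(out) <- c("cea_cohort", "data.frame")
  out
}

#' Summary-score columns of a cohort for one instrument and timepoint
#'
#' @param records A `cea_cohort` data frame.
#' @param instrument `"SAQ"` or `"SF36"`.
#' @param timepoint `"pre"` or `"post"`.
#' @return Numeric vector of per-patient summary scores (mean of the
#'   instrument's dimensions), 0-100.
#' @export
cohort_summary_score <- function(records, instrument = CEA_INSTRUMENTS,
                                 timepoint = c("pre", "post")) {
  instrument <- match.arg(instrument)
  timepoint <- match.arg(timepoint)
  cols <- sprintf("%s_%s_%d", tolower(instrument), timepoint,
                  seq_len(.N_DIMENSIONS[[instrument]]))
  rowMeans(records[cols])
}

#' Check that a generated cohort recovers its specification
#'
#' Aggregates the cohort through [aggregate_ledger()] and the questionnaire
#' scoring path and reports the relative error of every recovered statistic
#' against its spec target: mean length of stay, per-capita billing by
#' category (lost productivity is compared against `los_mean * wage`), and
#' the mean post-minus-pre utility gain per instrument.
#'
#' @param records A `cea_cohort` from [generate_cohort()].
#' @param spec The [cohort_spec()] the cohort was generated from.
#' @return Data frame: `arm`, `statistic`, `target`, `recovered`,
#'   `rel_error`.
#' @export
roundtrip_check <- function(records, spec = cohort_spec()) {
  rows <- list()
  add <- function(arm, statistic, target, recovered) {
    rel <- if (target != 0) abs(recovered - target) / abs(target) else
      abs(recovered)
    rows[[length(rows) + 1L]] <<- data.frame(
      arm = arm, statistic = statistic, target = target,
      recovered = recovered, rel_error = rel)
  }
  for (arm in CEA_ARMS) {
    sub <- records[records$arm == arm, ]
    ledger <- aggregate_ledger(records, arm)
    add(arm, "mean_los_days", spec$los_mean[[arm]], mean(sub$los_days))
    for (category in names(spec$bills[[arm]]))
      add(arm, paste0("per_capita_", category), spec$bills[[arm]][[category]],
          ledger$per_capita[[category]])
    add(arm, "per_capita_lost_productivity",
        lost_productivity(spec$los_mean[[arm]]),
        ledger$per_capita[["lost_productivity"]])
    for (instr in CEA_INSTRUMENTS) {
      gain <- mean(to_utility(cohort_summary_score(sub, instr, "post")) -
                     to_utility(cohort_summary_score(sub, instr, "pre")))
      add(arm, paste0("utility_gain_", instr),
          spec$utility_gain[[instr]][[arm]], gain)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
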