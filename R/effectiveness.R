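# Questionnaire scoring (SF-36, Seattle Angina Questionnaire) and QALY-gain
# computation.

.N_DIMENSIONS <- c(SF36 = 8L, SAQ = 5L)

#' Score a quality-of-life instrument from its dimension scores
#'
#' Both instruments report each health dimension on a 0-100 scale (0 worst,
#' 100 best): SF-36 has eight dimensions (physical function, role-physical,
#' bodily pain, general health, energy, social function, role-emotional,
#' emotional well-being), the SAQ five (physical limitation, angina
#' stability, angina frequency, treatment satisfaction, disease perception).
#' The summary score is the unweighted mean of the dimensions.
#'
#' @param dimension_scores Numeric vector of dimension scores in `[0, 100]`,
#'   length 8 (SF-36) or 5 (SAQ).
#' @param instrument `"SF36"` or `"SAQ"`.
#' @return A list of class `cea_score` with fields `instrument`,
#'   `dimensions`, `summary`.
#' @export
score_instrument <- function(dimension_scores, instrument = CEA_INSTRUMENTS) {
  instrument <- match.arg(instrument)
  n <- .N_DIMENSIONS[[instrument]]
  if (length(dimension_scores) != n)
    stop(sprintf("%s requires exactly %d dimension scores, got %d",
                 instrument, n, length(dimension_scores)))
  if (any(!is.finite(dimension_scores)) ||
      any(dimension_scores < 0) || any(dimension_scores > 100))
    stop("dimension scores must lie in [0, 100]")
  structure(list(instrument = instrument,
                 dimensions = as.numeric(dimension_scores),
                 summary = mean(dimension_scores)),
            class = "cea_score")
}

#' Map an instrument summary score to a utility weight
#'
#' Linear mapping `summary / 100`, so the all-100 response maps to utility 1
#' and the all-0 response to 0. (No external valuation tariff is applied;
#' see the methods vignette for the rationale and caveats.)
#'
#' @param score A `cea_score` from [score_instrument()], or a bare summary
#'   value in `[0, 100]`.
#' @return Utility weight in `[0, 1]`.
#' @export
to_utility <- function(score) {
  s <- if (inherits(score, "cea_score")) score$summary else score
  if (!is.numeric(s) || any(s < 0) || any(s > 100))
    stop("summary score must lie in [0, 100]")
  s / 100
}

#' Discounted QALYs gained from an intervention
#'
#' Compares continuously discounted quality-adjusted survival after the
#' intervention against before:
#' `Qi * (1 - exp(-r * Li)) / r - Q * (1 - exp(-r * L)) / r`,
#' where `Q`/`Qi` are the pre/post quality weights, `L`/`Li` the pre/post
#' affected durations in years, and `r` the annual discount rate. As
#' `r -> 0` the expression tends to the undiscounted `Qi*Li - Q*L`, which is
#' returned exactly for `r < 1e-9`.
#'
#' @param Q Pre-intervention quality weight (may be negative, in `[-1, 1]`).
#' @param Qi Post-intervention quality weight (in `[-1, 1]`).
#' @param L Pre-intervention duration, years (>= 0).
#' @param Li Post-intervention duration, years (>= 0).
#' @param r Annual discount rate (>= 0).
#' @return QALYs gained (may be negative).
#' @export
qalys_gained <- function(Q, Qi, L, Li, r = 0.03) {
  stopifnot(L >= 0, Li >= 0, r >= 0,
            abs(Q) <= 1, abs(Qi) <= 1)
  if (r < 1e-9) return(Qi * Li - Q * L)
  Qi * (1 - exp(-r * Li)) / r - Q * (1 - exp(-r * L)) / r
}
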