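# Patient-level costing: the four-category ledger (hospitalization,
# medication, travel/hotel, lost productivity), wage-based indirect costs,
# medication present value, and Rial/USD conversion.

#' Exchange rate used throughout: Iranian Rials per US dollar (2014 central
#' bank rate).
#' @export
IRR_PER_USD <- 26509

#' Wage model for lost-productivity costing
#'
#' The indirect cost of a hospital stay is valued at the 2014 average
#' minimum wage: the midpoint of the statutory minimum (269 USD/month) and
#' maximum (353 USD/month), i.e. 311 USD/month over 26 working days.
#'
#' @param monthly_wage Monthly wage in USD (default 311).
#' @param working_days_per_month Working days per month (default 26).
#' @return A list of class `cea_wage`.
#' @export
wage_model <- function(monthly_wage = 311, working_days_per_month = 26) {
  if (monthly_wage <= 0) stop("wage must be positive")
  if (working_days_per_month < 1 || working_days_per_month > 31)
    stop("working days per month must lie in [1, 31]")
  structure(list(monthly_wage = monthly_wage,
                 working_days_per_month = working_days_per_month),
            class = "cea_wage")
}

#' Lost-productivity cost of a hospital stay
#'
#' `days * monthly_wage / working_days_per_month`.
#'
#' @param days_hospitalized Length of stay in days (>= 0); vectorized.
#' @param wage A [wage_model()].
#' @return Cost in USD.
#' @export
lost_productivity <- function(days_hospitalized, wage = wage_model()) {
  if (any(days_hospitalized < 0)) stop("days hospitalized must be non-negative")
  days_hospitalized * wage$monthly_wage / wage$working_days_per_month
}

#' Present value of an ongoing medication cost
#'
#' A six-month drug bill is doubled to an annual cost, then summed over a
#' fixed number of years with annual discounting. Payments fall at the start
#' of each year by default (annuity-due, t = 0..years-1); set
#' `timing = "arrears"` for end-of-year payments (t = 1..years).
#'
#' @param six_month_cost Drug cost over six months, USD (>= 0).
#' @param rate Annual discount rate (default 0.03).
#' @param years Number of years covered (default 10).
#' @param timing `"due"` (default) or `"arrears"`.
#' @return Discounted present value in USD.
#' @export
medication_present_value <- function(six_month_cost, rate = 0.03, years = 10,
                                     timing = c("due", "arrears")) {
  timing <- match.arg(timing)
  if (any(six_month_cost < 0)) stop("medication cost must be non-negative")
  if (rate < 0) stop("discount rate must be non-negative")
  if (years < 1) stop("years must be at least 1")
  annual <- 2 * six_month_cost
  t <- if (timing == "due") 0:(years - 1) else 1:years
  annual * sum((1 + rate)^(-t))
}

#' Convert Iranian Rials to US dollars
#' @param amount Amount in IRR (>= 0); vectorized.
#' @return Amount in USD at the fixed 2014 rate.
#' @export
rial_to_usd <- function(amount) {
  if (any(amount < 0)) stop("amount must be non-negative")
  amount / IRR_PER_USD
}

#' Convert US dollars to Iranian Rials
#' @param amount Amount in USD (>= 0); vectorized.
#' @return Amount in IRR at the fixed 2014 rate.
#' @export
usd_to_rial <- function(amount) {
  if (any(amount < 0)) stop("amount must be non-negative")
  amount * IRR_PER_USD
}

#' Aggregate patient-level bills into a cost ledger
#'
#' Sums the four cost categories (direct medical: hospitalization and
#' medication; direct non-medical: travel/hotel; indirect: lost
#' productivity) over one arm's patients and derives per-capita values.
#' Internal arithmetic is unrounded; use [format_ledger()] for the
#' reporting convention (totals to 1 decimal, per-capita to 2).
#'
#' @param records Data frame of patient records with columns `arm`,
#'   `hospitalization`, `medication`, `travel_hotel`, `lost_productivity`
#'   (USD).
#' @param arm `"CABG"` or `"PCI"`.
#' @return A list of class `cea_ledger` with per-category totals,
#'   `per_capita` vector, `total`, and `n_patients`.
#' @export
aggregate_ledger <- function(records, arm = CEA_ARMS) {
  arm <- match.arg(arm)
  cats <- c("hospitalization", "medication", "travel_hotel",
            "lost_productivity")
  stopifnot(is.data.frame(records), all(c("arm", cats) %in% names(records)))
  sub <- records[records$arm == arm, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records for arm ", arm)
  if (any(as.matrix(sub[cats]) < 0)) stop("negative cost amounts in records")
  totals <- vapply(sub[cats], sum, numeric(1))
  structure(list(arm = arm, n_patients = nrow(sub),
                 totals = totals, total = sum(totals),
                 per_capita = totals / nrow(sub),
                 per_capita_total = sum(totals) / nrow(sub)),
            class = "cea_ledger")
}

#' Format a ledger with the reporting rounding convention
#'
#' @param ledger A `cea_ledger`.
#' @return Data frame with category, total (1 decimal) and per-capita
#'   (2 decimals) columns, plus a Total row.
#' @export
format_ledger <- function(ledger) {
  data.frame(category = c(names(ledger$totals), "total"),
             total_usd = round(c(ledger$totals, ledger$total), 1),
             per_capita_usd = round(c(ledger$per_capita,
                                      ledger$per_capita_total), 2),
             row.names = NULL)
}

#' @export
print.cea_ledger <- function(x, ...) {
  cat(sprintf("Cost ledger: %s arm, n = %d\n", x$arm, x$n_patients))
  print(format_ledger(x), row.names = FALSE)
  invisible(x)
}
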