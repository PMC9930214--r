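# Parameter handling: the base-case parameter set (transition probabilities,
# utilities under two instruments, per-state costs, each with a low-high
# range), rate/probability conversion, and PSA distribution fitting.

#' Model state and arm labels
#'
#' The cohort model distinguishes six health states after revascularization:
#' stable disease, repeat CABG, repeat PCI, cerebrovascular accident (CVA),
#' death from coronary artery disease, and death from other causes. The two
#' death states are absorbing.
#'
#' @format Character vectors.
#' @name model-labels
NULL

#' @rdname model-labels
#' @export
CEA_STATES <- c("stable", "repeat_cabg", "repeat_pci", "cva",
                "cad_death", "other_death")

#' @rdname model-labels
#' @export
CEA_ARMS <- c("CABG", "PCI")

#' @rdname model-labels
#' @export
CEA_INSTRUMENTS <- c("SAQ", "SF36")

# transition keys in Stable-row order (destination order matches CEA_STATES)
.TRANSITION_KEYS <- c("stay_stable", "to_repeat_cabg", "to_repeat_pci",
                      "to_cva", "to_cad_death", "to_other_death")
.SHARED_KEYS <- c("cad_death_after_stable", "cad_death_after_cva",
                  "death_other_causes")
.REWARD_STATES <- c("stable", "repeat_cabg", "repeat_pci", "cva")
.COST_STATES <- c(.REWARD_STATES, "cad_death", "other_death")

#' Convert an occurrence rate to a per-period transition probability
#'
#' Uses the standard exponential relation `p = 1 - exp(-r * t)` linking a
#' constant hazard `r` over a period of length `t` to the probability of at
#' least one event in that period.
#'
#' @param r Occurrence rate per unit time (non-negative).
#' @param t Period length, in the same time units (non-negative).
#' @return Probability in `[0, 1)`.
#' @seealso [probability_to_rate()] for the inverse transform.
#' @examples
#' rate_to_probability(0.1, 0.5)
#' @export
rate_to_probability <- function(r, t) {
  stopifnot(is.numeric(r), is.numeric(t))
  if (any(r < 0)) stop("rate `r` must be non-negative")
  if (any(t < 0)) stop("time `t` must be non-negative")
  -expm1(-r * t)
}

#' Convert a per-period probability back to an occurrence rate
#'
#' Inverse of [rate_to_probability()]: `r = -log(1 - p) / t`.
#'
#' @param p Probability in `[0, 1)`.
#' @param t Period length (positive).
#' @return Occurrence rate per unit time.
#' @export
probability_to_rate <- function(p, t) {
  stopifnot(is.numeric(p), is.numeric(t))
  if (any(p < 0) || any(p >= 1)) stop("`p` must lie in [0, 1)")
  if (any(t <= 0)) stop("time `t` must be positive")
  -log1p(-p) / t
}

#' Construct a single model parameter entry
#'
#' An entry couples a point value with a low-high uncertainty range and a
#' kind tag that controls validation and the PSA sampling distribution
#' (beta for probabilities and utilities, gamma for costs).
#'
#' @param id Character label, unique within a parameter set.
#' @param mean Point (base-case) value.
#' @param low,high Range bounds, `low <= mean <= high`.
#' @param kind One of `"probability"`, `"utility"`, `"cost"`.
#' @return A list of class `cea_param_entry`.
#' @export
param_entry <- function(id, mean, low, high, kind) {
  kind <- match.arg(kind, c("probability", "utility", "cost"))
  entry <- list(id = as.character(id), mean = as.numeric(mean),
                low = as.numeric(low), high = as.numeric(high), kind = kind)
  .validate_entry(entry)
  structure(entry, class = "cea_param_entry")
}

.validate_entry <- function(entry) {
  id <- entry$id
  if (!is.finite(entry$mean) || !is.finite(entry$low) || !is.finite(entry$high))
    stop(sprintf("parameter '%s': non-finite value or range", id))
  if (entry$low > entry$mean || entry$mean > entry$high)
    stop(sprintf("parameter '%s': range must satisfy low <= mean <= high (got %g, %g, %g)",
                 id, entry$low, entry$mean, entry$high))
  if (entry$kind == "probability") {
    # ranges may overshoot [0,1] in print (they are clamped before PSA
    # fitting), but the point value itself must be a probability
    if (entry$mean < 0 || entry$mean > 1)
      stop(sprintf("parameter '%s': probability mean outside [0, 1]", id))
    if (entry$high < 0 || entry$low > 1)
      stop(sprintf("parameter '%s': probability range entirely outside [0, 1]", id))
  }
  if (entry$kind == "cost" && entry$low < 0)
    stop(sprintf("parameter '%s': cost range must be non-negative", id))
  invisible(entry)
}

#' Fit a PSA sampling distribution to a parameter entry
#'
#' Ranges are read as 95% confidence intervals, so the implied standard
#' deviation is `(high - low) / 3.92`. Costs get a gamma distribution by
#' moment matching (`shape = (mean/sd)^2`, `rate = mean/sd^2`). Probabilities
#' and utilities get a beta distribution by moment matching; a probability
#' range overshooting `[0, 1]` is clamped first, and a utility whose support
#' extends outside `[0, 1]` (negative utilities are allowed) is rescaled
#' affinely onto `[0, 1]` using its own bounds, sampled there, and mapped
#' back. A degenerate range (`high == low`) yields a fixed (point-mass)
#' distribution. In every case the analytic mean of the fitted distribution
#' equals the entry mean on the original scale.
#'
#' @param entry A [param_entry()] (or any list with `mean`, `low`, `high`,
#'   `kind` fields).
#' @return A list of class `cea_dist` with fields `family`
#'   (`"beta"`, `"gamma"` or `"fixed"`), shape parameters, and the affine
#'   support `(lo, hi)` used to map beta draws back to the original scale.
#' @seealso [sample_dist()], [dist_mean()]
#' @export
fit_distribution <- function(entry) {
  .validate_entry(entry)
  m <- entry$mean; lo <- entry$low; hi <- entry$high
  if (entry$kind == "probability") {
    lo <- max(lo, 0); hi <- min(hi, 1)
    if (lo > m || m > hi)
      stop(sprintf("parameter '%s': mean outside clamped range", entry$id))
  }
  if (hi == lo) {
    return(structure(list(family = "fixed", value = m, lo = lo, hi = hi),
                     class = "cea_dist"))
  }
  sdev <- (hi - lo) / 3.92
  if (entry$kind == "cost") {
    shape <- (m / sdev)^2
    rate <- m / sdev^2
    if (!is.finite(shape) || shape <= 0 || rate <= 0)
      stop(sprintf("parameter '%s': cannot fit a gamma distribution", entry$id))
    return(structure(list(family = "gamma", shape = shape, rate = rate,
                          lo = 0, hi = Inf), class = "cea_dist"))
  }
  # beta, possibly on a rescaled support
  if (lo < 0 || hi > 1) {
    support <- c(lo, hi)
  } else {
    support <- c(0, 1)
  }
  width <- support[2] - support[1]
  mu <- (m - support[1]) / width
  v <- (sdev / width)^2
  if (mu <= 0 || mu >= 1 || v >= mu * (1 - mu))
    stop(sprintf("parameter '%s': (mean, sd) infeasible for a beta distribution",
                 entry$id))
  nu <- mu * (1 - mu) / v - 1
  structure(list(family = "beta", shape1 = mu * nu, shape2 = (1 - mu) * nu,
                 lo = support[1], hi = support[2]), class = "cea_dist")
}

#' Analytic mean of a fitted PSA distribution
#'
#' @param dist A `cea_dist` from [fit_distribution()].
#' @return The mean on the original parameter scale.
#' @export
dist_mean <- function(dist) {
  switch(dist$family,
         fixed = dist$value,
         gamma = dist$shape / dist$rate,
         beta = dist$lo + (dist$hi - dist$lo) *
           dist$shape1 / (dist$shape1 + dist$shape2),
         stop("unknown distribution family"))
}

#' Draw samples from a fitted PSA distribution
#'
#' @param dist A `cea_dist` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n` on the original parameter scale.
#' @export
sample_dist <- function(dist, n = 1) {
  switch(dist$family,
         fixed = rep(dist$value, n),
         gamma = stats::rgamma(n, shape = dist$shape, rate = dist$rate),
         beta = dist$lo + (dist$hi - dist$lo) *
           stats::rbeta(n, dist$shape1, dist$shape2),
         stop("unknown distribution family"))
}

# ---- parameter set -------------------------------------------------------

.required_ids <- function() {
  c(sprintf("transition.%s.%s", rep(CEA_ARMS, each = 6), .TRANSITION_KEYS),
    sprintf("shared.%s", .SHARED_KEYS),
    sprintf("utility.%s.%s.%s",
            rep(CEA_INSTRUMENTS, each = 8),
            rep(rep(CEA_ARMS, each = 4), 2), .REWARD_STATES),
    sprintf("cost.%s.%s", rep(CEA_ARMS, each = 6), .COST_STATES))
}

#' Assemble a validated model parameter set
#'
#' @param entries A data frame with columns `id`, `mean`, `low`, `high`,
#'   `kind`, containing exactly the entries required by the model: 12
#'   per-arm transition probabilities, 3 shared probabilities, 16 utilities
#'   (8 per instrument), 12 per-state costs.
#' @param annual_discount_rate Annual discount rate (default 0.03).
#' @param cycle_length_years Cycle length in years (default 0.5).
#' @param entry_age_years Cohort entry age (default 59; descriptive).
#' @return An object of class `cea_parameters`.
#' @export
model_parameters <- function(entries, annual_discount_rate = 0.03,
                             cycle_length_years = 0.5, entry_age_years = 59) {
  stopifnot(is.data.frame(entries),
            all(c("id", "mean", "low", "high", "kind") %in% names(entries)))
  entries <- as.data.frame(entries)[, c("id", "mean", "low", "high", "kind")]
  entries$id <- as.character(entries$id)
  entries$kind <- as.character(entries$kind)
  for (i in seq_len(nrow(entries))) .validate_entry(as.list(entries[i, ]))
  need <- .required_ids()
  missing <- setdiff(need, entries$id)
  if (length(missing))
    stop("missing parameter entries: ", paste(missing, collapse = ", "))
  extra <- setdiff(entries$id, need)
  if (length(extra))
    stop("unknown parameter entries: ", paste(extra, collapse = ", "))
  if (anyDuplicated(entries$id))
    stop("duplicated parameter ids: ",
         paste(unique(entries$id[duplicated(entries$id)]), collapse = ", "))
  if (annual_discount_rate < 0) stop("discount rate must be non-negative")
  if (cycle_length_years <= 0) stop("cycle length must be positive")
  rownames(entries) <- entries$id
  structure(list(entries = entries[need, ],
                 annual_discount_rate = annual_discount_rate,
                 cycle_length_years = cycle_length_years,
                 entry_age_years = entry_age_years),
            class = "cea_parameters")
}

#' Point values of a parameter set as a named vector
#'
#' @param params A `cea_parameters` object.
#' @return Named numeric vector of base-case means, keyed by entry id.
#' @export
param_values <- function(params) {
  stats::setNames(params$entries$mean, params$entries$id)
}

#' Replace the point value of one parameter
#'
#' Used by one-way sensitivity analysis and the PSA to perturb a single
#' entry while leaving everything else at base case. The replacement is not
#' range-checked against the entry's own low/high (deliberately: DSA probes
#' endpoints, PSA draws can exceed them), but kind invariants still apply
#' for probabilities.
#'
#' @param params A `cea_parameters` object.
#' @param id Entry id.
#' @param value New point value.
#' @return The modified `cea_parameters` object.
#' @export
set_param <- function(params, id, value) {
  if (!id %in% params$entries$id) stop("unknown parameter id: ", id)
  if (params$entries[id, "kind"] == "probability")
    value <- min(max(value, 0), 1)
  params$entries[id, "mean"] <- value
  params
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("Model parameter set:", nrow(x$entries), "entries\n")
  cat(sprintf("  discount %.1f%%/yr, cycle %.2g yr, entry age %g\n",
              100 * x$annual_discount_rate, x$cycle_length_years,
              x$entry_age_years))
  tab <- table(x$entries$kind)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# ---- YAML I/O ------------------------------------------------------------

.entry_from_yaml <- function(id, node, kind) {
  for (f in c("value", "low", "high")) {
    if (is.null(node[[f]]) || !is.numeric(node[[f]]))
      stop(sprintf("parameter '%s': missing or non-numeric field '%s'", id, f))
  }
  list(id = id, mean = node$value, low = node$low, high = node$high,
       kind = kind)
}

#' Load a model parameter file
#'
#' Reads a YAML parameter file with `transitions` (per arm), `shared`,
#' `utilities` (per instrument and arm), `costs` (per arm) blocks, plus an
#' optional `settings` block, validates every entry, and returns a
#' `cea_parameters` object. The packaged default, `base_case.yaml`,
#' holds the base-case value and 95% range of every model input.
#'
#' @param path Path to a YAML parameter file.
#' @return A validated `cea_parameters` object.
#' @seealso [default_parameters()] for the packaged base case.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  doc <- yaml::read_yaml(path)
  rows <- list()
  add <- function(e) rows[[length(rows) + 1L]] <<- e
  for (arm in CEA_ARMS) {
    block <- doc$transitions[[arm]]
    if (is.null(block)) stop("missing transitions block for arm ", arm)
    for (key in .TRANSITION_KEYS) {
      if (is.null(block[[key]]))
        stop(sprintf("missing transition entry 'transition.%s.%s'", arm, key))
      add(.entry_from_yaml(sprintf("transition.%s.%s", arm, key),
                           block[[key]], "probability"))
    }
  }
  for (key in .SHARED_KEYS) {
    if (is.null(doc$shared[[key]]))
      stop(sprintf("missing shared entry 'shared.%s'", key))
    add(.entry_from_yaml(sprintf("shared.%s", key), doc$shared[[key]],
                         "probability"))
  }
  for (instr in CEA_INSTRUMENTS) {
    for (arm in CEA_ARMS) {
      block <- doc$utilities[[instr]][[arm]]
      if (is.null(block))
        stop(sprintf("missing utilities block for %s/%s", instr, arm))
      for (st in .REWARD_STATES) {
        if (is.null(block[[st]]))
          stop(sprintf("missing utility entry 'utility.%s.%s.%s'",
                       instr, arm, st))
        add(.entry_from_yaml(sprintf("utility.%s.%s.%s", instr, arm, st),
                             block[[st]], "utility"))
      }
    }
  }
  for (arm in CEA_ARMS) {
    block <- doc$costs[[arm]]
    if (is.null(block)) stop("missing costs block for arm ", arm)
    for (st in .COST_STATES) {
      if (is.null(block[[st]]))
        stop(sprintf("missing cost entry 'cost.%s.%s'", arm, st))
      add(.entry_from_yaml(sprintf("cost.%s.%s", arm, st), block[[st]],
                           "cost"))
    }
  }
  entries <- do.call(rbind, lapply(rows, as.data.frame))
  st <- doc$settings
  model_parameters(entries,
                   annual_discount_rate = st$annual_discount_rate %||% 0.03,
                   cycle_length_years = st$cycle_length_years %||% 0.5,
                   entry_age_years = st$entry_age_years %||% 59)
}

#' Packaged base-case parameter set
#'
#' @return The `cea_parameters` object loaded from the packaged
#'   `base_case.yaml` file.
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", "base_case.yaml",
                              package = "coronaryCEA", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
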