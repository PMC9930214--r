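# Report assembly: end-to-end runs that write CSV (and optional plot)
# outputs for the base case, the sensitivity analyses, and the synthetic
# cohort. A thin command-line wrapper over these functions ships in
# inst/cli/coronarycea.R.

.ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Run the base-case analysis and write its report
#'
#' Runs [compare_arms()] and [cea_table()] for each requested instrument and
#' writes one CSV per instrument (`base_case_<instrument>.csv`, columns:
#' strategy, QALYs, incremental QALYs, cost, incremental cost, ICER,
#' verdict, ACER, NMB) plus a cohort trace CSV per arm.
#'
#' @param params A `cea_parameters` object (default: packaged base case).
#' @param settings A [cea_settings()] list.
#' @param instruments Instruments to analyze (default both).
#' @param out_dir Output directory, created if needed.
#' @return Named list of `cea_result` objects, invisibly.
#' @export
report_base_case <- function(params = default_parameters(),
                             settings = cea_settings(),
                             instruments = CEA_INSTRUMENTS,
                             out_dir = ".") {
  .ensure_dir(out_dir)
  results <- lapply(instruments, function(instr) {
    traces <- compare_arms(params, instr, settings)
    res <- cea_table(traces, wtp = settings$wtp,
                     gdp_per_capita = settings$gdp_per_capita)
    utils::write.csv(res$table,
                     file.path(out_dir, sprintf("base_case_%s.csv", instr)),
                     row.names = FALSE)
    for (arm in CEA_ARMS)
      write_trace(traces[[arm]],
                  file.path(out_dir, sprintf("trace_%s_%s.csv", instr, arm)))
    res
  })
  names(results) <- instruments
  invisible(results)
}

#' Run the sensitivity analyses and write their reports
#'
#' Writes the per-trial PSA CSV (`psa_trials.csv`: trial, delta cost, delta
#' QALY, NMB at the reference WTP), the CEAC CSV (`ceac.csv`), the tornado
#' CSV (`tornado.csv`), and — unless `plots = FALSE` — CE-plane, CEAC and
#' tornado figures as SVG.
#'
#' @param params A `cea_parameters` object.
#' @param n_trials Number of PSA trials.
#' @param seed Integer RNG seed.
#' @param instrument Instrument for the incremental outcomes.
#' @param settings A [cea_settings()] list.
#' @param wtp_grid WTP grid for the CEAC.
#' @param out_dir Output directory.
#' @param plots Write SVG figures?
#' @return List with `psa`, `ceac`, `tornado`, invisibly.
#' @export
report_psa <- function(params = default_parameters(), n_trials = 5000,
                       seed = 1, instrument = CEA_INSTRUMENTS,
                       settings = cea_settings(),
                       wtp_grid = seq(0, 100000, by = 1000),
                       out_dir = ".", plots = TRUE) {
  instrument <- match.arg(instrument)
  .ensure_dir(out_dir)
  psa <- run_psa(params, n_trials = n_trials, seed = seed,
                 instrument = instrument, settings = settings)
  trials <- psa$trials
  trials$nmb <- nmb(settings$wtp, trials$delta_qaly, trials$delta_cost)
  utils::write.csv(trials, file.path(out_dir, "psa_trials.csv"),
                   row.names = FALSE)
  curve <- ceac(psa, wtp_grid)
  utils::write.csv(curve, file.path(out_dir, "ceac.csv"), row.names = FALSE)
  torn <- tornado(params, instrument, settings)
  utils::write.csv(torn, file.path(out_dir, "tornado.csv"),
                   row.names = FALSE)
  if (plots) {
    ggplot2::ggsave(file.path(out_dir, "ce_plane.svg"),
                    plot_ce_plane(psa, settings$wtp), width = 6, height = 5)
    ggplot2::ggsave(file.path(out_dir, "ceac.svg"), plot_ceac(curve),
                    width = 6, height = 4)
    ggplot2::ggsave(file.path(out_dir, "tornado.svg"), plot_tornado(torn),
                    width = 7, height = 5)
  }
  invisible(list(psa = psa, ceac = curve, tornado = torn))
}

#' Generate a synthetic cohort and write it with its round-trip report
#'
#' Writes `cohort.csv` (one row per patient) and `roundtrip.csv` (recovered
#' statistics vs targets, from [roundtrip_check()]).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed.
#' @param out_dir Output directory.
#' @return List with `cohort` and `roundtrip`, invisibly.
#' @export
report_synth <- function(spec = cohort_spec(), seed = 1, out_dir = ".") {
  .ensure_dir(out_dir)
  cohort <- generate_cohort(spec, seed)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  check <- roundtrip_check(cohort, spec)
  utils::write.csv(check, file.path(out_dir, "roundtrip.csv"),
                   row.names = FALSE)
  invisible(list(cohort = cohort, roundtrip = check))
}
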