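params <- default_parameters()

test_that("transition matrices reproduce the base-case structure", {
  M_pci <- build_matrix(params, "PCI")
  # Stable row renormalized by the printed row sum (0.9996 for PCI)
  expect_equal(M_pci["stable", "repeat_cabg"], 0.1505 / 0.9996,
               tolerance = 1e-12)
  M_cabg <- build_matrix(params, "CABG")
  expect_equal(sum(c(0.9476, 0.006, 0.005, 0.001, 0.0371, 0.003)), 0.9997)
  expect_equal(M_cabg["stable", "stable"], 0.9476 / 0.9997, tolerance = 1e-12)
  # CVA row: shared death probabilities, remainder back to Stable
  for (M in list(M_cabg, M_pci)) {
    expect_equal(M["cva", "cad_death"], 0.074)
    expect_equal(M["cva", "other_death"], 0.004)
    expect_equal(M["cva", "stable"], 0.922)
  }
  # repeat states are tunnels onto the corresponding procedure's Stable row
  expect_equal(M_pci["repeat_cabg", ], M_cabg["stable", ])
  expect_equal(M_cabg["repeat_pci", ], M_pci["stable", ])
  # stochastic, absorbing deaths
  for (M in list(M_cabg, M_pci)) {
    expect_true(all(abs(rowSums(M) - 1) < 1e-12))
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(unname(M["cad_death", ]), c(0, 0, 0, 0, 1, 0))
    expect_equal(unname(M["other_death", ]), c(0, 0, 0, 0, 0, 1))
  }
})

test_that("an all-stay matrix keeps the cohort in Stable", {
  p <- params
  for (key in c("to_repeat_cabg", "to_repeat_pci", "to_cva",
                "to_cad_death", "to_other_death"))
    p <- set_param(p, paste0("transition.CABG.", key), 0)
  p <- set_param(p, "transition.CABG.stay_stable", 1)
  M <- build_matrix(p, "CABG")
  tr <- run_cohort(M, build_rewards(p, "CABG", "SAQ"), 10, 0.03)
  expect_equal(unname(tr$occupancy[11, "stable"]), 1)
})

test_that("cohort propagation matches the explicit matrix-power oracle", {
  set.seed(42)
  for (rep in 1:5) {
    M <- rand_stochastic_matrix()
    init <- stats::rexp(6); init <- init / sum(init)
    tr <- run_cohort(M, make_rewards(), 100, 0.03, init = init)
    for (k in c(1, 7, 30, 100)) {
      oracle <- as.numeric(init %*% matrix_power(M, k))
      expect_lt(max(abs(tr$occupancy[k + 1, ] - oracle)), 1e-10)
    }
  }
})

test_that("cohort mass is conserved and death occupancy is non-decreasing", {
  set.seed(99)
  for (rep in 1:10) {
    M <- rand_stochastic_matrix()
    M["cad_death", ] <- c(0, 0, 0, 0, 1, 0)
    M["other_death", ] <- c(0, 0, 0, 0, 0, 1)
    tr <- run_cohort(M, make_rewards(), 50, 0)
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-10)
    dead <- tr$occupancy[, "cad_death"] + tr$occupancy[, "other_death"]
    expect_true(all(diff(dead) >= -1e-12))
  }
})

test_that("zero rewards accrue nothing; constant utility gives u * H", {
  M <- build_matrix(params, "CABG")
  tr <- run_cohort(M, make_rewards(), 25, 0.03)
  expect_equal(tr$total_cost, 0)
  expect_equal(tr$total_qaly, 0)
  Mi <- diag(6); dimnames(Mi) <- list(CEA_STATES, CEA_STATES)
  tr <- run_cohort(Mi, make_rewards(utility = c(0.7, 0, 0, 0, 0, 0)), 12, 0)
  expect_equal(tr$total_qaly, 0.7 * 12)
})

test_that("base-case totals match a step-by-step recomputation", {
  # independent spreadsheet-style oracle: explicit matrix powers per cycle
  M <- build_matrix(params, "CABG")
  rw <- build_rewards(params, "CABG", "SAQ")
  H <- 30; r <- 0.03; cl <- 0.5
  init <- c(1, 0, 0, 0, 0, 0)
  dead <- c("cad_death", "other_death")
  cost <- qaly <- 0
  for (k in 0:(H - 1)) {
    x_k <- as.numeric(init %*% matrix_power(M, k))
    x_k1 <- as.numeric(init %*% matrix_power(M, k + 1))
    names(x_k) <- names(x_k1) <- CEA_STATES
    disc <- (1 + r)^(-k * cl)
    qaly <- qaly + disc * sum(x_k * rw$utility)
    cost <- cost + disc * (sum(x_k * rw$cost_recurring) +
                             sum((x_k1[dead] - x_k[dead]) *
                                   rw$cost_transition[dead]))
  }
  tr <- run_cohort(M, rw, H, r)
  expect_equal(tr$total_cost, cost, tolerance = 1e-10)
  expect_equal(tr$total_qaly, qaly, tolerance = 1e-10)
})

test_that("discounted totals are monotone in horizon and in discount rate", {
  M <- build_matrix(params, "CABG")
  rw <- build_rewards(params, "CABG", "SAQ")  # CABG utilities all >= 0
  costs <- qalys <- numeric(0)
  for (H in c(5, 10, 20, 40)) {
    tr <- run_cohort(M, rw, H, 0.03)
    costs <- c(costs, tr$total_cost)
    qalys <- c(qalys, tr$total_qaly)
  }
  expect_true(all(diff(costs) > 0))
  expect_true(all(diff(qalys) > 0))
  by_rate <- sapply(c(0, 0.03, 0.10), function(r) {
    tr <- run_cohort(M, rw, 30, r)
    c(tr$total_cost, tr$total_qaly)
  })
  expect_true(all(diff(by_rate[1, ]) < 0))
  expect_true(all(diff(by_rate[2, ]) < 0))
})

test_that("run_cohort rejects invalid inputs", {
  M <- build_matrix(params, "CABG")
  bad <- unclass(M); bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(run_cohort(bad, make_rewards(), 10, 0.03), "stochastic")
  expect_error(run_cohort(M, make_rewards(), 0, 0.03), "at least one")
  expect_error(run_cohort(M, make_rewards(), 10, 0.03,
                          init = c(0.5, 0, 0, 0, 0, 0)), "sum to 1")
})

test_that("compare_arms pairs identical settings and is symmetric", {
  traces <- compare_arms(params, "SAQ")
  expect_named(traces, c("CABG", "PCI"))
  expect_gt(traces$CABG$total_qaly, traces$PCI$total_qaly)
  sym <- compare_arms(symmetric_parameters(), "SAQ")
  expect_equal(sym$CABG$total_qaly, sym$PCI$total_qaly)
  expect_equal(sym$CABG$total_cost, sym$PCI$total_cost)
})

test_that("a one-cycle horizon reduces to hand-computable rewards", {
  s1 <- cea_settings(horizon_cycles = 1)
  traces <- compare_arms(params, "SAQ", s1)
  v <- param_values(params)
  # cycle 0: whole cohort in Stable, no discounting yet
  expect_equal(traces$CABG$total_qaly, v[["utility.SAQ.CABG.stable"]])
  M <- build_matrix(params, "CABG")
  expected_cost <- v[["cost.CABG.stable"]] +
    M["stable", "cad_death"] * v[["cost.CABG.cad_death"]] +
    M["stable", "other_death"] * v[["cost.CABG.other_death"]]
  expect_equal(traces$CABG$total_cost, expected_cost)
})

test_that("trace CSV export round-trips occupancy and totals", {
  tr <- compare_arms(params, "SAQ")$CABG
  f <- tempfile(fileext = ".csv")
  df <- write_trace(tr, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(back), tr$horizon_cycles + 1)
  expect_equal(back$stable, unname(tr$occupancy[, "stable"]))
  expect_equal(back$cum_discounted_cost[nrow(back)], tr$total_cost)
})
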