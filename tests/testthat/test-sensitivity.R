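params <- default_parameters()

test_that("one-way analysis records endpoint outcomes and swing", {
  base <- param_values(params)[["cost.CABG.stable"]]
  # degenerate range: zero swing
  ow <- one_way(params, "cost.CABG.stable", base, base, "SAQ")
  expect_equal(ow$swing, 0)
  # utility perturbation: iNMB endpoints differ by WTP x induced dQALY diff
  s <- cea_settings()
  id <- "utility.SAQ.CABG.stable"
  lo <- 0.108; hi <- 0.163
  ow <- one_way(params, id, lo, hi, "SAQ", s)
  dq <- function(v) {
    tr <- compare_arms(set_param(params, id, v), "SAQ", s)
    tr$CABG$total_qaly - tr$PCI$total_qaly
  }
  expect_equal(ow$inmb_high - ow$inmb_low, s$wtp * (dq(hi) - dq(lo)),
               tolerance = 1e-8)
  expect_gt(ow$swing, 0)
  expect_error(one_way(params, "nope", 0, 1), "unknown parameter")
  expect_error(one_way(params, id, 1, 0), "must not exceed")
})

test_that("tornado sorts by swing with wider ranges of a linear parameter first", {
  torn <- tornado(params, "SAQ")
  expect_true(all(diff(torn$swing) <= 0))
  expect_true(all(torn$swing >= 0))
  expect_setequal(torn$param,
                  params$entries$id[params$entries$high >
                                      params$entries$low])
  # nested ranges on a linear (utility) parameter: wider sorts first
  id <- "utility.SAQ.CABG.stable"
  narrow <- one_way(params, id, 0.12, 0.15, "SAQ")
  wide <- one_way(params, id, 0.108, 0.163, "SAQ")
  expect_gt(wide$swing, narrow$swing)
})

test_that("PSA is reproducible and trial outcomes are finite", {
  a <- run_psa(params, 25, seed = 123)
  b <- run_psa(params, 25, seed = 123)
  expect_identical(a$trials, b$trials)
  c50 <- run_psa(params, 50, seed = 123)
  # trial i does not depend on the number of trials requested
  expect_identical(a$trials, c50$trials[1:25, ])
  expect_true(all(is.finite(c50$trials$delta_cost)))
  expect_true(all(is.finite(c50$trials$delta_qaly)))
  expect_error(run_psa(params, 0), "at least 1")
})

test_that("a degenerate parameter set gives the base case in every trial", {
  p <- params
  p$entries$low <- p$entries$mean
  p$entries$high <- p$entries$mean
  psa <- run_psa(p, 3, seed = 9)
  traces <- compare_arms(params, "SAQ")
  expect_equal(psa$trials$delta_cost,
               rep(traces$CABG$total_cost - traces$PCI$total_cost, 3))
  expect_equal(psa$trials$delta_qaly,
               rep(traces$CABG$total_qaly - traces$PCI$total_qaly, 3))
})

test_that("sampled parameters recover their base-case means", {
  n <- 400
  psa <- run_psa(params, n, seed = 2024, keep_draws = TRUE)
  entries <- params$entries
  for (id in colnames(psa$draws)) {
    x <- psa$draws[, id]
    se <- stats::sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - entries[id, "mean"]), 3 * se + 1e-12,
              label = sprintf("mean recovery for %s", id))
    if (entries[id, "kind"] == "cost") expect_true(all(x >= 0))
    if (entries[id, "kind"] != "cost") {
      d <- fit_distribution(as.list(entries[id, ]))
      expect_true(all(x >= d$lo - 1e-12 & x <= d$hi + 1e-12))
    }
  }
})

test_that("CEAC equals the acceptance fraction and behaves at the edges", {
  set.seed(77)
  psa <- make_psa(delta_cost = stats::rnorm(4000, 0, 5000),
                  delta_qaly = stats::runif(4000, 0.1, 2))
  grid <- seq(0, 50000, by = 5000)
  curve <- ceac(psa, grid)
  for (w in grid)
    expect_identical(curve$probability[curve$wtp == w],
                     acceptance_fraction(psa, w))
  # wtp = 0 collapses to the fraction of cost-saving trials
  expect_equal(curve$probability[curve$wtp == 0],
               mean(psa$trials$delta_cost < 0))
  # all dE >= 0: monotone non-decreasing in wtp, rising from ~0.5
  expect_true(all(diff(curve$probability) >= 0))
  expect_equal(curve$probability[1], 0.5, tolerance = 0.05)
  expect_error(ceac(psa, numeric(0)), "non-empty")
  expect_error(ceac(psa, c(2, 1)), "strictly increasing")
})

test_that("acceptance fraction matches a constructed dominant/dominated mixture", {
  dominant <- cbind(-abs(stats::rnorm(700, 1e4, 1e3)),
                    abs(stats::rnorm(700, 1, 0.1)))
  dominated <- cbind(abs(stats::rnorm(300, 1e4, 1e3)),
                     -abs(stats::rnorm(300, 1, 0.1)))
  pts <- rbind(dominant, dominated)
  psa <- make_psa(pts[, 1], pts[, 2])
  expect_equal(acceptance_fraction(psa, 24987), 0.7)
  expect_equal(acceptance_fraction(make_psa(-100, 0.5), 1000), 1)
  expect_equal(acceptance_fraction(make_psa(100, -0.5), 1000), 0)
})

test_that("base-case dominance is robust across every tornado endpoint", {
  torn <- tornado(params, "SAQ")
  expect_true(all(torn$verdict_low == "dominant"))
  expect_true(all(torn$verdict_high == "dominant"))
})
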