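test_that("rate/probability conversion matches the exponential relation", {
  expect_equal(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(0.1, 0.5), 0.04877058, tolerance = 1e-7)
  expect_lt(abs(rate_to_probability(10, 10) - 1), 1e-40)
  expect_equal(probability_to_rate(0, 1), 0)
  expect_equal(probability_to_rate(0.04877058, 0.5), 0.1, tolerance = 1e-6)
  expect_equal(probability_to_rate(0.5, 1), 0.6931472, tolerance = 1e-7)
  expect_error(rate_to_probability(-0.1, 1), "non-negative")
  expect_error(probability_to_rate(1, 1), "\\[0, 1\\)")
})

test_that("conversion round-trips on [0, 0.999]", {
  p <- seq(0, 0.999, length.out = 200)
  for (t in c(0.5, 1, 2)) {
    back <- rate_to_probability(probability_to_rate(p, t), t)
    expect_lt(max(abs(back - p)), 1e-10)
  }
})

test_that("fitted distributions preserve the entry mean on the original scale", {
  p <- default_parameters()
  for (id in p$entries$id) {
    entry <- as.list(p$entries[id, ])
    if (entry$high == entry$low) next
    d <- fit_distribution(entry)
    expect_lt(abs(dist_mean(d) - entry$mean), 1e-9)
  }
})

test_that("distribution families follow the kind tag", {
  # probability: beta whose analytic mean is the entry value
  d <- fit_distribution(param_entry("p", 0.009, 0.008, 0.012, "probability"))
  expect_identical(d$family, "beta")
  expect_equal(dist_mean(d), 0.009, tolerance = 1e-12)
  # cost: gamma by moment matching
  sdev <- (2912 - 1941) / 3.92
  d <- fit_distribution(param_entry("c", 2426, 1941, 2912, "cost"))
  expect_identical(d$family, "gamma")
  expect_equal(d$shape, (2426 / sdev)^2, tolerance = 1e-12)
  expect_equal(d$rate, 2426 / sdev^2, tolerance = 1e-12)
  # degenerate range: point mass
  d <- fit_distribution(param_entry("f", 0.5, 0.5, 0.5, "utility"))
  expect_identical(d$family, "fixed")
  expect_identical(unique(sample_dist(d, 5)), 0.5)
})

test_that("negative-utility entries are rescaled onto their own bounds", {
  d <- fit_distribution(param_entry("u", -0.357, -0.3928, -0.3214, "utility"))
  expect_identical(d$family, "beta")
  expect_equal(c(d$lo, d$hi), c(-0.3928, -0.3214))
  expect_equal(dist_mean(d), -0.357, tolerance = 1e-12)
  set.seed(11)
  x <- sample_dist(d, 2000)
  expect_true(all(x >= -0.3928 & x <= -0.3214))
})

test_that("probability ranges overshooting [0,1] are clamped before fitting", {
  d <- fit_distribution(param_entry("p", 0.9476, 0.85284, 1.04236,
                                    "probability"))
  expect_identical(d$family, "beta")
  expect_equal(c(d$lo, d$hi), c(0, 1))
  expect_equal(dist_mean(d), 0.9476, tolerance = 1e-12)
  set.seed(12)
  expect_true(all(sample_dist(d, 2000) <= 1))
})

test_that("the packaged base case loads with the full entry complement", {
  p <- default_parameters()
  expect_s3_class(p, "cea_parameters")
  kinds <- table(p$entries$kind)
  expect_identical(sum(grepl("^transition\\.", p$entries$id)), 12L)
  expect_identical(sum(grepl("^shared\\.", p$entries$id)), 3L)
  expect_identical(as.integer(kinds[["utility"]]), 16L)
  expect_identical(as.integer(kinds[["cost"]]), 12L)
  v <- param_values(p)
  expect_equal(v[["transition.CABG.stay_stable"]], 0.9476)
  expect_equal(v[["transition.PCI.to_repeat_cabg"]], 0.1505)
  expect_equal(v[["utility.SAQ.PCI.repeat_cabg"]], -0.357)
  expect_equal(v[["cost.CABG.other_death"]], 5700)
  expect_equal(p$annual_discount_rate, 0.03)
  expect_equal(p$cycle_length_years, 0.5)
  expect_equal(p$entry_age_years, 59)
})

test_that("malformed parameter files fail validation naming the offender", {
  path <- system.file("extdata", "base_case.yaml", package = "coronaryCEA")
  doc <- yaml::read_yaml(path)
  rewrite <- function(doc) {
    f <- tempfile(fileext = ".yaml")
    yaml::write_yaml(doc, f)
    f
  }
  bad <- doc
  bad$costs$CABG$stable$low <- 99999   # low > high
  expect_error(load_parameters(rewrite(bad)), "cost.CABG.stable")
  bad <- doc
  bad$utilities$SAQ$PCI$cva <- NULL    # missing utility entry
  expect_error(load_parameters(rewrite(bad)), "utility.SAQ.PCI.cva")
  bad <- doc
  bad$transitions$PCI$to_cva$value <- "oops"
  expect_error(load_parameters(rewrite(bad)), "transition.PCI.to_cva")
  expect_error(load_parameters(tempfile()), "not found")
})

test_that("set_param perturbs one entry and clamps probabilities", {
  p <- default_parameters()
  p2 <- set_param(p, "cost.CABG.stable", 3000)
  expect_equal(param_values(p2)[["cost.CABG.stable"]], 3000)
  expect_equal(param_values(p2)[["cost.PCI.stable"]],
               param_values(p)[["cost.PCI.stable"]])
  p3 <- set_param(p, "transition.CABG.stay_stable", 1.04236)
  expect_equal(param_values(p3)[["transition.CABG.stay_stable"]], 1)
  expect_error(set_param(p, "no.such.param", 1), "unknown parameter")
})
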