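test_that("the fourteen input variables carry the printed distributions", {
  v <- input_variables(human_sp)
  expect_equal(nrow(v), 14)
  expect_equal(v$mean[v$name == "glenoid_inclination"], 115.12)
  expect_equal(v$sd[v$name == "glenoid_inclination"], 0.3)
  expect_equal(v$mean[v$name == "stability_ratio"], 0)
  expect_equal(v$sd[v$name == "stability_ratio"], 4)
  vc <- input_variables(chimp_sp)
  expect_equal(vc$mean[vc$name == "stability_ratio"], 13.13)
})

test_that("input draws are seed-reproducible with correct sample moments", {
  v <- input_variables(human_sp)
  x1 <- draw_inputs(v, 50, 7)
  x2 <- draw_inputs(v, 50, 7)
  expect_identical(x1, x2)
  expect_false(identical(x1, draw_inputs(v, 50, 8)))

  ## zero-SD rows collapse to the means
  v0 <- v; v0$sd <- 0
  x0 <- draw_inputs(v0, 10, 1)
  expect_equal(matrix(as.numeric(x0), 10, 14), matrix(v$mean, 10, 14, byrow = TRUE))

  ## law of large numbers: per-column mean and SD within 1% at n = 1e5
  xl <- draw_inputs(v, 1e5, 123)
  expect_equal(unname(apply(xl, 2, mean)), v$mean, tolerance = 0.01 * max(abs(v$mean)))
  expect_equal(unname(apply(xl, 2, stats::sd)), v$sd, tolerance = 0.01)
  expect_true(all(abs(apply(xl, 2, stats::sd) - v$sd) / v$sd < 0.01))
})

test_that("zero input variance collapses the simulation to the deterministic model", {
  v <- input_variables(human_sp)
  v$sd <- 0
  model <- make_instance_model("mid_support", human_sp, seed = 1)
  mc <- run_monte_carlo(model, v, 5, 99)
  det <- solve_instance("mid_support", human_sp, seed = 1)
  expect_equal(mc$n_infeasible, 0)
  for (i in 1:5) {
    expect_equal(unname(mc$samples[i, ]), unname(det$normalized[cuff_outputs()]),
                 tolerance = 1e-9)
  }
})

test_that("Monte Carlo blocks are bit-reproducible for a fixed seed", {
  v <- input_variables(chimp_sp)
  model <- make_instance_model("late_support", chimp_sp, seed = 2)
  m1 <- run_monte_carlo(model, v, 15, 31)
  m2 <- run_monte_carlo(model, v, 15, 31)
  expect_identical(m1$samples, m2$samples)
  expect_identical(m1$n_infeasible, m2$n_infeasible)
})

test_that("CDF construction uses type-7 quantiles at the eleven levels", {
  ## constant samples: every level maps to the constant
  cdf <- build_cdf(rep(40, 150))
  expect_equal(cdf$values, rep(40, 11))
  expect_equal(unname(cdf$percentiles), rep(40, 5))

  ## uniform grid 0..100: median at 50, monotone values
  cdf <- build_cdf(seq(0, 100, length.out = 101))
  expect_equal(cdf$values[6], 50, tolerance = 0.5)
  expect_equal(cdf$levels, c(0.01, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.99))
  expect_true(all(diff(cdf$values) >= 0))
  expect_true(all(diff(cdf$percentiles) >= 0))

  ## infeasible iterations excluded and reported; too few is an error
  cdf <- build_cdf(c(rep(10, 120), rep(NA, 9)))
  expect_equal(cdf$n, 120)
  expect_equal(cdf$n_infeasible, 9)
  expect_error(build_cdf(c(rep(10, 50), rep(NA, 70))), "n_infeasible = 70")
})

test_that("finite-difference sensitivity matches the Gaussian closed form", {
  ## linear toy y = a x + b: S(level) = dnorm(qnorm(level)) / level exactly,
  ## independent of a, b and the input distribution parameters
  vars <- data.frame(name = "x", mean = 3, sd = 0.7)
  simulate <- function(X) matrix(5 * X[, 1] - 2, ncol = 1,
                                 dimnames = list(NULL, "y"))
  levels <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  sens <- mc_sensitivity(simulate, vars, n = 1e5, seed = 17, levels = levels)
  closed <- stats::dnorm(stats::qnorm(levels)) / levels
  expect_equal(as.numeric(sens$factors[1, , 1]), closed, tolerance = 0.05)

  ## sigma-only scaling option: S = |dp/dmu| * sigma = dnorm(qnorm(level))
  sens2 <- mc_sensitivity(simulate, vars, n = 2e4, seed = 17, levels = 0.5,
                          scaling = "sigma")
  expect_equal(as.numeric(sens2$factors[1, 1, 1]), stats::dnorm(0),
               tolerance = 0.05)
})

test_that("an input the model ignores has exactly zero sensitivity", {
  vars <- data.frame(name = c("x", "dummy"), mean = c(0, 10), sd = c(1, 2))
  simulate <- function(X) matrix(2 * X[, 1], ncol = 1, dimnames = list(NULL, "y"))
  sens <- mc_sensitivity(simulate, vars, n = 2000, seed = 5)
  expect_equal(unname(sens$averaged["dummy", "y"]), 0)
  expect_gt(sens$averaged["x", "y"], 0.1)
})

test_that("the default study design enumerates 42 analyses", {
  an <- enumerate_analyses()
  expect_equal(nrow(an), 42)
  expect_equal(nrow(unique(an)), 42)
  expect_setequal(unique(an$species), c("human", "chimpanzee"))
  expect_setequal(unique(an$output), cuff_outputs())
  ## one species, one instance -> 7 analyses
  an1 <- enumerate_analyses(study_config(species = "human",
                                         instances = "mid_support"))
  expect_equal(nrow(an1), 7)
})

test_that("a scaled-down suite produces all 42 analyses with valid CDFs", {
  suite <- shared_suite()
  expect_s3_class(suite, "cuffmc_suite")
  expect_length(suite$results, 42)
  expect_equal(suite$manifest$n_analyses, 42)
  for (r in suite$results) {
    expect_length(r$cdf$levels, 11)
    expect_length(r$cdf$percentiles, 5)
    expect_true(all(diff(r$cdf$values) >= 0))
    expect_true(all(r$cdf$values >= 0 & r$cdf$values <= 100))
    expect_gte(r$cdf$n, 100)
  }
  ## per-run manifest records seeds and infeasibility counts
  expect_length(suite$manifest$runs, 6)
  for (run in suite$manifest$runs) {
    expect_true(is.numeric(run$seed))
    expect_gte(run$n_infeasible, 0)
  }
})
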