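test_that("maximum force is PCSA times specific tension", {
  expect_equal(max_force(2.81, 88), 247.28)
  expect_equal(max_force(human_sp$muscle_elements$teres_minor, 88), 247.28)
  expect_equal(max_force(5.62, 88), 2 * max_force(2.81, 88))   # linearity
  expect_equal(max_force(1e-9, 88), 88e-9)
  expect_error(max_force(2.81, 0), "sigma_max")
})

test_that("stability evaluation decomposes compression and shear correctly", {
  fr <- glenoid_frame(c(0, 0, 0), c(0, 0.05, 0))
  ratios <- c(0.4, 0.6, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)

  ## pure compression: margins are ratio_d * F_c, positive
  se <- stability_eval(c(0, 0, -200), fr, ratios)
  expect_equal(se$margins, ratios * 200)
  expect_equal(se$compression, 200)
  expect_false(se$dislocating)

  ## shear exactly ratio_d * F_c along a rim direction: zero margin
  se <- stability_eval(c(0, 0.4 * 100, -100), fr, ratios)  # superior shear
  expect_equal(se$margin, 0, tolerance = 1e-9)
  expect_equal(se$margins[1], 0, tolerance = 1e-9)
  expect_equal(se$allowable_ratio, 0.4)

  ## shear at 22.5 deg between ratios 0.4 and 0.6: allowable 0.5 by interpolation
  az <- pi / 8
  shear_dir <- sin(az) * fr$x_axis + cos(az) * fr$y_axis
  se <- stability_eval(50 * shear_dir + c(0, 0, -100), fr, ratios)
  expect_equal(se$allowable_ratio, 0.5, tolerance = 1e-9)
  expect_equal(se$margin, 0.5 * 100 - 50, tolerance = 1e-9)

  ## dislocating load: no compression with nonzero shear, all margins negative
  se <- stability_eval(c(0, 80, 10), fr, ratios)
  expect_true(se$dislocating)
  expect_true(all(se$margins < 0))
})

test_that("zero external load yields the all-zero force solution", {
  arms <- matrix(c(0, 0, 0.03, 0, 0, 0.05), 3, 2)
  pulls <- matrix(c(0, -0.6, -0.8, 0, -0.6, -0.8), 3, 2)
  colnames(arms) <- colnames(pulls) <- c("m1", "m2")
  sol <- solve_muscle_forces(toy_geom(arms, pulls), toy_load(), fmax = c(1000, 1000))
  expect_true(sol$feasible)
  expect_equal(unname(sol$forces), c(0, 0), tolerance = 1e-6)
  expect_lt(sol$equilibrium_residual, 1e-6)
})

test_that("p = 2 solutions match the closed-form stress-weighted sharing", {
  a <- c(0.03, 0.05); M <- 10; Fm <- c(1000, 1000)
  arms <- rbind(0, 0, a); colnames(arms) <- c("m1", "m2")
  pulls <- matrix(c(0, 0, -1, 0, 0, -1), 3, 2, dimnames = list(NULL, c("m1", "m2")))
  sol <- solve_muscle_forces(toy_geom(arms, pulls), toy_load(moment = c(0, 0, -M)),
                             fmax = Fm, p = 2, stability = FALSE)
  closed <- Fm^2 * a * M / sum(a^2 * Fm^2)
  expect_true(sol$feasible)
  expect_equal(unname(sol$forces), closed, tolerance = 1e-4)

  ## independent dense grid search on the single degree of freedom
  f0 <- c(0, M / a[2]); dir <- c(a[2], -a[1])
  best <- grid_oracle_1d(f0, dir, Fm, p = 2)
  expect_lt(max(abs(sol$forces - best$f)), 1e-3)
  expect_lte(sol$objective, best$value + 1e-9)
})

test_that("p = 3 solutions with two moment constraints match grid search", {
  A <- rbind(c(0.02, -0.01, 0.015), c(0, 0, 0), c(0.03, 0.05, -0.01))
  colnames(A) <- paste0("m", 1:3)
  pulls <- matrix(rep(c(0, 0, -1), 3), 3, 3, dimnames = list(NULL, paste0("m", 1:3)))
  Fm <- c(600, 800, 700)
  b <- c(4, 0, 6)
  sol <- solve_muscle_forces(toy_geom(A, pulls), toy_load(moment = -b),
                             fmax = Fm, p = 3, stability = FALSE)
  expect_true(sol$feasible)
  expect_lt(sol$equilibrium_residual, 1e-6)

  f0 <- c(200, 0, 0)                       # A f0 = b
  dir <- c(-0.5, 0.5, 1)                   # null direction of the two rows
  best <- grid_oracle_1d(f0, dir, Fm, p = 3)
  expect_lt(max(abs(sol$forces - best$f)), 1e-3)
  expect_lte(sol$objective, best$value + 1e-9)

  ## scaling all capacities and the demanded moments together leaves
  ## normalized forces invariant (homogeneous objective)
  sol2 <- solve_muscle_forces(toy_geom(A, pulls), toy_load(moment = -2.5 * b),
                              fmax = 2.5 * Fm, p = 3, stability = FALSE)
  expect_equal(sol2$normalized, sol$normalized, tolerance = 1e-3)
})

test_that("a binding stability margin recruits a zero-moment stabilizer", {
  ## m1: inferiorly-directed stabilizer with no moment arm; m2: mover
  arms <- rbind(0, 0, c(0, 0.02)); colnames(arms) <- c("stabilizer", "mover")
  pulls <- matrix(c(0, -1, 0, 0, -0.2, -0.98), 3, 2,
                  dimnames = list(NULL, c("stabilizer", "mover")))
  Fm <- c(1000, 1000)
  load <- toy_load(moment = c(0, 0, -4), demand = c(0, -500, 0))
  geom <- toy_geom(arms, pulls, ratios = rep(0.5, 8))

  unc <- solve_muscle_forces(geom, load, Fm, p = 2, stability = FALSE)
  se_unc <- stability_eval(-load$gh_force_demand +
                             as.numeric(pulls %*% unc$forces), geom$frame, geom$ratios)
  expect_lt(se_unc$margin, 0)                # unconstrained optimum violates margin
  expect_lt(unc$forces[["stabilizer"]], 1e-3)

  sol <- solve_muscle_forces(geom, load, Fm, p = 2, stability = TRUE)
  expect_true(sol$feasible)
  expect_gt(sol$forces[["stabilizer"]], 100)  # recruited
  ## closed form: mover fixed at 200 by the moment; stabilizer at margin = 0
  expect_equal(sol$forces[["mover"]], 200, tolerance = 1e-3)
  expect_equal(sol$forces[["stabilizer"]], 362, tolerance = 1e-3)

  ## dense grid oracle over the single free force with the margin filter
  mt <- margin_t_fun(c(0, 200), c(1, 0), pulls, -load$gh_force_demand,
                     geom$frame, 0.5)
  best <- grid_oracle_1d(c(0, 200), c(1, 0), Fm, p = 2,
                         feasible_t = function(ts) mt(ts) >= 0)
  expect_lt(max(abs(sol$forces - best$f)), 1e-3)
})

test_that("four-muscle problems with binding stability match grid search", {
  A <- cbind(c(0.02, 0, 0), c(0, 0.02, 0), c(0, 0, 0.02), c(-0.01, -0.01, -0.01))
  colnames(A) <- paste0("m", 1:4)
  pulls <- cbind(c(0, -1, 0), c(0, -0.8, -0.6), c(0, -0.6, -0.8),
                 c(0, -0.2, -0.9798))
  colnames(pulls) <- paste0("m", 1:4)
  Fm <- rep(1000, 4)
  load <- toy_load(moment = -c(2, 2, 2), demand = c(0, -400, 0))
  geom <- toy_geom(A, pulls, ratios = rep(0.5, 8))

  sol <- solve_muscle_forces(geom, load, Fm, p = 3, stability = TRUE)
  expect_true(sol$feasible)
  expect_lt(sol$equilibrium_residual, 1e-6)
  expect_gte(sol$stability$margin, -1e-6)

  mt <- margin_t_fun(c(100, 100, 100, 0), c(1, 1, 1, 2), pulls,
                     -load$gh_force_demand, geom$frame, 0.5)
  best <- grid_oracle_1d(c(100, 100, 100, 0), c(1, 1, 1, 2), Fm, p = 3,
                         feasible_t = function(ts) mt(ts) >= -1e-9)
  expect_lt(max(abs(sol$forces - best$f)), 1e-3)
  expect_lte(sol$objective, best$value + 1e-9)
})

test_that("unattainable moment demands are flagged infeasible, not thrown", {
  arms <- rbind(0, 0, c(0.02, 0.01)); colnames(arms) <- c("m1", "m2")
  pulls <- matrix(c(0, 0, -1, 0, 0, -1), 3, 2, dimnames = list(NULL, c("m1", "m2")))
  sol <- solve_muscle_forces(toy_geom(arms, pulls), toy_load(moment = c(0, 0, -50)),
                             fmax = c(100, 100), stability = FALSE)
  expect_false(sol$feasible)
  expect_gt(sol$equilibrium_residual, 1)
  expect_true(is.list(sol$diagnostics))
})

test_that("deterministic species solutions satisfy all constraints", {
  for (sp in list(human_sp, chimp_sp)) {
    for (inst in c("early_support", "mid_support", "late_support")) {
      sol <- solve_instance(inst, sp)
      expect_true(sol$feasible, label = paste(sp$species_id, inst))
      expect_lt(sol$equilibrium_residual, 1e-6)
      expect_gte(sol$stability$margin, -1e-6)
      expect_true(all(sol$normalized >= 0 & sol$normalized <= 100))
      expect_true(all(sol$stability_margins >= -1e-6))
    }
  }
})
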