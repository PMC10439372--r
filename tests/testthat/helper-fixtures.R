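## Shared fixtures: packaged species sets (loaded once per test run) and
## small toy-problem builders used by the optimizer oracle tests.

human_sp <- load_species(species_config_path("human"))
chimp_sp <- load_species(species_config_path("chimpanzee"))

## Printed PCSA table (absolute cm^2, relative cm^2/kg) for both species.
printed_pcsa <- data.frame(
  element = c("deltoid_middle", "deltoid_posterior", "deltoid_anterior",
              "infraspinatus_upper", "infraspinatus_lower",
              "subscapularis_upper", "subscapularis_middle", "subscapularis_lower",
              "supraspinatus", "teres_minor"),
  human_abs = c(7.42, 4.29, 8.84, 6.37, 7.67, 2.83, 3.72, 5.10, 3.15, 2.81),
  chimp_abs = c(28.95, 11.06, 12.10, 11.08, 13.34, 11.19, 14.71, 20.17, 19.92, 5.48),
  human_rel = c(0.103, 0.060, 0.123, 0.088, 0.107, 0.039, 0.052, 0.071, 0.044, 0.039),
  chimp_rel = c(0.643, 0.246, 0.269, 0.246, 0.296, 0.249, 0.327, 0.448, 0.443, 0.122)
)

## A planar toy muscle system: n elements with hand-set moment-arm columns
## and pull directions, a neutral glenoid frame, and isotropic ratios.
toy_geom <- function(arms, pulls, ratios = rep(0.6, 8)) {
  frame <- glenoid_frame(c(0, 0, 0), c(0, 0.05, 0))
  list(moment_arms = arms, pull_dirs = pulls, frame = frame, ratios = ratios)
}

toy_load <- function(moment = c(0, 0, 0), demand = c(0, 0, 0)) {
  list(instance = "toy", gh_moment = moment, gh_force_demand = demand)
}

## Dense 1-D grid-search oracle for toys whose equality constraints leave a
## single degree of freedom: f = f0 + t * dir, t scanned densely over the
## box. `p` is the stress-objective exponent; `feasible_t` optionally maps
## the t-grid to a logical feasibility mask (vectorized).
grid_oracle_1d <- function(f0, dir, fmax, p, feasible_t = NULL,
                           n_grid = 400001L) {
  t_bounds <- c(-Inf, Inf)
  for (i in seq_along(f0)) {
    if (abs(dir[i]) < 1e-15) next
    rng <- sort(c((0 - f0[i]) / dir[i], (fmax[i] - f0[i]) / dir[i]))
    t_bounds <- c(max(t_bounds[1], rng[1]), min(t_bounds[2], rng[2]))
  }
  scan <- function(lo, hi) {
    ts <- seq(lo, hi, length.out = n_grid)
    Fmat <- outer(ts, dir) + matrix(f0, length(ts), length(f0), byrow = TRUE)
    obj <- rowSums(sweep(Fmat, 2, fmax, `/`)^p)
    if (!is.null(feasible_t)) obj[!feasible_t(ts)] <- Inf
    k <- which.min(obj)
    list(value = obj[k], f = Fmat[k, ], t = ts[k], step = ts[2] - ts[1])
  }
  best <- scan(t_bounds[1], t_bounds[2])
  ## refine around the coarse optimum for sub-millinewton resolution
  best2 <- scan(max(t_bounds[1], best$t - 2 * best$step),
                min(t_bounds[2], best$t + 2 * best$step))
  if (best2$value <= best$value) best2 else best
}

## Vectorized stability margin over the same 1-D family, for isotropic
## ratio profiles: margin(t) = ratio * comp(t) - |shear(t)|.
margin_t_fun <- function(f0, dir, pulls, r0, frame, ratio) {
  R0 <- r0 + as.numeric(pulls %*% f0)
  Rv <- as.numeric(pulls %*% dir)
  function(ts) {
    a <- sum(R0 * frame$x_axis) + ts * sum(Rv * frame$x_axis)
    b <- sum(R0 * frame$y_axis) + ts * sum(Rv * frame$y_axis)
    comp <- -(sum(R0 * frame$z_axis) + ts * sum(Rv * frame$z_axis))
    ratio * comp - sqrt(a^2 + b^2)
  }
}
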