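## Internal muscle force prediction: stress-based static optimization with
## moment equilibrium, force bounds, and the eight-direction glenoid
## stability constraint.

#' Maximum force capacity of a muscle element
#'
#' `absolute PCSA x specific tension`. The specific tension of the original
#' models is unpublished; the package default is 88 N/cm^2 and is exposed in
#' the study configuration. Normalized (percentage) force outputs depend on
#' it only through the force bounds.
#'
#' @param element A muscle element spec (from a `cuffmc_species`), or a
#'   numeric PCSA in cm^2.
#' @param sigma_max Specific tension, N/cm^2 (> 0).
#' @return Maximum isometric force, N.
#' @export
max_force <- function(element, sigma_max = 88) {
  if (sigma_max <= 0) stop("sigma_max must be > 0", call. = FALSE)
  pcsa <- if (is.list(element)) element$absolute_pcsa else element
  pcsa * sigma_max
}

.rim_azimuths <- seq(0, 2 * pi - pi / 4, by = pi / 4)  # superior -> anterior ...

## interpolated allowable ratio at shear azimuth (radians from superior
## toward anterior), plus local slope for gradients
.ratio_at <- function(az, ratios) {
  az <- az %% (2 * pi)
  idx <- floor(az / (pi / 4))
  frac <- az / (pi / 4) - idx
  i1 <- (idx %% 8) + 1
  i2 <- ((idx + 1) %% 8) + 1
  list(value = (1 - frac) * ratios[i1] + frac * ratios[i2],
       slope = (ratios[i2] - ratios[i1]) / (pi / 4))
}

#' Evaluate the glenoid stability constraint for a joint reaction
#'
#' Decomposes the glenoid reaction force in the glenoid frame: compression
#' is the component along `-z` (into the glenoid face), shear is the
#' in-plane remainder. The allowable shear-to-compression ratio at the shear
#' azimuth is linearly interpolated between the two adjacent 45-degree rim
#' directions; the scalar stability margin is
#' `allowable_ratio * compression - |shear|`. Eight per-direction margins
#' are also reported: the shear magnitude is attributed to the two rim
#' directions adjacent to its azimuth with linear angular weights, and
#' `margin_d = ratio_d * compression - attributed shear_d`. A
#' non-positive compression with nonzero shear is a dislocating load: all
#' margins are reported negative and flagged.
#'
#' @param reaction Reaction force on the glenoid, world 3-vector (N).
#' @param frame A `cuffmc_glenoid_frame`.
#' @param ratios Length-8 numeric vector of directional stability ratios
#'   (or a `cuffmc_stability` object, whose offset-applied baseline is used).
#' @return List: `margins` (length 8, N), `margin` (scalar azimuth margin,
#'   N), `allowable_ratio`, `compression` (N), `shear` (in-plane 2-vector,
#'   components along the frame x/y axes, N), `dislocating` flag.
#' @export
stability_eval <- function(reaction, frame, ratios) {
  stopifnot(inherits(frame, "cuffmc_glenoid_frame"))
  if (inherits(ratios, "cuffmc_stability")) ratios <- ratios$baseline
  stopifnot(length(ratios) == 8)
  a <- sum(reaction * frame$x_axis)   # anterior shear
  b <- sum(reaction * frame$y_axis)   # superior shear
  comp <- -sum(reaction * frame$z_axis)
  smag <- sqrt(a * a + b * b)

  if (comp <= 0 && smag > 0) {
    return(list(margins = ratios * comp - smag, margin = -smag + min(ratios) * comp,
                allowable_ratio = NA_real_, compression = comp,
                shear = c(anterior = a, superior = b), dislocating = TRUE))
  }

  if (smag == 0) {
    margins <- ratios * comp
    return(list(margins = margins, margin = min(margins),
                allowable_ratio = NA_real_, compression = comp,
                shear = c(anterior = 0, superior = 0), dislocating = FALSE))
  }

  az <- atan2(a, b) %% (2 * pi)      # 0 = superior, increasing anteriorly
  r <- .ratio_at(az, ratios)
  idx <- floor(az / (pi / 4))
  frac <- az / (pi / 4) - idx
  w <- numeric(8)
  w[(idx %% 8) + 1] <- 1 - frac
  w[((idx + 1) %% 8) + 1] <- frac
  margins <- ratios * comp - w * smag
  list(margins = margins, margin = r$value * comp - smag,
       allowable_ratio = r$value, compression = comp,
       shear = c(anterior = a, superior = b), dislocating = FALSE)
}

## smooth stability margin + gradient wrt muscle forces, for the solver
.stability_gfun <- function(U, r0, frame, ratios, eps = 1e-8) {
  ux <- as.numeric(crossprod(frame$x_axis, U))
  uy <- as.numeric(crossprod(frame$y_axis, U))
  uz <- as.numeric(crossprod(frame$z_axis, U))
  r0x <- sum(r0 * frame$x_axis); r0y <- sum(r0 * frame$y_axis)
  r0z <- sum(r0 * frame$z_axis)
  function(f) {
    a <- r0x + sum(ux * f)
    b <- r0y + sum(uy * f)
    comp <- -(r0z + sum(uz * f))
    s2 <- a * a + b * b
    smag <- sqrt(s2 + eps * eps)
    if (s2 < 1e-16) {
      rr <- list(value = min(ratios), slope = 0)
      daz <- numeric(length(f))
    } else {
      az <- atan2(a, b) %% (2 * pi)
      rr <- .ratio_at(az, ratios)
      daz <- (b * ux - a * uy) / s2
    }
    val <- rr$value * comp - smag
    grad <- rr$value * (-uz) + comp * rr$slope * daz - (a * ux + b * uy) / smag
    list(value = val, grad = grad)
  }
}

#' Solve for muscle element forces by constrained static optimization
#'
#' Minimizes the stress-based cost `sum((f_i / fmax_i)^p)` subject to
#' moment equilibrium about all three glenohumeral axes
#' (`moment_arms %*% f = -gh_moment`), force bounds `0 <= f_i <= fmax_i`,
#' and (optionally) the glenoid stability constraint that the dislocating
#' shear of the joint reaction not exceed the azimuth-interpolated
#' allowable ratio times the compressive force. The joint reaction on the
#' glenoid is `pull_dirs %*% f - gh_force_demand` (muscle pull transmitted
#' to the humerus plus the net external force on the arm). Non-convergence
#' or constraint violation yields `feasible = FALSE` with diagnostics; the
#' constraints are never silently relaxed.
#'
#' @param geom Model geometry from [build_model_geometry()] (fields
#'   `moment_arms`, `pull_dirs`, `frame`, `ratios`), or a list with those
#'   fields for toy problems.
#' @param load A `cuffmc_load` (or list with `gh_moment`,
#'   `gh_force_demand`).
#' @param fmax Per-element maximum forces, N.
#' @param pcsa Per-element PCSAs (used only for reporting; bounds encode
#'   the stress objective scale).
#' @param p Objective exponent (2 or 3; default 3).
#' @param stability Apply the stability constraint? Default `TRUE`.
#' @param tol_eq Equilibrium feasibility tolerance, N m.
#' @param tol_stab Stability feasibility tolerance, N.
#' @return Object of class `cuffmc_solution`: `forces` (N, named),
#'   `normalized` (percent of maximum force), `reaction` (N, world),
#'   `equilibrium_residual` (N m), `stability_margins` (8, N),
#'   `stability` (full [stability_eval()] result), `feasible`, `objective`,
#'   `diagnostics`.
#' @export
solve_muscle_forces <- function(geom, load, fmax, pcsa = NULL, p = 3,
                                stability = TRUE, tol_eq = 1e-6,
                                tol_stab = 1e-6) {
  A <- geom$moment_arms
  U <- geom$pull_dirs
  n <- ncol(A)
  stopifnot(length(fmax) == n, all(fmax > 0))
  beq <- -as.numeric(load$gh_moment)
  r0 <- -as.numeric(load$gh_force_demand)   # net external force on the arm

  obj <- function(f) sum((f / fmax)^p)
  grd <- function(f) p * (f / fmax)^(p - 1) / fmax
  gfun <- if (stability) .stability_gfun(U, r0, geom$frame, geom$ratios) else NULL

  res <- al_solve(obj, grd, x0 = numeric(n), lower = numeric(n), upper = fmax,
                  Aeq = A, beq = beq, gfun = gfun)

  f <- res$par
  reaction <- r0 + as.numeric(U %*% f)
  se <- stability_eval(reaction, geom$frame, geom$ratios)
  feasible <- res$converged && res$eq_residual <= tol_eq &&
    (!stability || se$margin >= -tol_stab)

  structure(list(
    instance = load$instance %||% NA_character_,
    forces = stats::setNames(f, colnames(A)),
    normalized = stats::setNames(100 * f / fmax, colnames(A)),
    reaction = reaction,
    equilibrium_residual = res$eq_residual,
    stability_margins = se$margins,
    stability = se,
    feasible = feasible,
    objective = res$objective,
    diagnostics = list(converged = res$converged,
                       outer_iterations = res$outer_iterations,
                       ineq_violation = res$ineq_violation)
  ), class = "cuffmc_solution")
}

#' @export
print.cuffmc_solution <- function(x, ...) {
  cat(sprintf("<cuffmc_solution> %s, feasible=%s, eq residual %.2e N*m\n",
              x$instance, x$feasible, x$equilibrium_residual))
  print(round(x$normalized, 2))
  invisible(x)
}

#' The seven rotator cuff output elements, in reporting order
#'
#' @return Character vector of the seven cuff element names whose
#'   normalized forces are the probabilistic outputs.
#' @export
cuff_outputs <- function() {
  c("infraspinatus_upper", "infraspinatus_lower",
    "subscapularis_upper", "subscapularis_middle", "subscapularis_lower",
    "supraspinatus", "teres_minor")
}

#' Build the deterministic model state and solve one support instance
#'
#' Convenience wrapper running the full pipeline for a single model state:
#' posture, geometry (optionally perturbed), external load, and the
#' constrained force solution.
#'
#' @inheritParams generate_posture
#' @param sigma_max Specific tension, N/cm^2.
#' @param p Objective exponent.
#' @param group_draws,inclination_shift_cm,stability_pct_draw Perturbation
#'   state passed to [build_model_geometry()].
#' @param posture,bones Optional pre-built fixtures.
#' @return A `cuffmc_solution`.
#' @export
solve_instance <- function(instance, species, seed = 1L, sigma_max = 88, p = 3,
                           group_draws = NULL, inclination_shift_cm = 0,
                           stability_pct_draw = NULL, posture = NULL,
                           bones = NULL) {
  posture <- posture %||% generate_posture(instance, species, seed)
  geom <- build_model_geometry(species, posture, group_draws,
                               inclination_shift_cm, stability_pct_draw)
  load <- external_load(instance, species, posture = posture)
  fmax <- vapply(species$muscle_elements, max_force, 0, sigma_max = sigma_max)
  solve_muscle_forces(geom, load, fmax, p = p)
}
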