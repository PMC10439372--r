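## Static inverse dynamics of the support phase: substrate hand force and
## the net glenohumeral moment / reaction-force demand.

## Winter-style centre-of-mass locations, fraction of segment length from
## the proximal joint.
.com_fractions <- list(arm = 0.436, forearm = 0.430, hand = 0.506)

#' Substrate hand force for a support instance
#'
#' Hand forces equal half of body weight in the double-support instances
#' (early and late support) and full body weight in the single-support
#' instance (mid support), directed as the upward substrate reaction at the
#' hand.
#'
#' @param instance Support instance.
#' @param body_mass Body mass, kg (> 0... zero allowed for the degenerate
#'   massless check).
#' @param g Gravitational acceleration, m/s^2 (default 9.81).
#' @return Force 3-vector, N (world frame, +y up).
#' @export
#' @examples
#' hand_force("mid_support", 72)    # magnitude 706.32 N
#' hand_force("early_support", 45)  # magnitude 220.725 N
hand_force <- function(instance, body_mass, g = 9.81) {
  instance <- match.arg(instance, .instances)
  if (body_mass < 0) stop("body_mass must be >= 0", call. = FALSE)
  frac <- if (instance == "mid_support") 1 else 0.5
  c(0, frac * body_mass * g, 0)
}

#' Net glenohumeral load from a posture and applied forces
#'
#' Quasi-static inverse dynamics for the arm free body: the moment about the
#' glenohumeral centre is the sum of `r x F` over the hand force (applied at
#' the grip point) and segment weights (applied at segment centres of mass);
#' the reaction-force demand is `-(hand force + sum of segment weights)`,
#' i.e. the net joint contact force the glenoid must supply absent muscles.
#' Both outputs are exactly linear in the applied forces.
#'
#' @param posture A `cuffmc_posture`.
#' @param hand_force Applied hand force 3-vector, N.
#' @param segment_masses Named list/vector with `arm`, `forearm`, `hand`
#'   masses in kg.
#' @param g Gravitational acceleration, m/s^2.
#' @return Object of class `cuffmc_load`: `instance`, `hand_force`,
#'   `gh_moment` (N m), `gh_force_demand` (N).
#' @export
gh_load <- function(posture, hand_force, segment_masses, g = 9.81) {
  stopifnot(inherits(posture, "cuffmc_posture"))
  gh <- posture$gh
  coms <- list(
    arm = gh + .com_fractions$arm * (posture$elbow - gh),
    forearm = posture$elbow + .com_fractions$forearm * (posture$wrist - posture$elbow),
    hand = posture$wrist + .com_fractions$hand * (posture$hand_point - posture$wrist) * 2
  )
  moment <- cross3(posture$hand_point - gh, hand_force)
  net_force <- hand_force
  for (s in c("arm", "forearm", "hand")) {
    w <- c(0, -as.numeric(segment_masses[[s]]) * g, 0)
    moment <- moment + cross3(coms[[s]] - gh, w)
    net_force <- net_force + w
  }
  structure(list(
    instance = posture$instance,
    hand_force = hand_force,
    gh_moment = moment,
    gh_force_demand = -net_force
  ), class = "cuffmc_load")
}

#' Segment masses for a species
#'
#' @param species A `cuffmc_species`.
#' @return Named list of segment masses (kg) from the configured
#'   anthropometric mass fractions.
#' @export
segment_masses <- function(species) {
  lapply(species$segment_mass_fractions, function(f) f * species$body_mass)
}

#' External load for a species and support instance
#'
#' Convenience wrapper: species hand-force rule plus static inverse dynamics
#' on the instance posture.
#'
#' @inheritParams generate_posture
#' @param posture Optional pre-built posture (default: generated from
#'   `instance`, `species`, `seed`).
#' @param g Gravitational acceleration.
#' @return A `cuffmc_load`.
#' @export
external_load <- function(instance, species, posture = NULL, seed = 1L, g = 9.81) {
  posture <- posture %||% generate_posture(instance, species, seed)
  gh_load(posture, hand_force(instance, species$body_mass, g),
          segment_masses(species), g)
}
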