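## Synthetic study fixtures: static support-phase postures of horizontal
## bimanual arm suspension and parametric bone geometry. The raw kinematics
## behind the original deterministic models are unpublished, so these
## fixtures are idealized three-point arm configurations consistent with the
## task description: arm elevated above 100 degrees, elbow near-extended,
## with the hand over the overhead support.
##
## World frame: right-handed, x anterior, y superior, z lateral (right side).
## Angles in degrees at the interface, radians internally.

.instances <- c("early_support", "mid_support", "late_support")

## Whole-arm lean (degrees anterior of vertical) and elbow flexion per
## static instance. Mid support is the single-support instance with the hand
## directly above the glenohumeral joint.
.posture_spec <- list(
  early_support = list(lean = 3,  forearm_angle = -1.5),
  mid_support   = list(lean = 0,  forearm_angle = 0),
  late_support  = list(lean = -1.5, forearm_angle = 0.75)
)

#' Generate a static support-phase posture
#'
#' Builds an idealized right-arm suspension posture for one of the three
#' static support instances. The humerus leans a few degrees anterior
#' (early), vertical (mid), or posterior (late) of the vertical through the
#' glenohumeral joint, with a near-extended elbow; a small seeded angular
#' jitter (SD 0.05 degrees, zero for mid support lean) makes distinct seeds
#' distinct while keeping every posture inside the task envelope.
#'
#' @param instance One of `"early_support"`, `"mid_support"`, `"late_support"`.
#' @param species A `cuffmc_species` parameter set (segment lengths are taken
#'   from it).
#' @param seed Integer seed; postures are bit-identical for a fixed seed.
#' @return Object of class `cuffmc_posture`: joint centres (`gh`, `elbow`,
#'   `wrist`), `hand_point` (grip), `acromion_marker`, elevation and flexion
#'   angles (degrees).
#' @export
generate_posture <- function(instance, species, seed = 1L) {
  instance <- match.arg(instance, .instances)
  stopifnot(inherits(species, "cuffmc_species"))
  ps <- .posture_spec[[instance]]

  ## seeded jitter, independent of species so that chimpanzee postures are
  ## exact segment-rescalings of the human ones (same kinematic inputs)
  rs <- .with_seed(seed + match(instance, .instances) * 1000L, function() {
    stats::rnorm(2, 0, 0.05)
  })
  lean <- ps$lean + if (instance == "mid_support") 0 else rs[1]
  fore_angle <- ps$forearm_angle + if (instance == "mid_support") 0 else 0.5 * rs[2]

  gh <- c(0, 1.40, 0.20)
  L <- species$segment_lengths
  hdir <- c(sin(deg2rad(lean)), cos(deg2rad(lean)), 0)
  fdir <- c(sin(deg2rad(fore_angle)), cos(deg2rad(fore_angle)), 0)
  elbow <- gh + L$arm * hdir
  wrist <- elbow + L$forearm * fdir
  hand_point <- wrist + 0.5 * L$hand * fdir

  structure(list(
    instance = instance,
    species_id = species$species_id,
    gh = gh, elbow = elbow, wrist = wrist, hand_point = hand_point,
    acromion_marker = gh + as.numeric(species$fixture$acromion_offset),
    humerothoracic_elevation = .elevation_deg(gh, elbow),
    elbow_flexion = .flexion_deg(gh, elbow, wrist)
  ), class = "cuffmc_posture")
}

.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483629))
  fn()
}

.elevation_deg <- function(gh, elbow) {
  hum <- unitize(elbow - gh)
  rad2deg(acos(max(-1, min(1, sum(hum * c(0, -1, 0))))))
}

.flexion_deg <- function(gh, elbow, wrist) {
  a <- unitize(gh - elbow)
  b <- unitize(wrist - elbow)
  180 - rad2deg(acos(max(-1, min(1, sum(a * b)))))
}

#' Rescale a human posture to chimpanzee segment lengths
#'
#' Translates the wrist, elbow and hand points along the unchanged segment
#' directions so that segment magnitudes equal the chimpanzee arm and forearm
#' lengths; joint orientation is preserved exactly. The acromion marker is
#' shifted to the chimpanzee scapular offset without rotating any segment.
#'
#' @param human_posture A `cuffmc_posture` built from the human model.
#' @param chimp The chimpanzee `cuffmc_species` parameter set.
#' @return A `cuffmc_posture` with chimpanzee segment lengths.
#' @export
rescale_to_chimpanzee <- function(human_posture, chimp) {
  stopifnot(inherits(human_posture, "cuffmc_posture"),
            inherits(chimp, "cuffmc_species"))
  p <- human_posture
  if (vnorm(p$elbow - p$gh) < 1e-9 || vnorm(p$wrist - p$elbow) < 1e-9) {
    stop("degenerate (zero-length) segment in input posture", call. = FALSE)
  }
  L <- chimp$segment_lengths
  hdir <- unitize(p$elbow - p$gh)
  fdir <- unitize(p$wrist - p$elbow)
  elbow <- p$gh + L$arm * hdir
  wrist <- elbow + L$forearm * fdir
  hand_dir <- if (vnorm(p$hand_point - p$wrist) < 1e-12) fdir else unitize(p$hand_point - p$wrist)
  structure(list(
    instance = p$instance,
    species_id = chimp$species_id,
    gh = p$gh, elbow = elbow, wrist = wrist,
    hand_point = wrist + 0.5 * L$hand * hand_dir,
    acromion_marker = p$gh + as.numeric(chimp$fixture$acromion_offset),
    humerothoracic_elevation = .elevation_deg(p$gh, elbow),
    elbow_flexion = .flexion_deg(p$gh, elbow, wrist)
  ), class = "cuffmc_posture")
}

#' Distance from glenoid centroid to the superior glenoid landmark
#'
#' Chosen so that the printed inclination standard deviation (in cm of
#' mediolateral landmark shift) spans approximately a 20 degree total
#' inclination range over +/- 3 SD: `distance = 3 * sd / tan(10 deg)`.
#'
#' @param inclination_sd_cm Landmark SD in centimetres.
#' @return Centroid-to-superior-point distance in metres.
#' @export
glenoid_superior_distance <- function(inclination_sd_cm) {
  3 * (inclination_sd_cm / 100) / tan(deg2rad(10))
}

#' Generate parametric bone geometry for a species
#'
#' Builds template scapula and humerus geometries in their bone frames:
#' the scapula as a flat attachment region behind the glenoid (landmarks:
#' glenoid centroid at the frame origin, superior glenoid point, superior
#' scapular reference, fossa bounding box), the humerus with its head sphere
#' and shaft cylinder wrap objects and the deltoid tuberosity landmark.
#' The template is fully parametric in the species' bone lengths and wrap
#' radii; output is deterministic (the seed argument is accepted for
#' interface symmetry with the posture generator and does not alter the
#' template).
#'
#' @param species A `cuffmc_species` parameter set.
#' @param seed Integer seed (kept for interface uniformity; geometry is
#'   deterministic).
#' @return Named list with `cuffmc_bone` objects `scapula` and `humerus`.
#' @export
generate_bone_geometry <- function(species, seed = 1L) {
  stopifnot(inherits(species, "cuffmc_species"))
  fx <- species$fixture
  Ls <- species$bone_lengths$scapula
  Lh <- species$bone_lengths$humerus
  d_sup <- glenoid_superior_distance(species$glenoid_inclination_sd)

  scapula <- structure(list(
    bone = "scapula",
    longitudinal_length = Ls,
    landmark_set = list(
      glenoid_centroid = c(0, 0, 0),
      glenoid_superior = c(0, d_sup, 0),
      superior_reference = c(0, fx$scapula_top_fraction * Ls, 0),
      fossa_min = c(-0.25 * Ls, -Ls, -Ls),
      fossa_max = c(0.25 * Ls, fx$scapula_top_fraction * Ls, 0.1 * Ls)
    ),
    wrap_objects = list()
  ), class = "cuffmc_bone")

  humerus <- structure(list(
    bone = "humerus",
    longitudinal_length = Lh,
    landmark_set = list(
      gh_centre = c(0, 0, 0),
      deltoid_tuberosity = c(0, 0.369 * Lh, 0.064 * Lh),
      distal_end = c(0, Lh, 0)
    ),
    wrap_objects = list(
      humeral_head = list(type = "sphere", centre = c(0, 0, 0),
                          radius = fx$humeral_head_radius, bone = "humerus"),
      shaft_cylinder = list(type = "cylinder", point = c(0, 0, 0),
                            axis = c(0, 1, 0), radius = fx$shaft_radius,
                            bone = "humerus")
    )
  ), class = "cuffmc_bone")

  list(scapula = scapula, humerus = humerus)
}

#' Export fixtures as JSON landmark files
#'
#' @param species A `cuffmc_species`.
#' @param seed Integer seed for posture generation.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
export_fixtures <- function(species, seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bones <- generate_bone_geometry(species, seed)
  postures <- lapply(.instances, generate_posture, species = species, seed = seed)
  names(postures) <- .instances
  paths <- c(
    bones = file.path(dir, sprintf("%s_bones.json", species$species_id)),
    postures = file.path(dir, sprintf("%s_postures.json", species$species_id))
  )
  jsonlite::write_json(lapply(bones, unclass), paths[["bones"]],
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(postures, unclass), paths[["postures"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
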