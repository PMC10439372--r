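## Geometry engine: glenoid coordinate frame and inclination, attachment
## perturbation and element coupling, string-muscle paths with spherical and
## cylindrical wrapping, and moment arms about the glenohumeral centre.

#' Construct a glenoid coordinate frame
#'
#' @param centroid Glenoid centroid, world 3-vector (m).
#' @param superior_point Superior glenoid landmark, world 3-vector (m).
#' @param anterior Reference anterior direction used to build the
#'   anterior-posterior x axis (default world +x).
#' @return Object of class `cuffmc_glenoid_frame` with orthonormal `x_axis`
#'   (anterior), `y_axis` (centroid to superior point), `z_axis` (lateral,
#'   the compression direction is `-z_axis`), and `inclination_angle`
#'   (degrees from the neutral frame whose y axis is world-superior).
#' @export
glenoid_frame <- function(centroid, superior_point, anterior = c(1, 0, 0)) {
  y <- unitize(superior_point - centroid)
  x <- unitize(anterior - sum(anterior * y) * y)
  z <- cross3(x, y)
  structure(list(
    centroid = centroid,
    superior_point = superior_point,
    x_axis = x, y_axis = y, z_axis = z,
    inclination_angle = rad2deg(atan2(sum(y * c(0, 0, 1)), sum(y * c(0, 1, 0))))
  ), class = "cuffmc_glenoid_frame")
}

#' Incline the glenoid by shifting its superior landmark
#'
#' The superior glenoid point travels along a rotation arc about the
#' anterior-posterior x axis through the centroid; the rotation angle is
#' `atan2(shift, d)` where `d` is the centroid-to-superior distance, so a
#' one-SD mediolateral landmark shift corresponds to one third of a
#' 10 degree half-range. The centroid and x axis are preserved exactly and
#' the axes are re-orthonormalized.
#'
#' @param frame A `cuffmc_glenoid_frame`.
#' @param superior_point_shift_cm Landmark shift in centimetres along the arc
#'   (positive tilts the glenoid face superiorly toward +z).
#' @return A new `cuffmc_glenoid_frame`.
#' @export
incline_glenoid <- function(frame, superior_point_shift_cm) {
  stopifnot(inherits(frame, "cuffmc_glenoid_frame"))
  d <- vnorm(frame$superior_point - frame$centroid)
  theta <- atan2(superior_point_shift_cm / 100, d)
  sup <- frame$centroid +
    rotate_about(frame$superior_point - frame$centroid, frame$x_axis, theta)
  glenoid_frame(frame$centroid, sup, anterior = frame$x_axis)
}

#' Perturb an attachment coordinate
#'
#' Applies independent per-axis Gaussian perturbations to a mean attachment
#' coordinate (fractions of longitudinal bone length): `mean + sd * draw`.
#' Results are clamped to the attachment bounding box (`bounds`, default
#' \[-1, 1\] per axis); each clamp increments the package clamp counter (see
#' [clamp_counter()]) so that simulation runs can report truncation counts
#' while keeping iteration counts exact.
#'
#' @param mean,sd Numeric 3-vectors (fractions of bone length), `sd >= 0`.
#' @param draw Numeric 3-vector of standard-normal deviates.
#' @param bounds Length-2 clamp bounds.
#' @return Perturbed (possibly clamped) 3-vector.
#' @export
perturb_attachment <- function(mean, sd, draw, bounds = c(-1, 1)) {
  if (any(sd < 0)) stop("attachment SD must be >= 0", call. = FALSE)
  out <- mean + sd * draw
  lo <- out < bounds[1]
  hi <- out > bounds[2]
  if (any(lo | hi)) {
    .cuffmc_state$clamp_count <- .cuffmc_state$clamp_count + sum(lo | hi)
    out[lo] <- bounds[1]
    out[hi] <- bounds[2]
  }
  out
}

#' Couple a child element's attachment to its parent
#'
#' Lower/middle elements of multi-element muscles are expressed as per-axis
#' percentage differences from the upper element's coordinates, so the
#' elements translate as a unit under perturbation:
#' `child = parent * (1 + offset)` per axis.
#'
#' @param parent_coords Parent attachment 3-vector (fractions of bone length).
#' @param offsets Per-axis fractional offsets.
#' @return Child attachment 3-vector.
#' @export
#' @examples
#' couple_elements(c(0.2, 0.3, 0.6), c(0.5, -0.1, 0))  # c(0.3, 0.27, 0.6)
couple_elements <- function(parent_coords, offsets) {
  if (any(parent_coords == 0 & offsets != 0)) {
    stop("undefined percentage base: parent coordinate is zero on an axis with nonzero offset",
         call. = FALSE)
  }
  parent_coords * (1 + offsets)
}

## ---- muscle path solving -------------------------------------------------

.tangent_arc_2d <- function(o2, i2, r, hint2) {
  ## 2D circle at the origin; returns NULL when the straight segment clears
  ## the circle, else touch angles and arc for the near-side taut string.
  do <- vnorm(o2); di <- vnorm(i2)
  seg <- i2 - o2
  t <- -sum(o2 * seg) / sum(seg * seg)
  tc <- max(0, min(1, t))
  cp <- o2 + tc * seg
  if (vnorm(cp) >= r) return(NULL)
  phi_o <- atan2(o2[2], o2[1]); phi_i <- atan2(i2[2], i2[1])
  ao <- acos(min(1, r / do)); ai <- acos(min(1, r / di))
  cand <- list()
  for (s in c(1, -1)) {
    t_o <- phi_o + s * ao
    t_i <- phi_i - s * ai
    arc <- ((s * (t_i - t_o)) %% (2 * pi))
    if (arc < pi) {
      mid <- t_o + s * arc / 2
      cand[[length(cand) + 1]] <- list(t_o = t_o, t_i = t_i, arc = arc,
                                       mid = c(cos(mid), sin(mid)))
    }
  }
  if (!length(cand)) return(NULL)
  if (length(cand) == 1) return(cand[[1]])
  ## prefer the side the straight segment already favours (near side); fall
  ## back to the supplied hint for the symmetric through-centre case
  ref <- if (vnorm(cp) > 1e-9) cp else hint2
  scores <- vapply(cand, function(k) sum(k$mid * ref), 0)
  cand[[which.max(scores)]]
}

.solve_sphere_wrap <- function(origin, insertion, centre, r, hint) {
  for (p in list(origin, insertion)) {
    if (vnorm(p - centre) <= r) {
      stop("muscle endpoint lies inside a wrap object", call. = FALSE)
    }
  }
  ov <- origin - centre; iv <- insertion - centre
  n <- cross3(ov, iv)
  if (vnorm(n) < 1e-12) {
    ## collinear with the centre: wrap plane fixed by the hint
    n <- cross3(ov, hint)
    if (vnorm(n) < 1e-12) n <- cross3(ov, c(0, 1, 0))
    if (vnorm(n) < 1e-12) n <- cross3(ov, c(1, 0, 0))
  }
  n <- unitize(n)
  ex <- unitize(ov)
  ey <- cross3(n, ex)
  o2 <- c(sum(ov * ex), sum(ov * ey))
  i2 <- c(sum(iv * ex), sum(iv * ey))
  hint2 <- c(sum(hint * ex), sum(hint * ey))
  sol <- .tangent_arc_2d(o2, i2, r, hint2)
  if (is.null(sol)) return(NULL)
  to3 <- function(a) centre + r * (cos(a) * ex + sin(a) * ey)
  t_o <- to3(sol$t_o); t_i <- to3(sol$t_i)
  len <- vnorm(origin - t_o) + r * sol$arc + vnorm(t_i - insertion)
  list(via = rbind(origin, t_o, t_i, insertion), length = len, arc = sol$arc,
       touch_origin = t_o, touch_insertion = t_i)
}

.solve_cylinder_wrap <- function(origin, insertion, point, axis, r, hint) {
  axis <- unitize(axis)
  perp <- function(p) {
    v <- p - point
    v - sum(v * axis) * axis
  }
  for (p in list(origin, insertion)) {
    if (vnorm(perp(p)) <= r) {
      stop("muscle endpoint lies inside a wrap object", call. = FALSE)
    }
  }
  e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * axis) * axis
  if (vnorm(e1) < 1e-9) e1 <- c(0, 0, 1) - sum(c(0, 0, 1) * axis) * axis
  e1 <- unitize(e1)
  e2 <- cross3(axis, e1)
  p2 <- function(p) { v <- perp(p); c(sum(v * e1), sum(v * e2)) }
  o2 <- p2(origin); i2 <- p2(insertion)
  zo <- sum((origin - point) * axis); zi <- sum((insertion - point) * axis)
  hv <- hint - sum(hint * axis) * axis
  hint2 <- c(sum(hv * e1), sum(hv * e2))
  sol <- .tangent_arc_2d(o2, i2, r, hint2)
  if (is.null(sol)) return(NULL)
  t_flat_o <- sqrt(max(0, sum(o2 * o2) - r^2))
  t_flat_i <- sqrt(max(0, sum(i2 * i2) - r^2))
  l_flat <- t_flat_o + r * sol$arc + t_flat_i
  dz <- zi - zo
  z_to <- zo + dz * t_flat_o / l_flat
  z_ti <- zo + dz * (t_flat_o + r * sol$arc) / l_flat
  to3 <- function(a, z) point + r * (cos(a) * e1 + sin(a) * e2) + z * axis
  t_o <- to3(sol$t_o, z_to); t_i <- to3(sol$t_i, z_ti)
  len <- sqrt(l_flat^2 + dz^2)
  list(via = rbind(origin, t_o, t_i, insertion), length = len, arc = sol$arc,
       touch_origin = t_o, touch_insertion = t_i)
}

#' Solve a muscle path around wrap obstacles
#'
#' Muscles are vector strings from origin to insertion. If the straight
#' segment clears every wrap object the path is the straight line; otherwise
#' the taut-string (shortest) path around the obstacle is built: tangent
#' segments plus a great-circle arc on spheres, or the unrolled-geodesic
#' tangent arc on cylinders. Only the single obstacle assigned to the path is
#' considered (one sphere or one cylinder per element). The string takes the
#' side of the obstacle nearer the straight segment; for the symmetric
#' through-centre case the `hint` direction breaks the tie.
#'
#' @param origin,insertion World 3-vectors (m); must differ and must lie
#'   outside the wrap obstacle.
#' @param wraps List of wrap objects (each a list with `type`
#'   (`"sphere"`/`"cylinder"`), geometry fields, and the `bone` it is fixed
#'   to), possibly empty.
#' @param hint Optional side hint (world 3-vector).
#' @return Object of class `cuffmc_path`: `via_points` (matrix, ordered
#'   origin to insertion), `path_length`, `straight_length`, `wrapped` flag,
#'   `insertion_direction` (unit pull direction at the insertion),
#'   `effective_point` and `effective_direction` (application point and unit
#'   pull direction of the force transmitted to the humerus system: the
#'   origin-side tangent point for humerus-fixed wraps, else the insertion).
#' @export
solve_path <- function(origin, insertion, wraps = list(), hint = NULL) {
  straight <- vnorm(insertion - origin)
  if (straight < 1e-12) stop("origin and insertion coincide", call. = FALSE)
  if (is.null(hint)) hint <- c(0, 1, 0)

  sol <- NULL
  wrap_bone <- NA_character_
  for (w in wraps) {
    s <- switch(w$type,
      sphere = .solve_sphere_wrap(origin, insertion, w$centre, w$radius, hint),
      cylinder = .solve_cylinder_wrap(origin, insertion, w$point, w$axis, w$radius, hint),
      stop("unknown wrap type: ", w$type, call. = FALSE)
    )
    if (!is.null(s)) {
      sol <- s
      wrap_bone <- w$bone %||% "humerus"
      break
    }
  }

  if (is.null(sol)) {
    structure(list(
      via_points = rbind(origin, insertion),
      path_length = straight,
      straight_length = straight,
      wrapped = FALSE,
      insertion_direction = unitize(origin - insertion),
      effective_point = insertion,
      effective_direction = unitize(origin - insertion)
    ), class = "cuffmc_path")
  } else {
    humerus_fixed <- identical(wrap_bone, "humerus")
    structure(list(
      via_points = sol$via,
      path_length = sol$length,
      straight_length = straight,
      wrapped = TRUE,
      insertion_direction = unitize(sol$touch_insertion - insertion),
      effective_point = if (humerus_fixed) sol$touch_origin else insertion,
      effective_direction = if (humerus_fixed) {
        unitize(origin - sol$touch_origin)
      } else {
        unitize(sol$touch_insertion - insertion)
      }
    ), class = "cuffmc_path")
  }
}

#' Moment arm of a muscle path about the glenohumeral centre
#'
#' `r x u`, where `r` runs from the joint centre to the path's effective
#' application point on the humerus system and `u` is the unit pull
#' direction there (for paths wrapping a humerus-fixed obstacle this is the
#' origin-side tangent point, so the moment includes the obstacle contact
#' contribution and satisfies the tendon-excursion identity).
#'
#' @param path A `cuffmc_path`.
#' @param gh_center Glenohumeral joint centre, world 3-vector (m).
#' @return Moment-arm 3-vector (m).
#' @export
moment_arm <- function(path, gh_center) {
  stopifnot(inherits(path, "cuffmc_path"))
  cross3(path$effective_point - gh_center, path$effective_direction)
}

## ---- attachment resolution and world assembly ----------------------------

#' Resolve per-element attachment fractions
#'
#' Applies (optional) standard-normal perturbation draws to the four
#' perturbed attachment groups and propagates coupled child elements, which
#' move rigidly with their parents. `NULL` draws give the mean geometry.
#'
#' @param species A `cuffmc_species`.
#' @param group_draws Optional named list of standard-normal 3-vector draws.
#' @return Per-element list of `origin`/`insertion` fraction 3-vectors.
#' @export
resolve_attachment_fractions <- function(species, group_draws = NULL) {
  dists <- species$attachment_distributions
  group_pos <- lapply(dists, function(d) {
    dr <- group_draws[[d$element_group]] %||% c(0, 0, 0)
    perturb_attachment(d$mean, d$sd, dr)
  })
  els <- species$muscle_elements
  out <- lapply(els, function(e) list(origin = NULL, insertion = NULL))
  resolve_side <- function(e, side) {
    a <- e[[side]]
    switch(a$kind,
      group = group_pos[[a$group]],
      fixed = a$fixed,
      parent = NULL)
  }
  for (nm in names(els)) {
    out[[nm]]$origin <- resolve_side(els[[nm]], "origin")
    out[[nm]]$insertion <- resolve_side(els[[nm]], "insertion")
  }
  for (nm in names(els)) {  # second pass: coupled children
    for (side in c("origin", "insertion")) {
      a <- els[[nm]][[side]]
      if (a$kind == "parent") {
        parent_coords <- out[[a$parent]][[side]]
        out[[nm]][[side]] <- couple_elements(parent_coords, a$offsets)
      }
    }
  }
  out
}

## Bone frames for a posture. Scapula frame: world-aligned, anchored so the
## glenoid centroid sits medial to the GH centre; fractions measured
## (anterior, medial, inferior-from-superior-reference). Humerus frame:
## origin at GH, y distal along the shaft.
.bone_frames <- function(species, posture) {
  gh <- posture$gh
  fx <- species$fixture
  y_h <- unitize(posture$elbow - gh)
  x_h <- unitize(c(1, 0, 0) - sum(c(1, 0, 0) * y_h) * y_h)
  z_h <- cross3(x_h, y_h)
  centroid <- gh + c(0, 0, -fx$glenoid_centroid_offset)
  s0 <- centroid + c(0, fx$scapula_top_fraction * species$bone_lengths$scapula, 0)
  list(gh = gh, centroid = centroid, scapula_origin = s0,
       humerus_axes = list(x = x_h, y = y_h, z = z_h))
}

.attachment_world <- function(frac, bone, frames, species) {
  if (bone == "scapula") {
    L <- species$bone_lengths$scapula
    frames$scapula_origin +
      L * (frac[1] * c(1, 0, 0) - frac[3] * c(0, 1, 0) - frac[2] * c(0, 0, 1))
  } else {
    L <- species$bone_lengths$humerus
    ax <- frames$humerus_axes
    frames$gh + L * (frac[1] * ax$x + frac[3] * ax$y + frac[2] * ax$z)
  }
}

#' Assemble the world-frame musculoskeletal geometry for one model state
#'
#' Resolves (possibly perturbed) attachment fractions to world coordinates,
#' builds the wrap obstacles and the (possibly inclined) glenoid frame, and
#' solves every muscle path with its moment arm about the glenohumeral
#' centre.
#'
#' @param species A `cuffmc_species`.
#' @param posture A `cuffmc_posture` for the support instance.
#' @param group_draws Optional named list of standard-normal 3-vector draws
#'   for the four perturbed attachment groups.
#' @param inclination_shift_cm Mediolateral shift of the superior glenoid
#'   landmark from its mean, cm.
#' @param stability_pct_draw Stability perturbation draw in percent
#'   (default: the species offset, i.e. the deterministic ratios).
#' @return List with `paths`, `moment_arms` (3 x n matrix), `pull_dirs`
#'   (3 x n), `fmax` implied by `sigma_max` left to the caller, `frame`
#'   (glenoid), `ratios` (length-8), `elements` (names), `gh`.
#' @export
build_model_geometry <- function(species, posture, group_draws = NULL,
                                 inclination_shift_cm = 0,
                                 stability_pct_draw = NULL) {
  frames <- .bone_frames(species, posture)
  fracs <- resolve_attachment_fractions(species, group_draws)
  fx <- species$fixture
  ax <- frames$humerus_axes
  wraps_world <- list(
    humeral_head = list(type = "sphere", centre = frames$gh,
                        radius = fx$humeral_head_radius, bone = "humerus"),
    shaft_cylinder = list(type = "cylinder", point = frames$gh, axis = ax$y,
                          radius = fx$shaft_radius, bone = "humerus")
  )

  els <- species$muscle_elements
  paths <- vector("list", length(els)); names(paths) <- names(els)
  arms <- matrix(0, 3, length(els), dimnames = list(NULL, names(els)))
  pulls <- arms
  for (i in seq_along(els)) {
    e <- els[[i]]
    o <- .attachment_world(fracs[[e$name]]$origin, e$origin$bone, frames, species)
    ins <- .attachment_world(fracs[[e$name]]$insertion, e$insertion$bone, frames, species)
    w <- if (!is.na(e$wrap)) wraps_world[e$wrap] else list()
    p <- solve_path(o, ins, w)
    paths[[i]] <- p
    arms[, i] <- moment_arm(p, frames$gh)
    pulls[, i] <- p$effective_direction
  }

  d_sup <- glenoid_superior_distance(species$glenoid_inclination_sd)
  frame <- glenoid_frame(frames$centroid, frames$centroid + c(0, d_sup, 0))
  if (inclination_shift_cm != 0) frame <- incline_glenoid(frame, inclination_shift_cm)

  pct <- stability_pct_draw %||% species$stability$offset_pct
  ratios <- perturb_stability(species$stability, pct)

  list(paths = paths, moment_arms = arms, pull_dirs = pulls,
       frame = frame, ratios = ratios, elements = names(els),
       gh = frames$gh, attachment_fractions = fracs)
}
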