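## Species parameter sets: anthropometry, muscle PCSAs, attachment-site
## distributions, and directional glenoid stability ratios for the human and
## chimpanzee glenohumeral models.

#' Locate a packaged species configuration file
#'
#' @param species `"human"` or `"chimpanzee"`.
#' @return Path to the YAML configuration shipped with the package.
#' @export
species_config_path <- function(species = c("human", "chimpanzee")) {
  species <- match.arg(species)
  system.file("extdata", paste0(species, ".yaml"), package = "cuffmc", mustWork = TRUE)
}

.axis_names <- c("anterior_posterior", "medial_lateral", "superior_inferior")

.check <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("species config validation failed for '%s': %s", field, msg),
         call. = FALSE)
  }
}

.as_vec3 <- function(x, field) {
  x <- suppressWarnings(as.numeric(x))
  .check(length(x) == 3 && !anyNA(x), field, "must be a numeric 3-vector")
  names(x) <- .axis_names
  x
}

#' Load and validate a species parameter set
#'
#' Reads a YAML species configuration and performs full schema and invariant
#' validation: positive mass/stature, strictly positive standard deviations,
#' exactly ten muscle elements, coupled elements naming an existing parent,
#' stability ratios in (0, 1.5] with exactly eight rim directions, and
#' relative PCSA values consistent with absolute PCSA over body mass to three
#' decimals.
#'
#' @param config_path Path to a species YAML file (see
#'   [species_config_path()] for the packaged human and chimpanzee files).
#' @return An object of class `cuffmc_species`: a validated list with
#'   anthropometry, `muscle_elements`, `attachment_distributions`,
#'   glenoid inclination parameters, and a `cuffmc_stability` ratio set.
#' @export
#' @examples
#' hum <- load_species(species_config_path("human"))
#' hum$body_mass
load_species <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("species config file not found: ", config_path, call. = FALSE)
  }
  raw <- yaml::read_yaml(config_path)

  for (f in c("species", "body_mass", "stature", "segment_lengths",
              "segment_mass_fractions", "bone_lengths", "fixture", "glenoid",
              "stability", "attachment_distributions", "muscle_elements")) {
    .check(!is.null(raw[[f]]), f, "missing field")
  }
  .check(raw$species %in% c("human", "chimpanzee"), "species",
         "must be 'human' or 'chimpanzee'")
  .check(is.numeric(raw$body_mass) && raw$body_mass > 0, "body_mass", "must be > 0")
  .check(is.numeric(raw$stature) && raw$stature > 0, "stature", "must be > 0")

  seg <- lapply(raw$segment_lengths, as.numeric)
  for (s in c("arm", "forearm", "hand")) {
    .check(!is.null(seg[[s]]) && seg[[s]] > 0,
           paste0("segment_lengths$", s), "must be present and > 0")
  }
  segm <- lapply(raw$segment_mass_fractions, as.numeric)
  for (s in c("arm", "forearm", "hand")) {
    .check(!is.null(segm[[s]]) && segm[[s]] > 0 && segm[[s]] < 0.2,
           paste0("segment_mass_fractions$", s), "must be in (0, 0.2)")
  }
  bones <- lapply(raw$bone_lengths, as.numeric)
  for (b in c("scapula", "humerus")) {
    .check(!is.null(bones[[b]]) && bones[[b]] > 0,
           paste0("bone_lengths$", b), "must be present and > 0")
  }

  gl <- raw$glenoid
  .check(is.numeric(gl$inclination_mean_cm), "glenoid$inclination_mean_cm", "missing")
  .check(is.numeric(gl$inclination_sd_cm) && gl$inclination_sd_cm >= 0,
         "glenoid$inclination_sd_cm", "SD must be >= 0")

  stab <- stability_ratios(
    baseline   = as.numeric(raw$stability$baseline),
    directions = unlist(raw$stability$directions),
    offset_pct = as.numeric(raw$stability$offset_pct %||% 0),
    sd_pct     = as.numeric(raw$stability$sd_pct %||% 0),
    offset_mode = raw$stability$offset_mode %||% "multiplicative"
  )

  dists <- list()
  for (g in c("infraspinatus_origin", "subscapularis_origin",
              "supraspinatus_origin", "deltoid_insertion")) {
    d <- raw$attachment_distributions[[g]]
    .check(!is.null(d), paste0("attachment_distributions$", g), "missing field")
    mean <- .as_vec3(d$mean, paste0(g, "$mean"))
    sd <- .as_vec3(d$sd, paste0(g, "$sd"))
    .check(all(sd > 0), paste0(g, "$sd"), "SD components must be strictly positive")
    .check(all(abs(mean) <= 1), paste0(g, "$mean"),
           "attachment fractions must lie in [-1, 1]")
    dists[[g]] <- list(element_group = g, bone = d$bone %||% "scapula",
                       mean = mean, sd = sd)
  }

  els <- raw$muscle_elements
  .check(length(els) == 10, "muscle_elements",
         sprintf("exactly 10 muscle elements required, got %d", length(els)))
  el_names <- vapply(els, function(e) e$name %||% "", "")
  .check(!anyDuplicated(el_names), "muscle_elements", "duplicate element names")

  parse_attach <- function(a, field, el_names) {
    .check(!is.null(a$bone) && a$bone %in% c("scapula", "humerus"),
           paste0(field, "$bone"), "must be 'scapula' or 'humerus'")
    kind <- c("group", "fixed", "parent")[c(!is.null(a$group), !is.null(a$fixed),
                                            !is.null(a$parent))]
    .check(length(kind) == 1, field, "exactly one of group/fixed/parent required")
    out <- list(bone = a$bone, kind = kind)
    if (kind == "group") {
      out$group <- a$group
    } else if (kind == "fixed") {
      out$fixed <- .as_vec3(a$fixed, paste0(field, "$fixed"))
      .check(all(abs(out$fixed) <= 1), field, "fixed fractions must be in [-1, 1]")
    } else {
      .check(a$parent %in% el_names, field,
             sprintf("unknown parent element '%s'", a$parent))
      out$parent <- a$parent
      out$offsets <- .as_vec3(a$offsets, paste0(field, "$offsets"))
    }
    out
  }

  elements <- lapply(els, function(e) {
    nm <- e$name
    .check(is.numeric(e$absolute_pcsa) && e$absolute_pcsa > 0,
           paste0(nm, "$absolute_pcsa"), "must be > 0")
    rel <- relative_pcsa(e$absolute_pcsa, raw$body_mass)
    if (!is.null(e$printed_relative_pcsa)) {
      .check(abs(rel - e$printed_relative_pcsa) <= 5e-4 + 1e-9,
             paste0(nm, "$printed_relative_pcsa"),
             sprintf("absolute_pcsa / body_mass = %.4f disagrees with printed %.3f",
                     e$absolute_pcsa / raw$body_mass, e$printed_relative_pcsa))
    }
    list(
      name = nm,
      absolute_pcsa = as.numeric(e$absolute_pcsa),
      relative_pcsa = rel,
      printed_relative_pcsa = as.numeric(e$printed_relative_pcsa %||% rel),
      origin = parse_attach(e$origin, paste0(nm, "$origin"), el_names),
      insertion = parse_attach(e$insertion, paste0(nm, "$insertion"), el_names),
      wrap = e$wrap %||% NA_character_
    )
  })
  names(elements) <- el_names

  for (e in elements) {
    for (side in c("origin", "insertion")) {
      a <- e[[side]]
      if (a$kind == "group") {
        .check(a$group %in% names(dists), paste0(e$name, "$", side),
               sprintf("unknown attachment distribution '%s'", a$group))
      }
    }
  }

  structure(list(
    species_id = raw$species,
    body_mass = as.numeric(raw$body_mass),
    stature = as.numeric(raw$stature),
    segment_lengths = seg,
    segment_mass_fractions = segm,
    bone_lengths = bones,
    fixture = raw$fixture,
    glenoid_inclination_mean = as.numeric(gl$inclination_mean_cm),
    glenoid_inclination_sd = as.numeric(gl$inclination_sd_cm),
    stability = stab,
    stability_offset_pct = stab$offset_pct,
    stability_sd_pct = stab$sd_pct,
    attachment_distributions = dists,
    muscle_elements = elements
  ), class = "cuffmc_species")
}

#' @export
print.cuffmc_species <- function(x, ...) {
  cat(sprintf("<cuffmc_species> %s: mass %.1f kg, stature %.2f m, %d muscle elements\n",
              x$species_id, x$body_mass, x$stature, length(x$muscle_elements)))
  invisible(x)
}

#' Relative muscle PCSA
#'
#' Physiological cross-sectional area normalized by body mass, the form used
#' for the between-species muscle capacity comparison. Reported to three
#' decimals in tabular output.
#'
#' @param absolute_pcsa Muscle physiological cross-sectional area, cm^2 (> 0).
#' @param body_mass Body mass, kg (> 0).
#' @return Relative PCSA in cm^2/kg, rounded to 3 decimals.
#' @export
#' @examples
#' relative_pcsa(7.42, 72)   # 0.103
#' relative_pcsa(19.92, 45)  # 0.443
relative_pcsa <- function(absolute_pcsa, body_mass) {
  if (!is.numeric(absolute_pcsa) || !is.numeric(body_mass) ||
      any(absolute_pcsa <= 0) || any(body_mass <= 0)) {
    stop("absolute_pcsa and body_mass must be positive", call. = FALSE)
  }
  round(absolute_pcsa / body_mass, 3)
}

#' Construct a directional glenoid stability-ratio set
#'
#' Eight direction-specific ratios of the maximum tolerable dislocating shear
#' force to the concurrent compressive force, at 45 degree spacing around the
#' glenoid rim starting superior and proceeding anteriorly.
#'
#' @param baseline Numeric length-8 vector of baseline ratios, each in (0, 1.5].
#' @param directions Character length-8 direction labels.
#' @param offset_pct Species offset in percent applied to all eight
#'   directions (0 for the human baseline; 13.13 for the deeper chimpanzee
#'   glenoid).
#' @param sd_pct Standard deviation (percent of baseline) of the probabilistic
#'   stability perturbation; all eight directions are perturbed as a unit.
#' @param offset_mode `"multiplicative"` (default; ratio scaled by
#'   `1 + offset_pct/100`) or `"additive"` (`ratio + offset_pct/100`).
#' @param apply_offset Apply `offset_pct` to the baseline immediately?
#'   (Used when loading a species whose config stores the human baseline plus
#'   a species offset.) Default `TRUE`.
#' @return Object of class `cuffmc_stability` with fields `directions`,
#'   `baseline` (offset already applied), `human_baseline` (pre-offset),
#'   `offset_pct`, `sd_pct`, `offset_mode`.
#' @export
stability_ratios <- function(baseline, directions = NULL, offset_pct = 0,
                             sd_pct = 0, offset_mode = "multiplicative",
                             apply_offset = TRUE) {
  .check(length(baseline) == 8, "stability$baseline", "exactly 8 ratios required")
  .check(all(baseline > 0 & baseline <= 1.5), "stability$baseline",
         "ratios must lie in (0, 1.5]")
  .check(sd_pct >= 0, "stability$sd_pct", "SD must be >= 0")
  .check(offset_mode %in% c("multiplicative", "additive"), "stability$offset_mode",
         "must be 'multiplicative' or 'additive'")
  directions <- directions %||% c("superior", "anterosuperior", "anterior",
                                  "anteroinferior", "inferior", "posteroinferior",
                                  "posterior", "posterosuperior")
  .check(length(directions) == 8, "stability$directions", "exactly 8 directions")
  obj <- structure(list(directions = as.character(directions),
                        baseline = as.numeric(baseline),
                        human_baseline = as.numeric(baseline),
                        offset_pct = as.numeric(offset_pct),
                        sd_pct = as.numeric(sd_pct),
                        offset_mode = offset_mode),
                   class = "cuffmc_stability")
  if (isTRUE(apply_offset) && offset_pct != 0) {
    obj <- apply_stability_offset(obj, offset_pct, mode = offset_mode)
  }
  obj
}

#' Apply a species stability offset to a baseline ratio set
#'
#' The chimpanzee glenoid is approximately 13.13% deeper than the human
#' glenoid, encoded as a 13.13% greater capacity to withstand shear for a
#' given compressive force: each directional ratio is scaled by
#' `1 + offset_pct/100` (default interpretation), identically in all eight
#' directions. An additive interpretation (`ratio + offset_pct/100`) is
#' selectable via `mode`.
#'
#' @param baseline A `cuffmc_stability` object (ratios before the offset).
#' @param offset_pct Offset in percent; must be >= -100.
#' @param mode `"multiplicative"` (default) or `"additive"`.
#' @return A `cuffmc_stability` object with the offset applied to `baseline`
#'   and recorded in `offset_pct`; `human_baseline` keeps the pre-offset values.
#' @export
#' @examples
#' h <- stability_ratios(rep(0.5, 8))
#' c8 <- apply_stability_offset(h, 13.13)
#' c8$baseline / h$baseline  # 1.1313 in all eight directions
apply_stability_offset <- function(baseline, offset_pct, mode = "multiplicative") {
  stopifnot(inherits(baseline, "cuffmc_stability"))
  if (offset_pct < -100) stop("offset_pct must be >= -100", call. = FALSE)
  out <- baseline
  out$baseline <- if (mode == "additive") {
    baseline$human_baseline + offset_pct / 100
  } else {
    baseline$human_baseline * (1 + offset_pct / 100)
  }
  out$offset_pct <- offset_pct
  out$offset_mode <- mode
  out
}

#' Perturb a stability-ratio set as a unit
#'
#' Monte Carlo stability perturbation: all eight directions are varied
#' together by a single percentage draw around the species offset.
#'
#' @param stab A `cuffmc_stability` object (with species offset applied).
#' @param pct_draw Percent perturbation drawn from N(offset_pct, sd_pct).
#' @return Numeric length-8 vector of perturbed ratios.
#' @keywords internal
perturb_stability <- function(stab, pct_draw) {
  if (stab$offset_mode == "additive") {
    stab$human_baseline + pct_draw / 100
  } else {
    stab$human_baseline * (1 + pct_draw / 100)
  }
}

#' Export the per-species PCSA table
#'
#' @param species A `cuffmc_species` object, or a list of them.
#' @param path Optional CSV output path.
#' @return A data.frame with columns `species`, `element`,
#'   `absolute_pcsa_cm2`, `relative_pcsa_cm2_per_kg`.
#' @export
pcsa_table <- function(species, path = NULL) {
  if (inherits(species, "cuffmc_species")) species <- list(species)
  rows <- do.call(rbind, lapply(species, function(sp) {
    data.frame(
      species = sp$species_id,
      element = vapply(sp$muscle_elements, `[[`, "", "name"),
      absolute_pcsa_cm2 = vapply(sp$muscle_elements, `[[`, 0, "absolute_pcsa"),
      relative_pcsa_cm2_per_kg = vapply(sp$muscle_elements, `[[`, 0, "relative_pcsa"),
      row.names = NULL
    )
  }))
  if (!is.null(path)) utils::write.csv(rows, path, row.names = FALSE)
  rows
}

#' Serialize a species parameter set back to YAML
#'
#' Writes a YAML file that [load_species()] reads back to a field-wise
#' identical parameter set (round-trip invariant).
#'
#' @param species A `cuffmc_species` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_species <- function(species, path) {
  stopifnot(inherits(species, "cuffmc_species"))
  ser_attach <- function(a) {
    out <- list(bone = a$bone)
    if (a$kind == "group") out$group <- a$group
    if (a$kind == "fixed") out$fixed <- unname(a$fixed)
    if (a$kind == "parent") {
      out$parent <- a$parent
      out$offsets <- unname(a$offsets)
    }
    out
  }
  raw <- list(
    species = species$species_id,
    body_mass = species$body_mass,
    stature = species$stature,
    segment_lengths = species$segment_lengths,
    segment_mass_fractions = species$segment_mass_fractions,
    bone_lengths = species$bone_lengths,
    fixture = species$fixture,
    glenoid = list(inclination_mean_cm = species$glenoid_inclination_mean,
                   inclination_sd_cm = species$glenoid_inclination_sd),
    stability = list(directions = species$stability$directions,
                     baseline = species$stability$human_baseline,
                     offset_pct = species$stability$offset_pct,
                     sd_pct = species$stability$sd_pct,
                     offset_mode = species$stability$offset_mode),
    attachment_distributions = lapply(species$attachment_distributions, function(d) {
      list(bone = d$bone, mean = unname(d$mean), sd = unname(d$sd))
    }),
    muscle_elements = lapply(unname(species$muscle_elements), function(e) {
      list(name = e$name, absolute_pcsa = e$absolute_pcsa,
           printed_relative_pcsa = e$printed_relative_pcsa,
           origin = ser_attach(e$origin), insertion = ser_attach(e$insertion),
           wrap = if (is.na(e$wrap)) NULL else e$wrap)
    })
  )
  yaml::write_yaml(raw, path, precision = 12)
  invisible(path)
}
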