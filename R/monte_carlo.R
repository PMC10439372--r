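## Probabilistic engine: joint Gaussian perturbation of the fourteen
## morphological inputs, Monte Carlo simulation per (species, instance),
## cumulative distribution functions at eleven probability levels, and
## mean-perturbation sensitivity factors with common random numbers.

.cdf_levels <- c(0.01, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.99)
.summary_percentiles <- c(1, 25, 50, 75, 99)

#' The fourteen probabilistic input variables of a species model
#'
#' Twelve attachment coordinates (four attachment groups by three axes),
#' the glenoid inclination landmark coordinate (cm), and the stability-ratio
#' set perturbed as a unit (percent of baseline).
#'
#' @param species A `cuffmc_species`.
#' @return data.frame with columns `name`, `mean`, `sd` (native units).
#' @export
input_variables <- function(species) {
  rows <- list()
  for (g in names(species$attachment_distributions)) {
    d <- species$attachment_distributions[[g]]
    for (k in 1:3) {
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0(g, "_", c("ap", "ml", "si")[k]),
        mean = unname(d$mean[k]), sd = unname(d$sd[k]))
    }
  }
  rows[[length(rows) + 1]] <- data.frame(name = "glenoid_inclination",
                                         mean = species$glenoid_inclination_mean,
                                         sd = species$glenoid_inclination_sd)
  rows[[length(rows) + 1]] <- data.frame(name = "stability_ratio",
                                         mean = species$stability_offset_pct,
                                         sd = species$stability_sd_pct)
  do.call(rbind, rows)
}

#' Draw the Monte Carlo input sample matrix
#'
#' Independent Gaussian draws per input variable (covariance between
#' morphological features is assumed negligible and is not modelled),
#' reproducible for a fixed seed. The underlying standard-normal matrix is
#' attached as attribute `"z"` so that sensitivity analyses can shift an
#' input mean while reusing common random numbers.
#'
#' @param variables data.frame with `name`, `mean`, `sd` (see
#'   [input_variables()]).
#' @param n Number of iterations (>= 1).
#' @param seed Integer seed.
#' @return `n x nrow(variables)` matrix with variable names as columns and
#'   attribute `"z"` (the standard-normal draws).
#' @export
draw_inputs <- function(variables, n, seed) {
  stopifnot(n >= 1)
  z <- .with_seed(seed, function() {
    matrix(stats::rnorm(n * nrow(variables)), nrow = n)
  })
  x <- sweep(sweep(z, 2, variables$sd, `*`), 2, variables$mean, `+`)
  colnames(x) <- variables$name
  attr(x, "z") <- z
  x
}

#' Build a per-iteration model closure for one species and instance
#'
#' Precomputes the posture, external load and force bounds, returning a
#' function that maps one row of native-unit input draws to the seven
#' normalized rotator cuff forces (percent of maximum force) plus a
#' feasibility flag. One model solve yields all seven outputs, so the seven
#' analyses of one (species, instance) run share identical model states.
#'
#' @inheritParams solve_instance
#' @return function(x) -> list(`normalized` named length-7, `feasible`).
#' @export
make_instance_model <- function(instance, species, seed = 1L, sigma_max = 88,
                                p = 3) {
  posture <- generate_posture(instance, species, seed)
  load <- external_load(instance, species, posture = posture)
  fmax <- vapply(species$muscle_elements, max_force, 0, sigma_max = sigma_max)
  dists <- species$attachment_distributions
  outs <- cuff_outputs()

  function(x) {
    gd <- lapply(dists, function(d) {
      v <- x[paste0(d$element_group, "_", c("ap", "ml", "si"))]
      (as.numeric(v) - d$mean) / d$sd
    })
    geom <- build_model_geometry(
      species, posture, group_draws = gd,
      inclination_shift_cm = as.numeric(x["glenoid_inclination"]) -
        species$glenoid_inclination_mean,
      stability_pct_draw = as.numeric(x["stability_ratio"]))
    sol <- solve_muscle_forces(geom, load, fmax, p = p)
    list(normalized = sol$normalized[outs], feasible = sol$feasible)
  }
}

#' Run one Monte Carlo analysis block (all seven outputs)
#'
#' @param model Closure from [make_instance_model()].
#' @param variables Input variable table (see [input_variables()]).
#' @param n Iterations.
#' @param seed Integer seed.
#' @param inputs Optional pre-drawn input matrix (overrides
#'   `variables`/`n`/`seed` for the draws).
#' @return List: `samples` (`n x 7` normalized forces, percent; infeasible
#'   iterations are `NA`), `feasible` (logical vector), `n_infeasible`,
#'   `inputs`.
#' @export
run_monte_carlo <- function(model, variables, n, seed, inputs = NULL) {
  x <- inputs %||% draw_inputs(variables, n, seed)
  outs <- cuff_outputs()
  samples <- matrix(NA_real_, nrow(x), length(outs),
                    dimnames = list(NULL, outs))
  feasible <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    ## degenerate perturbed geometry (e.g. an attachment drawn inside a wrap
    ## obstacle) is recorded as an infeasible iteration, never imputed
    r <- tryCatch(model(x[i, ]), error = function(e) list(feasible = FALSE))
    feasible[i] <- isTRUE(r$feasible)
    if (feasible[i]) samples[i, ] <- r$normalized
  }
  list(samples = samples, feasible = feasible,
       n_infeasible = sum(!feasible), inputs = x)
}

#' Build a cumulative distribution function at the eleven study levels
#'
#' Empirical quantiles (linear interpolation between order statistics,
#' the type-7 rule) of the feasible normalized-force samples at probability
#' levels 0.01, 0.1, ..., 0.9, 0.99, plus the 1/25/50/75/99 percentile
#' summary. Infeasible iterations are excluded with a reported count; at
#' least `min_samples` feasible samples are required.
#'
#' @param samples Numeric vector of normalized forces (percent); `NA`
#'   marks infeasible iterations.
#' @param min_samples Minimum feasible sample count (default 100).
#' @return Object of class `cuffmc_cdf`: `levels`, `values`, `percentiles`
#'   (named by percentile), `n`, `n_infeasible`.
#' @export
build_cdf <- function(samples, min_samples = 100) {
  n_inf <- sum(is.na(samples))
  ok <- samples[!is.na(samples)]
  if (length(ok) < min_samples) {
    stop(sprintf("too few feasible samples for CDF construction: %d feasible, n_infeasible = %d",
                 length(ok), n_inf), call. = FALSE)
  }
  vals <- unname(stats::quantile(ok, probs = .cdf_levels, type = 7))
  pct <- unname(stats::quantile(ok, probs = .summary_percentiles / 100, type = 7))
  structure(list(levels = .cdf_levels, values = vals,
                 percentiles = stats::setNames(pct, .summary_percentiles),
                 n = length(ok), n_infeasible = n_inf),
            class = "cuffmc_cdf")
}

#' Mean-perturbation sensitivity factors by finite differences
#'
#' For each input variable the probability of the output falling at or
#' below the base-run CDF value of each level is re-estimated with the
#' input mean shifted by `+/- h_sd` standard deviations, reusing common
#' random numbers (the identical standard-normal draw matrix). The
#' absolute sensitivity factor at level `p` is
#' `|dp/dmu| * sigma / p` (`scaling = "eq1"`, default) or `|dp/dmu| * sigma`
#' (`scaling = "sigma"`).
#'
#' @param simulate function(X) mapping an `n x k` input matrix to an
#'   `n x m` output matrix (rows may be `NA` for infeasible states).
#' @param variables Input table (`name`, `mean`, `sd`).
#' @param n Iterations per evaluation.
#' @param seed Seed for the common draws.
#' @param levels Probability levels (default the eleven study levels).
#' @param h_sd Finite-difference step in input SDs (default 0.1).
#' @param scaling `"eq1"` or `"sigma"`.
#' @return List: `factors` (array `k x levels x m`), `averaged`
#'   (`k x m` matrix, mean over levels), `thresholds` (base CDF values,
#'   `levels x m`).
#' @export
mc_sensitivity <- function(simulate, variables, n, seed,
                           levels = .cdf_levels, h_sd = 0.1,
                           scaling = c("eq1", "sigma")) {
  scaling <- match.arg(scaling)
  k <- nrow(variables)
  x0 <- draw_inputs(variables, n, seed)
  z <- attr(x0, "z")
  y0 <- simulate(x0)
  m <- ncol(y0)
  out_names <- colnames(y0) %||% paste0("out", seq_len(m))

  thresholds <- matrix(NA_real_, length(levels), m,
                       dimnames = list(NULL, out_names))
  for (j in seq_len(m)) {
    ok <- y0[, j][!is.na(y0[, j])]
    thresholds[, j] <- stats::quantile(ok, probs = levels, type = 7)
  }

  factors <- array(NA_real_, dim = c(k, length(levels), m),
                   dimnames = list(variables$name, levels, out_names))
  ecdf_at <- function(y, t) {
    ok <- y[!is.na(y)]
    vapply(t, function(tt) mean(ok <= tt), 0)
  }
  for (i in seq_len(k)) {
    h <- h_sd * variables$sd[i]
    if (h == 0) { factors[i, , ] <- 0; next }
    for (sgn in c(1, -1)) {
      xs <- x0
      xs[, i] <- variables$mean[i] + sgn * h + variables$sd[i] * z[, i]
      ys <- simulate(xs)
      for (j in seq_len(m)) {
        pj <- ecdf_at(ys[, j], thresholds[, j])
        if (sgn == 1) factors[i, , j] <- pj else
          factors[i, , j] <- (factors[i, , j] - pj) / (2 * h)
      }
    }
  }
  scale_vec <- if (scaling == "eq1") {
    outer(variables$sd, levels, function(s, p) s / p)
  } else {
    matrix(variables$sd, k, length(levels))
  }
  for (j in seq_len(m)) factors[, , j] <- abs(factors[, , j]) * scale_vec
  averaged <- apply(factors, c(1, 3), mean)
  list(factors = factors, averaged = averaged, thresholds = thresholds)
}

#' Default study configuration
#'
#' Defaults reproduce the full study design: two species, three static
#' support instances, seven rotator cuff outputs, 2500 Monte Carlo
#' iterations per analysis, CDFs at eleven probability levels, and
#' sensitivity factors averaged over levels then instances.
#'
#' @param ... Overrides of the default fields.
#' @return A `cuffmc_config` list.
#' @export
study_config <- function(...) {
  cfg <- list(
    species = c("human", "chimpanzee"),
    species_paths = NULL,         # default: packaged configs
    instances = .instances,
    n_iterations = 2500,
    seed = 1L,
    sigma_max = 88,
    objective_exponent = 3,
    min_samples = 100,
    sensitivity = list(enabled = TRUE, n = NULL, h_sd = 0.1, scaling = "eq1"),
    g = 9.81
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (nm == "sensitivity") utils::modifyList(cfg$sensitivity, over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = "cuffmc_config")
}

#' Enumerate the planned Monte Carlo analyses
#'
#' @param config A `cuffmc_config` (default [study_config()]).
#' @return data.frame with one row per analysis (species x instance x
#'   output); the default design has 42 rows.
#' @export
enumerate_analyses <- function(config = study_config()) {
  expand.grid(species = config$species, instance = config$instances,
              output = cuff_outputs(), KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

#' Run the full probabilistic analysis suite
#'
#' For every species and support instance: draws the fourteen-input Gaussian
#' sample, solves the stability-constrained optimization per iteration,
#' builds the seven output CDFs, and (optionally) computes the
#' mean-perturbation sensitivity factors averaged across the eleven levels
#' and then across the three instances. Per-analysis seeds are derived
#' deterministically from the base seed, so identical configurations give
#' bit-identical results.
#'
#' @param config A `cuffmc_config`.
#' @param species_sets Optional pre-loaded list of `cuffmc_species`
#'   (named by species id).
#' @return Object of class `cuffmc_suite`: `results` (list of per-analysis
#'   records with `species`, `instance`, `output`, `cdf`, `samples`),
#'   `sensitivities` (per species: averaged 14 x 7 matrix),
#'   `manifest` (seeds, iteration/infeasibility/clamp counts, config hash).
#' @export
run_analysis_suite <- function(config = study_config(), species_sets = NULL) {
  reset_clamp_counter()
  if (is.null(species_sets)) {
    species_sets <- lapply(config$species, function(s) {
      path <- config$species_paths[[s]] %||% species_config_path(s)
      load_species(path)
    })
    names(species_sets) <- config$species
  }

  results <- list()
  sensitivities <- list()
  run_log <- list()

  for (sp_name in config$species) {
    sp <- species_sets[[sp_name]]
    vars <- input_variables(sp)
    inst_sens <- list()
    for (inst in config$instances) {
      seed_i <- derive_seed(config$seed, sp_name, inst)
      model <- make_instance_model(inst, sp, seed = config$seed,
                                   sigma_max = config$sigma_max,
                                   p = config$objective_exponent)
      mc <- run_monte_carlo(model, vars, config$n_iterations, seed_i)
      for (out in cuff_outputs()) {
        cdf <- build_cdf(mc$samples[, out], min_samples = config$min_samples)
        results[[paste(sp_name, inst, out, sep = ".")]] <- list(
          species = sp_name, instance = inst, output = out,
          cdf = cdf, samples = mc$samples[, out])
      }
      run_log[[paste(sp_name, inst, sep = ".")]] <- list(
        seed = seed_i, n = config$n_iterations, n_infeasible = mc$n_infeasible)

      if (isTRUE(config$sensitivity$enabled)) {
        n_sens <- config$sensitivity$n %||% config$n_iterations
        simulate <- function(X) {
          y <- matrix(NA_real_, nrow(X), 7, dimnames = list(NULL, cuff_outputs()))
          for (r in seq_len(nrow(X))) {
            res <- tryCatch(model(X[r, ]), error = function(e) list(feasible = FALSE))
            if (isTRUE(res$feasible)) y[r, ] <- res$normalized
          }
          y
        }
        sens <- mc_sensitivity(simulate, vars, n = n_sens, seed = seed_i,
                               h_sd = config$sensitivity$h_sd,
                               scaling = config$sensitivity$scaling)
        inst_sens[[inst]] <- sens$averaged
      }
    }
    if (length(inst_sens)) {
      sensitivities[[sp_name]] <- Reduce(`+`, inst_sens) / length(inst_sens)
    }
  }

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    base_seed = config$seed,
    n_iterations = config$n_iterations,
    n_analyses = length(results),
    runs = run_log,
    clamp_count = clamp_counter()
  )
  structure(list(results = results, sensitivities = sensitivities,
                 manifest = manifest, config = config),
            class = "cuffmc_suite")
}

#' @export
print.cuffmc_suite <- function(x, ...) {
  cat(sprintf("<cuffmc_suite> %d analyses, %d iterations each, seed %d\n",
              length(x$results), x$manifest$n_iterations, x$manifest$base_seed))
  invisible(x)
}
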