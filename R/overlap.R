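## Between-species comparison: overlap of human and chimpanzee normalized
## muscle-force distributions, plus figure and table rendering.

#' Percentile summary of one Monte Carlo analysis
#'
#' @param result One per-analysis record of a `cuffmc_suite` (with fields
#'   `species`, `instance`, `output`, `cdf`), or a `cuffmc_cdf` plus
#'   explicit identifiers.
#' @param output,instance Identifiers when `result` is a bare `cuffmc_cdf`.
#' @return Object of class `cuffmc_percentiles`: `output`, `instance`,
#'   `q` (named 1/25/50/75/99 percentiles, percent of maximum force).
#' @export
percentile_summary <- function(result, output = NULL, instance = NULL) {
  if (inherits(result, "cuffmc_cdf")) {
    q <- result$percentiles
  } else {
    q <- result$cdf$percentiles
    output <- output %||% result$output
    instance <- instance %||% result$instance
  }
  structure(list(output = output, instance = instance, q = q),
            class = "cuffmc_percentiles")
}

#' Assess overlap between human and chimpanzee force distributions
#'
#' Interval-intersection flags on the 99% prediction bands:
#' `range_overlaps` (the two 1-99 ranges intersect), `inner50_overlaps`
#' (the human 25-75 band intersects the chimpanzee 1-99 range),
#' `human_median_above_chimp_range` (human median exceeds the entire
#' chimpanzee range), and the package's operational definition of
#' functional overlap: `inner50_overlaps AND NOT
#' human_median_above_chimp_range`.
#'
#' @param human,chimp `cuffmc_percentiles` summaries of the same output and
#'   instance.
#' @return Object of class `cuffmc_overlap` with the flags and both
#'   percentile sets.
#' @export
assess_overlap <- function(human, chimp) {
  stopifnot(inherits(human, "cuffmc_percentiles"),
            inherits(chimp, "cuffmc_percentiles"))
  if (!identical(human$output, chimp$output) ||
      !identical(human$instance, chimp$instance)) {
    stop(sprintf("mismatched summaries: %s/%s vs %s/%s",
                 human$output, human$instance, chimp$output, chimp$instance),
         call. = FALSE)
  }
  h <- human$q; c_ <- chimp$q
  range_overlaps <- h[["1"]] <= c_[["99"]] && c_[["1"]] <= h[["99"]]
  inner50_overlaps <- h[["25"]] <= c_[["99"]] && c_[["1"]] <= h[["75"]]
  above <- h[["50"]] > c_[["99"]]
  structure(list(
    output = human$output, instance = human$instance,
    human_percentiles = h, chimp_percentiles = c_,
    range_overlaps = range_overlaps,
    inner50_overlaps = inner50_overlaps,
    human_median_above_chimp_range = above,
    functional_overlap = inner50_overlaps && !above
  ), class = "cuffmc_overlap")
}

#' Overlap table for a complete analysis suite
#'
#' @param suite A `cuffmc_suite` containing both species.
#' @return data.frame with one row per (output, instance): percentile
#'   columns for both species and the four overlap flags.
#' @export
overlap_table <- function(suite) {
  stopifnot(inherits(suite, "cuffmc_suite"))
  rows <- list()
  for (inst in suite$config$instances) {
    for (out in cuff_outputs()) {
      h <- suite$results[[paste("human", inst, out, sep = ".")]]
      c_ <- suite$results[[paste("chimpanzee", inst, out, sep = ".")]]
      if (is.null(h) || is.null(c_)) {
        stop("incomplete suite: missing ", inst, "/", out, call. = FALSE)
      }
      ov <- assess_overlap(percentile_summary(h), percentile_summary(c_))
      rows[[length(rows) + 1]] <- data.frame(
        output = out, instance = inst,
        human_p1 = ov$human_percentiles[["1"]], human_p25 = ov$human_percentiles[["25"]],
        human_p50 = ov$human_percentiles[["50"]], human_p75 = ov$human_percentiles[["75"]],
        human_p99 = ov$human_percentiles[["99"]],
        chimp_p1 = ov$chimp_percentiles[["1"]], chimp_p25 = ov$chimp_percentiles[["25"]],
        chimp_p50 = ov$chimp_percentiles[["50"]], chimp_p75 = ov$chimp_percentiles[["75"]],
        chimp_p99 = ov$chimp_percentiles[["99"]],
        range_overlaps = ov$range_overlaps,
        inner50_overlaps = ov$inner50_overlaps,
        human_median_above_chimp_range = ov$human_median_above_chimp_range,
        functional_overlap = ov$functional_overlap)
    }
  }
  do.call(rbind, rows)
}

## long CDF table (species, output, instance, level, force_pct)
cdf_table <- function(suite) {
  do.call(rbind, lapply(unname(suite$results), function(r) {
    data.frame(species = r$species, output = r$output, instance = r$instance,
               level = r$cdf$levels, force_pct = r$cdf$values)
  }))
}

#' Render figures and machine-readable tables for a suite
#'
#' Writes, per species, a box-and-whisker-style percentile figure (one
#' panel per output and instance, 21 panels) and a sensitivity bar matrix;
#' plus CSV tables (CDF levels, percentile summaries, overlap flags,
#' sensitivity factors) and a JSON run manifest. Rendering touches no
#' random state, and repeated calls on the same suite produce byte-identical
#' CSV output.
#'
#' @param suite A complete two-species `cuffmc_suite`.
#' @param dir Output directory (created if needed).
#' @param figures Write PNG figures? Default `TRUE`.
#' @return Named character vector of written file paths, invisibly.
#' @export
render_reports <- function(suite, dir, figures = TRUE) {
  stopifnot(inherits(suite, "cuffmc_suite"))
  if (!length(suite$results)) stop("empty suite", call. = FALSE)
  ot <- overlap_table(suite)   # also validates completeness
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  paths <- c(
    cdf = file.path(dir, "cdf_levels.csv"),
    percentiles = file.path(dir, "percentile_summary.csv"),
    overlap = file.path(dir, "overlap_table.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  ct <- cdf_table(suite)
  utils::write.csv(ct, paths[["cdf"]], row.names = FALSE)
  pt <- do.call(rbind, lapply(unname(suite$results), function(r) {
    data.frame(species = r$species, output = r$output, instance = r$instance,
               percentile = as.integer(names(r$cdf$percentiles)),
               force_pct = unname(r$cdf$percentiles))
  }))
  utils::write.csv(pt, paths[["percentiles"]], row.names = FALSE)
  utils::write.csv(ot, paths[["overlap"]], row.names = FALSE)
  jsonlite::write_json(suite$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA)

  for (sp in names(suite$sensitivities)) {
    p <- file.path(dir, sprintf("sensitivity_%s.csv", sp))
    s <- suite$sensitivities[[sp]]
    df <- data.frame(input = rownames(s), s, check.names = FALSE, row.names = NULL)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[paste0("sensitivity_", sp)]] <- p
  }

  if (isTRUE(figures)) {
    for (sp in suite$config$species) {
      sub <- pt[pt$species == sp, ]
      wide <- stats::reshape(sub, idvar = c("output", "instance"),
                             timevar = "percentile", direction = "wide")
      names(wide) <- sub("force_pct\\.", "p", names(wide))
      g <- ggplot2::ggplot(wide, ggplot2::aes(x = instance)) +
        ggplot2::geom_boxplot(ggplot2::aes(ymin = p1, lower = p25, middle = p50,
                                           upper = p75, ymax = p99),
                              stat = "identity", fill = "grey80") +
        ggplot2::facet_wrap(~output, ncol = 4) +
        ggplot2::labs(y = "Muscle force (% of maximum)", x = NULL,
                      title = sprintf("%s rotator cuff force distributions", sp)) +
        ggplot2::theme_bw() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
      fp <- file.path(dir, sprintf("forces_%s.png", sp))
      ggplot2::ggsave(fp, g, width = 10, height = 6, dpi = 150)
      paths[[paste0("forces_", sp)]] <- fp

      if (!is.null(suite$sensitivities[[sp]])) {
        s <- suite$sensitivities[[sp]]
        long <- data.frame(input = rep(rownames(s), ncol(s)),
                           output = rep(colnames(s), each = nrow(s)),
                           factor = as.numeric(s))
        gs <- ggplot2::ggplot(long, ggplot2::aes(x = input, y = factor)) +
          ggplot2::geom_col(fill = "steelblue") +
          ggplot2::facet_wrap(~output, ncol = 4, scales = "free_y") +
          ggplot2::coord_flip() +
          ggplot2::labs(x = NULL, y = "Absolute sensitivity factor",
                        title = sprintf("%s input sensitivities", sp)) +
          ggplot2::theme_bw()
        sp_path <- file.path(dir, sprintf("sensitivity_%s.png", sp))
        ggplot2::ggsave(sp_path, gs, width = 10, height = 7, dpi = 150)
        paths[[paste0("sensitivity_fig_", sp)]] <- sp_path
      }
    }
  }
  invisible(paths)
}

#' Qualitative force-sharing pattern summary
#'
#' Reports (without gating anything) whether the default-model solutions
#' reproduce the expected qualitative pattern: human early/mid support
#' concentrating force in infraspinatus and teres minor with silent
#' subscapularis and supraspinatus; chimpanzee spreading low-to-moderate
#' force across all cuff muscles; and late support confined to a narrow
#' low-force band for both species.
#'
#' @param suite A `cuffmc_suite`.
#' @param quiet Suppress the printed summary?
#' @return Named logical flags, invisibly unless `quiet = FALSE`.
#' @export
pattern_summary <- function(suite, quiet = FALSE) {
  med <- function(sp, inst, out) {
    r <- suite$results[[paste(sp, inst, out, sep = ".")]]
    if (is.null(r)) return(NA_real_)
    unname(r$cdf$percentiles[["50"]])
  }
  h_inf <- max(med("human", "early_support", "infraspinatus_lower"),
               med("human", "mid_support", "infraspinatus_lower"),
               med("human", "early_support", "teres_minor"),
               med("human", "mid_support", "teres_minor"), na.rm = TRUE)
  h_silent <- max(med("human", "early_support", "subscapularis_upper"),
                  med("human", "mid_support", "subscapularis_upper"),
                  med("human", "early_support", "supraspinatus"),
                  med("human", "mid_support", "supraspinatus"), na.rm = TRUE)
  c_meds <- vapply(cuff_outputs(), function(o) {
    max(med("chimpanzee", "early_support", o), med("chimpanzee", "mid_support", o),
        na.rm = TRUE)
  }, 0)
  late <- vapply(suite$config$species, function(sp) {
    max(vapply(cuff_outputs(), function(o) med(sp, "late_support", o), 0), na.rm = TRUE)
  }, 0)
  flags <- c(
    human_loads_infra_teres = isTRUE(h_inf > 10),
    human_subscap_supra_silent = isTRUE(h_silent < 1),
    chimp_disperses_low_moderate = isTRUE(all(c_meds < 60)) && isTRUE(any(c_meds > 0.5)),
    late_support_low_band = isTRUE(all(late <= 8))
  )
  if (!quiet) {
    message("Qualitative force-sharing pattern (informational):")
    for (nm in names(flags)) message(sprintf("  %-30s %s", nm, flags[[nm]]))
  }
  invisible(flags)
}
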