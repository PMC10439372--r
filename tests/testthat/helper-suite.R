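## A single scaled-down analysis suite shared by the study-design and
## acceptance tests (computed lazily, once per test run). 160 iterations
## keeps the full 42-analysis enumeration honest while staying fast and
## leaves buffer over the 100-feasible-sample CDF floor in the runs with
## the highest infeasibility rates.
.suite_cache <- new.env(parent = emptyenv())

shared_suite <- function() {
  if (is.null(.suite_cache$suite)) {
    cfg <- study_config(n_iterations = 160, seed = 3L,
                        min_samples = 100,
                        sensitivity = list(enabled = FALSE))
    .suite_cache$suite <- run_analysis_suite(cfg)
  }
  .suite_cache$suite
}

## Synthetic suite with hand-built CDFs (no simulation), for report and
## overlap plumbing tests.
fake_suite <- function() {
  levels <- c(0.01, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.99)
  results <- list()
  set.seed(11)
  for (spn in c("human", "chimpanzee")) {
    for (inst in c("early_support", "mid_support", "late_support")) {
      for (out in cuff_outputs()) {
        base <- if (spn == "human") 30 else 5
        vals <- sort(base * levels + stats::runif(11, 0, 0.5))
        pct <- stats::setNames(vals[c(1, 4, 6, 8, 11)], c(1, 25, 50, 75, 99))
        cdf <- structure(list(levels = levels, values = vals,
                              percentiles = pct, n = 120, n_infeasible = 0),
                         class = "cuffmc_cdf")
        results[[paste(spn, inst, out, sep = ".")]] <-
          list(species = spn, instance = inst, output = out, cdf = cdf,
               samples = vals)
      }
    }
  }
  sens <- matrix(stats::runif(14 * 7), 14, 7,
                 dimnames = list(input_variables(human_sp)$name, cuff_outputs()))
  structure(list(results = results,
                 sensitivities = list(human = sens, chimpanzee = sens),
                 manifest = list(config_hash = "fake", base_seed = 11,
                                 n_iterations = 120, n_analyses = 42,
                                 runs = list(), clamp_count = 0),
                 config = study_config(n_iterations = 120, seed = 11)),
            class = "cuffmc_suite")
}
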