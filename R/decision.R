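#' Run the full decision analysis
#'
#' The end-to-end DAIVE pipeline: fit the saturated Bayesian factorial model
#' for every outcome, compute posterior expected outcomes for all `2^k`
#' candidate conditions, scale outcomes to 0-1, combine them with the
#' swing-weighted linear value function, select the value-maximizing
#' condition, and (optionally) run the weight-variation sweeps and
#' preference scenarios. All intermediate artifacts are retained.
#'
#' @param dataset participant-level trial data (see [fit_factorial_bayes()]).
#' @param design a [factorial_design()].
#' @param outcomes named character vector mapping outcome names to dataset
#'   columns (e.g. `c(beliefs = "beliefs", ...)`); names must match `points`.
#' @param points named positive swing points per outcome.
#' @param covariates named list mapping outcome names to covariate column
#'   vectors (e.g. `list(beliefs = "baseline")`); outcomes not listed get no
#'   covariate.
#' @param prior a [prior_spec()].
#' @param config a [sampler_config()]; chain seeds are offset per outcome so
#'   the whole report is reproducible from one seed.
#' @param rounding,basis,bounds,direction decision options, see [decide()].
#' @param sweep_plan a [weight_sweep_plan()] or `NULL` to skip the sweeps.
#' @param scenarios a [scenario_set()] or `NULL` to skip scenarios.
#' @return An object of class `daive_report`: `fits` (per-outcome
#'   posteriors), `effect_summaries`, `means` ([condition_means()]),
#'   `decision` (weights, value table, selected condition), `top2` (the two
#'   best conditions and their value gap), `step1`, `step2`, `scenarios`,
#'   `converged`, and a `config` echo.
#' @export
run_daive <- function(dataset, design, outcomes, points,
                      covariates = list(),
                      prior = prior_spec(), config = sampler_config(),
                      rounding = c("exact", "nearest_0.1"),
                      basis = "candidate_range", bounds = NULL, direction = 1,
                      sweep_plan = NULL, scenarios = NULL) {
  rounding <- match.arg(rounding)
  stopifnot(length(outcomes) >= 1L, !is.null(names(outcomes)),
            setequal(names(outcomes), names(points)))
  fits <- list()
  eos <- list()
  for (i in seq_along(outcomes)) {
    nm <- names(outcomes)[i]
    cfg_i <- config
    cfg_i$seed <- config$seed + (i - 1L)
    fits[[nm]] <- fit_factorial_bayes(
      dataset, outcome = outcomes[[nm]], design = design,
      covariates = covariates[[nm]] %||% character(),
      prior = prior, config = cfg_i)
    eos[[nm]] <- predict_conditions(fits[[nm]])
  }
  means <- condition_means(eos)
  dec <- decide(means, points[names(outcomes)], rounding = rounding,
                basis = basis, bounds = bounds, direction = direction)
  vt <- dec$value_table
  top2 <- list(labels = vt$label[1:2], values = vt$value[1:2],
               gap = vt$value[1] - vt$value[2])
  report <- list(
    design = design, fits = fits,
    effect_summaries = lapply(fits, summarize_effects),
    means = means, decision = dec, selected = dec$selected, top2 = top2,
    step1 = if (!is.null(sweep_plan))
      sweep_step1(means, sweep_plan, rounding, basis, bounds, direction),
    step2 = if (!is.null(sweep_plan))
      sweep_step2(means, sweep_plan, rounding, basis, bounds, direction),
    scenarios = if (!is.null(scenarios))
      run_scenarios(means, scenarios, rounding, basis, bounds, direction),
    converged = all(vapply(fits, `[[`, TRUE, "converged")),
    config = list(prior = prior, sampler = config, points = points,
                  rounding = rounding, basis = basis, bounds = bounds,
                  direction = direction))
  class(report) <- "daive_report"
  report
}

#' @export
print.daive_report <- function(x, ...) {
  cat("DAIVE decision report\n")
  cat(sprintf("  outcomes: %s\n", paste(names(x$fits), collapse = ", ")))
  cat(sprintf("  weights (%s): %s\n", x$decision$weights$mode,
              paste(sprintf("%s=%.3g", names(x$decision$weights$weights),
                            x$decision$weights$weights), collapse = ", ")))
  cat(sprintf("  selected condition: %s (V = %.3f)\n",
              x$selected$label, x$selected$value))
  cat(sprintf("  runner-up: %s (V = %.3f, gap %.3f)\n",
              x$top2$labels[2], x$top2$values[2], x$top2$gap))
  if (!x$converged)
    cat("  WARNING: at least one fit did not pass convergence checks;\n",
        "  treat this report as provisional\n")
  if (!is.null(x$step1)) {
    sel <- unique(c(x$step1$selected, x$step2$selected))
    cat(sprintf("  weight sweeps: %d settings, selection%s: %s\n",
                nrow(x$step1) + nrow(x$step2),
                if (length(sel) > 1L) "s" else "",
                paste(sel, collapse = "; ")))
  }
  invisible(x)
}

selection_factors <- function(x) {
  if (inherits(x, "daive_report")) x <- x$selected
  if (inherits(x, "daive_selection")) x <- x$label
  stopifnot(is.character(x))
  if (length(x) == 1L && grepl(",", x)) x <- trimws(strsplit(x, ",")[[1]])
  setdiff(x, "None")
}

#' Compare two selected interventions
#'
#' Lists the factor sets at their higher level in each selection and their
#' symmetric difference (set semantics, order-insensitive).
#'
#' @param a,b `daive_report`s, `daive_selection`s, condition labels such as
#'   `"SE, P"`, or character vectors of factor abbreviations.
#' @return A list: `a`, `b` (factor sets), `symmetric_difference`,
#'   `identical`.
#' @export
compare_selections <- function(a, b) {
  if (inherits(a, "daive_report") && inherits(b, "daive_report") &&
      !identical(a$design$factors$name, b$design$factors$name))
    stop("reports come from different designs")
  fa <- selection_factors(a)
  fb <- selection_factors(b)
  list(a = fa, b = fb,
       symmetric_difference = union(setdiff(fa, fb), setdiff(fb, fa)),
       identical = setequal(fa, fb))
}
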