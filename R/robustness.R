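#' Plan for systematically varying outcome weights
#'
#' Describes the two-step robustness exercise around an initial points
#' vector: Step 1 incrementally reduces the secondary outcomes' points
#' (least important first, holding all other points constant), Step 2
#' incrementally increases them (more important secondary first) until all
#' outcomes are equally important. Grids are explicit point vectors so any
#' published grid — including ones with a final jump to the floor or to
#' equality — can be encoded exactly; [points_grid()] builds regular ones.
#'
#' @param initial_points named positive numeric vector, ordered or orderable
#'   by importance (the first name is the primary outcome).
#' @param step1_grids named list, in sweep order (least important outcome
#'   first): for each swept outcome the decreasing point values to visit
#'   (all below its initial points, ending at its floor).
#' @param step2_grids named list, in sweep order (most important secondary
#'   outcome first): increasing point values to visit (all above its initial
#'   points, ending at the primary outcome's points).
#' @return An object of class `weight_sweep_plan`.
#' @export
weight_sweep_plan <- function(initial_points, step1_grids, step2_grids) {
  stopifnot(!is.null(names(initial_points)), all(initial_points > 0))
  for (nm in names(step1_grids)) {
    g <- step1_grids[[nm]]
    if (!nm %in% names(initial_points)) stop("unknown outcome in step 1: ", nm)
    if (any(diff(g) >= 0) || any(g >= initial_points[nm]) || any(g < 0))
      stop("step 1 grid for '", nm,
           "' must decrease strictly from below its initial points, floor >= 0")
  }
  primary <- names(initial_points)[which.max(initial_points)]
  for (nm in names(step2_grids)) {
    g <- step2_grids[[nm]]
    if (!nm %in% names(initial_points)) stop("unknown outcome in step 2: ", nm)
    if (any(diff(g) <= 0) || any(g <= initial_points[nm]))
      stop("step 2 grid for '", nm,
           "' must increase strictly from above its initial points")
    if (max(g) > initial_points[primary])
      stop("step 2 grid for '", nm, "' exceeds the primary outcome's points")
  }
  structure(list(initial_points = initial_points, step1_grids = step1_grids,
                 step2_grids = step2_grids, primary = primary),
            class = "weight_sweep_plan")
}

#' Regular point grid helper
#'
#' `seq(from, to, by = +/-step)` excluding `from`, with `to` appended if the
#' regular steps do not land on it (the "final jump").
#'
#' @param from starting points (excluded from the result).
#' @param to endpoint (always included).
#' @param step positive step size.
#' @return Numeric vector of point values.
#' @export
points_grid <- function(from, to, step) {
  stopifnot(step > 0)
  s <- if (to < from) seq(from - step, to, by = -step)
       else seq(from + step, to, by = step)
  if (length(s) == 0L || s[length(s)] != to) s <- c(s, to)
  s
}

#' The leaflet trial's default weight-variation plan
#'
#' Initial points 100 (beliefs), 50 (knowledge), 25 (satisfaction). Step 1
#' reduces satisfaction 25 -> 15 -> 5, then knowledge 50 -> 40 -> ... -> 10
#' -> 5 (8 point settings including the initial one). Step 2 increases
#' knowledge 50 -> 60 -> ... -> 100, then satisfaction 25 -> 35 -> ... -> 85
#' with a final jump to 100, ending with all three outcomes at 100 points
#' (13 settings including the initial one).
#'
#' @return A [weight_sweep_plan()].
#' @export
leaflet_sweep_plan <- function() {
  weight_sweep_plan(
    initial_points = c(beliefs = 100, knowledge = 50, satisfaction = 25),
    step1_grids = list(satisfaction = c(15, 5),
                       knowledge = c(40, 30, 20, 10, 5)),
    step2_grids = list(knowledge = c(60, 70, 80, 90, 100),
                       satisfaction = c(35, 45, 55, 65, 75, 85, 100)))
}

sweep_rows <- function(initial_points, grids) {
  pts <- initial_points
  rows <- list(pts)
  for (nm in names(grids)) {
    for (v in grids[[nm]]) {
      pts[nm] <- v
      rows[[length(rows) + 1L]] <- pts
    }
  }
  do.call(rbind, rows)
}

run_sweep <- function(means, points_rows, rounding, basis, bounds, direction) {
  res <- lapply(seq_len(nrow(points_rows)), function(i)
    decide(means, points_rows[i, ], rounding = rounding, basis = basis,
           bounds = bounds, direction = direction))
  out <- as.data.frame(points_rows)
  out$selected <- vapply(res, function(r) r$selected$label, character(1))
  out$selected_index <- vapply(res, function(r) r$selected$index, numeric(1))
  out$value <- vapply(res, function(r) r$selected$value, numeric(1))
  structure(out, decisions = res, class = c("sweep_table", "data.frame"))
}

#' Step 1: systematically reduce the secondary outcomes' importance
#'
#' Starting at the plan's initial points, walks each Step-1 grid in order
#' (least important outcome first, holding all other points constant; swept
#' outcomes stay at their floor while later ones are swept), re-deriving
#' weights, values and the selected condition at every point setting.
#'
#' @param means a [condition_means()] object.
#' @param plan a [weight_sweep_plan()] (default [leaflet_sweep_plan()]).
#' @param rounding,basis,bounds,direction passed to [decide()].
#' @return A data frame (class `sweep_table`): one row per point setting
#'   with the points per outcome, the selected condition's label, index and
#'   value; full per-row decisions in attribute `decisions`.
#' @export
sweep_step1 <- function(means, plan = leaflet_sweep_plan(),
                        rounding = "exact", basis = "candidate_range",
                        bounds = NULL, direction = 1) {
  stopifnot(inherits(plan, "weight_sweep_plan"))
  run_sweep(means, sweep_rows(plan$initial_points, plan$step1_grids),
            rounding, basis, bounds, direction)
}

#' Step 2: systematically increase the secondary outcomes' importance
#'
#' As [sweep_step1()], but walking the Step-2 grids (more important
#' secondary outcome first) up to equal importance with the primary outcome.
#'
#' @inheritParams sweep_step1
#' @return A `sweep_table` data frame.
#' @export
sweep_step2 <- function(means, plan = leaflet_sweep_plan(),
                        rounding = "exact", basis = "candidate_range",
                        bounds = NULL, direction = 1) {
  stopifnot(inherits(plan, "weight_sweep_plan"))
  run_sweep(means, sweep_rows(plan$initial_points, plan$step2_grids),
            rounding, basis, bounds, direction)
}

#' Named preference scenarios
#'
#' @param scenarios named list; each element a list with `points` (named
#'   nonnegative vector, at least one positive) and optional `description`.
#' @return An object of class `scenario_set`.
#' @export
scenario_set <- function(scenarios) {
  stopifnot(length(scenarios) >= 1L, !is.null(names(scenarios)))
  for (nm in names(scenarios)) {
    s <- scenarios[[nm]]
    if (is.null(s$points) || all(s$points == 0) || any(s$points < 0))
      stop("scenario '", nm,
           "' needs nonnegative points with at least one positive")
    if (is.null(s$description)) scenarios[[nm]]$description <- ""
  }
  structure(scenarios, class = "scenario_set")
}

#' The leaflet trial's preference scenarios
#'
#' The initial preferences plus six scenarios that deviate from them:
#' secondary outcomes reversed; each outcome alone as the single primary
#' outcome; and two two-outcome ties.
#'
#' @return A [scenario_set()].
#' @export
leaflet_scenarios <- function() {
  p <- function(b, k, s) c(beliefs = b, knowledge = k, satisfaction = s)
  scenario_set(list(
    initial = list(points = p(100, 50, 25), description = "Initial preferences."),
    scenario_1 = list(points = p(100, 25, 50),
      description = "Relative importance of knowledge and satisfaction reversed."),
    scenario_2 = list(points = p(100, 0, 0),
      description = "Medication beliefs as the single primary outcome."),
    scenario_3 = list(points = p(0, 100, 0),
      description = "Objective knowledge as the single primary outcome."),
    scenario_4 = list(points = p(0, 0, 100),
      description = "Satisfaction with information as the single primary outcome."),
    scenario_5 = list(points = p(100, 100, 0),
      description = "Beliefs and knowledge equally important."),
    scenario_6 = list(points = p(100, 0, 100),
      description = "Beliefs and satisfaction equally important.")))
}

#' Evaluate named preference scenarios
#'
#' Runs an independent decision per scenario. Outcomes with zero points are
#' excluded from scaling and weighting (weight 0).
#'
#' @param means a [condition_means()] object.
#' @param scenarios a [scenario_set()] (default [leaflet_scenarios()]).
#' @param rounding,basis,bounds,direction passed to [decide()].
#' @return A data frame (class `sweep_table`): scenario name, points per
#'   outcome, description, selected condition; per-scenario decisions in
#'   attribute `decisions`.
#' @export
run_scenarios <- function(means, scenarios = leaflet_scenarios(),
                          rounding = "exact", basis = "candidate_range",
                          bounds = NULL, direction = 1) {
  stopifnot(inherits(scenarios, "scenario_set"))
  res <- lapply(scenarios, function(s)
    decide(means, s$points, rounding = rounding, basis = basis,
           bounds = bounds, direction = direction))
  pts <- do.call(rbind, lapply(scenarios, `[[`, "points"))
  out <- data.frame(scenario = names(scenarios), pts,
                    description = vapply(scenarios, `[[`, character(1),
                                         "description"),
                    selected = vapply(res, function(r) r$selected$label,
                                      character(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, decisions = res, class = c("sweep_table", "data.frame"))
}
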