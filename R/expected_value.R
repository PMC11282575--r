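#' Posterior expected outcomes for every candidate condition
#'
#' For each posterior draw and each of the `2^k` candidate conditions,
#' computes the predicted outcome `Yhat = b0 + sum(coef x coded term value)`
#' (plus covariate terms at reference values). No screening of effects is
#' applied: every term contributes to every prediction.
#'
#' @param post a [fit_factorial_bayes()] result.
#' @param covariate_values reference covariate values for prediction:
#'   `"mean"` (default) predicts for the average participant (covariates at
#'   their sample means), or a named numeric vector of raw-scale values.
#' @return An object of class `expected_outcomes`: `draws` (matrix, draws x
#'   conditions), `mean` (per-condition posterior mean), `conditions` (the
#'   [enumerate_conditions()] table) and `outcome`.
#' @export
predict_conditions <- function(post, covariate_values = "mean") {
  stopifnot(inherits(post, "daive_posterior"))
  design <- post$design
  cond <- enumerate_conditions(design)
  C <- build_model_matrix(design, cond, coding = post$coding)
  coefs <- post$draws[, colnames(C), drop = FALSE]
  yhat <- coefs %*% t(C)
  if (length(post$covariates)) {
    if (identical(covariate_values, "mean")) {
      cv <- post$covariate_centers  # centered at fit, so contribution is 0
    } else {
      missing <- setdiff(post$covariates, names(covariate_values))
      if (length(missing))
        stop("missing covariate value(s): ", paste(missing, collapse = ", "))
      cv <- covariate_values[post$covariates]
    }
    shift <- drop(post$draws[, post$covariates, drop = FALSE] %*%
                    (cv - post$covariate_centers))
    yhat <- yhat + shift
  }
  colnames(yhat) <- cond$label
  structure(list(draws = yhat, mean = colMeans(yhat), conditions = cond,
                 outcome = post$outcome, design = design),
            class = "expected_outcomes")
}

#' @export
print.expected_outcomes <- function(x, ...) {
  cat(sprintf("Posterior expected outcomes for '%s' (%d draws x %d conditions)\n",
              x$outcome, nrow(x$draws), ncol(x$draws)))
  best <- which.max(x$mean)
  cat(sprintf("  best condition by posterior mean: %s (%.3f)\n",
              x$conditions$label[best], x$mean[best]))
  invisible(x)
}

#' Assemble per-condition posterior means for several outcomes
#'
#' @param ... named [predict_conditions()] results (or a single named list
#'   of them). Names default to each object's outcome name.
#' @return An object of class `condition_means`: a conditions x outcomes
#'   matrix of posterior-mean expected outcomes, with the condition table as
#'   attribute `conditions`, the design as `design`, and the per-draw
#'   matrices retained as `draws`.
#' @export
condition_means <- function(...) {
  eos <- list(...)
  if (length(eos) == 1L && !inherits(eos[[1]], "expected_outcomes"))
    eos <- eos[[1]]
  stopifnot(length(eos) >= 1L,
            all(vapply(eos, inherits, TRUE, "expected_outcomes")))
  if (is.null(names(eos)) || any(!nzchar(names(eos))))
    names(eos) <- vapply(eos, `[[`, character(1), "outcome")
  cond <- eos[[1]]$conditions
  for (e in eos)
    if (!identical(e$conditions$label, cond$label))
      stop("expected-outcome tables come from different designs")
  M <- vapply(eos, `[[`, numeric(nrow(cond)), "mean")
  M <- matrix(M, nrow = nrow(cond),
              dimnames = list(cond$label, names(eos)))
  structure(M, conditions = cond, design = eos[[1]]$design,
            draws = lapply(eos, `[[`, "draws"),
            class = c("condition_means", "matrix"))
}

#' Derive outcome weights from swing-weighting points
#'
#' Weights are each outcome's points divided by the total points. In
#' `"nearest_0.1"` mode each exact weight is additionally rounded to the
#' nearest 0.1 (so 100/50/25 points give 0.6/0.3/0.1); rounded weights need
#' not sum to 1, and both are returned.
#'
#' @param points named positive numeric vector of swing points.
#' @param rounding `"exact"` or `"nearest_0.1"`.
#' @return A list of class `swing_weights`: `points`, `exact`, `rounded`,
#'   `mode`, and `weights` (the vector selected by `rounding`).
#' @export
swing_points_to_weights <- function(points,
                                    rounding = c("exact", "nearest_0.1")) {
  rounding <- match.arg(rounding)
  if (any(points <= 0)) stop("swing points must be positive")
  exact <- points / sum(points)
  rounded <- round(exact * 10) / 10
  structure(list(points = points, exact = exact, rounded = rounded,
                 mode = rounding,
                 weights = if (rounding == "exact") exact else rounded),
            class = "swing_weights")
}

#' @export
print.swing_weights <- function(x, ...) {
  cat("Swing weights (", x$mode, " mode)\n", sep = "")
  tab <- rbind(points = x$points, exact = round(x$exact, 4),
               rounded = x$rounded)
  print(tab)
  invisible(x)
}

#' Scale per-condition outcomes to a common 0-1 range
#'
#' Puts each outcome on a 0-1 scale where 0 is worst and 1 is best. Under
#' the default candidate-range basis the worst candidate condition maps to 0
#' and the best to 1 (an affine map per outcome, so any positive affine
#' transform of an outcome leaves the scaled values unchanged). A fixed-range
#' basis uses supplied instrument bounds instead. `direction = -1` marks a
#' lower-is-better outcome.
#'
#' @param means a [condition_means()] object or conditions x outcomes matrix.
#' @param basis `"candidate_range"` or `"fixed_range"`.
#' @param bounds for `"fixed_range"`: a 2 x J matrix or named list of
#'   `c(lo, hi)` per outcome.
#' @param direction +1 (higher is better, default) or -1 per outcome;
#'   recycled.
#' @return A matrix like `means` with values in 0..1 (candidate-range basis
#'   guarantees an exact 0 and 1 per column).
#' @export
scale_outcomes <- function(means, basis = c("candidate_range", "fixed_range"),
                           bounds = NULL, direction = 1) {
  basis <- match.arg(basis)
  M <- unclass_means(means)
  J <- ncol(M)
  direction <- rep(direction, length.out = J)
  S <- M
  for (j in seq_len(J)) {
    if (basis == "candidate_range") {
      lo <- min(M[, j]); hi <- max(M[, j])
      if (hi - lo <= 0)
        stop("zero candidate range for outcome '", colnames(M)[j],
             "'; use the fixed-range basis")
    } else {
      if (is.null(bounds)) stop("fixed_range basis needs bounds")
      b <- if (is.list(bounds)) bounds[[colnames(M)[j]]] else bounds[, j]
      if (is.null(b) || length(b) != 2L)
        stop("no bounds for outcome '", colnames(M)[j], "'")
      lo <- b[1]; hi <- b[2]
      if (hi <= lo) stop("invalid bounds for outcome '", colnames(M)[j], "'")
    }
    S[, j] <- (M[, j] - lo) / (hi - lo)
    if (direction[j] < 0) S[, j] <- 1 - S[, j]
  }
  S
}

unclass_means <- function(means) {
  M <- means
  class(M) <- "matrix"
  attr(M, "conditions") <- NULL; attr(M, "draws") <- NULL
  attr(M, "design") <- NULL
  as.matrix(M)
}

#' Combine scaled outcomes into expected values
#'
#' Evaluates the linear value function `V = sum_j w_j * Y_j` for every
#' candidate condition and ranks conditions by descending value.
#'
#' @param scaled conditions x outcomes matrix of scaled (0-1) outcomes.
#' @param weights a [swing_points_to_weights()] object or named numeric
#'   vector aligned with the outcome columns.
#' @param conditions optional [enumerate_conditions()] table for labels and
#'   tie-break bookkeeping (taken from `scaled`'s source when available).
#' @return A data frame of class `value_table`, ranked by descending value:
#'   `rank`, `index`, `label`, `n_high`, one scaled column per outcome, and
#'   `value`.
#' @export
compute_value <- function(scaled, weights, conditions = NULL) {
  w <- if (inherits(weights, "swing_weights")) weights$weights else weights
  M <- unclass_means(scaled)
  if (is.null(names(w))) {
    if (length(w) != ncol(M)) stop("weight/outcome mismatch")
    names(w) <- colnames(M)
  }
  if (!setequal(names(w), colnames(M)))
    stop("weight names do not match outcome columns")
  w <- w[colnames(M)]
  V <- drop(M %*% w)
  if (is.null(conditions)) conditions <- attr(scaled, "conditions")
  if (is.null(conditions))
    conditions <- data.frame(index = seq_len(nrow(M)),
                             label = rownames(M) %||% as.character(seq_len(nrow(M))),
                             n_high = NA_integer_)
  out <- data.frame(index = conditions$index, label = conditions$label,
                    n_high = conditions$n_high, stringsAsFactors = FALSE)
  for (j in colnames(M)) out[[paste0("scaled_", j)]] <- M[, j]
  out$value <- V
  # rank: value desc; ties prefer fewer higher-level factors, then index
  ord <- order(-out$value, out$n_high, out$index)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out[, c("rank", setdiff(names(out), "rank"))],
            weights = w, class = c("value_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the value-maximizing condition from a value table
#'
#' Ties on value are broken in favor of fewer factors at their higher level
#' (the smaller intervention package), then by condition index; the ranking
#' in the table already reflects this.
#'
#' @param vt a [compute_value()] result.
#' @return A list of class `daive_selection`: `index`, `label`, `n_high`,
#'   `value`, `tied` (labels sharing the maximal value, if any).
#' @export
select_condition <- function(vt) {
  stopifnot(inherits(vt, "value_table"))
  top <- vt[1L, ]
  tied <- vt$label[abs(vt$value - top$value) < 1e-12]
  structure(list(index = top$index, label = top$label, n_high = top$n_high,
                 value = top$value, tied = tied),
            class = "daive_selection")
}

#' @export
print.daive_selection <- function(x, ...) {
  cat(sprintf("Selected condition: %s (expected value %.3f)\n",
              x$label, x$value))
  if (length(x$tied) > 1L)
    cat("  note: tied with", paste(setdiff(x$tied, x$label), collapse = ", "),
        "- tie broken toward fewer higher-level components\n")
  invisible(x)
}

#' One-shot decision at a given points vector
#'
#' Convenience wrapper: weights from points, scale, value, select.
#'
#' @param means a [condition_means()] object.
#' @param points named positive swing points (outcomes with zero points are
#'   dropped from scaling and weighting).
#' @param rounding weight mode, see [swing_points_to_weights()].
#' @param basis,bounds,direction see [scale_outcomes()].
#' @return A list: `points`, `weights`, `value_table`, `selected`.
#' @export
decide <- function(means, points, rounding = c("exact", "nearest_0.1"),
                   basis = "candidate_range", bounds = NULL, direction = 1) {
  rounding <- match.arg(rounding)
  M <- unclass_means(means)
  if (is.null(names(points)) && length(points) == ncol(M))
    names(points) <- colnames(M)
  if (!all(names(points) %in% colnames(M)))
    stop("points name(s) not among outcomes")
  if (all(points == 0)) stop("at least one outcome needs positive points")
  direction <- rep(direction, length.out = ncol(M))
  names(direction) <- colnames(M)
  keep <- names(points)[points > 0]
  Mk <- M[, keep, drop = FALSE]
  attr(Mk, "conditions") <- attr(means, "conditions")
  w <- swing_points_to_weights(points[keep], rounding)
  S <- scale_outcomes(Mk, basis = basis, bounds = bounds,
                      direction = direction[keep])
  attr(S, "conditions") <- attr(means, "conditions")
  vt <- compute_value(S, w)
  list(points = points, weights = w, value_table = vt,
       selected = select_condition(vt))
}

#' Per-draw distribution of condition values
#'
#' Evaluates the value function on each posterior draw rather than on
#' posterior means. Under a fixed-range basis this commutes with averaging
#' (the value function is linear), so the draw-mean values equal the
#' mean-then-value results; under the candidate-range basis the scaling
#' itself depends on the draw, and the two can diverge — this function makes
#' that divergence inspectable instead of hiding it.
#'
#' @param means a [condition_means()] built from predictions that retained
#'   their draws.
#' @param points,rounding,basis,bounds,direction as in [decide()].
#' @return A draws x conditions matrix of values.
#' @export
value_draws <- function(means, points, rounding = "exact",
                        basis = "fixed_range", bounds = NULL, direction = 1) {
  draws <- attr(means, "draws")
  if (is.null(draws)) stop("no per-draw predictions retained")
  M <- unclass_means(means)
  if (is.null(names(points)) && length(points) == ncol(M))
    names(points) <- colnames(M)
  keep <- names(points)[points > 0]
  w <- swing_points_to_weights(points[keep], rounding)$weights
  direction <- rep(direction, length.out = ncol(M))
  names(direction) <- colnames(M)
  nd <- nrow(draws[[keep[1]]])
  V <- matrix(0, nd, ncol(draws[[keep[1]]]),
              dimnames = dimnames(draws[[keep[1]]]))
  for (j in keep) {
    D <- draws[[j]]
    if (basis == "fixed_range") {
      b <- if (is.list(bounds)) bounds[[j]] else bounds[, j]
      if (is.null(b)) stop("no bounds for outcome '", j, "'")
      Sj <- (D - b[1]) / (b[2] - b[1])
    } else {
      rng <- apply(D, 1L, range)
      Sj <- (D - rng[1, ]) / (rng[2, ] - rng[1, ])
    }
    if (direction[j] < 0) Sj <- 1 - Sj
    V <- V + w[j] * Sj
  }
  V
}

#' Export a value table as CSV
#'
#' One row per condition, ranked: the "factors set to higher level" label,
#' scaled outcome columns and the expected value.
#'
#' @param vt a [compute_value()] result.
#' @param path file path.
#' @return `vt`, invisibly.
#' @export
write_value_table <- function(vt, path) {
  utils::write.csv(as.data.frame(vt), path, row.names = FALSE)
  invisible(vt)
}
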