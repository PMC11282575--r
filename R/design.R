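#' Define a two-level full factorial design
#'
#' A design is an ordered set of `k` two-level factors. Each factor has a
#' `low` and a `high` level; by convention the high level is the "on" or
#' "enhanced" level of the candidate intervention component, so conditions
#' are naturally described by the set of factors set to their higher level.
#'
#' @param factors either a character vector of factor names (level labels
#'   default to `"low"`/`"high"`), or a data frame with columns `name`,
#'   `low_label`, `high_label` and optionally `abbrev` (short label used in
#'   condition labels; defaults to the name).
#' @return An object of class `factorial_design` with elements `factors`
#'   (data frame) and `k`.
#' @examples
#' d <- factorial_design(c("A", "B", "C"))
#' n_conditions(d)
#' @export
factorial_design <- function(factors) {
  if (is.character(factors)) {
    factors <- data.frame(name = factors,
                          low_label = "low", high_label = "high",
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(factors),
            all(c("name", "low_label", "high_label") %in% names(factors)))
  if (is.null(factors$abbrev)) factors$abbrev <- factors$name
  if (nrow(factors) < 1L) stop("a design needs at least one factor")
  if (anyDuplicated(factors$name)) stop("factor names must be unique")
  structure(list(factors = factors, k = nrow(factors)),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf("2^%d full factorial design (%d candidate conditions)\n",
              x$k, n_conditions(x)))
  for (i in seq_len(x$k))
    cat(sprintf("  %s: %s / %s\n", x$factors$name[i],
                x$factors$low_label[i], x$factors$high_label[i]))
  invisible(x)
}

#' Number of candidate conditions in a design
#' @param design a [factorial_design()].
#' @return `2^k`.
#' @export
n_conditions <- function(design) {
  stopifnot(inherits(design, "factorial_design"))
  2L^design$k
}

#' The five-factor information-leaflet design
#'
#' The 2^5 design of the AET (adjuvant endocrine therapy) information-leaflet
#' optimization trial: five candidate leaflet components, each operationalized
#' as a two-level factor. `diagrams`, `concerns` and `patient` are on/off;
#' `benefits` and `side_effects` are enhanced/basic.
#'
#' @return A `factorial_design` with 32 candidate conditions.
#' @export
leaflet_design <- function() {
  factorial_design(data.frame(
    name = c("diagrams", "benefits", "side_effects", "concerns", "patient"),
    low_label = c("off", "basic", "basic", "off", "off"),
    high_label = c("on", "enhanced", "enhanced", "on", "on"),
    abbrev = c("D", "B", "SE", "C", "P"),
    stringsAsFactors = FALSE))
}

#' Enumerate all candidate conditions of a design
#'
#' Conditions are ordered with the first factor varying slowest and the high
#' level listed before the low level, so condition 1 has every factor at its
#' higher level and condition `2^k` has every factor at its lower level
#' (the layout used in the trial's condition table).
#'
#' @param design a [factorial_design()].
#' @return A data frame with one row per condition: `index` (1..2^k),
#'   `label` (comma-separated abbreviations of the factors at their higher
#'   level, `"None"` if all are low), `n_high`, and one character column per
#'   factor holding `"low"` or `"high"`.
#' @export
enumerate_conditions <- function(design) {
  stopifnot(inherits(design, "factorial_design"))
  k <- design$k
  nm <- design$factors$name
  # first factor slowest, high ("bit" 0) before low
  grid <- expand.grid(rep(list(c("high", "low")), k),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_len(k)), drop = FALSE]
  names(grid) <- nm
  out <- cbind(data.frame(index = seq_len(2L^k)), grid)
  out$n_high <- rowSums(grid == "high")
  out$label <- condition_label(design, grid)
  out[, c("index", "label", "n_high", nm)]
}

#' Label conditions by their higher-level factors
#'
#' @param design a [factorial_design()].
#' @param conditions a data frame with one `"low"`/`"high"` column per factor.
#' @return Character vector like `"SE, P"`, or `"None"` when every factor is
#'   at its lower level.
#' @export
condition_label <- function(design, conditions) {
  ab <- design$factors$abbrev
  nm <- design$factors$name
  apply(as.matrix(conditions[, nm, drop = FALSE]), 1L, function(r) {
    hi <- ab[r == "high"]
    if (length(hi) == 0L) "None" else paste(hi, collapse = ", ")
  })
}

#' Enumerate the saturated model's effect terms
#'
#' All non-empty subsets of the factors: the `k` main effects, then all
#' two-way interactions, and so on up to the single `k`-way interaction —
#' `2^k - 1` terms in total, ordered by interaction order and then
#' lexicographically by factor position.
#'
#' @param design a [factorial_design()].
#' @return A named list of integer vectors (factor positions); names are term
#'   labels such as `"diagrams:patient"`.
#' @export
model_terms <- function(design) {
  stopifnot(inherits(design, "factorial_design"))
  k <- design$k
  nm <- design$factors$name
  terms <- list()
  for (ord in seq_len(k)) {
    combos <- utils::combn(k, ord, simplify = FALSE)
    names(combos) <- vapply(combos, function(ix) paste(nm[ix], collapse = ":"),
                            character(1))
    terms <- c(terms, combos)
  }
  terms
}

#' Build the saturated design matrix for a set of condition assignments
#'
#' @param design a [factorial_design()].
#' @param assignments a data frame with one `"low"`/`"high"` column per
#'   factor (rows may repeat, e.g. one row per participant).
#' @param coding `"effect"` maps low to -1 and high to +1; `"treatment"`
#'   maps low to 0 and high to 1. Interaction columns are products of the
#'   constituent main-effect columns. Fitted cell means from the saturated
#'   model are identical under either coding.
#' @return A numeric matrix with an `"(Intercept)"` column followed by one
#'   column per model term.
#' @export
build_model_matrix <- function(design, assignments,
                               coding = c("effect", "treatment")) {
  coding <- match.arg(coding)
  nm <- design$factors$name
  missing <- setdiff(nm, names(assignments))
  if (length(missing))
    stop("assignments lack factor column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(unlist(lapply(assignments[nm], unique))),
                 c("low", "high"))
  if (length(bad))
    stop("factor levels must be 'low'/'high'; found: ",
         paste(bad, collapse = ", "))
  lowval <- if (coding == "effect") -1 else 0
  main <- vapply(nm, function(f) ifelse(assignments[[f]] == "high", 1, lowval),
                 numeric(nrow(assignments)))
  main <- matrix(main, nrow = nrow(assignments),
                 dimnames = list(NULL, nm))
  terms <- model_terms(design)
  X <- matrix(1, nrow(assignments), length(terms) + 1L,
              dimnames = list(NULL, c("(Intercept)", names(terms))))
  for (j in seq_along(terms))
    X[, j + 1L] <- apply(main[, terms[[j]], drop = FALSE], 1L, prod)
  X
}

#' Read a factorial design from a YAML file
#'
#' Expected layout: a top-level `factors` list, each entry with `name`,
#' `low_label`, `high_label` and optionally `abbrev`.
#'
#' @param path file path.
#' @return A `factorial_design`.
#' @export
read_design_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$factors)) stop("YAML design must have a 'factors' list")
  df <- do.call(rbind, lapply(spec$factors, function(f) {
    if (is.null(f$name) || is.null(f$low_label) || is.null(f$high_label))
      stop("each factor needs name, low_label and high_label")
    data.frame(name = f$name, low_label = f$low_label,
               high_label = f$high_label,
               abbrev = if (is.null(f$abbrev)) f$name else f$abbrev,
               stringsAsFactors = FALSE)
  }))
  factorial_design(df)
}

#' Write a design to YAML
#' @param design a [factorial_design()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_design_yaml <- function(design, path) {
  factors <- lapply(seq_len(design$k), function(i)
    as.list(design$factors[i, c("name", "low_label", "high_label", "abbrev")]))
  yaml::write_yaml(list(factors = factors), path)
  invisible(path)
}

#' Export the condition table as CSV
#'
#' One row per condition with the factors shown at their instrument-level
#' labels (e.g. on/off, enhanced/basic), mirroring the trial's printed
#' condition table.
#'
#' @param design a [factorial_design()].
#' @param path file path.
#' @param n_per_condition optional vector of randomization counts to append.
#' @return The exported data frame, invisibly.
#' @export
write_condition_table <- function(design, path, n_per_condition = NULL) {
  cond <- enumerate_conditions(design)
  nm <- design$factors$name
  for (i in seq_along(nm)) {
    f <- design$factors[i, ]
    cond[[nm[i]]] <- ifelse(cond[[nm[i]]] == "high",
                            f$high_label, f$low_label)
  }
  if (!is.null(n_per_condition)) {
    stopifnot(length(n_per_condition) == nrow(cond))
    cond$n_randomized <- n_per_condition
  }
  utils::write.csv(cond, path, row.names = FALSE)
  invisible(cond)
}
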