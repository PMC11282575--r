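#' Per-condition randomization counts of the leaflet trial
#'
#' The number of participants randomized to each of the 32 conditions of the
#' 2^5 leaflet trial, in the condition order of [enumerate_conditions()]
#' (condition 1 = all factors high). Totals 1603.
#'
#' @return Integer vector of length 32.
#' @export
leaflet_n_per_condition <- function() {
  c(55L, 54L, 53L, 38L, 53L, 56L, 47L, 58L,
    45L, 57L, 42L, 50L, 54L, 41L, 49L, 63L,
    45L, 55L, 56L, 42L, 61L, 52L, 54L, 58L,
    44L, 51L, 40L, 50L, 46L, 39L, 43L, 52L)
}

#' Specify the ground truth of a synthetic factorial trial
#'
#' Describes the data-generating world behind [generate_trial()]: per-outcome
#' regression coefficients on the effect-coded saturated model, residual
#' scales, a cross-outcome residual correlation, per-condition sample sizes,
#' and a baseline measurement of the primary outcome.
#'
#' @param design a [factorial_design()].
#' @param outcomes named list; each element is a list with components
#'   `intercept` (numeric), `effects` (named numeric vector keyed by term
#'   labels from [model_terms()]; omitted terms are zero), `sd` (residual SD,
#'   > 0), optional `baseline_coef` (coefficient on the baseline measurement,
#'   default 0) and optional `range` (length-2 bounds used when discretizing).
#' @param resid_cor cross-outcome residual correlation: a scalar (compound
#'   symmetric) or a full correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite).
#' @param n_per_condition scalar or vector of length `2^k`, each >= 1.
#' @param baseline list with `mean`, `sd` and `range` for the baseline
#'   measurement of the primary (first) outcome; draws are from a normal
#'   truncated to `range` by resampling.
#' @param seed integer RNG seed recorded in the spec (used by
#'   [generate_trial()] unless overridden).
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(design, outcomes, resid_cor = 0.3,
                       n_per_condition = 50L,
                       baseline = list(mean = 5, sd = 6, range = c(-20, 20)),
                       seed = 1L) {
  stopifnot(inherits(design, "factorial_design"), length(outcomes) >= 1L,
            !is.null(names(outcomes)), all(nzchar(names(outcomes))))
  terms <- names(model_terms(design))
  J <- length(outcomes)
  for (nm in names(outcomes)) {
    o <- outcomes[[nm]]
    if (is.null(o$intercept) || is.null(o$sd))
      stop("outcome '", nm, "' needs intercept and sd")
    if (o$sd < 0) stop("residual SD must be >= 0 for outcome '", nm, "'")
    if (!is.null(o$effects)) {
      bad <- setdiff(names(o$effects), terms)
      if (length(bad))
        stop("unknown model term(s) in outcome '", nm, "': ",
             paste(bad, collapse = ", "))
    }
    if (is.null(o$baseline_coef)) outcomes[[nm]]$baseline_coef <- 0
  }
  if (is.matrix(resid_cor)) {
    R <- resid_cor
    stopifnot(nrow(R) == J, ncol(R) == J)
    if (max(abs(R - t(R))) > 1e-10 || max(abs(diag(R) - 1)) > 1e-10)
      stop("resid_cor must be symmetric with unit diagonal")
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("resid_cor must be positive semi-definite")
  } else {
    stopifnot(length(resid_cor) == 1L, resid_cor > -1, resid_cor < 1)
    R <- matrix(resid_cor, J, J); diag(R) <- 1
  }
  nc <- n_conditions(design)
  if (length(n_per_condition) == 1L)
    n_per_condition <- rep(n_per_condition, nc)
  stopifnot(length(n_per_condition) == nc, all(n_per_condition >= 1))
  structure(list(design = design, outcomes = outcomes, resid_cor = R,
                 n_per_condition = as.integer(n_per_condition),
                 baseline = baseline, seed = as.integer(seed)),
            class = "truth_spec")
}

#' Default ground truth emulating the leaflet trial
#'
#' A three-outcome truth on the instruments' natural scales — beliefs
#' differential (-20..20, with a baseline measurement), objective knowledge
#' (0..8) and satisfaction with information (0..11) — with per-condition
#' sample sizes equal to the trial's randomization counts (n = 1603 total).
#' Default effects encode a plausible component-performance pattern (a clear
#' patient-input main effect on beliefs plus a smaller side-effects effect
#' and their synergy); override `effects` to study other worlds.
#'
#' @param effects optional named list of per-outcome named effect vectors
#'   replacing the defaults.
#' @param resid_cor,n_per_condition,seed see [truth_spec()].
#' @return A `truth_spec` for [leaflet_design()].
#' @export
leaflet_truth <- function(effects = NULL, resid_cor = 0.3,
                          n_per_condition = leaflet_n_per_condition(),
                          seed = 1L) {
  def <- list(
    beliefs = c(patient = 0.8, side_effects = 0.4, `side_effects:patient` = 0.3),
    knowledge = c(benefits = 0.3, side_effects = 0.2),
    satisfaction = c(patient = 0.3, diagrams = 0.2))
  if (!is.null(effects)) def[names(effects)] <- effects
  truth_spec(
    leaflet_design(),
    outcomes = list(
      beliefs = list(intercept = 6, effects = def$beliefs, sd = 5,
                     baseline_coef = 0.5, range = c(-20, 20)),
      knowledge = list(intercept = 5.5, effects = def$knowledge, sd = 1.6,
                       range = c(0, 8)),
      satisfaction = list(intercept = 7, effects = def$satisfaction, sd = 2.4,
                          range = c(0, 11))),
    resid_cor = resid_cor, n_per_condition = n_per_condition, seed = seed)
}

rnorm_truncated <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  while (any(out <- x < range[1] | x > range[2]))
    x[out] <- stats::rnorm(sum(out), mean, sd)
  x
}

#' Generate a synthetic participant-level trial dataset
#'
#' For each condition, draws the specified number of participants. Each
#' outcome is intercept + sum(term coefficient x effect-coded term value) +
#' baseline coefficient x baseline score + residual, with residuals
#' correlated across outcomes within participant. Fully reproducible from
#' the seed; the truth is attached for recovery tests.
#'
#' @param design a [factorial_design()].
#' @param truth a [truth_spec()] for the same design.
#' @param seed RNG seed; defaults to the seed recorded in `truth`.
#' @param discretize if `TRUE`, round outcomes to integers and clip them to
#'   each outcome's `range` (the instruments' attainable scores), as needed
#'   before item-level disaggregation.
#' @return A data frame (class `trial_dataset`) with columns `participant`,
#'   `condition` (index), the factor columns (`"low"`/`"high"`), `baseline`,
#'   and one column per outcome. Attributes: `design`, `truth`, `seed`,
#'   `discretized`.
#' @export
generate_trial <- function(design, truth, seed = truth$seed,
                           discretize = FALSE) {
  stopifnot(inherits(truth, "truth_spec"))
  set.seed(seed)
  cond <- enumerate_conditions(design)
  nm <- design$factors$name
  idx <- rep(cond$index, truth$n_per_condition)
  dat <- cond[idx, c("index", nm)]
  names(dat)[1] <- "condition"
  rownames(dat) <- NULL
  n <- nrow(dat)
  dat <- cbind(participant = seq_len(n), dat)

  X <- build_model_matrix(design, dat, coding = "effect")
  b <- truth$baseline
  dat$baseline <- rnorm_truncated(n, b$mean, b$sd, b$range)

  onames <- names(truth$outcomes)
  J <- length(onames)
  sds <- vapply(truth$outcomes, `[[`, numeric(1), "sd")
  Sigma <- diag(sds, J) %*% truth$resid_cor %*% diag(sds, J)
  # correlated residuals via the Cholesky root; sd 0 columns stay exactly 0
  L <- chol(Sigma + diag(1e-12, J))
  eps <- matrix(stats::rnorm(n * J), n, J) %*% L
  eps[, sds == 0] <- 0

  terms <- colnames(X)[-1]
  for (j in seq_len(J)) {
    o <- truth$outcomes[[j]]
    beta <- stats::setNames(numeric(length(terms)), terms)
    if (!is.null(o$effects)) beta[names(o$effects)] <- o$effects
    y <- o$intercept + drop(X[, -1, drop = FALSE] %*% beta) +
      o$baseline_coef * dat$baseline + eps[, j]
    if (discretize) {
      y <- round(y)
      if (!is.null(o$range)) y <- pmin(pmax(y, o$range[1]), o$range[2])
    }
    dat[[onames[j]]] <- y
  }
  if (discretize) {
    dat$baseline <- round(dat$baseline)
    dat$baseline <- pmin(pmax(dat$baseline, b$range[1]), b$range[2])
  }
  structure(dat, design = design, truth = truth, seed = seed,
            discretized = discretize,
            class = c("trial_dataset", "data.frame"))
}

#' Write a trial dataset and its truth specification to disk
#'
#' The dataset is written as plain CSV (one row per participant); the truth
#' specification, including the generating seed, as YAML alongside it.
#'
#' @param dataset a [generate_trial()] result.
#' @param path CSV path; the YAML goes to `sub("\\\\.csv$", "_truth.yaml", path)`.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  truth <- attr(dataset, "truth")
  if (!is.null(truth)) {
    meta <- list(
      seed = attr(dataset, "seed"),
      discretized = isTRUE(attr(dataset, "discretized")),
      n_per_condition = truth$n_per_condition,
      resid_cor = as.vector(truth$resid_cor),
      baseline = truth$baseline,
      outcomes = lapply(truth$outcomes, function(o)
        list(intercept = o$intercept, sd = o$sd,
             baseline_coef = o$baseline_coef,
             effects = as.list(o$effects))))
    yaml::write_yaml(meta, sub("\\.csv$", "_truth.yaml", path))
  }
  invisible(path)
}

# distribute an integer sum over n_items items each in 1..5 by sequential
# conditional draws (each item uniform over the values that keep the
# remaining total attainable)
distribute_items <- function(total, n_items = 5L, lo = 1L, hi = 5L) {
  stopifnot(total >= n_items * lo, total <= n_items * hi)
  items <- integer(n_items)
  rem <- total
  for (i in seq_len(n_items)) {
    left <- n_items - i
    lo_i <- max(lo, rem - left * hi)
    hi_i <- min(hi, rem - left * lo)
    items[i] <- if (lo_i == hi_i) lo_i else sample(lo_i:hi_i, 1L)
    rem <- rem - items[i]
  }
  items
}

#' Satisfaction rating categories
#'
#' The five response categories of the satisfaction-with-information
#' instrument; `"about right"` and `"none needed"` indicate satisfaction.
#' @return Character vector of length 5.
#' @export
satisfaction_categories <- function() {
  c("too much", "about right", "too little", "none received", "none needed")
}

#' Disaggregate outcome scores into item-level instrument responses
#'
#' Adds item-level blocks whose instrument scores reproduce the stored
#' outcome scores exactly: 5 necessity + 5 concern belief items (1..5) whose
#' differential equals the beliefs score, 8 true/false knowledge responses
#' agreeing with the answer key on exactly the knowledge score, and 11
#' satisfaction ratings of which exactly the satisfaction score fall in a
#' satisfied category. The disaggregation is stochastic (the necessity total
#' is drawn uniformly over its attainable values, items by sequential
#' conditional draws) and seed-reproducible.
#'
#' @param dataset a discretized [generate_trial()] result (integer scores).
#' @param knowledge_key logical vector of length 8 with exactly 4 `TRUE`.
#' @param seed RNG seed.
#' @param beliefs,knowledge,satisfaction outcome column names.
#' @return The dataset with columns `nec_1..5`, `con_1..5`, `know_1..8`
#'   (logical) and `sat_1..11` appended, and the key stored in the
#'   `knowledge_key` attribute.
#' @export
generate_item_responses <- function(dataset,
                                    knowledge_key = rep(c(TRUE, FALSE), 4),
                                    seed = 1L,
                                    beliefs = "beliefs",
                                    knowledge = "knowledge",
                                    satisfaction = "satisfaction") {
  stopifnot(sum(knowledge_key) == 4L, length(knowledge_key) == 8L)
  for (col in c(beliefs, knowledge, satisfaction))
    if (is.null(dataset[[col]])) stop("missing outcome column: ", col)
  bd <- dataset[[beliefs]]; ks <- dataset[[knowledge]]; ss <- dataset[[satisfaction]]
  if (any(bd != round(bd)) || any(ks != round(ks)) || any(ss != round(ss)))
    stop("item-level disaggregation needs integer scores; ",
         "generate the trial with discretize = TRUE")
  if (any(bd < -20 | bd > 20)) stop("beliefs differential outside -20..20")
  if (any(ks < 0 | ks > 8)) stop("knowledge score outside 0..8")
  if (any(ss < 0 | ss > 11)) stop("satisfaction score outside 0..11")
  set.seed(seed)
  n <- nrow(dataset)
  nec <- matrix(0L, n, 5); con <- matrix(0L, n, 5)
  kno <- matrix(NA, n, 8); sat <- matrix("", n, 11)
  cats <- satisfaction_categories()
  good <- c("about right", "none needed")
  bad <- setdiff(cats, good)
  for (i in seq_len(n)) {
    d <- bd[i]
    # necessity total in 5..25 with concern total = necessity - d also in 5..25
    ns_lo <- max(5L, 5L + d); ns_hi <- min(25L, 25L + d)
    ns <- if (ns_lo == ns_hi) ns_lo else sample(ns_lo:ns_hi, 1L)
    nec[i, ] <- distribute_items(ns)
    con[i, ] <- distribute_items(ns - d)
    hit <- sample(8L, ks[i])
    kno[i, ] <- !knowledge_key
    kno[i, hit] <- knowledge_key[hit]
    si <- sample(11L, ss[i])
    sat[i, ] <- sample(bad, 11, replace = TRUE)
    if (length(si)) sat[i, si] <- sample(good, length(si), replace = TRUE)
  }
  colnames(nec) <- paste0("nec_", 1:5)
  colnames(con) <- paste0("con_", 1:5)
  colnames(kno) <- paste0("know_", 1:8)
  colnames(sat) <- paste0("sat_", 1:11)
  out <- cbind(dataset, as.data.frame(nec), as.data.frame(con),
               as.data.frame(kno), as.data.frame(sat, stringsAsFactors = FALSE))
  for (a in c("design", "truth", "seed", "discretized"))
    attr(out, a) <- attr(dataset, a)
  attr(out, "knowledge_key") <- knowledge_key
  class(out) <- class(dataset)
  out
}
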