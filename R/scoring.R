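#' Beliefs differential score
#'
#' Sum of the five necessity items minus the sum of the five concern items,
#' each item on a 1..5 agreement scale, giving a score in -20..+20. Higher
#' scores mean necessity beliefs outweigh concerns.
#'
#' @param necessity,concerns numeric vectors of length 5 (one respondent) or
#'   matrices/data frames with 5 columns (one row per respondent).
#' @return Integer score(s) in -20..+20.
#' @export
beliefs_differential <- function(necessity, concerns) {
  necessity <- as_item_matrix(necessity, 5L, "necessity")
  concerns <- as_item_matrix(concerns, 5L, "concerns")
  if (nrow(necessity) != nrow(concerns))
    stop("necessity and concerns must have the same number of respondents")
  check_range(necessity, 1, 5, "necessity")
  check_range(concerns, 1, 5, "concerns")
  drop(rowSums(necessity) - rowSums(concerns))
}

#' Objective knowledge score
#'
#' Number of the eight true/false responses matching the answer key (0..8).
#'
#' @param responses logical vector of length 8, or matrix with 8 columns.
#' @param key logical vector of length 8 (the answer key).
#' @return Integer score(s) in 0..8.
#' @export
knowledge_score <- function(responses, key) {
  responses <- as_item_matrix(responses, 8L, "responses")
  if (length(key) != 8L) stop("key must have 8 items")
  if (anyNA(responses) || anyNA(key)) stop("missing responses not supported")
  drop(rowSums(responses == matrix(key, nrow(responses), 8L, byrow = TRUE)))
}

#' Satisfaction-with-information score
#'
#' Across the 11 information domains, counts ratings indicating satisfaction:
#' `"about right"` or `"none needed"` score 1, all other categories
#' (`"too much"`, `"too little"`, `"none received"`) score 0, giving 0..11.
#'
#' @param ratings character vector of length 11, or matrix with 11 columns,
#'   with values from [satisfaction_categories()].
#' @return Integer score(s) in 0..11.
#' @export
satisfaction_score <- function(ratings) {
  ratings <- as_item_matrix(ratings, 11L, "ratings")
  bad <- setdiff(unique(as.vector(ratings)), satisfaction_categories())
  if (length(bad))
    stop("invalid satisfaction categories: ", paste(bad, collapse = ", "))
  drop(rowSums(matrix(ratings %in% c("about right", "none needed"),
                      nrow(ratings))))
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of an item set:
#' `alpha = m/(m-1) * (1 - sum(item variances) / variance of item sums)`,
#' with sample (n-1) variances.
#'
#' @param items numeric matrix or data frame, respondents in rows (n >= 2),
#'   items in columns (m >= 2). Missing values are rejected.
#' @return Alpha (<= 1; can be negative).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (anyNA(items)) stop("missing item responses not supported")
  n <- nrow(items); m <- ncol(items)
  if (n < 2L || m < 2L) stop("need at least 2 respondents and 2 items")
  vt <- stats::var(rowSums(items))
  if (vt <= 0) stop("total-score variance is zero; alpha undefined")
  m / (m - 1) * (1 - sum(apply(items, 2L, stats::var)) / vt)
}

#' Score item-level blocks of a trial dataset
#'
#' Recomputes the three outcome scores from the item columns produced by
#' [generate_item_responses()] (or read from CSV with the same column
#' naming), appending them as `<prefix>beliefs`, `<prefix>knowledge` and
#' `<prefix>satisfaction`.
#'
#' @param dataset data frame with columns `nec_1..5`, `con_1..5`,
#'   `know_1..8`, `sat_1..11`.
#' @param key answer key; defaults to the dataset's `knowledge_key` attribute.
#' @param prefix prefix for the new columns (default `"scored_"`).
#' @return The dataset with scored columns appended.
#' @export
score_trial_items <- function(dataset, key = attr(dataset, "knowledge_key"),
                              prefix = "scored_") {
  if (is.null(key)) stop("no answer key: supply 'key'")
  need <- c(paste0("nec_", 1:5), paste0("con_", 1:5),
            paste0("know_", 1:8), paste0("sat_", 1:11))
  missing <- setdiff(need, names(dataset))
  if (length(missing))
    stop("missing item columns: ", paste(missing, collapse = ", "))
  dataset[[paste0(prefix, "beliefs")]] <- beliefs_differential(
    dataset[paste0("nec_", 1:5)], dataset[paste0("con_", 1:5)])
  dataset[[paste0(prefix, "knowledge")]] <- knowledge_score(
    dataset[paste0("know_", 1:8)], key)
  dataset[[paste0(prefix, "satisfaction")]] <- satisfaction_score(
    dataset[paste0("sat_", 1:11)])
  dataset
}

as_item_matrix <- function(x, m, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != m) stop(what, " must have ", m, " items")
  x
}

check_range <- function(x, lo, hi, what) {
  if (anyNA(x)) stop("missing ", what, " items not supported")
  if (any(x < lo | x > hi) || any(x != round(x)))
    stop(what, " items must be integers in ", lo, "..", hi)
  invisible(x)
}
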