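#' Prior specification for the Bayesian factorial ANOVA
#'
#' Independent normal priors on regression coefficients and an inverse-gamma
#' prior on the residual variance. The factorial effect coefficients get
#' N(0, `coef_sd`^2) priors on the raw outcome scale (default SD 5, the
#' diffuse prior used for this model class); the intercept gets a much wider
#' N(0, `intercept_sd`^2) so the grand mean is essentially unrestricted.
#' Baseline-covariate coefficients share `coef_sd`.
#'
#' @param coef_sd prior SD for effect and covariate coefficients (> 0).
#' @param intercept_sd prior SD for the intercept (> 0).
#' @param resid_shape,resid_rate inverse-gamma shape and rate for the
#'   residual variance (both > 0; default 0.01/0.01, near-flat).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(coef_sd = 5, intercept_sd = 50,
                       resid_shape = 0.01, resid_rate = 0.01) {
  stopifnot(coef_sd > 0, intercept_sd > 0, resid_shape > 0, resid_rate > 0)
  structure(list(coef_sd = coef_sd, intercept_sd = intercept_sd,
                 resid_shape = resid_shape, resid_rate = resid_rate),
            class = "prior_spec")
}

#' Sampler configuration
#'
#' @param chains number of chains (>= 1).
#' @param iter iterations per chain (including warmup).
#' @param warmup warmup iterations discarded per chain (0 <= warmup < iter).
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer RNG seed.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4L, iter = 2000L, warmup = 1000L,
                           thin = 1L, seed = 1L) {
  stopifnot(chains >= 1L, iter > warmup, warmup >= 0L, thin >= 1L)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Fit the saturated Bayesian factorial model for one outcome
#'
#' Fits `y = b0 + X b + Z g + e`, where `X` holds all `2^k - 1` factorial
#' main and interaction terms (effect coding by default), `Z` optional
#' baseline covariates (centered before fitting), and `e ~ N(0, sigma^2)`.
#' The model is conditionally conjugate, so sampling is by exact Gibbs
#' alternation: coefficients given `sigma^2` from their multivariate-normal
#' (ridge-type) full conditional, and `sigma^2` given the coefficients from
#' its inverse-gamma full conditional.
#'
#' @param dataset a data frame with the design's factor columns
#'   (`"low"`/`"high"`), the outcome, and any covariates; typically a
#'   [generate_trial()] result or real trial data in the same layout.
#' @param outcome name of the outcome column.
#' @param design a [factorial_design()].
#' @param covariates character vector of covariate column names (centered
#'   internally; centers are stored for prediction).
#' @param prior a [prior_spec()].
#' @param config a [sampler_config()].
#' @param coding model-matrix coding (see [build_model_matrix()]); cell-mean
#'   predictions are coding-invariant under the saturated model.
#' @param fixed_sigma if supplied, the residual SD is held at this value and
#'   only coefficients are sampled (also enables the no-data, prior-only
#'   limit with a zero-row dataset).
#' @param rhat_threshold convergence flag threshold for split R-hat.
#' @return An object of class `daive_posterior`: `draws` (matrix, one row
#'   per retained draw; columns `(Intercept)`, the term labels, covariates,
#'   `sigma`), `chain` (chain id per draw), `diagnostics` (per-parameter
#'   split R-hat and effective sample size), `converged`, plus the design,
#'   coding, outcome name and covariate centers needed for prediction.
#' @export
fit_factorial_bayes <- function(dataset, outcome, design,
                                covariates = character(),
                                prior = prior_spec(),
                                config = sampler_config(),
                                coding = c("effect", "treatment"),
                                fixed_sigma = NULL,
                                rhat_threshold = 1.01) {
  coding <- match.arg(coding)
  stopifnot(inherits(design, "factorial_design"),
            inherits(prior, "prior_spec"), inherits(config, "sampler_config"))
  n <- nrow(dataset)
  if (n == 0L && is.null(fixed_sigma))
    stop("prior-only mode (no rows) requires fixed_sigma")

  if (n > 0L) {
    y <- dataset[[outcome]]
    if (is.null(y)) stop("outcome column not found: ", outcome)
    if (!all(is.finite(y))) stop("non-finite outcome values")
    X <- build_model_matrix(design, dataset, coding = coding)
  } else {
    y <- numeric(0)
    X <- build_model_matrix(design, enumerate_conditions(design),
                            coding = coding)[0, , drop = FALSE]
  }
  centers <- stats::setNames(numeric(length(covariates)), covariates)
  for (cv in covariates) {
    z <- dataset[[cv]]
    if (is.null(z)) stop("covariate column not found: ", cv)
    if (!all(is.finite(z))) stop("non-finite covariate values: ", cv)
    centers[cv] <- mean(z)
    X <- cbind(X, z - centers[cv])
    colnames(X)[ncol(X)] <- cv
  }
  p <- ncol(X)
  if (n > 0L && qr(X)$rank < p)
    stop("design matrix is rank deficient; the saturated model is not ",
         "estimable on these data")

  prior_prec <- c(1 / prior$intercept_sd^2,
                  rep(1 / prior$coef_sd^2, p - 1L))
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)

  n_keep <- (config$iter - config$warmup) %/% config$thin
  draws <- matrix(NA_real_, config$chains * n_keep, p + 1L,
                  dimnames = list(NULL, c(colnames(X), "sigma")))
  chain_id <- rep(seq_len(config$chains), each = n_keep)

  set.seed(config$seed)
  for (ch in seq_len(config$chains)) {
    sigma2 <- if (!is.null(fixed_sigma)) fixed_sigma^2 else
      stats::var(y) * stats::runif(1, 0.5, 2)  # overdispersed chain starts
    if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
    row0 <- (ch - 1L) * n_keep
    kept <- 0L
    for (it in seq_len(config$iter)) {
      # beta | sigma2: N(A^-1 Xty/sigma2, A^-1), A = XtX/sigma2 + prior prec
      A <- XtX / sigma2 + diag(prior_prec, p)
      R <- chol(A)
      mu <- backsolve(R, forwardsolve(t(R), Xty / sigma2))
      beta <- mu + backsolve(R, stats::rnorm(p))
      if (is.null(fixed_sigma)) {
        rss <- yty - 2 * sum(beta * Xty) + drop(crossprod(beta, XtX %*% beta))
        rss <- max(rss, 0)
        sigma2 <- 1 / stats::rgamma(1, shape = prior$resid_shape + n / 2,
                                    rate = prior$resid_rate + rss / 2)
      }
      if (it > config$warmup && (it - config$warmup) %% config$thin == 0L) {
        kept <- kept + 1L
        draws[row0 + kept, ] <- c(beta, sqrt(sigma2))
      }
    }
  }

  diag_tab <- mcmc_diagnostics(draws, chain_id)
  converged <- all(is.na(diag_tab$rhat) | diag_tab$rhat < rhat_threshold)
  if (!converged)
    warning("split R-hat above ", rhat_threshold, " for: ",
            paste(diag_tab$parameter[!is.na(diag_tab$rhat) &
                                       diag_tab$rhat >= rhat_threshold],
                  collapse = ", "),
            "; treat results as provisional (increase iterations)")

  structure(list(draws = draws, chain = chain_id, outcome = outcome,
                 design = design, coding = coding, covariates = covariates,
                 covariate_centers = centers, prior = prior, config = config,
                 diagnostics = diag_tab, converged = converged),
            class = "daive_posterior")
}

#' @export
print.daive_posterior <- function(x, ...) {
  cat(sprintf("Bayesian saturated factorial fit for outcome '%s'\n", x$outcome))
  cat(sprintf("  %d draws (%d chains), %s coding, %d terms + intercept",
              nrow(x$draws), x$config$chains, x$coding,
              length(model_terms(x$design))))
  if (length(x$covariates))
    cat(", covariates:", paste(x$covariates, collapse = ", "))
  cat(sprintf("\n  max split R-hat %.3f, min ESS %.0f%s\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Summarize posterior effects with credible intervals
#'
#' @param post a [fit_factorial_bayes()] result.
#' @param level central credible-interval probability in (0, 1).
#' @param include `"effects"` for the factorial terms only (ordered as
#'   [model_terms()]), or `"all"` to also include the intercept, covariate
#'   coefficients and residual SD.
#' @return A data frame: `term`, posterior `mean`, `sd`, `lower`, `upper`,
#'   and `excludes_zero` (interval entirely on one side of zero).
#' @export
summarize_effects <- function(post, level = 0.95,
                              include = c("effects", "all")) {
  include <- match.arg(include)
  stopifnot(inherits(post, "daive_posterior"), nrow(post$draws) > 0)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be a probability strictly between 0 and 1")
  pars <- if (include == "effects") names(model_terms(post$design))
          else colnames(post$draws)
  a <- (1 - level) / 2
  out <- do.call(rbind, lapply(pars, function(pn) {
    d <- post$draws[, pn]
    q <- stats::quantile(d, c(a, 1 - a), names = FALSE)
    data.frame(term = pn, mean = mean(d), sd = stats::sd(d),
               lower = q[1], upper = q[2],
               excludes_zero = q[1] > 0 || q[2] < 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "level") <- level
  out
}

#' Forest plot of effect summaries
#'
#' @param x a [summarize_effects()] data frame.
#' @param ... passed to [graphics::plot()].
#' @return The summary, invisibly.
#' @export
plot_effects <- function(x, ...) {
  n <- nrow(x)
  ylim <- c(0.5, n + 0.5)
  graphics::plot(x$mean, rev(seq_len(n)), xlim = range(x$lower, x$upper, 0),
                 ylim = ylim, pch = 19, yaxt = "n", ylab = "",
                 xlab = "effect (outcome units)", ...)
  graphics::segments(x$lower, rev(seq_len(n)), x$upper, rev(seq_len(n)))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = rev(seq_len(n)), labels = x$term, las = 1,
                 cex.axis = 0.6)
  invisible(x)
}

#' Export posterior draws and an effect summary to CSV
#'
#' @param post a [fit_factorial_bayes()] result.
#' @param draws_path,summary_path file paths (either may be `NULL` to skip).
#' @param level credible level for the summary.
#' @return `invisible(NULL)`.
#' @export
write_posterior_csv <- function(post, draws_path = NULL, summary_path = NULL,
                                level = 0.95) {
  if (!is.null(draws_path))
    utils::write.csv(cbind(chain = post$chain, as.data.frame(post$draws)),
                     draws_path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(summarize_effects(post, level), summary_path,
                     row.names = FALSE)
  invisible(NULL)
}

# split R-hat and a crude effective sample size (initial positive-sequence
# autocorrelation estimator) per parameter
mcmc_diagnostics <- function(draws, chain_id) {
  pars <- colnames(draws)
  res <- lapply(pars, function(pn) {
    x <- draws[, pn]
    if (stats::sd(x) < 1e-12 || anyNA(x))
      return(data.frame(parameter = pn, rhat = NA_real_, ess = NA_real_))
    halves <- split(x, paste(chain_id, ave(seq_along(x), chain_id,
                                           FUN = function(i) i > mean(i))))
    m <- length(halves); nh <- min(lengths(halves))
    halves <- lapply(halves, function(h) h[seq_len(nh)])
    means <- vapply(halves, mean, 0); vars <- vapply(halves, stats::var, 0)
    W <- mean(vars); B <- nh * stats::var(means)
    rhat <- if (W > 0) sqrt(((nh - 1) / nh * W + B / nh) / W) else NA_real_
    ess <- sum(vapply(halves, ess_one, 0))
    data.frame(parameter = pn, rhat = rhat, ess = ess)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

ess_one <- function(x) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0.05) break
    s <- s + rho[k]
  }
  n / (1 + 2 * s)
}
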