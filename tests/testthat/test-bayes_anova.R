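test_that("with no data the coefficient posterior reproduces the prior", {
  d <- tiny_design(2)
  empty <- data.frame(A = character(), B = character(), y = numeric())
  fit <- quiet_fit(empty, "y", d, fixed_sigma = 1,
                   config = sampler_config(chains = 2, iter = 3000,
                                           warmup = 500, seed = 1))
  draws <- fit$draws[, c("A", "B", "A:B")]
  # MC tolerance: se(mean) = 5/sqrt(5000) ~ 0.07, se(sd) ~ 0.05; 4 SE bands
  expect_equal(unname(colMeans(draws)), rep(0, 3), tolerance = 0.3)
  expect_equal(unname(apply(draws, 2, sd)), rep(5, 3), tolerance = 0.25)
  expect_equal(sd(fit$draws[, "(Intercept)"]), 50, tolerance = 2.5)
})

test_that("Gibbs draws match the closed-form conjugate posterior at fixed sigma", {
  d <- tiny_design(2)
  truth <- tiny_truth(d, list(y = c(A = 1, B = -0.5)), sds = 2,
                      n_per_condition = 10)
  dat <- generate_trial(d, truth, seed = 8)
  prior <- prior_spec(coef_sd = 1.5, intercept_sd = 1.5)
  sig <- 2
  fit <- quiet_fit(dat, "y", d, prior = prior, fixed_sigma = sig,
                   config = sampler_config(chains = 2, iter = 6000,
                                           warmup = 1000, seed = 2))
  X <- build_model_matrix(d, dat)
  prec <- diag(rep(1 / 1.5^2, 4)) + crossprod(X) / sig^2
  Sigma <- solve(prec)
  mu <- drop(Sigma %*% crossprod(X, dat$y)) / sig^2
  B <- fit$draws[, colnames(X)]
  # se(mean) = sd/sqrt(n_draws) ~ 0.15/100; 5 SE ~ 0.01
  expect_equal(unname(colMeans(B)), unname(mu), tolerance = 0.012)
  expect_equal(unname(cov(B)), unname(Sigma), tolerance = 0.1)
})

test_that("posterior means agree with the OLS oracle at large n", {
  d <- tiny_design(3)
  truth <- tiny_truth(d, list(y = c(A = 1, `B:C` = 0.6)), sds = 1,
                      n_per_condition = 100)
  dat <- generate_trial(d, truth, seed = 12)
  fit <- quiet_fit(dat, "y", d,
                   config = sampler_config(chains = 2, iter = 1500,
                                           warmup = 500, seed = 3))
  X <- build_model_matrix(d, dat)
  ols <- lm(dat$y ~ X - 1)
  # shrinkage O(sigma^2/(25 n)) is negligible; MC se ~ 0.035/sqrt(2000)
  expect_equal(unname(colMeans(fit$draws[, colnames(X)])),
               unname(coef(ols)), tolerance = 0.02)
  expect_equal(mean(fit$draws[, "sigma"]), summary(ols)$sigma,
               tolerance = 0.05)
})

test_that("baseline covariate adjustment recovers its coefficient", {
  d <- tiny_design(2)
  truth <- truth_spec(d, outcomes = list(
    y = list(intercept = 2, effects = c(A = 1), sd = 1, baseline_coef = 0.5)),
    resid_cor = 0, n_per_condition = 150,
    baseline = list(mean = 3, sd = 2, range = c(-10, 10)))
  dat <- generate_trial(d, truth, seed = 21)
  fit <- quiet_fit(dat, "y", d, covariates = "baseline",
                   config = sampler_config(chains = 2, iter = 1500,
                                           warmup = 500, seed = 4))
  expect_equal(mean(fit$draws[, "baseline"]), 0.5, tolerance = 0.1)
  expect_equal(mean(fit$draws[, "A"]), 1, tolerance = 0.2)
})

test_that("sampling is seed-deterministic and prior-dominated in the limit", {
  d <- tiny_design(2)
  truth <- tiny_truth(d, list(y = c(A = 2)), sds = 1, n_per_condition = 10)
  dat <- generate_trial(d, truth, seed = 5)
  cfg <- sampler_config(chains = 2, iter = 400, warmup = 200, seed = 9)
  expect_identical(quiet_fit(dat, "y", d, config = cfg)$draws,
                   quiet_fit(dat, "y", d, config = cfg)$draws)

  shrunk <- quiet_fit(dat, "y", d, config = cfg,
                      prior = prior_spec(coef_sd = 1e-4))
  expect_lt(max(abs(colMeans(shrunk$draws[, c("A", "B", "A:B")]))), 1e-3)
})

test_that("posterior predictive cell means are coding-invariant", {
  d <- tiny_design(2)
  truth <- tiny_truth(d, list(y = c(A = 1, `A:B` = -0.8)), sds = 1,
                      n_per_condition = 50)
  dat <- generate_trial(d, truth, seed = 31)
  cfg <- sampler_config(chains = 2, iter = 2000, warmup = 500, seed = 6)
  m_eff <- predict_conditions(quiet_fit(dat, "y", d, config = cfg,
                                        coding = "effect"))$mean
  m_trt <- predict_conditions(quiet_fit(dat, "y", d, config = cfg,
                                        coding = "treatment"))$mean
  # MC tolerance: posterior sd of a cell mean ~ 1/sqrt(50); se ~ 0.0026
  expect_equal(m_eff, m_trt, tolerance = 0.05)
})

test_that("fit rejects degenerate inputs", {
  d <- tiny_design(2)
  truth <- tiny_truth(d, list(y = c(A = 1)), sds = 1, n_per_condition = 5)
  dat <- generate_trial(d, truth, seed = 1)
  one_cell <- dat[dat$A == "high" & dat$B == "high", ]
  expect_error(quiet_fit(one_cell, "y", d), "rank deficient")
  dat$y[1] <- NA
  expect_error(quiet_fit(dat, "y", d), "non-finite")
  expect_error(quiet_fit(dat, "nope", d), "not found")
  expect_error(fit_factorial_bayes(dat[0, ], "y", d), "fixed_sigma")
})

test_that("effect summaries report central intervals and zero-exclusion", {
  d <- tiny_design(2)
  mk_post <- function(draws) {
    structure(list(draws = draws, design = d,
                   chain = rep(1L, nrow(draws))),
              class = "daive_posterior")
  }
  n <- 4000
  set.seed(7)
  draws <- cbind(`(Intercept)` = rnorm(n), A = 2, B = rnorm(n),
                 `A:B` = rnorm(n, 0, 1), sigma = 1)
  s <- summarize_effects(mk_post(draws), 0.95)
  expect_equal(s$term, c("A", "B", "A:B"))
  a <- s[s$term == "A", ]
  expect_equal(c(a$lower, a$upper), c(2, 2))
  expect_true(a$excludes_zero)
  expect_false(s$excludes_zero[s$term == "B"])
  ab <- s[s$term == "A:B", ]
  expect_equal(c(ab$lower, ab$upper), c(-1.96, 1.96), tolerance = 0.08)
  expect_error(summarize_effects(mk_post(draws), 1.2), "level")
})

test_that("non-convergence is flagged, not hidden", {
  d <- tiny_design(1)
  truth <- tiny_truth(d, list(y = c(A = 1)), sds = 1, n_per_condition = 40)
  dat <- generate_trial(d, truth, seed = 2)
  # split R-hat of any finite chain set exceeds an impossibly strict bound
  expect_warning(
    fit <- fit_factorial_bayes(dat, "y", d,
                               config = sampler_config(chains = 2, iter = 400,
                                                       warmup = 200, seed = 1),
                               rhat_threshold = 0.5),
    "R-hat")
  expect_false(fit$converged)
})
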