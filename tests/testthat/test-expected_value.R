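fixed_post <- function(design, draws) {
  structure(list(draws = draws, design = design, coding = "effect",
                 covariates = character(),
                 covariate_centers = setNames(numeric(0), character(0)),
                 outcome = "y", chain = rep(1L, nrow(draws))),
            class = "daive_posterior")
}

test_that("condition predictions follow the coding algebra draw by draw", {
  d <- tiny_design(2)
  X <- build_model_matrix(d, enumerate_conditions(d))
  # posterior concentrated at intercept 10, no effects
  flat <- matrix(rep(c(10, 0, 0, 0, 1), each = 50), 50,
                 dimnames = list(NULL, c(colnames(X), "sigma")))
  eo <- predict_conditions(fixed_post(d, flat))
  expect_equal(unname(eo$mean), rep(10, 4))

  # single main effect c for every draw: high - low = 2c per draw
  cdraw <- flat; cdraw[, "A"] <- 1.7
  eo2 <- predict_conditions(fixed_post(d, cdraw))
  hi <- eo2$conditions$A == "high"
  for (i in c(1, 25, 50))
    expect_equal(unique(eo2$draws[i, hi] - eo2$draws[i, !hi]), 2 * 1.7)
})

test_that("predictions equal a matrix-free dot-product oracle", {
  d <- tiny_design(3)
  truth <- tiny_truth(d, list(y = c(A = 1, `A:B` = 0.5)), sds = 1,
                      n_per_condition = 20)
  dat <- generate_trial(d, truth, seed = 17)
  fit <- quiet_fit(dat, "y", d,
                   config = sampler_config(chains = 1, iter = 120,
                                           warmup = 20, seed = 2))
  eo <- predict_conditions(fit)
  cond <- enumerate_conditions(d)
  terms <- model_terms(d)
  fnames <- d$factors$name
  for (i in c(1, 57, 100)) {        # spot-check draws
    for (ci in c(1, 5, 8)) {        # and conditions
      x <- vapply(terms, function(ix)
        prod(ifelse(cond[ci, fnames[ix]] == "high", 1, -1)), numeric(1))
      manual <- fit$draws[i, "(Intercept)"] +
        sum(fit$draws[i, names(terms)] * x)
      expect_equal(unname(eo$draws[i, ci]), unname(manual))
    }
  }
})

test_that("covariate policy shifts predictions by coefficient times offset", {
  d <- tiny_design(2)
  truth <- truth_spec(d, outcomes = list(
    y = list(intercept = 0, effects = c(A = 1), sd = 1, baseline_coef = 1)),
    resid_cor = 0, n_per_condition = 30,
    baseline = list(mean = 2, sd = 1, range = c(-10, 10)))
  dat <- generate_trial(d, truth, seed = 3)
  fit <- quiet_fit(dat, "y", d, covariates = "baseline",
                   config = sampler_config(chains = 1, iter = 200,
                                           warmup = 100, seed = 4))
  at_mean <- predict_conditions(fit)
  at_x <- predict_conditions(fit,
                             covariate_values = c(baseline = mean(dat$baseline) + 2))
  expect_equal(at_x$mean - at_mean$mean,
               rep(2 * mean(fit$draws[, "baseline"]), 4),
               ignore_attr = TRUE)
  expect_error(predict_conditions(fit, covariate_values = c(other = 1)),
               "missing covariate")
})

test_that("swing points convert to weights exactly and in rounded mode", {
  w <- swing_points_to_weights(c(beliefs = 100, knowledge = 50,
                                 satisfaction = 25), "nearest_0.1")
  expect_equal(unname(w$weights), c(0.6, 0.3, 0.1))
  expect_equal(unname(w$exact), c(100, 50, 25) / 175)
  expect_equal(sum(w$exact), 1)
  expect_equal(unname(swing_points_to_weights(c(y = 100))$weights), 1)
  expect_equal(unname(swing_points_to_weights(rep(1, 4))$weights), rep(0.25, 4))
  expect_error(swing_points_to_weights(c(1, 0)), "positive")
})

test_that("candidate-range scaling maps worst to 0, best to 1, affinely", {
  M <- cbind(y = c(2, 4, 6, 8))
  expect_equal(unname(scale_outcomes(M)[, 1]), c(0, 1/3, 2/3, 1))

  set.seed(10)
  Y <- cbind(a = rnorm(8), b = runif(8))
  S <- scale_outcomes(Y)
  expect_equal(unname(apply(S, 2, min)), c(0, 0))
  expect_equal(unname(apply(S, 2, max)), c(1, 1))
  # positive affine transforms leave scaled values unchanged
  expect_equal(scale_outcomes(cbind(a = 3 * Y[, 1] + 7, b = Y[, 2])), S,
               ignore_attr = TRUE)
  # direction flag flips lower-is-better outcomes
  expect_equal(scale_outcomes(Y, direction = c(-1, 1))[, 1], 1 - S[, 1])
  expect_error(scale_outcomes(cbind(y = rep(1, 4))), "zero candidate range")
  expect_equal(unname(scale_outcomes(cbind(y = c(0, 5, 10)), "fixed_range",
                                     bounds = list(y = c(0, 20)))[, 1]),
               c(0, 0.25, 0.5))
  expect_error(scale_outcomes(M, "fixed_range"), "bounds")
})

test_that("value combines scaled outcomes linearly and ranks conditions", {
  S <- matrix(c(1, 0.5, 0, 0.2,
                0, 1, 0.4, 0.6,
                0.3, 0, 1, 0.8), 4, 3,
              dimnames = list(NULL, c("mb", "ok", "si")))
  w <- c(mb = 0.6, ok = 0.3, si = 0.1)
  vt <- compute_value(S, w)
  manual <- drop(S %*% w)
  expect_equal(vt$value, sort(manual, decreasing = TRUE))
  expect_equal(vt$index[1], which.max(manual))

  # weight concentrated on one outcome reproduces its own ranking
  vt1 <- compute_value(S, c(mb = 1, ok = 0, si = 0))
  expect_equal(vt1$index, order(S[, "mb"], decreasing = TRUE))

  # identical scaled outcomes give identical values
  vt2 <- compute_value(S[c(1, 1, 1), ], w)
  expect_equal(length(unique(vt2$value)), 1L)

  expect_error(compute_value(S, c(mb = 1, nope = 0, si = 0)), "match")
})

test_that("value ranking is invariant to positive rescaling of points", {
  set.seed(11)
  M <- fake_means(cbind(a = rnorm(8), b = rnorm(8), c = rnorm(8)),
                  tiny_design(3))
  p <- c(a = 100, b = 50, c = 25)
  d1 <- decide(M, p)
  d2 <- decide(M, 7.3 * p)
  expect_equal(d1$value_table$index, d2$value_table$index)
  expect_equal(d1$selected$label, d2$selected$label)
})

test_that("a single outcome reduces selection to its argmax", {
  set.seed(12)
  M <- fake_means(cbind(y = rnorm(8)), tiny_design(3))
  dec <- decide(M, c(y = 100))
  expect_equal(dec$selected$index, unname(which.max(M[, "y"])))
})

test_that("value ties prefer the smaller intervention package", {
  M <- fake_means(cbind(y = c(3, 1, 3, 0, 1, 1, 0, 0)), tiny_design(3))
  # conditions 1 (A,B,C high) and 3 (A,B high... ) tie on value
  dec <- decide(M, c(y = 1))
  cond <- enumerate_conditions(tiny_design(3))
  tied <- which(M[, "y"] == 3)
  expect_equal(dec$selected$index,
               unname(tied[which.min(cond$n_high[tied])]))
  expect_gt(length(dec$selected$tied), 1L)
})

test_that("per-draw and mean-then-value agree exactly under fixed-range scaling", {
  d <- tiny_design(2)
  truth <- tiny_truth(d, list(a = c(A = 1), b = c(B = 0.5)), sds = c(1, 1),
                      n_per_condition = 15)
  dat <- generate_trial(d, truth, seed = 23)
  cfg <- sampler_config(chains = 1, iter = 150, warmup = 50, seed = 5)
  M <- condition_means(a = predict_conditions(quiet_fit(dat, "a", d, config = cfg)),
                       b = predict_conditions(quiet_fit(dat, "b", d, config = cfg)))
  bounds <- list(a = c(-10, 10), b = c(-10, 10))
  p <- c(a = 100, b = 50)
  V <- value_draws(M, p, basis = "fixed_range", bounds = bounds)
  S <- scale_outcomes(M, "fixed_range", bounds = bounds)
  vt <- compute_value(S, swing_points_to_weights(p))
  expect_equal(colMeans(V)[vt$label], setNames(vt$value, vt$label),
               tolerance = 1e-12)
})
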