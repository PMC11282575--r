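# shared fixtures for the test suite; everything is generated in code

tiny_design <- function(k) factorial_design(LETTERS[seq_len(k)])

# noiseless truth with a handful of named effects per outcome
tiny_truth <- function(design, effects_by_outcome, sds = 0,
                       intercepts = 10, n_per_condition = 4, seed = 1L) {
  J <- length(effects_by_outcome)
  sds <- rep(sds, length.out = J)
  intercepts <- rep(intercepts, length.out = J)
  outs <- lapply(seq_len(J), function(j)
    list(intercept = intercepts[j], effects = effects_by_outcome[[j]],
         sd = sds[j]))
  names(outs) <- names(effects_by_outcome)
  truth_spec(design, outs, resid_cor = 0,
             n_per_condition = n_per_condition,
             baseline = list(mean = 0, sd = 1, range = c(-5, 5)), seed = seed)
}

# short-chain fit, silencing the Monte-Carlo R-hat flag that short chains
# can trip; convergence behaviour has its own tests
quiet_fit <- function(...) suppressWarnings(fit_factorial_bayes(...))

# a condition_means-like matrix with hand-set values
fake_means <- function(M, design = tiny_design(round(log2(nrow(M))))) {
  cond <- enumerate_conditions(design)
  stopifnot(nrow(M) == nrow(cond))
  rownames(M) <- cond$label
  structure(M, conditions = cond, design = design,
            class = c("condition_means", "matrix"))
}

# brute-force single-shot decision: weights, scale, argmax by hand
oracle_decide_index <- function(M, points) {
  keep <- names(points)[points > 0]
  w <- points[keep] / sum(points[keep])
  S <- apply(M[, keep, drop = FALSE], 2L,
             function(y) (y - min(y)) / (max(y) - min(y)))
  unname(which.max(drop(S %*% w)))
}
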