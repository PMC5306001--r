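# Independent oracles and small fixtures used across the test files.

# Brute-force maximiser of the interval likelihood, written directly from
# the model definition (phi = inverse-logit of the linear predictor, an
# interval of t days survives with probability phi^t). Independent of the
# package's fitting path.
brute_force_logexp <- function(X, y, t) {
  nll <- function(beta) {
    phi <- 1 / (1 + exp(-drop(X %*% beta)))
    p <- phi^t
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  best <- NULL
  for (s in list(rep(0, ncol(X)), c(3, rep(0, ncol(X) - 1L)))) {
    o <- optim(s, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(coef = best$par, loglik = -best$value)
}

# A small hand-checkable encounter history: mixed exposures, one failure.
tiny_history <- function() {
  data.frame(
    nest_id = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 5L, 5L, 6L),
    interval_start_day = 0L, interval_end_day = 0L,
    exposure_days = c(3L, 3L, 2L, 3L, 3L, 3L, 3L, 1L, 3L, 3L, 2L, 3L),
    survived = c(1L, 1L, 1L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 1L, 1L),
    ach_m1 = c(.3, .3, .3, .4, .4, .5, .5, .5, .2, .6, .6, .45),
    ach_m2 = c(.5, .5, .5, .75, .75, .7, .7, .7, .55, .8, .8, .6),
    ach_m3 = c(.5, .5, .5, .8, .8, .7, .7, .7, .65, .8, .8, .6),
    init_date = c(10L, 10L, 10L, 12L, 12L, 20L, 20L, 20L, 8L, 25L, 25L, 15L))
}

# Curve sampler whose curves are flat in time but vary between nests:
# isolates the growth-driven component of measurement-timing bias.
flat_varying_sampler <- function(mean = 0.6, sd = 0.15) {
  function() constant_curve(abs(rnorm(1, mean, sd)) + 1e-6)
}
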