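test_that("intercept derivation inverts the compounding of daily survival", {
  expect_equal(derive_intercept(0.5, 1), 0)
  expect_equal(derive_intercept(0.25, 2), 0)      # daily survival 0.5
  b0 <- derive_intercept(0.35, 28)
  expect_equal(b0, qlogis(0.35^(1 / 28)))
  expect_equal(plogis(b0)^28, 0.35, tolerance = 1e-12)
  expect_equal(b0, 3.2646, tolerance = 1e-4)
  expect_error(derive_intercept(0, 28))
  expect_error(derive_intercept(1, 28))
})

test_that("initiation dates and entry ages follow their stated distributions", {
  set.seed(5)
  d <- sample_initiation_date(10000, skew = -15, season_length = 60)
  expect_true(all(d >= 1))
  expect_lt(abs(mean(d) - 15), 3 * (30 / 7) / sqrt(10000))
  expect_equal(sd(d), 30 / 7, tolerance = 0.05)
  d_late <- sample_initiation_date(10000, skew = 15, season_length = 60)
  expect_lt(abs(mean(d_late) - 45), 3 * (30 / 7) / sqrt(10000))
  expect_equal(sample_initiation_date(5, -15, 60, sd = 0), rep(15L, 5))

  e <- sample_entry_age(10000, L = 28)
  expect_true(all(e >= 1 & e <= 28))
  expect_lt(abs(mean(e) - 14), 3 * (28 / 6) / sqrt(10000))
  expect_equal(sample_entry_age(5, 28, sd = 0), rep(14L, 5))
})

test_that("forced survival extremes give deterministic fates and measurements", {
  cv <- growth_curve(1, 15)
  set.seed(1)
  sure <- simulate_nest(cv, init_date = 10, beta0 = Inf, beta1 = 0,
                        eps_sd = 0, L = 28)
  expect_identical(sure$fate, "fledged")
  expect_identical(sure$last_active_age, 28L)
  expect_identical(sure$ach_m2, sure$ach_m3)

  doomed <- simulate_nest(cv, init_date = 10, beta0 = -Inf, beta1 = 0,
                          eps_sd = 0, L = 28)
  expect_identical(doomed$fate, "failed")
  expect_identical(doomed$last_active_age, 1L)
  expect_equal(doomed$ach_m2, ach(cv, 11))
  expect_lt(doomed$ach_m2, doomed$ach_m3)
})

test_that("encounter histories follow the 3-day visit schedule", {
  nest <- list(nest_id = 1L, init_date = 0L, fate = "fledged",
               last_active_age = 28L, ach_m1 = .1, ach_m2 = .5, ach_m3 = .5)
  h <- build_encounter_history(nest, entry_age = 14, visit_interval = 3,
                               L = 28)
  expect_equal(h$exposure_days, c(3L, 3L, 3L, 3L, 2L))
  expect_equal(h$interval_start_day, c(14L, 17L, 20L, 23L, 26L))
  expect_equal(h$interval_end_day, c(17L, 20L, 23L, 26L, 28L))
  expect_true(all(h$survived == 1L))

  nest$fate <- "failed"; nest$last_active_age <- 15L
  h <- build_encounter_history(nest, 14, 3, 28)
  expect_equal(nrow(h), 1L)
  expect_equal(h$survived, 0L)
  expect_equal(h$exposure_days, 3L)

  nest$last_active_age <- 10L
  expect_equal(nrow(build_encounter_history(nest, 14, 3, 28)), 0L)

  # a nest that became inactive on its entry day was never seen active
  nest$last_active_age <- 14L
  expect_equal(nrow(build_encounter_history(nest, 14, 3, 28)), 0L)

  nest$last_active_age <- 22L
  h <- build_encounter_history(nest, 14, 3, 28)
  expect_equal(h$survived, c(1L, 1L, 0L))   # failure in (20, 23]
  expect_error(build_encounter_history(nest, 0, 3, 28), "entry_age")
  expect_error(build_encounter_history(nest, 29, 3, 28), "entry_age")
})

test_that("vectorised dataset builder agrees with the per-nest operations", {
  set.seed(42)
  d <- simulate_dataset(scenario_config(n_nests = 300, beta1 = -0.2))
  rebuilt <- do.call(rbind, lapply(seq_len(nrow(d$nests)), function(i) {
    build_encounter_history(as.list(d$nests[i, ]), d$nests$entry_age[i],
                            d$config$visit_interval,
                            d$config$nesting_period)
  }))
  rownames(rebuilt) <- NULL
  expect_equal(d$history, rebuilt)
})

test_that("dataset-level invariants hold and simulation is reproducible", {
  set.seed(7)
  d <- simulate_dataset(scenario_config(beta1 = 0.1))
  n <- d$nests
  fl <- n$fate == "fledged"
  expect_true(all(n$ach_m2[fl] == n$ach_m3[fl]))
  # failed nests are measured strictly earlier, except the edge case of a
  # failure on the final day, when the two measurement days coincide
  early_fail <- !fl & n$last_active_age < 28
  expect_true(all(n$ach_m2[early_fail] < n$ach_m3[early_fail]))
  expect_true(all(n$ach_m2[!fl] <= n$ach_m3[!fl]))
  expect_true(all(n$ach_m1 <= n$ach_m2))
  # fledged nests are never lost to left truncation
  expect_true(all(n$included[fl & n$entry_age < 28]))
  h <- d$history
  # intervals contiguous within a nest; at most one failure, in the last row
  for (id in unique(h$nest_id)[1:50]) {
    hi <- h[h$nest_id == id, ]
    expect_true(all(hi$interval_start_day[-1] ==
                      hi$interval_end_day[-nrow(hi)]))
    expect_true(all(hi$survived[-nrow(hi)] == 1L))
  }
  # per-nest exposure never exceeds the span from entry to L
  tot <- tapply(h$exposure_days, h$nest_id, sum)
  span <- 28 - n$entry_age[match(as.integer(names(tot)), n$nest_id)] +
    d$config$visit_interval
  expect_true(all(tot <= span))

  set.seed(123)
  d1 <- simulate_dataset(scenario_config())
  set.seed(123)
  d2 <- simulate_dataset(scenario_config())
  expect_identical(d1$history, d2$history)
  expect_identical(d1$nests, d2$nests)

  empty <- simulate_dataset(scenario_config(n_nests = 0))
  expect_equal(nrow(empty$history), 0L)
  expect_equal(nrow(empty$nests), 0L)
})

test_that("fledge fraction rises monotonically with a positive ACH effect", {
  frac <- vapply(c(0, 0.15, 0.3), function(b1) {
    set.seed(31)
    d <- simulate_dataset(scenario_config(beta1 = b1, n_nests = 8000))
    mean(d$nests$fate == "fledged")
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("observed-nest count matches an independent truncation oracle", {
  # Under beta1 = 0, fate is independent of the growth curve, so the
  # probability a nest is still active on its entry day e is E_eps[phi^e]
  # integrated over the rounded, clamped entry-age distribution, with
  # entry at age L contributing no observable interval.
  L <- 28; b0 <- qlogis(0.35^(1 / 28))
  p_entry <- diff(pnorm(seq(0.5, L + 0.5), L / 2, L / 6))
  p_entry <- p_entry / sum(p_entry)
  eps <- seq(-4, 4, length.out = 401) * 0.05
  w <- dnorm(eps, 0, 0.05); w <- w / sum(w)
  surv_to <- vapply(1:L, function(e)
    sum(w * plogis(b0 + eps)^e), numeric(1))
  oracle <- sum(p_entry[1:(L - 1)] * surv_to[1:(L - 1)])

  set.seed(17)
  inc <- replicate(30, {
    d <- simulate_dataset(scenario_config(beta1 = 0))
    mean(d$nests$included)
  })
  se <- sd(inc) / sqrt(length(inc))
  expect_lt(abs(mean(inc) - oracle), 3 * se + 0.002)
})

test_that("encounter histories survive a CSV round trip", {
  set.seed(2)
  d <- simulate_dataset(scenario_config(n_nests = 50))
  path <- tempfile(fileext = ".csv")
  write_encounter_csv(d$history, path)
  back <- read_encounter_csv(path)
  expect_equal(back, d$history, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_encounter_csv(bad), "missing columns")
})
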