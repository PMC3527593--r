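unit_bout_log <- function(days = 60) {
  tibble::tibble(day = seq_len(days), w = c(1, rep(0, days - 1)))
}

test_that("parameter validation enforces the antagonistic structure", {
  expect_error(banister_params(0, 1, 2, tau1 = 2, tau2 = 10), "exceed")
  expect_error(banister_params(0, -1, 2, 10, 2), "k1")
  p <- banister_params(1.42, 7e-5, 1.1e-3, 50, 4.8)
  expect_s3_class(p, "banister_params")
})

test_that("single-bout response follows the closed form", {
  p <- banister_params(0, 1, 2, 10, 2)
  sim <- banister_simulate(unit_bout_log(), p)
  # bout on day 1 influences day 2 onward: r(d) = e^(-d/10) - 2 e^(-d/2)
  d <- 1:10
  expect_equal(sim$output[1 + d], exp(-d / 10) - 2 * exp(-d / 2),
               tolerance = 1e-12)
  expect_equal(sim$output[2], exp(-0.1) - 2 * exp(-0.5), tolerance = 1e-12)
  expect_equal(sim$output[2], -0.3082, tolerance = 1e-4)
  expect_equal(sim$output[11], 0.3544, tolerance = 1e-3)
  expect_equal(sim$output[1], 0)  # same-day training has no effect yet

  zero <- banister_simulate(tibble::tibble(day = 1:30, w = 0),
                            banister_params(5, 1, 2, 10, 2))
  expect_true(all(zero$output == 5))
})

test_that("recursive simulation equals the O(T^2) direct sum", {
  for (seed in 1:5) {
    w <- withr::with_seed(seed, runif(300, 0, 100) *
                            (runif(300) > 0.2))
    p <- random_valid_params(seed + 100)
    got <- banister_simulate(tibble::tibble(day = seq_along(w), w = w), p)
    want <- oracle_banister_direct(w, p)
    expect_equal(got$output, want, tolerance = 1e-9)
  }
})

test_that("influences decompose the output exactly and behave as expected", {
  log <- make_schedule(season_scenario())
  p <- table2_performance_params()
  infl <- banister_influences(log, p)
  expect_true(all(infl$pi >= 0))
  expect_true(all(infl$ni >= 0))
  expect_equal(infl$output, p$y0 + infl$pi - infl$ni, tolerance = 1e-12)
  expect_equal(infl$output, banister_simulate(log, p)$output,
               tolerance = 1e-15)

  zero <- banister_influences(tibble::tibble(day = 1:10, w = 0), p)
  expect_true(all(zero$pi == 0) && all(zero$ni == 0))

  # single bout: fatigue is almost gone by 1 + 5*tau2 while adaptation remains
  pb <- banister_params(0, 1, 2, 30, 2)
  one <- banister_influences(unit_bout_log(), pb)
  at <- 2 + ceiling(5 * pb$tau2)  # 5 fatigue time constants after onset
  expect_lt(one$ni[at] / one$ni[2], 0.01)
  expect_gt(one$pi[at] / one$pi[2], 0.6)
})

test_that("fatigue rises faster than adaptation after a load step", {
  p <- table2_performance_params()
  step_log <- tibble::tibble(day = 1:120, w = c(rep(0, 60), rep(50, 60)))
  infl <- banister_influences(step_log, p)
  # normalized by each component's steady-state increment k*tau*w
  horizon <- 61 + ceiling(p$tau2)
  ni_frac <- infl$ni[horizon] / (p$k2 * p$tau2 * 50)
  pi_frac <- infl$pi[horizon] / (p$k1 * p$tau1 * 50)
  expect_gt(ni_frac / pi_frac, 1)
})

test_that("model response is linear and superposable in the load", {
  p <- random_valid_params(7)
  w1 <- withr::with_seed(1, runif(100, 0, 50))
  w2 <- withr::with_seed(2, runif(100, 0, 50))
  as_log <- function(w) tibble::tibble(day = seq_along(w), w = w)
  s1 <- banister_simulate(as_log(w1), p)$output
  s2 <- banister_simulate(as_log(w2), p)$output
  s12 <- banister_simulate(as_log(w1 + w2), p)$output
  s3 <- banister_simulate(as_log(3 * w1), p)$output
  expect_equal(s3 - p$y0, 3 * (s1 - p$y0), tolerance = 1e-9)
  expect_equal(s12 - p$y0, (s1 - p$y0) + (s2 - p$y0), tolerance = 1e-9)
})

test_that("closed-form timing matches hand values and the numeric oracle", {
  p <- banister_params(0, 1, 2, 10, 2)
  tim <- banister_timing(p)
  expect_equal(tim$t_n, 2.5 * log(2), tolerance = 1e-12)
  expect_equal(tim$t_g, 2.5 * log(10), tolerance = 1e-12)

  num <- banister_timing_numeric(p)
  expect_gt(num$t_n, 1.72)
  expect_lt(num$t_n, 1.75)
  expect_gt(num$t_g, 5.74)
  expect_lt(num$t_g, 5.77)

  # parameter means of the reference population
  tim2 <- banister_timing(table2_performance_params())
  expect_equal(tim2$t_n, 14.63, tolerance = 1e-3)
  expect_equal(tim2$t_g, 27.07, tolerance = 1e-3)

  # degenerate and undefined cases
  expect_equal(banister_timing(banister_params(0, 1, 1, 10, 2))$status,
               "degenerate")
  expect_equal(banister_timing(banister_params(0, 1, 1, 10, 2))$t_n, 0)
  expect_true(is.na(banister_timing(banister_params(0, 2, 1, 10, 2))$t_n))
  expect_true(is.na(banister_timing_numeric(
    banister_params(0, 2, 1, 10, 2))$t_n))
  expect_error(banister_timing_numeric(banister_params(0, 1, 2, 10, 2),
                                       horizon = 1),
               "horizon")
})

test_that("timing is monotone in the gains and constants", {
  base <- banister_params(0, 1e-4, 1e-3, 50, 5)
  more_fatigue <- banister_params(0, 1e-4, 2e-3, 50, 5)
  slower_adapt <- banister_params(0, 1e-4, 1e-3, 80, 5)
  expect_gt(banister_timing(more_fatigue)$t_n, banister_timing(base)$t_n)
  expect_gt(banister_timing(slower_adapt)$t_g, banister_timing(base)$t_g)
})

test_that("noiseless observations are refit essentially exactly", {
  log <- make_schedule(season_scenario())
  truth <- table2_performance_params()
  obs <- banister_simulate(log, truth) |>
    dplyr::filter(day %% 7 == 5) |>
    dplyr::transmute(day, value = output)
  fit <- banister_fit(log, obs)
  expect_lt(abs(fit$params$tau1 - truth$tau1) / truth$tau1, 0.05)
  expect_lt(abs(fit$params$tau2 - truth$tau2) / truth$tau2, 0.05)
  expect_gt(fit$r2, 0.999)
  # optimizer sanity: returned objective no worse than at the true parameters
  rss_true <- sum((obs$value -
                     banister_simulate(log, truth)$output[obs$day])^2)
  expect_lte(fit$diagnostics$objective, rss_true + 1e-12)
  expect_equal(tidy(fit)$term, c("y0", "k1", "k2", "tau1", "tau2"))
  expect_equal(glance(fit)$n_obs, nrow(obs))
})

test_that("degenerate and malformed observation sets are rejected/flagged", {
  log <- make_schedule(season_scenario(weeks = 10))
  const <- tibble::tibble(day = 7 * (1:10) - 2, value = 5)
  fit <- banister_fit(log, const)
  expect_true(is.na(fit$r2))
  expect_true(fit$diagnostics$degenerate_observations)

  expect_error(banister_fit(log, const[1:5, ]), "at least 8")
  bad_days <- tibble::tibble(day = c(1:7, 500), value = rnorm(8))
  expect_error(banister_fit(log, bad_days), "within the training log")
})
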