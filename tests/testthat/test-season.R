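test_that("performance normalization follows the velocity definition", {
  expect_equal(normalize_performance(velocity_ms = 1.64,
                                     national_best_ms = 1.64), 100)
  expect_equal(normalize_performance(time_400m_s = 280,
                                     national_best_ms = 1.6),
               89.29, tolerance = 1e-4)
  # scale consistency: doubling velocity and reference changes nothing
  expect_equal(normalize_performance(velocity_ms = 2 * 1.4,
                                     national_best_ms = 2 * 1.6),
               normalize_performance(velocity_ms = 1.4,
                                     national_best_ms = 1.6))
  expect_error(normalize_performance(time_400m_s = 0, national_best_ms = 1.6),
               "> 0")
  expect_error(normalize_performance(national_best_ms = 1.6), "exactly one")
})

test_that("log relationship is recovered exactly on noiseless data", {
  hf <- c(2, 4, 6, 8, 10, 12)
  d <- tibble::tibble(week = 1:6, hf = hf, performance = 70 + 5 * log(hf))
  fit <- fit_log_relationship(d)
  expect_equal(fit$intercept, 70, tolerance = 1e-9)
  expect_equal(fit$slope, 5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(glance(fit)$form, "log")

  d$hf[3] <- 0
  expect_error(fit_log_relationship(d), "week/row: 3")
  d$hf <- 5
  expect_error(fit_log_relationship(d), "singular")
  expect_error(fit_log_relationship(d[1:2, ]), ">= 3")
})

test_that("log fit R2 lands in the band implied by the noise level", {
  # perf = a + b log(hf) + e; expected R2 = var(signal) / (var(signal)+sigma2)
  r2s <- sapply(1:20, function(seed) {
    withr::with_seed(seed, {
      hf <- exp(runif(30, 0, 2.5))
      signal <- 80 + 6 * log(hf)
      perf <- signal + rnorm(30, 0, 2)
      fit_log_relationship(tibble::tibble(hf = hf, performance = perf))$r2
    })
  })
  sig_var <- 6^2 * 2.5^2 / 12  # b^2 * Var(U(0, 2.5))
  expected <- sig_var / (sig_var + 2^2)
  expect_gt(median(r2s), expected - 0.12)
  expect_lt(median(r2s), expected + 0.12)
})

test_that("slope estimates are unbiased under the null (b = 0)", {
  slopes <- sapply(1:200, function(seed) {
    withr::with_seed(seed, {
      hf <- exp(runif(30, 0, 2))
      perf <- 80 + rnorm(30, 0, 1)
      fit_log_relationship(tibble::tibble(hf = hf, performance = perf))$slope
    })
  })
  expect_lt(abs(mean(slopes)), 0.05)
})

test_that("RR-HF linearity fit detects saturation and exact linearity", {
  hf <- seq(1, 10, length.out = 20)
  d <- tibble::tibble(hf = hf, mean_rr_ms = 800 + 30 * hf)
  fit <- fit_rr_hf_linearity(d)
  expect_equal(fit$slope, 30, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_false(fit$saturation_flag)

  expect_error(fit_rr_hf_linearity(tibble::tibble(hf = rep(2, 5),
                                                  mean_rr_ms = 1:5 * 100)),
               "singular")
})

test_that("independent RR and HF rarely exceed the saturation R2", {
  r2s <- sapply(1:100, function(seed) {
    withr::with_seed(seed, {
      fit_rr_hf_linearity(tibble::tibble(hf = runif(30, 1, 10),
                                         mean_rr_ms = rnorm(30, 1000, 50)))$r2
    })
  })
  expect_gte(mean(r2s < 0.2), 0.95)
})

test_that("capping RR lowers the linear R2 on the same draws", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      hf <- runif(30, 1, 10)
      rr <- 800 + 30 * hf + rnorm(30, 0, 20)
      capped <- pmin(rr, 800 + 30 * median(hf))
      d_lin <- tibble::tibble(hf = hf, mean_rr_ms = rr)
      d_cap <- tibble::tibble(hf = hf, mean_rr_ms = capped)
      expect_lt(fit_rr_hf_linearity(d_cap)$r2, fit_rr_hf_linearity(d_lin)$r2)
    })
  }
})

test_that("timing correlations are scale-free with matching p-values", {
  cohort <- tibble::tibble(
    t_n_perf = c(6, 10, 14, 18, 24),
    t_n_hf = 2 * c(6, 10, 14, 18, 24),
    t_g_perf = c(9, 15, 25, 35, 43),
    t_g_hf = c(9, 15, 25, 35, 43)
  )
  res <- correlate_timing(cohort, n_perm = 500, seed = 1)
  expect_equal(res$r, c(1, 1), tolerance = 1e-12)
  expect_equal(res$index, c("t_n", "t_g"))

  expect_error(correlate_timing(cohort[1:3, ]), "fewer than 4")

  # analytic and permutation p agree under the null
  diffs <- sapply(1:100, function(seed) {
    d <- withr::with_seed(seed, tibble::tibble(
      t_n_perf = rnorm(10), t_n_hf = rnorm(10),
      t_g_perf = rnorm(10), t_g_hf = rnorm(10)
    ))
    res <- correlate_timing(d, n_perm = 2000, seed = seed)
    abs(res$p_value - res$p_perm)
  })
  expect_lt(mean(diffs), 0.02)
})

test_that("cohort report summarises athletes and relationships", {
  log <- make_schedule(season_scenario(weeks = 12))
  make_fit <- function(seed) {
    ath <- sample_athlete(degenerate_population(), seed = seed)
    rec <- generate_observations(log, ath, seed = seed + 500)
    list(
      performance = banister_fit(
        log, dplyr::transmute(rec, day, value = performance)),
      hf = banister_fit(log, dplyr::transmute(rec, day, value = hf)),
      record = rec
    )
  }
  fits <- list(S1 = make_fit(1), S2 = make_fit(2))
  records <- purrr::map(fits, "record")
  rep2 <- cohort_report(fits, records)
  expect_setequal(unique(rep2$athletes$athlete), c("S1", "S2"))
  expect_equal(nrow(rep2$athletes), 4)  # 2 athletes x 2 variables
  expect_true(all(c("mean", "sd") %in% names(rep2$summary)))
  expect_equal(nrow(rep2$relationships), 2)

  single <- cohort_report(fits["S1"])
  expect_true(all(is.na(single$summary$sd)))
  mean_tau1 <- single$summary$mean[single$summary$variable == "performance" &
                                     single$summary$parameter == "tau1"]
  expect_equal(mean_tau1, fits$S1$performance$params$tau1)

  expect_error(cohort_report(list()), "empty")

  # deterministic CSV output
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort_report(rep2, d1)
  write_cohort_report(rep2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
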