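#' Describe a synthetic training season
#'
#' The default scenario mirrors a 30-week competitive swim season with two
#' overload/taper cycles: a first cycle of 8 baseline weeks, a four-week
#' intensive block (weeks 9-12) and a three-week taper (weeks 13-15); then a
#' second cycle with six baseline weeks (16-21), a five-week intensive block
#' (weeks 22-26) and a four-week recovery (weeks 27-30). Block multipliers
#' raise the baseline daily load by 50%/60% during the intensive blocks and
#' roughly halve it during the tapers, the typical overload and taper
#' magnitudes in competitive swimming.
#'
#' @param weeks Season length in weeks (default 30).
#' @param blocks Tibble with `start_week`, `end_week`, `multiplier`; the
#'   ranges must tile `1..weeks` without overlap.
#' @param sessions_per_week Training days per week (default 6; the remaining
#'   days are rest days with zero load).
#' @param base_daily_load Baseline training amount per training day in
#'   arbitrary units (default 6). The gains of [default_population()] are
#'   expressed per arbitrary load unit, so only the product of load scale and
#'   gain is meaningful; 6 a.u. is the scale at which those reference gains
#'   keep both outputs inside physiological ranges (a few percent performance
#'   swing, HF power positive all season).
#' @param start_date First day of the season (default `"2011-09-05"`, a
#'   Monday, so weeks run Monday-Sunday).
#' @return A list of class `season_scenario`.
#' @export
season_scenario <- function(weeks = 30,
                            blocks = NULL,
                            sessions_per_week = 6,
                            base_daily_load = 6,
                            start_date = "2011-09-05") {
  check_number(weeks, "weeks", min = 1)
  if (is.null(blocks)) {
    blocks <- tibble(
      start_week = c(1, 9, 13, 16, 22, 27),
      end_week = c(8, 12, 15, 21, 26, 30),
      multiplier = c(1, 1.5, 0.5, 1, 1.6, 0.45)
    )
    blocks <- blocks[blocks$start_week <= weeks, ]
    blocks$end_week <- pmin(blocks$end_week, weeks)
  }
  blocks <- as_tibble(blocks)
  covered <- unlist(purrr::map2(blocks$start_week, blocks$end_week, seq))
  if (length(covered) != weeks || anyDuplicated(covered) ||
      !setequal(covered, seq_len(weeks))) {
    abort("`blocks` must tile weeks 1..weeks exactly once.")
  }
  if (any(blocks$multiplier <= 0)) abort("Block multipliers must be > 0.")
  if (sessions_per_week < 1 || sessions_per_week > 7) {
    abort("`sessions_per_week` must be between 1 and 7.")
  }
  structure(
    list(weeks = weeks, blocks = blocks,
         sessions_per_week = sessions_per_week,
         base_daily_load = base_daily_load,
         start_date = as.Date(start_date)),
    class = "season_scenario"
  )
}

#' Build the daily training log of a scenario
#'
#' Deterministic: each week has `sessions_per_week` training days (the first
#' days of the week) at `base_daily_load * multiplier` and rest days at zero.
#'
#' @param scenario A [season_scenario()].
#' @param seed Unused (the schedule is deterministic); accepted so all
#'   generators share an interface.
#' @return A `training_log` tibble with columns `day`, `date`, `week`, `w`.
#' @export
make_schedule <- function(scenario = season_scenario(), seed = NULL) {
  if (!inherits(scenario, "season_scenario")) {
    abort("`scenario` must come from season_scenario().")
  }
  days <- scenario$weeks * 7L
  day <- seq_len(days)
  week <- (day - 1L) %/% 7L + 1L
  day_in_week <- (day - 1L) %% 7L + 1L
  mult <- numeric(scenario$weeks)
  for (b in seq_len(nrow(scenario$blocks))) {
    rng <- seq(scenario$blocks$start_week[b], scenario$blocks$end_week[b])
    mult[rng] <- scenario$blocks$multiplier[b]
  }
  w <- ifelse(day_in_week <= scenario$sessions_per_week,
              scenario$base_daily_load * mult[week], 0)
  out <- tibble(
    day = day,
    date = scenario$start_date + day - 1L,
    week = week,
    w = w
  )
  class(out) <- c("training_log", class(out))
  out
}

#' Default athlete population (cohort means and SDs)
#'
#' Means and standard deviations of the two-component model parameters for
#' the performance output (baseline in m/s-like units) and the HF-power
#' output (baseline in s^2/Hz-like units), matching the magnitudes reported
#' for skilled junior swimmers: slow adaptation constants near 50 d (perf) /
#' 42 d (HF) and fast fatigue constants near 4.8 d / 4.2 d.
#'
#' @return Nested list with `performance` and `hf`, each holding `mean` and
#'   `sd` vectors over `(y0, k1, k2, tau1, tau2)`.
#' @export
default_population <- function() {
  list(
    performance = list(
      mean = c(y0 = 1.42, k1 = 7e-5, k2 = 1.1e-3, tau1 = 50, tau2 = 4.8),
      sd = c(y0 = 0.12, k1 = 6e-5, k2 = 1.4e-3, tau1 = 14, tau2 = 2.9)
    ),
    hf = list(
      mean = c(y0 = 8.36, k1 = 0.007, k2 = 0.18, tau1 = 42, tau2 = 4.2),
      sd = c(y0 = 5.22, k1 = 0.006, k2 = 0.16, tau1 = 15, tau2 = 2.3)
    )
  )
}

#' Draw a synthetic athlete
#'
#' Samples true model parameters for both outputs from truncated normal
#' distributions around the population means/SDs. Truncation (gains > 0,
#' `tau2 > 0`, `tau1 > tau2 + 0.5` for each output) is enforced by joint
#' rejection: the whole athlete is redrawn until every parameter is in its
#' validity region, so the marginals are truncated normals and any latent
#' correlation survives intact. With `timing_cor > 0` the performance and HF
#' draws of each parameter share a bivariate-normal latent with that
#' correlation, inducing a matching correlation between the athletes'
#' performance and HF timing indices. The log link ties performance to HF as
#' `perf = link_a + link_b * log(hf)`.
#'
#' @param population A population list as from [default_population()].
#' @param timing_cor Correlation of the per-parameter latents between the two
#'   outputs (default 0 = independent).
#' @param noise_frac Observation noise SD for both outputs, expressed as a
#'   fraction of each output's true seasonal range (default 0.05).
#' @param seed Optional integer seed.
#' @return A list of class `synthetic_athlete` with `performance` and `hf`
#'   [banister_params], the log-link coefficients, noise settings and the
#'   RR-level map (`rr = rr_intercept + rr_slope * hf` plus noise).
#' @export
sample_athlete <- function(population = default_population(),
                           timing_cor = 0, noise_frac = 0.05, seed = NULL) {
  check_number(timing_cor, "timing_cor", min = -1, max = 1)
  check_number(noise_frac, "noise_frac", min = 0)
  for (out in c("performance", "hf")) {
    p <- population[[out]]
    if (any(p$sd < 0)) abort("Population SDs must be >= 0.")
    if (p$mean[["tau1"]] <= p$mean[["tau2"]]) {
      abort("Infeasible population: mean tau1 must exceed mean tau2.")
    }
  }
  with_seed_if(seed, {
    par_names <- c("y0", "k1", "k2", "tau1", "tau2")
    draw_pair <- function() {
      # correlated standard-normal latents, one pair per parameter
      z_p <- rnorm(5L)
      z_h <- timing_cor * z_p + sqrt(1 - timing_cor^2) * rnorm(5L)
      names(z_p) <- names(z_h) <- par_names
      draw_one <- function(pop, z) pop$mean[par_names] + pop$sd[par_names] * z
      list(p = draw_one(population$performance, z_p),
           h = draw_one(population$hf, z_h))
    }
    in_region <- function(v) {
      v[["k1"]] > 0 && v[["k2"]] > 0 && v[["tau2"]] > 0 &&
        v[["tau1"]] > v[["tau2"]] + 0.5
    }
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 10000L) abort("Infeasible truncation region in athlete draw.")
      d <- draw_pair()
      if (in_region(d$p) && in_region(d$h)) break
    }
    structure(
      list(
        performance = banister_params(d$p[["y0"]], d$p[["k1"]], d$p[["k2"]],
                                      d$p[["tau1"]], d$p[["tau2"]]),
        hf = banister_params(d$h[["y0"]], d$h[["k1"]], d$h[["k2"]],
                             d$h[["tau1"]], d$h[["tau2"]]),
        link_a = 1.0, link_b = 0.2,
        noise_frac = noise_frac,
        rr_intercept = 850, rr_slope = 20, rr_noise_sd = 15
      ),
      class = "synthetic_athlete"
    )
  })
}

#' Generate a season of weekly observations
#'
#' Simulates both true outputs daily, samples them on one measurement day per
#' week (default day 5, the Friday of a Monday-started week, matching a
#' Thursday-night recording followed by a Friday time-trial), and adds
#' Gaussian observation noise with SD `noise_frac * range(true series)`.
#' Nightly mean RR is derived from true HF through the athlete's linear map;
#' `rr_cap_ms` optionally saturates it for testing the RR-HF linearity screen.
#'
#' @param log A training log from [make_schedule()] or [build_daily_series()].
#' @param athlete A [sample_athlete()] result.
#' @param measurement_day Day of week (1-7) of the weekly measurement.
#' @param link `"independent"` (each output driven by its own parameters,
#'   default) or `"log"` (performance derived from true HF through the
#'   athlete's log link).
#' @param noise_frac Override of the athlete's observation noise fraction.
#' @param rr_cap_ms Optional upper cap on nightly mean RR (saturation).
#' @param seed Optional integer seed.
#' @return A `season_record` tibble: `week`, `day`, `performance`, `hf`,
#'   `mean_rr_ms`, plus the noiseless `performance_true` and `hf_true`.
#' @export
generate_observations <- function(log, athlete, measurement_day = 5,
                                  link = c("independent", "log"),
                                  noise_frac = NULL, rr_cap_ms = NULL,
                                  seed = NULL) {
  link <- match.arg(link)
  assert_training_log(log, "generate_observations")
  if (!inherits(athlete, "synthetic_athlete")) {
    abort("`athlete` must come from sample_athlete().")
  }
  check_number(measurement_day, "measurement_day", min = 1, max = 7)
  noise_frac <- noise_frac %||% athlete$noise_frac
  n_weeks <- nrow(log) %/% 7L
  m_day <- 7L * (seq_len(n_weeks) - 1L) + as.integer(measurement_day)

  perf_daily <- banister_simulate(log, athlete$performance)$output
  hf_daily <- banister_simulate(log, athlete$hf)$output
  hf_true <- hf_daily[m_day]
  perf_true <- if (link == "log") {
    if (any(hf_true <= 0)) {
      abort("Log link requires positive true HF on all measurement days.")
    }
    athlete$link_a + athlete$link_b * log(hf_true)
  } else {
    perf_daily[m_day]
  }

  with_seed_if(seed, {
    perf_sd <- noise_frac * diff(range(perf_true))
    hf_sd <- noise_frac * diff(range(hf_true))
    perf_obs <- perf_true + rnorm(n_weeks, 0, perf_sd)
    hf_obs <- hf_true + rnorm(n_weeks, 0, hf_sd)
    rr <- athlete$rr_intercept + athlete$rr_slope * hf_true +
      rnorm(n_weeks, 0, if (noise_frac > 0) athlete$rr_noise_sd else 0)
    if (!is.null(rr_cap_ms)) rr <- pmin(rr, rr_cap_ms)
    out <- tibble(
      week = seq_len(n_weeks),
      day = m_day,
      performance = perf_obs,
      hf = hf_obs,
      mean_rr_ms = rr,
      performance_true = perf_true,
      hf_true = hf_true
    )
    class(out) <- c("season_record", class(out))
    out
  })
}

#' Synthesize one night of RR intervals
#'
#' Beat-domain construction with known band content: each interval is the
#' mean RR plus sinusoidal high-frequency (respiratory, default 0.25 Hz) and
#' low-frequency (default 0.1 Hz) modulations evaluated at the accumulated
#' beat time, plus Gaussian jitter. The analytic band membership of the two
#' tones is what the wavelet chain is validated against.
#'
#' @param mean_rr_ms Mean interval in ms.
#' @param hf_amp_ms,lf_amp_ms Modulation amplitudes in ms.
#' @param duration_min Recording length in minutes.
#' @param hf_freq_hz,lf_freq_hz Modulation frequencies in Hz.
#' @param jitter_ms SD of the additive Gaussian beat jitter.
#' @param seed Optional integer seed.
#' @return An [rr_series].
#' @export
generate_rr_night <- function(mean_rr_ms = 1000, hf_amp_ms = 20,
                              lf_amp_ms = 10, duration_min = 480,
                              hf_freq_hz = 0.25, lf_freq_hz = 0.1,
                              jitter_ms = 3, seed = NULL) {
  check_number(hf_amp_ms, "hf_amp_ms", min = 0)
  check_number(lf_amp_ms, "lf_amp_ms", min = 0)
  check_number(jitter_ms, "jitter_ms", min = 0)
  if (mean_rr_ms - hf_amp_ms - lf_amp_ms - 3 * jitter_ms <= 0) {
    abort("Modulation amplitudes and jitter allow non-positive RR intervals.")
  }
  with_seed_if(seed, {
    dur_s <- duration_min * 60
    n_guess <- ceiling(dur_s / (mean_rr_ms / 1000)) + 10L
    jit <- if (jitter_ms > 0) rnorm(n_guess, 0, jitter_ms) else numeric(n_guess)
    rr <- numeric(n_guess)
    t <- 0
    n <- 0L
    while (t < dur_s) {
      n <- n + 1L
      if (n > length(jit)) {
        jit <- c(jit, if (jitter_ms > 0) rnorm(n_guess, 0, jitter_ms)
                 else numeric(n_guess))
      }
      val <- mean_rr_ms +
        hf_amp_ms * sin(2 * pi * hf_freq_hz * t) +
        lf_amp_ms * sin(2 * pi * lf_freq_hz * t) +
        jit[n]
      rr[n] <- val
      t <- t + val / 1000
    }
    rr_series(rr[seq_len(n)])
  })
}
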