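#' Parameters of the two-component impulse-response model
#'
#' The fitness-fatigue model describes an output (performance, or an HRV band
#' power) as a baseline plus two antagonistic first-order responses to daily
#' training amounts w(t):
#'
#'   output(t) = y0 + k1 * sum_{i<t} w(i) e^{-(t-i)/tau1}
#'                  - k2 * sum_{i<t} w(i) e^{-(t-i)/tau2}
#'
#' The slow positive component (gain `k1`, time constant `tau1`) is the
#' adaptation; the fast negative component (`k2`, `tau2`) is the fatigue. A
#' bout on day i first influences day i + 1.
#'
#' @param y0 Initial (baseline) output level, in the output's units.
#' @param k1,k2 Non-negative gains of the positive and negative components,
#'   in output units per arbitrary load unit.
#' @param tau1,tau2 Time constants in days; `tau1 > tau2 > 0`.
#' @return A list of class `banister_params`.
#' @examples
#' banister_params(y0 = 0, k1 = 1, k2 = 2, tau1 = 10, tau2 = 2)
#' @export
banister_params <- function(y0, k1, k2, tau1, tau2) {
  check_number(y0, "y0")
  check_number(k1, "k1", min = 0)
  check_number(k2, "k2", min = 0)
  check_number(tau2, "tau2", min = 0, strict_min = TRUE)
  check_number(tau1, "tau1", min = 0, strict_min = TRUE)
  if (tau1 <= tau2) {
    abort(sprintf(
      "`tau1` (%s) must exceed `tau2` (%s): adaptation outlasts fatigue.",
      format(tau1), format(tau2)))
  }
  structure(list(y0 = y0, k1 = k1, k2 = k2, tau1 = tau1, tau2 = tau2),
            class = "banister_params")
}

#' @export
print.banister_params <- function(x, ...) {
  cat(sprintf(
    "<banister_params> y0=%.4g  k1=%.4g  k2=%.4g  tau1=%.4g d  tau2=%.4g d\n",
    x$y0, x$k1, x$k2, x$tau1, x$tau2))
  invisible(x)
}

assert_banister_params <- function(params, fn) {
  if (!inherits(params, "banister_params")) {
    if (is.list(params) &&
        all(c("y0", "k1", "k2", "tau1", "tau2") %in% names(params))) {
      params <- banister_params(params$y0, params$k1, params$k2,
                                params$tau1, params$tau2)
    } else {
      abort(sprintf("`%s()` expects `banister_params`.", fn))
    }
  }
  params
}

# O(T) recursive convolutions of w with the two exponential kernels;
# p[t] = sum_{i<t} w[i] exp(-(t-i)/tau)
exp_convolutions <- function(w, tau1, tau2) {
  n <- length(w)
  e1 <- exp(-1 / tau1)
  e2 <- exp(-1 / tau2)
  p <- numeric(n)
  q <- numeric(n)
  acc1 <- 0
  acc2 <- 0
  for (t in seq_len(n)) {
    p[t] <- acc1
    q[t] <- acc2
    acc1 <- (acc1 + w[t]) * e1
    acc2 <- (acc2 + w[t]) * e2
  }
  list(p = p, q = q)
}

#' Simulate the modelled output over a season
#'
#' @param log A training log (tibble with daily amounts `w`; see
#'   [build_daily_series()] or [make_schedule()]).
#' @param params A [banister_params] object.
#' @return The log tibble with an `output` column appended.
#' @examples
#' log <- tibble::tibble(day = 1:20, w = c(1, rep(0, 19)))
#' banister_simulate(log, banister_params(0, 1, 2, 10, 2))
#' @export
banister_simulate <- function(log, params) {
  params <- assert_banister_params(params, "banister_simulate")
  assert_training_log(log, "banister_simulate")
  conv <- exp_convolutions(log$w, params$tau1, params$tau2)
  out <- as_tibble(log)
  out$output <- params$y0 + params$k1 * conv$p - params$k2 * conv$q
  out
}

#' Daily positive and negative influences
#'
#' Decomposes the modelled response into the adaptation series
#' `pi = k1 * sum w e^(-dt/tau1)` and the fatigue series
#' `ni = k2 * sum w e^(-dt/tau2)`, so that `y0 + pi - ni` reproduces
#' [banister_simulate()] exactly.
#'
#' @inheritParams banister_simulate
#' @return The log tibble with `pi`, `ni` and `output` columns appended.
#' @export
banister_influences <- function(log, params) {
  params <- assert_banister_params(params, "banister_influences")
  assert_training_log(log, "banister_influences")
  conv <- exp_convolutions(log$w, params$tau1, params$tau2)
  out <- as_tibble(log)
  out$pi <- params$k1 * conv$p
  out$ni <- params$k2 * conv$q
  out$output <- params$y0 + out$pi - out$ni
  out
}

#' Closed-form taper-timing indices
#'
#' For a single unit training bout the response is
#' `r(t) = k1 e^(-t/tau1) - k2 e^(-t/tau2)`. When `k2 > k1 > 0` the response
#' first dips below baseline and then peaks:
#' `t_n = tau1 tau2 / (tau1 - tau2) * log(k2 / k1)` is the time to recover
#' the pre-bout level, and
#' `t_g = tau1 tau2 / (tau1 - tau2) * log(k2 tau1 / (k1 tau2))` the time to
#' peak. The taper-duration window lies between them. With `k2 <= k1` the dip
#' is absent and `t_n` is undefined (`NA`, status `"undefined"`; the boundary
#' `k1 == k2` is reported `"degenerate"` with `t_n = 0`).
#'
#' @param params A [banister_params] object.
#' @return One-row tibble with `t_n`, `t_g` (days) and `status`.
#' @examples
#' banister_timing(banister_params(0, 1, 2, 10, 2))  # t_n = 2.5 log 2
#' @export
banister_timing <- function(params) {
  params <- assert_banister_params(params, "banister_timing")
  scale <- params$tau1 * params$tau2 / (params$tau1 - params$tau2)
  if (params$k1 <= 0 || params$k2 < params$k1) {
    return(tibble(t_n = NA_real_, t_g = NA_real_, status = "undefined"))
  }
  t_n <- scale * log(params$k2 / params$k1)
  t_g <- scale * log(params$k2 * params$tau1 / (params$k1 * params$tau2))
  status <- if (params$k2 == params$k1) "degenerate" else "ok"
  tibble(t_n = t_n, t_g = t_g, status = status)
}

#' Numeric taper-timing indices (grid oracle)
#'
#' Evaluates the single-bout response on a fine time grid and locates the
#' post-dip zero up-crossing (`t_n`, refined by linear interpolation between
#' bracketing grid points) and the maximum (`t_g`). Serves as an independent
#' check of [banister_timing()].
#'
#' @param params A [banister_params] object.
#' @param dt Grid step in days (default 0.01).
#' @param horizon Grid end in days (default: starts at `12 * tau1` and doubles
#'   until the peak is interior); with an explicit horizon an error is raised
#'   when the peak is not bracketed within it.
#' @return One-row tibble with `t_n`, `t_g` and `status`.
#' @export
banister_timing_numeric <- function(params, dt = 0.01, horizon = NULL) {
  params <- assert_banister_params(params, "banister_timing_numeric")
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  if (params$k1 <= 0 || params$k2 < params$k1) {
    return(tibble(t_n = NA_real_, t_g = NA_real_, status = "undefined"))
  }
  adaptive <- is.null(horizon)
  horizon <- horizon %||% (12 * params$tau1)
  repeat {
    t <- seq(dt, horizon, by = dt)
    r <- params$k1 * exp(-t / params$tau1) - params$k2 * exp(-t / params$tau2)
    i_max <- which.max(r)
    if (i_max < length(t)) break
    if (!adaptive || horizon > 1e6) {
      abort("banister_timing_numeric(): horizon too short to bracket the peak.")
    }
    horizon <- 2 * horizon
  }
  cross <- which(r[-length(r)] <= 0 & r[-1L] > 0)
  if (length(cross) == 0L) {
    t_n <- if (params$k2 == params$k1) 0 else NA_real_
  } else {
    i <- cross[1L]
    # linear interpolation of the sign change
    t_n <- t[i] + dt * (0 - r[i]) / (r[i + 1L] - r[i])
  }
  status <- if (params$k2 == params$k1) "degenerate" else "ok"
  tibble(t_n = t_n, t_g = t[i_max], status = status)
}

# exact least squares for y ~ b0 + b1 * a1 - b2 * a2 subject to b1, b2 >= 0:
# enumerate the 4 sign-constraint activity patterns and keep the feasible
# solution with the smallest residual sum of squares
constrained_linear_fit <- function(a1, a2, y) {
  n <- length(y)
  best <- NULL
  for (pattern in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE),
                       c(FALSE, FALSE))) {
    x <- cbind(intercept = rep(1, n),
               if (pattern[1L]) a1,
               if (pattern[2L]) -a2)
    fit <- stats::lm.fit(x, y)
    beta <- fit$coefficients
    if (anyNA(beta)) next  # rank-deficient pattern
    k1 <- if (pattern[1L]) beta[2L] else 0
    k2 <- if (pattern[2L]) beta[length(beta)] else 0
    if (k1 < 0 || k2 < 0) next
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(y0 = unname(beta[1L]), k1 = unname(k1), k2 = unname(k2),
                   rss = rss)
    }
  }
  best
}

# objective for a (tau1, tau2) pair: profile out (y0, k1, k2) exactly
profile_rss <- function(tau1, tau2, w, obs_day, obs_value) {
  conv <- exp_convolutions(w, tau1, tau2)
  constrained_linear_fit(conv$p[obs_day], conv$q[obs_day], obs_value)
}

#' Fit the two-component model to weekly observations
#'
#' Least-squares fit of the fitness-fatigue model to observed outputs
#' (performance or an HRV band power) measured on a subset of days. The model
#' is linear in `(y0, k1, k2)` given the time constants, so the fit nests an
#' exact constrained linear solve (gains non-negative, baseline free) inside
#' a search over `(tau1, tau2)`: a log-spaced coarse grid followed by
#' Nelder-Mead refinement from the best grid points.
#'
#' @param log A training log with daily amounts `w`.
#' @param observations Data frame with columns `day` (1-based day index into
#'   the log) and `value`; at least 8 observations are required (5 free
#'   parameters). Non-uniform spacing and missing weeks are fine.
#' @param bounds List with `tau1` and `tau2` ranges in days (defaults
#'   `c(10, 120)` and `c(0.5, 30)`); `tau1 > tau2 + min_sep` is enforced.
#' @param grid_size Coarse grid resolution per axis (default 20).
#' @param n_refine Number of best grid points refined locally (default 5).
#' @param min_sep Minimum `tau1 - tau2` separation in days (default 0.5).
#' @return A `banister_fit` object: `params`, `daily` (day, w, fitted `output`,
#'   `pi`, `ni`), `observations` (with fitted values and residuals), `r2`
#'   (1 - SS_res/SS_tot), `r2_cor` (squared Pearson correlation), `timing`
#'   (closed-form `t_n`/`t_g`), and `diagnostics`. Supports [tidy()],
#'   [glance()], [augment()] and [autoplot()].
#' @examples
#' log <- make_schedule(season_scenario(weeks = 10))
#' truth <- banister_params(1.4, 7e-5, 1.1e-3, 50, 4.8)
#' obs <- banister_simulate(log, truth) |>
#'   dplyr::filter(day %% 7 == 5) |>
#'   dplyr::transmute(day, value = output)
#' fit <- banister_fit(log, obs)
#' @export
banister_fit <- function(log, observations,
                         bounds = list(tau1 = c(10, 120), tau2 = c(0.5, 30)),
                         grid_size = 20, n_refine = 5, min_sep = 0.5) {
  assert_training_log(log, "banister_fit")
  if (!all(c("day", "value") %in% names(observations))) {
    abort("`observations` must have `day` and `value` columns.")
  }
  obs <- dplyr::arrange(as_tibble(observations), .data$day)
  if (nrow(obs) < 8L) {
    abort("banister_fit() needs at least 8 observations for 5 free parameters.")
  }
  if (any(obs$day < 1L) || any(obs$day > nrow(log))) {
    abort("Observation days must lie within the training log span.")
  }
  w <- log$w
  y <- obs$value
  obs_day <- as.integer(obs$day)

  ss_tot <- sum((y - mean(y))^2)
  degenerate <- ss_tot <= .Machine$double.eps * max(1, sum(y^2))

  t1_grid <- exp(seq(log(bounds$tau1[1L]), log(bounds$tau1[2L]),
                     length.out = grid_size))
  t2_grid <- exp(seq(log(bounds$tau2[1L]), log(bounds$tau2[2L]),
                     length.out = grid_size))
  grid <- expand.grid(tau1 = t1_grid, tau2 = t2_grid)
  grid <- grid[grid$tau1 > grid$tau2 + min_sep, ]
  grid$rss <- purrr::map2_dbl(grid$tau1, grid$tau2, function(t1, t2) {
    sol <- profile_rss(t1, t2, w, obs_day, y)
    if (is.null(sol)) Inf else sol$rss
  })
  grid <- grid[order(grid$rss), ]

  # Nelder-Mead refinement on log taus from the best coarse points
  objective <- function(par) {
    t1 <- exp(par[1L])
    t2 <- exp(par[2L])
    if (t1 < bounds$tau1[1L] || t1 > bounds$tau1[2L] ||
        t2 < bounds$tau2[1L] || t2 > bounds$tau2[2L] ||
        t1 <= t2 + min_sep) {
      return(.Machine$double.xmax)
    }
    sol <- profile_rss(t1, t2, w, obs_day, y)
    if (is.null(sol)) .Machine$double.xmax else sol$rss
  }
  starts <- head(grid, n_refine)
  refined <- purrr::pmap(starts, function(tau1, tau2, rss) {
    optim(log(c(tau1, tau2)), objective, method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-12))
  })
  values <- purrr::map_dbl(refined, "value")
  best <- refined[[which.min(values)]]
  tau1_hat <- exp(best$par[1L])
  tau2_hat <- exp(best$par[2L])
  sol <- profile_rss(tau1_hat, tau2_hat, w, obs_day, y)
  params <- banister_params(sol$y0, sol$k1, sol$k2, tau1_hat, tau2_hat)

  daily <- banister_influences(log, params)
  fitted_obs <- daily$output[obs_day]
  obs$fitted <- fitted_obs
  obs$residual <- y - fitted_obs
  r2 <- if (degenerate) NA_real_ else 1 - sol$rss / ss_tot
  r2_cor <- if (degenerate || sd0(fitted_obs) == 0) NA_real_ else
    cor(y, fitted_obs)^2

  structure(
    list(
      params = params,
      daily = daily,
      observations = obs,
      r2 = r2,
      r2_cor = r2_cor,
      timing = banister_timing(params),
      diagnostics = list(
        converged = best$convergence == 0,
        iterations = unname(best$counts[1L]),
        objective = best$value,
        grid_points = nrow(grid),
        n_refine = n_refine,
        degenerate_observations = degenerate
      )
    ),
    class = "banister_fit"
  )
}

#' @export
print.banister_fit <- function(x, ...) {
  cat("Two-component training-response fit\n")
  print(x$params)
  cat(sprintf("  R2 = %.4f on %d observations (R2_cor = %.4f)\n",
              x$r2, nrow(x$observations), x$r2_cor))
  cat(sprintf("  t_n = %.2f d, t_g = %.2f d (%s)\n",
              x$timing$t_n, x$timing$t_g, x$timing$status))
  if (!x$diagnostics$converged) cat("  WARNING: optimizer did not converge\n")
  if (x$diagnostics$degenerate_observations) {
    cat("  WARNING: constant observations; R2 undefined\n")
  }
  invisible(x)
}
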