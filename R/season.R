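#' Normalize a 400-m performance to percent of national best
#'
#' The performance criterion is the mean 400-m freestyle velocity expressed
#' as a percentage of the best national velocity. Provide either the trial
#' time in seconds or the velocity directly; vectors are accepted.
#'
#' @param time_400m_s Trial time(s) in seconds (velocity = 400 / time).
#' @param velocity_ms Velocity in m/s (alternative to `time_400m_s`).
#' @param national_best_ms National best velocity in m/s.
#' @return Percent of the national best (numeric vector).
#' @examples
#' normalize_performance(velocity_ms = 1.64, national_best_ms = 1.64)  # 100
#' normalize_performance(time_400m_s = 280, national_best_ms = 1.6)
#' @export
normalize_performance <- function(time_400m_s = NULL, velocity_ms = NULL,
                                  national_best_ms) {
  if (is.null(velocity_ms) == is.null(time_400m_s)) {
    abort("Provide exactly one of `time_400m_s` or `velocity_ms`.")
  }
  if (any(national_best_ms <= 0)) abort("`national_best_ms` must be > 0.")
  if (!is.null(time_400m_s)) {
    if (any(time_400m_s <= 0)) abort("`time_400m_s` must be > 0.")
    velocity_ms <- 400 / time_400m_s
  }
  if (any(velocity_ms <= 0)) abort("`velocity_ms` must be > 0.")
  100 * velocity_ms / national_best_ms
}

new_relationship_fit <- function(model, data, form, x_name, y_name) {
  # noiseless synthetic data legitimately produce exact fits; the stock
  # "essentially perfect fit" warning is noise in that setting
  s <- withCallingHandlers(
    summary(model),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- coef(s)
  structure(
    list(
      intercept = co[1L, 1L],
      slope = co[2L, 1L],
      r2 = s$r.squared,
      r2_cor = cor(data$.y, stats::fitted(model))^2,
      p_value = co[2L, 4L],
      n = nrow(data),
      form = form,
      x = x_name,
      y = y_name,
      model = model
    ),
    class = "relationship_fit"
  )
}

#' @export
print.relationship_fit <- function(x, ...) {
  cat(sprintf("<relationship_fit> %s: %s = %.4g %+.4g * %s\n",
              x$form, x$y, x$intercept, x$slope,
              if (x$form == "log") sprintf("log(%s)", x$x) else x$x))
  cat(sprintf("  R2 = %.4f, p(slope) = %.3g, n = %d\n", x$r2, x$p_value, x$n))
  invisible(x)
}

#' Per-athlete logarithmic HF-performance relationship
#'
#' Ordinary least squares of performance on the natural log of nightly HF
#' power, the within-athlete dose-response curve linking parasympathetic
#' activity to performance. The inverse direction (log HF on performance) is
#' available via `direction`.
#'
#' @param data Data frame with the two columns named by `hf` and
#'   `performance` (and optionally `week`, used in error messages).
#' @param hf,performance Column names (strings).
#' @param direction `"perf_on_loghf"` (default) or `"loghf_on_perf"`.
#' @return A `relationship_fit` (intercept, slope, `r2`, slope p-value, `n`);
#'   supports [tidy()] and [glance()].
#' @export
fit_log_relationship <- function(data, hf = "hf", performance = "performance",
                                 direction = c("perf_on_loghf",
                                               "loghf_on_perf")) {
  direction <- match.arg(direction)
  h <- check_column(data, hf, "fit_log_relationship")
  p <- check_column(data, performance, "fit_log_relationship")
  keep <- !is.na(h) & !is.na(p)
  h <- h[keep]
  p <- p[keep]
  if (length(h) < 3L) abort("fit_log_relationship() needs >= 3 paired points.")
  if (any(h <= 0)) {
    wk <- if ("week" %in% names(data)) data$week[keep][which(h <= 0)[1L]] else
      which(h <= 0)[1L]
    abort(sprintf(
      "HF power must be > 0 for the log fit (offending week/row: %s).", wk))
  }
  df <- if (direction == "perf_on_loghf") {
    tibble(.x = log(h), .y = p)
  } else {
    tibble(.x = p, .y = log(h))
  }
  if (sd0(df$.x) == 0) {
    abort("fit_log_relationship(): predictor is constant (singular design).")
  }
  model <- lm(.y ~ .x, data = df)
  new_relationship_fit(model, df, "log",
                       x_name = if (direction == "perf_on_loghf") hf else
                         performance,
                       y_name = if (direction == "perf_on_loghf") performance
                       else hf)
}

#' RR-interval versus HF-power linearity (saturation screen)
#'
#' Ordinary least squares of nightly mean RR length on HF power. Vagal
#' saturation - HF power no longer tracking vagal outflow at long RR - shows
#' up as a weak fit, so a low R2 flags the athlete for cautious HF
#' interpretation.
#'
#' @param data Data frame with the columns named by `mean_rr` and `hf`.
#' @param mean_rr,hf Column names (strings).
#' @param saturation_r2 R2 below which the `saturation_flag` is set
#'   (default 0.2).
#' @return A `relationship_fit` with an extra `saturation_flag` field.
#' @export
fit_rr_hf_linearity <- function(data, mean_rr = "mean_rr_ms", hf = "hf",
                                saturation_r2 = 0.2) {
  r <- check_column(data, mean_rr, "fit_rr_hf_linearity")
  h <- check_column(data, hf, "fit_rr_hf_linearity")
  keep <- !is.na(r) & !is.na(h)
  r <- r[keep]
  h <- h[keep]
  if (length(r) < 3L) abort("fit_rr_hf_linearity() needs >= 3 paired points.")
  if (sd0(h) == 0) {
    abort("fit_rr_hf_linearity(): HF power is constant (singular design).")
  }
  df <- tibble(.x = h, .y = r)
  model <- lm(.y ~ .x, data = df)
  out <- new_relationship_fit(model, df, "linear", x_name = hf,
                              y_name = mean_rr)
  out$saturation_flag <- out$r2 < saturation_r2
  out
}

#' Cross-athlete correlation of the timing indices
#'
#' Pearson correlation, across athletes, between the performance and HF
#' versions of each timing index: days to recover baseline (`t_n`) and days
#' to peak (`t_g`). Reports the analytic t-distribution p-value and a seeded
#' permutation p-value as a small-sample companion. Athletes with an
#' undefined index are dropped pairwise.
#'
#' @param cohort Data frame with columns `t_n_perf`, `t_n_hf`, `t_g_perf`,
#'   `t_g_hf` (one row per athlete); see [timing_table()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed for the permutations.
#' @return Tibble with one row per index: `index`, `r`, `p_value`, `p_perm`,
#'   `n`.
#' @export
correlate_timing <- function(cohort, n_perm = 10000, seed = NULL) {
  needed <- c("t_n_perf", "t_n_hf", "t_g_perf", "t_g_hf")
  if (!all(needed %in% names(cohort))) {
    abort(sprintf("`cohort` must have columns %s.",
                  paste0("`", needed, "`", collapse = ", ")))
  }
  one_index <- function(x, y, label) {
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]
    y <- y[keep]
    n <- length(x)
    if (n < 4L) {
      abort(sprintf(
        "correlate_timing(): fewer than 4 athletes with defined %s.", label))
    }
    r <- cor(x, y)
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p_t <- 2 * pt(-abs(t_stat), df = n - 2)
    p_perm <- with_seed_if(seed, {
      perm <- replicate(n_perm, abs(cor(x, sample(y))))
      (sum(perm >= abs(r)) + 1) / (n_perm + 1)
    })
    tibble(index = label, r = r, p_value = p_t, p_perm = p_perm, n = n)
  }
  dplyr::bind_rows(
    one_index(cohort$t_n_perf, cohort$t_n_hf, "t_n"),
    one_index(cohort$t_g_perf, cohort$t_g_hf, "t_g")
  )
}

#' @importFrom stats pt
NULL

#' Timing-index table from per-athlete fits
#'
#' Convenience bridge from fitted models to the cohort table consumed by
#' [correlate_timing()].
#'
#' @param fits Named list (one element per athlete) of lists with components
#'   `performance` and `hf`, each a `banister_fit`.
#' @return Tibble with `athlete`, `t_n_perf`, `t_g_perf`, `t_n_hf`, `t_g_hf`.
#' @export
timing_table <- function(fits) {
  if (length(fits) == 0L) abort("`fits` is empty.")
  purrr::imap_dfr(fits, function(f, id) {
    tibble(
      athlete = id,
      t_n_perf = f$performance$timing$t_n,
      t_g_perf = f$performance$timing$t_g,
      t_n_hf = f$hf$timing$t_n,
      t_g_hf = f$hf$timing$t_g
    )
  })
}

#' Cohort summary report
#'
#' Collates per-athlete model parameters, goodness of fit and timing indices
#' for both outputs into the standard cohort layout: a per-athlete table, a
#' mean/SD summary per output variable, and (when season records are given)
#' the per-athlete HF-performance log fits and RR-HF linearity screens.
#'
#' @param fits Named list per athlete with `performance` and `hf`
#'   `banister_fit` components (as for [timing_table()]).
#' @param records Optional named list of `season_record` tibbles (or one
#'   combined data frame with an `athlete` column) used for the relationship
#'   fits.
#' @return A list of class `cohort_report` with tibbles `athletes`, `summary`
#'   and optionally `relationships`.
#' @export
cohort_report <- function(fits, records = NULL) {
  if (length(fits) == 0L) {
    abort("cohort_report(): no fits supplied (empty report).")
  }
  athletes <- purrr::imap_dfr(fits, function(f, id) {
    purrr::imap_dfr(f[c("performance", "hf")], function(fit, variable) {
      p <- fit$params
      tibble(
        athlete = id, variable = variable,
        r2 = fit$r2, y0 = p$y0, k1 = p$k1, k2 = p$k2,
        tau1 = p$tau1, tau2 = p$tau2,
        t_n = fit$timing$t_n, t_g = fit$timing$t_g
      )
    })
  })
  n_athletes <- length(fits)
  summary_tbl <- athletes |>
    tidyr::pivot_longer(c("r2", "y0", "k1", "k2", "tau1", "tau2",
                          "t_n", "t_g"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$variable, .data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (n_athletes > 1L) sd(.data$value[!is.na(.data$value)]) else
        NA_real_,
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )

  out <- list(athletes = athletes, summary = summary_tbl)
  if (!is.null(records)) {
    if (is.data.frame(records)) {
      if (!"athlete" %in% names(records)) {
        abort("A combined `records` data frame needs an `athlete` column.")
      }
      records <- split(records, records$athlete)
    }
    out$relationships <- purrr::imap_dfr(records, function(rec, id) {
      # an athlete with non-positive HF weeks has no valid log fit; report NA
      # for that athlete instead of aborting the whole cohort
      logfit <- tryCatch(fit_log_relationship(rec), error = function(e) NULL)
      rrfit <- fit_rr_hf_linearity(rec)
      tibble(
        athlete = id,
        log_intercept = logfit$intercept %||% NA_real_,
        log_slope = logfit$slope %||% NA_real_,
        log_r2 = logfit$r2 %||% NA_real_,
        log_p = logfit$p_value %||% NA_real_,
        rr_hf_slope = rrfit$slope, rr_hf_r2 = rrfit$r2,
        saturation_flag = rrfit$saturation_flag
      )
    })
  }
  class(out) <- "cohort_report"
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d athletes\n\n",
              dplyr::n_distinct(x$athletes$athlete)))
  cat("Per-variable parameter summary (mean +/- SD):\n")
  print(x$summary, n = Inf)
  if (!is.null(x$relationships)) {
    cat("\nPer-athlete HF-performance and RR-HF relationships:\n")
    print(x$relationships, n = Inf)
  }
  invisible(x)
}

#' Write a cohort report to CSV files
#'
#' Deterministic: identical inputs produce byte-identical files.
#'
#' @param report A [cohort_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_report <- function(report, dir) {
  if (!inherits(report, "cohort_report")) {
    abort("`report` must come from cohort_report().")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(report[[nm]], path, progress = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
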