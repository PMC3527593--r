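#' Spectral-analysis configuration
#'
#' Bundles the tunable settings of the wavelet HRV chain. Band edges follow
#' the short-term HRV convention: LF 0.04-0.15 Hz (sympathetic plus mixed
#' influences), HF 0.15-0.4 Hz (parasympathetic / respiratory).
#'
#' @param rate_hz Tachogram resampling rate; must exceed twice the upper HF
#'   edge (default 4 Hz).
#' @param bands Named list with numeric `lf` and `hf` ranges in Hz.
#' @param wavelet Mother wavelet for [modwt_energies()] (default `"db8"`).
#' @param assignment How dyadic levels map to bands: `"majority"` (default;
#'   a level belongs wholly to the band covering the majority of its nominal
#'   interval) or `"prorata"` (level energy split by bandwidth overlap).
#' @param units `"ms2"` (band power in ms squared, default) or `"s2_per_hz"`
#'   (power converted to seconds squared and divided by the band width in Hz).
#' @param window_min Window length in minutes for [nightly_spectral_summary()].
#' @return A list of class `hrv_config`.
#' @export
hrv_config <- function(rate_hz = 4,
                       bands = list(lf = c(0.04, 0.15), hf = c(0.15, 0.4)),
                       wavelet = "db8",
                       assignment = c("majority", "prorata"),
                       units = c("ms2", "s2_per_hz"),
                       window_min = 5) {
  assignment <- match.arg(assignment)
  units <- match.arg(units)
  if (!all(c("lf", "hf") %in% names(bands))) {
    abort("`bands` must contain `lf` and `hf` ranges.")
  }
  bands <- lapply(bands, function(b) sort(as.numeric(b)))
  if (rate_hz <= 2 * bands$hf[2L]) {
    abort("`rate_hz` must exceed twice the upper HF band edge.")
  }
  structure(
    list(rate_hz = rate_hz, bands = bands, wavelet = wavelet,
         assignment = assignment, units = units, window_min = window_min),
    class = "hrv_config"
  )
}

#' Read a spectral configuration from JSON or YAML
#'
#' Accepts a file holding any subset of the [hrv_config()] fields; missing
#' fields take the defaults. YAML files require the `yaml` package.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `hrv_config` list.
#' @export
read_hrv_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: '%s'.", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML configs requires the 'yaml' package; use JSON instead.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- cfg[intersect(names(cfg), names(formals(hrv_config)))]
  if (!is.null(args$bands)) args$bands <- lapply(args$bands, as.numeric)
  do.call(hrv_config, args)
}

#' Resample an RR series to a uniform tachogram
#'
#' Linearly interpolates the valid (beat time, interval) pairs onto a uniform
#' grid so that frequency-domain analysis applies. Gaps left by invalid beats
#' are bridged by the interpolation. No detrending happens here; the band
#' operation subtracts the mean itself.
#'
#' @param series An [rr_series].
#' @param rate_hz Sampling rate of the grid in Hz (default 4).
#' @return A tibble of class `tachogram` with columns `time_s`, `rr_ms` and
#'   attribute `sample_rate_hz`.
#' @export
resample_tachogram <- function(series, rate_hz = 4) {
  assert_rr_series(series, "resample_tachogram")
  check_number(rate_hz, "rate_hz", min = 0, strict_min = TRUE)
  tt <- series$beat_time_s[series$valid]
  rr <- series$rr_ms[series$valid]
  if (length(tt) < 2L || (max(tt) - min(tt)) < 2 / rate_hz) {
    abort("resample_tachogram() needs >= 2 valid beats spanning >= 2 samples.")
  }
  grid <- seq(min(tt), max(tt), by = 1 / rate_hz)
  out <- tibble(
    time_s = grid,
    rr_ms = approx(tt, rr, xout = grid, rule = 2, ties = mean)$y
  )
  attr(out, "sample_rate_hz") <- rate_hz
  class(out) <- c("tachogram", class(out))
  out
}

# nominal frequency interval [fs/2^(j+1), fs/2^j] of each detail level
level_intervals <- function(rate_hz, n_levels) {
  j <- seq_len(n_levels)
  tibble(level = j, f_lo_hz = rate_hz / 2^(j + 1), f_hi_hz = rate_hz / 2^j)
}

band_overlap_fraction <- function(f_lo, f_hi, band) {
  pmax(0, pmin(f_hi, band[2L]) - pmax(f_lo, band[1L])) / (f_hi - f_lo)
}

#' Wavelet band powers of a uniform tachogram
#'
#' Subtracts the mean, runs a MODWT ([modwt_energies()]) deep enough for the
#' lowest LF edge, and aggregates the per-level energies into LF, HF and total
#' power. With `assignment = "majority"` each detail level belongs to the band
#' covering most of its nominal dyadic interval; with `"prorata"` level
#' energies are split by bandwidth overlap. `ptot_power` sums every detail
#' level whose interval reaches below the upper HF edge (i.e. LF, HF and the
#' very-low-frequency levels down to the deepest computed). In `"s2_per_hz"`
#' mode each band power is converted from ms squared to s squared and divided
#' by its nominal bandwidth.
#'
#' @param tach A `tachogram` from [resample_tachogram()].
#' @param config An [hrv_config()].
#' @return One-row tibble with `hf_power`, `lf_power`, `ptot_power`,
#'   `lf_hf_ratio`, `units`; attributes `levels` (per-level tibble with
#'   energies in ms squared and band assignment) and `smooth_energy_ms2`.
#' @export
band_powers <- function(tach, config = hrv_config()) {
  if (!inherits(tach, "tachogram")) {
    if (is.data.frame(tach) && all(c("time_s", "rr_ms") %in% names(tach))) {
      class(tach) <- c("tachogram", class(tach))
    } else {
      abort("`tach` must be a tachogram from resample_tachogram().")
    }
  }
  fs <- attr(tach, "sample_rate_hz") %||% config$rate_hz
  lf <- config$bands$lf
  hf <- config$bands$hf
  n_levels <- ceiling(log2(fs / lf[1L])) - 1L

  x <- tach$rr_ms - mean(tach$rr_ms)
  en <- modwt_energies(x, n_levels, wavelet = config$wavelet)

  lev <- level_intervals(fs, n_levels)
  lev$energy_ms2 <- en$detail
  lev$lf_frac <- band_overlap_fraction(lev$f_lo_hz, lev$f_hi_hz, lf)
  lev$hf_frac <- band_overlap_fraction(lev$f_lo_hz, lev$f_hi_hz, hf)
  if (config$assignment == "majority") {
    lev$band <- dplyr::case_when(
      lev$hf_frac >= 0.5 ~ "hf",
      lev$lf_frac >= 0.5 ~ "lf",
      lev$f_lo_hz < lf[1L] ~ "vlf",
      TRUE ~ "above_hf"
    )
    hf_ms2 <- sum(lev$energy_ms2[lev$band == "hf"])
    lf_ms2 <- sum(lev$energy_ms2[lev$band == "lf"])
  } else {
    lev$band <- dplyr::case_when(
      lev$hf_frac > 0 & lev$lf_frac > 0 ~ "lf/hf",
      lev$hf_frac > 0 ~ "hf",
      lev$lf_frac > 0 ~ "lf",
      lev$f_lo_hz < lf[1L] ~ "vlf",
      TRUE ~ "above_hf"
    )
    hf_ms2 <- sum(lev$energy_ms2 * lev$hf_frac)
    lf_ms2 <- sum(lev$energy_ms2 * lev$lf_frac)
  }
  ptot_ms2 <- sum(lev$energy_ms2[lev$f_lo_hz < hf[2L]])

  if (config$units == "s2_per_hz") {
    conv <- function(p_ms2, width_hz) (p_ms2 * 1e-6) / width_hz
    hf_out <- conv(hf_ms2, diff(hf))
    lf_out <- conv(lf_ms2, diff(lf))
    ptot_out <- conv(ptot_ms2, hf[2L] - min(lev$f_lo_hz))
  } else {
    hf_out <- hf_ms2
    lf_out <- lf_ms2
    ptot_out <- ptot_ms2
  }

  out <- tibble(
    hf_power = hf_out,
    lf_power = lf_out,
    ptot_power = ptot_out,
    lf_hf_ratio = ifelse(hf_ms2 > 0, lf_ms2 / hf_ms2, NA_real_),
    units = config$units
  )
  attr(out, "levels") <- lev
  attr(out, "smooth_energy_ms2") <- en$smooth
  out
}

#' Nightly spectral summary of an RR recording
#'
#' Partitions the night into consecutive windows of `window_min` minutes,
#' computes wavelet band powers per complete window, and averages across
#' windows (robust to within-night nonstationarity). The LF/HF ratio is the
#' ratio of the averaged band powers.
#'
#' @param series An [rr_series] (run [filter_artifacts()] first).
#' @param config An [hrv_config()]; `config$window_min` sets the window, and
#'   `window_min = Inf` analyses the whole night as a single window.
#' @return One-row tibble with the across-window mean `hf_power`, `lf_power`,
#'   `ptot_power`, `lf_hf_ratio`, plus `units`, `n_windows` and
#'   `pct_beats_flagged`.
#' @export
nightly_spectral_summary <- function(series, config = hrv_config()) {
  assert_rr_series(series, "nightly_spectral_summary")
  win_s <- config$window_min * 60
  tt <- series$beat_time_s
  span <- if (any(series$valid)) max(tt[series$valid]) else 0
  if (!is.finite(win_s)) win_s <- span
  n_win <- floor(span / win_s)
  if (is.na(n_win) || n_win < 1L) {
    abort("nightly_spectral_summary(): no complete window in the recording.")
  }
  windows <- purrr::map(seq_len(n_win), function(k) {
    lo <- (k - 1) * win_s
    hi <- k * win_s
    idx <- tt > lo & tt <= hi
    sub <- series[idx, , drop = FALSE]
    class(sub) <- class(series)
    tryCatch(
      band_powers(resample_tachogram(sub, config$rate_hz), config),
      error = function(e) NULL
    )
  })
  windows <- purrr::compact(windows)
  if (length(windows) == 0L) {
    abort("nightly_spectral_summary(): no window had enough valid beats.")
  }
  powers <- dplyr::bind_rows(windows)
  tibble(
    hf_power = mean(powers$hf_power),
    lf_power = mean(powers$lf_power),
    ptot_power = mean(powers$ptot_power),
    lf_hf_ratio = mean(powers$lf_power) / mean(powers$hf_power),
    units = config$units,
    n_windows = length(windows),
    pct_beats_flagged = attr(series, "pct_flagged") %||% 100 * mean(!series$valid)
  )
}
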