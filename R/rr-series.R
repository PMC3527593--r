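#' Construct an RR-interval series
#'
#' An `rr_series` is a tibble with one row per heart beat: the interval length
#' `rr_ms` (milliseconds), the cumulative beat time `beat_time_s` (seconds from
#' recording start, i.e. the cumulative sum of the intervals) and a logical
#' `valid` flag marking beats accepted as normal. All downstream HRV
#' computations use valid beats only.
#'
#' @param rr_ms Numeric vector of RR intervals in milliseconds; all must be
#'   strictly positive.
#' @param valid Logical vector of per-beat validity flags (default: all valid).
#' @return A tibble of class `rr_series` with columns `beat_time_s`, `rr_ms`,
#'   `valid`.
#' @examples
#' rr_series(c(1000, 990, 1010))
#' @export
rr_series <- function(rr_ms, valid = rep(TRUE, length(rr_ms))) {
  if (!is.numeric(rr_ms) || length(rr_ms) == 0L) {
    abort("`rr_ms` must be a non-empty numeric vector.")
  }
  if (anyNA(rr_ms) || any(rr_ms <= 0)) {
    bad <- which(is.na(rr_ms) | rr_ms <= 0)[1L]
    abort(sprintf("RR intervals must be positive: element %d is %s.",
                  bad, format(rr_ms[bad])))
  }
  if (length(valid) != length(rr_ms) || !is.logical(valid) || anyNA(valid)) {
    abort("`valid` must be a logical vector matching `rr_ms` with no NA.")
  }
  out <- tibble(
    beat_time_s = cumsum(rr_ms) / 1000,
    rr_ms = as.numeric(rr_ms),
    valid = valid
  )
  class(out) <- c("rr_series", class(out))
  out
}

assert_rr_series <- function(x, fn) {
  if (!is.data.frame(x) || !all(c("beat_time_s", "rr_ms", "valid") %in% names(x))) {
    abort(sprintf(
      "`%s()` expects an `rr_series` (columns beat_time_s, rr_ms, valid).", fn))
  }
  invisible(x)
}

#' Read a nocturnal RR-interval recording
#'
#' Reads RR intervals from either a plain-text file (one interval in
#' milliseconds per line, `#` comments and blank lines allowed) or a Polar
#' HRM-style sectioned text file whose `[HRData]` section lists one interval
#' in milliseconds per line (first column when several are present).
#'
#' @param path Path to the recording.
#' @param format `"plain_ms"` (default) or `"hrm"`.
#' @return An [rr_series] with all beats initially marked valid.
#' @examples
#' f <- tempfile()
#' writeLines(c("1000", "990", "1010"), f)
#' read_rr_file(f)
#' @export
read_rr_file <- function(path, format = c("plain_ms", "hrm")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("RR file not found: '%s'.", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "hrm") {
    start <- grep("^\\[HRData\\]", lines, ignore.case = TRUE)
    if (length(start) == 0L) {
      abort(sprintf("No [HRData] section found in HRM file '%s'.", path))
    }
    idx <- seq(start[1L] + 1L, length(lines))
    sec_end <- grep("^\\[", lines[idx])
    if (length(sec_end) > 0L) idx <- idx[seq_len(sec_end[1L] - 1L)]
    line_no <- idx
    body <- sub("\\s.*$", "", trimws(lines[idx]))  # first column
  } else {
    body <- sub("#.*$", "", lines)
    line_no <- seq_along(body)
    keep <- trimws(body) != ""
    body <- trimws(body[keep])
    line_no <- line_no[keep]
  }
  if (length(body) == 0L) {
    abort(sprintf("RR file '%s' contains no interval data.", path))
  }
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(is.na(vals) | vals <= 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "RR file '%s': invalid interval '%s' at line %d (must be a positive number in ms).",
      path, body[bad[1L]], line_no[bad[1L]]))
  }
  rr_series(vals)
}

#' Flag artifact beats in an RR series
#'
#' Automated stand-in for visual validation of nocturnal recordings: a beat is
#' flagged invalid when its interval falls outside `[min_ms, max_ms]` or when
#' it differs from the previous *valid* beat by more than a fraction
#' `max_rel_jump` of that beat's length. Only the `valid` flags change; the
#' intervals and beat times are untouched, so filtering is idempotent.
#'
#' @param series An [rr_series].
#' @param min_ms,max_ms Absolute physiological interval range in ms
#'   (defaults 300 and 2000, i.e. 30-200 beats/min).
#' @param max_rel_jump Maximum allowed relative beat-to-beat change
#'   (default 0.3); must lie in (0, 1).
#' @return The series with updated `valid` flags and an attribute
#'   `pct_flagged` (percent of beats flagged by this call or earlier). A
#'   warning is raised when more than 5% of beats end up flagged.
#' @examples
#' filter_artifacts(rr_series(c(1000, 3000, 1000)))
#' @export
filter_artifacts <- function(series, min_ms = 300, max_ms = 2000,
                             max_rel_jump = 0.3) {
  assert_rr_series(series, "filter_artifacts")
  if (min_ms >= max_ms) abort("`min_ms` must be smaller than `max_ms`.")
  check_number(max_rel_jump, "max_rel_jump", min = 0, max = 1, strict_min = TRUE)
  if (max_rel_jump >= 1) abort("`max_rel_jump` must be < 1.")

  rr <- series$rr_ms
  valid <- series$valid & rr >= min_ms & rr <= max_ms
  # relative-jump pass against the last accepted beat (sequential by nature)
  last <- NA_real_
  for (i in seq_along(rr)) {
    if (!valid[i]) next
    if (!is.na(last) && abs(rr[i] - last) > max_rel_jump * last) {
      valid[i] <- FALSE
    } else {
      last <- rr[i]
    }
  }
  out <- series
  out$valid <- valid
  pct <- 100 * mean(!valid)
  attr(out, "pct_flagged") <- pct
  if (pct > 5) {
    warn(sprintf("%.1f%% of beats flagged as artifacts (> 5%%).", pct))
  }
  out
}

#' Time-domain HRV indices
#'
#' Computes the five classical time-domain heart-rate-variability indices from
#' the valid beats of an RR series: SDNN (sample SD of all normal intervals),
#' RMSSD (root mean square of successive differences), pNN50 (percent of
#' successive-difference pairs exceeding 50 ms), SDANN (sample SD of
#' per-segment mean RR) and SDNNIDX (mean of per-segment sample SDs), with
#' segments being contiguous `segment_min`-minute windows of the recording.
#' Successive-difference pairs straddling an invalid beat are excluded rather
#' than interpolated. A trailing incomplete segment is dropped; when fewer
#' than two usable segments exist, SDANN and SDNNIDX are reported `NA`.
#'
#' @param series An [rr_series].
#' @param segment_min Segment length in minutes for SDANN/SDNNIDX (default 5).
#' @return A one-row tibble with columns `mean_rr_ms`, `sdnn_ms`, `rmssd_ms`,
#'   `pnn50_pct`, `sdann_ms`, `sdnnidx_ms`, `n_valid_beats`, `n_segments`.
#' @examples
#' time_domain_indices(rr_series(c(1000, 950, 1050, 1000)))
#' @export
time_domain_indices <- function(series, segment_min = 5) {
  assert_rr_series(series, "time_domain_indices")
  check_number(segment_min, "segment_min", min = 0, strict_min = TRUE)
  rr <- series$rr_ms[series$valid]
  tt <- series$beat_time_s[series$valid]
  if (length(rr) < 2L) {
    abort("time_domain_indices() needs at least 2 valid beats.")
  }
  # successive differences between beats adjacent in the original recording
  adj <- series$valid[-1L] & series$valid[-nrow(series)]
  d <- diff(series$rr_ms)[adj]

  rmssd <- if (length(d) > 0L) sqrt(mean(d^2)) else NA_real_
  pnn50 <- if (length(d) > 0L) 100 * mean(abs(d) > 50) else NA_real_

  seg_len <- segment_min * 60
  seg <- floor(tt / seg_len) + 1L
  n_complete <- floor(max(series$beat_time_s) / seg_len)
  keep <- seg <= n_complete
  seg_stats <- tibble(seg = seg[keep], rr = rr[keep]) |>
    dplyr::group_by(.data$seg) |>
    dplyr::summarise(n = dplyr::n(), m = mean(.data$rr), s = sd(.data$rr),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= 2L)
  if (nrow(seg_stats) >= 2L) {
    sdann <- sd(seg_stats$m)
    sdnnidx <- mean(seg_stats$s)
  } else {
    sdann <- NA_real_
    sdnnidx <- NA_real_
  }

  tibble(
    mean_rr_ms = mean(rr),
    sdnn_ms = sd(rr),
    rmssd_ms = rmssd,
    pnn50_pct = pnn50,
    sdann_ms = sdann,
    sdnnidx_ms = sdnnidx,
    n_valid_beats = length(rr),
    n_segments = nrow(seg_stats)
  )
}
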