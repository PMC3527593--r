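# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive loops / direct definitions so they share no code path
# with the package implementation.

# time-domain HRV indices, straight from the definitions
oracle_time_domain <- function(series, segment_min = 5) {
  rr <- series$rr_ms
  tt <- series$beat_time_s
  ok <- series$valid
  vals <- rr[ok]
  sdnn <- sd(vals)
  diffs <- c()
  for (i in seq_len(length(rr) - 1)) {
    if (ok[i] && ok[i + 1]) diffs <- c(diffs, rr[i + 1] - rr[i])
  }
  rmssd <- if (length(diffs)) sqrt(sum(diffs^2) / length(diffs)) else NA_real_
  pnn50 <- if (length(diffs)) 100 * sum(abs(diffs) > 50) / length(diffs) else
    NA_real_
  seg_len <- segment_min * 60
  n_complete <- floor(max(tt) / seg_len)
  means <- c()
  sds <- c()
  for (k in seq_len(n_complete)) {
    in_seg <- ok & tt >= (k - 1) * seg_len & tt < k * seg_len
    if (sum(in_seg) >= 2) {
      means <- c(means, mean(rr[in_seg]))
      sds <- c(sds, sd(rr[in_seg]))
    }
  }
  list(
    mean_rr_ms = mean(vals), sdnn_ms = sdnn, rmssd_ms = rmssd,
    pnn50_pct = pnn50,
    sdann_ms = if (length(means) >= 2) sd(means) else NA_real_,
    sdnnidx_ms = if (length(sds) >= 2) mean(sds) else NA_real_
  )
}

# direct O(T^2) double-sum evaluation of the two-component model
oracle_banister_direct <- function(w, params) {
  n <- length(w)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- params$y0
    if (t > 1) {
      for (i in seq_len(t - 1)) {
        acc <- acc + params$k1 * w[i] * exp(-(t - i) / params$tau1) -
          params$k2 * w[i] * exp(-(t - i) / params$tau2)
      }
    }
    out[t] <- acc
  }
  out
}

# one-sided periodogram band power (signal units squared); bins sum to the
# population variance of x (discrete Parseval)
oracle_periodogram_band <- function(x, fs, band) {
  x <- x - mean(x)
  n <- length(x)
  pow <- Mod(fft(x))^2 / n^2
  freq <- (seq_len(n) - 1) * fs / n
  fold <- pmin(freq, fs - freq)  # map the mirrored half onto [0, fs/2]
  sum(pow[fold >= band[1] & fold < band[2]])
}

# random RR series with occasional large excursions, for property tests
random_rr_series <- function(n, seed) {
  withr::with_seed(seed, {
    rr <- 1000 + cumsum(rnorm(n, 0, 15))
    rr <- pmax(rr, 400)
    jump <- runif(n) < 0.05
    rr[jump] <- rr[jump] + sample(c(-300, 300), sum(jump), replace = TRUE)
    valid <- runif(n) > 0.03
    rr_series(rr, valid = valid)
  })
}

random_valid_params <- function(seed) {
  withr::with_seed(seed, {
    tau2 <- runif(1, 1, 15)
    tau1 <- tau2 + runif(1, 2, 80)
    k1 <- runif(1, 1e-5, 1e-2)
    k2 <- k1 * runif(1, 1.2, 30)
    banister_params(runif(1, -1, 10), k1, k2, tau1, tau2)
  })
}

table2_performance_params <- function() {
  banister_params(y0 = 1.42, k1 = 7e-5, k2 = 1.1e-3, tau1 = 50, tau2 = 4.8)
}

table2_hf_params <- function() {
  banister_params(y0 = 8.36, k1 = 0.007, k2 = 0.18, tau1 = 42, tau2 = 4.2)
}

# population used by recovery experiments: a cohort of identical athletes
# with the reference parameter means and no between-athlete spread
degenerate_population <- function() {
  pop <- default_population()
  pop$performance$sd[] <- 0
  pop$hf$sd[] <- 0
  pop
}
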