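# Maximal-overlap discrete wavelet transform (MODWT), implemented here
# because no wavelet package ships with the target environment. Only what
# the HRV band-power chain needs: per-level detail energies with an exact
# energy (Parseval) decomposition.

# Daubechies extremal-phase scaling filters, normalised so sum(g) = sqrt(2).
wavelet_scaling_filter <- function(wavelet) {
  switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    db6 = c(0.11154074335008017, 0.4946238903983854, 0.7511339080215775,
            0.3152503517092432, -0.22626469396516913, -0.12976686756709563,
            0.09750160558707936, 0.02752286553001629, -0.031582039318031156,
            0.0005538422009938016, 0.004777257511010651,
            -0.001077301084996392),
    db8 = c(0.05441584224308161, 0.3128715909144659, 0.6756307362980128,
            0.5853546836548691, -0.015829105256023893, -0.2840155429624281,
            0.00047248457399797254, 0.128747426620186, -0.01736930100202211,
            -0.04408825393106472, 0.013981027917015516, 0.008746094047015655,
            -0.00487035299301066, -0.000391740372995977, 0.0006754494059985568,
            -0.00011747678400228192),
    abort(sprintf(
      "Unknown wavelet '%s' (available: haar, db2, db4, db6, db8).", wavelet))
  )
}

# quadrature-mirror wavelet filter from a scaling filter
wavelet_qmf <- function(g) rev(g) * (-1)^(seq_along(g) - 1L)

#' Per-level MODWT energies of a signal
#'
#' Runs a maximal-overlap (undecimated) discrete wavelet transform by circular
#' FFT filtering and returns the mean squared detail coefficients per level
#' plus the final smoothing-level energy. With `boundary = "reflection"` the
#' series is extended to twice its length by reflection before the circular
#' transform, which removes wrap-around artifacts while keeping the energy
#' decomposition exact: the per-level energies plus the smooth energy sum to
#' the (population) variance-like mean square of the analysed series.
#'
#' @param x Numeric signal (will not be detrended here).
#' @param n_levels Decomposition depth J.
#' @param wavelet Wavelet name: `"haar"`, `"db2"`, `"db4"`, `"db6"` or
#'   `"db8"` (default; Daubechies extremal phase, 16 taps).
#' @param boundary `"reflection"` (default) or `"periodic"`.
#' @return A list with `detail` (length-J vector of mean squared detail
#'   coefficients, signal units squared), `smooth` (scalar smooth-level
#'   energy) and `total` (their sum, equal to `mean(x_centered^2)` of the
#'   analysed extension).
#' @examples
#' e <- modwt_energies(sin(2 * pi * 0.25 * seq(0, 150, by = 0.25)), 4)
#' sum(e$detail) + e$smooth - e$total
#' @export
modwt_energies <- function(x, n_levels, wavelet = "db8",
                           boundary = c("reflection", "periodic")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(x) || anyNA(x)) abort("`x` must be numeric with no NA.")
  g <- wavelet_scaling_filter(wavelet)
  h <- wavelet_qmf(g)
  gt <- g / sqrt(2)
  ht <- h / sqrt(2)
  if (boundary == "reflection") x <- c(x, rev(x))
  n <- length(x)
  # the level-J equivalent filter spans (2^J - 1)(L - 1) + 1 samples
  span <- (2^n_levels - 1) * (length(g) - 1) + 1
  if (n < span) {
    abort(sprintf(
      "Series too short for %d-level '%s' MODWT: need >= %d samples, have %d.",
      n_levels, wavelet, span, n))
  }
  v <- x
  detail <- numeric(n_levels)
  for (j in seq_len(n_levels)) {
    gap <- 2^(j - 1L)
    fg <- numeric(n)
    fh <- numeric(n)
    pos <- (gap * (seq_along(gt) - 1L)) %% n + 1L
    for (i in seq_along(gt)) {
      fg[pos[i]] <- fg[pos[i]] + gt[i]
      fh[pos[i]] <- fh[pos[i]] + ht[i]
    }
    fv <- fft(v)
    w <- Re(fft(fv * fft(fh), inverse = TRUE)) / n
    v <- Re(fft(fv * fft(fg), inverse = TRUE)) / n
    detail[j] <- mean(w^2)
  }
  smooth <- mean(v^2)
  list(detail = detail, smooth = smooth, total = sum(detail) + smooth)
}
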