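#' Tidy a two-component model fit
#'
#' @param x A `banister_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @method tidy banister_fit
#' @export
tidy.banister_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("y0", "k1", "k2", "tau1", "tau2"),
    estimate = c(p$y0, p$k1, p$k2, p$tau1, p$tau2)
  )
}

#' Glance at a two-component model fit
#'
#' @param x A `banister_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit-level statistics, including both R2
#'   conventions, the timing indices and optimizer diagnostics.
#' @method glance banister_fit
#' @export
glance.banister_fit <- function(x, ...) {
  tibble(
    r2 = x$r2,
    r2_cor = x$r2_cor,
    sigma = sqrt(mean(x$observations$residual^2)),
    n_obs = nrow(x$observations),
    t_n = x$timing$t_n,
    t_g = x$timing$t_g,
    timing_status = x$timing$status,
    converged = x$diagnostics$converged,
    objective = x$diagnostics$objective
  )
}

#' Augment the observations of a two-component model fit
#'
#' @param x A `banister_fit`.
#' @param ... Unused.
#' @return The observation tibble with `fitted` and `residual` columns.
#' @method augment banister_fit
#' @export
augment.banister_fit <- function(x, ...) {
  x$observations
}

#' Tidy a relationship fit
#'
#' @param x A `relationship_fit`.
#' @param ... Unused.
#' @return Tibble with intercept and slope rows.
#' @method tidy relationship_fit
#' @export
tidy.relationship_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)",
             if (x$form == "log") sprintf("log(%s)", x$x) else x$x),
    estimate = c(x$intercept, x$slope)
  )
}

#' Glance at a relationship fit
#'
#' @param x A `relationship_fit`.
#' @param ... Unused.
#' @return One-row tibble with `r2`, `r2_cor`, slope `p_value`, `n`, `form`
#'   and, for the RR-HF screen, the `saturation_flag`.
#' @method glance relationship_fit
#' @export
glance.relationship_fit <- function(x, ...) {
  out <- tibble(
    r2 = x$r2,
    r2_cor = x$r2_cor,
    p_value = x$p_value,
    n = x$n,
    form = x$form
  )
  if (!is.null(x$saturation_flag)) out$saturation_flag <- x$saturation_flag
  out
}
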