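## broom-style methods ---------------------------------------------------------

#' Tidy a two-state melting fit
#'
#' One row per thermodynamic parameter, in the formation convention.
#'
#' @param x A `g4_two_state_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `unit`.
#' @method tidy g4_two_state_fit
#' @export
tidy.g4_two_state_fit <- function(x, ...) {
  tibble(
    term = c("Tm", "dH", "dS", "minus_TdS_ref", "dG_ref"),
    estimate = c(x$Tm, x$dH, x$dS, x$minus_TdS_ref, x$dG_ref),
    unit = c("degC", "kcal/mol", "kcal/(mol K)", "kcal/mol", "kcal/mol")
  )
}

#' Glance at a two-state melting fit
#'
#' @param x A `g4_two_state_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit diagnostics: van't Hoff `r.squared`, number
#'   of in-window points, window bounds, reference temperature, ramp
#'   direction, fitting method, and the independent enthalpy estimates
#'   (`dH_vh` from the lnK regression, `dH_global` from the global signal
#'   fit, `dS_vh` from the lnK intercept).
#' @method glance g4_two_state_fit
#' @export
glance.g4_two_state_fit <- function(x, ...) {
  tibble(
    r.squared = x$r2,
    nobs = x$n_vh,
    window_lo = x$window[1],
    window_hi = x$window[2],
    T_ref = x$T_ref,
    direction = x$direction,
    method = x$method,
    dH_vh = x$dH,
    dH_global = x$dH_global,
    dS_vh = x$dS_vh
  )
}

#' @method as_tibble g4_two_state_fit
#' @export
as_tibble.g4_two_state_fit <- function(x, ...) tidy(x)
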