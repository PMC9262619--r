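## Two-state UV melting analysis ----------------------------------------------
##
## Conventions: the equilibrium constant is the unfolding ratio
## K(T) = (1 - alpha)/alpha with alpha the folded fraction,
## so ln K(T) = dH/R * (1/T - 1/Tm) with dH the *formation*
## enthalpy (negative for a folding transition). All reported dH, dS, dG are
## formation quantities; dS for table parity is dH/Tm so that dG(Tm) = 0
## holds exactly.

#' Construct / validate a melting curve
#'
#' A melting curve is a tibble with columns `temperature_C` and `absorbance`
#' plus metadata attributes: the ramp `direction` ("heating" or "cooling"),
#' the recording `wavelength_nm` and the `ramp_rate` in degrees C per minute.
#' Temperatures are normalized to increasing order; at least 20 points are
#' required so that both baselines are represented.
#'
#' @param data Data frame with columns `temperature_C` and `absorbance`.
#' @param direction Ramp direction.
#' @param wavelength_nm Detection wavelength (default 295, where quadruplex
#'   unfolding is hypochromic).
#' @param ramp_rate Ramp rate metadata, degrees C / min.
#' @return A `g4_melting_curve` tibble.
#' @export
as_melting_curve <- function(data, direction = c("heating", "cooling"),
                             wavelength_nm = 295, ramp_rate = 0.2) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(data),
            all(c("temperature_C", "absorbance") %in% names(data)))
  out <- as_tibble(data)[, c("temperature_C", "absorbance")]
  if (nrow(out) < 20L) {
    abort("a melting curve needs at least 20 points spanning both baselines",
          class = "g4_curve_error")
  }
  if (is.unsorted(out$temperature_C, strictly = TRUE)) {
    if (is.unsorted(rev(out$temperature_C), strictly = TRUE)) {
      ord <- order(out$temperature_C)
      out <- out[ord, ]
      if (anyDuplicated(out$temperature_C)) {
        abort("temperatures must be strictly monotonic",
              class = "g4_curve_error")
      }
    } else {
      out <- out[rev(seq_len(nrow(out))), ]
    }
  }
  attr(out, "direction") <- direction
  attr(out, "wavelength_nm") <- wavelength_nm
  attr(out, "ramp_rate") <- ramp_rate
  class(out) <- c("g4_melting_curve", class(out))
  out
}

curve_direction <- function(curve) attr(curve, "direction") %||% "heating"

## Baselines -------------------------------------------------------------------

#' Fit linear folded / unfolded baselines
#'
#' Least-squares lines through the low-temperature (folded) and
#' high-temperature (unfolded) regions of a melting curve, evaluable at any
#' temperature. Default regions are the lowest and highest 15% of the
#' temperature span.
#'
#' @param curve A `g4_melting_curve`.
#' @param low_region,high_region Length-2 numeric temperature intervals
#'   (degrees C); `NULL` for the defaults.
#' @param tail_fraction Fraction of the temperature span used for each
#'   default region.
#' @return A `g4_baselines` object with `folded` and `unfolded` components
#'   (each `c(intercept, slope)`).
#' @export
fit_baselines <- function(curve, low_region = NULL, high_region = NULL,
                          tail_fraction = 0.15) {
  stopifnot(inherits(curve, "g4_melting_curve"))
  Tv <- curve$temperature_C
  span <- diff(range(Tv))
  low_region <- low_region %||% c(min(Tv), min(Tv) + tail_fraction * span)
  high_region <- high_region %||% c(max(Tv) - tail_fraction * span, max(Tv))
  fit_one <- function(region, label) {
    sel <- Tv >= region[1] & Tv <= region[2]
    if (sum(sel) < 3L) {
      abort(sprintf("%s baseline region contains %d point(s); need >= 3",
                    label, sum(sel)), class = "g4_baseline_error")
    }
    if (diff(range(Tv[sel])) == 0) {
      abort(sprintf("%s baseline region is degenerate (constant temperature)",
                    label), class = "g4_baseline_error")
    }
    m <- lm(absorbance ~ temperature_C, data = curve[sel, ])
    setNames(coef(m), c("intercept", "slope"))
  }
  structure(list(folded = fit_one(low_region, "folded (low-T)"),
                 unfolded = fit_one(high_region, "unfolded (high-T)"),
                 low_region = low_region, high_region = high_region),
            class = "g4_baselines")
}

baseline_at <- function(b, temperature) b[["intercept"]] + b[["slope"]] * temperature

#' Convert a melting curve to a folded-fraction curve
#'
#' `alpha(T) = (A(T) - A_unfolded(T)) / (A_folded(T) - A_unfolded(T))`,
#' clipped to `[0, 1]`. Works whether folding raises or lowers the
#' absorbance; errors if the baselines cross inside the data range
#' (ill-conditioned denominator).
#'
#' @param curve A `g4_melting_curve`.
#' @param baselines A `g4_baselines` from [fit_baselines()] (fitted from the
#'   same curve); `NULL` fits defaults.
#' @return A `g4_fraction_curve` tibble with columns `temperature_C`, `alpha`.
#' @export
folded_fraction <- function(curve, baselines = NULL) {
  stopifnot(inherits(curve, "g4_melting_curve"))
  baselines <- baselines %||% fit_baselines(curve)
  Tv <- curve$temperature_C
  num <- curve$absorbance - baseline_at(baselines$unfolded, Tv)
  den <- baseline_at(baselines$folded, Tv) - baseline_at(baselines$unfolded, Tv)
  if (min(den) < 0 && max(den) > 0) {
    abort("folded and unfolded baselines cross inside the data range",
          class = "g4_baseline_error")
  }
  out <- tibble(temperature_C = Tv,
                alpha = pmin(pmax(num / den, 0), 1))
  attr(out, "direction") <- curve_direction(curve)
  class(out) <- c("g4_fraction_curve", class(out))
  out
}

## Tm --------------------------------------------------------------------------

#' Melting temperature from a folded-fraction curve
#'
#' Temperature at folded fraction 0.5, linearly interpolated at the crossing.
#' With `smooth = FALSE` (default) multiple crossings are treated as a
#' monotonicity violation and raise an error; `smooth = TRUE` first applies a
#' shape-preserving isotonic (monotone) regression, which leaves noiseless
#' monotone data untouched and yields a single crossing on noisy data.
#'
#' @param frac A `g4_fraction_curve`.
#' @param smooth Apply isotonic smoothing before locating the crossing.
#' @return Tm in degrees C.
#' @export
melting_temperature <- function(frac, smooth = FALSE) {
  stopifnot(inherits(frac, "g4_fraction_curve"))
  Tv <- frac$temperature_C
  a <- frac$alpha
  if (smooth) {
    a <- -isoreg(Tv, -a)$yf
  }
  s <- sign(a - 0.5)
  crossings <- which(s[-length(s)] * s[-1L] < 0 |
                       (s[-length(s)] != 0 & s[-1L] == 0))
  if (length(crossings) == 0L) {
    if (any(s == 0)) crossings <- which(s == 0)[1]
    else abort("folded fraction never crosses 0.5", class = "g4_tm_error")
  }
  cross_T <- vapply(crossings, function(i) {
    if (i == length(a) || a[i + 1L] == a[i]) return(Tv[i])
    Tv[i] + (0.5 - a[i]) * (Tv[i + 1L] - Tv[i]) / (a[i + 1L] - a[i])
  }, numeric(1))
  cross_T <- unique(round(cross_T, 10))
  if (length(cross_T) > 1L) {
    abort(sprintf(
      "folded fraction crosses 0.5 %d times (non-monotonic transition)",
      length(cross_T)), class = "g4_tm_error")
  }
  cross_T
}

## van't Hoff ------------------------------------------------------------------

#' Van't Hoff regression of a folded-fraction curve
#'
#' Regresses `ln K` on `1/T` (K in kelvin) with `K = (1 - alpha)/alpha`,
#' using only points whose folded fraction lies inside `window`, weighted by
#' `(alpha (1-alpha))^2` (inverse variance of `ln K` under absorbance noise).
#' Formation-convention parameters: `dH = slope * R`, `dS = -intercept * R`.
#' Points with fraction exactly 0 or 1 inside the window are excluded with a
#' warning.
#'
#' @param frac A `g4_fraction_curve`.
#' @param window Folded-fraction window used for the fit.
#' @param R Gas constant, kcal/(mol K).
#' @param eps Clip bound applied to `alpha` before taking logs.
#' @return List with `dH`, `dS`, `r2`, `n`, `window`.
#' @export
vant_hoff <- function(frac, window = c(0.15, 0.85), R = .Rgas, eps = 1e-6) {
  stopifnot(inherits(frac, "g4_fraction_curve"), length(window) == 2L)
  a <- frac$alpha
  inside <- a > window[1] & a < window[2]
  saturated <- inside & (a <= eps | a >= 1 - eps)
  if (any(saturated)) {
    warn(sprintf("%d point(s) with folded fraction at 0 or 1 excluded from the van't Hoff fit",
                 sum(saturated)))
    inside <- inside & !saturated
  }
  if (sum(inside) < 5L) {
    abort(sprintf("only %d point(s) inside the van't Hoff window [%g, %g]; need >= 5",
                  sum(inside), window[1], window[2]), class = "g4_vanthoff_error")
  }
  a_in <- pmin(pmax(a[inside], eps), 1 - eps)
  TK <- celsius_to_kelvin(frac$temperature_C[inside])
  df <- data.frame(lnK = log((1 - a_in) / a_in), invT = 1 / TK,
                   w = (a_in * (1 - a_in))^2)
  m <- lm(lnK ~ invT, data = df, weights = w)
  list(dH = unname(coef(m)[2]) * R,
       dS = -unname(coef(m)[1]) * R,
       r2 = summary(m)$r.squared,
       n = sum(inside),
       window = window)
}

#' Thermodynamic parameters from enthalpy and melting temperature
#'
#' Table-parity relations: `dS = dH / Tm` (Tm in kelvin), `-T_ref dS` and
#' `dG(T_ref) = dH - T_ref dS`. By construction `dG(Tm) = 0`.
#'
#' @param dH Formation enthalpy, kcal/mol.
#' @param Tm Melting temperature, degrees C.
#' @param T_ref Reference temperature, kelvin (303.15 for 30 degrees C).
#' @return List with `dS` (kcal/(mol K)), `minus_TdS_ref` and `dG_ref`
#'   (kcal/mol).
#' @examples
#' thermo_from_hm(-53.7, 44.1)$dG_ref  # about -2.4 kcal/mol
#' @export
thermo_from_hm <- function(dH, Tm, T_ref = .Tref_default) {
  TmK <- celsius_to_kelvin(Tm)
  stopifnot(TmK > 0, T_ref > 0)
  dS <- dH / TmK
  list(dS = dS, minus_TdS_ref = -T_ref * dS, dG_ref = dH - T_ref * dS)
}

## Full fit --------------------------------------------------------------------

two_state_alpha <- function(temperature_C, dH, Tm, R = .Rgas) {
  1 / (1 + exp(dH / R * (1 / celsius_to_kelvin(temperature_C) -
                           1 / celsius_to_kelvin(Tm))))
}

two_state_absorbance <- function(temperature_C, dH, Tm, f0, f1, u0, u1,
                                 R = .Rgas) {
  a <- two_state_alpha(temperature_C, dH, Tm, R)
  a * (f0 + f1 * temperature_C) + (1 - a) * (u0 + u1 * temperature_C)
}

#' Fit the two-state melting model to a curve
#'
#' The analysis follows the classic route - linear baseline extrapolation,
#' folded fraction, Tm at fraction 0.5, van't Hoff regression of `ln K` vs
#' `1/T` - with one refinement enabled by default (`method = "global"`): the
#' four baseline parameters together with (dH, Tm) are re-estimated by a
#' global Levenberg-Marquardt fit of the full two-state signal, and the
#' reported van't Hoff parameters are then computed from the folded fraction
#' implied by those refined baselines. Fixed tail-fraction baseline regions
#' (`method = "regions"`) are biased whenever the tails still contain
#' partially melted material; the global fit removes that bias and is exact
#' on noiseless two-state data.
#'
#' @param curve A `g4_melting_curve`.
#' @param low_region,high_region Baseline regions (see [fit_baselines()]).
#' @param window Van't Hoff folded-fraction window.
#' @param T_ref Reference temperature in kelvin for `dG_ref`.
#' @param method `"global"` (default) or `"regions"` (plain tail-region
#'   pipeline).
#' @return A `g4_two_state_fit`: `dH` (van't Hoff, kcal/mol), `dS` (= dH/Tm),
#'   `Tm` (degrees C), `dG_ref`, `minus_TdS_ref`, `baselines`, `r2` of the
#'   lnK regression, the fit `window`, diagnostics (`dS_vh` from the lnK
#'   intercept, global-fit `dH_global`), and the data used.
#' @export
fit_two_state <- function(curve, low_region = NULL, high_region = NULL,
                          window = c(0.15, 0.85), T_ref = .Tref_default,
                          method = c("global", "regions")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "g4_melting_curve"))
  baselines <- fit_baselines(curve, low_region, high_region)
  ## region-based initialization may be ill-conditioned (e.g. crossing
  ## baselines for a broad transition); the global fit can still recover
  frac <- tryCatch(folded_fraction(curve, baselines),
                   error = function(e) if (method == "global") NULL
                                       else stop(e))
  tm0 <- if (is.null(frac)) NA_real_ else
    tryCatch(melting_temperature(frac, smooth = TRUE),
             error = function(e) NA_real_)
  vh0 <- if (is.null(frac)) NULL else
    tryCatch(vant_hoff(frac, window), error = function(e) NULL)
  dH_global <- NA_real_
  if (method == "global") {
    start <- list(
      dH = if (!is.null(vh0)) vh0$dH else -50,
      Tm = if (!is.na(tm0)) tm0 else mean(range(curve$temperature_C)),
      f0 = baselines$folded[["intercept"]], f1 = baselines$folded[["slope"]],
      u0 = baselines$unfolded[["intercept"]], u1 = baselines$unfolded[["slope"]])
    g <- global_two_state(curve, start)
    if (!is.null(g)) {
      baselines$folded <- c(intercept = g[["f0"]], slope = g[["f1"]])
      baselines$unfolded <- c(intercept = g[["u0"]], slope = g[["u1"]])
      dH_global <- g[["dH"]]
      tm0 <- g[["Tm"]]
      frac <- folded_fraction(curve, baselines)
      vh0 <- vant_hoff(frac, window)
    }
  }
  if (is.null(frac)) frac <- folded_fraction(curve, baselines)
  if (is.null(vh0)) vh0 <- vant_hoff(frac, window)  # propagate the error
  if (is.na(tm0)) tm0 <- melting_temperature(frac, smooth = TRUE)
  if (tm0 < min(curve$temperature_C) || tm0 > max(curve$temperature_C)) {
    abort("fitted Tm lies outside the data range", class = "g4_tm_error")
  }
  th <- thermo_from_hm(vh0$dH, tm0, T_ref)
  structure(list(
    dH = vh0$dH, dS = th$dS, Tm = tm0,
    dG_ref = th$dG_ref, minus_TdS_ref = th$minus_TdS_ref,
    T_ref = T_ref, baselines = baselines, r2 = vh0$r2,
    window = window, n_vh = vh0$n,
    dS_vh = vh0$dS, dH_global = dH_global,
    direction = curve_direction(curve),
    method = method, curve = curve, fraction = frac
  ), class = "g4_two_state_fit")
}

## Global 6-parameter fit; multistart fallback over Tm when the first
## attempt fails or fits poorly. Returns named coefficients or NULL.
global_two_state <- function(curve, start) {
  d <- data.frame(T = curve$temperature_C, A = curve$absorbance)
  lo <- c(-300, min(d$T), -Inf, -Inf, -Inf, -Inf)
  hi <- c(-0.5, max(d$T), Inf, Inf, Inf, Inf)
  try_fit <- function(st) {
    st$dH <- min(max(st$dH, lo[1]), hi[1])
    st$Tm <- min(max(st$Tm, lo[2]), hi[2])
    tryCatch(
      minpack.lm::nlsLM(
        A ~ two_state_absorbance(T, dH, Tm, f0, f1, u0, u1),
        data = d, start = st, lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  best <- try_fit(start)
  rss <- function(f) sum(residuals(f)^2)
  tss <- sum((d$A - mean(d$A))^2)
  if (is.null(best) || rss(best) > 0.05 * tss) {
    for (tm0 in seq(min(d$T) + 5, max(d$T) - 5, by = 10)) {
      st <- start
      st$Tm <- tm0
      am <- two_state_alpha(d$T, st$dH, tm0)
      X <- cbind(am, am * d$T, 1 - am, (1 - am) * d$T)
      b <- tryCatch(qr.solve(X, d$A), error = function(e) NULL)
      if (!is.null(b)) {
        st$f0 <- b[1]; st$f1 <- b[2]; st$u0 <- b[3]; st$u1 <- b[4]
      }
      f <- try_fit(st)
      if (!is.null(f) && (is.null(best) || rss(f) < rss(best))) best <- f
    }
  }
  if (is.null(best)) NULL else coef(best)
}

#' @export
print.g4_two_state_fit <- function(x, ...) {
  cat(sprintf(
    "<g4_two_state_fit> (%s, %s)\n  Tm = %.2f C  dH = %.1f kcal/mol  dG(%.2f K) = %.2f kcal/mol  r2 = %.5f\n",
    x$direction, x$method, x$Tm, x$dH, x$T_ref, x$dG_ref, x$r2))
  invisible(x)
}

## Comparisons and replicates --------------------------------------------------

#' Free-energy difference between two fits
#'
#' `dG_ref(A) - dG_ref(B)` at the common reference temperature; errors if the
#' two fits used different reference temperatures. Antisymmetric in its
#' arguments.
#'
#' @param fitA,fitB `g4_two_state_fit` objects.
#' @return ddG in kcal/mol.
#' @export
delta_delta_g <- function(fitA, fitB) {
  stopifnot(inherits(fitA, "g4_two_state_fit"),
            inherits(fitB, "g4_two_state_fit"))
  if (!isTRUE(all.equal(fitA$T_ref, fitB$T_ref))) {
    abort("fits have different reference temperatures",
          class = "g4_thermo_error")
  }
  fitA$dG_ref - fitB$dG_ref
}

#' Detect melting hysteresis between heating and cooling ramps
#'
#' Compares the melting temperatures obtained from a heating and a cooling
#' curve; a difference above `threshold` flags a kinetically limited
#' (non-equilibrium) transition.
#'
#' @param heating,cooling `g4_two_state_fit` objects or `g4_melting_curve`s
#'   (fitted on the fly).
#' @param threshold Flagging threshold in degrees C.
#' @return List with `hysteresis` (logical), `delta_Tm` (heating minus
#'   cooling, degrees C) and `threshold`.
#' @export
detect_hysteresis <- function(heating, cooling, threshold = 0.5) {
  as_fit <- function(x) {
    if (inherits(x, "g4_two_state_fit")) x else fit_two_state(x)
  }
  fh <- as_fit(heating); fc <- as_fit(cooling)
  d <- fh$Tm - fc$Tm
  list(hysteresis = abs(d) > threshold, delta_Tm = d, threshold = threshold)
}

#' Replicate summary of two-state fits
#'
#' Arithmetic mean and sample standard deviation of each thermodynamic
#' parameter over independent fits. With a single fit the SD is reported as
#' `NA` (undefined), not 0.
#'
#' @param fits List of `g4_two_state_fit` objects sharing `T_ref`.
#' @return Tibble with columns `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_replicates <- function(fits) {
  if (length(fits) == 0L) {
    abort("no fits supplied", class = "g4_thermo_error")
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "g4_two_state_fit")))
  trefs <- vapply(fits, `[[`, numeric(1), "T_ref")
  if (diff(range(trefs)) > 1e-9) {
    abort("fits have different reference temperatures",
          class = "g4_thermo_error")
  }
  pars <- c("Tm", "dH", "dS", "minus_TdS_ref", "dG_ref")
  purrr::list_rbind(purrr::map(pars, function(p) {
    v <- vapply(fits, `[[`, numeric(1), p)
    tibble(parameter = p, mean = mean(v),
           sd = if (length(v) > 1L) sd(v) else NA_real_,
           n = length(v))
  }))
}

#' Fit every replicate in a long melting table
#'
#' Splits a table in the melting-curve CSV dialect (columns `temperature_C`,
#' `absorbance`, `direction`, `replicate_id`) into individual curves, fits
#' each, and returns fits plus the replicate summary. Following common
#' practice, only heating curves enter the summary by default.
#'
#' @param data Long-format data frame.
#' @param directions Ramp directions included in the summary.
#' @param ... Passed to [fit_two_state()].
#' @return List with `fits` (tibble: replicate_id, direction, fit) and
#'   `summary` (see [summarize_replicates()]).
#' @export
fit_melting_replicates <- function(data, directions = "heating", ...) {
  stopifnot(all(c("temperature_C", "absorbance", "direction",
                  "replicate_id") %in% names(data)))
  groups <- dplyr::group_split(group_by(as_tibble(data),
                                        .data$replicate_id, .data$direction))
  fits <- purrr::list_rbind(purrr::map(groups, function(g) {
    curve <- as_melting_curve(g, direction = g$direction[1])
    tibble(replicate_id = g$replicate_id[1], direction = g$direction[1],
           fit = list(fit_two_state(curve, ...)))
  }))
  keep <- fits$direction %in% directions
  list(fits = fits, summary = summarize_replicates(fits$fit[keep]))
}
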