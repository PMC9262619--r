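## Synthetic melting curves ----------------------------------------------------

#' Specification of a synthetic two-state melting experiment
#'
#' Defines the ground truth for a simulated UV melting curve: a two-state
#' transition with formation enthalpy `dH` (< 0) and melting temperature
#' `Tm`, sloping linear baselines for the folded and unfolded states,
#' i.i.d. Gaussian absorbance noise, and the temperature grid of the
#' instrument ramp (default 10-90 degrees C in 0.2-degree steps, matching a
#' 0.2 degrees C/min ramp read once per minute). `lag_tau` emulates
#' heating/cooling hysteresis phenomenologically as a temperature lag of the
#' apparent transition.
#'
#' Default baseline slopes are small and unequal so that baseline
#' extrapolation is genuinely exercised; the default noise of 0.002 a.u.
#' makes triplicate scatter comparable to typical reported uncertainties.
#'
#' @param dH Formation enthalpy, kcal/mol (negative).
#' @param Tm Melting temperature, degrees C; must lie inside the grid.
#' @param baseline_folded,baseline_unfolded `c(intercept, slope)` in a.u.
#'   and a.u./degree C.
#' @param noise_sd Gaussian noise SD, a.u.
#' @param T_start,T_stop,T_step Temperature grid, degrees C.
#' @param seed Integer seed; simulation is bit-reproducible given the spec.
#' @param lag_tau Hysteresis lag in degrees C (0 = equilibrium).
#' @param n_replicates Number of replicate curves derived from `seed`.
#' @return A `g4_sim_spec` list.
#' @export
g4_sim_spec <- function(dH = -53.7, Tm = 44.1,
                        baseline_folded = c(0.30, -5e-4),
                        baseline_unfolded = c(0.16, -1.5e-3),
                        noise_sd = 0.002,
                        T_start = 10, T_stop = 90, T_step = 0.2,
                        seed = 1L, lag_tau = 0, n_replicates = 1L) {
  stopifnot(T_step > 0, noise_sd >= 0, n_replicates >= 1L)
  if (Tm <= T_start || Tm >= T_stop) {
    abort(sprintf("Tm = %g lies outside the temperature grid [%g, %g]",
                  Tm, T_start, T_stop), class = "g4_sim_error")
  }
  structure(list(dH = dH, Tm = Tm,
                 baseline_folded = baseline_folded,
                 baseline_unfolded = baseline_unfolded,
                 noise_sd = noise_sd,
                 T_start = T_start, T_stop = T_stop, T_step = T_step,
                 seed = as.integer(seed), lag_tau = lag_tau,
                 n_replicates = as.integer(n_replicates)),
            class = "g4_sim_spec")
}

sim_grid <- function(spec) seq(spec$T_start, spec$T_stop, by = spec$T_step)

#' Simulate a melting curve
#'
#' Noiseless signal: `A(T) = alpha(T) * baseline_folded(T) +
#' (1 - alpha(T)) * baseline_unfolded(T)` with the exact two-state fraction
#' `alpha(T) = 1 / (1 + K(T))`, `K(T) = exp(dH/R (1/T - 1/Tm))` (formation
#' convention, `dS = dH/Tm`), so that `alpha(Tm) = 0.5` exactly. Gaussian
#' noise is added with a deterministic RNG stream derived from the spec seed
#' (and the replicate/direction), leaving the global RNG state untouched.
#' With a hysteresis lag the apparent transition shifts by `+lag_tau/2` on
#' heating and `-lag_tau/2` on cooling.
#'
#' @param spec A [g4_sim_spec()].
#' @param direction `"heating"` or `"cooling"` (cooling curves are recorded
#'   high-to-low temperature).
#' @param replicate Replicate index (offsets the noise seed).
#' @return A `g4_melting_curve`.
#' @examples
#' curve <- simulate_curve(g4_sim_spec(noise_sd = 0))
#' fit_two_state(curve)
#' @export
simulate_curve <- function(spec, direction = c("heating", "cooling"),
                           replicate = 1L) {
  stopifnot(inherits(spec, "g4_sim_spec"))
  direction <- match.arg(direction)
  Tv <- sim_grid(spec)
  Tm_eff <- spec$Tm + if (direction == "heating") spec$lag_tau / 2
                      else -spec$lag_tau / 2
  a <- two_state_alpha(Tv, spec$dH, Tm_eff)
  A <- a * (spec$baseline_folded[1] + spec$baseline_folded[2] * Tv) +
    (1 - a) * (spec$baseline_unfolded[1] + spec$baseline_unfolded[2] * Tv)
  if (spec$noise_sd > 0) {
    A <- A + with_local_seed(
      spec$seed + 1000L * (as.integer(replicate) - 1L) +
        (direction == "cooling"),
      rnorm(length(Tv), 0, spec$noise_sd))
  }
  df <- tibble(temperature_C = Tv, absorbance = A)
  if (direction == "cooling") df <- df[rev(seq_len(nrow(df))), ]
  as_melting_curve(df, direction = direction, ramp_rate = 0.2)
}

## evaluate expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a heating/cooling pair with optional hysteresis
#'
#' With `lag_tau = 0` the two curves share the same expected signal; a
#' positive lag shifts the apparent Tm by `+lag_tau/2` (heating) and
#' `-lag_tau/2` (cooling), giving a Tm difference of `lag_tau`.
#'
#' @param spec A [g4_sim_spec()] (set `lag_tau` for a positive control).
#' @return List with `heating` and `cooling` curves.
#' @export
simulate_hysteresis_pair <- function(spec) {
  list(heating = simulate_curve(spec, "heating"),
       cooling = simulate_curve(spec, "cooling"))
}

#' Simulate replicate melting curves
#'
#' Each replicate uses a distinct noise stream derived from the spec seed.
#'
#' @param spec A [g4_sim_spec()] with `n_replicates` set.
#' @param direction Ramp direction.
#' @return Long tibble in the melting CSV dialect (`temperature_C`,
#'   `absorbance`, `direction`, `replicate_id`).
#' @export
simulate_replicates <- function(spec, direction = "heating") {
  purrr::list_rbind(purrr::map(seq_len(spec$n_replicates), function(i) {
    curve <- simulate_curve(spec, direction, replicate = i)
    tibble(temperature_C = curve$temperature_C,
           absorbance = curve$absorbance,
           direction = direction,
           replicate_id = sprintf("rep%d", i))
  }))
}
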