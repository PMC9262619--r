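# piecewise curve with exactly flat transition-free tails, for the literal
# baseline-extrapolation operations
piecewise_curve <- function(bf = c(0.30, -5e-4), bu = c(0.16, -1.5e-3),
                            Tm = 50, width = 8) {
  Tv <- seq(10, 90, by = 0.5)
  a <- ifelse(Tv < Tm - width, 1, ifelse(Tv > Tm + width, 0,
                                         (Tm + width - Tv) / (2 * width)))
  A <- a * (bf[1] + bf[2] * Tv) + (1 - a) * (bu[1] + bu[2] * Tv)
  as_melting_curve(tibble::tibble(temperature_C = Tv, absorbance = A))
}

test_that("baseline fitting recovers known slopes on clean data", {
  cv <- piecewise_curve()
  b <- fit_baselines(cv, low_region = c(10, 40), high_region = c(60, 90))
  expect_equal(unname(b$folded), c(0.30, -5e-4), tolerance = 1e-6)
  expect_equal(unname(b$unfolded), c(0.16, -1.5e-3), tolerance = 1e-6)
})

test_that("flat baselines return the plateau absorbances", {
  cv <- piecewise_curve(bf = c(0.31, 0), bu = c(0.17, 0))
  b <- fit_baselines(cv, low_region = c(10, 40), high_region = c(60, 90))
  expect_equal(b$folded[["intercept"]], 0.31, tolerance = 1e-9)
  expect_equal(abs(b$folded[["slope"]]), 0, tolerance = 1e-9)
  expect_equal(b$unfolded[["intercept"]], 0.17, tolerance = 1e-9)
})

test_that("degenerate baseline regions raise errors", {
  cv <- piecewise_curve()
  expect_error(fit_baselines(cv, low_region = c(10, 10.6)),
               class = "g4_baseline_error")  # two points
  expect_error(fit_baselines(cv, low_region = c(-20, -10)),
               class = "g4_baseline_error")  # outside the data
})

test_that("folded fraction is exact on clean data and clipped to [0,1]", {
  cv <- piecewise_curve()
  b <- fit_baselines(cv, low_region = c(10, 40), high_region = c(60, 90))
  fr <- folded_fraction(cv, b)
  expect_true(all(fr$alpha >= 0 & fr$alpha <= 1))
  expect_equal(fr$alpha[cv$temperature_C == 90], 0, tolerance = 1e-9)
  expect_equal(fr$alpha[cv$temperature_C == 50], 0.5, tolerance = 1e-9)
  # true two-state curve: fraction from the generating baselines matches the
  # generating sigmoid to numerical precision
  spec <- g4_sim_spec(noise_sd = 0)
  cv2 <- simulate_curve(spec)
  b2 <- list(folded = c(intercept = 0.30, slope = -5e-4),
             unfolded = c(intercept = 0.16, slope = -1.5e-3))
  class(b2) <- "g4_baselines"
  fr2 <- folded_fraction(cv2, b2)
  truth <- quadfold:::two_state_alpha(fr2$temperature_C, spec$dH, spec$Tm)
  expect_equal(fr2$alpha, truth, tolerance = 1e-6)
})

test_that("crossing baselines inside the data range are rejected", {
  Tv <- seq(10, 90, by = 1)
  cv <- as_melting_curve(tibble::tibble(temperature_C = Tv,
                                        absorbance = 0.2 + 1e-3 * Tv))
  b <- list(folded = c(intercept = 0.10, slope = 2e-3),
            unfolded = c(intercept = 0.19, slope = 0))
  class(b) <- "g4_baselines"
  expect_error(folded_fraction(cv, b), class = "g4_baseline_error")
})

test_that("Tm interpolation is exact and guards against bad transitions", {
  spec <- g4_sim_spec(noise_sd = 0)
  fr <- folded_fraction(simulate_curve(spec),
                        structure(list(
                          folded = c(intercept = 0.30, slope = -5e-4),
                          unfolded = c(intercept = 0.16, slope = -1.5e-3)),
                          class = "g4_baselines"))
  expect_equal(melting_temperature(fr), 44.1, tolerance = 0.01)
  # symmetric synthetic sigmoid: Tm equals the inflection temperature
  expect_equal(melting_temperature(fr, smooth = TRUE),
               melting_temperature(fr), tolerance = 1e-9)

  flat <- fr
  flat$alpha <- rep(0.2, nrow(flat))
  expect_error(melting_temperature(flat), class = "g4_tm_error")
  wiggly <- fr
  wiggly$alpha <- 0.5 + 0.2 * sin(seq(0, 6 * pi, length.out = nrow(wiggly)))
  expect_error(melting_temperature(wiggly), class = "g4_tm_error")
})

test_that("van't Hoff regression recovers the generating enthalpy", {
  spec <- g4_sim_spec(noise_sd = 0)
  b <- structure(list(folded = c(intercept = 0.30, slope = -5e-4),
                      unfolded = c(intercept = 0.16, slope = -1.5e-3)),
                 class = "g4_baselines")
  fr <- folded_fraction(simulate_curve(spec), b)
  vh <- vant_hoff(fr)
  expect_equal(vh$dH, -53.7, tolerance = 1e-3)
  expect_equal(vh$r2, 1, tolerance = 1e-9)
  # entropy from the intercept agrees with dH/Tm for an exact two-state curve
  expect_equal(vh$dS, -53.7 / (44.1 + 273.15), tolerance = 1e-6)
  expect_error(vant_hoff(fr, window = c(0.49, 0.51)),
               class = "g4_vanthoff_error")
})

test_that("thermo relations reproduce the reported table rows", {
  for (i in seq_len(nrow(table2_expected))) {
    row <- table2_expected[i, ]
    th <- thermo_from_hm(row$dH, row$Tm, 303.15)
    expect_equal(round(th$dG_ref, 1), row$dG30, tolerance = 0.051,
                 label = sprintf("dG30 of %s", row$name))
    expect_lt(abs(th$minus_TdS_ref - row$mTdS), 0.2)
  }
  # at the melting temperature the free energy vanishes by construction
  th <- thermo_from_hm(-60, 55, 55 + 273.15)
  expect_equal(th$dG_ref, 0, tolerance = 1e-12)
})

test_that("free-energy differences are antisymmetric and guarded", {
  f1 <- fit_two_state(simulate_curve(g4_sim_spec(noise_sd = 0)))
  f2 <- fit_two_state(simulate_curve(g4_sim_spec(dH = -72.9, Tm = 61.5,
                                                 noise_sd = 0)))
  expect_equal(delta_delta_g(f2, f1), -delta_delta_g(f1, f2))
  expect_equal(delta_delta_g(f1, f1), 0)
  f3 <- fit_two_state(simulate_curve(g4_sim_spec(noise_sd = 0)),
                      T_ref = 310)
  expect_error(delta_delta_g(f1, f3), class = "g4_thermo_error")
})

test_that("every fit satisfies dG(Tm) = 0 under the dS = dH/Tm convention", {
  for (spec in list(g4_sim_spec(noise_sd = 0),
                    g4_sim_spec(dH = -71.4, Tm = 65.5),
                    g4_sim_spec(dH = -45, Tm = 38, seed = 7))) {
    f <- fit_two_state(simulate_curve(spec))
    dG_at_Tm <- f$dH - (f$Tm + 273.15) * f$dS
    expect_equal(dG_at_Tm, 0, tolerance = 1e-9)
  }
})

test_that("hysteresis detection flags only genuine lags", {
  eq <- simulate_hysteresis_pair(g4_sim_spec(noise_sd = 0))
  h0 <- detect_hysteresis(eq$heating, eq$cooling)
  expect_false(h0$hysteresis)
  expect_equal(h0$delta_Tm, 0, tolerance = 1e-6)

  lag <- simulate_hysteresis_pair(g4_sim_spec(lag_tau = 3))
  h3 <- detect_hysteresis(lag$heating, lag$cooling)
  expect_true(h3$hysteresis)
  expect_equal(h3$delta_Tm, 3, tolerance = 0.3)
  expect_false(detect_hysteresis(lag$heating, lag$cooling,
                                 threshold = 5)$hysteresis)

  noisy <- simulate_hysteresis_pair(g4_sim_spec())
  expect_false(detect_hysteresis(noisy$heating, noisy$cooling)$hysteresis)
})

test_that("replicate summaries report means, SDs and the n = 1 convention", {
  f <- fit_two_state(simulate_curve(g4_sim_spec(noise_sd = 0)))
  s3 <- summarize_replicates(list(f, f, f))
  expect_true(all(s3$sd == 0))
  expect_equal(s3$mean[s3$parameter == "Tm"], f$Tm)
  s1 <- summarize_replicates(list(f))
  expect_true(all(is.na(s1$sd)))
  expect_error(summarize_replicates(list()), class = "g4_thermo_error")

  reps <- simulate_replicates(g4_sim_spec(noise_sd = 0, n_replicates = 3))
  fr <- fit_melting_replicates(reps)
  expect_equal(fr$summary$mean[fr$summary$parameter == "dH"], -53.7,
               tolerance = 1e-3)
})

test_that("fit objects expose tidy, glance and both enthalpy estimates", {
  f <- fit_two_state(simulate_curve(g4_sim_spec(noise_sd = 0)))
  td <- tidy(f)
  expect_identical(td$term,
                   c("Tm", "dH", "dS", "minus_TdS_ref", "dG_ref"))
  expect_equal(td$estimate[td$term == "dG_ref"], -2.39, tolerance = 0.01)
  gl <- glance(f)
  expect_equal(gl$dH_vh, gl$dH_global, tolerance = 1e-6)
  expect_equal(gl$r.squared, 1, tolerance = 1e-9)
})
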