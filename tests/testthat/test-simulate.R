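test_that("the noiseless fraction is exactly one half at Tm", {
  spec <- g4_sim_spec(noise_sd = 0)
  a_tm <- quadfold:::two_state_alpha(spec$Tm, spec$dH, spec$Tm)
  expect_identical(a_tm, 0.5)
  # and monotone decreasing over the grid for a folding (dH < 0) transition
  a <- quadfold:::two_state_alpha(seq(10, 90, 0.2), spec$dH, spec$Tm)
  expect_true(all(diff(a) < 0))
})

test_that("the default grid has 401 points and rejects out-of-grid Tm", {
  cv <- simulate_curve(g4_sim_spec(noise_sd = 0))
  expect_equal(nrow(cv), 401L)
  expect_equal(range(cv$temperature_C), c(10, 90))
  expect_error(g4_sim_spec(Tm = 5), class = "g4_sim_error")
  expect_error(g4_sim_spec(Tm = 95), class = "g4_sim_error")
})

test_that("simulation is bit-reproducible and leaves the RNG alone", {
  spec <- g4_sim_spec(noise_sd = 0.002, seed = 42L)
  c1 <- simulate_curve(spec)
  c2 <- simulate_curve(spec)
  expect_identical(c1$absorbance, c2$absorbance)
  # distinct replicate and direction streams
  c3 <- simulate_curve(spec, replicate = 2L)
  expect_false(identical(c1$absorbance, c3$absorbance))
  # the simulation must not disturb an ongoing RNG stream
  set.seed(999)
  reference <- rnorm(2)
  set.seed(999)
  first <- rnorm(1)
  invisible(simulate_curve(spec))
  expect_identical(c(first, rnorm(1)), reference)
})

test_that("replicates carry distinct noise and a shared ground truth", {
  reps <- simulate_replicates(g4_sim_spec(n_replicates = 3))
  expect_setequal(unique(reps$replicate_id), c("rep1", "rep2", "rep3"))
  wide <- split(reps$absorbance, reps$replicate_id)
  expect_false(identical(wide$rep1, wide$rep2))
  expect_equal(length(wide$rep1), 401L)
})

test_that("full pipeline round-trips the generating parameters", {
  spec <- g4_sim_spec(noise_sd = 0)
  f <- fit_two_state(simulate_curve(spec))
  expect_lt(abs(f$dH - spec$dH) / abs(spec$dH), 0.001)
  expect_lt(abs(f$Tm - spec$Tm), 0.05)
})

test_that("the hysteresis lag shifts the apparent Tm symmetrically", {
  pair <- simulate_hysteresis_pair(g4_sim_spec(noise_sd = 0, lag_tau = 3))
  fh <- fit_two_state(pair$heating)
  fc <- fit_two_state(pair$cooling)
  expect_equal(fh$Tm - 44.1, 1.5, tolerance = 0.05)
  expect_equal(fc$Tm - 44.1, -1.5, tolerance = 0.05)
  # zero lag: expected curves identical
  p0 <- simulate_hysteresis_pair(g4_sim_spec(noise_sd = 0))
  expect_equal(sort(p0$heating$absorbance), sort(p0$cooling$absorbance))
})

test_that("every panel member re-parses and re-decomposes cleanly", {
  panel <- build_table1_panel()
  expect_gte(nrow(panel), 18L)
  expect_true("5'TQ" %in% panel$name)
  expect_equal(nchar(gsub("\\[BrG\\]", "B", panel$sequence[panel$name == "5'TQ"])),
               23L)
  expect_true("Q-5I-11I" %in% panel$name)
  for (i in seq_len(nrow(panel))) {
    seq <- parse_sequence(panel$sequence[i], panel$name[i],
                          first_index = panel$first_index[i])
    expect_s3_class(seq, "g4_seq")
    d <- tryCatch(decompose(seq), error = function(e) e)
    expect_s3_class(d, "g4_decomposition")
  }
})
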