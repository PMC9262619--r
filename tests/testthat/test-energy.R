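test_that("terms sum to the free-energy estimate and rules apply selectively", {
  q <- qref_seq()
  sc <- score_candidates(enumerate_candidates(q), q)
  expect_equal(purrr::map_dbl(sc$terms, function(tt) sum(tt$value)), sc$dG_est)

  pats <- purrr::map_chr(sc$column_patterns, paste, collapse = "|")
  rp <- sc[sc$descriptor == "+(lpp)" &
             pats == "syn-syn-anti|syn-anti-anti|syn-anti-anti|syn-anti-anti", ]
  ppp <- sc[sc$descriptor == "-(ppp)" & sc$n_syn == 1L, ]
  # the stacked lateral-loop 3'-adenine rewards only the hybrid fold
  expect_true("lateral3_end_purine" %in% rp$terms[[1]]$term)
  expect_false("lateral3_end_purine" %in% ppp$terms[[1]]$term)

  r1 <- sc[sc$descriptor == "+(lpp)" &
             pats == "syn-syn-syn|anti-anti-anti|anti-anti-anti|anti-anti-anti", ]
  ss <- r1$terms[[1]]
  expect_equal(ss$value[ss$term == "syn_syn_steps"],
               2 * g4_energy_model()$increments$syn_syn_step_penalty)
})

test_that("an all-zero increment model scores every candidate zero", {
  q <- qref_seq()
  zero <- do.call(g4_energy_model,
                  setNames(as.list(rep(0, 13)),
                           names(g4_energy_model()$increments)))
  sc <- score_candidates(enumerate_candidates(q), q, zero)
  expect_true(all(sc$dG_est == 0))
  expect_equal(sc$population, rep(1 / nrow(sc), nrow(sc)))
})

test_that("Boltzmann populations normalize and are shift-invariant", {
  expect_equal(boltzmann_populations(c(1, 1), T = 303.15), c(0.5, 0.5))
  dG <- c(0, 0.5, 1.0)
  p <- boltzmann_populations(dG, T = 303.15)
  expect_equal(sum(p), 1)
  expect_equal(p, oracle_boltzmann(dG, 303.15))
  expect_equal(boltzmann_populations(dG + 7.3, T = 303.15), p)
  expect_error(boltzmann_populations(numeric(0)), class = "g4_population_error")
})

test_that("population ratio factor matches the closed form", {
  expect_equal(population_ratio_factor(0, 303.15), 1)
  # about fivefold per -1 kcal/mol at 30 degrees C
  expect_equal(population_ratio_factor(-1, 303.15),
               exp(1 / (1.987e-3 * 303.15)), tolerance = 1e-12)
  expect_equal(population_ratio_factor(-0.5, 303.15),
               exp(0.5 / (1.987e-3 * 303.15)), tolerance = 1e-12)
  expect_equal(signif(population_ratio_factor(-0.5, 303.15), 3), 2.29)
})

test_that("population-derived free energies invert the ratio factor", {
  expect_equal(delta_g_from_populations(0.5, 0.5, 303.15), 0)
  # major hybrid vs parallel populations give about -0.50 kcal/mol
  expect_equal(round(delta_g_from_populations(0.62, 0.27, 303.15), 2), -0.50)
  for (ddG in c(-2, -0.37, 0.11, 1.9)) {
    r <- population_ratio_factor(ddG, 310)
    p1 <- r / (1 + r)
    expect_equal(delta_g_from_populations(p1, 1 - p1, 310), ddG,
                 tolerance = 1e-12)
  }
  expect_error(delta_g_from_populations(0, 0.5, 300),
               class = "g4_population_error")
})

test_that("energy model configuration round-trips through YAML", {
  m <- g4_energy_model(syn_syn_step_penalty = 0.77, T_ref = 298.15)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_energy_model(m, path)
  m2 <- read_energy_model(path)
  expect_equal(m2$increments, m$increments)
  expect_equal(m2$T_ref, 298.15)
  expect_error(g4_energy_model(not_a_rule = 1), class = "g4_model_error")
})

test_that("a stronger lateral-purine bonus never lowers the hybrid population", {
  q <- qref_seq()
  cands <- enumerate_candidates(q)
  pops <- purrr::map_dbl(seq(0, -3, by = -0.5), function(b) {
    sc <- score_candidates(cands, q,
                           g4_energy_model(lateral3_end_purine_bonus = b))
    sum(sc$population[sc$descriptor == "+(lpp)"])
  })
  expect_true(all(diff(pops) >= -1e-12))
})

test_that("calibrated defaults rank the observed conformer populations", {
  q <- qref_seq()
  sc <- score_candidates(enumerate_candidates(q), q)
  sc <- sc[order(sc$dG_est), ]
  pats <- purrr::map_chr(sc$column_patterns, paste, collapse = "|")
  # observed order: hybrid-1R' > parallel > hybrid-1R
  expect_identical(sc$descriptor[1:2], c("+(lpp)", "-(ppp)"))
  expect_identical(pats[1],
    "syn-syn-anti|syn-anti-anti|syn-anti-anti|syn-anti-anti")
})
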