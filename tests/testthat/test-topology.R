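test_that("Qref yields exactly the two stable intact-core topologies", {
  d <- decompose(qref_seq())
  topos <- enumerate_topologies(d, intact_only = TRUE)
  expect_setequal(topos$descriptor, c("+(lpp)", "-(ppp)"))
  expect_equal(nrow(topos), 2L)
  expect_true(all(topos$intact_tetrads == 3L))
  expect_true(all(topos$filled))
})

test_that("relaxed enumeration adds the vacancy-triad and two-layer folds", {
  topos <- enumerate_topologies(decompose(qref_seq()))
  llp <- topos[topos$descriptor == "-(llp)", ]
  expect_equal(nrow(llp), 1L)
  expect_equal(llp$intact_tetrads, 2L)
  expect_false(llp$filled)
  expect_equal(llp$n_tetrad_guanines, 11L)  # two tetrads plus a triad

  lll <- topos[topos$descriptor == "+(lll)", ]
  expect_equal(nrow(lll), 1L)
  expect_equal(lll$n_layers, 2L)
  expect_equal(lll$n_tetrad_guanines, 8L)
})

test_that("a 3-1-1 loop arrangement forces both 1-nt loops propeller", {
  d <- decompose(parse_sequence("GGCTAGGGTGGGTGGGTCAG", "Q-311-T"))
  topos <- enumerate_topologies(d, intact_only = TRUE)
  expect_setequal(topos$descriptor, c("+(lpp)", "-(ppp)"))
  kinds <- purrr::map(topos$loops, "kind")
  expect_true(all(purrr::map_chr(kinds, 2) == "p"))
  expect_true(all(purrr::map_chr(kinds, 3) == "p"))
})

test_that("unsatisfiable constraints give an empty candidate list, not an error", {
  # 3'-truncated parent: vacancy but no snapback G, so no intact core exists
  d <- decompose(parse_sequence("GGCTAGGGTCAGGGTGGGTCA", "3'delQ"))
  topos <- enumerate_topologies(d, intact_only = TRUE)
  expect_equal(nrow(topos), 0L)
})

test_that("enumeration equals brute-force assignment filtering on the panel", {
  panel <- build_table1_panel()
  for (i in seq_len(nrow(panel))) {
    seq <- parse_sequence(panel$sequence[i], panel$name[i],
                          first_index = panel$first_index[i])
    d <- tryCatch(decompose(seq), error = function(e) NULL)
    if (is.null(d)) next
    topos <- enumerate_topologies(d)
    expect_identical(topology_keys(topos),
                     oracle_keys(oracle_assignments(d$loops$length)),
                     label = sprintf("assignments for %s", panel$name[i]))
  }
})

test_that("descriptor strings round-trip through parse and format", {
  topos <- enumerate_topologies(decompose(qref_seq()))
  for (i in seq_len(nrow(topos))) {
    roles <- parse_descriptor(topos$descriptor[i])
    expect_identical(format_descriptor(roles), topos$descriptor[i])
    expect_identical(roles$kind, topos$loops[[i]]$kind)
    expect_identical(roles$sign, as.integer(sign(topos$loops[[i]]$sign)))
  }
  expect_identical(parse_descriptor("-(ppp)")$kind, c("p", "p", "p"))
  expect_identical(unique(parse_descriptor("-(ppp)")$sign), -1L)
  expect_error(parse_descriptor("+(qpp)"), class = "g4_descriptor_error")
  expect_error(parse_descriptor("lpp"), class = "g4_descriptor_error")
})

test_that("groove widths follow column directions", {
  topos <- enumerate_topologies(decompose(qref_seq()), intact_only = TRUE)
  ppp <- topos[topos$descriptor == "-(ppp)", ]
  expect_true(all(assign_grooves(ppp) == "medium"))

  lpp <- topos[topos$descriptor == "+(lpp)", ]
  loops <- lpp$loops[[1]]
  expect_identical(loops$groove[loops$kind == "l"], "narrow")
  expect_true(all(loops$groove[loops$kind == "p"] == "medium"))
  expect_identical(lpp$snapback[[1]]$groove, "wide")
  expect_setequal(assign_grooves(lpp), c("narrow", "medium", "wide"))
})

test_that("tetrad guanine counts reflect intact and partial layers", {
  topos <- enumerate_topologies(decompose(qref_seq()))
  for (i in seq_len(nrow(topos))) {
    expected <- if (!topos$filled[i] && !is.na(topos$vacancy_layer[i]) &&
                    topos$n_layers[i] == 3L) 11L else 4L * topos$intact_tetrads[i]
    expect_identical(count_tetrad_guanines(topos[i, ]), expected)
  }
  lpp <- topos[topos$descriptor == "+(lpp)", ]
  expect_identical(count_tetrad_guanines(lpp), 12L)
})
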