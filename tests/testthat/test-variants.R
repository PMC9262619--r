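intact_topology <- function(descriptor, seq = qref_seq()) {
  topos <- enumerate_topologies(decompose(seq), intact_only = TRUE)
  topos[topos$descriptor == descriptor, ]
}

test_that("the parallel snapback fold has an all-anti core with a syn fill-in", {
  vars <- enumerate_glycosidic_variants(intact_topology("-(ppp)"))
  expect_lte(nrow(vars), 4L)
  canonical <- vars[vars$n_syn == 1L, ]
  expect_equal(nrow(canonical), 1L)
  conf <- canonical$conformations[[1]]
  expect_identical(conf$conformation[conf$fill], "syn")
  expect_true(all(conf$conformation[!conf$fill] == "anti"))
  expect_true(canonical$homopolar_only)
  expect_equal(canonical$n_syn_syn_steps, 0L)
})

test_that("hybrid variants include the observed broken-column patterns", {
  vars <- enumerate_glycosidic_variants(intact_topology("+(lpp)"))
  expect_lte(nrow(vars), 4L)
  pats <- purrr::map_chr(vars$column_patterns, paste, collapse = "|")
  r_prime <- "syn-syn-anti|syn-anti-anti|syn-anti-anti|syn-anti-anti"
  r_all <- "syn-syn-syn|anti-anti-anti|anti-anti-anti|anti-anti-anti"
  expect_true(r_prime %in% pats)  # hybrid-1R': broken syn-syn-anti column
  expect_true(r_all %in% pats)    # hybrid-1R: interrupted all-syn column
})

test_that("stacking classification matches the hybrid conformers", {
  vars <- enumerate_glycosidic_variants(intact_topology("+(lpp)"))
  pats <- purrr::map_chr(vars$column_patterns, paste, collapse = "|")
  r1 <- vars[pats == "syn-syn-syn|anti-anti-anti|anti-anti-anti|anti-anti-anti", ]
  st <- classify_stacking(r1)
  expect_true(st$homopolar_only)          # hybrid-1R stacks only homopolar
  expect_equal(st$n_syn_syn_steps, 2L)    # two unfavourable syn-syn steps
  expect_length(st$step_polarity, 2L)

  rp <- vars[pats == "syn-syn-anti|syn-anti-anti|syn-anti-anti|syn-anti-anti", ]
  stp <- classify_stacking(rp)
  expect_false(stp$homopolar_only)        # hybrid-1R' has one heteropolar step
  expect_equal(sum(stp$step_polarity == "heteropolar"), 1L)
  expect_equal(stp$n_syn_syn_steps, 1L)

  all_anti <- enumerate_glycosidic_variants(intact_topology("-(ppp)"))
  canon <- all_anti[all_anti$n_syn == 1L, ]
  expect_equal(classify_stacking(canon)$n_syn_syn_steps, 0L)
})

test_that("variants are canonical under the global polarity flip", {
  for (desc in c("+(lpp)", "-(ppp)")) {
    vars <- enumerate_glycosidic_variants(intact_topology(desc))
    # no more syn than anti after canonicalization
    n_core <- nrow(vars$conformations[[1]])
    expect_true(all(vars$n_syn <= n_core / 2))
    # flipping every polarity is a no-op after canonicalization: the set of
    # conformation signatures is duplicate-free and of at most 2^(layers-1)
    sigs <- purrr::map_chr(vars$conformations, function(cc)
      paste(cc$conformation, collapse = ""))
    expect_identical(anyDuplicated(sigs), 0L)
    expect_lte(nrow(vars), 4L)
  }
})

test_that("the three observed Qref conformers appear in the candidate set", {
  cands <- enumerate_candidates(qref_seq(), intact_only = TRUE)
  pats <- purrr::map_chr(cands$column_patterns, paste, collapse = "|")
  found <- function(desc, pat) any(cands$descriptor == desc & pats == pat)
  expect_true(found("-(ppp)",
    "anti-anti-syn|anti-anti-anti|anti-anti-anti|anti-anti-anti"))
  expect_true(found("+(lpp)",
    "syn-syn-anti|syn-anti-anti|syn-anti-anti|syn-anti-anti"))
  expect_true(found("+(lpp)",
    "syn-syn-syn|anti-anti-anti|anti-anti-anti|anti-anti-anti"))
})
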