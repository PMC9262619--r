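## Additive stability model ----------------------------------------------------

#' Rule-based free-energy model for competing quadruplex folds
#'
#' An additive increment model scoring (topology, glycosidic variant)
#' candidates of one sequence relative to each other. Scores are *relative*
#' free energies in kcal/mol, not absolute folding energies; an intercept
#' absorbs the common baseline. Increments (all configurable, kcal/mol):
#'
#' * `syn_syn_step_penalty` - per stacked syn,syn pair within a G-column
#'   (poor base stacking along such steps).
#' * `anti_syn_step_penalty` - per 5'-anti-syn-3' step within a G-tract
#'   (syn guanines populate the 5'-end of tracts; an anti-to-syn transition
#'   along a tract is essentially never observed). The snapback fill-in
#'   residue, which genuinely adopts syn at a 3'-terminal position, is
#'   exempt.
#' * `heteropolar_interface_penalty` - per tetrad-tetrad interface of opposite
#'   polarity.
#' * `missing_tetrad_penalty` - per missing or incomplete tetrad layer
#'   (dominates vacancy-triad and two-layer folds).
#' * `central_1nt_homopolar_bonus` / `central_1nt_heteropolar_bonus` -
#'   stabilization conferred by a central single-nucleotide propeller loop,
#'   larger when it links outer tetrads of the same polarity. Defaults -4.5
#'   and -3.2 are the measured loop-shortening free energies for the
#'   homopolar (parallel / hybrid-1R) and heteropolar (hybrid-1R') folds.
#' * `lateral3_end_purine_bonus` - stacking of a purine at the last position
#'   of a 3-nt lateral loop bridging a narrow groove onto the outer tetrad.
#' * `first_position_purine_penalty` / `first_position_abasic_bonus` -
#'   hydrophobic cost of a solvent-exposed purine (or gain of an abasic
#'   site) at the first position of any loop.
#' * `brg_anti_penalty` - steric cost of holding a syn-favouring 8-bromo-dG
#'   in an anti conformation at a tetrad position.
#' * `overhang5_fill_clash_penalty` - clash of a 5'-flanking residue with a
#'   snapback fill-in guanine on the 5' face of the broken column.
#' * `snapback_cap_bonus` - capping of the snapback loop over the outer
#'   tetrad (common to filled folds; default 0).
#'
#' @param R Gas constant, kcal/(mol K).
#' @param T_ref Reference temperature in kelvin (303.15 K, i.e. 30 degrees C).
#' @param ... Named increment overrides.
#' @return An object of class `g4_energy_model`.
#' @export
g4_energy_model <- function(R = 1.987e-3, T_ref = 303.15, ...) {
  increments <- list(
    syn_syn_step_penalty = 1.0,
    anti_syn_step_penalty = 1.0,
    heteropolar_interface_penalty = 0.3,
    missing_tetrad_penalty = 3.0,
    central_1nt_homopolar_bonus = -4.5,
    central_1nt_heteropolar_bonus = -3.2,
    lateral3_end_purine_bonus = -1.8,
    first_position_purine_penalty = 0.3,
    first_position_abasic_bonus = -0.2,
    brg_anti_penalty = 2.0,
    overhang5_fill_clash_penalty = 2.0,
    snapback_cap_bonus = 0,
    intercept = 0
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(increments))
  if (length(unknown)) {
    abort(sprintf("unknown increment(s): %s", paste(unknown, collapse = ", ")),
          class = "g4_model_error")
  }
  increments[names(dots)] <- dots
  stopifnot(R > 0, T_ref > 0, all(is.finite(unlist(increments))))
  structure(list(R = R, T_ref = T_ref, increments = increments),
            class = "g4_energy_model")
}

#' @export
print.g4_energy_model <- function(x, ...) {
  cat(sprintf("<g4_energy_model> R = %g kcal/(mol K), T_ref = %g K\n",
              x$R, x$T_ref))
  inc <- unlist(x$increments)
  cat(paste(sprintf("  %-32s %+.2f", names(inc), inc), collapse = "\n"), "\n")
  invisible(x)
}

#' Read / write an energy model configuration
#'
#' The configuration is a YAML mapping with optional keys `R`, `T_ref` and an
#' `increments` mapping (all values in kcal/mol).
#'
#' @param path File path.
#' @return [read_energy_model()] returns a `g4_energy_model`.
#' @export
read_energy_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- c(cfg[intersect(names(cfg), c("R", "T_ref"))],
            cfg$increments %||% list())
  do.call(g4_energy_model, args)
}

#' @rdname read_energy_model
#' @param model A `g4_energy_model`.
#' @export
write_energy_model <- function(model, path) {
  stopifnot(inherits(model, "g4_energy_model"))
  yaml::write_yaml(list(R = model$R, T_ref = model$T_ref,
                        increments = model$increments), path)
  invisible(path)
}

## Scoring ---------------------------------------------------------------------

#' Score (topology, variant) candidates of a sequence
#'
#' Applies every matching rule of the energy model to each candidate row and
#' sums the increments into a relative free-energy estimate `dG_est`; every
#' applied rule appears as a named term. Boltzmann populations over the
#' candidate set at `model$T_ref` are appended.
#'
#' @param candidates Output of [enumerate_candidates()].
#' @param seq The `g4_seq` the candidates were enumerated from.
#' @param model A [g4_energy_model()].
#' @return The candidate tibble with list-column `terms` (tibble of term,
#'   value), `dG_est` and `population` columns, classed `g4_scores`.
#' @examples
#' qref <- parse_sequence("GGCTAGGGTCAGGGTGGGTCAG", "Qref")
#' sc <- score_candidates(enumerate_candidates(qref), qref)
#' sc[, c("descriptor", "dG_est", "population")]
#' @export
score_candidates <- function(candidates, seq, model = g4_energy_model()) {
  stopifnot(is.data.frame(candidates), inherits(seq, "g4_seq"),
            inherits(model, "g4_energy_model"))
  if (nrow(candidates) == 0L) return(candidates)
  check_candidate_seq(candidates, seq)
  scored <- purrr::list_rbind(
    purrr::map(seq_len(nrow(candidates)),
               function(i) score_one(candidates[i, ], seq, model)))
  out <- cbind_tbl(candidates, scored)
  out$population <- boltzmann_populations(out$dG_est, T = model$T_ref,
                                          R = model$R)
  class(out) <- c("g4_scores", setdiff(class(out), "g4_scores"))
  out
}

check_candidate_seq <- function(candidates, seq) {
  pos <- positions(seq)
  core_pos <- unlist(purrr::map(candidates$core, "position"))
  if (!all(core_pos %in% pos)) {
    abort("candidate core positions do not match the sequence",
          class = "g4_consistency_error")
  }
}

score_one <- function(cand, seq, model) {
  inc <- model$increments
  pos <- positions(seq)
  code_at <- function(p) seq$codes[match(p, pos)]
  loops <- cand$loops[[1]]
  conf <- cand$conformations[[1]]
  target <- cand$target_layers
  terms <- c(intercept = inc$intercept)
  add <- function(terms, name, value) {
    if (value != 0) terms[[name]] <- value
    terms
  }

  terms <- add(terms, "missing_tetrads",
               inc$missing_tetrad_penalty * (target - cand$intact_tetrads))
  terms <- add(terms, "syn_syn_steps",
               inc$syn_syn_step_penalty * cand$n_syn_syn_steps)
  terms <- add(terms, "anti_syn_steps",
               inc$anti_syn_step_penalty * count_anti_syn_steps(conf))
  terms <- add(terms, "heteropolar_interfaces",
               inc$heteropolar_interface_penalty * cand$n_heteropolar)

  ## central single-nucleotide propeller loop (middle of three inter-tract
  ## loops, spanning all layers across a medium groove in either topology)
  central <- 2L
  if (nrow(loops) == 3L &&
      loops$length[central] == 1L && loops$kind[central] == "p") {
    bonus <- if (cand$homopolar_only) inc$central_1nt_homopolar_bonus
             else inc$central_1nt_heteropolar_bonus
    terms <- add(terms, "central_1nt_loop", bonus)
  }

  ## 3'-terminal purine of a 3-nt lateral loop across a narrow groove
  n_lat3 <- sum(loops$kind == "l" & loops$length == 3L &
                  loops$groove %in% "narrow" &
                  is_purine_code(code_at(loops$end)))
  terms <- add(terms, "lateral3_end_purine",
               inc$lateral3_end_purine_bonus * n_lat3)

  ## first-position composition of every loop (snapback included)
  first_codes <- code_at(loops$start)
  snap <- cand$snapback[[1]]
  if (!is.null(snap) && !is.null(cand$core)) {
    dec_snap_first <- snapback_first_position(cand, seq)
    if (!is.na(dec_snap_first)) first_codes <- c(first_codes, dec_snap_first)
  }
  terms <- add(terms, "first_position_purine",
               inc$first_position_purine_penalty *
                 sum(is_purine_code(first_codes)))
  terms <- add(terms, "first_position_abasic",
               inc$first_position_abasic_bonus * sum(first_codes == "X"))

  ## syn-affine 8-bromo-dG locked anti at a tetrad position
  brg_anti <- sum(code_at(conf$position) == "BrG" & conf$conformation == "anti")
  terms <- add(terms, "brg_anti", inc$brg_anti_penalty * brg_anti)

  ## 5'-flanking residue clashing with a fill-in G on the 5' face of the
  ## broken column
  tract1_pos <- conf$position[conf$column == 1L & !conf$fill]
  has_overhang5 <- min(pos) < min(tract1_pos)
  if (has_overhang5 && isTRUE(cand$filled)) {
    tract1_layers <- conf$layer[conf$column == 1L & !conf$fill]
    fill_layer <- conf$layer[conf$fill]
    if (length(fill_layer) && fill_layer < min(tract1_layers)) {
      terms <- add(terms, "overhang5_fill_clash",
                   inc$overhang5_fill_clash_penalty)
    }
  }

  if (isTRUE(cand$filled)) {
    terms <- add(terms, "snapback_cap", inc$snapback_cap_bonus)
  }

  values <- unlist(terms)
  tibble(terms = list(tibble(term = names(values), value = unname(values))),
         dG_est = sum(values))
}

## 5'->3' anti->syn steps within tract residues of each column (fill exempt)
count_anti_syn_steps <- function(conf) {
  conf <- conf[!conf$fill, ]
  sum(vapply(unique(conf$column), function(k) {
    cc <- conf[conf$column == k, ]
    cc <- cc[order(cc$position), ]
    if (nrow(cc) < 2L) return(0L)
    sum(cc$conformation[-nrow(cc)] == "anti" & cc$conformation[-1L] == "syn")
  }, integer(1)))
}

snapback_first_position <- function(cand, seq) {
  snap <- cand$snapback[[1]]
  if (is.null(snap)) return(NA_character_)
  fill_pos <- cand$core[[1]]$position[cand$core[[1]]$fill]
  ## first residue of the snapback segment = residue after the last tract G
  core_tracts <- cand$core[[1]]$position[!cand$core[[1]]$fill]
  first <- max(core_tracts) + 1L
  pos <- positions(seq)
  if (first %in% pos && !(first %in% fill_pos)) seq$codes[match(first, pos)]
  else NA_character_
}

## Populations -----------------------------------------------------------------

#' Boltzmann populations of competing candidates
#'
#' `p_i` proportional to `exp(-dG_i / RT)`, normalized over the set; invariant
#' under adding a constant to every `dG`.
#'
#' @param dG Numeric vector of relative free energies (kcal/mol).
#' @param T Temperature in kelvin.
#' @param R Gas constant, kcal/(mol K).
#' @return Numeric vector of fractions summing to 1.
#' @export
boltzmann_populations <- function(dG, T = .Tref_default, R = .Rgas) {
  if (length(dG) == 0L) {
    abort("empty candidate set", class = "g4_population_error")
  }
  stopifnot(T > 0)
  w <- exp(-(dG - min(dG)) / (R * T))
  w / sum(w)
}

#' Population-ratio change implied by a free-energy difference
#'
#' `exp(-ddG / RT)`: a stabilization of about -1 kcal/mol at 30 degrees C
#' corresponds to roughly a fivefold increase of a population ratio.
#'
#' @param ddG Free-energy difference, kcal/mol.
#' @param T Temperature in kelvin.
#' @param model Optional [g4_energy_model()] supplying `R` (and `T` when not
#'   given explicitly).
#' @return Fold change (dimensionless).
#' @examples
#' population_ratio_factor(-1, 303.15)
#' @export
population_ratio_factor <- function(ddG, T = NULL, model = NULL) {
  R <- if (!is.null(model)) model$R else .Rgas
  T <- T %||% if (!is.null(model)) model$T_ref else .Tref_default
  stopifnot(T > 0)
  exp(-ddG / (R * T))
}

#' Free-energy difference implied by two populations
#'
#' `-RT ln(p_i / p_j)`; exact inverse of [population_ratio_factor()].
#'
#' @param p_i,p_j Population fractions in (0, 1).
#' @inheritParams population_ratio_factor
#' @return Free-energy difference in kcal/mol (negative when `p_i > p_j`).
#' @export
delta_g_from_populations <- function(p_i, p_j, T = NULL, model = NULL) {
  if (any(c(p_i, p_j) <= 0) || any(c(p_i, p_j) >= 1)) {
    abort("populations must lie strictly between 0 and 1",
          class = "g4_population_error")
  }
  R <- if (!is.null(model)) model$R else .Rgas
  T <- T %||% if (!is.null(model)) model$T_ref else .Tref_default
  -R * T * log(p_i / p_j)
}

#' Predict the major topology of G-rich sequences
#'
#' Full pipeline per sequence: parse, decompose, enumerate (topology x
#' variant) candidates, score with the energy model and report the descriptor
#' of the lowest-energy candidate together with its Boltzmann population.
#'
#' @param sequences A `g4_seq`, or a data frame with columns `name` and
#'   `sequence` (e.g. [g4_reference_panel()]).
#' @param model A [g4_energy_model()].
#' @param constraints See [g4_constraints()].
#' @return Tibble: `name`, `major_topology`, `major_population`, `n_candidates`.
#' @export
predict_major_topology <- function(sequences, model = g4_energy_model(),
                                   constraints = g4_constraints()) {
  if (inherits(sequences, "g4_seq")) {
    sequences <- tibble(name = sequences$name,
                        sequence = as.character(sequences),
                        .seq = list(sequences))
  } else {
    stopifnot(all(c("name", "sequence") %in% names(sequences)))
    sequences <- as_tibble(sequences)
    fi <- if ("first_index" %in% names(sequences)) sequences$first_index
          else rep(1L, nrow(sequences))
    fi[is.na(fi)] <- 1L
    sequences$.seq <- purrr::pmap(
      list(sequences$sequence, sequences$name, fi),
      function(s, n, f) parse_sequence(s, n, first_index = as.integer(f)))
  }
  purrr::list_rbind(purrr::map(sequences$.seq, function(sq) {
    sc <- score_candidates(enumerate_candidates(sq, constraints), sq, model)
    best <- sc[which.min(sc$dG_est), ]
    tibble(name = sq$name,
           major_topology = best$descriptor,
           major_population = best$population,
           n_candidates = nrow(sc))
  }))
}
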