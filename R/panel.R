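## Reference sequence panel ----------------------------------------------------

qref_string <- function() "GGCTAGGGTCAGGGTGGGTCAG"
q311_string <- function() "GGCTAGGGTGGGTGGGTCAG"

#' Substitution ledger for the reference mutant panel
#'
#' Single and double substitutions applied to the parent snapback sequence
#' Qref (and to its short-central-loop derivative Q-311-T) to generate the
#' study panel. Bromo substitutions place the syn-favouring 8-bromo-dG at
#' tetrad positions; I/X/T substitutions probe loop residues.
#'
#' @return Long tibble, one substitution per row: `name`, `parent`,
#'   `position`, `code`.
#' @export
g4_mutation_ledger <- function() {
  tibble::tribble(
    ~name,            ~parent,   ~position, ~code,
    "2BrQ",           "Qref",     2L, "BrG",
    "6BrQ",           "Qref",     6L, "BrG",
    "7BrQ",           "Qref",     7L, "BrG",
    "8BrQ",           "Qref",     8L, "BrG",
    "16BrQ",          "Qref",    16L, "BrG",
    "Q-5T",           "Qref",     5L, "T",
    "Q-5I",           "Qref",     5L, "I",
    "Q-5X",           "Qref",     5L, "X",
    "Q-11T",          "Qref",    11L, "T",
    "Q-11I",          "Qref",    11L, "I",
    "Q-11X",          "Qref",    11L, "X",
    "Q-5I-11I",       "Qref",     5L, "I",
    "Q-5I-11I",       "Qref",    11L, "I",
    "Q-3T-10T",       "Qref",     3L, "T",
    "Q-3T-10T",       "Qref",    10L, "T",
    "Q-3A",           "Qref",     3L, "A",
    "Q-3X",           "Qref",     3L, "X",
    "2BrQ-311-T",     "Q-311-T",  2L, "BrG",
    "6BrQ-311-T",     "Q-311-T",  6L, "BrG",
    "10BrQ-311-T",    "Q-311-T", 10L, "BrG",
    "14BrQ-311-T",    "Q-311-T", 14L, "BrG",
    "6,10BrQ-311-T",  "Q-311-T",  6L, "BrG",
    "6,10BrQ-311-T",  "Q-311-T", 10L, "BrG",
    "10BrQ-311-X",    "Q-311-T", 10L, "BrG",
    "10BrQ-311-X",    "Q-311-T",  9L, "X"
  )
}

apply_ledger_row <- function(parent_seq, positions, codes, name) {
  out <- parent_seq
  for (i in seq_along(positions)) {
    out <- apply_substitution(out, positions[i], codes[i])
  }
  out$name <- name
  out
}

#' Build the reference sequence panel
#'
#' Generates the complete study panel programmatically from the parent
#' sequences and the substitution ledger: the snapback parent Qref with its
#' 3-3-1 loop arrangement, every single/double mutant, the 5'-T flanked and
#' 3'-truncated variants, and the Q-311-T family in which the central 3-nt
#' loop is shortened to a single T. `major_topology` carries the
#' experimentally assigned predominant fold where one was resolved
#' (`NA` where the spectra were too heterogeneous).
#'
#' @param include_311 Include the short-central-loop (3-1-1) family.
#' @return Tibble: `name`, `sequence` (bracketed string), `first_index`,
#'   `major_topology`, `family`.
#' @examples
#' panel <- build_table1_panel()
#' table(panel$major_topology, useNA = "ifany")
#' @export
build_table1_panel <- function(include_311 = TRUE) {
  qref <- parse_sequence(qref_string(), "Qref")
  q311 <- parse_sequence(q311_string(), "Q-311-T")
  parents <- list(Qref = qref, `Q-311-T` = q311)

  ledger <- g4_mutation_ledger()
  seqs <- list(
    Qref = qref,
    `3'delQ` = g4_trim3(qref, label = "3'delQ"),
    `5'TQ` = g4_add_overhang5(qref, "T", label = "5'TQ", minus_one = TRUE)
  )
  for (nm in unique(ledger$name)) {
    rows <- ledger[ledger$name == nm, ]
    seqs[[nm]] <- apply_ledger_row(parents[[rows$parent[1]]],
                                   rows$position, rows$code, nm)
  }
  seqs[["Q-311-T"]] <- q311
  seqs[["5'TQ-311-T"]] <- g4_add_overhang5(q311, "T", label = "5'TQ-311-T",
                                           minus_one = TRUE)

  major <- c(
    Qref = "+(lpp)", `3'delQ` = NA, `2BrQ` = "+(lpp)", `6BrQ` = "+(lpp)",
    `7BrQ` = NA, `8BrQ` = NA, `16BrQ` = "+(lpp)", `5'TQ` = "-(ppp)",
    `Q-5T` = "-(ppp)", `Q-5I` = "+(lpp)", `Q-5X` = "-(ppp)",
    `Q-11T` = "+(lpp)", `Q-11I` = "+(lpp)", `Q-11X` = "+(lpp)",
    `Q-5I-11I` = "+(lpp)", `Q-3T-10T` = "+(lpp)", `Q-3A` = "+(lpp)",
    `Q-3X` = "+(lpp)",
    `Q-311-T` = "-(ppp)", `5'TQ-311-T` = "-(ppp)", `2BrQ-311-T` = "+(lpp)",
    `6BrQ-311-T` = NA, `10BrQ-311-T` = "+(lpp)", `14BrQ-311-T` = "+(lpp)",
    `6,10BrQ-311-T` = "+(lpp)", `10BrQ-311-X` = "+(lpp)")

  order_names <- c("Qref", "3'delQ", "2BrQ", "6BrQ", "7BrQ", "8BrQ", "16BrQ",
                   "5'TQ", "Q-5T", "Q-5I", "Q-5X", "Q-11T", "Q-11I", "Q-11X",
                   "Q-5I-11I", "Q-3T-10T", "Q-3A", "Q-3X",
                   "Q-311-T", "5'TQ-311-T", "2BrQ-311-T", "6BrQ-311-T",
                   "10BrQ-311-T", "14BrQ-311-T", "6,10BrQ-311-T",
                   "10BrQ-311-X")
  fam <- ifelse(grepl("311", order_names), "loop311", "core")
  out <- tibble(
    name = order_names,
    sequence = purrr::map_chr(order_names, function(n) as.character(seqs[[n]])),
    first_index = purrr::map_int(order_names, function(n) seqs[[n]]$first_index),
    major_topology = unname(major[order_names]),
    family = fam
  )
  if (!include_311) out <- dplyr::filter(out, .data$family == "core")
  out
}

#' @rdname build_table1_panel
#' @export
g4_reference_panel <- build_table1_panel

#' Published thermodynamic parameters for loop-shortening pairs
#'
#' The reported two-state melting parameters (mean over triplicate UV
#' melting experiments at 295 nm) for the three pairs of 3-3-1 vs 3-1-1
#' quadruplexes locked into a single conformer: the parallel fold (5'-T
#' flanked), the heteropolar hybrid-1R' (BrG following the 3-nt loop) and
#' the homopolar hybrid-1R (BrG at position 2). These printed values serve
#' as inputs for consistency checks of the thermodynamic relations.
#'
#' @return Tibble: `name`, `conformer`, `pair`, `loop_arrangement`,
#'   `Tm_C`, `dH_kcal_mol`, `minus_TdS30_kcal_mol`, `dG30_kcal_mol`,
#'   `ddG30_kcal_mol`.
#' @export
g4_published_thermo <- function() {
  tibble::tribble(
    ~name,            ~conformer,   ~pair, ~loop_arrangement, ~Tm_C, ~dH_kcal_mol, ~minus_TdS30_kcal_mol, ~dG30_kcal_mol, ~ddG30_kcal_mol,
    "5'TQ",           "parallel",    "A",  "3-3-1",  44.1, -53.7, 51.3, -2.4,  0,
    "5'TQ-311-T",     "parallel",    "A",  "3-1-1",  61.5, -72.9, 65.9, -6.9, -4.5,
    "16BrQ",          "hybrid-1R'",  "B",  "3-3-1",  49.3, -53.2, 50.0, -3.2,  0,
    "14BrQ-311-T",    "hybrid-1R'",  "B",  "3-1-1",  59.2, -72.3, 65.9, -6.4, -3.2,
    "2BrQ",           "hybrid-1R",   "C",  "3-3-1",  47.7, -53.9, 50.9, -3.0,  0,
    "2BrQ-311-T",     "hybrid-1R",   "C",  "3-1-1",  65.5, -71.4, 63.8, -7.5, -4.5
  )
}
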