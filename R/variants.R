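## Glycosidic variants and stacking polarity -----------------------------------
##
## Each tetrad layer carries a polarity: the rotational direction of its
## Hoogsteen donor progression around the four corners, "cw" or "ccw" viewed
## from the 5' face. The glycosidic conformation of a core guanine follows
## from its strand direction and the polarity of its layer: anti when the two
## agree, syn when they oppose. A snapback fill-in residue enters with
## reversed strand direction after folding back around a face, which is what
## makes it syn in an otherwise all-anti parallel fold.

polarity_dir <- function(pol) ifelse(pol == "cw", 1L, -1L)

conformation_of <- function(direction, pol) {
  ifelse(direction == polarity_dir(pol), "anti", "syn")
}

#' Enumerate glycosidic (syn/anti) variants of a topology
#'
#' Assigns a polarity to each tetrad layer (all `2^n_layers` combinations),
#' derives the per-residue syn/anti conformations, and canonicalizes under the
#' global flip symmetry (reversing every polarity swaps syn and anti
#' everywhere): the canonical form has no more syn than anti residues, ties
#' broken by lexicographic column-pattern order. Duplicates are removed, so a
#' three-layer topology yields at most four variants.
#'
#' @param topo One-row `g4_topologies` candidate.
#' @return A `g4_variants` tibble: polarities, residue conformations,
#'   column patterns, syn-syn step count and per-interface stacking polarity.
#' @export
enumerate_glycosidic_variants <- function(topo) {
  stopifnot(is.data.frame(topo), nrow(topo) == 1L)
  core <- topo$core[[1]]
  n_layers <- topo$n_layers
  grid <- expand.grid(rep(list(c("cw", "ccw")), n_layers),
                      stringsAsFactors = FALSE)
  seen <- character(0)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    pol <- unlist(grid[i, ], use.names = FALSE)
    v <- canonical_variant(core, pol)
    key <- paste(v$conf$conformation, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    rows[[length(rows) + 1L]] <- variant_row(topo, v)
  }
  out <- purrr::list_rbind(rows) |>
    mutate(variant_id = row_number()) |>
    select("variant_id", dplyr::everything())
  class(out) <- c("g4_variants", class(out))
  out
}

flip_polarity <- function(pol) ifelse(pol == "cw", "ccw", "cw")

variant_conformations <- function(core, pol) {
  mutate(core, conformation = conformation_of(.data$direction,
                                              pol[.data$layer]))
}

## apply the global flip symmetry; returns list(pol, conf, patterns)
canonical_variant <- function(core, pol) {
  a <- variant_conformations(core, pol)
  b <- variant_conformations(core, flip_polarity(pol))
  pa <- column_patterns(a); pb <- column_patterns(b)
  na_syn <- sum(a$conformation == "syn"); nb_syn <- sum(b$conformation == "syn")
  pick_a <- if (na_syn != nb_syn) na_syn < nb_syn
            else paste(pa, collapse = "|") <= paste(pb, collapse = "|")
  if (pick_a) list(pol = pol, conf = a, patterns = pa)
  else list(pol = flip_polarity(pol), conf = b, patterns = pb)
}

## Per-column conformation strings in stack-contiguous 5'->3' order: the
## fill-in residue of a broken column sits at whichever end of the stack it
## occupies (so the broken column of a hybrid snapback fold reads e.g.
## "syn-syn-anti" starting from the fill).
column_patterns <- function(conf) {
  vapply(sort(unique(conf$column)), function(k) {
    cc <- conf[conf$column == k, ]
    cc <- cc[order(cc$layer), ]
    if (nrow(cc) > 1L && any(cc$fill)) {
      ## orient so the tract residues read 5'->3'
      if (cc$direction[!cc$fill][1] == -1L) cc <- cc[rev(seq_len(nrow(cc))), ]
    } else if (cc$direction[1] == -1L) {
      cc <- cc[rev(seq_len(nrow(cc))), ]
    }
    paste(cc$conformation, collapse = "-")
  }, character(1))
}

count_syn_syn_steps <- function(conf) {
  sum(vapply(unique(conf$column), function(k) {
    cc <- conf[conf$column == k, ]
    cc <- cc[order(cc$layer), ]
    if (nrow(cc) < 2L) return(0L)
    sum(cc$conformation[-nrow(cc)] == "syn" & cc$conformation[-1L] == "syn")
  }, integer(1)))
}

interface_polarities <- function(pol) {
  if (length(pol) < 2L) return(character(0))
  ifelse(pol[-length(pol)] == pol[-1L], "homopolar", "heteropolar")
}

variant_row <- function(topo, v) {
  ifaces <- interface_polarities(v$pol)
  n_het <- sum(ifaces == "heteropolar")
  hom_only <- all(ifaces == "homopolar")
  tibble(
    descriptor = topo$descriptor,
    polarities = list(unname(v$pol)),
    conformations = list(select(v$conf, "position", "column", "layer",
                                "fill", "conformation")),
    column_patterns = list(v$patterns),
    n_syn = sum(v$conf$conformation == "syn"),
    n_syn_syn_steps = count_syn_syn_steps(v$conf),
    interfaces = list(ifaces),
    n_heteropolar = n_het,
    homopolar_only = hom_only
  )
}

#' Classify tetrad stacking of a glycosidic variant
#'
#' Recomputes, from a variant's conformations and layer polarities, the
#' polarity of every tetrad-tetrad interface (homopolar when adjacent layers
#' share a donor direction), the number of syn-syn steps within G-columns,
#' and whether the stack is exclusively homopolar.
#'
#' @param variant One-row `g4_variants` tibble.
#' @return List with `step_polarity` (per interface), `n_syn_syn_steps` and
#'   `homopolar_only`.
#' @export
classify_stacking <- function(variant) {
  stopifnot(is.data.frame(variant), nrow(variant) == 1L)
  pol <- variant$polarities[[1]]
  conf <- variant$conformations[[1]]
  interfaces <- interface_polarities(pol)
  list(
    step_polarity = interfaces,
    n_syn_syn_steps = count_syn_syn_steps(conf),
    homopolar_only = all(interfaces == "homopolar")
  )
}

#' Enumerate (topology x glycosidic variant) candidates
#'
#' Convenience wrapper: enumerate topologies for a decomposition (or a
#' sequence, which is decomposed first), then expand each into its canonical
#' glycosidic variants.
#'
#' @param x A `g4_seq` or `g4_decomposition`.
#' @param constraints See [g4_constraints()].
#' @param intact_only Restrict to candidates with a complete tetrad core.
#' @param ... Passed to [decompose()] when `x` is a sequence.
#' @return Tibble with one row per (topology, variant) pair; topology columns
#'   plus the variant columns of [enumerate_glycosidic_variants()].
#' @examples
#' qref <- parse_sequence("GGCTAGGGTCAGGGTGGGTCAG", "Qref")
#' cands <- enumerate_candidates(qref, intact_only = TRUE)
#' cands[, c("descriptor", "n_syn_syn_steps", "homopolar_only")]
#' @export
enumerate_candidates <- function(x, constraints = g4_constraints(),
                                 intact_only = FALSE, ...) {
  decomp <- if (inherits(x, "g4_decomposition")) x else decompose(x, ...)
  topos <- enumerate_topologies(decomp, constraints, intact_only = intact_only)
  if (nrow(topos) == 0L) return(topos)
  purrr::list_rbind(purrr::map(seq_len(nrow(topos)), function(i) {
    tr <- topos[i, ]
    vars <- enumerate_glycosidic_variants(tr)
    vars$descriptor <- NULL
    cbind_tbl(tr[rep(1L, nrow(vars)), ], vars)
  }))
}

cbind_tbl <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  for (nm in names(b)) a[[nm]] <- b[[nm]]
  a
}
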