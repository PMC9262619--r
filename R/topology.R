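## Topology enumeration --------------------------------------------------------
##
## Geometric model: the four G-columns occupy the corners 0..3 of a square
## (viewed from the 5' face); each column runs up (+1) or down (-1). Column 1
## (the 5'-terminal tract) is the reference: corner 0, direction up ("running
## towards the viewer"). Loops move between corners:
##
##   propeller (p): same direction, adjacent corner; the rotational progression
##     is dictated by the right-handed helicity: counter-clockwise (-) along an
##     up column, clockwise (+) along a down column.
##   lateral (l):   direction flips, adjacent corner, either rotational sign.
##   diagonal (d):  direction flips, opposite corner.
##
## Tetrad layers are numbered 1 (bottom) to n (top); an up column enters at the
## bottom. A lateral/diagonal loop connects two column ends on the same face; a
## propeller loop connects a 3' end to the next 5' end on the opposite face,
## spanning the grooves.

#' Constraint set for topology enumeration
#'
#' @param min_lateral Minimum loop length able to form a lateral loop in a
#'   three-layer fold (default 2). A single-nucleotide lateral loop is allowed
#'   only in two-layer folds.
#' @param min_diagonal Minimum loop length able to form a diagonal loop
#'   (default 4).
#' @param allow_propeller_snapback Admit a propeller-type snapback loop
#'   (excluded by default as structurally very unusual).
#' @return A named list of constraints.
#' @export
g4_constraints <- function(min_lateral = 2L, min_diagonal = 4L,
                           allow_propeller_snapback = FALSE) {
  list(min_lateral = as.integer(min_lateral),
       min_diagonal = as.integer(min_diagonal),
       allow_propeller_snapback = isTRUE(allow_propeller_snapback))
}

## sign of the forced propeller progression for a column direction d
propeller_sign <- function(d) -d

## corner reached from c by one rotational step of the given sign
corner_step <- function(c, sign) (c + sign) %% 4L

#' Enumerate feasible intramolecular topologies
#'
#' Generates every assignment of loop kind (propeller/lateral/diagonal) and
#' rotational sign to the intervening segments of a four-tract decomposition,
#' keeps those consistent with the geometric constraints, and annotates each
#' candidate with column directions, groove widths, snapback fill and the
#' number of intact tetrads. Two-layer candidates are generated only when they
#' require the two-layer exception (a single-nucleotide lateral loop);
#' otherwise they duplicate a three-layer fold with strictly fewer tetrads.
#'
#' @param decomp A `g4_decomposition` with exactly four tracts.
#' @param constraints See [g4_constraints()].
#' @param intact_only Keep only candidates whose tetrad core is complete
#'   (`intact_tetrads == target_layers`).
#' @return A `g4_topologies` tibble, one row per candidate topology, with
#'   list-columns `loops` (per-loop kind, sign, groove), `columns` (corner,
#'   direction and occupied layers per G-column), `core` (residue-to-layer
#'   map) and `snapback`. An unsatisfiable constraint set yields a zero-row
#'   tibble, not an error.
#' @examples
#' qref <- decompose(parse_sequence("GGCTAGGGTCAGGGTGGGTCAG", "Qref"))
#' enumerate_topologies(qref, intact_only = TRUE)$descriptor
#' @export
enumerate_topologies <- function(decomp, constraints = g4_constraints(),
                                 intact_only = FALSE) {
  stopifnot(inherits(decomp, "g4_decomposition"))
  if (nrow(decomp$tracts) != 4L) {
    abort(sprintf("topology enumeration supports four G-tracts, got %d",
                  nrow(decomp$tracts)),
          class = "g4_topology_error")
  }
  if (!is.na(decomp$vacancy) && decomp$vacancy != 1L) {
    abort("only a vacancy in the 5'-terminal tract is supported",
          class = "g4_topology_error")
  }
  target <- decomp$target_layers

  cands <- c(
    enumerate_layered(decomp, constraints, n_layers = target),
    if (target > 2L) enumerate_layered(decomp, constraints, n_layers = 2L)
  )
  out <- purrr::list_rbind(purrr::map(cands, finalize_topology,
                                      decomp = decomp,
                                      constraints = constraints))
  if (nrow(out) > 0L) {
    out <- mutate(out, topology_id = row_number()) |>
      select("topology_id", dplyr::everything())
  }
  if (intact_only && nrow(out) > 0L) {
    out <- dplyr::filter(out, .data$intact_tetrads == target)
  }
  class(out) <- c("g4_topologies", class(out))
  out
}

## kinds admissible for a loop of the given length
allowed_kinds <- function(len, constraints, n_layers, target) {
  kinds <- "p"
  lat_min <- if (n_layers < target) 1L else constraints$min_lateral
  if (len >= lat_min) kinds <- c(kinds, "l")
  if (len >= constraints$min_diagonal) kinds <- c(kinds, "d")
  kinds
}

## Depth-first enumeration over loop assignments for a fixed layer count.
## Returns a list of raw candidates: kinds, signs, corners, directions.
enumerate_layered <- function(decomp, constraints, n_layers) {
  target <- decomp$target_layers
  lens <- decomp$loops$length
  n_loops <- length(lens)
  out <- list()

  recurse <- function(i, kinds, signs, corners, dirs) {
    if (i > n_loops) {
      ## two-layer candidates must actually use the short-lateral exception
      if (n_layers < target &&
          !any(kinds == "l" & lens < constraints$min_lateral)) return()
      out[[length(out) + 1L]] <<- list(
        kinds = kinds, signs = signs, corners = corners, dirs = dirs,
        n_layers = n_layers)
      return()
    }
    c_cur <- corners[i]
    d_cur <- dirs[i]
    for (kind in allowed_kinds(lens[i], constraints, n_layers, target)) {
      moves <- switch(kind,
        p = list(list(sign = propeller_sign(d_cur), d = d_cur,
                      c = corner_step(c_cur, propeller_sign(d_cur)))),
        l = list(list(sign = 1L, d = -d_cur, c = corner_step(c_cur, 1L)),
                 list(sign = -1L, d = -d_cur, c = corner_step(c_cur, -1L))),
        d = list(list(sign = 1L, d = -d_cur, c = (c_cur + 2L) %% 4L))
      )
      for (mv in moves) {
        if (mv$c %in% corners[seq_len(i)]) next  # corner already occupied
        recurse(i + 1L, c(kinds, kind), c(signs, mv$sign),
                c(corners, mv$c), c(dirs, mv$d))
      }
    }
  }
  recurse(1L, character(0), integer(0), 0L, 1L)
  out
}

## Resolve layers, snapback fill, grooves and descriptor for a raw candidate.
## Returns a one-row tibble, or NULL if the candidate is geometrically
## inconsistent (deficient-tract endpoint not reachable by its loop).
finalize_topology <- function(cand, decomp, constraints = g4_constraints()) {
  target <- decomp$target_layers
  n_layers <- cand$n_layers
  dirs <- cand$dirs
  corners <- cand$corners
  has_vac <- !is.na(decomp$vacancy) && n_layers == target
  top <- n_layers
  exit_face <- if (dirs[4L] == 1L) top else 1L

  ## layers occupied by each column (bottom = 1)
  tract_len <- pmin(decomp$tracts$length, n_layers)
  occupied <- vector("list", 4L)
  vacancy_layer <- NA_integer_
  for (k in 1:4) {
    if (k == 1L && has_vac) next
    occupied[[k]] <- seq_len(n_layers)[seq_len(tract_len[k])]
    ## full columns span all layers; for two-layer folds every tract
    ## contributes its 5'-most guanines
  }
  if (has_vac) {
    len1 <- decomp$tracts$length[1L]  # target - 1
    if (cand$kinds[1L] %in% c("l", "d")) {
      ## 3' end of tract 1 must sit on the face where loop 1 connects,
      ## i.e. the 5' face of column 2
      face2 <- if (dirs[2L] == 1L) 1L else top
      if (face2 != top) return(NULL)  # up column, 3' end cannot reach bottom
      occupied[[1L]] <- (top - len1 + 1L):top
    } else {
      ## propeller loop 1: occupancy free, prefer the fillable arrangement
      vac <- exit_face
      occupied[[1L]] <- setdiff(seq_len(target), vac)
      if (any(diff(occupied[[1L]]) != 1L)) return(NULL)
    }
    vacancy_layer <- setdiff(seq_len(target), occupied[[1L]])
  }

  ## snapback fill
  filled <- FALSE
  snap <- NULL
  if (has_vac && !is.null(decomp$snapback)) {
    delta <- (corners[1L] - corners[4L]) %% 4L
    adjacent <- delta %in% c(1L, 3L)
    sb_sign <- if (delta == 1L) 1L else -1L
    if (adjacent) {
      if (decomp$snapback$segment_length >= 1L && vacancy_layer == exit_face) {
        ## lateral snapback: fold back around the exit face, filling the
        ## vacancy with a reversed-direction residue
        filled <- TRUE
        snap <- list(kind = "l", sign = sb_sign, filled = TRUE,
                     fill_layer = vacancy_layer, fill_dir = -dirs[4L])
      } else if (constraints$allow_propeller_snapback &&
                 sb_sign == propeller_sign(dirs[4L]) &&
                 vacancy_layer == (top + 1L - exit_face)) {
        ## propeller snapback: continue along the helicity to the opposite
        ## face, strand direction unchanged
        filled <- TRUE
        snap <- list(kind = "p", sign = sb_sign, filled = TRUE,
                     fill_layer = vacancy_layer, fill_dir = dirs[4L])
      } else {
        snap <- list(kind = "l", sign = sb_sign, filled = FALSE,
                     fill_layer = NA_integer_, fill_dir = NA_integer_)
      }
    }
  }

  intact <- if (n_layers < target) n_layers
            else if (!has_vac || filled) target else target - 1L
  n_tetrad_g <- if (has_vac && !filled) 4L * (target - 1L) + 3L
                else 4L * intact

  ## groove widths around the square: edge j lies between corners j and j+1
  ## (mod 4); medium between parallel columns, otherwise narrow when the
  ## Hoogsteen donor column (clockwise-first corner) runs up, wide when down.
  col_at <- match(0:3, corners)
  edge_width <- vapply(0:3, function(j) {
    d1 <- dirs[col_at[j + 1L]]
    d2 <- dirs[col_at[(j + 1L) %% 4L + 1L]]
    if (d1 == d2) "medium" else if (d1 == 1L) "narrow" else "wide"
  }, character(1))

  edge_of <- function(ca, cb) {
    if ((cb - ca) %% 4L == 1L) ca else if ((ca - cb) %% 4L == 1L) cb
    else NA_integer_
  }
  loop_groove <- vapply(1:3, function(i) {
    if (cand$kinds[i] == "d") return(NA_character_)
    e <- edge_of(corners[i], corners[i + 1L])
    edge_width[e + 1L]
  }, character(1))
  if (!is.null(snap)) {
    snap$groove <- edge_width[edge_of(corners[4L], corners[1L]) + 1L]
  }

  loops <- mutate(decomp$loops,
                  kind = cand$kinds, sign = cand$signs,
                  groove = loop_groove)
  columns <- tibble(
    column = 1:4,
    tract = 1:4,
    corner = corners,
    direction = dirs,
    layers = occupied
  )

  descriptor <- format_descriptor_roles(cand$kinds, cand$signs)

  ## residue -> (column, layer) map for the tetrad core
  core <- purrr::list_rbind(purrr::map(1:4, function(k) {
    lay <- occupied[[k]]
    res <- decomp$tracts$start[k]:decomp$tracts$end[k]
    res <- res[seq_along(lay)]
    if (dirs[k] == -1L) lay <- rev(lay)  # down column: 5' residue on top
    tibble(position = res, column = k, layer = lay,
           direction = dirs[k], fill = FALSE)
  }))
  if (filled) {
    core <- bind_rows(core, tibble(
      position = decomp$snapback$position, column = 1L,
      layer = vacancy_layer, direction = snap$fill_dir, fill = TRUE))
  }

  tibble(
    descriptor = descriptor,
    n_layers = n_layers,
    target_layers = target,
    intact_tetrads = intact,
    n_tetrad_guanines = n_tetrad_g,
    filled = filled,
    vacancy_layer = vacancy_layer,
    loops = list(loops),
    columns = list(columns),
    grooves = list(setNames(edge_width, paste0("edge", 0:3))),
    snapback = list(snap),
    core = list(arrange(core, .data$column, .data$layer))
  )
}

## Descriptor strings ----------------------------------------------------------

format_descriptor_roles <- function(kinds, signs) {
  sgn <- ifelse(signs > 0, "+", "-")
  if (length(unique(sgn)) == 1L) {
    sprintf("%s(%s)", sgn[1], paste(kinds, collapse = ""))
  } else {
    paste0(sgn, kinds, collapse = "")
  }
}

#' Format a topology descriptor string
#'
#' Builds the compact loop descriptor (e.g. `"+(lpp)"`): loop kinds `p`, `l`,
#' `d` in 5'-to-3' order with their rotational progression (`+` clockwise,
#' `-` counter-clockwise, factored out when uniform). The snapback loop is
#' omitted, as is conventional.
#'
#' @param x A one-row `g4_topologies` candidate, or a data frame / tibble of
#'   loop roles with columns `kind` and `sign`.
#' @return Descriptor string.
#' @export
format_descriptor <- function(x) {
  roles <- if (is.data.frame(x)) x
           else if (is_tibble(x$loops[[1]])) x$loops[[1]]
           else abort("cannot extract loop roles", class = "g4_descriptor_error")
  format_descriptor_roles(roles$kind, sign(roles$sign))
}

#' Parse a topology descriptor string
#'
#' Inverse of [format_descriptor()]: accepts the factored form `"+(lpp)"` and
#' the per-loop form `"+l-p+p"`.
#'
#' @param string Descriptor string.
#' @return Tibble of loop roles with columns `kind` and `sign`.
#' @export
parse_descriptor <- function(string) {
  stopifnot(is.character(string), length(string) == 1)
  s <- gsub("\\s", "", chartr("−–", "--", string))
  if (grepl("^[+-]\\([pld]+\\)$", s)) {
    sgn <- if (substr(s, 1, 1) == "+") 1L else -1L
    kinds <- strsplit(gsub("^[+-]\\(|\\)$", "", s), "")[[1]]
    return(tibble(kind = kinds, sign = rep(sgn, length(kinds))))
  }
  if (grepl("^([+-][pld])+$", s)) {
    m <- regmatches(s, gregexpr("[+-][pld]", s))[[1]]
    return(tibble(kind = substr(m, 2, 2),
                  sign = ifelse(substr(m, 1, 1) == "+", 1L, -1L)))
  }
  abort(sprintf("malformed topology descriptor '%s'", string),
        class = "g4_descriptor_error")
}

#' Groove widths of a topology candidate
#'
#' Returns the four groove widths around the quadruplex core: `medium`
#' between parallel columns, `narrow`/`wide` between antiparallel columns
#' following the Hoogsteen donor direction of the flanking columns.
#'
#' @param topo One-row `g4_topologies` candidate.
#' @return Named character vector of length 4 (`edge0`..`edge3`).
#' @export
assign_grooves <- function(topo) {
  stopifnot(is.data.frame(topo), nrow(topo) == 1L, "grooves" %in% names(topo))
  topo$grooves[[1]]
}

#' Number of guanines engaged in tetrads
#'
#' `4 * intact_tetrads` plus the members of an incomplete (triad) layer left
#' by an unfilled vacancy. A clean three-layer snapback fold has twelve
#' tetrad guanines, matching the twelve imino resonances such a structure
#' shows by NMR.
#'
#' @param topo One-row `g4_topologies` candidate.
#' @return Integer count.
#' @export
count_tetrad_guanines <- function(topo) {
  stopifnot(is.data.frame(topo), nrow(topo) == 1L)
  as.integer(topo$n_tetrad_guanines)
}
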