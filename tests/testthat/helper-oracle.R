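# Independent brute-force oracle for topology enumeration.
#
# Re-derives the feasible (kind, sign) assignments for a four-column
# intramolecular fold by exhaustive generation and explicit filtering,
# sharing no code with the package's recursive machine. Rules applied:
#  - column 1 starts at corner 0 running up (+1)
#  - propeller: direction kept; progression forced counter-clockwise along an
#    up column, clockwise along a down column
#  - lateral: direction flipped, either adjacent corner
#  - diagonal: direction flipped, opposite corner (sign +)
#  - all corners distinct
#  - length gates: lateral >= min_lateral (or >= 1 in a two-layer fold),
#    diagonal >= min_diagonal; two-layer assignments only when they use a
#    lateral shorter than min_lateral.
oracle_assignments <- function(loop_lengths, min_lateral = 2, min_diagonal = 4) {
  kinds_grid <- expand.grid(k1 = c("p", "l", "d"), k2 = c("p", "l", "d"),
                            k3 = c("p", "l", "d"), stringsAsFactors = FALSE)
  signs_grid <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1))
  res <- list()
  for (layers in c(3L, 2L)) {
    for (i in seq_len(nrow(kinds_grid))) for (j in seq_len(nrow(signs_grid))) {
      kinds <- unlist(kinds_grid[i, ], use.names = FALSE)
      signs <- unlist(signs_grid[j, ], use.names = FALSE)
      lat_min <- if (layers == 2L) 1 else min_lateral
      ok <- TRUE
      corner <- 0; dir <- 1; seen <- 0
      for (q in 1:3) {
        len <- loop_lengths[q]
        k <- kinds[q]; s <- signs[q]
        if (k == "l" && len < lat_min) { ok <- FALSE; break }
        if (k == "d" && len < min_diagonal) { ok <- FALSE; break }
        if (k == "p") {
          if (s != ifelse(dir == 1, -1, 1)) { ok <- FALSE; break }
          corner <- (corner + s) %% 4
        } else if (k == "l") {
          corner <- (corner + s) %% 4
          dir <- -dir
        } else {
          if (s != 1) { ok <- FALSE; break }
          corner <- (corner + 2) %% 4
          dir <- -dir
        }
        if (corner %in% seen) { ok <- FALSE; break }
        seen <- c(seen, corner)
      }
      if (!ok) next
      if (layers == 2L &&
          !any(kinds == "l" & loop_lengths < min_lateral)) next
      res[[length(res) + 1L]] <- list(kinds = kinds, signs = signs,
                                      layers = layers)
    }
  }
  res
}

oracle_keys <- function(assignments) {
  sort(vapply(assignments, function(a) {
    paste0(a$layers, ":", paste0(ifelse(a$signs > 0, "+", "-"), a$kinds,
                                 collapse = ""))
  }, character(1)))
}

topology_keys <- function(topos) {
  sort(vapply(seq_len(nrow(topos)), function(i) {
    l <- topos$loops[[i]]
    paste0(topos$n_layers[i], ":",
           paste0(ifelse(l$sign > 0, "+", "-"), l$kind, collapse = ""))
  }, character(1)))
}

# closed-form Boltzmann weights for a handful of energies
oracle_boltzmann <- function(dG, T, R = 1.987e-3) {
  w <- exp(-dG / (R * T))
  w / sum(w)
}
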