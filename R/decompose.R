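## G-tract decomposition -------------------------------------------------------

#' Decompose a sequence into G-tracts, loops and snapback architecture
#'
#' Identifies maximal runs of tract-forming residues (G and BrG) of length at
#' least `min_tract`, the intervening segments between consecutive tracts, and
#' the 5'/3' overhangs. When exactly one tract is one guanine short of
#' `target_layers` (a G-vacancy) while all others reach it, a lone 3'-terminal
#' G preceded by at least one non-tract residue is reported as a snapback
#' candidate able to fill the vacant tetrad position. A 3'-terminal tract of
#' full length suppresses snapback detection.
#'
#' @param seq A `g4_seq` (see [parse_sequence()]).
#' @param min_tract Minimum run length counted as a tract (default 2).
#' @param target_layers Intended number of stacked G-tetrad layers (default 3).
#' @return A `g4_decomposition`: tibbles of tracts and intervening loops,
#'   overhang strings, vacancy and snapback annotations.
#' @examples
#' qref <- parse_sequence("GGCTAGGGTCAGGGTGGGTCAG", "Qref")
#' decompose(qref)
#' @export
decompose <- function(seq, min_tract = 2L, target_layers = 3L) {
  stopifnot(inherits(seq, "g4_seq"), min_tract >= 1L, target_layers >= 2L)
  codes <- seq$codes
  pos <- positions(seq)
  n <- length(codes)

  g_like <- is_tract_code(codes)
  r <- rle(g_like)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(
    start = starts[r$values], end = ends[r$values],
    length = r$lengths[r$values]
  )
  tracts <- dplyr::filter(runs, .data$length >= min_tract)
  if (nrow(tracts) < 2L) {
    abort(sprintf("fewer than two G-tracts of length >= %d found in '%s'",
                  min_tract, seq$name),
          class = "g4_decomposition_error")
  }

  seg_string <- function(i, j) {
    if (j < i) "" else paste(bracket_codes(codes[i:j]), collapse = "")
  }

  k <- nrow(tracts)
  loops <- tibble(
    index = seq_len(k - 1L),
    start = tracts$end[-k] + 1L,
    end = tracts$start[-1L] - 1L
  ) |>
    mutate(
      segment = purrr::map2_chr(.data$start, .data$end, seg_string),
      length = .data$end - .data$start + 1L
    )
  if (any(loops$length < 1L)) {
    abort("adjacent G-tracts without an intervening residue are not supported",
          class = "g4_decomposition_error")
  }

  overhang5 <- seg_string(1L, tracts$start[1] - 1L)
  tail_start <- tracts$end[k] + 1L
  overhang3 <- seg_string(tail_start, n)

  ## Vacancy: exactly one deficient tract, all others at full height.
  deficient <- which(tracts$length == target_layers - 1L)
  full <- tracts$length >= target_layers
  vacancy <- if (length(deficient) == 1L && all(full[-deficient])) {
    deficient
  } else NA_integer_
  n_deficient <- length(deficient)

  ## Snapback: lone 3'-terminal G after a >=1-nt segment, only meaningful
  ## when a vacancy exists.
  snapback <- NULL
  if (!is.na(vacancy) && tail_start <= n &&
      is_tract_code(codes[n]) && (n - tail_start) >= 1L &&
      !is_tract_code(codes[n - 1L])) {
    snapback <- list(
      position = pos[n],
      segment = seg_string(tail_start, n - 1L),
      segment_length = n - tail_start
    )
    overhang3 <- ""  # accounted for by the snapback annotation
  }

  anchors <- k + (!is.null(snapback))
  if (anchors < 4L) {
    abort(sprintf(
      "'%s' provides only %d anchor points (G-tracts plus snapback G); an intramolecular quadruplex needs 4",
      seq$name, anchors), class = "g4_decomposition_error")
  }

  structure(
    list(
      seq = seq,
      tracts = mutate(tracts,
                      start = pos[.data$start], end = pos[.data$end]),
      loops = mutate(loops,
                     start = pos[.data$start], end = pos[.data$end]),
      overhang5 = overhang5,
      overhang3 = overhang3,
      vacancy = vacancy,
      n_deficient_tracts = n_deficient,
      snapback = snapback,
      min_tract = as.integer(min_tract),
      target_layers = as.integer(target_layers)
    ),
    class = "g4_decomposition"
  )
}

bracket_codes <- function(codes) {
  long <- nchar(codes) > 1L
  codes[long] <- paste0("[", codes[long], "]")
  codes
}

#' Reassemble a decomposition into its sequence string
#'
#' Exact inverse of [decompose()] on the originating sequence: concatenating
#' 5'-overhang, tracts, loops, snapback segment + G and 3'-overhang reproduces
#' the input string character for character.
#'
#' @param decomp A `g4_decomposition`.
#' @return Single sequence string (bracketed multi-letter codes).
#' @export
compose <- function(decomp) {
  stopifnot(inherits(decomp, "g4_decomposition"))
  seq <- decomp$seq
  pos <- positions(seq)
  piece <- function(i, j) {
    paste(bracket_codes(seq$codes[match(i, pos):match(j, pos)]), collapse = "")
  }
  k <- nrow(decomp$tracts)
  parts <- decomp$overhang5
  for (i in seq_len(k)) {
    parts <- c(parts, piece(decomp$tracts$start[i], decomp$tracts$end[i]))
    if (i < k) parts <- c(parts, decomp$loops$segment[i])
  }
  if (!is.null(decomp$snapback)) {
    parts <- c(parts, decomp$snapback$segment,
               bracket_codes(seq$codes[match(decomp$snapback$position, pos)]))
  }
  parts <- c(parts, decomp$overhang3)
  paste(parts, collapse = "")
}

#' @export
print.g4_decomposition <- function(x, ...) {
  cat(sprintf("<g4_decomposition> %s\n", x$seq$name))
  cat(sprintf("  tracts: %s\n",
              paste(sprintf("%d-%d", x$tracts$start, x$tracts$end),
                    collapse = ", ")))
  cat(sprintf("  loops:  %s\n",
              paste(sprintf("'%s'", x$loops$segment), collapse = ", ")))
  if (nzchar(x$overhang5)) cat(sprintf("  5'-overhang: %s\n", x$overhang5))
  if (nzchar(x$overhang3)) cat(sprintf("  3'-overhang: %s\n", x$overhang3))
  if (!is.na(x$vacancy))
    cat(sprintf("  vacancy: tract %d (one G short of %d layers)\n",
                x$vacancy, x$target_layers))
  if (!is.null(x$snapback))
    cat(sprintf("  snapback: G%d preceded by '%s'\n",
                x$snapback$position, x$snapback$segment))
  invisible(x)
}
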