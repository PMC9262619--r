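## Residue alphabet -----------------------------------------------------------

#' Residue alphabet for modified G-rich oligonucleotides
#'
#' The package works with DNA sequences that may carry non-natural residues:
#' inosine (`I`, hypoxanthine nucleoside), an abasic 1',2'-dideoxyribose site
#' (`X`) and the syn-favouring guanosine analog 8-bromo-2'-deoxyguanosine
#' (`BrG`). `BrG` participates in G-tracts like a guanine; `I` is a purine but
#' never joins a tract; `X` carries no nucleobase and is a legal loop residue
#' only.
#'
#' @return Character vector of the allowed residue codes.
#' @export
g4_alphabet <- function() c("A", "C", "G", "T", "I", "X", "BrG")

## Codes that can occupy a position of a G-tract / G-tetrad.
.tract_codes <- c("G", "BrG")
## Purine bases (ring-system rule for stacking interactions).
.purine_codes <- c("A", "G", "I", "BrG")

is_purine_code <- function(code) code %in% .purine_codes
is_tract_code <- function(code) code %in% .tract_codes

## Sequence class --------------------------------------------------------------

new_g4_seq <- function(name, codes, first_index = 1L, minus_one = FALSE) {
  structure(
    list(
      name = as.character(name),
      codes = as.character(codes),
      first_index = as.integer(first_index),
      minus_one = isTRUE(minus_one)
    ),
    class = "g4_seq"
  )
}

#' Parse a G-rich sequence with extended residue codes
#'
#' Tokenises a sequence string into residues. Single letters are single
#' residues; multi-letter codes are written in square brackets (`"[BrG]"`).
#' Whitespace and hyphens (used for display grouping, e.g.
#' `"GG-CTA-GGG-TCA-GGG-T-GGG-TCA-G"`) are stripped, and parsing is
#' case-insensitive.
#'
#' @param text Sequence string, possibly hyphenated/bracketed.
#' @param name Identifier attached to the sequence.
#' @param first_index Index given to the first residue. The core numbering is
#'   1-based; a single 5'-flanking residue can be numbered 0 (see
#'   [g4_add_overhang5()]).
#' @param minus_one If `TRUE` and `first_index == 0`, the residue at internal
#'   index 0 is *displayed* as "(-1)" for parity with common reporting of
#'   5'-overhangs; internal indices stay contiguous.
#' @return A `g4_seq` object: residues, name and numbering offset.
#' @examples
#' qref <- parse_sequence("GG-CTA-GGG-TCA-GGG-T-GGG-TCA-G", "Qref")
#' length(qref)
#' parse_sequence("GGCTA[BrG]GGTCAGGGTGGGTCAG", "6BrQ")
#' @export
parse_sequence <- function(text, name = "seq", first_index = 1L,
                           minus_one = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  clean <- gsub("[-[:space:]]", "", text)
  if (!nzchar(clean)) {
    abort("empty sequence: no residues left after stripping whitespace/hyphens",
          class = "g4_alphabet_error")
  }
  toks <- character(0)
  i <- 1L
  chars <- strsplit(clean, "", fixed = TRUE)[[1]]
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[[j]] != "]") j <- j + 1L
      if (j > length(chars)) {
        abort(sprintf("unterminated '[' at position %d", length(toks) + 1L),
              class = "g4_alphabet_error")
      }
      toks <- c(toks, paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  codes <- normalize_codes(toks)
  new_g4_seq(name, codes, first_index = first_index, minus_one = minus_one)
}

normalize_codes <- function(toks) {
  alpha <- g4_alphabet()
  idx <- match(toupper(toks), toupper(alpha))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(
      sprintf("unknown residue token '%s' at position %d (alphabet: %s)",
              toks[bad], bad, paste(alpha, collapse = ", ")),
      class = "g4_alphabet_error"
    )
  }
  alpha[idx]
}

#' @export
length.g4_seq <- function(x) length(x$codes)

#' Residue positions of a sequence
#'
#' Internal indices are contiguous integers starting at `first_index`
#' (1 for a core sequence, 0 when a 5'-overhang residue was added).
#'
#' @param seq A `g4_seq`.
#' @return Integer vector of residue indices.
#' @export
positions <- function(seq) {
  stopifnot(inherits(seq, "g4_seq"))
  seq$first_index + seq_along(seq$codes) - 1L
}

position_labels <- function(seq) {
  pos <- positions(seq)
  lab <- as.character(pos)
  if (seq$minus_one) lab[pos == 0L] <- "-1"
  lab
}

#' @export
as.character.g4_seq <- function(x, bracket = TRUE, ...) {
  out <- x$codes
  long <- nchar(out) > 1L
  if (bracket) out[long] <- paste0("[", out[long], "]")
  paste(out, collapse = "")
}

#' @export
print.g4_seq <- function(x, ...) {
  cat(sprintf("<g4_seq> %s (%d nt%s)\n5'-%s-3'\n",
              x$name, length(x),
              if (x$first_index != 1L)
                sprintf(", numbering from %s", position_labels(x)[1]) else "",
              as.character(x)))
  invisible(x)
}

#' @method as_tibble g4_seq
#' @export
as_tibble.g4_seq <- function(x, ...) {
  tibble(position = positions(x), label = position_labels(x), code = x$codes)
}

#' @export
`==.g4_seq` <- function(e1, e2) {
  identical(e1$codes, e2$codes) && identical(e1$first_index, e2$first_index)
}

## Edits -----------------------------------------------------------------------

#' Substitute a residue
#'
#' Returns a copy of the sequence differing only at `position`; the name is
#' annotated with a mutation label such as `"Qref-5T"` unless `label` is given.
#'
#' @param seq A `g4_seq`.
#' @param position Residue index (in the sequence's own numbering).
#' @param code Replacement residue code (see [g4_alphabet()]).
#' @param label Optional name for the mutant; default appends
#'   `-<position><code>`.
#' @examples
#' qref <- parse_sequence("GGCTAGGGTCAGGGTGGGTCAG", "Qref")
#' apply_substitution(qref, 5, "T")
#' @export
apply_substitution <- function(seq, position, code, label = NULL) {
  stopifnot(inherits(seq, "g4_seq"))
  code <- normalize_codes(code)
  pos <- positions(seq)
  i <- match(as.integer(position), pos)
  if (is.na(i)) {
    abort(sprintf("position %s outside sequence (%s..%s)",
                  position, min(pos), max(pos)),
          class = "g4_position_error")
  }
  codes <- seq$codes
  codes[i] <- code
  name <- label %||% sprintf("%s-%d%s", seq$name, as.integer(position), code)
  new_g4_seq(name, codes, seq$first_index, seq$minus_one)
}

#' Add a single 5'-flanking residue
#'
#' The added residue takes internal index `first_index - 1` of the original
#' sequence (index 0 for a core sequence); with `minus_one = TRUE` it is
#' displayed as "(-1)".
#'
#' @inheritParams apply_substitution
#' @param code Residue code of the flanking residue.
#' @param minus_one Display the new residue as "(-1)".
#' @export
g4_add_overhang5 <- function(seq, code, label = NULL, minus_one = FALSE) {
  stopifnot(inherits(seq, "g4_seq"))
  code <- normalize_codes(code)
  name <- label %||% sprintf("5'%s-%s", code, seq$name)
  new_g4_seq(name, c(code, seq$codes), seq$first_index - 1L, minus_one)
}

#' Delete the 3'-terminal residue
#'
#' @inheritParams apply_substitution
#' @export
g4_trim3 <- function(seq, label = NULL) {
  stopifnot(inherits(seq, "g4_seq"), length(seq) > 1L)
  name <- label %||% sprintf("3'del-%s", seq$name)
  new_g4_seq(name, head(seq$codes, -1L), seq$first_index, seq$minus_one)
}
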