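## FASTA-dialect and mutation-table IO ----------------------------------------

#' Read sequences from a FASTA-dialect file
#'
#' Standard FASTA layout (`>name` header lines, wrapped sequence lines); the
#' sequence lines may contain the extended bracketed codes of this package
#' (e.g. `[BrG]`) as well as hyphens and whitespace, which are ignored. A
#' hand-rolled reader is used because the extended residue alphabet
#' (multi-letter analog codes, abasic sites) does not fit standard
#' single-letter DNA containers.
#'
#' @param path File path.
#' @return Tibble with columns `name` and `sequence`.
#' @export
read_g4_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) {
    abort("not a FASTA file: first non-empty line must start with '>'",
          class = "g4_io_error")
  }
  idx <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(seq_along(names), function(i) {
    paste(lines[idx == i & !hdr], collapse = "")
  }, character(1))
  tibble(name = names, sequence = seqs)
}

#' Write sequences to a FASTA-dialect file
#'
#' @param panel Data frame with columns `name` and `sequence`, e.g.
#'   [build_table1_panel()].
#' @param path File path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_g4_fasta <- function(panel, path, width = 60L) {
  stopifnot(all(c("name", "sequence") %in% names(panel)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(panel))) {
    writeLines(paste0(">", panel$name[i]), con)
    s <- panel$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read / apply a sidecar mutation table
#'
#' Plain-text table (whitespace- or tab-separated, optional header) with
#' columns `name`, `position`, `code`, one substitution per line; multiple
#' lines with the same `name` accumulate into one mutant. Drives panel
#' generation from a parent sequence.
#'
#' @param path File path.
#' @return Tibble with columns `name`, `position`, `code`.
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("name", "position", "code"),
                          colClasses = c("character", "integer", "character"),
                          comment.char = "#")
  if (nrow(df) && identical(tolower(df$name[1]), "name")) df <- df[-1, ]
  as_tibble(df) |> mutate(position = as.integer(.data$position))
}

#' @rdname read_mutation_table
#' @param parent A `g4_seq` parent sequence.
#' @param table Mutation tibble as returned by [read_mutation_table()].
#' @return [apply_mutation_table()] returns a list of `g4_seq` mutants.
#' @export
apply_mutation_table <- function(parent, table) {
  stopifnot(inherits(parent, "g4_seq"))
  split(table, table$name)[unique(table$name)] |>
    purrr::imap(function(rows, nm) {
      apply_ledger_row(parent, rows$position, rows$code, nm)
    })
}
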