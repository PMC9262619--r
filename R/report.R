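## Report writers and melting CSV dialect -------------------------------------

#' Read / write melting curves in the package CSV dialect
#'
#' Columns `temperature_C`, `absorbance`, `direction` (heating|cooling) and
#' `replicate_id`; a header row is required. Schema violations name the
#' offending column.
#'
#' @param path File path.
#' @return Long tibble of melting data.
#' @export
read_melting_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("temperature_C", "absorbance", "direction", "replicate_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("melting CSV is missing column(s): %s",
                  paste(missing, collapse = ", ")), class = "g4_io_error")
  }
  bad <- !df$direction %in% c("heating", "cooling")
  if (any(bad)) {
    abort(sprintf("invalid direction '%s' in row %d (use heating|cooling)",
                  df$direction[which(bad)[1]], which(bad)[1]),
          class = "g4_io_error")
  }
  if (!is.numeric(df$temperature_C) || !is.numeric(df$absorbance)) {
    abort("temperature_C and absorbance must be numeric", class = "g4_io_error")
  }
  df[required]
}

#' @rdname read_melting_csv
#' @param data Long tibble (e.g. from [simulate_replicates()]).
#' @export
write_melting_csv <- function(data, path) {
  stopifnot(all(c("temperature_C", "absorbance", "direction",
                  "replicate_id") %in% names(data)))
  readr::write_csv(data, path)
  invisible(path)
}

## flatten list-columns of a candidate/score table for TSV output
flatten_scores <- function(scores) {
  base <- tibble(
    descriptor = scores$descriptor,
    n_layers = scores$n_layers,
    intact_tetrads = scores$intact_tetrads,
    n_tetrad_guanines = scores$n_tetrad_guanines,
    filled = scores$filled,
    variant = purrr::map_chr(scores$column_patterns,
                             function(p) paste(p, collapse = " | ")),
    n_syn_syn_steps = scores$n_syn_syn_steps,
    n_heteropolar = scores$n_heteropolar,
    homopolar_only = scores$homopolar_only,
    loop_kinds = purrr::map_chr(scores$loops, function(l)
      paste(sprintf("%s%s:%s", l$kind,
                    ifelse(l$sign > 0, "+", "-"), l$segment), collapse = ",")),
    grooves = purrr::map_chr(scores$grooves, paste, collapse = ",")
  )
  if ("dG_est" %in% names(scores)) {
    base$dG_est <- scores$dG_est
    base$population <- scores$population
    base$terms <- purrr::map_chr(scores$terms, function(tt)
      paste(sprintf("%s=%+.3f", tt$term, tt$value), collapse = ";"))
  }
  base
}

#' Write a topology / scoring report
#'
#' Writes a JSON report (per candidate: descriptor, loop table, column
#' directions, glycosidic variant, syn-syn counts, interface polarities and,
#' when scored, the term breakdown and Boltzmann population) plus a flat TSV
#' summary with one row per (topology, variant) for spreadsheet use. Output
#' is byte-stable for a given input.
#'
#' @param scores Candidate tibble from [enumerate_candidates()] or
#'   [score_candidates()].
#' @param json_path,tsv_path Output paths (`NULL` to skip one format).
#' @param name Sequence name recorded in the JSON header.
#' @return Invisibly, the flat summary tibble.
#' @export
write_topology_report <- function(scores, json_path = NULL, tsv_path = NULL,
                                  name = NULL) {
  flat <- flatten_scores(scores)
  if (!is.null(tsv_path)) readr::write_tsv(flat, tsv_path)
  if (!is.null(json_path)) {
    payload <- list(
      sequence = name,
      n_candidates = nrow(scores),
      candidates = purrr::map(seq_len(nrow(scores)), function(i) {
        row <- scores[i, ]
        out <- list(
          descriptor = row$descriptor,
          n_layers = row$n_layers,
          intact_tetrads = row$intact_tetrads,
          n_tetrad_guanines = row$n_tetrad_guanines,
          filled = row$filled,
          loops = as.data.frame(row$loops[[1]]),
          columns = as.data.frame(
            row$columns[[1]][c("column", "corner", "direction")]),
          grooves = as.list(row$grooves[[1]]),
          column_patterns = row$column_patterns[[1]],
          n_syn_syn_steps = row$n_syn_syn_steps,
          interfaces = row$interfaces[[1]],
          homopolar_only = row$homopolar_only
        )
        if ("dG_est" %in% names(row)) {
          out$dG_est <- row$dG_est
          out$population <- row$population
          out$terms <- as.data.frame(row$terms[[1]])
        }
        out
      })
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(flat)
}

#' Write a thermodynamic report
#'
#' TSV mirroring the usual melting-table layout: one row per sequence with
#' `Tm_C`, `dH_kcal_mol`, `minus_TdS_kcal_mol`, `dG_kcal_mol` (at the fit
#' reference temperature) and, when a reference fit is given, `ddG_kcal_mol`,
#' each as `mean +/- SD` over replicates.
#'
#' @param summaries Named list of replicate summaries (tibbles from
#'   [summarize_replicates()]), one per sequence.
#' @param path Output TSV path.
#' @param reference Name of the entry used as ddG reference, or `NULL`.
#' @return Invisibly, the report tibble.
#' @export
write_thermo_report <- function(summaries, path = NULL, reference = NULL) {
  fmt <- function(m, s, digits = 1) {
    if (is.na(s)) sprintf("%.*f", digits, round_half_up(m, digits))
    else sprintf("%.*f ± %.*f", digits, round_half_up(m, digits),
                 digits, round_half_up(s, digits))
  }
  get_par <- function(sm, p) unlist(sm[sm$parameter == p, c("mean", "sd")])
  ref_dG <- if (!is.null(reference)) get_par(summaries[[reference]], "dG_ref")[1]
            else NA_real_
  rows <- purrr::imap(summaries, function(sm, nm) {
    tm <- get_par(sm, "Tm"); dh <- get_par(sm, "dH")
    ts <- get_par(sm, "minus_TdS_ref"); dg <- get_par(sm, "dG_ref")
    tibble(
      sequence = nm,
      Tm_C = fmt(tm[1], tm[2]),
      dH_kcal_mol = fmt(dh[1], dh[2]),
      minus_TdS_kcal_mol = fmt(ts[1], ts[2]),
      dG_kcal_mol = fmt(dg[1], dg[2]),
      ddG_kcal_mol = if (is.na(ref_dG)) NA_character_
                     else fmt(dg[1] - ref_dG, NA)
    )
  })
  out <- purrr::list_rbind(rows)
  if (!is.null(path)) readr::write_tsv(out, path)
  invisible(out)
}
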