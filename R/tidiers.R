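# broom-style tidiers and re-exports so results drop straight into dplyr
# chains.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an identification run
#'
#' `tidy()` returns the kept top-5 species-match table; `glance()` a one-row
#' summary of the run.
#'
#' @param x An `id16s_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.id16s_run <- function(x, ...) {
  if (isTRUE(x$halted)) {
    return(tibble(accession = character(), genus = character(),
                  species = character(), percent_identity = numeric(),
                  mismatches = integer(), match_length = integer(),
                  target_length = integer(), query_length = integer(),
                  score = integer()))
  }
  as_tibble(x$matches)
}

#' @rdname tidy.id16s_run
#' @export
glance.id16s_run <- function(x, ...) {
  halted <- isTRUE(x$halted)
  tibble(
    sample_id = x$sample_id,
    halted = halted,
    level = if (halted) NA_character_ else x$interpretation$level,
    reported_taxon = if (halted) NA_character_ else
      x$interpretation$reported_taxon,
    rule_fired = if (halted) "no_dominant_genus" else
      x$interpretation$rule_fired,
    confidence = x$confidence,
    dominant_genus = if (is.null(x$genus_call)) NA_character_ else
      x$genus_call$top_genus,
    dominance_fraction = if (is.null(x$genus_call)) NA_real_ else
      x$genus_call$fraction,
    reads_in = x$log$reads_in %||% NA_integer_,
    reads_pass_qc = x$log$reads_pass_qc %||% NA_integer_,
    consensus_length = if (is.null(x$consensus)) NA_integer_ else
      (if (inherits(x$consensus, "consensus_seq")) x$consensus$length
       else nchar(as.character(x$consensus)))
  )
}

#' Tidy a genus call
#'
#' @param x A `genus_call`.
#' @param ... Unused.
#' @return The per-genus count tibble with the subsample fraction.
#' @export
tidy.genus_call <- function(x, ...) {
  x$counts |>
    dplyr::mutate(fraction = .data$n / x$subsample_size)
}

#' @rdname tidy.genus_call
#' @export
glance.genus_call <- function(x, ...) {
  tibble(genus = x$top_genus, genus_read_count = x$genus_read_count,
         subsample_size = x$subsample_size, fraction = x$fraction,
         halted = x$halted)
}

#' Tidy a paired McNemar test
#'
#' @param x A `paired_test`.
#' @param ... Unused.
#' @return A one-row tibble with the discordant counts and p-value.
#' @export
tidy.paired_test <- function(x, ...) {
  tibble(b = x$b, c = x$c, statistic = x$statistic, p.value = x$p.value,
         method = x$method)
}

#' Tidy an identification-level cross-tabulation
#'
#' @param x An `id_crosstab`.
#' @param ... Unused.
#' @return A long tibble: `level_b`, `level_a`, `n`.
#' @export
tidy.id_crosstab <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "n")) |>
    dplyr::mutate(level_a = as.character(.data$level_a),
                  level_b = as.character(.data$level_b)) |>
    dplyr::select("level_b", "level_a", "n")
}

#' Tidy a pairwise alignment
#'
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @return A one-row tibble of the identity accounting.
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  tibble(score = x$score, matches = x$matches, mismatches = x$mismatches,
         match_length = x$match_length,
         percent_identity = x$percent_identity,
         query_start = x$query_start, query_end = x$query_end,
         target_start = x$target_start, target_end = x$target_end)
}
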