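#' Paired identification levels of a published two-arm comparison
#'
#' The 153 paired identification levels (short-read Sanger arm A vs
#' long-read nanopore arm B) reconstructed from the filled cells of a
#' published method-comparison contingency table of clinical bacterial
#' isolates. Per-isolate taxa are not part of the printed table, so the
#' taxon columns are `NA`; the table supports marginal, cross-tabulation
#' and paired-test reproduction but not taxon concordance.
#'
#' The same data ship as a TSV at
#' `system.file("extdata", "ss_ont_levels.tsv", package = "ont16s")`.
#'
#' @return A 153-row paired-results tibble (`sample_id`, `level_a`,
#'   `taxon_a`, `level_b`, `taxon_b`).
#' @export
example_paired_levels <- function() {
  # counts[level_b, level_a]; rows/cols ordered no_id, family, genus, species
  counts <- matrix(
    c(1, 0, 0, 0,
      2, 4, 1, 0,
      4, 6, 16, 8,
      1, 0, 15, 95),
    nrow = 4, byrow = TRUE,
    dimnames = list(id_levels(), id_levels()))
  idx <- which(counts > 0, arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(idx)), function(k) {
    n <- counts[idx[k, 1], idx[k, 2]]
    tibble(level_a = rep(colnames(counts)[idx[k, 2]], n),
           level_b = rep(rownames(counts)[idx[k, 1]], n))
  })
  out <- dplyr::bind_rows(rows)
  tibble(sample_id = sprintf("iso%03d", seq_len(nrow(out))),
         level_a = as_id_level(out$level_a),
         taxon_a = NA_character_,
         level_b = as_id_level(out$level_b),
         taxon_b = NA_character_)
}
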