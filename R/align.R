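#' Alignment scoring scheme
#'
#' BLASTN-like defaults: match +2, mismatch -3, gap open -5, gap extend -2.
#' A gap of length L costs `gap_open + L * gap_extend`. IUPAC ambiguity codes
#' in either sequence score as a match whenever the two base sets intersect,
#' so an ambiguity call in a consensus is never penalized against a
#' compatible reference base.
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores; `mismatch`,
#'   `gap_open` and `gap_extend` are costs and must be negative.
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                          gap_extend = -2L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_scoring")
}

align_core <- function(query, target, scoring, mode) {
  stopifnot(is.character(query), length(query) == 1,
            is.character(target), length(target) == 1)
  if (nchar(query) == 0 || nchar(target) == 0) abort("empty sequence")
  n <- nchar(query); m <- nchar(target)
  maxb <- max(n, m)
  if (maxb <= 400L) {
    # small problems: run the full matrix outright, no heuristics
    return(align_dp_cpp(query, target, scoring$match, scoring$mismatch,
                        -scoring$gap_open, -scoring$gap_extend,
                        0L, mode == "global"))
  }
  band <- max(16L, abs(n - m) + 8L)
  res <- align_dp_cpp(query, target, scoring$match, scoring$mismatch,
                      -scoring$gap_open, -scoring$gap_extend,
                      band, mode == "global")
  # widen the band until the score converges on the full-DP optimum
  while (band < maxb) {
    band <- min(maxb, band * 2L)
    wider <- align_dp_cpp(query, target, scoring$match, scoring$mismatch,
                          -scoring$gap_open, -scoring$gap_extend,
                          if (band >= maxb) 0L else band, mode == "global")
    if (wider$score == res$score) {
      res <- wider
      break
    }
    res <- wider
  }
  res
}

alignment_stats <- function(aligned_query, aligned_target) {
  if (nchar(aligned_query) == 0) {
    return(list(matches = 0L, mismatches = 0L, match_length = 0L,
                percent_identity = 0))
  }
  qc <- strsplit(aligned_query, "")[[1]]
  tc <- strsplit(aligned_target, "")[[1]]
  pair <- qc != "-" & tc != "-"
  span <- which(pair)
  if (length(span) == 0) {
    return(list(matches = 0L, mismatches = 0L, match_length = 0L,
                percent_identity = 0))
  }
  lo <- span[1]; hi <- span[length(span)]
  qs <- qc[lo:hi]; ts <- tc[lo:hi]
  both <- qs != "-" & ts != "-"
  matches <- sum(iupac_compatible(qs[both], ts[both]))
  match_length <- hi - lo + 1L
  list(matches = as.integer(matches),
       mismatches = as.integer(match_length - matches),
       match_length = as.integer(match_length),
       percent_identity = 100 * matches / match_length)
}

#' Semi-global pairwise alignment with BLAST-like identity accounting
#'
#' Aligns `query` against `target` with free end gaps on either sequence
#' ("overlap" alignment), so a read may sit inside a longer reference and
#' vice versa. Identity is computed over the matched span only: the alignment
#' columns between the first and the last aligned base pair, with internal
#' gap columns counted as mismatches — the convention behind the percent
#' identity / mismatches / match length columns of a BLAST-style result
#' table. The dynamic program is banded and the band is widened until the
#' score converges, so the reported score equals the full-matrix optimum.
#'
#' @param query,target DNA strings (IUPAC codes allowed).
#' @param scoring An [align_scoring()] scheme.
#' @return An object of class `pairwise_alignment`: a list with
#'   `aligned_query`, `aligned_target` (gapped strings over the aligned
#'   region), `score`, `matches`, `mismatches`, `match_length`,
#'   `percent_identity`, and 1-based `query_start/end`, `target_start/end`.
#' @examples
#' align_semiglobal("ACGTACGT", "ACGAACGT")$percent_identity
#' @export
align_semiglobal <- function(query, target, scoring = align_scoring()) {
  res <- align_core(toupper(query), toupper(target), scoring, "overlap")
  out <- c(res, alignment_stats(res$aligned_query, res$aligned_target))
  structure(out, class = "pairwise_alignment")
}

#' @rdname align_semiglobal
#' @details `align_global()` penalizes end gaps (Needleman-Wunsch); it is
#'   used when two consensus sequences of unequal length must be compared
#'   column by column.
#' @export
align_global <- function(query, target, scoring = align_scoring()) {
  res <- align_core(toupper(query), toupper(target), scoring, "global")
  out <- c(res, alignment_stats(res$aligned_query, res$aligned_target))
  structure(out, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "<pairwise_alignment> score %d | identity %.2f%% (%d/%d, %d mismatches)\n",
    x$score, x$percent_identity, x$matches, x$match_length, x$mismatches))
  invisible(x)
}

#' Rank database centroids against a query sequence
#'
#' Aligns the query semi-globally against every centroid in the reference
#' database and returns the `k` best hits ordered by percent identity
#' (descending), then number of mismatches (ascending), with remaining ties
#' broken by accession so the ordering is total and reproducible.
#'
#' @param query A DNA string (a consensus sequence or a single read).
#' @param db A `centroid_db` tibble.
#' @param k Maximum number of hits returned.
#' @param scoring An [align_scoring()] scheme.
#' @return A tibble with one row per hit: `accession`, `genus`, `species`,
#'   `percent_identity`, `mismatches`, `match_length`, `target_length`,
#'   `query_length`, `score`.
#' @export
best_hits <- function(query, db, k = 5L, scoring = align_scoring()) {
  stopifnot(nrow(db) >= 1, k >= 1)
  query <- toupper(if (inherits(query, "consensus_seq")) as.character(query)
                   else query)
  alns <- lapply(db$sequence, function(s) align_semiglobal(query, s, scoring))
  tibble(
    accession = db$accession,
    genus = db$genus,
    species = db$species,
    percent_identity = vapply(alns, `[[`, 0, "percent_identity"),
    mismatches = vapply(alns, `[[`, 0L, "mismatches"),
    match_length = vapply(alns, `[[`, 0L, "match_length"),
    target_length = nchar(db$sequence),
    query_length = nchar(query),
    score = vapply(alns, `[[`, 0L, "score")
  ) |>
    dplyr::arrange(dplyr::desc(.data$percent_identity), .data$mismatches,
                   .data$accession) |>
    dplyr::slice_head(n = k)
}
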