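#' Quality-filter long amplicon reads
#'
#' Removes reads shorter than `min_length` nucleotides or whose arithmetic
#' mean Phred score falls below `min_mean_phred` (defaults 20 nt and Phred 7).
#' Both bounds are strict removals — a read of exactly 20 nt with mean
#' quality exactly 7 is kept. The mean is the plain arithmetic mean of the
#' integer Phred scores, not the Phred of the mean error probability.
#'
#' @param reads A reads tibble (`read_id`, `sequence`, `quals`).
#' @param params A [qc_params()] bundle.
#' @return The retained reads, original order preserved.
#' @export
filter_reads <- function(reads, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  if (nrow(reads) == 0) return(reads)
  len_ok <- nchar(reads$sequence) >= params$min_length
  mean_q <- vapply(reads$quals, function(q) mean(as.numeric(q)), 0)
  reads[len_ok & mean_q >= params$min_mean_phred, , drop = FALSE]
}

#' Randomly subsample reads for the genus screen
#'
#' Draws `n` reads uniformly without replacement; when fewer than `n` reads
#' are available all reads are returned (low-yield samples are still
#' processed). The draw is reproducible for a fixed seed and leaves the
#' global RNG state untouched.
#'
#' @param reads A reads tibble.
#' @param n Subsample size (default 1,000).
#' @param seed RNG seed.
#' @return A reads tibble with `min(n, nrow(reads))` rows.
#' @export
subsample_reads <- function(reads, n = 1000L, seed = 1L) {
  stopifnot(n >= 1)
  if (nrow(reads) <= n) return(reads)
  keep <- withr::with_seed(seed, sample.int(nrow(reads), n))
  reads[keep, , drop = FALSE]
}

#' Assign each read to the genus of its best database hit
#'
#' Every read is aligned semi-globally against every centroid; the read takes
#' the genus of its single best hit (identity-ranked as in [best_hits()]).
#' A read is left unassigned (`NA` genus) when its best identity falls below
#' `min_identity`, or when centroids from different genera tie exactly for
#' the best (identity, mismatches) — there is no information to break such a
#' tie.
#'
#' @param reads A reads tibble.
#' @param db A `centroid_db` tibble.
#' @param min_identity Assignment floor in percent identity.
#' @param scoring An [align_scoring()] scheme.
#' @return A tibble `read_id`, `genus` (NA when unassignable),
#'   `percent_identity`.
#' @export
classify_reads <- function(reads, db, min_identity = 80,
                           scoring = align_scoring()) {
  stopifnot(nrow(db) >= 1)
  res <- purrr::map(reads$sequence, function(s) {
    hits <- best_hits(s, db, k = nrow(db), scoring = scoring)
    top <- hits[1, ]
    tied <- hits$percent_identity == top$percent_identity &
      hits$mismatches == top$mismatches
    genus <- if (top$percent_identity < min_identity ||
                 length(unique(hits$genus[tied])) > 1) NA_character_
             else top$genus
    list(genus = genus, identity = top$percent_identity)
  })
  tibble(read_id = reads$read_id,
         genus = vapply(res, `[[`, "", "genus"),
         percent_identity = vapply(res, `[[`, 0, "identity"))
}

#' Determine the dominant genus of a read subsample
#'
#' The stop rule of the screening stage: each subsampled read votes for the
#' genus of its best database hit, and the pipeline proceeds only when one
#' genus claims strictly more than `threshold` (default 50%) of the
#' subsample. Unassignable reads keep their place in the denominator, so
#' junk reads count against dominance.
#'
#' @param sample A reads tibble (typically the output of
#'   [subsample_reads()]).
#' @param db A `centroid_db` tibble.
#' @param threshold Dominance threshold as a fraction of the subsample.
#' @param min_identity Per-read assignment floor, see [classify_reads()].
#' @param scoring An [align_scoring()] scheme.
#' @return An object of class `genus_call`: list with `genus` (NA when
#'   halted), `genus_read_count`, `subsample_size`, `fraction`, `halted`,
#'   and `counts`, a per-genus tally tibble including the unassigned count.
#' @export
dominant_genus <- function(sample, db, threshold = 0.5, min_identity = 80,
                           scoring = align_scoring()) {
  if (nrow(sample) == 0) abort("empty read sample: nothing to screen")
  cls <- classify_reads(sample, db, min_identity = min_identity,
                        scoring = scoring)
  counts <- cls |>
    dplyr::count(.data$genus, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$genus)
  assigned <- counts[!is.na(counts$genus), , drop = FALSE]
  n_total <- nrow(sample)
  if (nrow(assigned) == 0) {
    top_genus <- NA_character_; top_n <- 0L
  } else {
    top_genus <- assigned$genus[1]; top_n <- assigned$n[1]
  }
  fraction <- top_n / n_total
  halted <- !(fraction > threshold)
  structure(list(genus = if (halted) NA_character_ else top_genus,
                 top_genus = top_genus,
                 genus_read_count = as.integer(top_n),
                 subsample_size = as.integer(n_total),
                 fraction = fraction, halted = halted, counts = counts),
            class = "genus_call")
}

#' @export
print.genus_call <- function(x, ...) {
  if (x$halted) {
    cat(sprintf(
      "<genus_call> HALTED: no genus exceeds the dominance threshold (best: %s, %.1f%% of %d reads)\n",
      x$top_genus %||% "none", 100 * x$fraction, x$subsample_size))
  } else {
    cat(sprintf("<genus_call> %s: %d/%d reads (%.1f%%)\n", x$genus,
                x$genus_read_count, x$subsample_size, 100 * x$fraction))
  }
  invisible(x)
}
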