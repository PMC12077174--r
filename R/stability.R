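# Read-subset consensus-stability analysis: prefix subsets, Hamming distance
# to the all-reads ("expected") consensus, and the minimum-read rule.

#' Expected consensus from all reads of a sample
#'
#' The consensus built from every quality-passed read, which anchors the
#' stability curve: subsets are compared against it.
#'
#' @param reads A reads tibble of QC-passed reads.
#' @param profile A `genus_profile`.
#' @param params A [consensus_params()] bundle.
#' @param min_identity Read placement floor, see [accumulate_frequencies()].
#' @return A `consensus_seq`.
#' @export
expected_consensus <- function(reads, profile, params = consensus_params(),
                               min_identity = 80) {
  freq <- accumulate_frequencies(reads, profile, min_identity = min_identity)
  call_consensus(freq, params)
}

#' Hamming distance between two consensus sequences
#'
#' For equal-length sequences this is the plain count of differing
#' positions. Sequences of unequal length are first aligned globally and the
#' distance is the number of substitution columns plus gap columns. Masked
#' `N` positions compare unequal to every base (and equal to `N`), so
#' depth-driven masking surfaces as distance. Zero if and only if the
#' sequences are identical.
#'
#' @param a,b `consensus_seq` objects or DNA strings.
#' @param scoring Scoring used when an alignment is needed.
#' @return A non-negative integer.
#' @export
hamming_distance <- function(a, b, scoring = align_scoring()) {
  sa <- toupper(if (inherits(a, "consensus_seq")) as.character(a) else a)
  sb <- toupper(if (inherits(b, "consensus_seq")) as.character(b) else b)
  if (nchar(sa) == 0 || nchar(sb) == 0) abort("empty sequence")
  if (nchar(sa) == nchar(sb)) {
    ca <- strsplit(sa, "")[[1]]
    cb <- strsplit(sb, "")[[1]]
    return(sum(ca != cb))
  }
  aln <- align_global(sa, sb, scoring)
  ca <- strsplit(aln$aligned_query, "")[[1]]
  cb <- strsplit(aln$aligned_target, "")[[1]]
  sum(ca != cb)
}

#' Consensus stability over growing prefix read subsets
#'
#' Reproduces the read-requirement analysis: the reads are taken in file
#' order, the first `increment` reads form the first subset, the first
#' `2 * increment` the second, and so on up to `max_reads` or the total read
#' count, whichever is smaller. Each subset's consensus is compared to the
#' expected (all-reads) consensus by [hamming_distance()]. A subset too
#' shallow to produce a consensus is recorded with `NA` distance.
#'
#' @param reads QC-passed reads in original file order (subsets are
#'   prefixes, not random samples).
#' @param profile A `genus_profile`.
#' @param params A [stability_params()] bundle.
#' @param min_identity Read placement floor.
#' @return A `stability_curve` tibble: `subset_size`, `hd`, `identical`;
#'   attribute `expected` holds the expected `consensus_seq`.
#' @export
stability_series <- function(reads, profile, params = stability_params(),
                             min_identity = 80) {
  stopifnot(inherits(params, "stability_params"))
  n <- nrow(reads)
  expected <- expected_consensus(reads, profile, params$consensus,
                                 min_identity = min_identity)
  sizes <- seq(params$increment, params$max_reads, by = params$increment)
  sizes <- sizes[sizes < n]
  last <- min(n, params$max_reads)
  if (length(sizes) == 0 || sizes[length(sizes)] < last) {
    sizes <- c(sizes, last)
  }
  rows <- purrr::map(sizes, function(s) {
    cs <- tryCatch(
      expected_consensus(reads[seq_len(s), , drop = FALSE], profile,
                         params$consensus, min_identity = min_identity),
      error = function(e) NULL)
    if (is.null(cs)) {
      tibble(subset_size = s, hd = NA_integer_, identical = FALSE)
    } else {
      hd <- hamming_distance(cs, expected)
      tibble(subset_size = s, hd = as.integer(hd), identical = hd == 0L)
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "expected") <- expected
  class(out) <- c("stability_curve", class(out))
  out
}

#' Minimum read count for a stable consensus
#'
#' Operationalizes the "where the curves flatten" criterion: the smallest
#' subset size from which every curve stays within `tolerance` base pairs of
#' its expected consensus for that subset and every larger one. The default
#' tolerance of 4 bp reflects the observed residual differences that do not
#' change an identification. If no size qualifies, the largest observed size
#' is returned flagged as not stable.
#'
#' @param curves A `stability_curve` or list of them.
#' @param tolerance Maximum tolerated Hamming distance in base pairs.
#' @return A one-row tibble: `min_reads`, `stable`.
#' @export
min_reads_for_stability <- function(curves, tolerance = 4L) {
  if (inherits(curves, "stability_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1)
  sizes <- sort(unique(unlist(lapply(curves, `[[`, "subset_size"))))
  ok_from <- function(s) {
    all(vapply(curves, function(cv) {
      tail_hd <- cv$hd[cv$subset_size >= s]
      length(tail_hd) == 0 ||
        (!anyNA(tail_hd) && all(tail_hd <= tolerance))
    }, TRUE))
  }
  for (s in sizes) {
    if (ok_from(s)) {
      return(tibble(min_reads = as.integer(s), stable = TRUE))
    }
  }
  tibble(min_reads = as.integer(sizes[length(sizes)]), stable = FALSE)
}

#' Export a stability curve as TSV
#'
#' @param curve A `stability_curve` tibble.
#' @param path Output path.
#' @export
write_stability_tsv <- function(curve, path) {
  readr::write_tsv(as_tibble(curve), path, progress = FALSE)
  invisible(path)
}
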