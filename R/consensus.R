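# Genus profile construction (center-star MSA) and cutoff-based consensus
# calling over the per-column frequency matrix.

# number of '-' characters in the aligned center row between consecutive
# center residues; slot p (0..L) sits between residue p and p+1
insertion_slots <- function(center_aligned_chars, L) {
  is_res <- center_aligned_chars != "-"
  resid <- cumsum(is_res)
  tabulate(resid[!is_res] + 1L, nbins = L + 1L)
}

expand_star_row <- function(center_aligned_chars, seq_aligned_chars,
                            ins_master, L) {
  is_res <- center_aligned_chars != "-"
  resid <- cumsum(is_res)
  slot_of_gap <- resid[!is_res]                    # 0..L
  gap_chars <- seq_aligned_chars[!is_res]
  slots <- split(gap_chars, factor(slot_of_gap, levels = 0:L))
  pads <- mapply(function(ch, w) c(ch, rep("-", w - length(ch))),
                 slots, ins_master, SIMPLIFY = FALSE)
  res_chars <- seq_aligned_chars[is_res]           # length L
  pieces <- vector("list", 2L * L + 1L)
  pieces[seq(1L, 2L * L + 1L, by = 2L)] <- pads
  if (L > 0) pieces[seq(2L, 2L * L, by = 2L)] <- as.list(res_chars)
  unlist(pieces, use.names = FALSE)
}

#' Build a genus-specific alignment profile from centroid sequences
#'
#' All centroids of the screened genus are multiply aligned by the
#' center-star method: the centroid with the greatest summed pairwise
#' alignment score to the others is taken as the center, every other
#' centroid is aligned globally to it, and the pairwise alignments are merged
#' into one gapped profile. The profile reflects the intra-genus diversity of
#' the reference sequences and fixes the coordinate system in which read
#' frequencies are accumulated. With a single centroid the profile is that
#' sequence.
#'
#' @param centroids A `centroid_db` tibble (or subset) whose records all
#'   share one genus.
#' @param scoring An [align_scoring()] scheme.
#' @return An object of class `genus_profile`: list with `genus`,
#'   `accessions`, `rows` (named gapped strings, one per centroid), `ncol`,
#'   `majority` (ungapped column-majority string used as alignment target)
#'   and `col_map` (profile column of each majority-string position).
#' @export
build_genus_profile <- function(centroids, scoring = align_scoring()) {
  stopifnot(nrow(centroids) >= 1)
  if (length(unique(centroids$genus)) != 1) {
    abort("profile construction requires centroids from a single genus")
  }
  seqs <- setNames(toupper(centroids$sequence), centroids$accession)
  n <- length(seqs)
  if (n == 1) {
    rows <- seqs
  } else {
    score_sum <- numeric(n)
    for (a in seq_len(n - 1)) {
      for (b in seq(a + 1, n)) {
        s <- align_global(seqs[a], seqs[b], scoring)$score
        score_sum[a] <- score_sum[a] + s
        score_sum[b] <- score_sum[b] + s
      }
    }
    # center: maximal summed score, ties by accession order for determinism
    center_i <- order(-score_sum, names(seqs))[1]
    center <- seqs[[center_i]]
    L <- nchar(center)
    others <- seqs[-center_i]
    alns <- lapply(others, function(s) {
      a <- align_global(s, center, scoring)
      list(center = strsplit(a$aligned_target, "")[[1]],
           seq = strsplit(a$aligned_query, "")[[1]])
    })
    ins <- lapply(alns, function(a) insertion_slots(a$center, L))
    ins_master <- Reduce(pmax, ins, rep(0L, L + 1L))
    center_chars <- strsplit(center, "")[[1]]
    rows_chars <- c(
      setNames(list(expand_star_row(center_chars, center_chars,
                                    ins_master, L)), names(seqs)[center_i]),
      mapply(function(a, ins_i) {
        expand_star_row(a$center, a$seq, ins_master, L)
      }, alns, ins, SIMPLIFY = FALSE))
    rows <- vapply(rows_chars, paste, "", collapse = "")
    rows <- rows[names(seqs)]                      # original record order
  }
  mat <- do.call(rbind, strsplit(rows, ""))
  ncol_profile <- ncol(mat)
  majority_chars <- apply(mat, 2, function(col) {
    tab <- table(col)
    bases <- tab[names(tab) != "-"]
    if (length(bases) == 0) return("-")
    best <- names(bases)[bases == max(bases)][1]   # alphabetical tie-break
    gapn <- if ("-" %in% names(tab)) tab[["-"]] else 0L
    if (gapn > max(bases)) "-" else best           # base wins exact ties
  })
  keep <- majority_chars != "-"
  structure(list(genus = centroids$genus[1],
                 accessions = centroids$accession,
                 rows = rows, ncol = ncol_profile,
                 majority = paste(majority_chars[keep], collapse = ""),
                 col_map = which(keep)),
            class = "genus_profile")
}

#' @export
print.genus_profile <- function(x, ...) {
  cat(sprintf("<genus_profile> %s: %d centroid(s), %d columns\n",
              x$genus, length(x$accessions), x$ncol))
  invisible(x)
}

#' Accumulate read base frequencies over a genus profile
#'
#' Every quality-passed read (not just the screening subsample) is aligned
#' semi-globally to the profile's column-majority string; its bases and
#' deletions are tallied into the profile columns it covers. Read insertions
#' relative to the profile are dropped — the consensus is defined over the
#' profile's coordinate system. Reads aligning at less than `min_identity`
#' percent identity are skipped and counted in the attributes.
#'
#' @param reads A reads tibble of QC-passed reads.
#' @param profile A `genus_profile`.
#' @param min_identity Placement floor in percent identity.
#' @param scoring An [align_scoring()] scheme.
#' @return A `freq_matrix` tibble with one row per profile column: `column`,
#'   `A`, `C`, `G`, `T`, `gap`, `depth`; attributes `n_reads_used`,
#'   `n_reads_skipped` and `genus`.
#' @export
accumulate_frequencies <- function(reads, profile, min_identity = 80,
                                   scoring = align_scoring()) {
  stopifnot(inherits(profile, "genus_profile"))
  counts <- matrix(0L, nrow = 5, ncol = profile$ncol,
                   dimnames = list(c("A", "C", "G", "T", "gap"), NULL))
  col_map <- as.integer(profile$col_map)
  used <- 0L; skipped <- 0L
  for (s in reads$sequence) {
    aln <- align_semiglobal(s, profile$majority, scoring)
    if (aln$percent_identity < min_identity) {
      skipped <- skipped + 1L
      next
    }
    tally_alignment_cpp(counts, aln$aligned_query, aln$aligned_target,
                        aln$target_start, col_map)
    used <- used + 1L
  }
  out <- tibble(column = seq_len(profile$ncol),
                A = counts["A", ], C = counts["C", ], G = counts["G", ],
                T = counts["T", ], gap = counts["gap", ])
  out$depth <- out$A + out$C + out$G + out$T + out$gap
  attr(out, "n_reads_used") <- used
  attr(out, "n_reads_skipped") <- skipped
  attr(out, "genus") <- profile$genus
  class(out) <- c("freq_matrix", class(out))
  out
}

#' Call a cutoff-based consensus from a frequency matrix
#'
#' Implements the per-position interpretation rule of the long-read
#' consensus: at every profile column covered by at least `min_depth` reads,
#' the bases (and the gap state) whose frequency among covering reads
#' reaches `interpretation_cutoff` form the call set. A single base is
#' emitted as is; several bases collapse to their IUPAC ambiguity code; a
#' dominant gap deletes the column from the consensus (a gap tying with a
#' base loses). Columns below `min_depth` are trimmed at the ends of the
#' profile and masked as `N` internally; columns where no base reaches the
#' cutoff are emitted as `N`. The emitted sequence never contains gap
#' characters.
#'
#' @param freq A `freq_matrix` tibble from [accumulate_frequencies()].
#' @param params A [consensus_params()] bundle (40% cutoff, depth 5 by
#'   default).
#' @return An object of class `consensus_seq`: list with `sequence`,
#'   `per_position_depth`, `masked_positions` (low-depth `N`s, consensus
#'   coordinates), `no_call_positions`, `profile_columns` and `length`.
#' @export
call_consensus <- function(freq, params = consensus_params()) {
  stopifnot(inherits(params, "consensus_params"))
  depth <- freq$depth
  called <- depth >= params$min_depth
  if (!any(called)) {
    abort(paste0("no consensus obtainable: no profile column is covered by ",
                 "at least ", params$min_depth, " reads"))
  }
  window <- seq(min(which(called)), max(which(called)))
  seq_chars <- character(0)
  pos_depth <- integer(0)
  pos_col <- integer(0)
  masked <- integer(0)
  no_call <- integer(0)
  base_counts <- as.matrix(freq[, c("A", "C", "G", "T")])
  gap_counts <- freq$gap
  for (j in window) {
    d <- depth[j]
    if (d < params$min_depth) {
      seq_chars <- c(seq_chars, "N")
      pos_depth <- c(pos_depth, d)
      pos_col <- c(pos_col, j)
      masked <- c(masked, length(seq_chars))
      next
    }
    f_base <- base_counts[j, ] / d
    f_gap <- gap_counts[j] / d
    call_set <- names(f_base)[f_base >= params$interpretation_cutoff]
    gap_in_set <- f_gap >= params$interpretation_cutoff
    if (gap_in_set && f_gap > max(f_base)) next    # dominant gap: deletion
    if (length(call_set) == 0) {
      char <- "N"
      no_call_here <- TRUE
    } else {
      char <- if (length(call_set) == 1) call_set else iupac_code(call_set)
      no_call_here <- FALSE
    }
    seq_chars <- c(seq_chars, char)
    pos_depth <- c(pos_depth, d)
    pos_col <- c(pos_col, j)
    if (no_call_here) no_call <- c(no_call, length(seq_chars))
  }
  if (length(seq_chars) == 0) {
    abort("no consensus obtainable: every callable column was gap-dominant")
  }
  structure(list(sequence = paste(seq_chars, collapse = ""),
                 per_position_depth = pos_depth,
                 masked_positions = masked,
                 no_call_positions = no_call,
                 profile_columns = pos_col,
                 length = length(seq_chars)),
            class = "consensus_seq")
}

#' @export
as.character.consensus_seq <- function(x, ...) x$sequence

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf(
    "<consensus_seq> %d nt (%d masked, %d uncalled), median depth %d\n",
    x$length, length(x$masked_positions), length(x$no_call_positions),
    as.integer(stats::median(x$per_position_depth))))
  invisible(x)
}

#' Export a frequency matrix as TSV
#'
#' @param freq A `freq_matrix` tibble.
#' @param path Output path.
#' @export
write_frequency_tsv <- function(freq, path) {
  readr::write_tsv(as_tibble(freq), path, progress = FALSE)
  invisible(path)
}
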