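# Independent oracles used across the suite. These deliberately share no
# code with the package: the aligner oracle is a plain-R full-matrix dynamic
# program, and the interpretation oracle is a scalar re-statement of the
# decision ladder.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# full O(nm) affine-gap DP, overlap (free end gaps) scoring; score only
oracle_overlap_score <- function(q, t, match = 2, mismatch = -3,
                                 gap_open = 5, gap_extend = 2) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc)
  m <- length(tc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0
  M[, 1] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      s <- if (qc[i - 1] == tc[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    }
  }
  max(M[n + 1, ], M[, m + 1])
}

# scalar restatement of the interpretation ladder for the exhaustive grid
oracle_interpret_level <- function(identity, separation, group, mode,
                                   species_min = 99, genus_min = 97,
                                   family_min = 95, actino_min = 99.6,
                                   actino_sep = 0.4, myco_min = 100) {
  sp_floor <- switch(group, general = species_min,
                     actinomycete = actino_min, mycobacterium = myco_min)
  sep_ok <- if (group == "actinomycete") {
    if (mode == "modified") TRUE else separation > actino_sep
  } else {
    separation > 0
  }
  if (identity >= sp_floor && sep_ok) return("species")
  if (identity >= genus_min) return("genus")
  if (identity >= family_min) return("family")
  "no_id"
}

# minimal species-match rows for interpretation tests
make_matches <- function(identities, species, genera = NULL,
                         match_length = 1400L) {
  genera <- genera %||% vapply(strsplit(species, " "), `[`, "", 1)
  tibble::tibble(
    accession = sprintf("ACC%02d", seq_along(identities)),
    genus = genera,
    species = species,
    percent_identity = identities,
    mismatches = as.integer(round((100 - identities) / 100 * match_length)),
    match_length = as.integer(rep(match_length, length.out =
                                    length(identities))),
    target_length = 1500L,
    query_length = 1500L,
    score = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reads tibble from plain sequences at uniform quality
reads_from_seqs <- function(seqs, qual = 20L) {
  tibble::tibble(
    read_id = sprintf("r%04d", seq_along(seqs)),
    sequence = seqs,
    quals = lapply(nchar(seqs), function(L) rep(as.integer(qual), L)))
}

# toy single-genus database from explicit sequences
toy_db <- function(seqs, genus = "GenusA",
                   species = paste(genus, paste0("sp", seq_along(seqs)))) {
  ont16s::read_reference_fasta(write_ref_fasta_tmp(seqs, genus, species))
}

write_ref_fasta_tmp <- function(seqs, genus, species) {
  path <- tempfile(fileext = ".fasta")
  epithet <- vapply(strsplit(species, " "), function(x)
    paste(x[-1], collapse = " "), "")
  writeLines(as.vector(rbind(
    paste0(">T", sprintf("%03d", seq_along(seqs)), "|", genus, "|", epithet),
    seqs)), path)
  path
}

write_fastq_tmp <- function(lines) {
  path <- tempfile(fileext = ".fastq")
  writeLines(lines, path)
  path
}
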