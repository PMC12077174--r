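#' Decode and encode Phred+33 quality strings
#'
#' Modern nanopore FASTQ uses the Sanger/Illumina-1.8 convention where the
#' ASCII character `!` encodes Phred score 0. Scores outside 0..93 cannot be
#' represented and are rejected.
#'
#' @param qual A single quality string.
#' @param scores An integer vector of Phred scores.
#' @return `phred_decode()` returns an integer vector of scores;
#'   `phred_encode()` returns a single quality string.
#' @examples
#' phred_decode("IIII")
#' phred_encode(c(40L, 40L))
#' @export
phred_decode <- function(qual) {
  stopifnot(is.character(qual), length(qual) == 1)
  codes <- utf8ToInt(qual)
  if (length(codes) > 0 && (min(codes) < 33L || max(codes) > 126L)) {
    abort("quality string contains characters outside the Phred+33 range")
  }
  codes - 33L
}

#' @rdname phred_decode
#' @export
phred_encode <- function(scores) {
  scores <- as.integer(scores)
  if (length(scores) > 0 && (min(scores) < 0L || max(scores) > 93L)) {
    abort("Phred scores must lie in 0..93 for Phred+33 encoding")
  }
  intToUtf8(scores + 33L)
}

validate_dna <- function(sequence, what = "sequence", allow_iupac = FALSE) {
  sequence <- toupper(sequence)
  pattern <- if (allow_iupac) "^[ACGTMRWSYKVHDBN]*$" else "^[ACGTN]*$"
  bad <- !grepl(pattern, sequence)
  if (any(bad)) {
    abort(paste0(what, " contains characters outside the DNA alphabet (",
                 "first offender: record ", which(bad)[1], ")"))
  }
  sequence
}

#' Read a 4-line FASTQ file of long amplicon reads
#'
#' Strict 4-line-per-record FASTQ with Phred+33 qualities (the format emitted
#' by current nanopore basecallers for "passed" reads). Lowercase bases are
#' uppercased; characters outside `A/C/G/T/N` are rejected rather than
#' guessed at. A record whose quality string length differs from its sequence
#' length raises a parse error naming the record.
#'
#' @param path Path to an uncompressed FASTQ file, one barcoded sample per
#'   file.
#' @return A tibble with columns `read_id` (character), `sequence`
#'   (character) and `quals` (list of integer Phred scores, one per base).
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    return(tibble(read_id = character(), sequence = character(),
                  quals = list()))
  }
  if (length(lines) %% 4 != 0) {
    abort(paste0("malformed FASTQ (", path, "): ", length(lines),
                 " lines is not a multiple of 4"))
  }
  idx <- seq(1, length(lines), by = 4)
  headers <- lines[idx]
  seqs <- lines[idx + 1]
  plus <- lines[idx + 2]
  quals <- lines[idx + 3]
  if (any(!startsWith(headers, "@"))) {
    abort(paste0("malformed FASTQ record ", which(!startsWith(headers, "@"))[1],
                 ": header does not start with '@'"))
  }
  if (any(!startsWith(plus, "+"))) {
    abort(paste0("malformed FASTQ record ", which(!startsWith(plus, "+"))[1],
                 ": separator line does not start with '+'"))
  }
  bad_len <- nchar(seqs) != nchar(quals)
  if (any(bad_len)) {
    k <- which(bad_len)[1]
    abort(paste0("malformed FASTQ record ", k, " ('",
                 sub("^@", "", strsplit(headers[k], "[ \t]")[[1]][1]),
                 "'): sequence and quality lengths differ"))
  }
  if (any(nchar(seqs) == 0)) {
    abort(paste0("malformed FASTQ record ", which(nchar(seqs) == 0)[1],
                 ": empty sequence"))
  }
  ids <- sub("^@", "", vapply(strsplit(headers, "[ \t]"), `[`, "", 1))
  tibble(
    read_id = ids,
    sequence = validate_dna(seqs, "read sequence"),
    quals = lapply(quals, phred_decode)
  )
}

#' @rdname read_fastq
#' @param reads A reads tibble as returned by `read_fastq()` or
#'   [simulate_reads()].
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quals") %in% names(reads)))
  qual_str <- vapply(reads$quals, phred_encode, "")
  out <- rbind(paste0("@", reads$read_id), reads$sequence, "+", qual_str)
  writeLines(as.vector(out), path)
  invisible(path)
}

parse_centroid_headers <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 2 | n_fields > 3)) {
    abort(paste0("reference FASTA header does not follow ",
                 "'accession|genus|species_epithet' or ",
                 "'accession|Genus species': '",
                 headers[which(n_fields < 2 | n_fields > 3)[1]], "'"))
  }
  accession <- vapply(parts, `[`, "", 1)
  rest <- lapply(parts, function(p) trimws(p[-1]))
  genus <- character(length(parts))
  species <- character(length(parts))
  for (k in seq_along(rest)) {
    r <- rest[[k]]
    if (length(r) == 2) {            # accession|genus|epithet
      genus[k] <- r[1]
      species[k] <- paste(r[1], r[2])
    } else {                         # accession|Genus species
      toks <- strsplit(r, "[ ]+")[[1]]
      if (length(toks) < 2) {
        abort(paste0("reference FASTA header species field is not a ",
                     "binomial: '", headers[k], "'"))
      }
      genus[k] <- toks[1]
      species[k] <- paste(toks, collapse = " ")
    }
  }
  tibble(accession = accession, genus = genus, species = species)
}

new_centroid_db <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("accession", "genus", "species") %in% names(df)))
  if (!"sequence" %in% names(df)) abort("centroid table lacks sequences")
  if (anyDuplicated(df$accession) > 0) {
    abort(paste0("duplicate accession in reference database: '",
                 df$accession[anyDuplicated(df$accession)], "'"))
  }
  first_tok <- vapply(strsplit(df$species, " "), `[`, "", 1)
  if (any(first_tok != df$genus)) {
    abort("genus must be the first token of the species binomial")
  }
  if (any(nchar(df$sequence) == 0)) abort("empty centroid sequence")
  if (nrow(df) == 0) abort("reference database must contain at least one record")
  df$sequence <- validate_dna(df$sequence, "centroid sequence",
                              allow_iupac = TRUE)
  class(df) <- c("centroid_db", class(df))
  df
}

#' Read a centroid-style 16S reference database
#'
#' A curated reference carries one representative ("centroid") sequence per
#' species group. Two header dialects are accepted:
#' `>accession|genus|species_epithet` and `>accession|Genus species`.
#' Alternatively, plain FASTA headers (`>accession`) can be combined with a
#' taxonomy TSV holding columns `accession`, `genus`, `species`.
#'
#' @param path Path to the reference FASTA (wrapped or unwrapped).
#' @param taxonomy Optional path to a taxonomy TSV mapping accession to genus
#'   and species.
#' @return A `centroid_db` tibble with columns `accession`, `genus`,
#'   `species`, `sequence`.
#' @export
read_reference_fasta <- function(path, taxonomy = NULL) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  if (is.null(taxonomy)) {
    tax <- parse_centroid_headers(headers)
  } else {
    accession <- vapply(strsplit(headers, "[| \t]"), `[`, "", 1)
    map <- readr::read_tsv(taxonomy, show_col_types = FALSE,
                           progress = FALSE)
    stopifnot(all(c("accession", "genus", "species") %in% names(map)))
    miss <- setdiff(accession, map$accession)
    if (length(miss) > 0) {
      abort(paste0("taxonomy file lacks accession(s): ",
                   paste(head(miss, 3), collapse = ", ")))
    }
    tax <- tibble(accession = accession) |>
      dplyr::left_join(as_tibble(map), by = "accession") |>
      dplyr::select("accession", "genus", "species")
  }
  tax$sequence <- unname(seqs)
  new_centroid_db(tax)
}

#' @rdname read_reference_fasta
#' @param db A `centroid_db` tibble.
#' @export
write_reference_fasta <- function(db, path) {
  set <- Biostrings::BStringSet(setNames(
    db$sequence,
    paste(db$accession, db$genus,
          vapply(strsplit(db$species, " "), function(x)
            paste(x[-1], collapse = " "), ""),
          sep = "|")))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Genus index of a reference database
#'
#' @param db A `centroid_db` tibble.
#' @return A named list mapping each genus to the row positions of its
#'   centroid records.
#' @export
genus_index <- function(db) {
  split(seq_len(nrow(db)), db$genus)
}

#' Write a consensus sequence as FASTA
#'
#' @param consensus A `consensus_seq` object (see [call_consensus()]).
#' @param path Output file path.
#' @param name Sequence name to place in the FASTA header.
#' @export
write_consensus_fasta <- function(consensus, path, name = "consensus") {
  set <- Biostrings::BStringSet(setNames(as.character(consensus), name))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
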