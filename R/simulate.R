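# Synthetic-data generator: centroid-style reference databases with
# controlled divergence, nanopore-like long reads under an explicit error
# model, and Sanger-like ~500 nt fragments. All randomness flows from
# explicit seed arguments; the global RNG state is never touched.

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

# substitute exactly round(rate * L) positions to a different base
mutate_sites <- function(sequence, rate) {
  chars <- strsplit(sequence, "")[[1]]
  k <- round(rate * length(chars))
  if (k == 0) return(sequence)
  pos <- sample.int(length(chars), k)
  chars[pos] <- vapply(chars[pos],
                       function(b) sample(setdiff(DNA_BASES, b), 1), "")
  paste(chars, collapse = "")
}

#' Generate a centroid-style reference database with controlled divergence
#'
#' Emulates a curated species-representative 16S reference: a common root
#' sequence is drawn uniformly over A/C/G/T, each genus ancestor is derived
#' from it, and each species centroid from its genus ancestor, so that the
#' realized pairwise substitution divergence between congeneric species is
#' approximately `intra_divergence` and between genera at least
#' `inter_divergence` (each lineage is mutated at half the requested
#' pairwise rate). Deterministic for a fixed seed.
#'
#' @param n_genera,species_per_genus Database shape.
#' @param intra_divergence Target pairwise substitution fraction between
#'   congeneric species.
#' @param inter_divergence Target pairwise substitution fraction between
#'   genera; must exceed `intra_divergence`.
#' @param seq_length Centroid length in nucleotides (default 1,500, the
#'   full-length 16S rRNA gene).
#' @param seed RNG seed.
#' @return A list with `db` (a `centroid_db` tibble) and `truth` (tibble
#'   `species`, `sequence` of the true template per species).
#' @export
make_reference <- function(n_genera = 3L, species_per_genus = 3L,
                           intra_divergence = 0.01,
                           inter_divergence = 0.08,
                           seq_length = 1500L, seed = 1L) {
  stopifnot(intra_divergence < inter_divergence, seq_length >= 100)
  withr::with_seed(seed, {
    root <- random_dna(seq_length)
    rows <- list()
    for (g in seq_len(n_genera)) {
      genus <- paste0("Genus", LETTERS[g])
      ancestor <- mutate_sites(root, inter_divergence / 2)
      for (s in seq_len(species_per_genus)) {
        epithet <- paste0("species", letters[s])
        rows[[length(rows) + 1L]] <- tibble(
          accession = sprintf("SIM%02d%02d", g, s),
          genus = genus,
          species = paste(genus, epithet),
          sequence = mutate_sites(ancestor, intra_divergence / 2))
      }
    }
    db <- new_centroid_db(dplyr::bind_rows(rows))
    list(db = db, truth = tibble(species = db$species,
                                 sequence = db$sequence))
  })
}

#' Construct a challenge-organism reference
#'
#' Builds a genus holding two congeneric species whose sequences are
#' identical over the first `region_end` bases and differ only beyond it —
#' the situation where sequencing the first ~500 nt cannot resolve the
#' species but the full-length gene can. An outgroup genus is added so the
#' genus screen has something to reject.
#'
#' @param seq_length Template length.
#' @param n_diffs Substitutions placed beyond `region_end`.
#' @param region_end Last position of the conserved 5' region (default 500,
#'   the classic short-read window).
#' @param seed RNG seed.
#' @return As [make_reference()]; the first species (`GenusA speciesa`) is
#'   the intended truth.
#' @export
make_challenge_reference <- function(seq_length = 1500L, n_diffs = 10L,
                                     region_end = 500L, seed = 1L) {
  stopifnot(region_end < seq_length, n_diffs >= 1)
  withr::with_seed(seed, {
    a <- random_dna(seq_length)
    chars <- strsplit(a, "")[[1]]
    pos <- sample(seq(region_end + 1L, seq_length), n_diffs)
    chars[pos] <- vapply(chars[pos],
                         function(b) sample(setdiff(DNA_BASES, b), 1), "")
    b <- paste(chars, collapse = "")
    out <- mutate_sites(a, 0.08)
    db <- new_centroid_db(tibble(
      accession = c("CHA01", "CHA02", "OUT01"),
      genus = c("GenusA", "GenusA", "GenusB"),
      species = c("GenusA speciesa", "GenusA speciesb", "GenusB speciesa"),
      sequence = c(a, b, out)))
    list(db = db, truth = tibble(species = db$species,
                                 sequence = db$sequence))
  })
}

simulate_one_read <- function(tchars, model) {
  L <- length(tchars)
  keep <- runif(L) >= model$deletion_rate
  bases <- tchars[keep]
  n_del <- L - length(bases)
  subm <- runif(length(bases)) < model$substitution_rate
  if (any(subm)) {
    bases[subm] <- vapply(bases[subm],
                          function(b) sample(setdiff(DNA_BASES, b), 1), "")
  }
  insm <- runif(length(bases)) < model$insertion_rate
  if (any(insm)) {
    reps <- ifelse(insm, 2L, 1L)
    out <- rep(bases, reps)
    out[cumsum(reps)[insm]] <- sample(DNA_BASES, sum(insm), replace = TRUE)
  } else {
    out <- bases
  }
  if (model$read_length_sd > 0) {
    want <- round(rnorm(1, length(out), model$read_length_sd))
    want <- max(1L, min(length(out), want))
    out <- out[seq_len(want)]
  }
  list(sequence = paste(out, collapse = ""),
       n_sub = sum(subm), n_ins = sum(insm), n_del = n_del)
}

#' Simulate nanopore-like long reads from a template
#'
#' Each read is the template corrupted by independent per-base substitution,
#' insertion and deletion draws under the given [error_model()], with Phred
#' qualities drawn from a normal distribution. The applied per-read error
#' counts are retained as columns for oracle checks.
#'
#' @param template A DNA string (typically a species truth sequence).
#' @param n Number of reads.
#' @param model An [error_model()].
#' @param seed RNG seed.
#' @return A reads tibble: `read_id`, `sequence`, `quals`, plus applied
#'   error counts `n_sub`, `n_ins`, `n_del`.
#' @export
simulate_reads <- function(template, n, model = error_model(), seed = 1L) {
  stopifnot(nchar(template) > 0, n >= 1)
  tchars <- strsplit(toupper(template), "")[[1]]
  withr::with_seed(seed, {
    sims <- lapply(seq_len(n), function(i) simulate_one_read(tchars, model))
    seqs <- vapply(sims, `[[`, "", "sequence")
    quals <- lapply(nchar(seqs), function(L) {
      pmin(50L, pmax(1L, as.integer(round(
        rnorm(L, model$quality_mean, model$quality_sd)))))
    })
    tibble(read_id = sprintf("read_%05d", seq_len(n)),
           sequence = seqs, quals = quals,
           n_sub = vapply(sims, `[[`, 0L, "n_sub"),
           n_ins = vapply(sims, `[[`, 0L, "n_ins"),
           n_del = vapply(sims, `[[`, 0L, "n_del"))
  })
}

#' Simulate a Sanger-like short consensus fragment
#'
#' Returns the first `length` bases of the template (the classic ~500 nt
#' V1-V3 window), optionally with a small substitution rate. When the
#' template is shorter than `length` the whole template is returned with a
#' warning.
#'
#' @param template A DNA string.
#' @param length Fragment length (default 500).
#' @param error_rate Substitution fraction applied to the fragment.
#' @param seed RNG seed (used only when `error_rate > 0`).
#' @return A DNA string.
#' @export
simulate_sanger <- function(template, length = 500L, error_rate = 0,
                            seed = 1L) {
  template <- toupper(template)
  if (nchar(template) < length) {
    warn("template shorter than the requested fragment; returning it whole")
    frag <- template
  } else {
    frag <- substr(template, 1L, length)
  }
  if (error_rate > 0) {
    frag <- withr::with_seed(seed, mutate_sites(frag, error_rate))
  }
  frag
}
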