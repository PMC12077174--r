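# End-to-end drivers tying the modules into the two workflows: isolate
# identification from a FASTQ, and the read-subset stability analysis.

as_reads <- function(x) {
  if (is.character(x) && length(x) == 1) read_fastq(x) else as_tibble(x)
}

as_reference <- function(x, taxonomy = NULL) {
  if (is.character(x) && length(x) == 1) {
    read_reference_fasta(x, taxonomy)
  } else if (inherits(x, "centroid_db")) {
    x
  } else {
    new_centroid_db(x)
  }
}

genus_group <- function(genus, group_map = NULL) {
  if (!is.null(group_map) && genus %in% names(group_map)) {
    match.arg(group_map[[genus]],
              c("general", "actinomycete", "mycobacterium"))
  } else {
    "general"
  }
}

#' Run the full long-read identification pipeline on one sample
#'
#' Executes quality filtering, random subsampling, the dominant-genus
#' screen, genus-profile construction, frequency accumulation over all
#' passing reads, consensus calling, database matching, the match-length
#' exclusion and the CLSI-style interpretation. When no genus claims more
#' than the dominance threshold of the subsample the pipeline stops and the
#' returned object is flagged `halted` with no interpretation.
#'
#' @param fastq Path to a FASTQ file, or a reads tibble.
#' @param reference Path to a reference FASTA, or a `centroid_db` tibble.
#' @param config A [run_config()] bundle.
#' @param taxonomy Optional taxonomy TSV path (see
#'   [read_reference_fasta()]).
#' @param sample_id Label used in reports.
#' @return An object of class `id16s_run` with fields `genus_call`,
#'   `profile`, `freq`, `consensus`, `matches`, `excluded`,
#'   `interpretation`, `confidence`, `halted`, `log` (per-stage read
#'   counts) and `config`.
#' @export
run_identify <- function(fastq, reference, config = run_config(),
                         taxonomy = NULL, sample_id = "sample") {
  reads <- as_reads(fastq)
  db <- as_reference(reference, taxonomy)
  log <- list(reads_in = nrow(reads))
  passed <- filter_reads(reads, config$qc)
  log$reads_pass_qc <- nrow(passed)
  if (nrow(passed) == 0) abort("genus_screen: no read passes quality filtering")
  sub <- subsample_reads(passed, config$subsample_n, seed = config$seed)
  log$subsample_size <- nrow(sub)
  call <- dominant_genus(sub, db, threshold = config$dominance_threshold)
  log$dominant_genus <- call$genus
  log$dominance_fraction <- call$fraction
  base <- list(sample_id = sample_id, genus_call = call, log = log,
               config = config)
  if (call$halted) {
    out <- c(base, list(halted = TRUE, profile = NULL, freq = NULL,
                        consensus = NULL, matches = NULL, excluded = NULL,
                        interpretation = NULL, confidence = NA_real_))
    class(out) <- "id16s_run"
    return(out)
  }
  centroids <- db[db$genus == call$genus, , drop = FALSE]
  profile <- build_genus_profile(centroids)
  freq <- accumulate_frequencies(passed, profile)
  log$reads_placed <- attr(freq, "n_reads_used")
  consensus <- call_consensus(freq, config$consensus)
  matches <- rank_matches(consensus, db, k = 5L)
  filt <- apply_length_filter(matches, arm = config$arm,
                              params = config$interpretation)
  group <- genus_group(call$genus, config$group_map)
  interp <- interpret_matches(filt$kept, group = group,
                              params = config$interpretation)
  conf <- if (nrow(filt$kept) > 0) {
    confidence_score(filt$kept, call, consensus,
                     params = config$interpretation)
  } else {
    0
  }
  out <- c(base, list(halted = FALSE, profile = profile, freq = freq,
                      consensus = consensus, matches = filt$kept,
                      excluded = filt$excluded, interpretation = interp,
                      confidence = conf))
  out$log <- log
  class(out) <- "id16s_run"
  out
}

#' Identify a pre-built consensus (short-read arm)
#'
#' Matching plus interpretation only, for an externally produced sequence
#' such as a ~500 nt Sanger consensus.
#'
#' @param consensus A DNA string or `consensus_seq`.
#' @param reference Reference database (path or tibble).
#' @param config A [run_config()]; set `arm = "short"` for Sanger-style
#'   input.
#' @param group Organism group override; defaults to the top genus's entry
#'   in `config$group_map`.
#' @return An `id16s_run`-like object of class `id16s_run` (no read
#'   stages).
#' @export
identify_consensus <- function(consensus, reference,
                               config = run_config(arm = "short"),
                               group = NULL) {
  db <- as_reference(reference)
  matches <- rank_matches(consensus, db, k = 5L)
  filt <- apply_length_filter(matches, arm = config$arm,
                              params = config$interpretation)
  if (is.null(group)) {
    group <- if (nrow(filt$kept) > 0) {
      genus_group(filt$kept$genus[1], config$group_map)
    } else {
      "general"
    }
  }
  interp <- interpret_matches(filt$kept, group = group,
                              params = config$interpretation)
  conf <- if (nrow(filt$kept) > 0) {
    confidence_score(filt$kept, NULL, NULL, params = config$interpretation)
  } else {
    0
  }
  out <- list(sample_id = "consensus", genus_call = NULL, halted = FALSE,
              profile = NULL, freq = NULL, consensus = consensus,
              matches = filt$kept, excluded = filt$excluded,
              interpretation = interp, confidence = conf,
              log = list(), config = config)
  class(out) <- "id16s_run"
  out
}

#' @export
print.id16s_run <- function(x, ...) {
  if (isTRUE(x$halted)) {
    cat(sprintf("<id16s_run> %s: pipeline stopped, no dominant genus (best %.1f%%)\n",
                x$sample_id, 100 * x$genus_call$fraction))
    return(invisible(x))
  }
  cat(sprintf("<id16s_run> %s: %s%s (confidence %.2f)\n", x$sample_id,
              x$interpretation$level,
              if (is.na(x$interpretation$reported_taxon)) "" else
                paste0(" ", x$interpretation$reported_taxon),
              x$confidence))
  invisible(x)
}

#' Run the consensus-stability workflow on one sample
#'
#' Filters reads, screens for the dominant genus, then computes the
#' prefix-subset stability curve against the all-reads consensus.
#'
#' @inheritParams run_identify
#' @return A list of class `stability_run`: `genus_call`, `curve`
#'   (a `stability_curve`), `summary` (from [min_reads_for_stability()]).
#' @export
run_stability <- function(fastq, reference, config = run_config(),
                          taxonomy = NULL) {
  reads <- as_reads(fastq)
  db <- as_reference(reference, taxonomy)
  passed <- filter_reads(reads, config$qc)
  if (nrow(passed) == 0) abort("genus_screen: no read passes quality filtering")
  sub <- subsample_reads(passed, config$subsample_n, seed = config$seed)
  call <- dominant_genus(sub, db, threshold = config$dominance_threshold)
  if (call$halted) abort("pipeline stopped: no dominant genus")
  profile <- build_genus_profile(db[db$genus == call$genus, , drop = FALSE])
  curve <- stability_series(passed, profile, config$stability)
  structure(list(genus_call = call, curve = curve,
                 summary = min_reads_for_stability(curve)),
            class = "stability_run")
}

#' Run the two-arm comparison workflow
#'
#' @param pairs Path to a paired-levels TSV or a paired-results tibble.
#' @return A list of class `compare_run`: `crosstab`, `marginals`,
#'   `tests` (improvement tests at family/genus/species) and
#'   `concordance` (species and genus ranks).
#' @export
run_compare <- function(pairs) {
  if (is.character(pairs) && length(pairs) == 1) {
    pairs <- read_paired_levels(pairs)
  }
  tab <- cross_tabulate(pairs)
  tests <- dplyr::bind_rows(lapply(c("family", "genus", "species"),
                                   function(lv) {
    tst <- level_improvement_test(tab, lv)
    tibble(at_least = lv, b = tst$b, c = tst$c, p.value = tst$p.value)
  }))
  conc <- if (all(is.na(pairs$taxon_a)) || all(is.na(pairs$taxon_b))) {
    NULL
  } else {
    dplyr::bind_rows(concordance(pairs, "species"),
                     concordance(pairs, "genus"))
  }
  structure(list(crosstab = tab, marginals = crosstab_marginals(tab),
                 tests = tests, concordance = conc),
            class = "compare_run")
}

#' @export
print.compare_run <- function(x, ...) {
  print(x$crosstab)
  cat("\nImprovement tests (exact McNemar):\n")
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}

#' Write the identification result report
#'
#' Emits the machine-readable artifacts of one run into a directory:
#' `report.json` (summary, top-5 table, excluded matches, provenance block
#' with config hash and seed), `report.tsv` (the top-5 table),
#' `consensus.fasta` and `frequency.tsv`.
#'
#' @param run An `id16s_run`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_identify_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  provenance <- list(config_hash = rlang::hash(run$config),
                     seed = run$config$seed, stages = run$log)
  report <- list(
    sample_id = run$sample_id,
    halted = isTRUE(run$halted),
    level = if (isTRUE(run$halted)) "halted" else run$interpretation$level,
    reported_taxon = if (isTRUE(run$halted)) NA else
      run$interpretation$reported_taxon,
    rule_fired = if (isTRUE(run$halted)) "no_dominant_genus" else
      run$interpretation$rule_fired,
    confidence = run$confidence,
    matches = run$matches,
    excluded = run$excluded,
    provenance = provenance)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  if (!isTRUE(run$halted)) {
    readr::write_tsv(run$matches, file.path(dir, "report.tsv"),
                     progress = FALSE)
    write_consensus_fasta(run$consensus, file.path(dir, "consensus.fasta"),
                          name = run$sample_id)
    if (!is.null(run$freq)) {
      write_frequency_tsv(run$freq, file.path(dir, "frequency.tsv"))
    }
  }
  invisible(dir)
}
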