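#' Parameter constructors for the identification pipeline
#'
#' Small validated parameter bundles mirroring the knobs of the long-read 16S
#' identification workflow. Defaults follow the published pipeline
#' configuration: reads shorter than 20 nt or with mean Phred below 7 are
#' discarded, 1,000 reads are subsampled for the genus screen, a genus must
#' claim strictly more than 50% of the subsample, the consensus uses a 40%
#' per-position interpretation cutoff and a minimum depth of 5 reads, and the
#' stability analysis grows prefix subsets in 500-read increments up to
#' 20,500 reads.
#'
#' @param min_length Minimum read length in nucleotides kept by QC.
#' @param min_mean_phred Minimum arithmetic mean Phred score kept by QC.
#' @return A validated parameter list of class matching the constructor.
#' @name pipeline-params
NULL

#' @rdname pipeline-params
#' @export
qc_params <- function(min_length = 20L, min_mean_phred = 7) {
  stopifnot(min_length >= 1, min_mean_phred >= 0)
  structure(list(min_length = as.integer(min_length),
                 min_mean_phred = as.numeric(min_mean_phred)),
            class = "qc_params")
}

#' @rdname pipeline-params
#' @param interpretation_cutoff Minimum per-column base frequency for a base to
#'   enter the consensus call set (fraction of covering reads).
#' @param min_depth Minimum number of reads covering a column for it to be
#'   called at all.
#' @export
consensus_params <- function(interpretation_cutoff = 0.40, min_depth = 5L) {
  stopifnot(interpretation_cutoff > 0, interpretation_cutoff <= 1, min_depth >= 1)
  structure(list(interpretation_cutoff = as.numeric(interpretation_cutoff),
                 min_depth = as.integer(min_depth)),
            class = "consensus_params")
}

#' @rdname pipeline-params
#' @param family_min,genus_min,species_min Percent-identity floors for family,
#'   genus and species level identification of organisms in the general group.
#' @param actino_species_min Species-level identity floor for aerobic
#'   actinomycetes.
#' @param actino_separation Minimum identity separation (percentage points) to
#'   the next distinct species required for an actinomycete species call in
#'   standard mode.
#' @param myco_species_min Species-level identity floor for *Mycobacterium*.
#' @param min_match_len_long,min_match_len_short Matches with aligned span
#'   shorter than these are excluded before interpretation (long = full-length
#'   nanopore arm, short = ~500 nt Sanger arm).
#' @param mode `"standard"` applies the actinomycete separation clause;
#'   `"modified"` awards species level at `actino_species_min` irrespective of
#'   the separation.
#' @param family_map Optional named character vector mapping genus to family
#'   for family-level reporting.
#' @export
interpretation_params <- function(family_min = 95.0, genus_min = 97.0,
                                  species_min = 99.0,
                                  actino_species_min = 99.6,
                                  actino_separation = 0.4,
                                  myco_species_min = 100.0,
                                  min_match_len_long = 1250L,
                                  min_match_len_short = 400L,
                                  mode = c("standard", "modified"),
                                  family_map = NULL) {
  mode <- match.arg(mode)
  stopifnot(family_min <= genus_min, genus_min <= species_min, species_min <= 100)
  structure(list(family_min = family_min, genus_min = genus_min,
                 species_min = species_min,
                 actino_species_min = actino_species_min,
                 actino_separation = actino_separation,
                 myco_species_min = myco_species_min,
                 min_match_len_long = as.integer(min_match_len_long),
                 min_match_len_short = as.integer(min_match_len_short),
                 mode = mode, family_map = family_map),
            class = "interpretation_params")
}

#' @rdname pipeline-params
#' @param increment Subset-size step, in reads, for the stability series.
#' @param max_reads Largest prefix subset evaluated.
#' @param consensus Consensus parameters used for every subset.
#' @export
stability_params <- function(increment = 500L, max_reads = 20500L,
                             consensus = consensus_params()) {
  stopifnot(increment >= 1, max_reads %% increment == 0)
  structure(list(increment = as.integer(increment),
                 max_reads = as.integer(max_reads),
                 consensus = consensus),
            class = "stability_params")
}

#' @rdname pipeline-params
#' @param qc Quality-filter parameters, see [qc_params()].
#' @param subsample_n Number of reads randomly subsampled for the genus screen.
#' @param dominance_threshold Fraction of the subsample a genus must strictly
#'   exceed for the pipeline to continue.
#' @param interpretation Interpretation thresholds, see
#'   [interpretation_params()].
#' @param stability Stability-analysis parameters, see [stability_params()].
#' @param seed Seed driving the subsampling RNG.
#' @param arm `"long"` (full-length nanopore consensus) or `"short"`
#'   (~500 nt Sanger-style sequence); selects the match-length exclusion.
#' @param group_map Optional named character vector mapping genus to organism
#'   group (`"general"`, `"actinomycete"`, `"mycobacterium"`).
#' @export
run_config <- function(qc = qc_params(), subsample_n = 1000L,
                       dominance_threshold = 0.5,
                       consensus = consensus_params(),
                       interpretation = interpretation_params(),
                       stability = stability_params(),
                       seed = 1L, arm = c("long", "short"),
                       group_map = NULL) {
  arm <- match.arg(arm)
  stopifnot(subsample_n >= 1, dominance_threshold > 0, dominance_threshold < 1)
  structure(list(qc = qc, subsample_n = as.integer(subsample_n),
                 dominance_threshold = dominance_threshold,
                 consensus = consensus, interpretation = interpretation,
                 stability = stability, seed = as.integer(seed), arm = arm,
                 group_map = group_map),
            class = "run_config")
}

#' Nanopore-like read error model
#'
#' Per-base i.i.d. error model used by [simulate_reads()]. Rates are fractions
#' per template base. The default total error of 5% (3% substitutions, 1%
#' insertions, 1% deletions) sits at the low end of the error range reported
#' for earlier nanopore chemistries on which consensus-based identification
#' was validated.
#'
#' @param substitution_rate,insertion_rate,deletion_rate Per-base error rates.
#' @param quality_mean,quality_sd Normal distribution (in Phred units) from
#'   which per-base qualities are drawn (rounded, clamped to 1..50).
#' @param read_length_sd If positive, reads are truncated at a length drawn
#'   from Normal(template length, `read_length_sd`).
#' @return An object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.03, insertion_rate = 0.01,
                        deletion_rate = 0.01, quality_mean = 12,
                        quality_sd = 3, read_length_sd = 0) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  stopifnot(all(rates >= 0), sum(rates) < 0.5)
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 read_length_sd = read_length_sd),
            class = "error_model")
}
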