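# Consensus-to-database matching and CLSI-style interpretation of the
# identification level.

#' Rank the closest-matching species for a consensus sequence
#'
#' Aligns the consensus against every centroid and reports the best-matching
#' centroid of each species, sorted by percent identity (descending) and
#' number of mismatches (ascending) — the result-table ordering of the
#' identification workflow. At most `k` species rows are returned (five by
#' default, matching the reported top-5 table).
#'
#' @param consensus A `consensus_seq` object or DNA string.
#' @param db A `centroid_db` tibble.
#' @param k Maximum number of species rows.
#' @param scoring An [align_scoring()] scheme.
#' @return A tibble of species matches (one row per species).
#' @export
rank_matches <- function(consensus, db, k = 5L, scoring = align_scoring()) {
  hits <- best_hits(consensus, db, k = nrow(db), scoring = scoring)
  # hits are already sorted; the first row per species is its best centroid
  hits |>
    dplyr::distinct(.data$species, .keep_all = TRUE) |>
    dplyr::slice_head(n = k)
}

#' Exclude matches with an insufficient aligned span
#'
#' Matches are excluded when the match length falls below 1,250 bp for the
#' full-length long-read arm or 400 bp for the ~500 nt short-read arm
#' (strictly below: a 1,250-column match is kept on the long arm).
#'
#' @param matches A species-match tibble from [rank_matches()].
#' @param arm `"long"` or `"short"`.
#' @param params An [interpretation_params()] bundle.
#' @return A list with `kept` and `excluded` tibbles; `excluded` carries a
#'   `reason` column.
#' @export
apply_length_filter <- function(matches, arm = c("long", "short"),
                                params = interpretation_params()) {
  arm <- match.arg(arm)
  min_len <- if (arm == "long") params$min_match_len_long
             else params$min_match_len_short
  drop <- matches$match_length < min_len
  excluded <- matches[drop, , drop = FALSE]
  if (nrow(excluded) > 0) {
    excluded$reason <- sprintf("match length %d < %d (%s arm)",
                               excluded$match_length, min_len, arm)
  } else {
    excluded$reason <- character(0)
  }
  list(kept = matches[!drop, , drop = FALSE], excluded = excluded)
}

species_separation <- function(matches) {
  if (nrow(matches) < 2) return(Inf)
  top <- matches$species[1]
  other <- matches$percent_identity[matches$species != top]
  if (length(other) == 0) return(Inf)
  matches$percent_identity[1] - max(other)
}

#' Interpret ranked matches into an identification level
#'
#' The decision ladder follows CLSI-style interpretation of 16S identity:
#' species level requires the group's identity floor (99% general, 99.6%
#' aerobic actinomycetes, 100% *Mycobacterium* by default) plus positive
#' discrimination from the next closest distinct species — strictly more
#' than 0.4 percentage points for actinomycetes in standard mode, strictly
#' positive for the other groups (an exact tie between two species cannot
#' support a species call). Modified mode awards actinomycete species calls
#' at the identity floor irrespective of the separation. Below the species
#' rule, genus level requires 97% and family level 95%; below 95% the
#' organism is unidentified. Exactly one rule fires for any input.
#'
#' @param matches A length-filtered species-match tibble (ranking of
#'   [rank_matches()] preserved).
#' @param group Organism group of the screened genus.
#' @param params An [interpretation_params()] bundle (including `mode`).
#' @return An object of class `interpretation`: list with `level`,
#'   `reported_taxon`, `rule_fired`, `top_matches`, `separation`.
#' @export
interpret_matches <- function(matches,
                              group = c("general", "actinomycete",
                                        "mycobacterium"),
                              params = interpretation_params()) {
  group <- match.arg(group)
  if (nrow(matches) == 0) {
    return(structure(list(level = "no_id", reported_taxon = NA_character_,
                          rule_fired = "all_matches_excluded",
                          top_matches = matches, separation = NA_real_),
                     class = "interpretation"))
  }
  top <- matches[1, ]
  sep <- species_separation(matches)
  sp_min <- switch(group,
                   general = params$species_min,
                   actinomycete = params$actino_species_min,
                   mycobacterium = params$myco_species_min)
  sep_ok <- if (group == "actinomycete") {
    if (params$mode == "modified") TRUE else sep > params$actino_separation
  } else {
    sep > 0
  }
  if (top$percent_identity >= sp_min && sep_ok) {
    level <- "species"; taxon <- top$species
    rule <- paste0("species_", group,
                   if (group == "actinomycete") paste0("_", params$mode) else "")
  } else if (top$percent_identity >= params$genus_min) {
    level <- "genus"; taxon <- top$genus
    rule <- "genus_identity"
  } else if (top$percent_identity >= params$family_min) {
    level <- "family"
    taxon <- if (!is.null(params$family_map) &&
                 top$genus %in% names(params$family_map)) {
      params$family_map[[top$genus]]
    } else {
      paste0("family of ", top$genus)
    }
    rule <- "family_identity"
  } else {
    level <- "no_id"; taxon <- NA_character_
    rule <- "below_family_floor"
  }
  structure(list(level = level, reported_taxon = taxon, rule_fired = rule,
                 top_matches = matches, separation = sep),
            class = "interpretation")
}

#' @export
print.interpretation <- function(x, ...) {
  cat(sprintf("<interpretation> %s%s (rule: %s)\n", x$level,
              if (is.na(x$reported_taxon)) "" else
                paste0(": ", x$reported_taxon),
              x$rule_fired))
  invisible(x)
}

#' Species-attribution confidence score
#'
#' A documented composite in `[0, 1]`: the equally weighted mean of (i) the
#' top identity rescaled from the family floor to 100%, (ii) the separation
#' to the closest distinct species capped at one percentage point, (iii) the
#' dominant-genus fraction of the read screen, and (iv) the fraction of
#' consensus positions that are unmasked and unambiguous. Monotone
#' non-decreasing in each component; a perfect run (100% identity, >= 1 pp
#' separation, full dominance, clean consensus) scores 1.
#'
#' @param matches A species-match tibble (ranking preserved).
#' @param genus_call A `genus_call` from [dominant_genus()], or `NULL` (the
#'   dominance component then defaults to 1, e.g. for the short-read arm).
#' @param consensus A `consensus_seq`, or `NULL` (component defaults to 1).
#' @param params An [interpretation_params()] bundle (for the family floor).
#' @return A single numeric score in `[0, 1]`.
#' @export
confidence_score <- function(matches, genus_call = NULL, consensus = NULL,
                             params = interpretation_params()) {
  stopifnot(nrow(matches) >= 1)
  top_id <- matches$percent_identity[1]
  c1 <- min(1, max(0, (top_id - params$family_min) / (100 - params$family_min)))
  sep <- species_separation(matches)
  c2 <- min(1, max(0, sep))
  c3 <- if (is.null(genus_call)) 1 else min(1, max(0, genus_call$fraction))
  c4 <- if (is.null(consensus)) 1 else {
    chars <- strsplit(consensus$sequence, "")[[1]]
    mean(chars %in% DNA_BASES)
  }
  mean(c(c1, c2, c3, c4))
}
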