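test_that("rank_matches returns one row per species, top five, oracle-ordered", {
  ref <- make_reference(n_genera = 2, species_per_genus = 3,
                        intra_divergence = 0.02, seq_length = 500, seed = 31)
  query <- ref$truth$sequence[2]
  ranked <- rank_matches(query, ref$db)
  expect_equal(nrow(ranked), 5)                 # 6 species in the db
  expect_equal(ranked$species[1], ref$db$species[2])
  expect_equal(ranked$percent_identity[1], 100)
  expect_false(anyDuplicated(ranked$species) > 0)
  # ordering agrees with brute-force pairwise identities per species
  oracle <- vapply(ref$db$sequence, function(s)
    align_semiglobal(query, s)$percent_identity, 0)
  oracle_rank <- ref$db$species[order(-oracle, ref$db$accession)]
  expect_equal(ranked$species, head(oracle_rank, 5))
})

test_that("match-length exclusion is strict per arm", {
  m <- make_matches(c(100, 99.5, 99.0), paste("GenusA sp", 1:3),
                    match_length = 1400L)
  m$match_length <- c(1243L, 1250L, 286L)
  long <- apply_length_filter(m, "long")
  expect_equal(long$kept$match_length, 1250L)   # 1250 kept, 1243 excluded
  expect_equal(sort(long$excluded$match_length), c(286L, 1243L))
  expect_match(long$excluded$reason[1], "< 1250")
  short <- apply_length_filter(m, "short")
  expect_equal(sort(short$kept$match_length), c(1243L, 1250L))
  expect_equal(short$excluded$match_length, 286L)  # 286 < 400
})

test_that("the interpretation ladder fires the published decision branches", {
  # general organism, clear species-level call
  gen <- interpret_matches(make_matches(c(99.7, 99.2),
                                        c("GenusA sp1", "GenusA sp2")))
  expect_equal(gen$level, "species")
  expect_equal(gen$reported_taxon, "GenusA sp1")

  # actinomycete at 99.66/99.39: separation 0.27 <= 0.4
  act <- make_matches(c(99.66, 99.39),
                      c("Rhodococcus corynebacteroides",
                        "Rhodococcus kroppenstedtii"))
  std <- interpret_matches(act, group = "actinomycete")
  expect_equal(std$level, "genus")
  expect_equal(std$reported_taxon, "Rhodococcus")
  mod <- interpret_matches(act, group = "actinomycete",
                           params = interpretation_params(mode = "modified"))
  expect_equal(mod$level, "species")
  expect_equal(mod$reported_taxon, "Rhodococcus corynebacteroides")

  # below the 95% family floor: unidentified
  low <- interpret_matches(make_matches(c(94.85, 93.86),
                                        c("Desulfovibrio desulfuricans",
                                          "Desulfovibrio legallii")))
  expect_equal(low$level, "no_id")
  expect_true(is.na(low$reported_taxon))

  # mycobacterium requires 100%
  myc <- make_matches(c(99.9, 99.0),
                      c("Mycobacterium a", "Mycobacterium b"))
  expect_equal(interpret_matches(myc, group = "mycobacterium")$level, "genus")
  myc100 <- make_matches(c(100, 99.0),
                         c("Mycobacterium a", "Mycobacterium b"))
  expect_equal(interpret_matches(myc100, group = "mycobacterium")$level,
               "species")

  # everything excluded by the length filter
  none <- interpret_matches(make_matches(numeric(0), character(0)))
  expect_equal(none$level, "no_id")
  expect_equal(none$rule_fired, "all_matches_excluded")
})

test_that("family reporting uses the genus-family map when provided", {
  m <- make_matches(c(96.0, 95.5), c("GenusA sp1", "GenusB sp1"))
  plain <- interpret_matches(m)
  expect_equal(plain$level, "family")
  expect_equal(plain$reported_taxon, "family of GenusA")
  mapped <- interpret_matches(m, params = interpretation_params(
    family_map = c(GenusA = "Familyaceae")))
  expect_equal(mapped$reported_taxon, "Familyaceae")
})

test_that("exactly one ladder rule fires across the full decision grid", {
  params_std <- interpretation_params()
  params_mod <- interpretation_params(mode = "modified")
  m <- make_matches(c(100, 99), c("GenusA sp1", "GenusA sp2"))
  for (group in c("general", "actinomycete", "mycobacterium")) {
    for (mode in c("standard", "modified")) {
      p <- if (mode == "standard") params_std else params_mod
      for (identity in seq(94, 100, by = 0.5)) {
        for (separation in c(0, 0.2, 0.4, 0.6)) {
          runner <- identity - separation
          m$percent_identity <- c(identity, runner)
          got <- interpret_matches(m, group = group, params = p)$level
          # feed the oracle the same floating-point separation the
          # implementation derives from the two identities
          expect_equal(got, oracle_interpret_level(identity,
                                                   identity - runner,
                                                   group, mode),
                       info = paste(group, mode, identity, separation))
        }
      }
    }
  }
})

test_that("raising the species threshold can only demote a result", {
  rank_of <- function(level) match(level, c("no_id", "family", "genus",
                                            "species"))
  m <- make_matches(c(99.4, 98.0), c("GenusA sp1", "GenusA sp2"))
  lo <- interpret_matches(m, params = interpretation_params(species_min = 99))
  hi <- interpret_matches(m, params = interpretation_params(species_min = 99.5))
  expect_lte(rank_of(hi$level), rank_of(lo$level))
  expect_equal(lo$level, "species")
  expect_equal(hi$level, "genus")
})

test_that("length filtering composes with interpretation", {
  m <- make_matches(c(99.9, 99.2, 98.0), paste("GenusA sp", 1:3))
  m$match_length <- c(1400L, 1100L, 1400L)
  filt <- apply_length_filter(m, "long")
  via_filter <- interpret_matches(filt$kept)
  direct <- interpret_matches(m[m$match_length >= 1250, ])
  expect_equal(via_filter$level, direct$level)
  expect_equal(via_filter$reported_taxon, direct$reported_taxon)
})

test_that("the confidence score is anchored and monotone in its components", {
  perfect <- make_matches(c(100, 98.5), c("GenusA sp1", "GenusA sp2"))
  full_call <- structure(list(fraction = 1), class = "genus_call")
  clean <- structure(list(sequence = strrep("A", 100), length = 100L),
                     class = "consensus_seq")
  expect_equal(confidence_score(perfect, full_call, clean), 1.0)

  # top identity at the family floor with zero separation zeroes (i) and (ii)
  floor_m <- make_matches(c(95, 95), c("GenusA sp1", "GenusA sp2"))
  expect_equal(confidence_score(floor_m, full_call, clean), 0.5)

  # higher dominance can never lower the score
  d6 <- structure(list(fraction = 0.6), class = "genus_call")
  d9 <- structure(list(fraction = 0.9), class = "genus_call")
  m <- make_matches(c(99.5, 99.0), c("GenusA sp1", "GenusA sp2"))
  expect_gte(confidence_score(m, d9, clean), confidence_score(m, d6, clean))

  # masked or ambiguous consensus positions reduce component (iv)
  dirty <- structure(list(sequence = paste0(strrep("A", 90), strrep("N", 10)),
                          length = 100L), class = "consensus_seq")
  expect_lt(confidence_score(m, d9, dirty), confidence_score(m, d9, clean))
})
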