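freq_from_counts <- function(...) {
  # columns supplied as c(A, C, G, T, gap) vectors
  cols <- list(...)
  m <- do.call(rbind, cols)
  out <- tibble::tibble(column = seq_len(nrow(m)),
                        A = m[, 1], C = m[, 2], G = m[, 3], T = m[, 4],
                        gap = m[, 5])
  out$depth <- rowSums(m)
  class(out) <- c("freq_matrix", class(out))
  out
}

test_that("single- and duplicate-centroid profiles are the sequence itself", {
  db1 <- toy_db("ACGT")
  p1 <- build_genus_profile(db1)
  expect_equal(p1$ncol, 4)
  expect_equal(p1$majority, "ACGT")
  expect_equal(unname(p1$rows), "ACGT")

  db2 <- toy_db(c("ACGTACGT", "ACGTACGT"))
  p2 <- build_genus_profile(db2)
  expect_equal(p2$ncol, 8)
  expect_equal(unname(p2$rows), c("ACGTACGT", "ACGTACGT"))
})

test_that("center-star profile of three toy centroids has the expected width", {
  base <- "ACGTACGTACGTACGTACGTACGTACGT"          # 28 nt
  with_del <- paste0(substr(base, 1, 11), substr(base, 13, 28))  # 1 deletion
  with_sub <- paste0(substr(base, 1, 5), "T", substr(base, 7, 28))
  db <- toy_db(c(base, with_del, with_sub))
  p <- build_genus_profile(db)
  # merging the single-indel alignment into the star gives exactly the
  # center length: the deletion consumes a column, it does not add one
  expect_equal(p$ncol, 28)
  # every centroid is reconstructible from its profile row
  degapped <- gsub("-", "", p$rows)
  expect_equal(unname(degapped[db$accession]), db$sequence)
  expect_error(build_genus_profile(
    dplyr::mutate(db, genus = c("GenusA", "GenusA", "GenusB"))),
    "single genus")
})

test_that("profile rows always reconstruct their centroids", {
  ref <- make_reference(n_genera = 1, species_per_genus = 4,
                        intra_divergence = 0.03, seq_length = 400, seed = 12)
  p <- build_genus_profile(ref$db)
  degapped <- gsub("-", "", p$rows)
  expect_equal(unname(degapped[ref$db$accession]), ref$db$sequence)
})

test_that("frequency accumulation counts bases and deletions per column", {
  tmpl <- withr::with_seed(61, random_seq(60))
  prof <- build_genus_profile(toy_db(tmpl))
  reads5 <- reads_from_seqs(rep(tmpl, 5))
  fr <- accumulate_frequencies(reads5, prof)
  expect_true(all(fr$depth == 5))
  expect_equal(sum(fr$A + fr$C + fr$G + fr$T == 5), 60)

  # one read differing at position 10 gives a 4:1 split there
  ch <- strsplit(tmpl, "")[[1]]
  orig <- ch[10]
  ch[10] <- setdiff(c("A", "C", "G", "T"), orig)[1]
  fr2 <- accumulate_frequencies(
    reads_from_seqs(c(rep(tmpl, 4), paste(ch, collapse = ""))), prof)
  row10 <- fr2[fr2$column == 10, c("A", "C", "G", "T")]
  expect_equal(sort(as.numeric(row10), decreasing = TRUE)[1:2], c(4, 1))
  expect_equal(as.numeric(row10[[orig]]), 4)

  # frequency-matrix invariant: depth equals the sum of the five counts
  expect_equal(fr2$depth, fr2$A + fr2$C + fr2$G + fr2$T + fr2$gap)
})

test_that("low-identity reads are skipped during accumulation", {
  tmpl <- withr::with_seed(62, random_seq(300))
  junk <- withr::with_seed(63, random_seq(300))
  prof <- build_genus_profile(toy_db(tmpl))
  fr <- accumulate_frequencies(reads_from_seqs(c(tmpl, junk)), prof)
  expect_equal(attr(fr, "n_reads_used"), 1L)
  expect_equal(attr(fr, "n_reads_skipped"), 1L)
})

test_that("the 40% interpretation cutoff calls bases and ambiguities", {
  fr <- freq_from_counts(
    c(5, 0, 0, 0, 0),    # unanimous A
    c(3, 0, 2, 0, 0),    # A 60%, G 40%: both reach the cutoff -> R
    c(3, 2, 0, 0, 0),    # A 60%, C 40% -> M
    c(2, 2, 1, 0, 0))    # A 40%, C 40%, G 20% -> M
  cs <- call_consensus(fr, consensus_params())
  expect_equal(cs$sequence, "ARMM")
  # raising the cutoff resolves the ambiguities without touching unanimity
  cs60 <- call_consensus(fr, consensus_params(interpretation_cutoff = 0.6))
  expect_equal(substr(cs60$sequence, 1, 2), "AA")
})

test_that("columns below the minimum depth are trimmed or masked, never called", {
  fr <- freq_from_counts(
    c(4, 0, 0, 0, 0),    # depth 4 at the 5' end: trimmed
    c(6, 0, 0, 0, 0),
    c(0, 4, 0, 0, 0),    # internal depth 4: masked as N
    c(0, 0, 6, 0, 0),
    c(0, 0, 0, 4, 0))    # depth 4 at the 3' end: trimmed
  cs <- call_consensus(fr, consensus_params())
  expect_equal(cs$sequence, "ANG")
  expect_equal(cs$masked_positions, 2L)
  expect_equal(cs$profile_columns, 2:4)
  expect_false(grepl("-", cs$sequence))
})

test_that("no consensus is obtainable when every column is under-covered", {
  fr <- freq_from_counts(c(3, 0, 0, 0, 0), c(0, 4, 0, 0, 0))
  expect_error(call_consensus(fr), "no consensus obtainable")
})

test_that("gap handling: dominant gaps delete a column, ties go to the base", {
  fr <- freq_from_counts(
    c(10, 0, 0, 0, 0),
    c(3, 0, 0, 0, 7),    # gap 70% dominant: column deleted
    c(5, 0, 0, 0, 5),    # gap ties A: base wins
    c(10, 0, 0, 0, 0))
  cs <- call_consensus(fr, consensus_params())
  expect_equal(cs$sequence, "AAA")
  expect_equal(cs$profile_columns, c(1L, 3L, 4L))
})

test_that("raising the cutoff never increases the number of ambiguity codes", {
  withr::with_seed(64, {
    for (rep in 1:5) {
      counts <- lapply(1:40, function(i) {
        v <- as.numeric(stats::rmultinom(1, 20, c(0.4, 0.3, 0.2, 0.05, 0.05)))
        v[sample(5)]
      })
      fr <- do.call(freq_from_counts, counts)
      n_amb <- vapply(c(0.3, 0.4, 0.5, 0.6), function(cut) {
        cs <- call_consensus(fr, consensus_params(interpretation_cutoff = cut))
        sum(!strsplit(cs$sequence, "")[[1]] %in% c("A", "C", "G", "T", "N"))
      }, 0)
      expect_true(all(diff(n_amb) <= 0))
    }
  })
})

test_that("consensus calling is deterministic and recovers a noisy template", {
  tmpl <- withr::with_seed(65, random_seq(600))
  prof <- build_genus_profile(toy_db(tmpl))
  reads <- simulate_reads(tmpl, 30,
                          error_model(substitution_rate = 0.03,
                                      insertion_rate = 0.01,
                                      deletion_rate = 0.01), seed = 66)
  fr <- accumulate_frequencies(reads, prof)
  cs1 <- call_consensus(fr)
  cs2 <- call_consensus(accumulate_frequencies(reads, prof))
  expect_identical(cs1$sequence, cs2$sequence)
  expect_lte(hamming_distance(cs1, tmpl), 2)
})
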