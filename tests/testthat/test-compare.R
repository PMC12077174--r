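test_that("cross-tabulation reproduces the published marginals", {
  pairs <- example_paired_levels()
  expect_equal(nrow(pairs), 153)
  tab <- cross_tabulate(pairs)
  expect_equal(attr(tab, "n"), 153)
  # arm A (short-read): no_id 8, family 10, genus 32, species 103
  expect_equal(unname(colSums(tab)), c(8, 10, 32, 103))
  # arm B (long-read): no_id 1, family 7, genus 34, species 111
  expect_equal(unname(rowSums(tab)), c(1, 7, 34, 111))
})

test_that("cross-tabulation handles degenerate inputs and ignores pair order", {
  empty <- cross_tabulate(example_paired_levels()[0, ])
  expect_true(all(empty == 0))
  one <- cross_tabulate(tibble::tibble(sample_id = "s1",
                                       level_a = "species",
                                       level_b = "species"))
  expect_equal(sum(one), 1)
  expect_equal(one["species", "species"], 1)

  pairs <- example_paired_levels()
  shuffled <- pairs[withr::with_seed(81, sample(nrow(pairs))), ]
  expect_equal(unclass(cross_tabulate(shuffled)),
               unclass(cross_tabulate(pairs)))
  expect_error(cross_tabulate(tibble::tibble(sample_id = "x",
                                             level_a = "order",
                                             level_b = "species")),
               "unknown identification level")
})

test_that("the exact McNemar p-value matches hand-derived values", {
  expect_equal(mcnemar_exact(0, 0)$p.value, 1)
  expect_equal(mcnemar_exact(7, 0)$p.value, 2 * 0.5^7)        # 0.015625
  expect_equal(mcnemar_exact(11, 1)$p.value, 26 / 4096)       # ~0.00635
  expect_error(mcnemar_exact(-1, 2), "non-negative")
})

test_that("exact McNemar is symmetric and agrees with enumeration up to n = 20", {
  for (n in 0:20) {
    for (b in 0:n) {
      c <- n - b
      got <- mcnemar_exact(b, c)$p.value
      expect_equal(got, mcnemar_exact(c, b)$p.value)
      if (n > 0) {
        # brute-force binomial tail enumeration
        probs <- choose(n, 0:n) * 0.5^n
        expected <- min(1, 2 * sum(probs[0:min(b, c) + 1]))
        expect_equal(got, expected, info = paste(b, c))
        # independent oracle: the two-sided exact binomial test
        expect_equal(got,
                     stats::binom.test(min(b, c), n, 0.5)$p.value,
                     tolerance = 1e-12, info = paste(b, c))
      }
    }
  }
})

test_that("the chi-square variant matches stats::mcnemar.test and is labelled", {
  for (bc in list(c(11, 1), c(7, 3), c(16, 8))) {
    ours <- mcnemar_chisq(bc[1], bc[2])
    ref <- stats::mcnemar.test(matrix(c(5, bc[1], bc[2], 5), 2, 2))
    expect_equal(ours$p.value, unname(ref$p.value))
    expect_equal(ours$statistic, unname(ref$statistic))
  }
  expect_match(mcnemar_chisq(1, 1)$method, "chi-square")
  expect_match(mcnemar_exact(1, 1)$method, "exact")
})

test_that("level-improvement collapse reproduces the published significance", {
  tab <- cross_tabulate(example_paired_levels())
  genus <- level_improvement_test(tab, "genus")
  expect_equal(genus$b, 11)
  expect_equal(genus$c, 1)
  expect_lt(genus$p.value, 0.01)
  family <- level_improvement_test(tab, "family")
  expect_equal(family$b, 7)
  expect_equal(family$c, 0)
  expect_lt(family$p.value, 0.02)
  expect_equal(family$p.value, 0.015625)

  diag_only <- cross_tabulate(tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    level_a = rep(c("no_id", "family", "genus", "species"), 2),
    level_b = rep(c("no_id", "family", "genus", "species"), 2)))
  for (lv in c("family", "genus", "species")) {
    expect_equal(level_improvement_test(diag_only, lv)$p.value, 1)
  }
})

test_that("concordance counts agreeing taxa among pairs both reaching the rank", {
  pairs <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:6),
    level_a = c("species", "species", "species", "genus", "species", "no_id"),
    taxon_a = c("GenusA alpha", "GenusA beta", "GenusB gamma",
                "GenusC", "GenusD delta", NA),
    level_b = c("species", "species", "species", "species", "genus", "family"),
    taxon_b = c("GenusA alpha", "GenusA gamma", "GenusB gamma",
                "GenusC epsilon", "GenusD", "family of GenusX"))
  sp <- concordance(pairs, "species")
  expect_equal(sp$total, 3)       # rows 1-3 reached species in both arms
  expect_equal(sp$concordant, 2)  # row 2 disagrees on the epithet
  gn <- concordance(pairs, "genus")
  expect_equal(gn$total, 5)
  expect_equal(gn$concordant, 5)  # genera agree even where species differ

  all_same <- tibble::tibble(sample_id = "x", level_a = "species",
                             taxon_a = "GenusA alpha", level_b = "species",
                             taxon_b = "GenusA alpha")
  expect_equal(concordance(all_same, "species")$fraction, 1)

  none <- tibble::tibble(sample_id = "x", level_a = "no_id",
                         taxon_a = NA, level_b = "family",
                         taxon_b = "f")
  expect_warning(res <- concordance(none, "species"), "undefined")
  expect_true(is.na(res$fraction))
})

test_that("a 51-of-57 concordance scenario reproduces the 89% figure", {
  agree <- tibble::tibble(
    sample_id = sprintf("a%02d", 1:51),
    level_a = "species", taxon_a = "GenusA alpha",
    level_b = "species", taxon_b = "GenusA alpha")
  disagree <- tibble::tibble(
    sample_id = sprintf("d%02d", 1:6),
    level_a = "species", taxon_a = "GenusB beta",
    level_b = "species", taxon_b = "GenusB gamma")
  res <- concordance(dplyr::bind_rows(agree, disagree), "species")
  expect_equal(res$concordant, 51)
  expect_equal(res$total, 57)
  expect_equal(round(100 * res$fraction), 89)
})

test_that("slash-group species labels concord on any component epithet", {
  pairs <- tibble::tibble(
    sample_id = "s1", level_a = "species",
    taxon_a = "Mycobacterium mucogenicum",
    level_b = "species",
    taxon_b = "Mycobacterium phocaicum/mucogenicum")
  expect_equal(concordance(pairs, "species")$concordant, 1)
  pairs$taxon_a <- "Mycobacterium gordonae"
  expect_equal(concordance(pairs, "species")$concordant, 0)
})
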