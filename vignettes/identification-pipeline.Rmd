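---
title: "Consensus-based identification of bacterial isolates from long-read 16S rRNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-based identification of bacterial isolates from long-read 16S rRNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ont16s)
```

## The problem

Clinical laboratories confirm the identity of cultured bacterial isolates
that resist routine methods (ambiguous biochemistry, no MALDI-TOF match) by
sequencing the 16S rRNA gene. The classic approach reads the first ~500 nt
(variable regions V1–V3) by Sanger sequencing; it is accurate per base but
blind to diversity that lies downstream of that window. Long-read nanopore
sequencing covers the full ~1,500 nt gene, but individual reads carry
substantially more error, so a usable sequence must be distilled from many
reads. `ont16s` implements that distillation and the interpretive layer
around it:

1. **Quality filtering** — reads shorter than 20 nt or with arithmetic mean
   Phred below 7 are removed. Both bounds are strict ("shorter than",
   "below"): a 20 nt read at mean Phred exactly 7 survives. The mean is the
   plain mean of integer Phred scores; we deliberately do not convert to
   error probabilities first, taking the simplest reading of a "mean Phred
   quality score".
2. **Dominant-genus screen** — 1,000 reads (or all, if fewer) are drawn
   uniformly at random and each is assigned the genus of its best-matching
   reference centroid. The pipeline continues only if one genus claims
   *strictly more than* 50% of the subsample; otherwise it stops with a
   structured halt report. The denominator is the whole subsample:
   unassignable reads (best identity under 80%, or an exact cross-genus
   tie) still count against dominance, which keeps the stop rule
   conservative.
3. **Genus profile** — the centroids of the winning genus are multiply
   aligned by the center-star method into a profile that fixes the
   coordinate system for consensus calling.
4. **Frequency matrix and consensus** — *every* quality-passed read (not
   just the screening subsample) is aligned to the profile and its bases
   and deletions are tallied per profile column. At each column covered by
   at least 5 reads, bases reaching a 40% frequency cutoff form the call
   set: one base is emitted as is, several collapse to their IUPAC
   ambiguity code, and a dominant gap deletes the column.
5. **Matching and interpretation** — the consensus is compared against the
   whole reference; the best centroid per species is ranked by percent
   identity, then mismatches. After a match-length exclusion, a CLSI-style
   decision ladder assigns species / genus / family / no-identification.

The companion analyses are the read-subset **stability curve** (how many
reads a stable consensus needs) and the paired **method comparison**
(exact McNemar test, concordance) between the short-read and long-read
arms.

## Reference databases

The curated "centroid" databases used in clinical practice are
proprietary, so the package defines its own plain-FASTA dialect:
`>accession|genus|species_epithet` (or `>accession|Genus species`), with a
taxonomy TSV accepted as an alternative. A centroid is one representative
sequence per species group; `make_reference()` fabricates such databases
with controlled intra- and inter-genus divergence for testing and
simulation studies.

## The alignment kernel

All sequence comparison rests on one affine-gap pairwise aligner
(`align_semiglobal()`, `align_global()`), written in C++:

* **Scoring**: match +2, mismatch −3, gap open −5, gap extend −2, a
  BLASTN-like scheme; a gap of length $L$ costs $open + L \cdot ext$.
* **Semi-global ("overlap") mode** leaves end gaps free on either
  sequence, so a read can sit anywhere inside a longer reference and vice
  versa. Global mode penalizes end gaps and is used when two consensus
  sequences of unequal length must be compared column by column.
* **Identity accounting** is BLAST-like: the *matched span* runs from the
  first to the last aligned base pair; internal gap columns count as
  mismatches; `percent_identity = 100 * matches / match_length`. One
  consequence worth knowing: a substitution in the terminal base or two
  can fall off the matched span entirely (the aligner prefers to leave a
  trailing mismatch unaligned), so identity is monotone in substitutions
  only away from the extreme ends.
* **Ambiguity codes** (IUPAC) in either sequence count as a match whenever
  the two base sets intersect. The consensus caller emits such codes on
  purpose; penalizing them would misstate the identity of a perfectly
  reasonable consensus.
* **Banding**: problems up to 400 nt run the full dynamic-programming
  matrix outright. Longer problems run inside a diagonal band that starts
  at `max(16, |n − m| + 8)` and doubles until the score stops changing
  (falling back to the full matrix if it never does), so the reported
  score is the full-DP optimum for every input we have been able to
  construct, and the test suite checks exactly that against an
  independent plain-R dynamic program.
* **Ties** are broken deterministically (diagonal moves preferred, then
  gap-in-target, then gap-in-query; equal hits ordered by accession), so
  identical inputs always give byte-identical output.

## Consensus-calling details

Several small rules make the consensus well defined at the edges:

* The frequency denominator at a column is the number of reads *covering
  that column*, not the total read count — end columns naturally have
  lower coverage and are what the minimum depth plainly gates.
* The 40% cutoff is inclusive (`>= 0.40`), so a column split exactly
  60/40 yields an ambiguity code.
* A gap state participates in the cutoff computation. If the gap is
  strictly the most frequent state the column is deleted from the
  consensus (keeping emitted sequences free of gap characters); if a gap
  ties with a base, the base wins.
* Columns under the minimum depth are trimmed at the profile ends and
  masked as `N` internally, with positions recorded — masking never
  invents bases. If *no* column reaches the minimum depth the caller
  refuses with "no consensus obtainable", the behaviour expected of a
  sample with a handful of reads.
* Columns where no base reaches the cutoff (e.g. three-way splits) are
  emitted as `N` and recorded separately.
* Reads are aligned to the profile's **column-majority string** rather
  than to the full alignment or a profile HMM, with read gaps mapped back
  to profile columns and read insertions dropped (the consensus lives in
  the profile's coordinate system). This is an explicit, documented
  approximation chosen for speed and bookkeeping simplicity; for the
  intra-genus divergences a genus profile actually spans (a few percent)
  the majority string is an excellent alignment target.

## Interpretation thresholds

The decision ladder defaults are configuration, not claims about any
licensed guideline document: family ≥ 95%, genus ≥ 97%, species ≥ 99%
for general organisms; aerobic actinomycetes require ≥ 99.6% identity
*and* more than 0.4 percentage points of separation to the next distinct
species (the "modified" mode waives the separation clause);
*Mycobacterium* requires 100%. The 95% / 99.6% / 0.4 / 100% values are
the publicly quoted ones; the 97% and 99% general-group defaults follow
common practice and are surfaced in `interpretation_params()` rather than
hidden.

Two design choices were genuinely open:

* **Separation for non-actinomycetes.** We require strictly positive
  separation to the next distinct species for *any* species-level call:
  when two species tie exactly, the data cannot discriminate them, and
  reporting the alphabetically first would be arbitrary. This matters for
  "challenge organisms" whose species signal lies entirely beyond the
  first 500 nt — the short-read arm then ties both congeners at 100% and
  correctly demotes to genus, while the full-length arm resolves the
  species.
* **"Distance score"** is read as the difference in percent identity
  between the top species and the best hit belonging to a *different*
  species, the only reading consistent with published result tables.

Matches whose aligned span is shorter than 1,250 nt (long arm) or 400 nt
(short arm) are excluded before the ladder runs, strictly ("<"), and are
reported with a reason rather than silently dropped.

The **confidence score** is this package's own composite (the upstream
one is unpublished): the equal-weight mean of top identity rescaled from
the family floor, separation capped at one percentage point, the
dominant-genus fraction, and the fraction of clean (unmasked,
unambiguous) consensus positions. It is monotone in each component and
anchored so a perfect run scores 1.

## Stability analysis

`stability_series()` takes reads *in file order* (subsets are prefixes of
the growing sequencing run, not random samples), builds a consensus per
prefix in 500-read increments up to 20,500 reads, and computes the Hamming
distance to the all-reads "expected" consensus. Distances between
sequences of unequal length are computed over a global alignment with gap
columns counted; `N` compares unequal to any base so depth-driven masking
surfaces as distance. The published flattening criterion is visual;
`min_reads_for_stability()` operationalizes it as the smallest subset size
from which every curve stays within a tolerance (default 4 bp — the
residual difference magnitude observed not to change identifications) for
all larger subsets.

## Method comparison

`mcnemar_exact()` is the default test: with the discordant counts involved
(a dozen pairs at most), the exact binomial form — doubling the tail of
$\mathrm{Bin}(b + c, \tfrac12)$ at $\min(b, c)$, capped at 1 — is the
defensible choice; the continuity-corrected chi-square variant exists but
is always labelled and never substituted. "Improved from no-ID/family to
genus" is operationalized by collapsing the 4×4 level table to the paired
binary outcome "reached at least genus" (and likewise for family), the
only collapse consistent with the published significance bounds. Taxon
concordance at a rank counts pairs where both arms reached the rank;
slash-group labels ("*phocaicum/mucogenicum*") concord on any component.

## What the simulator does and does not emulate

`make_reference()` draws a root sequence uniformly over A/C/G/T, derives
genus ancestors and species centroids by substituting exact site counts;
each lineage is mutated at *half* the requested rate so the realized
**pairwise** divergence between congeners matches `intra_divergence`.
`simulate_reads()` applies i.i.d. per-base substitutions, insertions and
deletions (defaults 3% / 1% / 1%, a 5% total at the low end of the error
range of earlier nanopore chemistries) and draws Phred qualities from a
normal distribution. `simulate_sanger()` returns the 5′ fragment,
optionally with a small substitution rate.

Deliberately *not* modelled: homopolymer-biased and quality-correlated
errors, site-rate heterogeneity across the gene, strand effects, chimeras,
and reference databases with incomplete species coverage. Passing the
simulation suite therefore demonstrates that the algorithms are correct
under a clean error model, not that real-world accuracy figures transfer;
the contingency-table and rule-table checks are what tie the package to
published numbers.

All randomness flows from explicit `seed` arguments through
`withr::with_seed()`; no function touches the global RNG state.

## Problem sizes used by the test and acceptance suites

The suites run the pipeline at reduced but structurally faithful sizes,
chosen as the smallest problems that still exercise every rule: reference
databases of 2–6 species at full 1,500 nt length where the identity
arithmetic matters (consensus recovery, dominance, challenge organisms)
and 200–800 nt where it does not; read depths of 25–80 per sample; 10–20
seeded replicates per stochastic property. The published contingency table
is ingested at full size (153 isolates). The oracle-equivalence check runs
200 random pairs up to 60 nt against the plain-R full dynamic program.

## Known limitations

* The profile-majority alignment target can, in principle, misplace reads
  around dense indel clusters that a full read-to-MSA alignment would
  resolve; at 16S intra-genus divergences we have not observed this.
* Family-level reporting depends on a user-supplied genus→family map;
  without one the package reports the placeholder "family of *Genus*".
* Concordance on the published table is not computable (per-isolate taxa
  are not printed); it is exercised on synthetic pairs only.
* The stability series truncates at `max_reads`, but the expected
  consensus always uses all reads — with more reads than `max_reads` the
  final curve point need not be zero.
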