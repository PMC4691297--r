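---
title: "Methods: genic SSR mining, classification and comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genic SSR mining, classification and comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genicssr)
```

## The problem

Simple sequence repeats (SSRs, microsatellites) are tandem repetitions of
short DNA motifs. In coding sequences they are both functionally interesting
(they encode amino-acid runs and are under frame-preserving selection) and
practically valuable as transferable, co-dominant molecular markers. Surveys
of genic SSRs in conifers — e.g. the high-confidence gene catalogs of Norway
spruce (*Picea abies*) and loblolly pine (*Pinus taeda*) — compare species
by the per-megabase density of repeat loci, split into a long "class I"
(marker-grade, nominally ≥ 20 bp of tract) and a short "class II"
(nominally 12–19 bp).

`genicssr` implements that analysis end to end: perfect-repeat detection in
CDS FASTA, class assignment, motif canonicalisation, density /
composition / amino-acid summaries, and the comparative statistics — plus a
synthetic CDS generator with planted ground truth so each stage is testable
without multi-gigabase downloads.

## Detection model

A *perfect* SSR is an uninterrupted repetition of one motif. The scanner
considers every motif length (period) $k \in \{1, \dots, 10\}$. For each
$k$ it finds maximal stretches of the self-match predicate
$s[i] = s[i+k]$ (both bases in `{A,C,G,T}`); a maximal stretch of length
$\ell$ anchors a run at its leftmost position with
$n = \lfloor (\ell + k)/k \rfloor$ whole repeat units. The conventions,
declared here because upstream mining tools leave them ambiguous:

* **Whole units only.** A trailing partial unit neither counts toward the
  repeat number nor extends the reported tract; the published thresholds
  are stated in whole repeat counts.
* **Primitive periods only.** A motif that is itself periodic (e.g.
  `ATAT`) is never reported; the tract appears once, at its smallest
  period. This is the de-duplication that redundant multi-period searches
  need as a post-processing step.
* **Maximality.** The base before the run must not continue the period and
  no further whole unit fits on either side. Distinct tracts of different
  motifs may overlap by fewer than $k$ bases; both are reported.
* **Hard breaks.** `N` and IUPAC ambiguity codes terminate every run and
  never occur inside a reported motif, so assembly gaps cannot create or
  extend repeats.

The scanner core is compiled (Rcpp) — a linear pass per period — because the
validation suite rescans megabase-scale synthetic catalogs thousands of
times. Its output is checked against an independent pure-R brute-force
oracle that tests every `(start, period)` candidate from first principles.

## Class thresholds

Class membership is decided by per-period minimum repeat counts
(`ssr_thresholds()`):

| period | 1 | 2 | 3 | 4 | 5 | 6 | 7 | 8 | 9 | 10 |
|--------|---|---|---|---|---|---|---|---|---|----|
| class I minimum | 20 | 10 | 7 | 5 | 4 | 4 | 3 | 3 | 3 | 2 |
| class II minimum | 12 | 6 | 4 | 3 | 3 | 2 | 2 | 2 | 2 | — |

Class I is tested first; a tract that misses it falls to class II, else it
is dropped. The two locus sets are therefore disjoint by construction
(mirroring the SQL de-duplication such surveys apply when the short-repeat
search also returns the long repeats). Decamers have no class II entry, so
every reported decamer is class I. The nominal byte-length definitions
("≥ 20 bp", "12–19 bp") are descriptive only — the repeat-count table is
authoritative, and the two disagree at e.g. octamers, where two units
(16 bp) are class II and three (24 bp) class I with no 20 bp octamer tract
possible.

## Canonical motif classes

Motifs that are circular permutations of one another, or of each other's
reverse complements, describe the same repeat locus read differently, and
are clustered (AC = GT = CA = TG). The representative is the
lexicographically smallest orbit member under A < C < G < T — a
deterministic rule whose representatives coincide with the first-named
motifs in conventional tables (AAC, AAG, AAT, ACG, …). Exhaustive
enumeration gives 2 mononucleotide, 4 dinucleotide and 10 trinucleotide
primitive classes. We deliberately do *not* add plain (uncomplemented)
reversal to the group: some published tabulations merge, say, the ACG and
AGC orbits, which only reversal explains, but reversal has no biological
reading for a single-stranded CDS and would make class counts
unreproducible against the rotation+complement convention.

Each motif copy is also classified as `AT_RICH`, `GC_RICH` or `BALANCED`
(A+T vs G+C within one copy; ties are balanced). Balanced motifs form a
genuine third category excluded from both rich tallies — forcing a two-way
split would contradict the table arithmetic of published surveys, where the
AT-rich and GC-rich densities sum to less than the class total.

## Summaries

`summarize_dataset()` aggregates loci into the standard report. Notable
conventions:

* **Densities** are counts per Mbp with the *whole* dataset length (all
  genes, not only SSR-bearing ones) as denominator.
* **Monomers** appear in the by-period density table but are excluded from
  headline totals, gene counts and composition tables unless
  `include_monomers = TRUE`. Mononucleotide runs are hard to assay and
  inflated by sequencing error; published headline densities follow the
  same exclusion (their headline class totals equal the by-period column
  sums minus the monomer row).
* **Nucleotide differentials** count one motif copy per locus, not the
  whole tract — the convention recoverable from published tables, where the
  per-class nucleotide column sums equal the density-weighted sum of motif
  periods.
* **Tract length spread** is the population SD (denominator $n$).
* **Amino-acid profiles** translate, per locus, the codons lying entirely
  inside the tract in the gene's frame (CDS assumed to start in frame 0 at
  position 0 — the only convention needing no annotation beyond the CDS
  itself). Stop codons are tallied under `"*"` separately from amino
  acids.

## Comparative statistics

The heterogeneity test on $k$ density values $v_1, \dots, v_k$ is the
equal-expectation goodness-of-fit chi-square:

$$X^2 = \sum_i \frac{(v_i - \bar v)^2}{\bar v}, \qquad \mathrm{df} = k - 1,$$

with upper-tail p-value and no continuity correction. This is the unique
reading that reproduces the published comparative statistics from the
published density tables (e.g. densities 1768.2 vs 1541.9 give
$X^2 = 15.47$, printed as 15.4; a Yates-corrected version gives 11.9 where
12.9 is printed, ruling it out). Because the test is applied to densities
directly, the statistic scales linearly with the measurement scale — a
property the unit tests pin down, and a caveat for interpreting it as a
count-based test. Tract-length comparisons use the Welch unequal-variance
two-sided t-test (`stats::t.test`), appropriate for the unequal group sizes
and variances involved. `compare_datasets()` runs the full battery per
class: between-dataset density, within-dataset trimer-vs-hexamer, AT-rich
vs GC-rich, (A+T) vs (G+C) differentials, and the length t-test. No
multiple-testing correction is applied, matching survey practice.

## Synthetic data: what it emulates, and what not

The generator builds gene-sized CDS records (default 600–1500 bp) of
i.i.d. background at a configurable GC fraction, then plants perfect
repeat tracts at randomised, non-overlapping positions (≥ 12 bp apart).
Three mechanisms make the planted truth *exactly* the detectable locus set:

1. **Background repair.** Any window where the detector still finds a
   qualifying locus is locally resampled (the window plus one period each
   side) until the background is SSR-free; configurations the bounded
   retry budget cannot clean raise an error rather than returning a
   repeat-bearing string.
2. **Guard flanks.** Planting mutates the single base on either side of
   the tract when it would extend the repeat period, so the planted extent
   is the maximal run.
3. **Post-plant verification.** Each gene is rescanned and the detected
   set compared against the planted truth; junction artefacts are
   resampled away or the gene is rejected.

On every generated dataset, `recovery_report()` therefore scores precision
= recall = 1 by construction — which is what makes the generator a useful
oracle for pipeline plumbing, and also the limit of what such tests show:
the background has no codon structure, no compositional heterogeneity
along the gene, no imperfect or compound repeats, and the two synthetic
"catalogs" share no phylogenetic structure. Passing on synthetic data
validates the *algorithmic* contract (detection, classification,
aggregation, statistics), not the biological realism of any density value.

A `codon_aligned` flag places tracts at positions divisible by 3 for clean
amino-acid profile tests. Seeds fully determine output, byte for byte.

## Validation problem sizes and numerical choices

The shipped test-suite sizes were chosen as the smallest that still
exercise every code path convincingly: oracle equivalence on 500 random
sequences of 50–500 bp (plus repeat-dense compositions), exhaustive
canonicalisation checks for all motifs up to length 6, planted-recovery
coverage of every period 1–10 in both classes, and a two-catalog power
check at 1 Mbp per catalog (1000 genes × 1000 bp, GC 0.45 as typical for
conifer CDS, class II plants split ~70% hexamer / 30% trimer) with
class II densities in the published 1768:1542 ratio across 100 seeds —
the planted contrast yields $X^2 \approx 15.5$, $p \approx 8\times10^{-5}$,
so rejection at $\alpha = 0.01$ is expected in essentially every
replicate.

Degenerate inputs are errors, not silent results: all-zero density vectors,
single-value comparisons, zero-variance t-tests, empty motifs, non-ACGT
motifs, infeasible planting configurations. Empty FASTA files yield empty
datasets with a warning so pipelines compose. Floating-point equality in
identities (richness partitions, nucleotide conservation) is asserted to
near machine precision; agreement with published statistics is asserted to
1% relative tolerance or the precision the value was printed with,
whichever is looser for rounding of the printed inputs.

## Known limitations

* Perfect repeats only; imperfect and compound SSRs are out of scope.
* Single-strand scanning: reverse-complement equivalence is handled at
  canonicalisation, not detection — appropriate for CDS, not for genomic
  both-strand surveys.
* The frame-0 translation convention is an assumption about the input
  FASTA, not something the package can verify.
* The heterogeneity chi-square inherits the scale-dependence of being run
  on densities; treat its p-values as the published surveys do, as rough
  screens rather than calibrated tests.
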