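---
title: "Methods: circular-genome mutation-spectrum analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular-genome mutation-spectrum analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtspectra)
```

# The analysis problem

Mitochondrial DNA is circular, so a linear reference misrepresents exactly
the variants this package cares most about: deletion junctions near the
replication origin and very-long-range junctions that, on a circle, are
indistinguishable from short duplications (multimers). `mtspectra` therefore
consumes alignments against a *doubled* reference (dMT) — the circular
sequence concatenated with itself — and folds every coordinate back to
`[0, L)` after extraction. This vignette documents the models, conventions
and numerical choices behind each stage, what the synthetic-data generator
does and does not emulate, and the design decisions that were genuinely open.

# Coordinates and the doubled reference

All internal coordinates are 0-based, half-open, on the forward strand;
written tables are 1-based closed. An alignment at position `p` on the
doubled reference is equivalent to one at `p + L`; `normalize_position()`
maps both to `p mod L`, and the extractor merges evidence from the two
copies, counting each read once. Gene features that span the origin are
encoded as single records with `end < start` rather than split intervals.
Junction windows (`extract_window()`) are centred on the junction itself:
the `flank` bases ending at `center − 1` followed by the `flank` bases
starting at `center`. Windows containing `N` are flagged and skipped by
identity scoring, since an ambiguity code has no defensible match score.

# Variant extraction

The extractor walks CIGARs to build per-site mismatch pileups and junction
evidence. Three conventions matter:

* **Border trim.** Evidence within 5 bp of either read end is ignored
  (alignment artefacts concentrate there), but the read still counts toward
  depth. This is why support is slightly below depth even for planted
  fraction-1.0 variants.
* **Quality proxy.** Variant callers rarely document their internal score.
  Here, SNV quality is the mean phred of supporting bases at the site, and
  deletion quality is the minimum of the two flanking aligned-segment mean
  phreds (10 bp each side of the junction), averaged over supporting reads.
  Both are simple, testable, and monotone in the evidence quality.
* **Left alignment.** In repetitive context a deletion's breakpoints are
  ambiguous; the junction is shifted left while the base before the gap
  equals the last deleted base. The simulator canonicalises its truth tables
  the same way, so planted-recovery comparisons are representation-free.

Post-call filters are inclusive at the stated minima (support ≥ 4 / depth
≥ 50 / quality ≥ 20 for SNVs; 2 / 25 / 10 for deletions; allele fraction
≥ 0.005): a "minimum" admits its boundary value. Deletions partition at
15 000 bp: spans ≤ 15 kb are class `DEL`, longer junctions are `VLRD`. A
VLRD's length is the reference span of its junction *before* normalisation;
whether it is a deletion or a duplication is deliberately left open, which is
the honest reading of a circular chromosome. Discordant pairs are counted as
records with none of the bits {0x2, 0x4, 0x8, 0x100, 0x400} set — the
complement semantics of the flag mask 1294.

# Direct repeats

A direct repeat is a pair of same-strand copies of length ≥ 8 with at most
one mismatch per four nucleotides (`mismatches ≤ floor(length/4)`), copies
non-overlapping on the circle, reported only when *inclusion-maximal* among
valid intervals at the same copy offset. Maximality is needed because every
sub-window of a long repeat is otherwise itself a repeat; reporting maximal
units matches how repeat catalogues are binned by size. The production
search works per copy offset `d`: with weights +1 (match) and −3 (mismatch),
an interval is valid iff its weight sum is non-negative, so prefix sums plus
a sliding max-deque find the longest valid interval per start in near-linear
time, and maximality reduces to one sweep. A brute-force enumerator with a
completely different structure (per-anchor character scans, pairwise
containment checks) ships in the package solely as an oracle; the test suite
asserts identity of the two outputs on dozens of random circles. On random
sequence the definition admits many chance 8-mers — that density is a
property of the definition, not a bug, and the breakpoint statistic below is
a *pairwise* distance, which stays informative regardless.

The breakpoint statistic for a deletion is the minimum over repeat pairs of
the mean of the two copy-to-breakpoint circular distances, with the copy
assignment chosen by minimisation and distance measured to the nearest base
of a copy. Measuring to the nearest base (not the start) is the only choice
that is symmetric under genome rotation, which the tests verify. Null
libraries preserve the observed deletion-length multiset exactly: `n`
uniform starts, lengths shuffled and assigned, ends computed modulo `L` (null
deletions may wrap the origin — consistent with the circular treatment).
Observed and null distance samples are compared with a two-sided Welch test;
with fewer than two members in a set the means are still returned and the
p-value is flagged undefined.

# Breakpoint homology

Windows of ±10 bp around the 5' and 3' junctions are aligned with
Needleman–Wunsch under an affine gap model in the needle style: a gap of
length `k` costs `gap_open + k · gap_extend` (10 and 0.5 by default), match
+5, mismatch −4, and *end gaps are free*. The free-end-gap convention has a
visible consequence: two reverse-complementary-looking 4-mers such as `ACGT`
and `TGCA` do not align column-by-column for −16 but slide so their single
shared base pairs up (+5). Identity is matches over all alignment columns,
end-gap columns included. Scores are verified against exhaustive enumeration
of every alignment path for short pairs; tie-breaks on traceback prefer
substitution columns over gaps so identities are deterministic. The
identity–length relation uses Pearson correlation of identity against
log10(length) and a normality-gated two-group test at the 100-bp split, with
a length of exactly 100 assigned to the short group.

# Positional summaries

Sharing counts SNVs in 10-bp bins with presence/absence semantics per group
— several SNVs from one region in one bin are one instance — and reports the
occupied bins by sharing level in the categories 1, 2–3, 4–6 (regions) or 1,
2–3, ≥4 (animals). Allele-fraction profiles sum fractions in 100-bp bins and
scale the peak to 1; the all-zero profile is returned unnormalised and
flagged, and a partial final bin (when `L` is not a multiple of the width)
is kept and flagged. Per-gene load divides the count of SNVs in (or
deletions overlapping) each gene by gene length, with an optional
allele-fraction weighting for chord-diagram-style summaries, min-max scales
both vectors to [0, 1], and reports their Pearson correlation. VLRD–SNV
proximity is the circular distance from each VLRD 5' breakpoint to its
nearest SNV, with the co-positioning fraction the share of exact hits.

# Cohort statistics

The location test is gated: Shapiro–Wilk on each group at α = 0.05 routes to
Wilcoxon when either group rejects *and* the group is below the
central-limit exemption size (30); otherwise Welch. Factorial ANOVA fits the
main-effects linear model with type-II sums of squares (the standard choice
for unbalanced main-effects designs at 4–6 animals per cell; `car::Anova`
provides the distributional machinery), Tukey HSD for pairwise post-hoc
comparisons, and Bonferroni for multiplicity with the family size logged per
analysis rather than guessed globally. Animal enters as a fixed blocking
factor when requested, not a random effect, mirroring a three-way
(age, region, animal) analysis. The exact multi-set intersection test is
implemented in-package: the k-way intersection size under independent
uniform draws is obtained by chaining hypergeometric kernels —
conditional on the first `j` sets meeting in `m` elements, intersecting
with a set of size `n` is hypergeometric(N, m, n) — and the p-value is the
exact upper tail. For k = 2 this collapses to the classical hypergeometric
test, which the suite asserts; for k = 3 the distribution is checked against
10^5 Monte-Carlo draws.

# The synthetic-data generator

The generator emulates the *structure* the analysis assumes, not real
sequencing:

* uniform-composition circular genomes (default L = 16 300, mouse-mtDNA
  sized) with planted repeat pairs at exact Hamming distances and an
  annotated gene set whose last feature spans the origin;
* planted SNVs, deletions and VLRDs with specified heteroplasmy fractions;
  deletion lengths, when drawn rather than specified, follow the bimodal
  mixture 50% Uniform(1, 99) / 50% Uniform(1000, 15000), reflecting the
  short/long dichotomy of observed deletion-size distributions;
* paired 150-bp reads at a configured mean depth, placed uniformly on the
  circle and reported against the doubled reference; deletions appear as `D`
  CIGAR operations in junction-spanning reads (as a mapper with a large
  `maxindel` would emit), VLRDs additionally as discordant mate pairs
  lacking the proper-pair flag; base qualities constant Q30 and sequencing
  error off by default (read QC is an upstream contract), with a uniform
  substitution-error option for filter testing.

Two deliberate simplifications: carriage is expressed *locally* — a read
reflects the junctions and substitutions within its own span — so planted
variants are independently recoverable even when two deleted arcs could not
coexist on one molecule; and no nuclear-mitochondrial (Numts) contamination
is simulated, the pipeline instead accepting a read-ID exclusion list as the
upstream contract. Consequently, passing tests demonstrate correctness of
the *extraction and statistics machinery*, not robustness to mapping
artefacts, chimeras or error-prone real reads.

The cohort model draws per-sample counts as Poisson with expectation
`baseline × age multiplier × genotype-region multiplier × exp(animal
effect)`. Defaults plant the headline structure such data is expected to
show: baseline 20 SNVs per sample at 10 weeks, age multipliers (1, 10, 10)
— a ten-fold rise then plateau — deletion multipliers (1, 2.75, 2.75), a
genotype-region multiplier of 3 confined to COR/NAc/PVT, and a log-scale
animal effect SD of 0.1. These are testing devices chosen once, not
biological claims; they make planted effects detectable at n = 4 animals per
cell without being trivial.

# Problem sizes and determinism

The shipped tests run the full chain at L = 16 300 and depth 200 for
planted-variant recovery, 50 random 2-kb circles for repeat-oracle
equivalence, 100 seeded replicates of the null-library comparison, 10^5
Monte-Carlo draws for the intersection test, and 1000/100 seeded cohort
simulations for ANOVA calibration and power — sizes chosen so the whole
suite completes in minutes on one core while keeping every stochastic check
at three-sigma resolution. Every simulation is a pure function of its seed;
reruns of `run_pipeline()` with a fixed config are byte-identical, and
`scripts/acceptance.R` recomputes all reported quantities from scratch under
a caller-supplied seed.

# Known limitations

* No insertion or inversion calling; no base-quality recalibration; no
  mapper — the pipeline consumes SAM.
* The repeat definition is Hamming-based (ungapped); gapped repeats are out
  of scope.
* `VLRD` versus short-duplication identity is undecidable on a circle and
  is reported as a class, not resolved.
* The intersection test assumes independent uniform draws from a common
  background; structured backgrounds (e.g. position-biased SNVs) violate it.
* Welch/Wilcoxon gating at small n has limited power to detect
  non-normality; the gate's behaviour is itself simulated in the tests
  rather than assumed.
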