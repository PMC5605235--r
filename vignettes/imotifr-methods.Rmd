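---
title: "Methods: scanning, enrichment and spectroscopic analysis of i-motif DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning, enrichment and spectroscopic analysis of i-motif DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imotifr)
library(dplyr)
```

i-Motifs are four-stranded DNA structures formed by cytosine-rich
sequences: two parallel duplexes held together by intercalated,
hemi-protonated C:C^+^ base pairs. Because one cytosine of each pair must
be protonated, i-motifs are favoured at acidic pH, but sequences with long
enough cytosine tracts fold at neutral pH as well. This package implements
the computational side of a systematic screen for such sequences: a
folding-rule genome scanner, promoter and Gene Ontology enrichment
statistics for the hits, and the spectroscopic analyses (UV melting,
thermal difference spectra, CD pH titrations) used to characterize
candidate oligonucleotides. A family of seeded generators produces
synthetic data with known ground truth for every one of these stages, so
the entire pipeline is testable without any external download.

## The folding rule and its scanner

The screen's sequence model is the rule C~5~(N~1-19~C~5~)~3~: four tracts
of at least five consecutive cytosines separated by three loops of 1-19
arbitrary bases, where a loop may itself contain cytosine. `motif_rule()`
parameterizes the generalized form (tract base, tract length, tract count,
loop bounds), and `scan_sequences()` applies it to both strands: a
minus-strand hit is a match of the complementary G-run rule on the stored
sequence, reported on forward coordinates.

The rule alone does not define a unique decomposition of a matching
region, so the scanner canonicalizes:

* **Non-overlap, leftmost-first.** Hits on a strand are disjoint; scanning
  resumes after the end of each reported hit. This mirrors the common
  behaviour of pattern-based quadruplex scanners.
* **Leftmost-greedy registers.** Within a hit, each successive tract is
  placed at the earliest position that still admits a complete match, so
  loops are as short as possible (lexicographically minimal loop vector).
  This matters because loops may contain the tract base: in a run of 24
  cytosines the canonical decomposition is four 5-C tracts with three
  all-C loops of one base.
* **N handling.** `N` never matches a tract base (conservative for tract
  identity) but is a legal loop base.

The test suite checks the scanner against an independent brute-force
oracle (a lazy-quantified regular expression, which yields the same
leftmost/shortest-loop canonical form) on a thousand random sequences per
run, and against planted-truth genomes from `simulate_genome()`.

`decompose_tracts()` reuses the strict leftmost-greedy match to assign a
total loop length to an oligonucleotide. Some naturally occurring
candidates do not satisfy the strict rule as printed (for example, only
three runs of five or more cytosines); for these a fallback decomposition
is used -- the `n_tracts` longest maximal runs of the tract base, ties
broken leftmost, taken in genomic order, with loops as the inter-run gaps
-- and flagged with `fallback_used = TRUE`. Any convention here is a
choice: the printed stability figures do not define tract assignments for
non-conforming sequences, and the loop-length/stability correlations
reported by `pearson_cor()` on the bundled library depend on it (the
magnitude of the pH~T~ correlation in particular is sensitive; the sign is
not). We fix the convention above because it is deterministic, reproduces
the obvious decomposition for every rule-conforming oligonucleotide, and
degrades gracefully.

## Expected hit counts under an i.i.d. base model

`expected_hits_iid()` computes, in closed form, the expected number of
(start position, loop-length combination) placements of a rule in an
i.i.d. random sequence: each placement fixes `n_tracts * tract_len` tract
bases (probability `p^20` for the default rule) and leaves loop bases
free, so the expectation is `p^20` times the number of placements that fit
in the sequence. For a four-tract rule the number of loop combinations is
`(loop_max - loop_min + 1)^3` -- the cubic law that contrasts with the
roughly linear growth observed in real genomic screens, where cytosine
runs are far from independent.

Placement counting is chosen deliberately over counting distinct match
start positions: the two differ whenever several loop combinations match
at one start, and only the placement expectation has an exact closed form
and an exactly cubic loop-range law. The exhaustive tiny-sequence oracle
in the test suite enumerates all 4^8 sequences of length 8 for a miniature
two-tract rule and counts placements the same way. No clump or
first-occurrence correction is applied; this is the "simple probability"
expectation, not a prediction of non-overlapping hit counts.

## Promoter and GO enrichment

A promoter is defined as the 1 kb immediately upstream of a gene's
transcription start site: `[tss - 1000, tss)` for plus-strand genes and
`[tss + 1, tss + 1001)` for minus-strand genes (0-based, half-open;
windows are clipped at chromosome ends). One window per annotated gene is
used; transcript-level TSS multiplicity is out of scope. A hit overlaps a
promoter if it shares at least one base with the window, regardless of
strand pairing, since hits from either strand were screened against
promoters; each hit counts once overall but credits every gene whose
window it touches.

The chance expectation for the overlap fraction is the union coverage of
all promoter windows divided by genome length -- the simplest null in
which hits land uniformly at random. Enrichment is then a one-degree-of-
freedom goodness-of-fit over the two cells (overlapping, not overlapping)
without continuity correction; `chi_squared_enrichment()` attaches a
warning when an expected cell drops below one. GO over-representation
uses a two-sided Fisher's exact test per term, restricted to terms
annotating at least `min_genes` (default 100) genes of the universe so
that only reasonably powered hypotheses consume multiple-testing budget,
followed by Benjamini-Hochberg step-up adjustment over the tested terms.
Fisher's exact test is exact at any count, which matters because per-term
hit counts are small; GO-graph ancestor propagation is deliberately not
performed.

## UV melting curves

Melting and annealing temperatures are extracted by the first-derivative
method. Replicate scans are averaged on the temperature grid, the curve is
smoothed with a mild Savitzky-Golay filter (window 7 points, polynomial
order 2 -- enough to stabilize the derivative of 1 °C-sampled data without
biasing the transition midpoint), and `dA/dT` is formed by central
differences. Because an i-motif melt read at 295 nm is a hypochromic
drop, extrema of `|dA/dT|` are used, which makes the same code serve
heating and cooling branches. A candidate extremum is accepted if its
magnitude reaches 25% of the largest extremum; accepted extrema closer
than 4 °C apart are treated as noise ripples on a single transition
(only the largest is kept), and at most two transitions are reported,
ascending. Peak positions are refined by three-point parabolic
interpolation, and a numerically flat curve (derivative below 10^-9^ of
the absorbance range) reports no transition rather than a spurious one.

Hysteresis -- the signature of association kinetics slower than
dissociation -- is the difference between melting and annealing midpoints.
When a curve shows two melting transitions, `analyze_melt()` anchors the
hysteresis on the largest-amplitude transition of each branch, since a
single annealing temperature is typically resolved even for two-stage
melts.

## Thermal difference spectra

`compute_tds()` subtracts the folded (cold, 4 °C) absorbance spectrum
from the unfolded (hot, 95 °C) spectrum over 220-320 nm and rescales so
the maximum change is exactly +1. Classification uses band positions:
an i-motif TDS has its positive extremum at 240 ± 10 nm and a negative
trough of depth at least 0.2 at 295 ± 10 nm. A random-coil difference
spectrum has no deep trough anywhere in 280-320 nm and its positive
extremum in the unfolded-strand band at 275 ± 10 nm. Requiring the
positive-band position for the random-coil call (not merely the absence
of a 295 nm trough) keeps arbitrary non-DNA-like difference spectra --
for example a lone band at 260 nm -- in the `other` class instead of
labelling them random coil. The ± 10 nm windows and the 0.2 depth are
tolerances of our choosing; the band positions themselves are the
established signatures.

## CD pH titrations

The transitional pH (pH~T~, the pH of 50% folding) is the inflection
point of ellipticity at 288 nm versus pH. `fit_titration()` fits the
symmetric four-parameter logistic with a base-10 kernel,

$$E(\mathrm{pH}) = E_u + \frac{E_f - E_u}{1 + 10^{\,s\,(\mathrm{pH} - \mathrm{pH_T})}},$$

the standard Henderson-Hasselbalch-like titration form, whose inflection
is the parameter pH~T~ itself. Initialization takes the plateaus from the
data means at the two extreme pH values, pH~T~ from the pH whose
ellipticity is nearest the plateau midpoint, and a multistart over slopes
1, 2 and 4 (ties resolved toward the smallest slope); optimization uses
Levenberg-Marquardt least squares with pH~T~ bounded to the data range
plus one unit and slope bounded away from zero. Because the model is
affine-equivariant in the ellipticity, pH~T~ does not depend on whether
raw or normalized ellipticity is fitted. A series whose total excursion
does not stand clear of its point-to-point scatter (three times a robust
noise estimate from successive differences) is rejected as having no
transition rather than fitted. Summary tables round pH~T~ to 0.1 pH unit;
objects store full precision.

CD spectra themselves are classified by band positions: +288/-260 nm for
the folded i-motif, +273/-250 nm for the unfolded form, with ± 6 nm
windows chosen so the two positive bands, 15 nm apart, have disjoint
acceptance regions.

## Synthetic data: what it emulates, and what it does not

* `simulate_genome()` draws an i.i.d. background and embeds
  rule-conforming motifs with loop bases from the non-tract alphabet.
  After planting, the genome is rescanned and background near any
  discrepancy is redrawn, so the truth table is exact by construction.
  Real genomes are not i.i.d. -- CpG islands and C-run clustering are
  precisely why observed loop-length scaling is sub-cubic -- so scanner
  tests on synthetic genomes validate correctness, not genomic hit-count
  statistics.
* `simulate_melt_curve()` uses a two-state van't Hoff model,
  `theta(T) = 1/(1 + exp((dH/R)(1/T_m - 1/T)))`, with linear baselines,
  Gaussian noise (default 0.002 AU), and an apparent unfolding enthalpy
  default of 350 kJ/mol -- a realistic magnitude for intramolecular
  i-motifs with several C:C^+^ pairs, giving derivative peaks a few
  degrees wide. Hysteresis is mimicked phenomenologically by depressing
  the annealing midpoint (`anneal_offset`); no kinetic model is implied.
  Mixtures of two components emulate two-stage melts.
* `simulate_spectra()` and `simulate_cd_spectrum()` are Gaussian-band
  templates carrying the signature band positions with seeded noise; they
  are not fits to measured spectra, and band intensities are nominal.
* `simulate_titration()` evaluates the same logistic model the fitter
  assumes, plus noise -- closed-loop recovery therefore demonstrates
  estimator correctness, not robustness to model misspecification.

All generators are pure functions of their arguments including the seed.

## Problem sizes and numerical choices in the test suite

The shipped tests run the scanner-oracle comparison on 1,000 random
sequences of length up to 200 nt plus one 200 kb i.i.d. genome per
composition; melting-temperature recovery on 200 synthetic curves (T~m~
uniform on 10-80 °C, 1 °C grid, noise 0.002 AU); pH~T~ recovery on 100
noisy titrations (noise 0.3 mdeg on a 0.5-pH grid); classification
closed loops on 50 seeds per class; and a 200-replicate null simulation
(500 genes, five terms of 100) for false-discovery control. These sizes
make the whole suite complete in a few minutes on one CPU while leaving
the Monte-Carlo assertions comfortably away from their thresholds.

## Known limitations

* The scanner's canonicalization (non-overlap, leftmost-greedy) is one of
  several defensible conventions; on pathological inputs other
  pattern-based screens may delimit hits differently.
* The i.i.d. expectation is a per-placement mean, not a non-overlapping
  hit-count prediction; no clump correction is attempted.
* The enrichment null (uniform hit placement) ignores base-composition
  confounding between promoters and the genomic background, which in real
  data inflates enrichment; permutation nulls are out of scope.
* The loop-length/stability correlations depend on the tract/loop
  decomposition convention for sequences that violate the strict rule;
  the package reports its own convention's values rather than asserting
  any particular published magnitude.
* Van't Hoff thermodynamic parameter extraction (ΔH, ΔS) from melting
  curves and kinetic modelling of hysteresis are intentionally not
  implemented.

## A worked synthetic example

```{r example}
g <- simulate_genome(
  length = 50000,
  planted = list(
    list(loop_lengths = c(3, 3, 3), strand = "+"),
    list(loop_lengths = c(1, 5, 19), strand = "-")
  ),
  seed = 11
)
hits <- scan_sequences(g$record)
hits[, c("source_id", "start", "end", "strand", "total_loop_length")]

ann <- simulate_annotation(20, 50000, seed = 11)
w <- promoter_windows(ann$tss, 1000, ann$chrom_sizes)
ov <- overlap_hits(hits_to_bed(hits), w)
chance <- chance_expected_fraction(w, ann$chrom_sizes)
tidy(chi_squared_enrichment(ov$n_overlapping, nrow(hits), chance))
```
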