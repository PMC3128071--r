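---
title: "Methods: inter-CDS length distributions and the neutral rearrangement model"
author: "intercds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-CDS length distributions and the neutral rearrangement model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and design choices behind
`intercds`: what each computation assumes, which knobs matter, what the
synthetic clade generator does and does not emulate, and where numerical
decisions were genuinely open.

## The measurement: inter-CDS regions

All distances are measured between ORF boundaries of adjacent
protein-coding genes on the same chromosome: `right_cds_start −
left_cds_end − 1` bp, the number of nucleotides strictly between the two
coding sequences.  Pairs whose ORFs abut or overlap (length ≤ 0) are
excluded; "no overlap" is operationalized at ORF level because UTR
coordinates are unavailable in most annotation sources.  Multi-segment
CDS annotations are collapsed to the union span per gene — a convention,
since annotation sources differ in whether multi-exon structures occur.

Orientation follows from the flanking strands: convergent (`+ -`),
divergent (`- +`), unidirectional (equal strands).  The classification
is invariant under reading the chromosome from the other end (reverse
both strands, swap left/right), which the test suite asserts
exhaustively.

Two filters remove regions whose evolution is atypical: flank pairs that
hit each other with BLAST bitscore ≥ 50 in either direction (tandem
duplicates; the threshold is inclusive), and regions overlapped by ≥ 1 bp
of a repeat mask.  `adjacency_scope` controls whether non-coding
annotations break adjacency (`"all_features"`) or are ignored
(`"protein_coding_only"`, the default): annotations differ in how
completely they record non-coding genes, so both readings are provided
and neither is asserted as canonical.

## Region age from neighbourhood conservation

A region of a focal species is conserved in another species when (a)
both flanking genes have orthologs there, (b) those orthologs flank a
retained region themselves, and (c) each gene presents the same end (5'
or 3') to the region as its ortholog does.  Matching *facing ends*
rather than raw strand pairs makes the test invariant to arbitrary
chromosome reading direction and implies that the orientation class
matches.  One-to-many ortholog relations are accepted: any witnessing
combination counts, since the conservative alternative (requiring all)
would discard genuinely conserved neighbourhoods around duplicated
genes.  Regions flagged as tandem duplicates in the *other* species
cannot witness conservation, because they are excluded from analysis
everywhere.

Regions conserved nowhere are *young*; all others are *old*.  Old
regions are binned by the most distal clade (along the rootward path
from the focal leaf) containing a conserving species; intermediate
clades without conservation are ignored, since a single loss should not
rejuvenate a region.  `scheme_from_tree()` builds such schemes from the
attachment order of sister clades; because published groupings sometimes
merge several attachment levels into one class, the `breaks` argument
gives the number of consecutive levels per class, with the plain
`n_classes` form merging everything beyond the nearest `n_classes − 1`
levels into the farthest class.

## Length statistics

**Lower limit.**  The left edge of a stratum's length distribution is
estimated by the empirical 1% quantile (linear interpolation, rounded to
integer bp).  The sample minimum is available (`method = "min"`) but a
single mis-annotated ORF can drag it arbitrarily low; 1% tolerates a few
such errors while staying within a few bp of a genuine truncation point
at stratum sizes of a few hundred.  Below n = 20 the quantile is
meaningless and the estimator falls back to the minimum with a warning.
On 5,000 draws from a log-normal left-truncated at 150 bp the estimator
returns ≈ 164 bp: the bias of a 1% quantile relative to a hard edge.
Tests and the acceptance script use re-simulated bands around planted
truncation points rather than pretending the estimator is unbiased.

**Gaussian fits and the nested F-test.**  Lengths are log10-transformed
and binned (default width 0.1); one or two scaled Gaussian curves are
fitted to the bin counts by *variance-weighted* least squares with the
usual Poisson weights `1/max(count, 1)`.  The weighting matters: bin
counts have variance roughly equal to their mean, and fitting them
unweighted lets the second component chase noise in the high-count bins
— in calibration runs the unweighted nested F-test rejected a true
one-component model 32% of the time at α = 0.01, versus 3% with weights.
Models are compared by `F = [(RSS₁ − RSS₂)/Δp]/[RSS₂/(n_bins − p₂)]`
with `3k` free parameters per `k`-component fit.  The two-component fit
uses multi-start optimization (25%/75% quantile means plus four seeded
random starts; Levenberg–Marquardt, Nelder–Mead fallback), keeping the
best weighted RSS; since the models are nested, `RSS₂ > RSS₁` can only
mean the optimizer failed, and `compare_fits()` refuses to continue
rather than reporting a negative F.

**Composition and correlations.**  Under independent random
orientations, adjacent pairs are 25% divergent, 50% co-oriented, 25%
convergent; `orientation_composition_test()` is a χ² goodness-of-fit
test of the composition inside a length window against those
proportions, exposing the deficit of promoter-containing pairs at short
distances.  Cross-species summaries use the sample CV (n−1 denominator)
and Pearson correlation with the two-sided t-test (df = n − 2).

**Minimal promoter estimates.**  `report_minimal_space()` subtracts the
convergent (promoter-less) *lower limit* from each promoter-containing
class's lower limit.  Subtracting the convergent *mean* — an equally
plausible reading — yields negative estimates for several species, since
the convergent mean exceeds the promoter-class lower limit there; the
difference of two left edges is the defensible quantity and is the
convention used, noted by a message whenever the function runs.

## The neutral rearrangement simulator

The model asks whether old-region length distributions are what
length-weighted removal from the ancestral distribution would leave.
The total (old + young) observed distribution stands in for the
ancestor, assuming the length distribution is at equilibrium.  With
`N_total` regions and `N_young` removals, the per-nucleotide rate is
`p = N_young / Σ effective lengths`, and a region breaks with
`P = p × effective_length`, where the effective length is the full
length (Model A) or the length minus a minimal promoter offset, clamped
at zero (Model B — regions at or below the offset can never break,
emulating a strongly deleterious promoter disruption).

Two removal algorithms are provided because the natural readings of the
procedure differ: the default removes regions one at a time by weighted
sampling without replacement (exactly `N_young` removals); the
alternative (`bernoulli_sweep`) sweeps the whole set repeatedly,
breaking each region independently with probability `P` per sweep, and
truncates the final sweep by weighted choice if it overshoots.  The two
agree in distribution when `N_young ≪ N_total` (asserted on a fixture);
the sweep's survivor condition is implemented as *break if r < P*, the
only reading consistent with removal probabilities proportional to
length.  Each replicate (default 10, as averaged histograms are
reported) runs on an independently derived sub-seed, so any replicate is
individually reproducible.

Model fit is summarized two ways: a two-sample KS statistic between
pooled survivors and the observed old lengths, calibrated against a
simulated null (`simulate_ks_null()` generates independent
single-replicate realizations and computes their KS against the pooled
survivors — under model correctness the observed data behave like one
more realization); and a per-bin table of observed − simulated counts,
whose right tail exposes long regions the neutral model cannot account
for.  Insertions and deletions are deliberately ignored; the model is a
bag of lengths, not a chromosome.

## The synthetic clade generator

`clade_spec()` fixes the study conditions; generation is a pure function
of the spec (one master seed).  Defaults emulate the statistical
structure of compact yeast-like genomes:

* convergent gaps: log10-normal, mean 2.30, sd 0.35, no truncation — the
  promoter-less null, log-normal because neutral indels act
  multiplicatively on length;
* unidirectional gaps: mean 2.60, sd 0.30, left-truncated at 130 bp,
  plus a 7% long-tail component (mean 3.30, sd 0.20) — the elevated
  right tail of promoter-containing regions;
* divergent gaps: a truncated (170 bp) two-component mixture, 0.6 ×
  N(2.45, 0.12) + 0.4 × N(2.85, 0.12) — shared bi-directional versus
  independent double promoters.  The component sds match the
  two-component magnitudes used in the calibration analyses; the
  per-class overall spread (≈ 0.23) is then somewhat below the 0.30–0.45
  range typical of the single-Gaussian classes, a compromise that keeps
  the two promoter modes resolvable at stratum sizes of a few hundred;
* CDS lengths are constant (500 bp), so extraction recovers the drawn
  gaps exactly; strands are iid, so orientations follow the 25/50/25
  null.

Evolution proceeds along a rooted tree.  Each rearrangement cuts the
genome at a gap chosen with probability proportional to its length,
relocates the cut-off block into a uniformly chosen other gap, and draws
the two new junction lengths from the *young* strata: the ancestral
strata with log10 means shifted by log10(1.8) and sds scaled by 1.3, so
young regions are longer and more variable.  One relocation therefore
destroys two ancestral regions and creates two young ones; the published
mechanism is unspecified beyond counts and length-weighting, and this is
the simplest operator consistent with both.  Orthology is identity by
descent (confidence 1.0), and the truth table records each region's
branch of origin plus, via region-id retention, the species set that
conserves it — enough to compute every downstream expectation without
re-running the pipeline.

Long-tail draws of the unidirectional class are *protected*: their
rearrangement weight is zero, emulating stabilising selection on
unusually long regulatory regions.  Without protection the generator's
own length-weighted removal thins the old tail exactly as the neutral
simulator predicts and no excess exists to detect; with it, the observed
old distribution keeps long regions the neutral model over-removes,
reproducing the positive right-tail residuals seen in real
promoter-containing strata.

What the generator does **not** emulate: nucleotide sequences and indel
evolution (lengths change only by rearrangement), realistic chromosome
counts, inversions (strands are preserved by descent, so conservation
recovery is exact rather than merely expected), annotation errors, and
incomplete or erroneous orthology.  Passing tests on these bundles
therefore demonstrate correctness of the pipeline's logic under clean
inputs, not robustness to the noise of real annotation pipelines.

## Problem sizes and determinism

The test-suite and acceptance analyses use a 4-species clade with 2,800
genes per species (4 chromosomes × 700 genes) and 90 rearrangements per
terminal branch — about the gene count of a real yeast genome, giving
stratum sizes (≈ 650 divergent old regions) at which the mixture test
and the KS comparison have useful power while the whole analysis runs in
seconds.  Calibration suites use 200 replicates at n = 2,000; the
simulator oracle checks use 10⁵ replicates against exact enumeration at
n ≤ 6.  Every stochastic step takes an explicit seed, sub-seeds are
derived from one master seed, and `run_analysis()` writes byte-identical
outputs for identical inputs and seed.

## Known limitations

* The equilibrium-ancestor assumption (total distribution ≈ ancestral
  distribution) is only approximately satisfied — by the generator as by
  real genomes — so the convergent KS check sits close to its
  calibration boundary at realistic sample sizes.
* The lower-limit quantile has an upward bias of ~10 bp relative to a
  hard truncation at typical stratum sizes; comparisons across strata of
  similar size are unaffected, absolute values carry the bias.
* Age classes ignore conservation losses by design; a region conserved
  only in a distal clade is assigned the old class even if every nearer
  clade lost it.
* `read_annotation()` trusts its input's gene models; it validates
  coordinates and strands but cannot detect mis-annotated ORF
  boundaries, which propagate directly into length samples.
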