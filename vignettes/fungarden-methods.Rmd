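---
title: "Methods: molecular networking and chemical proportionality in layered gardens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular networking and chemical proportionality in layered gardens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fungarden)
```

# The problem

A leaf-cutter ant fungus garden is a spatially ordered bioreactor: plant
material enters at the top, is progressively decomposed by the fungal
cultivar and its microbial community, and spent substrate is discarded to a
trash pile. Sampling along that material flow — leaves (`L`), garden layers
top to bottom (`A`–`D`), trash layers (`TT`, `TM`, `TB`) — and acquiring
untargeted LC-MS/MS per sample yields thousands of features (m/z × retention
time with a peak area per sample). The analytical question is: *which pairs
of chemically related molecules change their relative abundance between
adjacent locations*, because those are the signatures of location-specific
transformation or degradation.

`fungarden` answers this in four steps: a spectral-similarity network to
find chemically related pairs, mass-shift annotation to name the implied
modification, a log ratio-of-ratios "proportionality" score per network edge
and location pair to find where the relationship changes, and cartography
export to place the result back in space.

# Models and assumptions

## Modified cosine and network topology

Fragment spectra of structurally related molecules share fragments either at
identical m/z or offset by the precursor-mass difference. The modified
cosine therefore admits candidate peak pairs within a fragment tolerance
(default 0.02 Da, a Q-TOF-scale setting) of either offset, weights
intensities as √I (so dominant fragments do not saturate the score),
L2-normalises each spectrum, and accepts candidate pairs greedily by
descending intensity product under a one-use-per-peak constraint. The greedy
sum is bounded by the optimal one-to-one assignment, which is bounded by 1;
on small spectra the test suite verifies greedy = optimal by exhaustive
search. Ties in the greedy ordering break deterministically toward the lower
m/z pair, so identical inputs give identical networks on any platform.

Before scoring, two cleaning filters are applied, both with inclusive
boundaries (a choice the underlying method leaves open; inclusivity is
pinned by tests): fragments within ±17 Da of the precursor are removed
(residual precursor signal carries no structural information and inflates
similarity), and only fragments ranking in the top 6 by intensity within
±50 Da of their own position are kept (local noise suppression that adapts
to spectral density).

Edges require cosine > 0.7 *and* at least 6 matched ions. The matched-ion
threshold is stated ambiguously in common practice ("more than 6" vs "at
least 6"); the default here is inclusive (≥ 6) and configurable. Two further
topology rules control network density: an edge survives only if each node
is among the other's top 10 neighbours by score (ranked after thresholding,
with ties broken by matched ions, then smaller |Δm/z|, then id — again for
determinism), and any connected component larger than 100 nodes has its
lowest-scoring edges removed, one score level at a time with re-checking,
until it fits. Removing tied-lowest edges together is the conservative
reading of "remove the lowest scoring edges"; the loop terminates because
every step strictly reduces the offending component's edge count. Singleton
nodes keep their own family id so downstream exports always have a complete
assignment.

## Exact masses

All annotation rests on monoisotopic atomic masses (H 1.0078250319, C 12
exactly, N 14.0030740052, O 15.9949146221, P 30.97376151, S 31.97207069 Da),
the proton (1.00727646 Da) and the electron (0.00054858 Da). [M+H]⁺ m/z is
the neutral atom sum plus a proton; a formula written as a cation (trailing
`+`) is its atom sum minus an electron. The two conventions agree for the
same ion written either way, which the tests assert. Published "accurate
mass" columns sometimes subtract a hydrogen *atom* from [M+H]⁺ rather than a
proton — a ~0.0005 Da reporting convention this package does not reproduce;
it computes from first principles only. ppm errors are signed as
(calculated − detected)/calculated × 10⁶, so a detected ion above the
calculated mass has negative error.

## Mass-shift catalog

Edge |Δprecursor| values are matched against a catalog of named
transformations at ±0.01 Da. The default tolerance is half the fragment
tolerance: precursor masses are better determined than fragments, and
0.01 Da separates every shipped catalog entry unambiguously. The shipped
entries (H₂, CH₂, O, C₂H₄, C₂H₄O, C₆H₁₀O₅, C₈H₂₁NO₂) are the shifts most
frequently discussed for decomposing plant material; the catalog is a plain
table (label, formula) validated against the formula calculator, and users
can extend it from a CSV. Deltas are counted unsigned — a shift reads "gain
or loss" — with direction carried by the proportionality score instead.

## Proportionality score

For features *N* and *M* joined by an edge, with aggregated areas in
locations S₁ and S₂,

$$\mathrm{score} = \log_{10}\frac{(N_{S_1}+k)/(M_{S_1}+k)}{(N_{S_2}+k)/(M_{S_2}+k)},
\qquad k = 10^{-10}.$$

Design choices, each configurable:

* **Log base 10** (the method's source writes an unbased log): base 10 makes
  the conventional cutoff of |score| > 1 mean exactly a tenfold change in
  the abundance ratio.
* **k = 1e−10** guards zero areas; with areas ≥ 1 its perturbation of the
  score is below 10⁻⁸, and a feature absent in one location produces the
  characteristic large finite score (the worked zero-numerator case gives
  −11.0).
* **Replicate aggregation = mean per location** before scoring, because the
  compared units are locations with replicate samples, and deposited
  proportionality tables in this workflow are per location pair; median and
  sum are available.
* **N = the heavier edge member**, so a positive score for (earlier, later)
  pairs means the heavier molecule is relatively enriched earlier, and a
  negative score means it accumulates downstream. Output headers document
  the convention.
* Scores are computed on **reference-normalised, untransformed** areas: the
  cube-root transform eases visual comparison of features spanning decades
  but would silently change score magnitudes (log of a ratio of cube roots
  is a third of the raw score), so it is off by default for scoring.

The score is antisymmetric in locations and in features, scale-invariant up
to the k-perturbation, and monotone in each numerator area — all asserted as
property tests.

## Preprocessing

The fixed order is: constant-feature removal → optional IQR low-variability
filter → reference-feature normalisation → optional cube root. The internal
standard (sulfamethazine, [M+H]⁺ m/z 279.0910, RT ≈ 2.55 min) can be
selected by id or located by an m/z ± 0.01 Da, RT ± 0.2 min window; it is
exempt from the filters (a perfectly spiked standard is itself constant) and
must be strictly positive in every sample — a zero reference is an error
naming the sample, never an imputation. The IQR filter's retained fraction
defaults to 0 (off) because only the *use* of an IQR filter, not its
fraction, is standard; it is exposed for users who want it. Missing values
are rejected rather than imputed.

# The synthetic garden

`generate_garden()` emulates the statistical structure the analysis assumes:

* **Abundance gradients.** Parent compounds enter with the leaves and decay
  geometrically along the 8-location chain (`base × decay^index`,
  default decay 0.25 per step); products mirror the profile
  (`base × decay^(7−index)`), accumulating toward the trash; flat features
  are available as negative controls. With decay 0.25, a decaying-parent /
  accumulating-product edge has an expected chain-pair score of
  2·log₁₀(0.25) ≈ −1.20 — beyond the cutoff but close enough that replicate
  noise exercises the decision boundary rather than trivialising it.
* **Replicates.** 5 samples per location (40 in total), scattered around the
  location mean by a mean-preserving lognormal (sdlog = `noise_sigma`,
  default 0.1); sigma 0.1–0.2 is typical peak-area CV territory for
  electrospray LC-MS.
* **Spectra.** Each family shares an 8-fragment backbone on a
  family-specific m/z grid (kept ≥ 20 Da below the precursor so the ±17 Da
  filter cannot touch it), with geometrically decreasing intensities so the
  window filter and √-weighting are exercised non-trivially. A product's
  spectrum shifts half of the backbone by the transformation delta,
  guaranteeing both direct and precursor-shifted matches. Generation fails
  loudly if the fragment count cannot satisfy the matched-ion threshold, or
  if two unrelated families could coincidentally share enough matchable
  fragments to link.
* **Ground truth.** Feature formulas (product m/z − parent m/z equals the
  planted delta to < 10⁻⁶ Da), family memberships, and — per transformation —
  the chain location pairs whose expected noise-free |score| exceeds 1,
  computed in closed form from the design profiles.
* **Geometry.** Spots sit on a unit grid, one z-slab per location, radius
  0.5 — arbitrary but fixed, since the cartography viewer needs only
  consistency.
* The default design (4 parents, 5 products, 1 spiked standard, 40 samples)
  keeps full-pipeline runs under a second, so the noisy-recovery experiment
  (20 seeds at sigma 0.2) runs comfortably inside a test suite.

What the generator deliberately does **not** model: chromatographic peak
shape, isotope envelopes, adducts beyond [M+H]⁺, in-source fragmentation,
co-elution, or real plant chemistry. Passing the recovery tests therefore
demonstrates the pipeline's correctness on data satisfying its assumptions,
not its performance on instrument data, where feature detection quality and
adduct confusion dominate.

# Numerical and degenerate-input behaviour

* Empty spectra score 0 against anything (not an error); empty candidate
  sets yield edgeless networks with singleton families.
* All ranking steps (greedy matching, top-K, capping, annotation ties) have
  total, documented tie-breaks; reruns are byte-identical given the same
  inputs, and the generator is byte-identical given the same seed.
* Scores recompute exactly from the areas stored in the records
  (asserted to 10⁻¹²).
* Readers validate counts and vocabularies: unknown location labels, samples
  without metadata, negative areas, missing precursors and malformed MGF
  blocks are errors naming the offender, never silent drops.

# Known limitations

* The mutual top-K rank is computed after thresholding; computing it before
  is a defensible alternative (the workflow description leaves it open) and
  would yield sparser networks. The choice is configurable at the candidate
  level.
* Family capping removes the component-minimum score level per iteration;
  other schedules (e.g. removing a single edge among ties) can yield
  different final components when ties straddle a split.
* The proportionality score is a fixed-cutoff prioritisation, not a
  statistical test: no replicate variance enters the score, and no
  multiple-testing control is applied — by design, matching the method it
  implements.
* Library matching reports the best hit above threshold; it does not
  estimate identification error rates.
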