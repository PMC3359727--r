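---
title: "CrystalCast methods: from raw characterization data to a diffraction-score prediction"
author: "CrystalCast authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CrystalCast methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CrystalCast)
```

# Overview

CrystalCast converts raw protein-characterization experiments into a small
set of summary statistics and routes them through a regression partition
tree to predict an ordinal crystallographic outcome. This vignette is the
package's own account of the models behind each step: what is fitted, which
parameters matter, which conventions were genuinely open choices, and what
the synthetic-data tests do and do not demonstrate.

The outcome scale is the 0–6 *diffraction score*: 0 no crystals; 1 crystals
that do not diffract; 2 diffraction worse than 10.00 Å; 3 10.00–4.01 Å;
4 4.00–2.81 Å; 5 2.80–2.01 Å; 6 2.00 Å or better. Each printed range
includes its endpoints, so `resolutionToScore()` maps 10.00 → 3, 4.00 → 4,
2.80 → 5 and 2.00 → 6.

# Sequence features

`monomerMW()` sums average (not monoisotopic) residue masses plus one
water; purified-protein work compares against average masses on gels and in
DLS-derived estimates, so monoisotopic masses would be systematically low.
`X` contributes the mean residue mass. `avgHydropathy()` is the plain
Kyte–Doolittle mean (GRAVY) with no sliding window — the feature describes
the whole chain, not local segments — and excludes `X`.

Disorder is an *injection point*. The predictor needs the longest
contiguous stretch of disordered residues (`l_dis`), but per-residue
disorder calls come from trained external predictors that this package
deliberately does not bundle or call over the network. Users supply calls
(two-column CSV, `readDisorderCalls()`); only in their absence does
`fallbackDisorder()` apply a deterministic heuristic: a per-residue
disorder-propensity scale (TOP-IDP-style, charged/structure-breaking
residues positive, hydrophobics negative) smoothed with a 15-residue
centered moving average and thresholded at 0.30. The window matches the
length scale at which short linkers should not count as disordered
segments; the threshold sits between the scale's order- and
disorder-promoting ranges. Every output produced this way is labelled
`"fallback, not DisEMBL"` so downstream users know a heuristic, not a
trained predictor, produced the calls. For multi-protein samples the
*maximum* monomer MW and *maximum* disorder stretch over the sequences are
used.

# DSF melt-curve analysis

A melt curve is fitted (after truncation, below) with

$$F(T) = b + \sum_{j=1}^{k} \frac{\Delta F_j}{1 + e^{(T_{m,j} - T)/s_j}}$$

by Levenberg–Marquardt least squares (`minpack.lm`). Derived per
transition: maximum slope $\Delta F_j / (4 s_j)$ (the derivative at the
midpoint) and the full width at half maximum of $dF/dT$,
$2\ln(3+2\sqrt{2})\,s_j \approx 3.5255\,s_j$ — both closed forms of the
Boltzmann sigmoid, asserted as identities in the tests.

**Truncation.** Past the melt, dye–protein aggregates quench and the signal
decays; fitting the decay would bias the transition parameters. The fit
region ends at the global maximum of the 3-point-moving-average-smoothed
fluorescence, with argmax ties broken to the *latest* index so monotone or
flat curves keep their full range.

**Initialization and restarts.** Midpoint seeds are the largest peaks of
the smoothed derivative; `s` seeds at 2 K; up to 5 restarts jitter the
seeds under a fixed local RNG (the caller's random stream is saved and
restored), so fits are reproducible. Non-convergence after the restart
bound raises an error carrying the best residual.

**Predictor value.** `r_dsf = F(303.15 K) / F(Tm_major)` evaluates the
*fitted* model at 30 °C and at the midpoint of the major (steepest)
transition. A well-folded protein starts near baseline, giving a small
ratio; pre-exposed hydrophobic surface raises it. The direction
(30 °C value in the numerator) is this package's convention and must be
respected by any imported tree thresholds. Input temperatures below 150
are treated as Celsius and converted.

**Transition count.** `selectTransitionCount()` accepts an extra
transition only when it improves the BIC by more than 10 (a conservative
threshold: three extra parameters must buy substantial residual
reduction). Pure-noise curves fit k = 1 with a warning. The rubric is
deliberately simple; the count can always be fixed by hand.

**Limitations.** The baseline is a single additive constant — sloping pre-
or post-transition baselines are not modelled; curves with strong linear
drift before the melt will bias `delta_f` slightly.

# SEC analysis

The run log's flow rate, fraction size and collection start convert the
time axis to continuous fraction coordinates
$f(t) = 1 + (t - t_0)\,\phi / v$. Fraction boundaries are **half-open** in
volume and indices are 1-based (a point exactly on a boundary opens the
next fraction); points before collection belong to fraction 0. The
half-open, 1-based convention matches fraction-collector hardware and is
stated explicitly because nothing in the file formats pins it down.

Peak seeding takes local maxima of the 5-point-smoothed trace above a noise
floor of median + 3×MAD of the raw trace (the raw-trace MAD makes the floor
conservative relative to the smoothed maxima, so flat noise yields no
candidates). The mixture $A(f) = \sum_i h_i e^{-(f-c_i)^2/2w_i^2}$ is
fitted by Levenberg–Marquardt with the same restart policy as DSF.

Two statistics are derived:

* `r_sec = RSS₁/TSS`, the residual of a *separate* single-Gaussian fit
  normalized by the total sum of squares (a 1 − R² form), clamped to
  [0, 1]. Normalizing by TSS makes the value dimensionless and comparable
  across instruments and loading amounts; it is invariant under rescaling
  of the absorbance axis. Constant traces have no defined value (missing).
* Pooled percent purity: the pool `[first, last]` in fraction indices is
  integrated over the continuous interval `[first, last + 1)` (consistent
  with the half-open mapping); purity is the in-pool integral of the pool's
  main component — the component with the largest in-pool integral, *not*
  the globally tallest one, so the number describes what was actually
  pooled — over the in-pool integral of the whole mixture. Component
  integrals use the Gaussian error function, checked in tests against
  numeric quadrature.

# DLS analysis

Vendor peak tables (radius, polydispersity, %Pd, %intensity, %mass per
peak, optional intensity-vs-radius histogram) are parsed as is; the package
does not deconvolve autocorrelation functions. The major peak is the
highest-intensity peak with hydrodynamic radius in 2–10 nm — the window
where monomeric and small-oligomer proteins scatter; outside it, salts and
aggregates dominate. If nothing qualifies, the global intensity maximum is
taken and flagged. Intensity ties break toward the smaller radius
(monomer-favoring). The user can override the choice; Pmaj, the oligomer
ratio and the score are recomputed.

Radius converts to mass by the globular-protein calibration
$MW(\mathrm{kDa}) = (1.68\,R_h)^{2.3398}$, the empirical power law used by
common vendor software; both constants are arguments because calibrations
differ. The oligomer ratio divides this mass by the sequence monomer mass
(≈1 monomer, ≈2 dimer). `Pmaj` is the major peak's intensity over the
total intensity of all peaks *at least as large* as it — smaller species
are excluded because they are typically buffer components that do not
compete during crystallization. The ordinal DLS score (4 = single peak
with %Pd < 15; 3 = single peak otherwise; 2 = multiple peaks, major ≥ 50%
intensity; 1 = otherwise) is a configurable display rubric; it is stored
but not a default predictor input.

# Gel-based scores

**Yield** is either a 0–5 visual score (5, "extremely high", pinned at
approximately 100 mg per liter of culture; the equivalence is linear in
the score) or mg of purified protein per liter of culture;
`effectiveYield()` prefers the visual score when both exist and tags which
kind it returned. **Limited proteolysis** scores each protease 1–5 from
the major band's MW change and intensity retention after 1 h and 24 h
digestion: 5 requires an essentially unchanged band at 24 h (≤5% MW
change, ≥90% intensity); 1 means the band is gone (<10%) already at 1 h;
the intermediate cuts (90%/50%/10%) interpolate between those defined
endpoints and ship as configuration. The per-protease scores are averaged,
unrounded. **SDS purity** is stored and serialized only: the package's
default feature set excludes it (cohorts that reach crystallization trials
are pre-filtered for purity, leaving the score uninformative), and it
likewise excludes Lp stability, which can be re-enabled for user-trained
trees by adding the column to the training cohort.

# Sample model and interchange format

A `ProteinSample` holds sequences plus, per experiment type, a list of
results and a selection. When several results of one type are selected,
the sample summary and the predictor use the arithmetic *mean* of each
summary value; an empty selection is a missing marker, never zero. Missing
features are carried explicitly (`NA` / `missingMask()`) and are *not*
imputed at this layer — how to route them is the predictor's decision.

Every result serializes to a standardized XML document
(`<protchar_result type=... version=...>` with `metadata`, optional raw
`series`, `analysis` values, and a typed payload element). Numbers are
written with 15 significant digits, so round trips preserve values well
beyond the guaranteed 9 significant digits; schema violations are rejected
naming the offending element. Projects are a thin JSON manifest of file
paths — no database.

# The predictor

`trainTree()` grows a CART-style regression tree: at each node, over all
features and all midpoints between adjacent observed values, it takes the
split maximizing the reduction in the sum of squared score deviations,
stopping at `minLeaf` (default 5) samples per child, `maxDepth` (default
5), or zero gain. Every node stores the mean and the 0–6 histogram of its
routed training samples, so leaf payloads are exact by construction (a
tested invariant). Samples missing the split feature go to the child with
more observed samples; the route is stored per node and reused verbatim at
prediction time — surrogate splits were rejected as the alternative
because majority-routing is the simplest contract that is deterministic
and explainable in the decision path.

`predictOutcome()` reports the leaf mean, the interpretation band
(configurable; below 1 "not likely to form crystals", 4.5 and above
"likely to form crystals with diffraction of 2.8 Å or better", two graded
bands between), the train/test histograms, and the path. A step is
*favorable* when the taken child's mean exceeds the sibling's, *neutral*
(not unfavorable) on exact ties, and flagged when a missing value was
routed. `crystallizationSuggestions()` maps each unfavorable split to
configured advice (disorder → truncate; yield/SEC → protocol changes; …);
a top-category sample with no crystals yet instead gets a pointer to
further screens. Published trees can be encoded verbatim in the JSON tree
format and run unchanged; which DLS quantity (Pmaj or the oligomer ratio)
a given tree uses is a property of that tree's definition — the package
computes both.

# Synthetic data and what the tests show

`synthDsfCurve()`, `synthSecChromatogram()`, `synthDlsExport()` and
`synthCohort()` emit files in exactly the dialects the parsers accept,
with the generative truth in JSON beside each fixture. Defaults represent
typical bench data: a 323 K melt of width 1.5 K over a 293–363 K ramp with
1% multiplicative noise; chromatogram peaks a few fractions wide with
small additive noise; a three-peak DLS table (small contaminant, 4 nm
protein peak, aggregate); cohorts of n = 100 with features drawn from
beta/lognormal/geometric shapes and a planted single-split rule with
outcome noise σ = 0.5.

Test problem sizes are deliberately small and fixed-seed: 20-seed
repetitions for DSF Tm recovery (|ΔTm| ≤ 0.5 K under 1% noise), SEC center
recovery (±0.1 fraction), and planted-threshold recovery (n = 100,
σ = 0.5); exhaustive enumerations for the DLS rules and for split
optimality at n ≤ 12. These demonstrate numerical correctness and
loop-closure of the pipeline — they do *not* demonstrate predictive
accuracy on real proteins, which depends entirely on the training cohort a
user supplies. Real instrument quirks not emulated: sloping DSF baselines,
SEC baseline drift and tailing (non-Gaussian) peaks, and DLS peak tables
whose intensity percentages do not sum to 100 (tolerated to 1%).

# Numerical choices, in one place

* Fits: Levenberg–Marquardt, ≤5 jittered restarts under a saved/restored
  local RNG; convergence accepted on `nls.lm` info codes 1–4.
* DSF truncation argmax ties → latest index; DSF Celsius/Kelvin cut at
  150; `r_dsf` evaluated at 303.15 K.
* BIC threshold 10 for adding a transition.
* SEC noise floor median + 3×MAD (raw trace); 5-point smoothing for
  seeding; purity via error-function integrals.
* Tree thresholds at midpoints; gain ties resolved toward the first
  feature in canonical order and the smallest threshold (deterministic);
  `r_sec`, `p_maj` clamped/validated to [0, 1].
* All generators and the CLI accept a seed; identical seed + spec ⇒
  byte-identical fixtures.
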