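---
title: "Quantifying exurban compactness and detecting bird threshold responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying exurban compactness and detecting bird threshold responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`exurbia` implements a complete analysis chain for one question in landscape
ecology: when low-density housing (exurban development) spreads through a
forested region, do forest and forest-edge birds respond to *how clustered*
that development is, over and above how much of it there is? This vignette
explains the models and procedures behind each stage, the tunable parameters
that matter, and the choices made where the design was genuinely open.

## Morphological spatial pattern analysis (MSPA)

The spatial-pattern primitive is a pixel-level classification of a binary
raster (foreground = exurban development, 30 m pixels by default) into seven
mutually exclusive morphological classes. With a structuring element given by
`connectivity` (8 by default: cardinals + diagonals) and an `edge_width` of
one pixel:

1. **Core** pixels survive `edge_width` successive erosions; an erosion
   removes any foreground pixel with at least one background pixel among its
   neighbours. Cells beyond the raster border count as background, so
   foreground touching the border erodes there — a deliberate, simple
   convention that slightly inflates edge at map margins.
2. **Islet**: every pixel of a foreground connected component containing no
   core. These are the isolated, scattered units.
3. **Edge** and **Perforation** partition the boundary zone (non-core pixels
   within `edge_width` geodesic dilation steps of core). Perforation faces
   only an enclosed background hole; everything else in the zone is Edge.
   Holes are background components not connected to the raster border under
   the complementary connectivity (4 when the foreground rule is 8), the
   standard topological pairing that avoids connectivity paradoxes.
4. The remaining *connector* pixels form components classified by their
   contacts with core-plus-boundary zones: touching two or more distinct
   core components makes a **Bridge**, two or more contacts to a single core
   component a **Loop**, a single contact a **Branch**.

These rules are implemented directly and verified in the test suite against
an independent brute-force implementation (exhaustively over all 65,536
binary 4x4 grids, and on random 12x12 grids, for both connectivities and
edge widths 1-2). Parity with the GUIDOS toolbox is *not* claimed: GUIDOS
adds sub-classes and option flags (transition pixels, intext). Everything
downstream depends only on the Islet vs non-Islet split, which the rules
above determine unambiguously at edge width 1. One open corner: appendages
hanging off Edge rather than Core are classified Branch here; published
tools do not document their convention.

## The compactness index

Within a circular buffer around a survey stop (pixel-centre-in-circle
membership), compactness is

> 100 x (1 - islet exurban pixels / all exurban pixels),

ranging from 0% (fully dispersed: every developed pixel an islet) to 100%
(fully clumped: no islets). Buffers containing no exurban pixels have no
defined compactness; those stop-years are excluded from gradient analyses
and counted. The index is computed from pixel counts, which at uniform pixel
size equals the area ratio. By construction it does not depend on the forest
raster, and converting islets into core-bearing blocks can only raise it.

Two buffer radii are used throughout: 400 m (a local, territory-scale zone
of influence) and 1 km (a landscape scale covering daily movements).

## Landscape predictors and Moran's I screening

Alongside compactness, each stop x year x radius gets: percent forest,
percent exurban development, the number of forest patches strictly greater
than 0.45 ha (8-connected; strictly more than 5 pixels at 30 m), and forest
edge. "Forest edge" is measured as the total length of forest/non-forest
boundaries between 4-adjacent cell pairs both inside the buffer, so the
buffer clip line itself contributes nothing; the source analyses delegate
this metric's precise definition elsewhere, so this is a documented
divergence risk.

Stop-level spatial autocorrelation is screened with classical Moran's I
using row-standardised inverse-distance weights (configurable) and a
two-sided permutation p-value (999 permutations, +1 correction). The weight
choice is a common ecology default; the statistic itself is cross-checked
in tests against an independent implementation and `ape::Moran.I`.

## Hierarchical count adjustment

Roadside counts are noisy measurements of abundance: observers differ, new
observers miss birds, route conditions vary by year, and counts are
over-dispersed. Counts `C_it` (stop i, year t) for one species are modelled
as Poisson with

```
log(mu_it) = beta0_stop + beta1_stop * Year_t + beta2 * FirstYear_it
             + Route_it + Observer_it + Error_it
```

Every stop has its own intercept and linear time trend; `Year_t` is centred
on the mid-study year and scaled to decades so trends are O(1) per decade.
Route, observer and record-level over-dispersion effects are zero-mean
normal with half-Normal(0, 2) priors on their scales; betas get
Normal(0, 10^2). The route effect is year-varying by default (route
conditions change among years); a static-route variant is a flag. Priors
are weakly informative defaults in the roadside-survey route-regression
tradition; none are stated by the source analyses.

Fitting is by MCMC (JAGS, two chains by default), reproducible under a
seed. The over-dispersion term is parametrised non-centredly
(`sd_eps * z`, `z ~ N(0,1)`): with a single count informing each
record-level effect, the centred form puts the sampler in a funnel and the
over-dispersion scale can fail to mix; the non-centred form removes the
pathology without changing the model. Convergence is monitored with split R-hat (each chain halved; R-hat =
sqrt(((n-1)/n W + B/n)/W)), and `adjusted_counts()` refuses to summarise a
fit whose worst R-hat exceeds 1.1 unless forced.

The "adjusted count" passed downstream is the posterior mean (median by
flag) of `exp(beta0_stop + beta1_stop * Year_t + Route_it)` — observer,
first-year and over-dispersion effects zeroed, route effect retained as
part of the stop's habitat context. This is the single most
interpretation-sensitive choice in the pipeline; `zero_route = TRUE`
removes the route term too.

## TITAN: threshold detection along the compactness gradient

For each species, candidate change points are midpoints between consecutive
distinct sorted gradient values leaving at least `min_split = 5` sites on
each side (ties collapse to one candidate). At each candidate the
Dufrene-Legendre indicator value is computed for both sides
(`IndVal = 100 x` relative mean abundance `x` occurrence frequency) and
standardised into a z-score against a permutation null (`n_perm = 250`
permutations of the gradient over sites, same candidate set). The species'
change point and direction (z- = declines past the threshold, z+ =
increases) come from the candidate/side pair with the largest z; published
TITAN variants differ on maximising z versus IndVal, and z-maximisation is
the default here (IndVal by flag). The p-value compares the observed
maximum IndVal over all candidates and sides with the permutation
distribution of the same maximum (+1 correction), so the selection effect
of scanning is controlled.

Uncertainty and quality come from `n_boot = 250` bootstrap resamples of
sites: **purity** is the fraction of replicates agreeing with the observed
direction, **reliability** the fraction achieving p <= 0.05, and the 5%/95%
quantiles of the bootstrap change points measure sharpness (narrow =
threshold-like, broad = gradual). Species are flagged at both the 0.90 and
0.95 purity/reliability levels. The bootstrap count is not pinned down by
the source text ("250 permutations ... and diagnostic indices"); 250 is the
most literal reading and is configurable. Degenerate resamples (no valid
split, or the species absent) are redrawn and counted.

Stop x year units are pooled along the gradient by default; analysing years
separately is possible by subsetting, since whether the original analysis
pooled is not stated.

## Loess screen and GAM model comparison

A locally weighted polynomial regression (tricube weights, degree 2, span
0.75) screens each species' abundance-compactness relationship for
nonlinearity, reported as an approximate F comparing loess and straight-line
residual sums of squares. There is no published cutoff, so the screen gates
nothing: all species proceed to TITAN, and the F is reported.

To weigh compactness against habitat loss and fragmentation, Gaussian
identity-link additive models regress adjusted counts on smooths
(penalized thin-plate splines, basis dimension 10) of compactness, percent
exurban, percent forest, forest patch count and forest edge, plus year as a
factor (no smooth). Smoothing parameters minimise GCV. Reported per model:
per-smooth effective degrees of freedom, approximate Wald-type p-values,
percent deviance explained (equal to 1 - RSS/TSS here), the GCV score, and
AIC computed with the penalized fit's effective degrees of freedom.
Backward selection repeatedly drops the term whose removal most lowers AIC
until no removal lowers it, and reports the full and best models with
delta-AIC relative to the best; best-model terms with p < 0.01 are flagged
as key factors.

A known statistical limitation, documented rather than patched: an AIC
comparison retains a superfluous ~1-edf predictor with asymptotic
probability around P(chi^2_1 > 2) ~ 0.16, and GCV occasionally
undersmooths a pure-noise term, so backward selection removes a noise
predictor in roughly 60-65% of replicates, not near-always. Alternatives
(shrinkage smooths, REML, inflated gamma, a delta-AIC parsimony rule) were
examined and deliberately not adopted as defaults, to keep the procedure
exactly as stated. Effective degrees of freedom are reported to one
decimal; no attempt is made to reproduce any particular integer rounding
convention.

## The synthetic-data generator

Because the original inputs (classified satellite imagery and survey
counts) are not redistributable, every stage is exercised on synthetic data
with known ground truth.

**Landscapes.** One square tile per stop (70 pixels ~ 2.1 km, so a 1-km
buffer fits), arranged in a mosaic. Development units sit on an internal
4-pixel lattice — so isolated units are never 8-adjacent, and 3x3 blocks
(the smallest core-bearing patch at edge width 1) never merge. Each stop
draws a latent compactness propensity; its target compactness per period is
the propensity times a rising per-period scale (defaults 0.22, 0.27, 0.46,
0.88), while total development grows from 2.5% to 4.2% of the tile.
Periods are realised by *infill*: islets convert in place into 3x3 blocks,
plus new units arrive — mirroring the observed trajectory of scattered
development becoming contiguous. The developed fraction is kept below the
regional values reported for real landscapes; what matters for every
downstream test is the compactness gradient, which spans 0-90% across
stops, rises monotonically in the mean across periods, and correlates > 0.9
with the declared per-stop targets. Forest is laid down as rectangles,
thinned over periods, and never overlaps development. Placement exhausts a
finite lattice pool; infeasible scenarios error with advice rather than
looping forever.

**Counts.** The hierarchical count model run forward, with a species
response added to the linear predictor: `"step"` species jump by a log-scale
`effect` on one side of a known change point on compactness, `"none"`
species ignore it. The default community mirrors the study design: 11
species — six "forest" species with z+ step responses at change points
spread over 20-70%, five "edge" species with mixed responses (z+, z-, and
one null). Default nuisance magnitudes (route s.d. 0.2, observer s.d. 0.2,
over-dispersion s.d. 0.3, first-year effect -0.3, per-stop trend s.d. 0.1
per decade) are not published quantities; they are chosen as realistic for
roadside count data and are fixed scenario properties, not tuning knobs.
Observers hand over per route in a staggered year, so the first-year effect
is identifiable from year-varying route effects. Every bundle ships a
machine-readable `ground_truth.json`; recovery tests read truth only from
it.

**What the generator does not emulate:** roads and route geometry, housing
density in physical units, spatially autocorrelated habitat beyond the tile
structure, species interactions, and detection processes other than the
modelled observer effects. Passing recovery tests therefore demonstrates
the estimators work when their assumptions hold, not that real landscapes
satisfy those assumptions.

## Problem sizes and numerical choices

Test and example runs use deliberately modest sizes chosen as desk-scale
defaults: parameter-recovery checks fit 40 stops x 4 periods with 2 chains
x 12,000 draws after 8,000 warm-up; the end-to-end demonstration runs the
full 105-stop, 4-period, 11-species scenario with shorter chains (direction
recovery is insensitive to residual R-hat) and a reduced bootstrap. The
MSPA oracle sweep is exhaustive at 4x4 and sampled at 12x12. Other
numerical conventions: permutation and bootstrap p-values use the +1
correction; a zero permutation standard deviation yields z = 0 with a
warning; candidate ties in the gradient collapse; quantiles are R type 7;
all randomness flows from explicit seeds (per-species streams are derived
from a hash of the species name, so community results are invariant to
column order).

## Known limitations

* MSPA here is the seven-class core analysis only — no distance-weighted
  cores, no GUIDOS bit-parity, no vector output.
* The compactness index assumes development is present; it is undefined
  (and the stop excluded) otherwise, so it cannot compare developed to
  undeveloped landscapes.
* Adjusted counts inherit all assumptions of the Poisson log-linear model;
  no detectability correction beyond observer effects is attempted.
* GAM term p-values are the usual Wald-type approximations on penalized
  fits and should be read as guides, not exact tests.
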