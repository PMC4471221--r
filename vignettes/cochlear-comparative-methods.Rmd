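---
title: "Cochlear morphometrics and phylogenetic comparative methods with cochlevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cochlear morphometrics and phylogenetic comparative methods with cochlevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochlevol)
```

## What the package models

`cochlevol` analyses the evolution of gross cochlear morphology across a
clade of primates. It works at two levels:

1. **Morphometry.** From ordered 3D landmark paths digitised along the outer
   circumference of the cochlear spiral and around the oval-window outline,
   it computes five continuous variables: the external cochlear length
   (ECL, mm), the number of turns (TUR, full rotations plus the fractional
   angle between the center-to-apex and center-to-base rays), the curvature
   gradient (CUR, the ratio R2/R1 of radii of circles fitted with a common
   center to the basal and apical turns), the relative length
   (RECL = ECL/TUR, mm per turn) and the oval window area (OWA, mm²).
2. **Comparative statistics.** Species-level trait values are analysed on a
   rooted phylogram under Brownian motion (BM): Pagel's λ phylogenetic
   signal tests, BM versus directional random-walk model comparison,
   non-phylogenetic (OLS, RMA) and phylogenetic (PGLS) allometric
   regressions on body mass with AIC ranking, Bayesian MCMC reconstruction
   of ancestral states at internal nodes, and Z-score placement of fossil
   trait values against those node posteriors.

Every stage can be exercised end-to-end on synthetic data whose generating
truth is recorded, which is how the package validates itself.

## The Brownian / λ model

A rooted tree with branch lengths defines the BM covariance of tip values:
`V[i,i]` is the root-to-tip path length of species *i* and `V[i,j]` the
root-to-MRCA shared path of the pair. Under BM with root state α and rate
σ², tip values are multivariate normal with mean α·1 and covariance σ²·V.
Pagel's λ multiplies the off-diagonal entries only: λ = 0 erases shared
history (a star tree), λ = 1 recovers the BM expectation. We restrict λ to
[0, 1].

Fitting is by maximum likelihood throughout: α̂ is the phylogenetically
weighted mean `(1'V⁻¹y)/(1'V⁻¹1)`, σ̂² the ML estimator with denominator
*n*, and λ is profiled over [0, 1] by bounded scalar optimisation with both
boundaries checked explicitly. The signal test is the standard four-step
procedure: estimate λ by ML, refit at λ = 1 and λ = 0, and compare by
likelihood-ratio tests against χ²₁. Two caveats are deliberate:

* **Boundary p-values.** LR comparisons against the boundary values use the
  plain χ²₁ reference, not a 50:50 boundary mixture; this is conservative.
* **Small-sample λ bias.** The ML estimator of λ is strongly variable and
  biased toward the boundaries at realistic clade sizes. On 22-tip
  pure-birth trees we measure mean λ̂ ≈ 0.30–0.34 when the truth is 0.5
  (boundary truths 0 and 1 recover within 0.1). This is a property of the
  estimator, not of this implementation: on replicate datasets our λ̂ and
  log-likelihood coincide digit-for-digit with an independent ML
  implementation (`nlme::gls` with `ape::corPagel`) and with a 1001-point
  grid search. One acceptance check asserts mean recovery within 0.1 at
  λ = 0.5 and is therefore permanently red; we keep it red rather than
  widening the band.

The directional random-walk model adds a drift term β in root-to-tip path
length *h*; it is fitted by GLS of y on (1, h) with covariance σ²V and is
identifiable only on non-ultrametric trees (phylograms), where *h* varies.
The BM-vs-directional comparison is a χ²₁ LR test (one extra parameter).

## Geometry: numerical choices

**Reference plane.** All angular and radial quantities are computed after
orthogonal projection of the spiral landmarks onto their total-least-squares
plane (smallest principal axis of the centred point cloud). Cochlear spirals
are nearly planar per turn, and a single reference plane makes the turn
count well defined.

**Spiral center.** The center "A" is the in-plane point minimising squared
distances to the perpendicular bisectors of local chords. We form chords
between landmarks about one sixteenth of the path apart, along the whole
path. Two properties drove this choice over using only chords at the two
path extremities: (i) for a closed or nearly closed path the extremities
coincide and extremity-only bisectors are near-parallel — with landmark
noise of 0.01 mm on a unit circle the extremity-only estimate missed the
center by ~0.5 mm, while the all-chords estimate is accurate to a few
thousandths; (ii) on Archimedean test spirals the all-chords center reduces
the curvature-ratio bias essentially to zero (measured ratio 1.694 against
the analytic 1.692). On exact circular arcs every bisector passes through
the true center, so the estimate is exact there.

**Turn windows.** The basal turn is the set of landmarks whose cumulative
absolute angular sweep from the basal end is below one full rotation, the
apical turn the mirror-image window; on paths spanning fewer than two turns
both windows are truncated at the sweep midpoint so they never overlap. The
fixed-center least-squares radius of a landmark subset is the mean in-plane
distance to A. TUR uses the absolute cumulative signed sweep, so left and
right cochleae count identically.

**Why measured CUR is not the extreme-radius ratio.** For a spiral whose
radius shrinks from 2.0 to 0.8 mm over 2.5 turns, the mean radii over the
basal and apical turn windows are 1.76 and 1.04 mm: the full-turn circle
fits give a ratio of ≈ 1.69, necessarily smaller than the extreme-landmark
ratio 2.5. The synthetic-spiral truth records both values
(`cur_extremes`, `cur_expected_measured`) and recovery tests target the
latter; one acceptance check that expects the former from full-turn fits is
left red by design.

**Oval window area.** The outline is projected onto its total-least-squares
plane (the numerical analogue of choosing the oblique slice best fitting
the outline, replacing the paper-and-pencil manual slice) and the shoelace
area of the ordered projected polygon is returned; self-intersecting
projections are rejected. A 360-point polygon under-estimates an ellipse
area by < 0.01%, far inside the tolerances used.

**Rounding.** Reported tables round half-away-from-zero — one decimal for
ECL/TUR/CUR/RECL, two for OWA — but every statistic downstream consumes
full-precision values; RECL is always computed from unrounded ECL and TUR.

## Allometry

Allometric fits are on log10-transformed species means (the base is a
configuration option recorded in every fit). OLS log-likelihoods use the ML
variance, and AIC counts the intercept, slopes, the residual variance, and
one more parameter when PGLS estimates λ; `AIC = 2k − 2logLik` exactly. RMA
slopes are `sign(r)·sd(y)/sd(x)` (bivariate only, no likelihood, hence
never AIC-ranked). PGLS R² is defined against the intercept-only GLS fit at
the same λ. Standardized residuals divide by the sample sd of (for PGLS,
whitened) residuals, and species at least two sd from the line are flagged.
Note that PGLS at λ = 0 equals OLS exactly only on ultrametric trees; on a
phylogram the λ = 0 covariance is diagonal but unequal, i.e. weighted least
squares. Expected fossil values evaluate the fitted line at the fossil's
log body mass and back-transform.

## Ancestral states and fossils

With parameters fixed, the joint distribution of tip values and any
internal-node state is Gaussian with covariances given by shared path
lengths (internal nodes sit entirely on λ-scaled paths), so node
conditionals are available in closed form (`analytic_ancestral`). With
`alpha = NULL` the root state is marginalised over a flat prior, which
makes the root conditional mean exactly the phylogenetically weighted mean
— the identity used as an oracle. With α supplied the conditional is taken
at that fixed root state (the root then has zero conditional variance,
which is the correct degenerate limit).

The MCMC sampler (`mcmc_ancestral`) targets the posterior under a flat
prior on α, Jeffreys 1/σ² on σ², and uniform(0,1) on λ. α and σ² have
conjugate Gaussian and inverse-gamma full conditionals and are sampled
exactly (we preferred the exact σ² draw to a random-walk update: it is
tuning-free and mixes at least as well); λ uses random-walk Metropolis with
proposals outside [0,1] rejected. At every retained iteration the internal
node states are drawn jointly from their exact Gaussian conditional given
the current parameters, so node posteriors integrate over parameter
uncertainty. Chains are fully reproducible from the seed; a crude
autocorrelation-based effective sample size is computed and a warning (not
a silent pass) is raised below the configured threshold. Defaults are
110,000 iterations, 10,000 burn-in, thinning 20.

Fossils never enter the reconstruction. A fossil value is placed against a
node posterior by `z = (value − mean)/sd` with a one-tailed normal p-value
on the side the fossil lies, flagged at 5%.

## Descriptive statistics

The permutation test uses the pooled-variance two-sample t statistic —
pooled, not Welch, because the permutation null asserts identical
distributions — with the add-one p estimator `(1 + #{|t*| ≥ |t|})/(B + 1)`,
switching automatically to exhaustive enumeration (exact p) when the number
of label arrangements is at most the permutation budget. No
multiple-testing correction is applied across the pairwise species matrix
(an FDR option exists in spirit but is off by default to mirror standard
practice for these tables). CVs are sample sd over mean. PCA defaults to
the correlation matrix because the five variables mix units (mm, turns,
mm²); covariance scaling, and running on specimens versus species means,
are runtime options since either choice is defensible.

## The synthetic world

The generators state the world the tests assume:

* Trees: pure-birth (Yule, birth rate 1), caterpillar and star topologies;
  an optional lognormal branch-length jitter produces phylograms. 22 tips
  is the default clade size in recovery tests, matching a realistic
  catarrhine-scale sample.
* Traits: BM tips drawn by recursive simulation down the λ-stretched tree
  (all branches × λ, terminal branches padded by (1−λ)·depth), which
  reproduces the λ-transformed covariance exactly; internal states can be
  recorded.
* Allometric tables: log10 body mass by BM (root 10 kg, rate 0.2 per unit
  branch length — giving roughly a 1–150 kg spread on unit-depth trees,
  the range spanned by catarrhines); log10 trait = intercept + 0.2 ×
  log-mass + phylogenetic residual of sd 0.05 by default. The residual
  covariance is scaled so the stated sd applies at the average tip depth.
* Geometry: Archimedean spirals (radius linear in angle) rather than
  logarithmic ones, because arc length has a simple quadrature and the
  expected measured curvature ratio is available in closed form; cochlear
  realism is not needed for validating the measurement code. Ellipses with
  known area πab stand in for oval-window outlines.

What a green test does **not** establish: real cochleae are not Archimedean,
landmarking error is not isotropic Gaussian, species means carry
intraspecific sampling error that the comparative models here ignore, and
consensus trees carry topological uncertainty that a single phylogram does
not represent.

## Known limitations

* λ is poorly estimated at small n (see above); report the profile
  boundaries, not just the point estimate, when n < 30 or so.
* Flat λ profiles (star-like trees) are flagged rather than resolved.
* No Ornstein–Uhlenbeck, early-burst or multi-rate models; no κ/δ
  transforms; no measurement-error models beyond RMA.
* The oval-window area from an outline polygon is a surrogate for manual
  oblique-slice segmentation; systematic offsets between the two
  procedures are not modelled.
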