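---
title: "ClearQuant: models, choices and limitations"
author: "ClearQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ClearQuant: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClearQuant)
```

## The measurement problem

Optical clearing renders tissue transparent by homogenizing refractive
indices, so that multiphoton autofluorescence (AF) and second harmonic
generation (SHG) signals survive to greater imaging depths. Comparing
clearing protocols therefore comes down to a depth-resolved question: how
fast does signal intensity decay as the focal plane moves into the tissue?
Light propagating through tissue attenuates by absorption and scattering,
which to first order follows the Beer-Lambert law

$$I(z) = I_0\, e^{-\mu_{\mathrm{eff}} z},$$

where $I_0$ is the surface intensity and $\mu_{\mathrm{eff}}$ an effective
attenuation coefficient combining absorption and scattering. A well-cleared
specimen has a small $\mu_{\mathrm{eff}}$; an opaque one loses its signal
within a few micrometres.

ClearQuant turns z-stacks (or pre-tabulated depth-intensity CSVs) into a
scalar transparency statistic per experiment and runs the factorial group
comparisons a clearing study needs. The chain is:

1. **Extraction** -- per-slice mean intensity over the frame or an ROI mask
   (`extractProfile`).
2. **Normalization** -- depth divided by the stack's maximum imaging depth
   $z_{max}$, intensity divided by the 8-bit ceiling 255
   (`normalizeProfile`).
3. **Smoothing** -- a reproducing-kernel (meshfree) approximant evaluated on
   a fixed grid of 201 normalized depths, $u = 0, 0.005, \ldots, 1$
   (`fitRK`, `evaluateOnGrid`).
4. **AUC** -- the trapezoidal area under the normalized intensity curve, a
   dimensionless number in $[0, 1]$ (`computeAUC`).
5. **Statistics** -- Shapiro-Wilk-gated ANOVA or aligned rank transform,
   with pairwise post-hoc contrasts (`aucAnova`, `alignedRankTransform`,
   `pairwisePosthoc`).

Normalizing by the per-experiment $z_{max}$ -- rather than by an estimated
tissue thickness -- makes experiments with unequal stack depths comparable;
this is why stage 3 exists at all: after normalization every experiment
lives on the unit square but is sampled at its own depths, and the common
0.005 grid restores a shared abscissa for group averaging.

## The reproducing-kernel approximant

Each normalized profile $(u_i, y_i)$ is approximated by
$y_h(u) = \sum_i \Psi_i(u)\, y_i$ with reproducing-kernel shape functions in
the standard particle construction: with monomial basis
$H(s) = (1, s, \ldots, s^n)^T$ and a kernel window $\phi_a$ of half-width
$a$,

$$M(u) = \sum_i H(u - u_i) H(u - u_i)^T\, \phi_a(u - u_i), \qquad
\Psi_i(u) = H(0)^T M(u)^{-1} H(u - u_i)\, \phi_a(u - u_i).$$

By construction the weights form a partition of unity and reproduce
polynomials up to the basis order exactly -- the two properties the test
suite asserts at every grid point ($|\sum_i \Psi_i - 1| < 10^{-10}$,
linear reproduction to $10^{-8}$, over random node layouts).

Choices, all configurable through `rkConfig()`:

* **Kernel**: cubic B-spline with compact support (default), the canonical
  choice in meshfree approximation; a truncated Gaussian is available for
  sensitivity checks.
* **Basis order**: 1 (linear). Order 0 reduces to Shepard smoothing, order
  2 is available but needs denser profiles (the fit requires at least
  `basisOrder + 2` points; profiles shorter than 4 points are rejected,
  which also protects moment-matrix conditioning).
* **Support**: $a = 2.5\times$ the median node spacing, widened adaptively
  (factor 1.5) wherever fewer than `basisOrder + 1` nodes fall inside the
  window or the moment matrix is ill-conditioned -- this happens routinely
  at the profile edges.
* **Conditioning**: the basis is evaluated in support-scaled coordinates
  $(u - u_i)/a$, a diagonal congruence that leaves the shape functions
  unchanged in exact arithmetic but keeps $M$ near unit scale. A relative
  ridge of $10^{-12}$ is added to the diagonal, its effect removed again by
  two iterative-refinement steps against the unridged matrix; the widening
  loop additionally requires `rcond(M)` above $10^{-5}$ because the
  attainable partition-of-unity error is of order $\kappa(M)\,\epsilon$.
* **Clamping**: grid values are clamped to $[0, 1]$; kernel overshoot must
  not push unphysical negative intensity into the AUC.

The AUC is computed from the smoothed grid curve by default (the curve is
what group averaging operates on); `auc.source = "raw"` integrates the raw
normalized profile instead as a sensitivity check. Because the trapezoid
rule is linear, the AUC of a group-mean curve equals the mean of the member
AUCs exactly -- asserted to $10^{-12}$ in the tests.

## Statistical battery

Quartiles use linear interpolation between order statistics, and the SD is
the sample SD; summaries report n, mean, SD, median, Q1 and Q3 per group and
channel, with the full AUC table sorted by group, specimen, region and AUC.

The route between parametric and rank-based tests is gated by a
Shapiro-Wilk test on the pooled residuals of the full fixed-effects model
(not on the raw response, which conflates group shifts with non-normality);
the gate's $W$, $p$ and direction are printed in the report, and
`stats.route` overrides it. Two-way ANOVA uses type-II sums of squares so
unbalanced specimen/region counts are handled sensibly.

For non-normal data the aligned rank transform (ART) is used: for each
effect (two mains, one interaction), every response is aligned by
subtracting all *other* effects' estimates -- built from unweighted cell
means -- leaving the residual plus the effect of interest; midranks of the
aligned responses then enter a full factorial ANOVA, of which only the
aligned-for effect is reported. The algebraic correctness of the alignment
(all stripped effects exactly zero on the aligned responses) is recomputed
on every call and attached as a diagnostic attribute. Post-hoc contrasts
default to Tukey HSD after ANOVA and to pairwise t contrasts on midranks
with Holm adjustment after ART. Stars follow the usual convention
(`*` p < 0.05, `**` p < 0.01, `***` p < 0.001, strict boundaries).

Two caveats of this battery, both visible in our simulations and worth
knowing before trusting p-values on real data:

* **Heteroscedasticity**: ART's null behaviour degrades when group spreads
  differ strongly. With a multiplicative (constant-CV) error model and
  group means spanning a 30:1 range, the false-positive rate for a truly
  null main effect can reach ~40% -- the low-variance groups' ranks are
  displaced wholesale by the sampling noise of the alignment estimates.
  This is a property of ART, not of this implementation (the alignment
  diagnostic is exactly zero); it is why the bundled end-to-end validation
  design compresses the dynamic range (see below).
* **Pseudo-replication**: specimens and regions are treated as independent
  replicates (no random-effect term). When several regions share a
  specimen, specimen-level variability makes them correlated and all
  fixed-effects tests anti-conservative. The simulator exposes exactly this
  structure, so the effect can be quantified before a design is trusted.

## The synthetic-data generator

`syntheticSpec()` parameterizes a full crossed imaging study under the
Beer-Lambert model with $\mu_{\mathrm{eff}}$ expressed per unit
*normalized* depth, so the noise-free AUC has the closed form
$(I_0/255)(1 - e^{-\mu})/\mu$ -- the oracle used throughout the tests.
Hierarchical variability mimics a real study: a specimen-level lognormal
factor on $\mu_{\mathrm{eff}}$ (lognormal keeps attenuation positive),
shared by all regions of that specimen, and a region-level Gaussian shift
on $I_0$, clamped to the valid range. Detector noise is additive Gaussian
on the 0--255 scale (default SD 2 grey levels) with a Poisson
photon-counting mode; intensities are clamped to $[0, 255]$ and rounded to
integers to emulate an 8-bit export. Per-experiment maximum depths are
drawn uniformly from 200--280 micrometres (a typical mounted-specimen
reservoir) with 400 slices per stack. All randomness derives from the
single spec seed via label-keyed sub-seeds, so identical specs give
bitwise-identical datasets regardless of evaluation order.

The default decay table (`clearingStudyGroups()`) encodes a six-group
clearing-by-fixation study (BABB, glycerol, uncleared, each with and
without formalin fixation, observed in AF and SHG). Its
$(\mu_{\mathrm{eff}}, I_0)$ pairs were calibrated once by inverting the
closed-form AUC at the transparency levels typical of such studies --
solvent-based clearing best (AF AUC ~0.12), glycerol intermediate,
uncleared tissue nearly opaque (~0.0035), SHG dimmer than AF throughout --
with surface intensities chosen channel-wise ($I_0$ 80--220 for AF, 10--80
for SHG). Between-experiment variability defaults (specimen log-SD 0.2,
region $I_0$ SD 15) put AUC coefficients of variation in the 15--40% range
typical of such measurements.

What the generator deliberately does **not** emulate: light-transport
physics beyond single-exponential decay (no scattering PSF, no depth
dependence of $\mu_{\mathrm{eff}}$), spatial structure within slices
(simulated stacks are laterally uniform), layered tissue anatomy, and
detector artefacts beyond additive/Poisson noise and quantization. Passing
tests therefore validate the *analysis chain*, not the biological
faithfulness of any particular dataset.

`fitMuEff()` inverts the decay by ordinary least squares of $\ln I$ on $z$
over the leading run of samples with intensity at least 1 grey level. The
fit stops at the first sample below that threshold: deeper samples where
noise re-crosses it would contribute spurious flat points and bias the
slope towards zero (with detector noise of SD 2 this bias reaches tens of
percent at high attenuation, whereas the truncated fit keeps the median
relative error near 1%).

### The end-to-end validation design

`validationStudySpec()` is the study used by the acceptance checks. It
keeps the clearing ordering of the default table
($\mu_{NC} > \mu_{GLY} > \mu_{BABB}$ in both channels) but differs in
three designed ways, each forced by one of the caveats above:

* the **fixation effect is a pure crossover** (fixation lowers BABB's
  expected AUC and raises glycerol's by the same amount, 0.03 in AF and
  0.003 in SHG, and leaves uncleared tissue untouched), so the expected
  fixation main effect is exactly zero while the interaction is strong --
  the pattern the pipeline must recover is then unambiguous: clearing and
  interaction significant, fixation not;
* the **dynamic range is compressed** to about 2:1 so group spreads are
  comparable and the ART heteroscedasticity pathology cannot masquerade as
  a fixation effect;
* it uses **9 specimens with one region each**, making experiments
  independent draws, because the fixed-effects battery assumes exactly
  that.

## Tissue thickness

`estimateThickness()` reports the deepest plane whose intensity is at least
a configurable fraction (default 5%) of the profile's peak. For a pure
Beer-Lambert decay this inverts to $-\ln(0.05)/\mu_{\mathrm{eff}}$ within
one z-step. It is a stated stand-in -- thickness from a single-channel
intensity profile is ill-posed in general -- and is kept separate from
$z_{max}$, which is an acquisition property, not a tissue property.

## Problem sizes and numerical tolerances in the tests

The test and acceptance runs use: 50 random node layouts for the RK
guarantees; 400-slice noise-free stacks for the closed-form AUC comparison
(tolerance 0.5%, observed error well below 0.1%); 100 replicates per
attenuation level (50 slices, noise SD 2) for parameter recovery (median
relative error under 5%); 2000 null replicates of a 2x2 design with 5
observations per cell for type-I calibration of both ANOVA (normal errors)
and ART (lognormal errors), requiring empirical error within [0.03, 0.07]
at $\alpha = 0.05$; and the 6x9 validation study above for the qualitative
end-to-end pattern. These sizes keep a full run within a couple of minutes
on one CPU while leaving Monte-Carlo error comfortably inside each
tolerance.

## Known limitations

* LIF and other proprietary microscope containers are not read; convert to
  multi-page TIFF (or export profile CSVs) upstream.
* Per-slice summarization is the arithmetic mean; median or integrated
  density are not offered.
* No ROI auto-detection and no arterial-layer segmentation; layer analyses
  require user-supplied ROI masks or label columns.
* No mixed-effects modeling: nested designs (regions within specimens) are
  analyzed as flat replicates, with the anti-conservatism that implies.
* The RK kernel, basis and support are stated defaults, not universal
  constants; different choices change curves within the kernel's
  approximation error, so they are exposed in the configuration and
  stamped into every output file's provenance header.
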