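---
title: "Scanning Number & Brightness: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning Number & Brightness: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanNB)
```

## The measurement

Scanning Number & Brightness (sN&B) turns repeated raster scans of a field
of view into per-pixel estimates of how many fluorescent complexes diffuse
through each observation volume and how bright each complex is. Two samples
with the same mean intensity are distinguished by their fluctuations: a few
bright oligomers fluctuate more than many dim monomers. With the per-pixel
time-mean $F = \langle F(t)\rangle$ and time-variance
$\langle\delta F(t)^2\rangle$ of the photon counts, the two estimators are

$$\varepsilon = \frac{\langle\delta F(t)^2\rangle}{F} - 1, \qquad
  n = \frac{F^2}{\langle\delta F(t)^2\rangle - F},$$

so that $n\,\varepsilon = F$ algebraically wherever both are defined.
$\varepsilon$ is the molecular brightness in counts per pixel dwell per
diffusing complex; dividing it by the brightness of a calibrated monomeric
fluorophore $\varepsilon_0$ gives the number of labeled subunits per
complex — the stoichiometry readout. Dividing the median ROI intensity by
$\varepsilon_0$ gives the expression level in subunits per effective
volume ($V_\mathrm{eff}$).

The package defaults mirror a two-photon acquisition with a 40 µs pixel
dwell, 156 nm pixels, stacks of 100 frames, a monomer reference of
$\varepsilon_0 = 0.048$ counts/40 µs/molecule (free Alexa488 in viscous
glycerol) and $V_\mathrm{eff} = 0.355$ fL.

## The generative model behind the simulator

`simulateFrameCounts()` draws, independently per pixel and frame,

1. a complex count $N_i \sim \mathrm{Poisson}(\bar n_i)$ for each species
   $i$ with $s_i$ subunits per complex,
2. labeled subunits $k \sim \mathrm{Binomial}(N_i s_i, p)$ with labeling
   efficiency $p$ (default 1, appropriate for SNAP-tag labeling, which is
   near-quantitative),
3. a photon count $\mathrm{Poisson}(\varepsilon_0 k + B)$ with uniform
   background $B$.

`expectedMoments()` gives the closed forms:
$\langle F\rangle = B + \sum_i \bar n_i s_i p\, \varepsilon_0$ and
$\mathrm{Var}(F) = \langle F\rangle + \sum_i \bar n_i E[k_i^2]
\varepsilon_0^2$ with $E[k_i^2] = s_i p (1-p) + (s_i p)^2$, so a single
fully analysed species has apparent brightness
$\varepsilon_0 (1 + (s-1)p)$. Every simulation stage is tested against
these oracles by parameter recovery.

Frames are treated as independent, which is correct when the interval
between raster scans is much longer than the residence time of a complex
in the observation volume (a complex with $D$ around 1 µm²/s crosses a
~0.3 µm beam waist in milliseconds, while a full frame takes tens of
milliseconds). `simulateDiffusionStack()` exists to validate exactly this
assumption: Brownian particles on a periodic plane are raster-scanned
through a 2-D Gaussian point-spread function, with positions advanced once
per scan line. Its tests confirm the monomer/dimer brightness doubling and
the halved particle number, and that slow diffusion (correlated frames)
degrades the variance estimate — which is why the fast tier is the
workhorse and the diffusion tier a cross-check. Note that raster sampling
of a 2-D Gaussian beam halves the apparent brightness relative to the
per-volume calibration (shape factor 1/2); ratios of brightnesses, which
carry the stoichiometry information, are unaffected.

Photobleaching is modeled as a deterministic linear ramp of the expected
signal across the stack, which is all the quality-control rule needs;
per-fluorophore stochastic bleaching, blinking and detector artifacts are
deliberately out of scope.

## Quality control and masking

A straight line is fitted to the frame means; the photobleach fraction is
the relative first-to-last decline of the fit, and any stack above 10% is
rejected outright (typical well-behaved acquisitions bleach by ~2%). The
default analysis rejects rather than detrends; an optional per-pixel linear
detrend exists (`computeNBMaps(detrend = TRUE)`, with the variance divisor
reduced by one degree of freedom for the fitted slope) for sensitivity
checks.

Background is removed by thresholding the mean-intensity map (Otsu by
default), not by subtracting a rate from $F$; at dim pixels this leaves a
downward brightness bias, which is documented rather than corrected, since
the analysis windows used here are far above background. File-supplied
exclusion masks stand in for the manual removal of out-of-focus pixels,
mobile structures and vesicles.

## Estimator precision: divisor and pooling

Two numerical choices matter far more than they might appear to.

**Variance divisor.** The classical notation
$\langle\delta F^2\rangle$ suggests the population divisor $T$, which is
the `computeNBMaps()` default. But with $T = 100$ frames the population
variance underestimates the true variance by the factor $(T-1)/T$, biasing
$\varepsilon$ by $-(1+\varepsilon)/T \approx -0.011$ counts/dwell — about
a quarter of a monomer unit, which is material when brightness is converted
to subunits. Quantitative stoichiometry therefore uses
`divisor = "sample"` ($T-1$, unbiased), and that is the pipeline default
(`nbRunConfig()`). At photon rates near 1 count/dwell the two divisors
also interact differently with the $1/F$ nonlinearity of the estimator;
the ratio-style checks in the test suite state their divisor explicitly.

**Moment pooling.** A single pixel's brightness estimate at $T = 100$ has
a sampling SD of roughly $\sqrt{2/T}\,(1+\varepsilon) \approx 0.15$
counts/dwell — three monomer units, swamping the monomer/dimer separation
of 0.048. Averaging the *moment maps* (mean and variance) over a $w \times
w$ boxcar before forming the ratios divides this SD by $w$ while leaving
region-level estimates unbiased in homogeneous regions. The pipeline
default is $w = 9$ (a ~1.4 µm patch at 156 nm pixels, matching the scale
of dendritic segments); histograms that must resolve monomer multiples are
built from these pooled values. The monomer calibration sample is a
homogeneous solution, so it tolerates more aggressive pooling ($w = 13$ in
the examples). Per-pixel maps (`smooth = 1`) remain the default of
`computeNBMaps()` itself, matching the defining equations.

For region-level summaries the package always prefers pooled moments:
`roiBrightness()` is `mean(variance)/mean(F) - 1` over the ROI and
`roiNumber()` is `mean(F)^2/(mean(variance) - mean(F))`. The per-pixel
number map in particular has the noise-dominated denominator
$\sigma^2 - F$ (its SD is several times its expectation at ~1 count/dwell),
so the median of per-pixel numbers is essentially meaningless at low
photon rates while the pooled estimator is well behaved; a median option
exists for bright data.

## Stoichiometry of one cell

The brightness histogram of an ROI (fixed bins of $\varepsilon_0/12$ by
default, negative values retained — they are real shot-noise-limited
pixels) is fitted with a single Gaussian; the fitted centre is the
brightness of the *major* receptor population, deliberately distinct from
the histogram mean. The fit is initialised at the modal bin with a robust
IQR-based width and falls back to the modal bin centre (flagged) if the
optimiser fails. Dividing by $\varepsilon_0$ gives subunits per complex;
expression regimes are classified as low (< 90 subunits/$V_\mathrm{eff}$),
physiological ([90, 600), the window in which receptors at native-like
densities are analysed; closed-left by convention so a cell at exactly 90
counts as physiological) and high (≥ 600).

## Species fractions from accumulated histograms

Pixels from all accepted cells whose expression falls in the window are
pooled into a unit-area accumulated histogram and decomposed into three
log-normal components: dimer, tetramer, and larger oligomers. The
log-normal is parameterised by its mode $m$ and log-space SD $\sigma$
(curve $A\exp(-(\ln x - (\ln m + \sigma^2))^2/2\sigma^2)/x$, analytic area
$A\sigma\sqrt{2\pi}$). Mode-anchoring is used because the constraint is on
peak positions: the dimer mode is fixed at exactly twice the monomer
reference mode and the tetramer at four times it, while the larger-oligomer
mode is free above the tetramer. Fractions are the normalised analytic
areas. Negative-brightness pixels are excluded here (log-normal support is
positive) but retained in the Gaussian peak fit.

Three numerical safeguards were found necessary and are on by default:

- **Zero-padded support.** The least-squares grid is extended with explicit
  zero-density bins beyond the largest reachable free mode. Without this,
  the free component can park at the edge of the observed range, where its
  reported area is unconstrained by the residuals and the fit degenerates.
- **Shape ceiling 0.6.** With shapes allowed up to 1.5 log-units, a very
  broad larger-oligomer component develops a heavy $1/x$ left tail that
  acts as a background and absorbs most of the dimer/tetramer mass (in
  recovery experiments a true dimer fraction of 0.75 collapsed to 0.19).
  The ceiling of 0.6 is far above any component width produced by the
  acquisition noise model and is exposed as `shapeRange`.
- **Deterministic multi-start.** The free-mode initialisation is scanned
  over {6, 8, 10} × the monomer mode and the lowest residual sum kept, so
  results are reproducible and order-independent.

In recovery experiments at the default acquisition conditions (cohorts of
96 × 96-pixel cells, 100 frames, pooling $w = 9$), designed
dimer/tetramer/octamer compositions are recovered within a few percent of
the pooled-pixel ground truth, and the free mode lands at the true octamer
brightness when an octamer species is present; the tests compute these
checks from scratch.

## Clusters and TR-FRET

The top decile of masked mean intensities (threshold at the smallest value
whose selection reaches the fraction; ties included) is labeled into
8-connected components, with components under 4 pixels kept in the
selection but not counted as clusters (both choices configurable; the
connectivity and minimum size are conventions, chosen once). Cluster
brightness is compared against out-of-cluster pixels restricted to the
intensity deciles that cluster pixels occupy — an expression-matched
comparison that distinguishes "more receptors" from "bigger oligomers".

TR-FRET image sets are shading-corrected by dividing with a rolling-ball
(grayscale opening) background estimate rescaled to preserve the image
mean (radius 50 px by default; the radius is a convention, the procedure a
division per the underlying protocol). Cells are selected on the donor
image, backgrounds are subtracted as scalars supplied by the user (the
estimation region is acquisition-specific), and the mean TR-FRET intensity
is corrected by a global donor-bleedthrough fraction, 6% by default, as
measured for the setup rather than estimated from data. On donor-only
cells the corrected signal distributes around zero — the null every
acquisition should reproduce.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data
generated at run time: mostly 64 × 64 × 100 stacks (the package's default
geometry), 96 × 96 cells for mixture cohorts, and 24 × 24 fields for the
(much slower) diffusion tier. These sizes were chosen so that every
sampling-based check sits several standard errors away from its decision
boundary while the whole suite completes in well under a minute of compute.
All randomness flows through explicit seeds; simulations restore the
caller's RNG state, and cohort results are independent of cell order.

## What passing tests do and do not show

The simulator reproduces the statistical structure sN&B assumes:
Poisson-distributed occupancy, binomial labeling, shot noise, uniform
background, and an optional linear bleach. It does not emulate detector
afterpulsing or dead time, triplet blinking, scanner distortion, focus
drift, vesicle traffic, or genuinely heterogeneous cell morphologies.
Parameter recovery on synthetic cohorts therefore validates the estimators
and the fitting machinery — not the optical calibration of a real
instrument, which enters entirely through $\varepsilon_0$ and
$V_\mathrm{eff}$. Real analyses should verify the monomer calibration and
the bleaching behaviour of their own acquisitions before interpreting
absolute stoichiometries.

## Known limitations

- Background is handled by masking, not subtraction; brightness at dim
  pixels is biased low.
- Error propagation from the calibration SEM into stoichiometry confidence
  intervals is not performed beyond first order.
- The mixture model fixes the component count at three (plus the monomer
  anchor); model selection over the number of oligomeric species is out of
  scope.
- The diffusion tier advances particle positions once per scan line, not
  per pixel; at membrane-typical diffusivities the within-line displacement
  is a few nanometres and negligible against the beam waist.
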