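---
title: "Species-independent color distances with segment classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-independent color distances with segment classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nscolor)
```

## The problem

Color-discrimination models — color-opponent coding (COC) for honeybees, the
color hexagon for trichromatic Hymenoptera, the receptor-noise-limited (RN)
model for any species with known receptor noise — all require the viewer's
photoreceptor sensitivities. When a signal is under selective pressure from
many viewers at once (a caterpillar seen by wasps, spiders, and birds), or
the viewer is unknown, no species-specific model applies. Segment
classification sidesteps the viewer entirely: it describes the *shape* of
the radiance spectrum $L(\lambda)$ reaching the eye, using only physical
quantities.

## The model

**Brightness.** Over a wavelength interval, brightness is the photon flux
$\beta(\lambda_a, \lambda_b) = \sum_{\lambda_a \le \lambda < \lambda_b}
L(\lambda)$, implemented as a plain *unweighted sum over grid samples* —
deliberately, because the classical brightness coordinate is defined that
way and is therefore bin-width dependent (about $5\times$ larger on a 1 nm
grid than on a 5 nm grid; see "Numerical choices"). For pigment colors
$L = R \cdot D$, the product of reflectance and illuminant; structural
colors violate this and must be supplied as measured radiance.

**Segments.** The visible range $(\lambda_1, \lambda_2)$ — configurable,
default 300–700 nm, the bee-relevant window — is split into $n + 1$ equal
segments for a viewer with $n$ receptor types. Each segment's *relative*
brightness is $S_i = \beta(\lambda_{i-1}, \lambda_i)/\beta(\lambda_1,
\lambda_2)$; the $S_i$ are dimensionless and sum to 1. For $n = 3$ the four
segments are labelled $B, G, Y, R$.

**Endler's coordinates** are polar: chroma $X_1 = \sqrt{(R-G)^2 +
(Y-B)^2}$, hue $X_2$ by a three-branch arcsine on $(Y-B)/X_1$ (branching on
$R \ge G$ and $Y \ge B$), and raw brightness $X_3 = \beta$. Chromatic
distances between polar loci need the law of cosines, and $X_3$ is on a
completely different scale from $X_1$ — a Euclidean distance over all three
coordinates would be swamped by brightness.

**NSC coordinates** fix both issues. Cartesian chromatic coordinates
$Z_i = S_{i+2} - S_i$ ($i = 1 \dots n-1$) and a *normalized* achromatic
coordinate $Z_n = \beta/\beta_m$, where $\beta_m$ is the brightness of a
perfect white reflector under the same illuminant, so $Z_n \in (0, 1]$ and
all coordinates are of order 1. The distance is

$$ d_{12} = \sqrt{\textstyle\sum_{i<n} (Z_{1i}-Z_{2i})^2 +
\alpha\,(Z_{1n}-Z_{2n})^2 }, $$

with the achromatic weight $\alpha$ a free parameter: $\alpha = 1$ is the
proposed model, $\alpha = 0$ recovers the chromatic-only classical scheme.
A second variant rescales each chromatic coordinate per mechanism,
$Z_i = 2(S_{i+2}-S_i)/(S_{i+2}+S_i)$, which removes segment-pair brightness
artifacts but can blow up when a segment pair is nearly dark — the package
refuses denominators below $10^{-9}$, naming the offending coordinate.

**Coordinate ordering.** The general definition $Z_i = S_{i+2} - S_i$ is
applied uniformly for every $n$, so a trichromat has $Z_1 = Y - B$ and
$Z_2 = R - G$. Trichromatic treatments often list $R - G$ first; the two
conventions are coordinate permutations with identical distances, and this
package keeps the general ordering so that $Z_i$ always pairs with the
opponent mechanism between receptors $i$ and $i+1$.

**Why the coordinates approximate opponency.** With receptor peaks evenly
spread, rectangular sensitivities and linear transduction, excitations are
approximately $E_S = B + G$, $E_M = G + Y$, $E_L = Y + R$
(`rect_excitations()`). Then $E_M - E_S = Y - B = Z_1$ and $E_L - E_M = R -
G = Z_2$ *exactly* in this approximation — the chromatic coordinates are
species-independent stand-ins for opponent mechanisms, whose defining
property (coefficients summing to zero, `make_opponent()`) forces equal
excitations to the origin.

## Comparator models

The three species-specific comparators consume an excitation triplet,
however obtained (measured quantum catches, or `rect_excitations()` for
quick approximations):

* **COC**: $A = -9.86 E_S + 7.70 E_M + 2.16 E_L$, $B = -5.17 E_S + 20.25
  E_M - 15.08 E_L$, city-block distance.
* **Hexagon**: $X = \sqrt{3}(E_L - E_S)/2$, $Y = E_M - (E_S + E_L)/2$,
  Euclidean distance in hexagon units. (Flattened renderings of the $X$
  equation sometimes read "$3(E_L - E_S)/2$"; the $\sqrt 3$ of the original
  hexagon geometry is implemented.)
* **RN loci**: $X = A(E_L - E_M)$, $Y = B(E_S - (aE_L + bE_M))$, Euclidean
  distance. $A, B, a, b$ are species-dependent and have *no defaults*; the
  logarithmic version of the model is obtained by log-transforming the
  excitations before building the locus.

Computing excitations from real sensitivity curves (quantum catch, von
Kries adaptation, transduction nonlinearity) is out of scope: published
comparator distances are taken as given, which is how the models are used
in evaluation studies.

## Evaluation harness

`compare_models()` rank-correlates (Spearman's $\rho$, average ranks for
ties) behavioral proportion-correct against per-pair distances from any set
of models, given as precomputed columns, numeric vectors, or distance
functions over stimulus ids. Detection experiments that swap target and
background roles can be collapsed with `average_reciprocal()`. No p-values
are attached by default: with the 4–5 pairs typical of these experiments a
rank test is degenerate.

## The synthetic generator, and what a green test establishes

`fixture_suite()` emulates the qualitative taxonomy of natural reflectance
shapes: sigmoids whose inflection wavelength distinguishes UV-absorbing
white (400 nm), yellow (500 nm) and red (600 nm); a Gaussian bell for green
(550 nm); flat gray spectra from 0.05 to 0.95 exercising only the
achromatic axis; near-black; and the perfect white standard. Noise, when
requested, is additive Gaussian clipped at zero, under a fixed seed.

What these fixtures do **not** emulate: real floral/leaf fine structure
(secondary peaks, NIR behavior), measurement noise correlated across
wavelengths, and structural (angle-dependent) colors. A green test on
fixtures therefore establishes the *mechanics* of the pipeline — exact
identities, bounds, metric properties, recoverability — not field validity
of the model, which only behavioral data can establish.

The model-recovery simulation is defined once: 11 fixture spectra under D65
at 5 nm, 8 stimulus pairs per replicate drawn uniformly (redrawn if any
model's distances are constant on the draw, which leaves $\rho$ undefined),
proportion correct $= 0.5 + 0.45\,\hat d_{\mathrm{NSC}} + \mathcal N(0,
0.02)$ clipped to $[0,1]$ with $\hat d$ min–max scaled, 200 replicates. The
noise level is a choice (no published value exists for the harness); 0.02
represents a well-powered behavioral experiment. NSC must attain the top
rank (ties included) in at least 95% of replicates.

## Numerical choices

* **Grids.** Uniform spacing only; mixed spacing errors out rather than
  being silently regridded, because the brightness sum is bin-width
  dependent. Resampling is linear interpolation and never extrapolates.
* **Segment membership.** Half-open $[\lambda_{i-1}, \lambda_i)$, last
  segment closed at $\lambda_2$: every sample counted exactly once. A flat
  spectrum on a 401-sample grid therefore has $S = (100, 100, 100, 101)/401$,
  not exactly $(0.25, \dots)$ — an inherent boundary-sample asymmetry of
  order one sample weight, which cancels in all comparisons between spectra
  on one grid.
* **Bin-width dependence.** $X_3$ scales with the number of samples (about
  $5\times$ between 5 nm and 1 nm grids); $Z_n = \beta/\beta_m$ cancels the
  dependence to well under 1%. The residual comes from interpolating the
  5 nm D65 table and boundary-sample assignment.
* **D65 units.** The embedded table is the standard relative spectral
  *power* distribution; because brightness is photon flux, `d65()` converts
  to relative photon flux ($\propto E(\lambda)\lambda$) by default, with
  `units = "energy"` available. The choice rescales $\beta$ and $\beta_m$
  together, so $Z_n$ is only mildly affected and chromatic coordinates only
  through the illuminant's shape.
* **Degenerate inputs.** All-black spectra (zero $\beta$) have undefined
  chromatic coordinates: error. The achromatic point $X_1 = 0$ has
  undefined hue: $X_2 = 0$ by convention, flagged `hue_defined = FALSE`.
  Reflectance above 1 warns but proceeds (spectrometer artifacts are
  common); negative values always error. Loci computed under different
  illuminants, variants, or partitions are refused by `nsc_distance()`.

## Known limitations

The model ignores the viewer entirely: it cannot show color constancy, and
it can assign positive distances to metamers (spectra indistinguishable to
an actual viewer). It compares spectral shapes, not perceptions; treat its
distances as a physical similarity index whose behavioral relevance must be
demonstrated per system. Light scatter between surface and eye (aquatic,
foggy, long-distance viewing) is not modelled — supply measured radiance in
such cases. Published headline correlations from bee experiments are not
reproducible inside this package because the underlying stimulus spectra
were never printed; the evaluation harness reproduces the *protocol*, and
external spectra can be dropped in via the standard CSV interfaces.
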