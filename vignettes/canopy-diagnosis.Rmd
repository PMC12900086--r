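---
title: "Canopy-cover tiller diagnosis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy-cover tiller diagnosis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricecanopy)
```

## The diagnostic model

The package implements a four-stage pipeline for deciding whether a rice
paddy has reached the tiller density at which mid-season drainage should
begin, using nothing but an overhead RGB photograph of the canopy.

**Stage 1 — pixel classification.** Every pixel is scored with the
red–green discriminant index

$$I = 128 + 128\,\frac{G - R}{G + R},$$

a normalized green–red contrast rescaled onto the 8-bit intensity range:
achromatic pixels ($R = G$) sit at the neutral value 128, pure green at
256, pure red at 0. Blue is deliberately excluded — paddy backgrounds
(water, wet soil) are blue-shifted, and a green-vs-red contrast separates
leaf tissue from them more robustly than a three-channel index. Pixels
with $I \ge 134$ (inclusive) are classified as rice leaf and stem. The
threshold 134 is the operational value for rice canopies and is exposed
as a parameter (`segment_canopy(..., threshold = )`, range 0–256) for
sensitivity analyses.

Two numerical choices matter at the boundary. First, $I$ is kept as an
unclamped real number and never rounded before thresholding: rounding
would create an undocumented second threshold at the half-integer.
(Whether a pixel such as $(61, 67)$, whose index is exactly 134, counts
as vegetation is therefore decided solely by the inclusive comparison —
it does.) Second, pixels with $R + G = 0$ (pure black or pure blue) are
assigned the neutral value 128 rather than a 0/0: black is never canopy,
and the neutral midpoint classifies it as background at any threshold
above 128 without a special case downstream.

**Stage 2 — canopy cover.** $C = 100\,k/N$ where $k$ is the vegetation
pixel count and $N$ the total. All pixels are counted; no border or
guide-overlay region is excluded, and no automatic cropping is applied —
framing (conventionally a 4 × 4 grid of 16 hills) is a capture-protocol
concern outside the package.

**Stage 3 — tiller estimation.** A quadratic regression converts cover
in percent to tiller density:

$$T = a C^2 + b C + c, \qquad
  (a, b, c) = (-0.0548,\ 9.13,\ 77.7)$$

with $T$ in tillers m⁻², $a$ in tillers m⁻² %⁻², $b$ in tillers m⁻² %⁻¹
and $c$ (the zero-cover intercept) in tillers m⁻². The built-in
coefficients derive from field calibration of 'Koshihikari' stands at
planting densities of 11.0–18.3 hills m⁻² and are applied unchanged to
all cultivars; the planting-density provenance is carried as metadata
but not enforced, since density is not observable from the inputs. The
cover range of the original calibration data is not published, so the
built-in model has no recorded calibration domain; models refitted with
`fit_model()` record the cover range of their own data.

The parabola opens downward and peaks at the vertex $-b/2a \approx
83.3\%$ cover; past it the model predicts fewer tillers for denser
canopies, which is an artefact, not biology. Estimates are never
clamped; instead `estimate_tillers()` raises an `extrapolated` flag past
the vertex (or outside a recorded calibration domain), so the diagnosis
can surface model limits rather than mask them.

**Stage 4 — diagnosis.** The estimate is compared with the cultivar's
target tiller number: 400 ('Fusaotome'), 360 ('Fusakogane'), 320
('Koshihikari') tillers m⁻², from prefectural cultivation guidelines.
The rule is inclusive — an estimate equal to the target already
diagnoses optimal drainage timing — and the comparison uses the
unrounded real-valued estimate; rounding to one decimal happens only in
human-readable display. Rounding before comparison would silently
introduce a third threshold between model and decision. Registry lookups
are case-sensitive exact matches (cultivar names are identifiers), and a
JSON config can extend or override the built-in targets. The guidelines
also vary targets by soil type; only cultivar-level values are published,
so soil type is not a registry key.

## Agreement statistics

`accuracy_report()` validates estimates against manual counts with five
metrics over $n \ge 2$ pairs: RMSE, MAE, mean bias, $R^2$ and Lin's
concordance correlation coefficient

$$\rho_c = \frac{2 s_{eo}}{s_e^2 + s_o^2 + (\bar e - \bar o)^2},$$

computed with population ($1/n$) moment denominators — Lin's original
estimator, chosen because it makes the decomposition
$\mathrm{RMSE}^2 = \mathrm{bias}^2 + s^2_{e-o}$ exact, which the test
suite asserts as an identity. Bias is defined as mean(estimated −
observed), so systematic underestimation by the image method appears as
a negative bias. $R^2$ is that of the ordinary least-squares line of
estimated on observed *with* intercept (equal to squared Pearson
correlation); regression through the origin was the alternative, but the
with-intercept convention is the default in every standard treatment of
method comparison and is assumed here. `error_in_days()` divides an
error magnitude by a daily tillering rate (reference range 12.0–24.3
tillers m⁻² day⁻¹ around drainage timing), expressing estimation error
in the operationally meaningful unit of days of growth.

## What the synthetic generator emulates — and what it does not

`render_canopy()` builds test scenes with an *exactly* known vegetation
fraction: exactly $\mathrm{round}(f N)$ pixels take colours from a
vegetation palette, the rest from a background palette. Palettes are
validated at construction to keep discriminant indices at ≥ 140
(vegetation) and ≤ 128 (background), a deliberate margin either side of
the 134 boundary so that segmentation recovers the construction mask
pixel-for-pixel and cover round-trips are exact rather than statistical.
Boundary behaviour itself is tested separately with hand-built pixels
such as $(61, 67)$ and $(62, 67)$.

Vegetation pixels are clustered into `grid_rows × grid_cols` blobs
(default 4 × 4, mimicking the 16-hill framing) by ranking every pixel on
its distance to the nearest jittered hill centre and taking the closest
$k$. This keeps blobs disjoint at low fractions and merges them
continuously as $f \to 1$, so one placement rule covers all feasible
fractions with the pixel count exact by construction — no separate
fallback branch is needed. Rendering is deterministic for a fixed spec
and seed, and restores the caller's RNG state.

The generator validates plumbing and statistics, not agronomy: blobs are
axis-aligned clusters, not leaves; there is no occlusion, leaf-angle
variation, specular water reflection, mixed boundary pixels, or
illumination gradient. Passing round-trip tests therefore demonstrates
that the pipeline's arithmetic and composition are correct, *not* that
the 134 threshold or the quadratic generalize to real field imagery —
that evidence must come from field calibration.

`simulate_calibration()` draws covers evenly spaced on a range with
tiller values from a known quadratic plus i.i.d. Gaussian noise, for
fit-recovery experiments; `simulate_growth()` produces linear tillering
series used to check that a constant estimator bias of $\Delta$ shifts
the day a series crosses a cultivar target by $\Delta/\text{rate}$ days
— the semantics behind `error_in_days()`.

## Numerical and interface choices

- Least squares in `fit_model()` is delegated to `stats::lm()` (QR
  factorization); the contract is the unique OLS minimizer, and tests
  cross-check the coefficients against independently solved normal
  equations. At least three distinct cover values are required.
- Image decoding uses the png and jpeg packages. PNG round-trips are
  bit-exact and used for all exact tests; JPEG is lossy with
  decoder-dependent IDCT rounding, so cover computed from JPEG input may
  differ at the margin across platforms. 16-bit PNGs are rejected rather
  than silently requantized; grayscale is promoted to R = G = B and
  alpha is dropped.
- The CLI (`canopy_cli()` plus the thin `inst/cli/ricecanopy.R` script)
  returns exit status 0 whenever the pipeline ran, regardless of the
  diagnosis outcome, reserving non-zero for operational failures with a
  machine-readable JSON error object on stderr. Structured outputs carry
  full-precision numbers; only summary lines round.
- Replicated evaluation data: when a paired CSV carries a `group`
  column, replicates are averaged within groups before comparison,
  matching the convention of comparing means of replicate images against
  means of replicate counts.

## Problem sizes in the test suite

The suite exercises: all 65,536 (R, G) channel combinations against a
scalar loop oracle; 50 random scenes (10–60 px per side) for exact
cover round-trips; 100 Monte-Carlo replicates of noisy calibration
(n = 200 points, σ = 5 tillers m⁻²) for unbiased coefficient recovery
within three standard errors; and 1,000 randomized trials of the
agreement-metric identities. These sizes give sub-pixel-exact or
3-standard-error resolution on every claim while keeping the full suite
in the tens of seconds.

## Known limitations

- The quadratic is calibrated for one cultivar group and planting-density
  range; outside them (or past 83.3 % cover) estimates are flagged, not
  corrected.
- No illumination or colour calibration: exposure shifts that move pixel
  indices across 134 change cover directly.
- Single-date diagnosis only; no growth forecasting or recommendation of
  a future drainage date.
- The agreement module quantifies error but applies no bias correction;
  an offset correction is straightforward if a local validation set
  justifies it.
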