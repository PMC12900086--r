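# ricecanopy

Tiller-density diagnosis of rice paddies from nadir canopy photographs.

Mid-season drainage — temporarily drying a flooded paddy to check late
tillering and aerate roots — is timed by when the stand reaches a
cultivar-specific target tiller number. Counting tillers by hand is slow,
so this package estimates them from a single overhead RGB photo of the
canopy and turns the estimate into a drainage-timing decision. It is
aimed at agronomists and crop-phenotyping developers who want the
image-to-decision pipeline as a scriptable, testable library rather than
a phone app.

## The method

1. **Segmentation.** Each pixel is scored with the red–green discriminant
   index

   *I* = 128 + 128 (G − R)/(G + R)

   (*I* = 128 for achromatic pixels; the blue channel is ignored). Pixels
   with *I* ≥ 134 are classified as rice leaf/stem.
2. **Canopy cover.** C (%) = 100 × vegetation pixels / total pixels.
3. **Tiller estimation.** A quadratic regression converts cover to tiller
   density:

   T (tillers m⁻²) = −0.0548 C² + 9.13 C + 77.7

   Estimates past the parabola's vertex (≈ 83.3 % cover) are flagged as
   extrapolated.
4. **Diagnosis.** T is compared with the cultivar's target tiller number
   (built-in registry: 'Fusaotome' 400, 'Fusakogane' 360, 'Koshihikari'
   320 tillers m⁻²). T at or above target ⇒ optimal timing for
   mid-season drainage.

Supporting modules provide agreement statistics for validating estimates
against manual counts (RMSE, MAE, mean bias, R², Lin's concordance
correlation coefficient, and the conversion of error magnitudes into
days of growth at a given tillering rate), least-squares refitting of the
cover→tiller model from calibration CSVs, and a synthetic canopy
generator that renders images with an *exactly* known vegetation
fraction so the whole pipeline can be verified without field data.

## Worked example

```r
library(ricecanopy)

# a synthetic 100 x 100 px canopy with exactly 37% vegetation
scene <- render_canopy(scene_spec(100, 100, target_fraction = 0.37, seed = 1))
diagnose_image(scene$image, "Fusakogane")
#> Canopy cover: 37.0% (3700 / 10000 px vegetation)
#> 340.5 tillers m-2 at 37.0% cover
#> Fusakogane: tiller number still insufficient
#>   estimated 340.5 vs target 360 tillers m-2 (margin -19.5)
```

The segmentation recovered the constructed 37 % cover exactly, the
quadratic maps it to 340.5 tillers m⁻², and since 340.5 < 360 the field
is not yet ready for drainage. Validating estimates against counts:

```r
obs <- c(300, 350, 400)
accuracy_report(obs + 10, obs)
#> Agreement over n = 3 pairs (tillers m-2):
#>   RMSE 10.0 | MAE 10.0 | bias +10.0 | R^2 1.0000 | CCC 0.971
error_in_days(34.6, 12.0)   # a 34.6 tillers m-2 error at 12 tillers/day
#> [1] 2.883333                # ... is under 3 days of growth progression
```

The same pipeline is scriptable from a shell via the installed CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ricecanopy.R", package="ricecanopy"))')" \
  diagnose field.png Koshihikari
```

with subcommands `diagnose`, `segment`, `evaluate`, `calibrate` and
`simulate` (run with no arguments for usage).

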