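# fvcover

Fractional vegetation coverage (FVC) — the share of ground covered by the
vertical projection of plant canopy — is a basic structural parameter in
plant ecology, and nadir RGB photographs taken with a camera or phone are
the cheapest way to measure it. The hard part is segmentation: deciding,
pixel by pixel, what is plant and what is soil, stone or litter, under
illumination that ranges from flat overcast light to direct sun full of
specular highlights and cast shadows.

`fvcover` implements four classical colour-based segmentation algorithms,
the FVC statistic, the standard accuracy assessment against reference
coverage, and a synthetic scene generator with pixel-exact ground truth for
benchmarking illumination robustness. It is aimed at field ecologists
processing quadrat photographs and at anyone comparing colour-index
segmentation rules under controlled conditions.

## The algorithms

For each pixel with 8-bit digital numbers (R, G, B):

| id | rule | vegetation iff |
|----|------|----------------|
| `fun01` | ratio + excess green | R/G < 0.95, B/G < 0.95, 2G − R − B > 20 |
| `fun02` | RGB decision tree | first matching strict-ordering rule is a leaf/flower class |
| `fun03` | ExG − ExR | 2G − B − R − (1.4R − G) > 0 |
| `fun04` | ExG + Otsu | 2G − B − R > t, t maximising between-class variance |

FVC is then `vegetation pixels / total pixels × 100`. Accuracy against a
reference is summarised by MAPE, BIAS, relBIAS, RMSE and relRMSE (population
means, n in every denominator), a measured-on-reference regression, a
two-group analysis of variance, and the distribution of per-image relative
errors.

## Worked example

Segment one synthetic sunlit scene with all four algorithms and compare with
its built-in ground truth:

```r
library(fvcover)

scenes <- generate_batch(3, scene_params(scenario = "noon", seed = 1), seed = 99)
sc <- scenes[[2]]
sc$true_coverage
#> [1] 33.11768

for (a in c("fun01", "fun02", "fun03", "fun04"))
  print(compute_fvc(segment_image(sc$image, a), a, "scene_0002"))
#> FVC 31.05% (20350 / 65536 vegetation pixels)
#> FVC 33.08% (21680 / 65536 vegetation pixels)
#> FVC 27.38% (17944 / 65536 vegetation pixels)
#> FVC 23.19% (15201 / 65536 vegetation pixels)
```

True coverage is 33.12%: under noon illumination the ratio algorithm loses
highlighted leaves (31.05%, underestimate), the decision tree stays closest
(33.08%), and the index/threshold algorithms drift further as shadows and
highlights distort the ExG histogram.

A small benchmark — scenes per scenario, frame size and seed are all
configurable:

```r
rep <- run_benchmark(benchmark_config(
  scenes_per_scenario = c(8L, 6L, 6L), height = 128, width = 128, seed = 7
))
rep$summary[, c("algorithm", "scenario", "n", "mape", "bias")]
#>    algorithm scenario n  mape    bias
#> 1      fun01 overcast 8  0.00   0.000
#> 2      fun02 overcast 8  2.12  -0.591
#> 3      fun03 overcast 8  0.00   0.000
#> 4      fun04 overcast 8  0.00   0.000
#> 5      fun01 forenoon 6  4.29  -1.351
#> 6      fun02 forenoon 6  4.80  -0.405
#> 7      fun03 forenoon 6  8.67  -2.890
#> 8      fun04 forenoon 6 35.78 -12.218
#> 9      fun01     noon 6  5.10  -1.710
#> 10     fun02     noon 6  5.04  -0.891
#> 11     fun03     noon 6 16.61  -5.863
#> 12     fun04     noon 6 35.12 -11.760
```

Overcast scenes are recovered exactly (or near-exactly for the decision
tree, which misses pale-lime leaves whose channels tie under noise);
direct-sun scenes degrade every algorithm, with the Otsu-based `fun04`
hurt most. `write_report()` writes the summary as CSV plus a plain-text
table; MAPE/BIAS columns follow the 2-decimal convention of published
accuracy tables.

Real photographs go through the same machinery:

```r
tab <- run_on_directory("photos/", c("fun01", "fun02"), reference = "reference.csv")
summarize_measurements(...)  # same summary table from any measurement CSV
```

A thin command-line wrapper with subcommands `simulate`, `segment`,
`measure`, `assess` and `benchmark` is installed at
`system.file("scripts", "fvcover", package = "fvcover")`.

## Scope

Reading PNG/JPEG/TIFF rasters, 0/255 mask PNGs and measurement/reference
CSVs is included. Manual reference delineation, radiometric calibration,
EXIF handling, shadow-compensation preprocessing and learned segmentation
are out of scope. See `vignettes/fvc-measurement.Rmd` for the model
assumptions, palette calibration, numerical choices and known limitations.
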