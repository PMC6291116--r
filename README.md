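# plasmaseg

Segmentation of plasma cells in stained bone-marrow aspirate
photomicrographs, for quantitative assessment of multiple myeloma smears.
It is aimed at image-analysis practitioners who need instance-level plasma
cell masks (nucleus + cytoplasm) from 8-bit RGB microscopy images,
including cells that touch or overlap in clusters.

## Method

An image is modeled as four regions — plasma-cell nucleus (Ω₁₁), plasma-cell
cytoplasm (Ω₁₀), background (Ω₀₁), unstained cells (Ω₀₀) — encoded as the
sign combinations of two level-set functions φ₁, φ₂. For each region and
each of nine color channels (R, G, B, H, S, V, L, a, b; all on [0, 255]) a
Gaussian N(μ, σ²) is fitted to labeled reference pixels. Channels are
weighted per region by the Bhattacharyya distance

D_B = (μ₁−μ₂)² / (4(σ₁²+σ₂²)) + ½ ln((σ₁²+σ₂²)/(2σ₁σ₂)),

kept only when the channel separates the region from both of its
competitors (threshold 1 for nucleus/cytoplasm, 3 for
background/unstained), with the larger of the two distances as the weight.
The fields minimize

E = η₁ E_p + η₂ E_d + α₁∫H(φ₁) + α₂∫H(φ₂) + β₁∫|∇H(φ₁)| + β₂∫|∇H(φ₂)|

where E_p sums −log of the per-region weighted Gaussian mixture densities
and E_d the weighted squared deviations from the region mean colors, each
over the four smoothed phase indicators (defaults η₁=1, η₂=3, α₁=α₂=0,
β₁=2, β₂=1). Pre-processing: 1% percentile contrast stretching and
replacement of pixels with 8-bit hue below 120 (unstained cells) by the
background color. Post-processing: small/scant-cytoplasm component
rejection; nuclei from k-means on the stained pixels (variant `tool1`) or
the Ω₁₁ phase (`tool2`); marker-controlled watershed on distance
transforms to split clusters; a circular-Hough circularity gate; and
rejection of cells whose nucleus exceeds 85% of the cell area
(lymphocyte-like).

A synthetic stained-smear generator with exact ground truth
(`generate_scene()`) and instance-level detection metrics
(TPR/PPV/F1/FDR at IoU ≥ 0.7) make every stage testable without clinical
data.

## Worked example

```r
library(plasmaseg)

# a labeled reference scene stands in for annotated training images
ref   <- generate_scene(default_scene_spec(), seed = 999)
stack <- to_channel_stack(contrast_stretch(ref$image))
model <- fit_region_model(stack, truth_region_masks(ref$truth$region_map))

sc  <- generate_scene(default_scene_spec(), seed = 1)   # 20 plasma cells
res <- run_pipeline(sc$image, model, pipeline_config(variant = "tool1"))

nrow(res$cells$instances)
#> [1] 20
head(res$cells$instances[, c("label", "area", "nucleus_area", "ratio")], 4)
#>   label area nucleus_area     ratio
#> 1     1  571          169 0.2959720
#> 2     2  342          151 0.4415205
#> 3     3  536          274 0.5111940
#> 4     4  580          226 0.3896552

evaluate_detections(list(res$cells), list(sc$truth$instance_map),
                    pipeline_config())$report
#> TPR (recall):    100.00 %
#> PPV (precision): 100.00 %
#> F1-score:        100.00 %
#> FDR:              0.00 %
```

Each instance row is one segmented cell: its pixel area, nucleus area, and
nucleus-to-cell area ratio (used to reject lymphocyte-like cells). The
channel weights derived from the shipped reference distance table show the
structure the method exploits — the nucleus is discriminated by B, H and V,
unstained cells almost entirely by hue:

```r
assign_weights(reference_distance_table())[c("B", "H", "V"), ]
#>   nucleus cytoplasm background unstained
#> B    5.74      1.17          0      0.00
#> H    1.76      1.76          0     73.13
#> V   14.48      2.17          0      0.00
```

A command-line front end is installed with the package
(`inst/cli/plasmaseg`): `plasmaseg run`, `plasmaseg synth`,
`plasmaseg eval`.

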