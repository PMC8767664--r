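# nucseg

Single-cell quantification of highly multiplexed fluorescence tissue
images (CODEX and similar platforms): nucleus instance segmentation with
a pluggable backend, overlap tiling and lossless stitching, artifact
filtering, mask expansion, lateral bleed compensation, and per-cell
marker quantification exported as CSV and FCS. For image analysts and
computational biologists who need a reproducible, scriptable path from a
multi-channel TIFF to a gated single-cell table.

## What it computes

Given a multi-channel image and a nuclear channel, the pipeline runs:

1. **Brightness scaling** — one shared factor
   `f = 0.875 · dtype_max / Q₀.₉₉(reference)` (capped to [1, 100])
   derived from a reference image.
2. **Tiling** — overlapping 512 px tiles (64 px overlap), edge tiles
   shifted inward; core regions partition the image.
3. **Segmentation** — any backend satisfying the
   `segment(gray) -> label image` contract; the built-in deterministic
   baseline is smoothing → threshold (computed once per image, shared by
   all tiles) → Euclidean distance transform → watershed.
4. **Stitching** — a mask is kept iff its centroid lies in its tile's
   core; no duplicates, no drops for objects smaller than the overlap.
5. **Artifact filtering** — objects below `min_area` pixels removed.
6. **Mask expansion** — nucleus masks grown 1–2 px to capture membrane
   signal, by nearest-centre assignment or by collision-limited
   iterative dilation.
7. **Lateral bleed compensation** — surface contact ratios
   `A[i,j] = (boundary pixels of i touching j) / (boundary pixels of i)`
   on the expanded masks; true signals recovered per channel by solving
   `(I + flank·(A − I)) s = observed` per connected component of the
   contact graph.
8. **Quantification/export** — per cell: centroid, nucleus size, raw and
   compensated channel means; CSV + FCS 3.1, label TIFF, ROI stack,
   overlay PNG.

Segmentation quality is scored with the standard instance metric: at IoU
thresholds t ∈ {0.50, …, 0.95}, `Q(t) = TP/(TP+FP+FN)`, AP = mean over
the 10 thresholds, mAP = mean AP over images. Residual spillover is
measured as the fraction of cells double positive for a mutually
exclusive marker pair.

A seedable synthetic-scene generator (elliptical nuclei with ground
truth, plus marker channels rendered under the exact contact-matrix
forward model the compensation inverts) makes every stage testable with
no external data.

## Worked example

```r
library(nucseg)

nuc   <- generate_nuclei(n_cells = 30, height = 256, width = 256, seed = 7)
scene <- render_spillover_channels(nuc$labels, grow_pixels = 2, seed = 7)

seg <- baseline_segment(get_channel(nuc$image, 1))
length(label_ids(seg))
#> [1] 30
mean_average_precision(list(list(pred = seg, gt = nuc$labels)))
#> <eval_report> 1 image(s), mAP = 0.8629
#>   per-image AP: 0.8629

tab <- quantify_cells(nuc$labels, scene$expanded_labels, scene$image)
tab <- apply_compensation(tab, scene$contacts)
head(as.data.frame(tab)[, c("cell_id", "x", "y", "size",
                            "marker1", "marker2",
                            "marker1_comp", "marker2_comp")], 4)
#>   cell_id      x      y size marker1  marker2 marker1_comp marker2_comp
#> 1       1  72.12  34.88  713  0.8237 116.2315       0.7643     107.2402
#> 2       2 117.88  52.79  513 90.5529   0.7923      90.5529       0.7923
#> 3       3 115.95  30.98  125 87.5679   0.7577      87.5679       0.7577
#> 4       4  83.79 241.76  127 87.3297   0.7228      87.3297       0.7228

dp_raw  <- double_positive_fraction(tab, "marker1", "marker2", 15, 15)
dp_comp <- double_positive_fraction(tab, "marker1", "marker2", 15, 15,
                                    use_compensated = TRUE)
sprintf("double-positive: raw %.3f -> compensated %.3f", dp_raw, dp_comp)
#> [1] "double-positive: raw 0.133 -> compensated 0.000"
```

All 30 synthetic nuclei are recovered (mAP 0.86 means masks match ground
truth well across strict IoU thresholds). Markers 1 and 2 are mutually
exclusive by construction, so the 13% of cells apparently positive for
both is pure lateral spillover from touching neighbours — compensation
removes it entirely, and each cell's compensated means return to its
true single-marker profile (e.g. cell 1: marker1 ≈ 0.8, marker2 ≈ 107).

A full directory run, with every stage and output above:

```r
cfg <- pipeline_config("input_dir", "output_dir", nuclear_channel = 1)
run_pipeline(cfg)
```

or from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/nucseg.R run --input input_dir --out output_dir --nuclear-channel 1
Rscript inst/cli/nucseg.R synth --n-cells 50 --size 512x512 --seed 0 --out scene_dir
Rscript inst/cli/nucseg.R evaluate --pred pred_dir --gt gt_dir
```

## Documentation

See `vignettes/nucseg-methods.Rmd` for the models, parameter defaults,
numerical choices (metric conventions, tie-breaking, degenerate cases)
and the limits of what the synthetic scenes demonstrate.
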