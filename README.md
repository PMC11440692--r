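# mitomorph

Quantitative analysis of mitochondria in transmission electron microscopy
(TEM) sections of glioma tissue, and evaluation of instance segmentations of
them.

Pathologists and imaging groups studying glioma grade mitochondrial
ultrastructure from TEM fields: how many mitochondria a tumor cell carries,
how large, elongated or round they are, how much of each organelle's
cross-section is occupied by respiratory cristae (MRC), and whether the
outer mitochondrial membrane (OMM) is intact. When a segmentation model
(e.g. Mask R-CNN) proposes the instances, its output has to be scored
against manual annotation before any biology is read off it. `mitomorph`
implements both halves of that workflow as a plain R package, with a
synthetic-data generator so every stage is testable without clinical
images.

## What it computes

**Morphometry** — the five standard indices, per mitochondrion *i* in cell
*c* at pixel scale *s* (µm/px):

- density `n_c / A_c` (count per µm² of cell area),
- area `A_i` (µm²), perimeter `P_i` (µm),
- area ratio `Σ A_i / A_c`,
- circularity `4πA_i / P_i²` (1 for a circle; ImageJ's definition),

plus cristae occupancy `|cristae mask| / |mito mask|` and a rule-based
three-type MRC health classification (Type 1 dense cristae + intact OMM …
Type 3 vanished cristae / ruptured OMM), with WHO grades 1–2 grouped as LGG
and 3–4 as HGG.

**Evaluation** — predictions with score < 0.5 are discarded; retained ones
are matched one-to-one to ground truth greedily by descending IoU, a pair
counting as TP at IoU ≥ 0.5. Per image and macro-averaged over N images:

```
Precision = (1/N) Σ TP/(TP+FP)        Recall = (1/N) Σ TP/(TP+FN)
F1        = (1/N) Σ TP/(TP+(FN+FP)/2)
perimeter error rate = (1/N) Σ mean over TP pairs of (P_pred − P_gt)/P_gt
area error rate      = (1/N) Σ mean over TP pairs of (A_pred − A_gt)/A_gt
```

Both error rates are signed; absolute-value companions are always reported.

**I/O** — label images (uncompressed TIFF via a built-in codec, or PNG) and
a COCO-style polygon/RLE JSON dialect; measurements as CSV.

## Worked example

```r
library(mitomorph)

# exact-arithmetic fixture: image 1 has 2 TP / 1 FP / 1 FN, image 2 is clean
fx <- reference_fixture()
evaluate_predictions(fx$pred, fx$gt)
#> <metrics_report> 2 image(s)
#>   Precision 0.8333  Recall 0.8333  F1 0.8333
#>   Perimeter error rate +0.0000 (|.| 0.0000)  Area error rate +0.0000 (|.| 0.0000)
```

Per image: precision is 2/3 and 1, so the macro value is 5/6 ≈ 0.8333; the
matched squares share their ground truth's dimensions, so both error rates
are exactly zero.

```r
# synthetic LGG/HGG contrast, end to end
spec <- synthetic_dataset_spec(n_images = 8, image_size_px = 384, seed = 42)
res  <- measure_dataset(generate_ground_truth(spec))
compare_groups(res$records, "area_um2", grouping = "group", test = "mann_whitney")
#> <group_comparison> area_um2 by LGG/HGG (instance unit)
#>  label  n      mean        sd    median
#>    LGG 44 0.3888284 0.1624152 0.3574023
#>    HGG 62 0.2442252 0.1095135 0.2201749
#>   mann_whitney: statistic 2163, p = 3.059e-07
```

High-grade profiles generate smaller, rounder, denser mitochondria with a
larger fraction of healthy Type-1 cristae — so the test detects the HGG <
LGG area contrast the generator encodes, and
`type_composition(classify_instances(res$records), by = "group")` shows the
Type-1 share highest in HGG (0.52 vs 0.25 in this run).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mitomorph.R", package = "mitomorph"))')
Rscript $CLI simulate --config spec.json --out sim/ --seed 3
Rscript $CLI measure  --annotations sim/ground_truth.json --out meas.csv
Rscript $CLI evaluate --pred pred.json --gt sim/ground_truth.json --out report.json
Rscript $CLI report   --measurements meas.csv --out report/
```

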