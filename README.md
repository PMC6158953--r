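# cellcut

Interactive and automatic graph-cut segmentation of grayscale cell
images, with a static or boundary-adaptive regularization parameter, and
the full evaluation battery that goes with it (accuracy index,
precision/recall/F1, ROC/AUC, Welch t-test, λ sweeps, noise-robustness
experiments). Everything is testable end-to-end on a built-in synthetic
microscopy-like image generator — no downloads required.

## Who this is for

Anyone segmenting bright roundish cells (fluorescence microscopy and
similar) who wants a small, fully deterministic, inspectable graph-cut
pipeline: image in, binary mask out, plus the tools to quantify how much
the graph-cut parameter λ actually matters for their data.

## The model

A labeling $S \in \{0,1\}^x$ of the $x$ pixels minimizes

$$E(S) = \lambda \sum_a -\log P(I_a \mid S_a) +
\sum_{(a,b)\in N,\ S_a\neq S_b} e^{-(I_a-I_b)^2 / 2\sigma^2}$$

where $P(I\mid S)$ are smoothed 256-bin histograms of foreground
($M_O$) / background ($M_B$) seed intensities — from user scribbles
(interactive) or an Otsu pre-segmentation (automatic) — and $N$ is the
4-neighborhood. The minimum is found exactly as a minimum s/t cut
(Edmonds–Karp in C++). In adaptive mode, λ is multiplied per t-link on
an extracted cell-boundary set $a_E$: by $c_p$ toward the object
terminal and by 0 toward the background terminal, which counteracts the
shrink bias of graph cuts (boundary pixels being shaved off when
scribbles under-sample their intensities). Defaults: λ₁ = 20, c_p = 20.
See `vignettes/graphcut-methods.Rmd` for the full account.

## Worked example

```r
library(cellcut)

s     <- synth_generate(synth_params(), seed = 1)   # image + ground truth
scr   <- generate_scribbles(s$truth, coverage = 0.15, seed = 2, erosion = 3)
seeds <- scribble_seeds(scr, s$image)               # interior-only scribbles

static   <- segment(s$image, seeds, mode = "static")
adaptive <- segment(s$image, seeds, mode = "adaptive")

confusion(static$mask, s$truth)
#> <confusion: TP 722  TN 3220  FP 115  FN 39>
confusion(adaptive$mask, s$truth)
#> <confusion: TP 750  TN 3205  FP 130  FN 11>
metrics_report(confusion(static$mask, s$truth))
#> <metrics: AI 0.9624  precision 0.8626  recall 0.9488  F1 0.9036>
metrics_report(confusion(adaptive$mask, s$truth))
#> <metrics: AI 0.9656  precision 0.8523  recall 0.9855  F1 0.9141>
```

The numbers tell the shrink-bias story: with conservative interior
scribbles the static cut drops 39 true cell pixels (FN, mostly boundary
ring), while the boundary-adaptive cut recovers most of them (FN 11,
recall 0.949 → 0.986) at a small precision cost — higher F1 overall.
With automatic Otsu seeding the two modes give essentially identical
results, because the Otsu foreground samples already cover boundary
intensities. Comparing per-image F1 vectors uses the Welch test:

```r
t_test_f1(c(0.80, 0.90, 0.85), c(0.60, 0.65, 0.70))
#> <t-test: t -4.8990, df 4.00, p 0.00805, significant>
```

## Command line

```sh
cellcut synth   --preset homogeneous --seed 4 --out demo/
cellcut segment --image demo/image.png --scribbles demo/scribbles.png \
                --mode adaptive --out demo/mask.png
cellcut eval    --pred demo/mask.png --truth demo/truth.png \
                --out demo/metrics.json
cellcut sweep   --image demo/image.png --truth demo/truth.png --auto \
                --grid 1:400:20 --out demo/sweep.csv
cellcut noise   --image demo/image.png --truth demo/truth.png --auto \
                --densities 0,0.05,0.1 --out demo/noise.csv
```

(`exec/cellcut` after installation, or call `cellcut_main()` directly.)

## Real datasets

The harness functions (`lambda_sweep`, `noise_experiment`, `roc_points`,
`aggregate_metrics` with pooled and per-image dialects) apply unchanged
to real images read with `read_gray_image()` (8/16-bit PNG/TIFF/PGM);
batch replication on the public U2OS / NIH3T3 / HT29 collections is out
of scope here and not tested.
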