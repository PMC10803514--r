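# mfdnet

Simultaneous prediction of four immunohistochemical indices — estrogen
receptor (ER), progesterone receptor (PR), HER-2 and Ki-67, each coded
severe(+) / mild(−) — from grayscale breast-ultrasound (BUS) nodule
images, with a lightweight multistage feature-distillation convolutional
network (MFD-Net).

IHC status drives breast-cancer treatment decisions but requires biopsy
tissue; an image-based estimate gives radiologists an early, non-invasive
second opinion.  The package is aimed at researchers who want a fully
self-contained, CPU-only, reproducible implementation of this multi-label
classification pipeline: every layer, loss and gradient is implemented in
the package (R with small C++ kernels), verified against brute-force
oracles and finite differences, and exercised end-to-end on a bundled
speckle-phantom generator — no GPU, no deep-learning framework, no patient
data.

## The model

MFD-Net distils features at multiple depths.  Each of the three stages
splits into

* a depth branch — a multi-kernel blueprint-separable convolution:
  low-rank factorised 1×1 channel mixing (`K = K_A K_B`, subspace
  `ceil(mu * C)`), then depthwise convolutions of sizes {3, 4, 6} summed,
  plus a residual;
* a distillation branch — `x + PW(GELU(sum_m DW_km(x)))`, followed by two
  1×1 distillations that compress to half the stage channels.

Distilled maps from every stage and the final depth map are concatenated
and compressed (1×1), gated by the ESCA attention block (a spatial gate in
series with a channel gate), max-pooled globally, and read out by four
simultaneous two-way soft-max heads.  The multi-kernel depthwise part of a
block with `C` channels holds `C(3² + 4² + 6²) = 61 C` weights — fewer
than one dense 6×6 convolution (`36 C²`) for any `C ≥ 2`.

Training minimises the sum of four per-head cross-entropies with plain
SGD (`w' = w − γ ∂L/∂w`); an opt-in *concurrent soft-max* objective
down-weights co-occurring non-target tags in the normaliser using the
training-set co-occurrence matrix `r_ij`:

    sigma*_i = exp(z_i) / (sum_{j != i} (1 - y_j)(1 - r_ij) exp(z_j) + exp(z_i))

Evaluation reports per-index precision, recall, accuracy and F1 from the
confusion counts.

## Worked example

Generate a synthetic cohort with the reported patient statistics
(294 patients, 500 images; ER+ 79.8%, PR+ 72.2%), train the desk-sized
preset on a 70/30 split, and evaluate all four indices:

```r
library(mfdnet)

cohort   <- cohort_spec(preset = "paper-cohort", seed = 42)
manifest <- generate_cohort(cohort, "bus_cohort")
cfg      <- run_config(preset = "desk", seed = 7)
fit      <- train_mfdnet(cfg, manifest)
ev       <- evaluate_mfdnet(fit$model, fit$split$test)
round(t(sapply(ev$metrics, function(m)
  unlist(m[c("precision", "recall", "accuracy", "f1")]))), 3)
```

```
#>      precision recall accuracy    f1
#> ER       0.939  0.878    0.853 0.908
#> PR       0.833  0.848    0.760 0.841
#> HER2     0.671  0.746    0.707 0.707
#> KI67     0.807  0.914    0.787 0.857
```

Each row is one immunomarker head on the held-out split: `precision` is
the fraction of predicted-severe calls that are truly severe, `recall` the
fraction of truly severe nodules that were called severe, and `f1` their
harmonic mean.  All four heads are produced by one forward pass per image.
The majority-class accuracies for this split are 0.820 (ER), 0.747 (PR),
0.527 (HER-2) and 0.700 (Ki-67): the desk-sized network beats every
baseline — by eighteen points on HER-2, whose classes are balanced, and by
one to nine points on the three high-prevalence indices, where the
baseline already sits close to the label model's Bayes accuracy.  The run
takes about ten minutes on one CPU core.  Single images are scored with
`predict_mfdnet()`, which returns the four calls with their positive-class
probabilities.

A command-line front end covering
`generate | crop | augment | split | train | evaluate | predict | summary`
is installed at `inst/cli/mfdnet` (see `system.file("cli", "mfdnet",
package = "mfdnet")`).

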