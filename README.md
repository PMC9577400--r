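# mmfuse

Attention-guided multimodal fusion for skin-lesion classification from
clinical photographs plus patient metadata.

Dermatologists rarely judge a lesion from a photo alone: age, anatomical
region, Fitzpatrick phototype and lesion symptoms (itching, bleeding,
recent growth) all inform the diagnosis. `mmfuse` implements a six-class
lesion classifier — ACK (actinic keratosis), BCC (basal cell carcinoma),
MEL (melanoma), NEV (nevus), SCC (squamous cell carcinoma), SEK
(seborrheic keratosis) — that estimates

&nbsp;&nbsp;&nbsp;&nbsp;*ŷ = p(y = c | x_img, x_meta)*

by fusing an image encoder and a metadata encoder through attention.
Each modality is first re-weighted by intra-modality multi-head
self-attention, *x′ = Softmax(QKᵀ/√d) V* with Q, K, V projected from that
modality's token sequence. Two inter-modality cross-attention paths then
let each modality guide the other: one path takes Query and Value from the
image tokens and Keys from the metadata tokens, the other the reverse.
The resulting sequences *x_meta″* and *x_img″* are concatenated and a
fully connected softmax layer outputs the six class probabilities.

The package is a complete desk-scale laboratory for this architecture:

* the 21-attribute clinical metadata schema with one-hot featurization and
  the all-zero missing convention (male → `[1,0]`, female → `[0,1]`,
  missing → `[0,0]`);
* the fusion network with ablation switches (no self-attention, no
  cross-attention, plain concatenation, image-only) and a CPU-friendly
  convolutional backbone, trained with SGD and a reduce-on-plateau
  schedule — forward *and* backward passes in plain R, verified against
  finite differences;
* evaluation metrics: accuracy, balanced accuracy (macro recall),
  aggregated pairwise multiclass AUC (Hand & Till), per-class ROC curves,
  confusion matrices, and mean ± SD fold summaries;
* a stratified k-fold cross-validation harness with on-the-fly
  augmentation, fold-paired across model variants;
* univariate metadata association tests and Friedman + Wilcoxon
  (Pratt, exact) method comparison;
* a synthetic image + metadata generator in the PAD-UFES-20 on-disk layout
  with one informativeness knob per modality (α for images, β for
  metadata), so every claim is testable without downloads. The real
  dataset's image folder + metadata CSV load through the same
  `read_pad_ufes()` interface.

## Worked example

Generate a small synthetic cohort (10 lesions per class, moderately
informative images, fully informative metadata), cross-validate three
model variants on one shared stratified split, and compare them:

```r
library(mmfuse)

ds <- generate_dataset(synth_spec(n_per_class = rep(10L, 6L), alpha = 0.5,
                                  beta = 1, seed = 1))
ds
#> Synthetic lesion dataset: 60 samples, 64 x 64 px
#>   alpha (image signal): 0.5 | beta (metadata signal): 1 | missing rate: 0.05 | seed: 1
#> ACK BCC MEL NEV SCC SEK
#>  10  10  10  10  10  10

cfg <- fusion_config(normalize_meta = TRUE)
ctl <- train_control(epochs = 20, lr0 = 0.05)
cv <- run_cv(ds, cfg, ctl, k = 3, variants = c("image_only", "concat", "full"),
             seed = 1)
cv
#> Cross-validated evaluation (3 folds)
#>   image_only  ACC 0.315 ± 0.140  BACC 0.315 ± 0.140  AUC 0.810 ± 0.075
#>   concat      ACC 0.583 ± 0.083  BACC 0.583 ± 0.083  AUC 0.854 ± 0.018
#>   full        ACC 0.528 ± 0.121  BACC 0.528 ± 0.121  AUC 0.837 ± 0.048

compare_methods(cv_fold_metrics(cv, "bacc"), reference = "full")
#> Friedman omnibus over 3 methods, 3 folds: p = 0.05971
#> Pairwise Wilcoxon signed-rank vs full
#>   image_only   p = 0.25
#>   concat       p = 0.5
```

With only three folds the exact Wilcoxon test cannot reach small
p-values, and at 60 samples and 20 epochs the fused and concatenation
variants are within noise of each other; the point of the example is the
metric machinery and the ordering — metadata-using variants clearly
outperform the image-only baseline when the metadata carries the class
signal. The packaged experiment (`signal_ordering_experiment()`, see
below) runs the same comparison at six times the sample count, where the
separation is unambiguous.

Single fits use the classic modelling idiom — `mmf_net()` returns a
fitted object with `print`, `summary`, `predict`, `coef` and `plot`
(loss/learning-rate trace) methods:

```r
fit <- mmf_net(ds$images, ds$labels, ds$records,
               config = cfg, control = ctl, schema = build_default_schema())
predict(fit, ds$images[1:2], ds$records[1:2])          # 2 x 6 probabilities
predict(fit, ds$images[1:2], ds$records[1:2], "class") # argmax labels
```

A thin command-line front end over the same functions lives in
`inst/cli/mmfuse.R` (`generate`, `crossval`, `compare` subcommands).

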