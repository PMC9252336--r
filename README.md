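# gaitPD

Classification of Parkinson's disease (PD) from wearable-sensor gait
features with a from-scratch residual convolutional network and an
improved focal loss.

## Who this is for

Researchers in clinical movement analysis who want a fully reproducible,
tested implementation of an image-encoding deep-learning pipeline for
tabular gait data — either to run on their own per-subject feature tables
(CSV) or to study the method's behaviour on synthetic cohorts with known
ground truth.

## The method

A cohort of subjects — the emulated study design has 296 PD patients
(230 early, 66 moderate-to-advanced by Hoehn–Yahr stage) and 161
age-matched healthy controls (HC) — is described by 194 features per
subject: 97 from a timed-up-and-go test (TUG), 7 from a spinning turn
(TURN), 86 from narrow-path walking (NARROW), plus sex, age, thigh and
lower-leg length. The pipeline is:

1. **SMOTE** balances the classes: each synthetic minority sample is
   `x + u·(x_nn − x)` for a minority point `x`, one of its k = 5 nearest
   minority neighbours `x_nn`, and `u ~ U(0,1)` (161 HC → 296).
2. **Min–max normalization** of the raw features to [0, 1], fit on the
   training partition.
3. **Polynomial elevated dimensions**: degree-2 expansion (originals,
   squares, pairwise products `x_i x_j`, i < j, lexicographic) truncated
   to 117² = 13 689 terms.
4. **Image encoding**: row-major reshape to 117 × 117, corner-aligned
   bilinear resize to 112 × 112; **random erasing** augmentation online
   per mini-batch during training.
5. **Residual network**: 1×1 stem (1 → 64 channels), three residual
   layers of two units (128, 256, 512 channels; stride-2 projection
   shortcuts halve the side 112 → 56 → 28 → 14), global average pooling
   to a 512-vector, 2-neuron sigmoid head; positive call at score ≥ 0.5.
6. **Improved focal loss** on the degree of correct prediction
   `p′` (the probability assigned to the true class):

   IFL(p′) = 0 if p′ < τ;  (1 − p′²)·(−log p′) otherwise,  τ = 0.05

   which focuses training on hard samples and drops outliers entirely;
   training uses RMSprop, LR 1e-3 decaying ×1/5 every 10 epochs, batch
   size 23, early stopping with best-weight restoration.
7. **Evaluation**: confusion matrix (T_HC, T_PD, F_HC, F_PD), accuracy,
   precision, recall, specificity, F1 (percent) and ROC/AUC.

Because the clinical dataset is private, the package ships a synthetic
cohort generator (`generateCohort`) reproducing the schema, group sizes
and a tunable class separation, so every stage is testable end to end.

## Worked example

```r
library(gaitPD)

cohort <- generateCohort(cohortConfig(seed = 1))
cohort
#> GaitCohort: 457 subjects x 194 features
#>   diagnosis: HC=161, PD=296
#>   severity:  early=230, moderate_advanced=66, none=161

balanced <- smoteBalance(cohort, k = 5, seed = 2)
table(diagnosis(balanced))
#>  HC  PD
#> 296 296

# a desk-scale experiment: reduced image/channel sizes, strong separation
cfg <- experimentConfig("pd_vs_hc", seed = 1)
cfg$cohort$effect_size <- 2.0
cfg$preprocessing$target_side <- 32
cfg$preprocessing$resize_to <- 28
cfg$network <- list(input_side = 28, stem_channels = 8,
                    layer_channels = c(16, 32, 64), units_per_layer = 2,
                    kernel = 3)
cfg$training$max_epochs <- 25
res <- runExperiment(cfg)
res$metrics$accuracy   # held-out accuracy on the 178-sample test set
#> [1] 94.38202
res$metrics$auc
#> [1] 0.9924252
```

The generated cohort has exactly the study's accounting: 457 subjects,
194 features, 296/161 class split; after SMOTE both classes have 296
samples and the stratified 70/30 split holds out 178. With a planted
class separation of 2 pooled SDs on 30% of the gait features the trained
network recovers the signal well above chance (94.4% here); with zero
separation it stays at ~50%.

Thin command-line wrappers live in `inst/exec/`:

```sh
Rscript inst/exec/gaitgen.R --n-pd 296 --n-hc 161 --effect-size 1.0 --seed 7 -o cohort.csv
Rscript inst/exec/pdexperiment.R --task pd_vs_hc --seed 7 --out-dir runs/exp1
```

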