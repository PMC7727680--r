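# pulmoseg

Lung field segmentation for axial chest CT, built for the common situation
where an object detector can *find* the lungs but delivers a coarse mask that
bounds the organ without hugging the lung wall. `pulmoseg` is aimed at
medical-image-analysis researchers and pipeline builders who need a
pixel-accurate lung mask, a reproducible slice-gating protocol, and a full
evaluation suite — all runnable offline, with a synthetic phantom standing in
for patient data.

The pipeline has two phases:

* **Phase 1 — lung-presence gate.** A slice-level classifier decides whether
  a slice contains lung at all. It follows a strict protocol: z-score feature
  normalisation with statistics learned on the training set only, random-search
  hyperparameter tuning with stratified 5-fold cross-validation (selection by
  mean validation accuracy), and final model selection by the highest test F1,
  where F1 = 2·PREC·SEN/(PREC+SEN). Classifier families: naive Bayes, MLP,
  KNN, random forest, and SVM with linear/polynomial/RBF kernels.

* **Phase 2 — Parzen-window boundary refinement.** The coarse mask is eroded
  by a disc of radius *r* into a seed. The seed's intensities define a
  foreground Parzen-window density

  $$\hat p(z) = \frac{1}{n h^d} \sum_{i=1}^n \delta\!\Big(\frac{z - z_i}{h}\Big),$$

  a two-stratum background density *b* is estimated from the tissue just
  outside a guard band and from the far field, and every pixel gets a
  membership probability *p = f/(f+b)*. The region then grows or contracts:
  each pass adds frontier pixels with *p ≥ τ* and removes boundary pixels
  with *p < τ*, until the movement stabilises (≤ `stability_tolerance`
  changed pixels) or `max_iterations` is reached. Components not touching the
  seed are dropped and interior holes (vessels) are filled.

The package also provides the six-score evaluation suite (accuracy,
sensitivity, Matthews correlation, Jaccard, Dice, boundary Hausdorff
distance), a Friedman/Nemenyi method comparison, single-frame DICOM and
PNG/TIFF readers, and a seeded synthetic thoracic-phantom generator with
exact ground truth and a detector-style mask corruptor.

## Worked example

Generate a phantom slice, corrupt its ground truth into a detector-style
coarse mask, refine, and score:

```r
library(pulmoseg)

ph     <- generate_phantom(phantom_spec(seed = 7))
coarse <- corrupt_mask(ph$mask, corruption_spec("erode", 4))
res    <- refine_boundary(ph$slice, coarse, parzen_config(seed = 1))
res
#> <segmentation_result> 128 x 128, 2992 foreground px, 5 iteration(s), converged=TRUE

round(rbind(coarse  = segmentation_metrics(coarse,   ph$mask),
            refined = segmentation_metrics(res$mask, ph$mask)), 4)
#>            mcc    acc    sen jaccard hd   dice
#> coarse  0.7889 0.9395 0.6684  0.6684  4 0.8013
#> refined 1.0000 1.0000 1.0000  1.0000  0 1.0000

res$changed_per_iteration
#> [1] 304 319 272  96   0
```

The eroded coarse mask covers only ~80% of the lung (Dice 0.80, Hausdorff
4 px). Five boundary passes later the front has advanced back to the lung
wall and stopped — the changed-pixel counts decay to zero — recovering the
ground truth exactly (Dice 1.0, Hausdorff 0). Gating works the same way at
the slice level:

```r
train <- generate_classification_dataset(50, 50, phantom_spec(seed = 11))
gate  <- train_gate(train, families = c("bayes", "knn"), n_draws = 5, seed = 1)
predict_gate(gate, generate_phantom(phantom_spec(seed = 99))$slice)
#> [1] "lung"
```

A thin command-line front end over the same functions ships in
`inst/cli/pulmoseg.R` with verbs `phantom`, `train-gate`, `segment`,
`evaluate` and `compare`.

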