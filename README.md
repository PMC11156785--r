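# liverdwi

Correction of cardiac-pulsation-induced signal loss in multi-repetition
diffusion-weighted MRI (DWI) of the liver.

Liver DWI is acquired as many repetitions per slice (by default twelve:
four repetitions × three diffusion directions at b = 800 s/mm²). Cardiac
motion destroys signal, predominantly in the left liver lobe, and lesions
there can vanish from the averaged image. Correction algorithms that favor
bright voxels recover the signal but tend to brighten vessels, which can
then mimic lesions. `liverdwi` provides the quantitative machinery for
this trade-off, for researchers working on DWI post-processing:

* **Quality score** — four ROI-based features of a processed image,
  normalized to the unprocessed trace-weighted reference: pulsation
  artifact `PA = ⟨I⟩_R1 / ⟨I⟩_R2`, vessel darkness
  `VD = ⟨I⟩_bg / ⟨I⟩_vessel`, lesion contrast-to-noise ratio
  `CNR = (⟨I⟩_lesion − ⟨I⟩_bg) / sd_bg`, and data consistency
  `DC = 1 − ⟨|I − I_ref|⟩_R2 / ⟨I_ref⟩_R2`; their mean is the total
  quality score `Qtotal` (reference = 1, larger is better).
* **Five conventional combination algorithms** (weighted averaging,
  p-mean, percentile, informed-RESTORE-style outlier exclusion, exception
  set) plus a `Qtotal`-maximizing parameter grid search.
* **Feature-guided network training** — a composite loss
  `L = −λ_DC·DC − λ_CNR·CNR − λ_PA·PA − λ_VD·VD + λ_DI·DI + λ_PA2·PA2 + λ_ξ·ξ`
  with analytic gradients, and a compact pure-R U-Net (im2col + BLAS
  convolutions, hand-written backprop, Adam) trained in two stages:
  pretraining on the trace reference, then feature-guided training with a
  moving-window early stop.
* **Synthetic phantom generator** — multi-repetition liver slices with
  ground-truth ROI masks, left-lobe dropouts, vessel flicker, lesions,
  parenchyma texture and noise, so the whole pipeline runs without
  patient data.

## Worked example

Generate a 20-slice phantom dataset, apply the optimal conventional
algorithm (outlier exclusion, `k = 10, ks2 = 21, thr = 0.3`), and score it
against the trace-weighted reference:

```r
library(liverdwi)

ds   <- generate_dataset(n_patients = 10, slices_per_patient = 2,
                         phantom_config(), seed = 42)
imgs <- lapply(ds, function(sl)
  combine_outlier_exclusion(sl$stack, k = 10, ks2 = 21, thr = 0.3))
round(score_dataset(ds, imgs)$mean, 3)
#>   pa_n   dc_n   vd_n  cnr_n qtotal
#>  1.336  0.991  0.880  1.386  1.148
```

Reading: the pulsation score improves by 34% and the lesion CNR by 39%
over plain trace averaging, at the cost of brightened vessels
(`vd_n < 1`) — the characteristic signature of bright-voxel-favoring
conventional corrections. `Qtotal > 1` indicates a net quality gain.

Training the feature-guided network on desk-scale phantoms:

```r
cfg <- phantom_config(height = 48, width = 48)
ds  <- generate_dataset(10, 2, cfg, seed = 11)
sp  <- split_patientwise(ds, train_frac = 0.8, seed = 11)

fit <- fit_pulsenet(sp$train, sp$test,
                    unet_spec(in_channels = 12, depth = 3,
                              base_channels = 16),
                    config = train_config("desk", seed = 1))
pred <- lapply(sp$test, function(sl) predict(fit, sl$stack))
round(score_dataset(sp$test, pred)$mean, 3)
#>   pa_n   dc_n   vd_n  cnr_n qtotal
#>  3.087  0.306  1.392  2.520  1.826
```

Unlike the conventional algorithm, the trained network *increases* vessel
darkness (`vd_n > 1`) while still correcting the pulsation loss — the
qualitative advantage of the feature-guided approach. (At desk scale on
homogeneous phantoms the network over-processes; see the vignette's
limitations section.)

A thin command-line interface over these functions is installed at
`inst/cli/liverdwi.R` (subcommands `phantom`, `score`, `combine`, `sweep`,
`benchmark`, `evaluate-loss`, `train`, `predict`; all randomized commands
take `--seed`).

## Package layout

| Area | Contents |
|---|---|
| `R/phantom.R` | phantom configuration, slice/dataset generation, ROI sets |
| `R/qscore.R` | trace reference, PA/VD/CNR/DC, normalization, `Qtotal` |
| `R/combine.R` | the five combination algorithms, grid search |
| `R/floss.R` | loss weights, MIP, PA2, dispersion, ξ, composite loss + gradient |
| `R/unet.R`, `R/nettrain.R` | U-Net layers/backprop, normalization, augmentation, patient-wise split, early stopping, `fit_pulsenet()` |
| `R/io.R` | NIfTI/YAML slice I/O, benchmark tables |
| `vignettes/` | methods vignette: models, parameters, design choices, limitations |
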