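# plvnet

Band-resolved EEG functional-connectivity analysis with phase-locking
values, for two-group / pre–post study designs such as resting-state EEG
of major depressive disorder (MDD) patients and healthy controls (HC)
around a musical-stimulation block.

## What it computes

For each subject, condition and frequency band (delta 0.5–4, theta 4–8,
alpha 8–13, beta 13–30 Hz):

* **PLV connectivity.** Instantaneous phase from the analytic signal
  *x + i H[x]*; for each channel pair the phase-locking value

  PLV = |⟨ e^{i(φₓ(t) − φᵧ(t))} ⟩ₜ| = √(⟨cos Δφ⟩² + ⟨sin Δφ⟩²),

  i.e. 1 for perfectly synchronized channels, 0 for no phase consistency.
* **Brain graphs.** The 19-channel PLV matrix binarized at 80 % of its
  maximum off-diagonal entry; mean clustering coefficient
  CC = (1/n) Σᵢ 2tᵢ/(kᵢ(kᵢ−1)), characteristic path length
  CPL = (1/n) Σᵢ Σ_{j≠i} d_{ij}/(n−1), and node degrees.
* **Statistics.** Two-sided permutation tests (Welch t statistic;
  sign-flips for paired pre/post, label permutations for MDD/HC).
* **Classification.** Stratified 10-fold cross-validation of SVM (RBF),
  decision tree, KNN and random forest on network features
  (default: delta mean CC, delta CPL, beta CPL), reported as accuracy /
  precision / recall with MDD as the positive class.

Because clinical recordings of this kind are typically not shareable, the
package ships a synthetic cohort generator (`generate_cohort()`) with
controlled band-specific phase coupling whose group/condition effect
*directions* mirror the reported phenomenology; every pipeline stage is
testable against it. See `vignettes/plvnet-methods.Rmd` for the model.

## Worked example

```r
library(plvnet)

cfg <- simulation_config(n_per_group = 8,
                         segment_layout = c(pre = 60, post = 60),
                         seed = 101)
cohort <- generate_cohort(cfg)                 # 32 labeled recordings
mats <- cohort_connectivity(cohort)            # 128 PLV matrices
tab <- metrics_table(mats)                     # binarize + graph metrics

cmp <- compare_cohort(tab$metrics, n_permutations = 999, seed = 7)
subset(cmp, band %in% c("delta", "beta") & contrast == "MDD_vs_HC" &
            within == "pre")
#>     contrast within  band  metric statistic p_value ...
#> 1  MDD_vs_HC    pre delta mean_cc     11.81   0.001
#> 5  MDD_vs_HC    pre delta     cpl     12.82   0.001
#> 25 MDD_vs_HC    pre  beta mean_cc     -1.96   0.080
#> 29 MDD_vs_HC    pre  beta     cpl     -4.40   0.001

feats <- extract_features(tab$metrics, standardize = FALSE)
crossval_classify(feats$x, feats$y, k = 10, seed = 55)
#> <classifier_report: 10-fold CV, positive = MDD>
#>   KNN  accuracy 1.0000  precision 1.0000  recall 1.0000
#>   SVM  accuracy 1.0000  precision 1.0000  recall 1.0000
#>   DT   accuracy 1.0000  precision 1.0000  recall 1.0000
#>   RF   accuracy 1.0000  precision 1.0000  recall 1.0000
```

Reading: in the delta band the synthetic MDD group sits above HC in both
mean clustering coefficient and characteristic path length (p = 0.001),
while its beta-band path length sits below HC — the built-in effect
directions — and the network features separate the groups perfectly at
this (deliberately strong) preset. Real cohorts are noisier; the accuracy
here validates the pipeline, not a clinical claim.

The same run end-to-end, with on-disk artifacts and a checksummed
manifest:

```r
run_pipeline(pipeline_config(synth = list(n_per_group = 8), seed = 101),
             "out/")
```

or from the shell (subcommands `run`, `simulate`, `preprocess`,
`connect`, `metrics`, `classify`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "plvnet.R", package = "plvnet"))')" \
    run --config config.yaml --out out/ --seed 101
```

Existing data can be supplied as EDF or delimited-text files with a JSON
manifest (`read_cohort()`), rather than simulated.

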