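---
title: "Methods: phase-locking-value brain networks in plvnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-locking-value brain networks in plvnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`plvnet` implements a band-resolved EEG functional-connectivity analysis
for a two-group (major depressive disorder vs healthy control),
two-condition (resting state before and after a musical-stimulation block)
design. The chain is:

1. **Preprocessing** — retain the 19 scalp channels of the 10–20 montage
   (`Fp1 … O2`), re-reference to the common average, band-limit with a
   zero-phase FIR filter (0.1–30 Hz), cut the session into its
   pre / music / post segments, and decompose each segment into the four
   canonical bands: delta (0.5–4 Hz), theta (4–8 Hz), alpha (8–13 Hz),
   beta (13–30 Hz).
2. **Connectivity** — per channel, the instantaneous phase is the angle of
   the analytic signal $x + i\,\mathcal{H}[x]$. For a channel pair the
   phase-locking value is the mean resultant length of the phase
   difference,
   $\mathrm{PLV} = \bigl|\langle e^{i(\phi_x(t)-\phi_y(t))}\rangle_t\bigr|
   = \sqrt{\langle\cos\Delta\phi\rangle^2+\langle\sin\Delta\phi\rangle^2}$,
   which is 1 under a constant phase relation and 0 when the phase
   difference has no preferred direction. The full matrix has a unit
   diagonal by definition.
3. **Network metrics** — the PLV matrix is binarized at 80 % of its
   maximum *off-diagonal* entry (strictly greater than the cut). On the
   binary graph: per-node clustering coefficient
   $CC_i = 2t_i/(k_i(k_i-1))$ averaged over all $n$ nodes,
   characteristic path length
   $CPL = \tfrac1n\sum_i \sum_{j\ne i} d_{ij}/(n-1)$ with breadth-first
   hop distances, and node degrees $k_i$.
4. **Statistics** — two-sided permutation tests with Welch's $t$ as the
   statistic: label permutations for MDD vs HC, sign flips of within-pair
   differences for pre vs post. Small problems are enumerated exactly.
5. **Classification** — per-subject features at the pre-stimulus resting
   state (default: delta mean CC, delta CPL, beta CPL), stratified
   10-fold cross-validation of SVM (RBF), decision tree, KNN and random
   forest, with standardization fitted inside training folds only and
   out-of-fold predictions pooled into accuracy / precision / recall
   (positive class MDD).

## Numerical choices

* **Filter realization.** Hamming-windowed sinc FIR, applied
  forward–backward (exact zero phase). The transition width is 25 % of
  the lower band edge with a 1 Hz floor; the floor keeps the filter
  length practical for the 0.1 Hz and 0.5 Hz edges. Hamming gives about
  −53 dB stop-band attenuation per pass, doubled by the two passes. The
  forward–backward pass leaves a boundary transient (odd-reflection
  padding cannot remove it for a signal cut mid-cycle), which is why
  **the first and last second of every segment is flagged invalid** and
  excluded from all phase statistics.
* **Thresholding.** The diagonal is excluded from the maximum used for
  the 80 % cut — the self-PLV is identically 1, and including it would fix
  the cut at 0.8 regardless of the data. The fixed-cut reading is
  available via `binarize(..., diagonal = "include")`. Ties at the cut
  are excluded (strict inequality).
* **Disconnected graphs.** CPL averages per node over *reachable*
  partners; isolated nodes contribute 0 (with a warning) and an edgeless
  graph has CPL `NA`. Consequence: on sparse thresholded graphs the
  cohort CPL can fall below 1 — it mixes path length with the fraction of
  connected nodes. This is the stated convention of the metric contract;
  interpret cohort CPL differences accordingly.
* **Degenerate features.** Constant feature columns are dropped with a
  classed warning; undefined CPL cells abort feature extraction with an
  error naming the cells.
* **Determinism.** One master seed is fanned out through a hash-based
  seed derivation (`derive_seed`) into per-subject, per-track, per-stage
  child streams, so partial reruns and full reruns produce identical
  bytes. Artifact files are written with 17 significant digits, making
  write/read round trips lossless.

## The synthetic cohort generator

The study's recordings are not public, so the generator stands in for
them. It is a *stated world*, not a fit to data: only the directions of
the reported effects are encoded, never magnitudes (the source reports no
connectivity magnitudes).

Per band $b$ a latent driver phase $\theta_b(t)$ wanders inside the band
(random centre frequency in the inner 76 % of the band plus a smooth
deviation, sd 12 % of bandwidth, ~1.2 Hz control rate, spline
interpolated — keeping ≥ 90 % of spectral power in band). Each channel
mixes the driver phasor with an independent narrowband phasor:

$$z_c(t) = \kappa\, e^{i(\theta_b(t)+\delta_c)} + (1-\kappa)\,
  e^{i\zeta_c(t)},$$

contributing $a_b \operatorname{Re}(z_c)$ to the channel. $\kappa = 1$
locks phases (PLV = 1 exactly), $\kappa = 0$ gives independent wandering
phases (finite-sample null PLV), and the expected PLV of a coupled pair
increases smoothly and strictly with $\kappa$ (the closure tests verify
the whole loop: generate → filter → Hilbert → PLV). The fixed per-channel
offsets $\delta_c$ leave PLV untouched but keep the driver out of the
channel average — without them the common average reference would
subtract the coupling it is meant to preserve, which is also why real
scalp EEG (with its varied source topographies) survives CAR.

Group and condition differences live entirely in the $\kappa$ map: each
band has a *core* community coupled at 0.85 and a *secondary* community
whose $\kappa$ varies by group and condition (e.g. delta secondary: MDD
pre 0.70 → post 0.55, HC 0.45; beta secondary: MDD pre 0.45 → post 0.55,
HC 0.70). Because the binarization cut tracks the core community's PLV,
the secondary community's edges appear or vanish with its $\kappa$,
yielding the reported directions: delta connectivity, clustering
coefficient and CPL higher in MDD than HC and decreasing after
stimulation; beta connectivity and CPL lower in MDD and increasing after
stimulation; alpha increasing after stimulation. Broadband white noise
(sd 1.4) puts the delta-band SNR near 10 dB; beta sits lower, as it does
in practice.

**What a green test does not establish:** the generator has no
volume-conduction mixing, no artifacts, no non-stationarity, no 1/f
background, and its effect magnitudes are conventions. The pipeline
analogue of the classification table (SVM ≥ 0.9 on the strong preset)
demonstrates that the *pipeline* recovers a built-in effect, not that the
clinical accuracy of 93.75 % is reproduced — that would require the
private cohort.

## Design points that were genuinely open

* **PLV vs "phase lag index" wording.** The source defines PLV in its
  methods but repeatedly says "phase lag index" in its results. The
  methods definition (Eqs. for the analytic signal and the resultant
  length) is implemented; PLI proper is out of scope.
* **Radical placement in the printed PLV formula.** Implemented as the
  mean resultant length (square root over the sum of squared averages),
  which bounds PLV in [0, 1] and makes the formula exactly the modulus of
  the complex-mean adjacency entry; both printed anchor cases (1 and 0)
  hold.
* **Garbled feature sentence.** The feature list reads as
  {delta mean CC, delta CPL, beta CPL} (three features); the two-feature
  reading is available via `features = c("delta_mean_cc", "beta_cpl")`.
* **CAR scope.** Applied over the 19 retained channels (the set actually
  analyzed); channel selection runs first.
* **Conditions analyzed.** Pre and post rest segments; the music segment
  is carried through segmentation but not analyzed.
* **Unnamed significance test.** Permutation tests (exact at these sample
  sizes) with Welch's *t*; no multiple-testing correction is added because
  the source applies none (noted, not silently corrected).
* **Classifier hyperparameters (unstated).** SVM: RBF, C = 1, gamma
  = 1/(d·var); KNN k = 3; tree: Gini, min leaf 1, unpruned; forest: 100
  trees, mtry = ⌊√d⌋. All exposed via `crossval_classify(params = )`.
* **Closure-test band.** Beta: the κ = 0 null level of narrowband PLV is
  bandwidth-limited (≈ $1/\sqrt{2\,\mathrm{bw}\,T}$ effective samples);
  60 s of delta cannot reach 0.05, beta comfortably does.

## Known limitations

Sub-hertz filter edges get a 1 Hz transition band, so the delta filter's
roll-off below 0.5 Hz is gentle. The EDF writer covers the 16-bit subset
the pipeline needs. CPL on disconnected graphs mixes density into the
metric (see above). The SMO solver targets desk-scale sample sizes (tens
of subjects), not large cohorts.
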