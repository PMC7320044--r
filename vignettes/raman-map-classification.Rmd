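---
title: "Classifying Raman hyperspectral tissue maps with PCA-LDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Raman hyperspectral tissue maps with PCA-LDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanmap)
```

## The problem

Raman microspectroscopic mapping records a full vibrational spectrum at every
pixel of a tissue section, so chemical differences between tissue types —
here benign oesophageal mucosa (normal squamous epithelium or Barrett's
oesophagus, BO) against oesophageal adenocarcinoma (OAC) — appear as
reproducible differences between per-pixel spectra. `ramanmap` implements the
complete chemometric chain used to turn such maps into a two-class tissue
classifier and a short list of discriminant marker bands, working on spectra
covering 725–1813 cm⁻¹ at 1 cm⁻¹ spacing (1089 channels).

The chain is, in order:

1. **Unfolding** the `rows × cols × m` cube into an `n × m` spectra matrix
   (one spectrum per row, pixels row-major).
2. **Savitzky–Golay smoothing** (21-point window, 2nd-order polynomial).
3. **AWLS baseline correction** — automatic weighted least squares, an
   iteratively reweighted Whittaker smoother that estimates and subtracts
   the fluorescence background of each spectrum.
4. **Kennard–Stone splitting** into 70% training / 30% validation sets.
5. **PCA** on the training spectra and **LDA with Mahalanobis distances**
   in the PC-score space; the PC count is chosen by **venetian-blinds
   cross-validation** with ten interleaved splits (or fixed by the user).
6. **Figures of merit** — accuracy, sensitivity, specificity — on the
   held-out validation spectra.
7. **Difference-between-mean (DBM) spectrum** and PCA loadings, from which
   marker bands are picked and annotated.
8. **Map images**: per-pixel PC scores and PCA reconstructions refolded onto
   the spatial grid.

## The model

Let $X \in \mathbb{R}^{n\times m}$ be the pre-processed training spectra.
PCA subtracts the training mean $\bar{x}$ and decomposes
$X_c = U\Sigma V^\top$; scores are $T = X_c V_K$ and the per-component
explained variance is $100\,\sigma_k^2 / \sum_j \sigma_j^2$. Validation
spectra are always projected with the *training* mean and loadings.

LDA models the two classes in score space with class means $\mu_1, \mu_2$
and a pooled within-class covariance
$S = \big(\sum_c \sum_{i\in c}(t_i-\mu_c)(t_i-\mu_c)^\top\big)/(n-2) +
\lambda_r I$ (ridge $\lambda_r = 10^{-8}$ for numerical safety). A spectrum
is assigned to the class with the smaller Mahalanobis squared distance
$D^2(t,\mu_c) = (t-\mu_c)^\top S^{-1}(t-\mu_c)$, with equal priors; the
reported discriminant function is $DF = D^2(t,\mu_2) - D^2(t,\mu_1)$, so
positive values mean the first (lexicographically smaller) class.
Equidistant points go to the smaller label — an explicit, documented
tie-break.

Validation metrics come from the confusion counts:
accuracy $= 100\,(TP+TN)/(TP+FP+TN+FN)$, sensitivity $= 100\,TP/(TP+FN)$,
specificity $= 100\,TN/(TN+FP)$. A metric whose denominator is zero is
flagged as undefined rather than silently zeroed.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `sg_window` | 21 | points | Savitzky–Golay window; fixed by the protocol |
| `sg_polyorder` | 2 | — | Savitzky–Golay polynomial degree |
| `awls_lambda` | 1e5 | — | Whittaker smoothness penalty; larger = stiffer baseline |
| `awls_max_iter` / `awls_tol` | 50 / 1e-6 | — | reweighting stop rules |
| `train_fraction` | 0.70 | — | Kennard–Stone training share |
| `n_splits` | 10 | — | venetian-blinds folds |
| `max_pcs` | 15 | — | largest candidate PC count |
| `ridge` | 1e-8 | — | pooled-covariance regulariser |
| `n_peaks` / `min_separation` / `min_prominence_frac` | 7 / 8 cm⁻¹ / 0.05 | — | marker picking |

The AWLS weighting constant (1e-4 on points above the running baseline) and
`awls_lambda` are implementation choices: the method's literature fixes only
the automatic weighting rule, not the penalty. The defaults were chosen once
on the synthetic generator — λ = 1e5 keeps the baseline stiff enough not to
dip into bands of 10–20 cm⁻¹ width while following backgrounds that vary on
the 100 cm⁻¹ scale — and both are exposed in `preprocess_config()` together
with a per-spectrum convergence report.

## Design choices made where the protocol is open

* **PCA mean-centring** uses the training mean only; centring is standard
  chemometric practice even where a protocol does not state it.
* **Kennard–Stone distances** are Euclidean on full pre-processed spectra,
  pooled over both classes (not per class, not on PC scores).
* **Venetian-blind ordering** is the Kennard–Stone selection order of the
  training rows — deterministic and stable across runs.
* **PC-count parsimony rule**: the selected K is the smallest candidate
  within 0.5 percentage points of the maximum cross-validated accuracy.
  Reported explained variance is cumulative over the training set.
* **Marker picking** is an explicit, reproducible stand-in for the usual
  visual reading of DBM + loading plots: strict local maxima of |DBM| with
  topographic prominence ≥ 5% of max |DBM|, taken greedily in decreasing
  |DBM| subject to an 8 cm⁻¹ separation, truncated to 7 bands, and
  annotated with |loading| on PC1/PC2 and a static band-assignment table.
* **Equal LDA priors**, matching the symmetric two-class discriminant plots
  this analysis family produces; priors are not data-share weighted.
* **Validation hygiene**: validation rows take no part in PCA fitting, LDA
  fitting, PC-count selection or marker extraction, so permuting validation
  labels provably changes no training-side quantity (this is tested).
* **Interface**: the package is function-first — `pcalda()` for the model,
  `run_case()`/`write_case_report()` for the orchestrated analysis with a
  versioned JSON report — rather than a shell tool; the documented text
  formats (`read_map_long_csv()`, `read_spectra_wide_csv()`) are the
  interchange surface.

## The synthetic generator

Tissue Raman maps of this kind are rarely public, so the package ships a
seeded generator (`synthetic_scenario()`, `generate_map()`) whose noiseless
pixel spectra are exactly a polynomial background plus Gaussian/Lorentzian
bands, scaled per class, with two noise sources: i.i.d. additive Gaussian
noise per channel (`noise_sd`, default 0.02 intensity units against common
bands of height 0.3–0.9) and per-pixel jitter of the baseline coefficients
(`baseline_jitter_sd`, default 0.05), emulating pixel-to-pixel background
variation. Class regions are spatially contiguous (`half_split`, `blob`) or
interleaved (`checkerboard`).

`case_presets()` encodes three two-class scenarios mirroring the patient
cases this analysis family reports: a shared tissue-like fingerprint
(nucleic-acid, protein, phosphate, CH₂ and amide I bands) with the malignant
profile raised by +0.3 units at that case's marker bands — case 1 at 900,
967, 1296, 1445, 1456, 1665 cm⁻¹; cases 2–3 at 1003, 1066, 1130, 1295,
1445, 1462 and 1672/1675 cm⁻¹ — and, for cases 2–3, an overall intensity
scale (1.2 / 1.15) on the malignant class, emulating the brighter
adenocarcinoma tissue. One deliberate exception: in case 1 the 1456 cm⁻¹
CH₂-deoxyribose band is placed on the *benign* profile, i.e. reduced in the
malignant class, consistent with the reduction of DNA-backbone signal in
cancerous tissue. This also reflects a mathematical fact of the fixed
pre-processing: after a 21-point Savitzky–Golay smooth, two same-signed
bands 11 cm⁻¹ apart merge into a single DBM maximum for *any* band width
(the smoothed midpoint always exceeds the band centres), whereas the
opposite-signed pair keeps two resolvable |DBM| extrema at 1444/1457 cm⁻¹.

What the generator does *not* emulate: cosmic-ray spikes, detector
etaloning, paraffin residuals, shot (Poisson) noise, instrument response,
or spatial correlation of the noise. Passing tests on this generator
therefore demonstrate the correctness and internal consistency of the
chain, not clinical performance on real tissue; the preset effect sizes are
stand-ins, not calibrated to any study.

## Numerical choices and degenerate inputs

* Apex detection for wavenumber calibration (silicon line at 520.4 cm⁻¹)
  uses 3-point parabolic interpolation around the discrete maximum and
  refuses spectra whose dominant peak is below 3× the median intensity;
  calibration is shift-only (no dispersion correction) and idempotent.
* The AWLS weight iteration starts from all-ones weights; "converged" means
  the weight pattern stopped changing (mean |Δw| < 1e-6). Non-convergence
  returns the last iterate and is flagged in the convergence report, not an
  error.
* A zero-variance matrix makes explained variance undefined and is an error
  in `pca_fit()`; a singular pooled covariance (after ridge) is an error in
  `lda_fit()`; a flat DBM yields an empty marker table with a warning.
* Ties: Kennard–Stone breaks distance ties by the lowest row index; marker
  candidates of equal |DBM| by the lower wavenumber; LDA-equidistant points
  by the smaller class label.

## Worked example

```{r example, eval = FALSE}
res <- run_case(case_config("case3", n_pcs = 2, seed = 1))
res
#> Raman map case analysis
#>   classes: BO vs OAC (positive: OAC)
#>   split: 280 training / 120 validation
#>   PCs: 2 (97.15% cumulative explained variance)
#>   validation accuracy 100.00%, sensitivity 100.00%, specificity 100.00%
#>   markers: 7 bands (1003, 1066, 1130, 1295, 1445, 1462, 1675 cm^-1)
plot(res)
```

On the default 20 × 20-pixel case-3 preset (400 spectra, 280/120 split) the
two tissue classes separate perfectly in validation, and the marker stage
returns exactly the seven bands the preset differs at.

## Problem sizes

The shipped tests run the full chain on 20 × 20-pixel maps for the headline
case analysis and 12 × 12-pixel maps (144 spectra) for the 20-seed
parameter-recovery sweeps; these sizes were chosen as the smallest maps on
which the spatial masks, the 70/30 split and the ten-fold cross-validation
all remain non-degenerate, and they keep the whole suite to a few minutes.
Larger maps change runtimes, not conclusions: the generator and every stage
are O(n) in the pixel count apart from Kennard–Stone's O(n²) distance
matrix.

## Known limitations

* Two classes only; no multi-class LDA, PLS-DA or probabilistic calibration.
* Shift-only wavenumber calibration.
* The marker-picking rule is one defensible formalisation of "most
  important discriminant features"; other rules (loading-weighted, signed
  selection) would pick slightly different tables on weakly structured DBM
  spectra.
* Kennard–Stone builds a full n × n distance matrix; maps beyond ~10⁴
  pixels should be split or subsampled first.
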