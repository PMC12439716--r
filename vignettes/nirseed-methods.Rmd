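---
title: "Models and methods behind nirseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirseed)
```

`nirseed` is a self-contained chemometric pipeline for FT-NIR seed-quality
calibration in oilseed *Brassica*: it simulates near-infrared spectra of
seed lots with known trait composition, screens contaminated samples,
builds partial least squares (PLS) calibrations per trait, and computes
the evaluation, multivariate, and genetic-variability statistics used in
seed phenotyping work. This vignette records the models, the tunable
parameters, and the design decisions — including the places where the
design space was genuinely open and a choice had to be made.

## The simulated panel

The synthetic panel plays the role of a diverse germplasm collection of
about one hundred seed lots, each described by eleven laboratory traits:
oil (%), protein (%), total glucosinolates (µmol/g defatted meal), phytic
acid (%), and seven fatty acids (% of oil: palmitic, stearic, oleic,
linoleic, linolenic, eicosenoic, erucic). Per-trait means, SDs and ranges
(`default_trait_params()`) describe a panel mixing canola-quality and
traditional high-erucic material, which is why the erucic range runs from
0.2 to 49.7 %.

### Reference values: moment-matched truncated normals under a Gaussian copula

Trait values must respect hard physical bounds, reproduce the target
mean/SD, and carry cross-trait correlations. `generate_reference()`
draws a latent multivariate normal and pushes each margin through a
truncated-normal quantile transform:

* The underlying location/scale of each margin is solved numerically so
  that the *truncated* distribution has the target mean exactly and the
  target SD as closely as the family allows. For right-skewed traits
  (erucic above all) no truncated normal on the stated interval attains
  the full target SD — a mean pinned near the lower bound combined with a
  wide SD requires a heavier-than-Gaussian tail. In the real panel that
  trait is bimodal (low- vs. high-erucic lines); here its SD tops out
  near 8 against a nominal 16.7. Means are always exact.
* Requested pairwise correlations are *realized* correlations: the latent
  correlation for each pair is calibrated (via a Hermite expansion of the
  margin transforms, solved by root finding) so the Pearson correlation
  of the generated values matches the request. Without this step the
  strong oleic–erucic correlation of −0.8 would attenuate to about
  −0.78.
* An earlier implementation used rejection with conditional resampling of
  out-of-bounds coordinates; it attenuated the oleic–erucic correlation
  to roughly −0.3 and was replaced by the copula construction, which is
  also deterministic and loop-free.

Default correlations impose only relationships with a clear biochemical
basis: oleic–erucic −0.8 (the erucic elongation pathway consumes oleic
acid), oil–palmitic −0.4 and oil–phytic −0.3. The magnitudes are
synthetic defaults, not measured values.

### Spectra: a Beer–Lambert mixture with scatter, water and a seed matrix

`generate_spectra()` builds absorbance on a uniform 4,000–12,000 cm⁻¹
grid (8 cm⁻¹ spacing, 1,001 points) as

$$A_i(\nu) = a_i\Big[\textstyle\sum_t c_{it}\, g_t(\nu) + w_i\, g_w(\nu) + B(\nu)\Big]
  + b_i + s_i(\nu - \bar\nu) + \varepsilon_{i\nu},$$

where each trait's signature $g_t$ is a sum of Gaussian bands, $w_i$ is a
per-sample water level, $B$ is a constant seed-matrix background,
$a_i, b_i, s_i$ are per-sample gain, offset and baseline tilt, and
$\varepsilon$ is white instrument noise. Noiseless, scatter-free spectra
are therefore an exact linear map of the reference table.

Band positions follow standard NIR assignments: C–H first overtones
(5,700–5,800 cm⁻¹), C–H/O–H combination bands (4,300–4,400 cm⁻¹) and C–H
second overtones (8,200–8,300 cm⁻¹) for the lipid traits; N–H and C=O
combination bands (6,500–6,600, 4,800–4,900 cm⁻¹) for protein and
glucosinolates; P–OH/O–H structure (5,750, 6,300, and a broad
5,000–7,600 cm⁻¹ combination) for phytic acid; and O–H water bands at
9,500/7,500/5,500 cm⁻¹.

Two additions were necessary to make the panel *calibratable at all*,
and both mirror real spectroscopy:

* **Lipid marker bands.** The shared C–H regions carry the total lipid
  signal, so oil and the seven fatty acids would be spectrally collinear
  (the minimum-norm recovery functional for oil has essentially infinite
  noise amplification). Each lipid trait therefore also carries the
  narrow band that distinguishes it in real spectra: the triglyceride
  ester C=O second overtone near 5,260 cm⁻¹ for total oil, cis =C–H
  first overtones at 6,010/6,090/6,170 cm⁻¹ for the unsaturated acids
  (shifting with double-bond count), and chain-length CH₂ combination
  bands at 4,145–4,292 cm⁻¹ for the saturated and very-long-chain acids.
* **A stable seed-matrix background.** SNV (below) rescales every
  spectrum by its own SD. If the spectrum is dominated by varying
  composition, that denominator is itself composition-dependent and the
  normalized data become strongly non-linear in the concentrations — oil
  recovery capped near R² = 0.33 even without noise. Real seed spectra
  sit on a large, nearly constant carbohydrate/fibre absorbance; the
  generator includes such a background, which anchors the normalization
  and restores near-linearity.

Scatter and noise defaults are instrument-realistic for a benchtop
FT-NIR: multiplicative gain SD 0.05, additive offset SD 0.02 AU,
baseline tilt SD 2 × 10⁻⁶ AU/cm⁻¹, and white noise SD 3 × 10⁻³ AU. With
the mean-centered spectral signal's RMS near 0.3 AU this corresponds to
a spectral signal-to-noise ratio of about 100.

### Contaminant samples

A fifth of the default panel is unusable, mimicking lots rejected for
high moisture or physical impurities. Moisture outliers gain the three
broad O–H bands scaled by `moisture_boost` (default 0.3 AU at the
strongest band, jittered ±30 % per sample). Impurity outliers gain a
shared carbohydrate-like signature (chaff/dust bands near 4,400, 5,800
and 6,900 cm⁻¹) plus an individual broad random bump. The shared
signature matters: seed-lot impurities have common chemistry, and a
purely sample-specific distortion would have no common spectral
direction for a low-rank screen to find.

## Preprocessing

Three pretreatments are implemented, each per spectrum:

* **SNV** — center and scale to unit SD (n−1 denominator); removes
  multiplicative and additive scatter exactly. A constant spectrum is an
  error, not silent zeros.
* **Detrending** — subtract a least-squares polynomial in wavenumber
  (default order 2), removing smooth baseline curvature.
* **Norris gap-segment derivative** — a centered moving average of
  `window` points (default 5) followed by a finite difference across a
  gap of `gap` points (default 3): first order
  $(m_{i+g}-m_{i-g})/(2g\,\Delta\nu)$, second order
  $(m_{i+g}-2m_i+m_{i-g})/(g\,\Delta\nu)^2$. The "window" is read as the
  smoothing-segment length in points and the "interval" as the gap size
  in points — the TQ-style segment/gap convention. Edge points with an
  incomplete stencil are dropped, so a derivative shortens the grid by
  `(window − 1) + 2·gap` points; no extrapolation is attempted.

**Ordering.** Defaults apply SNV *before* the derivative. The reverse
order — differentiate, then SNV — rescales each spectrum by the SD of
its derivative, which at realistic noise levels is dominated by
high-frequency noise; the per-sample signal scale is destroyed and oil
calibration collapses (validation R² below zero in our measurements).
Differentiating after scatter correction is purely linear and keeps the
mixture structure intact. Both orders remain expressible in the step
list.

**Per-trait defaults** (`default_preprocess()`): oil uses detrending
followed by SNV on the raw spectra; protein, glucosinolate and phytic
acid use SNV followed by a first derivative; the seven fatty acids use
SNV followed by a second derivative. Per-trait wavenumber sub-ranges
were evaluated and rejected as defaults: excluding the water-dominated
high-wavenumber region removes the very channels the model needs to
correct per-sample water variation, and destabilized validation badly.

## PLS calibration

`fit_pls()` implements single-response NIPALS PLS. X and y are centered,
never autoscaled (standard for absorbance data). Each component is
closed-form for one response — weight $w \propto X^\top y$, scores
$t = Xw$, loadings $p = X^\top t/t^\top t$, $q = y^\top t/t^\top t$,
deflation of X and y — so no inner iteration or convergence tolerance is
involved. The regression vector is $b = W(P^\top W)^{-1}q$; coefficients
for all nested sub-models are stored so cross-validation costs one fit
per fold. A zero-norm weight (y orthogonal to the deflated X) aborts
with the component index. `fit_pcr()` offers principal component
regression under the same contract, with SVD scores replacing NIPALS
scores.

The number of latent variables is chosen by seeded cross-validation
(`select_components()`): SECV(k) is the root-mean-squared
cross-validated residual and the smallest k attaining the minimum wins.
Leave-one-out is the default, following long-standing NIR practice;
`max_k` defaults to 12 because the default panel's latent dimension is
about 13 (eleven traits, water, and scatter residuals) and the CV guard
makes an over-generous ceiling harmless. Calibration/validation is a
seeded random 80/20 split; published seed-phenotyping calibrations use
per-trait splits anywhere from 4:1 to 8:1 without a stated selection
rule, so the fraction is configuration, not a constant.

## Outlier screening

Screening runs in the two stages used by commercial calibration
software, on SNV-treated spectra:

1. **Spectral screen.** PCA scores (default 5 components) are converted
   to the Mahalanobis H statistic
   $H_i = (t_i-\bar t)^\top S^{-1}(t_i-\bar t)$ with the
   n−1-denominator score covariance, so $\sum_i H_i = k(n-1)$. Samples
   with H ≥ 6 are rejected; retention is H < 6. H is computed in
   latent-score space because the raw-wavenumber covariance is singular
   (p ≫ n). Whether the conventional "H < 6" bound refers to the squared
   statistic, and with what normalization, is not standardized; the
   convention above is fixed and the threshold is configurable. Five
   components were chosen to span the contaminant subspace (the moisture
   direction with its amplitude spread, the impurity signature, and bump
   variability) while keeping the clean-sample H distribution — deflated
   by the contaminated covariance — well below the bound; many more
   components let genuine trait variation inflate clean H values toward
   the threshold.
2. **Chemical screen.** A preliminary PLS fit on the spectrally retained
   samples yields y-residuals; samples with |r| > 3·SD(r) are rejected
   (calibration residuals are mean-zero by construction, so the raw
   residual is compared to the spread).

On the default panel this two-stage screen recovers 18–20 of the 20
injected contaminants with at most 5 false flags (seeds 1–5), and the
end-to-end run retains close to 80 of 100 samples.

## Evaluation statistics

With $e = \hat y - y$: R² (one minus the residual sum of squares over
the total sum about the reference mean), RMSEC/RMSEP (root mean squared
error on the calibration/validation set), MAE, Bias (mean error), and
SEE — the bias-corrected error SD, $\sqrt{\frac{n}{n-1}(RMSEP^2 -
Bias^2)}$, identical to the n−1 SD of the errors and linked by
$RMSEP^2 = Bias^2 + \frac{n-1}{n}SEE^2$. SEC and SEP are SEE computed
on calibration and validation residuals; SECV comes from the component
search. RPD is the reference-subset SD over the corresponding standard
error; the package reports it on the validation set (`rpd_val`), on the
calibration set (`rpd_cal`), and from cross-validation (`rpd_cv`),
because the field uses both SD/SEP and SD/SECV definitions. The SD in
RPD is the SD of the evaluation subset in question, not the full panel.
The conventional reading — RPD below 2 unreliable, 2–3 usable for
screening, above 3 quantitative — is exposed as `rpd_grade()`.

## Multivariate and variability statistics

`pca()` computes components by SVD (equivalently, eigen-decomposition of
the covariance), with a deterministic sign convention (largest-magnitude
loading element positive). Spectral PCA is run on preprocessed spectra by
default. Trait-level PCA on the default panel puts the oleic–erucic pair
at the top of PC1 — the two loadings are symmetric up to sampling noise,
so which of the two leads is a coin flip, and only the pair-level
statement is stable.

`rcbd_anova()` is the closed-form balanced two-way decomposition
(genotype on g−1 df, block on r−1 df, error on (g−1)(r−1) df), checked in
the tests against `aov()`; the closed form is used directly because the
decomposition feeds the variance-component estimators and runs thousands
of times in Monte-Carlo checks. `gcv_pcv()` uses the standard estimators
$\hat\sigma^2_g = \max(0, (MS_g - MS_e)/r)$ (negative estimates
truncated to zero) and per-plot phenotypic variance
$\hat\sigma^2_p = \hat\sigma^2_g + MS_e$; the alternative that adds
$MS_e/r$ exists, and the per-plot form was chosen and documented because
it keeps GCV ≤ PCV with a ratio interpretable as the genotypic share of
per-plot variation. When an RCBD layout is derived from the reference
table (`rcbd_from_reference()`), block effects default to 10 % and plot
errors to 20 % of each trait's SD — typical laboratory repeatability,
which is why GCV/PCV ratios near 0.98 dominate the default report.

## Problem sizes and determinism

Default study sizes — 100 samples, 1,001 wavenumbers, leave-one-out CV
over at most 12 components, 500-replicate GCV recovery and
2,000-replicate F-test size checks — run the full test suite in well
under a minute on a laptop-class core. Every stage draws its randomness
from named sub-seeds of one master seed, so a configuration reruns to
bit-identical CSV output, and changing one stage's settings does not
perturb another stage's draws.

## Known limitations

* Truncated-normal margins cannot reproduce the SD of strongly skewed
  traits (erucic, linolenic, eicosenoic); means are exact, SDs are
  attenuated, and downstream variability statistics for those traits
  reflect the attenuated spread.
* Fatty acids enter the mixture as their percentage values, not as
  absolute masses (percentage of oil × oil); the linear-mixture contract
  keeps every stage testable, but it omits the mass-closure constraint
  of real seed spectra.
* The second-derivative treatments inherited from standard practice are
  noise-hungry; at the default SNR the fatty-acid calibrations are
  honest but mediocre (validation R² roughly 0.4–0.9 across traits),
  while oil, protein, glucosinolate and phytic acid calibrate well.
* Passing the simulation-based tests demonstrates that the pipeline
  recovers known structure under the generator's assumptions (Gaussian
  bands, linear mixing, white noise); it cannot certify performance on
  real instrument data, where band shapes, stray light and moisture
  interact non-linearly.

## A worked run

```{r, eval = FALSE}
res <- run_study(study_config(seed = 1), out_dir = "study-out")
res$reports$oil
res$variability
```

The bundle written to `out_dir` contains the simulated spectra,
reference and truth tables, the outlier report, per-trait calibration
reports, PCA scores/loadings/variance, the trait correlation matrix, the
variability report, and a JSON manifest with the full configuration and
seed.
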