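---
title: "Quantifying renal sodium: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying renal sodium: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephna)
```

## The problem

Sodium MRI (²³Na-MRI) produces a magnitude signal approximately
proportional to tissue sodium concentration. In the kidney the quantity of
interest is spatial: sodium rises from the cortex (outer parenchyma,
roughly 50–70 mmol/L) to the medulla (core, roughly 90–140 mmol/L), and
the steepness of that corticomedullary gradient reflects concentrating
ability. Loop diuretics such as furosemide block medullary sodium
reabsorption and flatten the gradient within tens of minutes, well before
serum electrolytes move.

`nephna` implements the full quantification chain — phantom-based
signal-to-concentration calibration, concentric-layer segmentation,
depth-resolved profiles, gradient slopes, inversion-recovery T1 mapping,
and the nonparametric statistics used for multi-site reproducibility and
dynamic studies — together with a seeded synthetic-data generator so every
stage is testable without scanner data.

## Signal model and calibration

The generator simulates the magnitude signal as

$$ S(\mathbf{x}) \;=\; k \, C(\mathbf{x}) \, f(T_1^{\mathrm{comp}}) \,
   B_1(\mathbf{x}) \;+\; \text{Rician noise}, $$

where $C$ is the truth concentration (mmol/L), $k$ the true calibration
slope (signal units per mmol/L), $B_1$ a smooth multiplicative transmit
field, and $f$ the spoiled steady-state saturation factor of the voxel's
compartment,

$$ f(T_1) = \frac{(1 - E)\,\sin\alpha}{1 - E\cos\alpha},
   \qquad E = e^{-TR/T_1} . $$

Quantification inverts this chain: phantom ROI mean signals (divided by
the transmit field) are regressed on the known phantom concentrations by
OLS — the intercept is fitted by default to absorb the Rician noise floor,
with a zero-intercept option — and the map is

$$ \hat C = \frac{S - b}{\,a \, B_1 \, (f_\mathrm{tissue}/f_\mathrm{phantom})\,}. $$

The saturation correction is a single per-compartment scalar ratio, not a
voxelwise map: the tissue/phantom T1 difference (defaults 26 vs 22 ms) is
a bulk effect of a few percent. Negative calibrated values are clipped to
zero and counted. No receive-B1 correction is applied anywhere; this is a
deliberate, documented bias source of the method being modelled.

Defaults `tr = 30` ms and `flip_deg = 45` give a tissue-vs-phantom
saturation signal difference of about 3%:

```{r}
saturation_bias(26, 22, tr = 30, flip = 45)
```

The acquisition's actual TR and flip angle were not available when these
defaults were chosen; they were picked once to make the bulk saturation
effect realistically small (a few percent) and are explicit arguments
everywhere they matter.

## Synthetic anatomy and the truth profile

Kidneys are nested ellipsoids: the outer surface is the whole kidney, the
inner ellipsoid the medullary core, and the shell between them the cortex.
This is the simplest geometry that supports concentric layers and a depth
axis in mm. Calibration phantom spheres (defaults 50, 100, 154 mmol/L —
the highest is the saline reference standard) sit in the field of view
away from the kidney.

With `profile_kind = "linear"` (the default, matching the observed
linearity of layer profiles) the truth concentration inside the kidney is
affine in boundary distance $d$:

$$ C(d) = a + b\,d, \qquad
   b = \frac{C_\mathrm{med} - C_\mathrm{cort}}{\bar d_\mathrm{med} - \bar d_\mathrm{cort}}, $$

anchored so that the *cortex-mask mean* equals `cortex_conc` and (with the
default span) the *medulla-mask mean* equals `medulla_conc` exactly. Two
consequences are worth stating plainly:

* Regional ROI means are exact by construction, which is what the
  reproducibility targets check.
* The extreme layers overshoot the compartment values: the profile passes
  through 72 and 136 mmol/L at the compartments' *mean* depths, so the
  outermost layer sits below 72 and the innermost above 136. A real
  kidney plateaus in the inner medulla; the synthetic core is steeper.
  Tests therefore check the profile *at the compartment mean depths*, not
  at the layer extremes.

The porcine default geometry (`porcine_subject_config()`) is a documented
calibration of the generator, not a measurement: its semi-axes
(50 × 31.7 × 31.7 mm, medullary scale 0.48) were scaled once so that the
cortex-to-medulla mean-depth separation is ≈ 14.1 mm, which turns the
53 → 92 mmol/L porcine profile into a slope of ≈ 2.76 mmol/L/mm. The
price of the nested-ellipsoid simplification is a thicker minor axis than
a real pig kidney. The human default uses a 0.33 medullary volume
fraction, which makes the whole-kidney mean the 0.33/0.67 mixture of the
compartment means (≈ 93 mmol/L for 136/72).

```{r}
cfg <- porcine_subject_config()
compartment_depth_span(cfg)
```

Inter-subject variability multiplies each subject's regional
concentrations by independent $1 + \mathrm{CoV}\cdot z$ draws (default
CoV 5%) and deliberately leaves geometry fixed: the quantity under test is
concentration recovery, and shared geometry lets layer profiles be
averaged across subjects without registration.

## Noise and transmit field

Noise is Rician: the magnitude of the clean signal plus a complex Gaussian
of scale `noise_sigma` (default 3 signal units, giving cortical SNR ≈ 15
at unit calibration slope). At zero signal the magnitude is Rayleigh with
mean $\sigma\sqrt{\pi/2}$; at SNR > 10 it is approximately Gaussian with
SD ≈ σ — both are tested. The transmit field is a low-order random
polynomial scaled to a ±10% deviation by default, shared across the time
points of a dynamic series (coil loading does not change between scans of
the same animal).

## Onion layers

`onion_layers()` computes the exact Euclidean distance (anisotropic voxel
spacing respected, compiled transform with a brute-force oracle in the
tests) from each in-mask voxel centre to the nearest background voxel, and
cuts the distances into `n_layers` equal-width bins. The bins span the
*occupied* depth range: voxel-centre depths can never be smaller than one
voxel spacing, so bins anchored at zero would leave the outermost bin
structurally empty at clinical voxel sizes. Bins are half-open with the
deepest voxel assigned to the innermost layer; any empty layer is an
error naming the first empty one. An equal-count (`"quantile"`) binning is
available; it splits depth ties deterministically so every layer is
populated. Layer depth for downstream fitting is the per-layer *mean*
distance in mm, not the bin midpoint — robust to irregular shapes. Default
layer counts are 7 (porcine) and 12 (human), reflecting renal size.

## Gradient and dynamics

`fit_gradient()` is an unweighted OLS of layer mean concentration on layer
mean depth (a voxel-count-weighted option exists). The slope is signed;
positive means concentration rises towards the medulla. $R^2$ of a
zero-variance profile is defined as 0, not NaN, so dynamic tables stay
total.

The washout model is exponential:
$m(t) = m_0 - (m_0 - m_\infty)(1 - e^{-t/\tau})$ with defaults
92 → 69 mmol/L and $\tau = 10$ min, so that $m(30) \approx 70$ and the
gradient is still changing at intermediate time points. The cortex drifts
linearly (+2 mmol/L per 30 min — the direction of the small,
non-significant cortical rise in the study being emulated). On top of the
deterministic curves, every scan's regional concentrations fluctuate by
`scan_cv` (default 7%, within the repeatability range reported for
quantitative sodium imaging). This term matters statistically: without
it, any consistent drift — however small — has the same sign in every
animal and an exact signed-rank test will flag it. The defaults were
fixed from a power calculation: they give ≈99% detection of the medullary
fall, with small (< 10%) probabilities of spuriously flagging the cortex
or whole kidney, at six animals.

## Statistics

The paired Wilcoxon signed-rank and unpaired rank-sum tests are exact for
small samples by full enumeration over the midranks (all $2^n$ sign
assignments, respectively all $\binom{n}{n_A}$ group splits), so ties are
handled exactly; beyond the enumeration limit a tie-corrected normal
approximation is used, with zeros handled by Pratt's method in the
signed-rank case (zeros are dropped entirely in exact mode). All p-values
are two-sided. Kruskal–Wallis (tie-corrected, χ² reference), Bonferroni
adjustment with an explicit family size, CoV, and OLS with $R^2$ and a
slope t-test complete the toolbox.

Two policy decisions deserve daylight:

* **Intersite comparisons** default to the unpaired rank-sum test, since
  the two sites enrol different volunteers; a paired mode (subjects
  matched by index) is available but not claimed to be the original
  analysis, whose description names a paired test for unpaired groups.
* **Multiplicity.** The gradient time course is Bonferroni-corrected over
  the post-baseline family, as is each region's time course; the
  per-region baseline-vs-final comparison is treated as its own
  prespecified hypothesis and reported at its raw two-sided p. With six
  subjects the smallest attainable exact two-sided p is $2/2^6 = 0.03125$,
  so a Bonferroni×6-corrected comparison can *never* reach 0.05 at that
  sample size: the pipeline honestly reports no corrected-significant
  time point for six animals, and demonstrates the corrected test firing
  at larger simulated cohorts. This granularity bound is a property of
  exact tests at n = 6, not a software limitation.

Serum panels are simulated independently of the imaging streams (flat
baselines — sodium 139, potassium 4.0, chloride 103 mmol/L, physiologic
values; the source report prints the potassium and chloride labels
apparently transposed, which is noted rather than silently corrected —
with 1% multiplicative noise). The gradient-vs-serum correlation is
computed across animal × post-baseline-time observations rather than
across the handful of time means: with only six points the *null*
expectation of $R^2$ is ≈ 0.2, which would make even a perfectly
independent serum panel look correlated; per-observation pairing keeps the
null $R^2$ near $1/(n-1)$ with $n = 36$.

## T1 mapping

Inversion-recovery series use the magnitude model
$|S_0(1 - 2e^{-TI/T_1})|$ with no polarity restoration (the inputs are
magnitude images; a dense-TI polarity-restored variant is unnecessary for
the default 8-TI sampling, which brackets the null points of both
compartments). Per voxel, $S_0$ is profiled out analytically and $T_1$
found by a coarse log-grid plus bracketed 1-D minimisation — deterministic,
with no convergence failures; voxels pinned to the search boundary are
flagged NaN and counted. The closed-form null point $TI = T_1\ln 2$ is the
independent cross-check. Recovery between inversions is assumed complete
(TR ≫ TI), the standard IR simplification.

## Numerical and testing choices

Problem sizes were chosen so the whole suite exercises full-size study
conditions while staying quick: human subjects on 48³ grids at 2 mm
(≈ 5 000 kidney voxels), porcine on 72 × 56 × 56; unit tests use smaller
ellipsoids where only structure is at stake; the distance-transform oracle
runs on masks up to 15³; the Monte-Carlo level check of the exact rank-sum
uses 2 000 replicates at n = 6 per group; T1 recovery is checked on ~100
sampled voxels per compartment at SNR 20. Determinism is end-to-end: one
root seed feeds named substreams (anatomy draws, per-scan noise, per-scan
physiologic fluctuation, serum), so any module can be re-run independently
and fixed seeds give bit-identical reports.

## What passing tests do and do not show

The generator emulates: two-compartment concentration contrast with a
linear depth profile, phantom-based calibration with a true slope and
noise floor, bulk T1 saturation differences, smooth transmit-field bias,
Rician statistics, inter-subject and repeat-scan variability, exponential
medullary washout, and flat serum chemistry. It does *not* emulate:
k-space acquisition or ultrashort-echo trajectories, respiratory motion
or gating, receive-coil sensitivity profiles, partial-volume mixing at
compartment boundaries, anatomically realistic medullary pyramids, or
intracellular/extracellular compartmentation. Passing the suite therefore
demonstrates that the *analysis chain* is correct and unbiased under a
faithful statistical model of the data — not that any scanner's images
satisfy that model.
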