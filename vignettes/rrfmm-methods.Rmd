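---
title: "Reduced-rank FMM models for multichannel ERPs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-rank FMM models for multichannel ERPs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrfmm)
```

## The model

A trial-averaged multichannel ERP is a T×G matrix of voltages on a time
grid mapped to $[0, 2\pi)$. `rrfmm` models it as a linear mixture of K
latent oscillatory sources,

$$Y(t) = M + B\,H(\vartheta, t) + \varepsilon(t), \qquad
  \varepsilon(t) \sim N_G(0, \Sigma),$$

where source $d$ contributes the regressor pair
$(\cos\psi_d(t), \sin\psi_d(t))$ with the Möbius phase
$\psi_d(t) = 2\arctan[\omega_d \tan((t-\alpha_d)/2)]$. The phase is
strictly monotone — the generator traverses its trajectory without
reversals — and gives unimodal, possibly asymmetric waveforms:
$\alpha_d$ is the latency of the response, $\omega_d \in (0,1]$ its
sharpness ($\omega = 1$ is a pure sinusoid; small $\omega$ concentrates
the deflection near $\alpha$). All channels share each source's
$(\alpha_d, \omega_d)$; the G×2 block $B^{(d)}$ carries channel
amplitudes $A_{gd}$ and phase offsets $\delta_{gd}$ via
$B_{g,2d-1} = A_{gd}\cos\delta_{gd}$,
$B_{g,2d} = -A_{gd}\sin\delta_{gd}$.

The physical motivation is dipolar: a cortical generator is an
equivalent current dipole whose moment traces an ellipse
$d(t) = L_1\cos\phi(t)\,e_1 + L_2\sin\phi(t)\,e_2 + z e_3$ in a plane,
and in a homogeneous infinite medium each electrode records
$\langle d(t), R_g\rangle / (4\pi\sigma\|R_g\|^3)$, which collapses
exactly to $m_g + A_g\cos(\phi(t) + \eta_g)$. When the ellipse
degenerates to a line ($L_1 = 0$ — a dipole of fixed orientation and
varying magnitude) every channel's $\eta_g$ is exactly $\pm\pi/2$, and
the mixing block becomes rank one: all channels share a single temporal
waveform up to a signed channel scale. That equivalence is the core of
the package: **fixed orientation $\iff$ rank$\,B^{(d)} = 1$**, so the
orientation hypothesis is a testable model restriction rather than a
post-hoc interpretation.

### Identifiability conventions

Several conventions are fixed once so that parameters are unique and
fits are reproducible:

* $\omega \in (0,1]$: the map $(\alpha,\omega) \to (\alpha+\pi,1/\omega)$
  produces the same waveform family, so the half-open interval removes
  the duplication.
* $\alpha$ is reduced modulo $2\pi$; fitted phases are wrapped to
  $(-\pi, \pi]$ — the wrap choice is observationally irrelevant (it is
  absorbed by $\delta$) but must be fixed for determinism.
* $A \ge 0$ and $\delta \in (-\pi, \pi]$.
* The trajectory's initial phase $\beta$ is not separately identifiable
  from data: only $\delta_{gd} = \eta_{gd} + \beta_d$ enters the
  likelihood. $\beta$ exists only in the simulator, where ground truth
  is known.
* The rank-one factorisation $B^{(d)} = u v^\top$ has a sign ambiguity;
  `signed_amplitudes()` resolves it by making the largest-magnitude
  entry of $u$ positive.

## The forward simulator

`simulate_erp()` is the package's synthetic-data engine. It implements
the idealized biophysics exactly: elliptical (or degenerate-linear)
moment trajectories, projection through the inner-product/inverse-cube
lead field of a homogeneous, infinite, isotropic medium, superposition
across sources, Gaussian channel noise that is independent across time
points with an arbitrary covariance $\Sigma$ across channels, optional
per-trial latency jitter (Gaussian shifts of $\alpha_d$), and epoch
averaging. Units are abstract but consistent (lengths, conductivity,
dipole moment); with the default $\sigma = 1/(4\pi)$ the lead constant
is simply $1/\|R\|^3$. Note that while the lead *constant* decays with
the cube of distance, the dipole *potential* decays with its square,
because $\langle d, R\rangle$ grows linearly in $\|R\|$.

What the simulator deliberately does **not** emulate: realistic
volume-conductor head models (skull/scalp layers, BEM/FEM), temporally
correlated or non-Gaussian sensor noise, ocular/muscle artifacts, and
drifting baselines. Passing recovery tests on these simulations
therefore demonstrates correctness of the estimator under the model's
own assumptions, not robustness to every pathology of real EEG.

`random_dipole_sources()` draws the study conditions used throughout
the test-suite simulations: deep, centrally placed sources
(depth ≈ 0.18 under a unit-radius electrode hemisphere) whose fields
reach most of the montage, semiaxes of order one, sharp waves
($\omega \in [0.08, 0.35]$, typical of unimodal ERP deflections), and
latencies spread around the cycle so components are temporally
distinct. Deep central sources are the physiologically sensible choice
for a generator meant to produce broadly distributed scalp responses;
shallow eccentric sources would concentrate signal on a few electrodes
and leave the rest noise-dominated. Noise levels are specified as a
fraction of the noiseless peak deflection (`noise_sd_at_peak()`), the
natural SNR scale for evoked responses.

## Estimation

`fit_fmm()` maximises the Gaussian likelihood by alternating updates,
exploiting that the model is linear in $(M, B)$ given
$\vartheta = \{(\alpha_d, \omega_d)\}$:

1. **Phase update.** Per component, on the partial residual with all
   other components removed, the profile objective (the
   covariance-weighted residual sum of squares after plugging in the
   closed-form linear update, rank-constrained if the component is
   fixed) is optimised over $(\alpha, \omega)$.
2. **Linear update.** Because all channels share one temporal design,
   the generalised-least-squares estimate of $(M, B)$ coincides with
   per-channel ordinary least squares and does not involve $\Sigma$.
   $\Sigma$ matters only for the rank-one projection: the constrained
   block minimises
   $\mathrm{tr}[\Sigma^{-1}(B - \tilde B)\,G\,(B-\tilde B)^\top]$ with
   $G$ the component's (centred) regressor Gram matrix, solved exactly
   by whitening, SVD truncation to the leading triplet, and
   unwhitening.
3. **Covariance update.** $\Sigma$ is re-estimated from the residuals
   (divisor T), either per-channel variances (`"diagonal"`, default) or
   the full empirical covariance.

Components are initialised sequentially by backfitting: each new
component is fitted to the running residual by full grid search. Within
the outer loop, each step is an exact coordinate-wise maximisation of
the same likelihood — the phase refits always retain the current value
as a candidate, the joint linear update conditions on the current
fixed-orientation blocks, and the covariance update is the exact
M-step — so the log-likelihood trace is non-decreasing by construction
(monitored to a 1e-8 relative tolerance in the tests).

### Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `omega_grid` | 30 log-spaced points in $[0.01, 1]$ | sharpness acts multiplicatively; log spacing covers sharp and sinusoidal waves evenly |
| `alpha_grid` | the sample points, capped at 128 | latency candidates at the data's own resolution; the cap bounds the search at high sampling rates |
| `local_refine` | on | Nelder–Mead inside the bracketing grid cell (≤ 200 evaluations) removes the grid quantisation from final estimates |
| `max_outer_iters` | 20 | the alternating scheme typically converges in < 10 outer iterations |
| `tol` | 1e-6 | relative log-likelihood change declaring convergence |
| `sigma_structure` | `"diagonal"` | full covariance needs T comfortably above G; diagonal is the robust default for averaged ERPs |

### Numerical choices and degenerate inputs

* **Pole-safe phase.** $\psi$ is computed as
  $2\,\mathrm{atan2}(\omega\sin\frac{t-\alpha}{2}, \cos\frac{t-\alpha}{2})$,
  which is continuous through the tangent pole at $t = \alpha + \pi$
  and agrees with the naive composition elsewhere (checked to 1e-10).
* **$\Sigma$ floor.** Diagonal entries are floored at
  $10^{-8}\times\overline{\mathrm{diag}}$ of the initial empirical
  covariance, so near-perfect fits cannot drive the likelihood to a
  singularity. $\Sigma$ is initialised at the empirical covariance of
  the observed voltages, which keeps the first profile updates well
  conditioned.
* **Ties.** Exactly equal singular values in a block SVD are broken by
  taking the first triplet returned by R's deterministic SVD; the event
  is recorded in the fit's `notes`.
* **Component order.** Components are sorted by decreasing explained
  variation after fitting, so identical inputs give identical outputs.
* **Constant channels.** A zero-variance channel has no defined R² —
  it is reported as `NA` and excluded from quantiles and channel
  selection rather than coerced to 0. With `sigma_structure = "full"`
  a constant channel makes the covariance singular and is rejected with
  advice to drop it or use the diagonal structure.
* **Rank-deficient designs** (e.g. duplicated components) abort with
  the offending columns named.

## Model comparison

Formal likelihood-ratio testing is deliberately avoided: with dozens of
channels both variants have large likelihoods dominated by channel
noise, so the comparison rests on descriptive goodness of fit.
`compare_models()` fits Model A (all components free) and Model B (all
components fixed; per-component mixed modes are supported by
`fit_fmm()` but the canonical comparison constrains all of them) with
identical K and configuration, then summarises each fit by the 95th
percentile of its channel-wise R² distribution:

* quantiles interpolate order statistics at position $1 + q(n-1)$ (the
  common statistical-software default; a convention must be fixed for
  bit-reproducibility);
* `difR² = p95(A) − p95(B)`;
* channel selection for reporting uses the upper tail (R² at or above
  the quantile) **of the complete model's** distribution, so that
  noise-dominated channels do not drive the comparison.

The percentile-value reading of the summary is the default; a
tail-mean alternative (averaging R² over the selected channels) is
exposed via `tail_mean = TRUE` but not used by the canonical report.
On rank-one generators at high SNR both models fit essentially
perfectly and difR² ≈ 0; on strongly elliptical generators the
rank-one restriction discards a genuine second spatial pattern and
difR² > 0. Near-zero difR² on real data is therefore evidence that the
fixed-orientation idealisation is adequate for that recording.

`summarize_comparisons()` implements the study-level aggregation
arithmetic: per-recording difR² plus a `Total` row of column means. The
bundled `inst/extdata/participant_r2_summaries.csv` carries benchmark
per-participant summaries from a visual-ERP model-comparison study and
is used to exercise exactly that arithmetic.

## Problem sizes in the shipped studies

The simulation studies run by the test suite and `scripts/acceptance.R`
use G = 16 electrodes, T = 256 samples, D = K = 2 sources, 50
replicates for parameter recovery at noise SD 5% of the peak
deflection, and noise SD 1% for the orientation-consistency
comparisons; oracle checks of the low-rank solvers use 100 random
instances of size n ≤ 30, p, q ≤ 5 against brute-force numerical
minimisers. These sizes are representative of single-participant ERP
analyses while keeping the full suite fast.

## Known limitations

* K is user-chosen; there is no automatic component-number selection,
  and no standard errors or confidence intervals are produced.
* The forward model is the idealized homogeneous infinite medium;
  electrode positions enter only through it, and no head-model realism
  is attempted.
* difR² is a descriptive statistic for one recording; aggregating it
  across participants (the `Total` row) is a summary, not a
  population-level inference procedure.
* Estimation assumes the averaged ERP is stationary across trials up to
  the modelled latency jitter; strong trial-to-trial amplitude or shape
  variability violates the averaging rationale.
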