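---
title: "Quantifying biased agonism with transduction coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biased agonism with transduction coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incretinbias)
library(dplyr)
```

## The problem

Agonists of the glucagon-family receptors (GLP-1R, GIPR, GCGR) can engage
G-protein/cAMP signaling and β-arrestin recruitment to different degrees —
*biased agonism*. Because raw potency and efficacy depend on receptor
expression, amplification, and assay dynamics, bias must be quantified on a
scale that cancels system- and assay-specific factors. This package
implements the transduction-coefficient approach on top of a plate-reader
processing pipeline: kinetic trace normalization, AUC/half-time summaries,
logistic concentration–response fits, operational-model fits, and the
Δ/ΔΔlog(τ/K~A~) statistics, plus Mesna-cleavage internalization
quantification. A synthetic-data generator reproduces the statistical
structure of the assay designs so that every stage can be validated
end to end.

## The operational model and the bias statistic

The Black–Leff operational model links agonist concentration $A$ to mean
response:

$$E(A) = \mathrm{basal} + (E_m - \mathrm{basal})
  \frac{\tau^n A^n}{(A + K_A)^n + \tau^n A^n}$$

* $E_m$ — maximal response the *system* can produce (response units);
* $\tau$ — operational efficacy of the agonist (dimensionless);
* $K_A$ — functional affinity (molar);
* $n$ — transducer slope;
* the transduction coefficient $\tau/K_A$ summarizes pathway activation per
  unit of agonist.

`fit_operational()` fits this model to all ligands of one assay replicate
jointly, sharing ($E_m$, $n$, basal) across ligands and estimating
(log τ, log K~A~) per ligand. Bias is then computed in two normalization
steps, each within an assay replicate (block):

1. $\Delta\log(\tau/K_A)$ — subtract the reference endogenous agonist
   (cancels system scale and day effects);
2. $\Delta\Delta\log(\tau/K_A)$ — subtract the reference pathway (cAMP by
   convention; positive values mean bias toward cAMP).

Per-block ΔΔ values are summarized as mean ± t-based 95% confidence
interval across blocks (`bias_interval()`), bias is called significant when
the interval excludes zero, and the anti-log $10^{\Delta\Delta}$ is reported
as the bias factor.

```{r, eval = FALSE}
cr <- simulate_cr_study(bias_scenario_params(0.5), n_blocks = 5,
                        noise = noise_model(seed = 1L))
bias_analysis(cr, reference_ligand = "reference", reference_pathway = "cAMP")
```

## Identifiability: what is, and is not, estimable

For $n = 1$ the operational model is observationally equivalent to a
3-parameter logistic with observed maximum $E_m\tau/(1+\tau)$ and
$EC_{50} = K_A/(1+\tau)$. On noise-free data this creates an exact
zero-residual ridge: any $E_m$ at or above the observed maximum can be
compensated by adjusting $\tau$ and $K_A$. Along that ridge

$$\log(\tau/K_A) = \log\frac{E_{max,obs}}{EC_{50,obs}} - \log E_m,$$

so the *absolute* transduction coefficient is anchored only if $E_m$ is
known, while *differences* between ligands fitted with a shared $E_m$ are
ridge-invariant — the $\log E_m$ term cancels. This is precisely why the
bias statistics are built from within-assay differences. Consequences in
the package:

* `bias_analysis()` runs with $E_m$ free; Δ and ΔΔ are unaffected by the
  ridge.
* Absolute `log_R` values are only validated in tests with `Em` fixed at
  the generating system maximum, which the simulation knows.
* The reported `se_log_R` comes from the Jacobian-based local covariance
  with an SVD pseudo-inverse, so weakly identified directions (full
  agonists' $K_A$; any parameter of a near-silent partial agonist) yield
  large, finite errors rather than failures. For very weak partial agonists
  (τ below roughly 0.1 at 5% CV) the error grows steeply, reproducing the
  known practical limit of this bias method; such ligands are additionally
  flagged `weak` when their response span is within three residual SDs of
  basal.
* The transducer slope is estimated (bounded 0.3–3) by default and can be
  fixed with `n_hill = 1`; the ΔΔ interval uses between-block scatter only
  and does not additionally propagate within-fit covariances, a documented
  simplification consistent with a per-assay randomized-block analysis.

## What the generator emulates

`simulate_cr_study()` and friends emulate the study designs the analysis
assumes, not the underlying cell biology:

* **Kinetics** (`simulate_kinetic_trace()`): a baseline read window followed
  by a rise–decay shape $e^{-k_{off}t} - e^{-k_{on}t}$ rescaled to unit
  peak. `decay_rate = 0` gives the sustained mini-G-like limit
  $1 - e^{-k_{on}t}$ (half-time $\ln 2 / k_{on}$; 0.462/min gives the
  1.5-min GLP-1R-like half-time, and a peak time
  $\ln(k_{on}/k_{off})/(k_{on}-k_{off})$ for transient β-arrestin-like
  responses). Ratiometric scenarios emit two channels in which the acceptor
  gains what the donor loses, giving the DERET/BRET-style monotone ratio.
* **Design**: concentration grids of 9 points spanning 1 pM–1 µM (evenly
  log-spaced) and 4–6 replicate blocks, matching typical
  concentration–response layouts; two matched pathways per block for bias
  studies.
* **Noise**: multiplicative Gaussian read noise (CV 5%), an additive floor
  of 1 response unit on the 100-unit system-maximum scale, and a per-(block,
  pathway) Gaussian offset of SD 0.1 log~10~ units applied to every ligand's
  log τ, emulating between-day assay drift that the per-assay Δ
  normalization is designed to cancel. The magnitudes are package defaults
  chosen to resemble plate-reader scatter; they are not measured values,
  and all are configurable through `noise_model()`.
* **Internalization plates** (`simulate_internalization_plate()`): no-Mesna
  wells read the full surface label, Mesna+vehicle wells the nonspecific
  background, and Mesna+agonist wells background plus the protected
  (internalized) fraction of the specific signal.

What the generator deliberately does *not* reproduce: receptor-trafficking
dynamics, ligand depletion, plate-position effects, heteroscedasticity
beyond the CV+floor model, or microscopy images (the internalization module
consumes per-region intensity tables; segmentation and illumination
correction are upstream concerns). Passing tests therefore demonstrate that
the *estimators* are correct under the stated statistical model, not that
any particular biological dataset satisfies that model.

## Numerical and design choices

* **Fitting** is least squares in log~10~-concentration space via bounded
  L-BFGS-B with data-driven initialization (basal from the minimum or the
  vehicle mean, $E_m$ just above the maximum, EC50 from an interpolated
  half-maximal crossing) and jittered multi-start on failure. Optimization
  runs at a moderate tolerance and is polished to closed-form precision
  when the residual is essentially zero (noise-free inputs).
* **Logistic fits**: the 3-parameter model fixes Hill at 1 and anchors
  basal at the vehicle mean when vehicle (0 M) wells are present; vehicle
  rows are never part of the log-concentration fit itself. Hill is bounded
  (0.1, 5) in 4-parameter fits to prevent pathological slopes on weak
  partial agonists. Per-block fits are summarized as mean ± SEM, the
  parameter-table convention, rather than one pooled fit with propagated
  errors.
* **Half-times** use interpolated threshold crossing by default
  (assumption-free); a one-phase association fit is available via
  `method = "fit"`. AUC is trapezoidal on the native time grid, no
  resampling; the `baseline_correct` flag subtracts the pre-agonist mean.
* **Vehicle normalization** divides by the time-matched vehicle mean trace,
  not a scalar, so vehicle drift is removed point by point.
* **Ratiometric blanks**: points whose blank-subtracted denominator is not
  positive are masked rather than discarding the well — transient
  instrument artifacts should not delete wells.
* **AUC concentration–response** expresses each well's
  baseline-normalized AUC as a fold of its block's vehicle AUC, so vehicle
  wells map to exactly 1 and the EC50 of the underlying response is
  preserved (the map is affine).
* **Internalization** subtracts the nonspecific (Mesna + vehicle) signal
  from both numerator and denominator, so no internalization gives exactly
  0 and full protection exactly 1; a raw-denominator mode is available
  behind `subtract_background = FALSE`.
* **Degenerate inputs** are flagged rather than silently fitted: flat
  concentration–response data are marked `unidentifiable`, flat traces get
  a missing half-time, strata with non-positive denominators are excluded
  with a warning.

## Validation scale

The test suite and the acceptance script validate the pipeline at sizes
chosen to give stable Monte-Carlo estimates while remaining quick on a
single CPU: 200 simulated two-pathway studies (5 blocks, 9 concentrations,
2 ligands, 5% CV, block SD 0.1) for bias-recovery and interval-coverage
checks, 200 simulated plates for internalization unbiasedness, and dense
grid-search oracles (0.01-resolution over logEC50 × Hill and
log τ × log K~A~) as independent checks on the optimizers.

## Known limitations

* Only monotone concentration–response models are provided; biphasic or
  bell-shaped responses are out of scope.
* Bias is quantified as ΔΔlog(τ/K~A~) only; alternative metrics (relative
  activity, equimolar comparison, kinetic bias) are not implemented.
* ΔΔ confidence intervals reflect between-assay scatter only; with very few
  blocks they are accordingly wide.
* Absolute transduction coefficients require an externally supplied system
  maximum; between-ligand comparisons do not.
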