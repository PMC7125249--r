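---
title: "Partition-function thermodynamics of PMV-corrected solvation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition-function thermodynamics of PMV-corrected solvation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmvlogp)
```

## The model

pmvlogp post-processes energy components produced by embedded-cluster
integral-equation (EC-RISM) calculations. Upstream, each solute is
characterised by a set of *states*: one row per (molecule, tautomer,
conformer, phase), carrying the electronic energy in solution $E^{\mathrm{sol}}_{tc}$,
the uncorrected excess chemical potential $\mu^{\mathrm{ex}}_{tc}$, the
partial molar volume $V^m_{tc}$ (solution phases), or the gas-phase energy
$E^{\mathrm{vac}}_{tc'}$ (vacuum rows). This package owns everything that
happens after those components exist.

The working estimate of a state's Gibbs energy ignores rotational and
vibrational entropy:

$$G_{tc} = E^{\mathrm{sol}}_{tc} + \mu^{\mathrm{ex,corr}}_{tc},
\qquad
\mu^{\mathrm{ex,corr}}_{tc} = c_\mu \mu^{\mathrm{ex}}_{tc} + c_V V^m_{tc} + c_q q .$$

The linear correction absorbs the known error of 3D RISM closures, which
scales with the partial molar volume; the charge term matters only for ionic
species and is carried at $q = 0$ by all octanol presets. Conformers are
collapsed by a discrete partition function, and tautomers (microstates) by a
second one:

$$G_t = -RT \ln \sum_c e^{-G_{tc}/RT}, \qquad
  G = -RT \ln \sum_t e^{-G_t/RT}.$$

Solvation free energies subtract a pooled gas-phase reference,
$\Delta_{\mathrm{solv}}G = G - \bigl(-RT\ln\sum_{tc'} e^{-E^{\mathrm{vac}}_{tc'}/RT}\bigr)$,
and the partition coefficient comes directly from the Gibbs energy
difference between the two liquid phases,

$$\log P = \frac{G_{\mathrm{wat}} - G_{\mathrm{oct}}}{RT \ln 10},$$

valid with *absolute* solution-phase energies because the gas-phase terms
cancel in the thermodynamic cycle. `solvation_free_energy()` exists
separately because training and solvation-database work need the explicit
vacuum reference; `predict_logp()` never touches it.

Correction parameters are trained by nonlinear least squares on
experimental solvation free energies,

$$L(c_\mu, c_V) = \sum_{\mathrm{molecules}}
  \Bigl(\Delta_{\mathrm{solv}}G_{\mathrm{model}} -
        \Delta_{\mathrm{solv}}G_{\mathrm{exp}}\Bigr)^2 ,$$

which is genuinely nonlinear whenever a molecule has more than one state,
since the parameters sit inside the exponents of the partition function.

## Parameters that matter

* **Temperature** — 298.15 K throughout (`thermo_constants()`), matching
  the measurement conditions; every exponentiating function accepts a
  constants object so tests can vary $T$. The gas constant defaults to the
  CODATA value $R = 1.98720425864083\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$
  and is overridable.
* **$c_\mu$** (dimensionless) — scale on the excess chemical potential.
  Fixed at exactly 1 in the water model and in all "1-par" octanol models;
  fitted in the "2-par" models (presets 1.33446 dry, 1.28924 wet).
* **$c_V$** (kcal mol$^{-1}$ Å$^{-3}$) — the PMV coefficient, the core of
  the correction. Water preset $-0.10251$; octanol presets between
  $-0.016$ and $-0.006$.
* **$c_q$** (kcal mol$^{-1}$ e$^{-1}$) — engages only for net charges;
  water preset $-15.728$, zero in the neutral-only octanol models.

`param_preset()` ships these five published models; `free_mask` records
which entries training may move, and fixed entries survive a fit bit-for-bit.

## Numerical choices

* **Log-sum-exp with a minimum shift** for every partition function.
  Absolute electronic energies reach $10^2$–$10^5$ kcal mol$^{-1}$, so
  naive exponentiation overflows immediately; after shifting by the minimum
  the largest exponent is exactly zero. States more than
  $RT\ln(1/\varepsilon) \approx 21$ kcal mol$^{-1}$ above the minimum
  underflow to no contribution — physically correct, since their Boltzmann
  weight is below $10^{-16}$.
* **Vacuum pooling.** The gas-phase reference pools all vacuum conformers of
  all tautomers into a single sum. The upstream gas-phase conformer set is
  not in one-to-one correspondence with the solution conformers, so a
  per-tautomer vacuum reference is not well defined; the pooled sum is the
  convention used consistently in training and in `solvation_free_energy()`.
* **Optimizer.** Deterministic multi-start: a Nelder-Mead simplex from the
  fixed 3×3 grid $c_\mu \in \{0.5, 1, 1.5\}$, $c_V \in \{0, -0.01, -0.1\}$,
  simplex tolerance $10^{-12}$, followed by a quasi-Newton (BFGS,
  numerical-gradient) polish from the best simplex solution. The polish is
  what pushes parameter agreement with the closed-form least-squares
  solution on single-state data below $10^{-8}$; the simplex alone stalls
  around $10^{-5}$. Single-free-parameter fits use bounded Brent
  minimisation on $[-5, 5]$ instead, because the simplex is unreliable in
  one dimension. The loss is evaluated through a precomputed padded index
  matrix so each evaluation is pure vectorised arithmetic.
* **Ties and degenerate inputs.** Tautomer ranking uses minimum ranks with
  lexicographic tie order; relative energies map all tied minima to 0.
  Empty ensembles, vacuum rows in solution-phase operations, molecules
  present in only one phase, constant experimental values in the descriptive
  regression, and datasets on which the loss cannot depend on a fitted
  parameter (all $\mu^{\mathrm{ex}} = V^m = 0$) are all hard errors rather
  than silent results.
* **Rounding.** Comparisons against printed tables use half-away-from-zero
  rounding (`round_half_up()`); base R's banker's rounding disagrees on
  exact ties. Raw full-precision values are always returned alongside.

## Design choices

* **Tabular, pipe-friendly surface.** Every user-facing function takes a
  data frame first and returns a tibble; the fitted model object supports
  `tidy()`/`glance()`/`autoplot()`. State tables are plain TSV/CSV with the
  schema `molecule_id, tautomer_id, conformer_id, phase, E_sol, E_vac,
  mu_ex, V_m, q`; since published supplementary component files come in
  heterogeneous layouts, this schema is the package's own, and users map
  their columns onto it when importing external material. Vacuum rows live
  in the same table under `phase = "vacuum"`, which keeps the pairing of
  solution and gas-phase ensembles explicit. An empty cell means absent;
  zero is always a value.
* **Reassignment is explicit input.** Conformations that change protonation
  state during upstream optimisation are relabelled through a user-supplied
  mapping file, never by structure perception — the package deliberately
  never sees coordinates.
* **Direct log P.** Partition coefficients are computed from absolute
  Gibbs energies per phase, not from two solvation free energies, avoiding
  an unnecessary (and cancelling) vacuum reference.
* **Model-dependent tautomer rankings.** `rank_shift_report()` compares
  stability orderings across arbitrary solvent/model columns and reports
  any discordance. On the packaged reference energies the ordering is
  invariant to the *solvent* (water vs either 2-par octanol model); the
  weaker 1-par octanol corrections reorder one close-lying pair
  (SM16_micro003/SM16_micro007, split by ~1 kcal mol$^{-1}$), which the
  report flags faithfully rather than suppressing.

## The synthetic-data generator

`generate_dataset()` draws component tables with a *known* ground truth so
that training, prediction and the outlier analyses are testable end to end
without any external database. Per molecule: partial molar volume uniform
on 50–400 Å$^3$; excess chemical potential linear in the volume with
negative slope plus molecule-level scatter ($\mu = 5 - 0.1\,V + \mathcal N(0,3)$,
spanning roughly $-40$ to $+5$ kcal mol$^{-1}$); absolute electronic
baseline uniform on $-5000$ to $-500$ kcal mol$^{-1}$ so the numerically
delicate code paths are always exercised; 1–3 tautomers separated by
2 kcal mol$^{-1}$ plus exponential gaps (mean 5); 1–5 conformers per
tautomer and phase with exponential spread of mean 1 kcal mol$^{-1}$ (the
1–5 cap mirrors the upstream practice of considering up to five
conformations per molecule); vacuum conformers within ±2 kcal mol$^{-1}$ of
the solution baseline. Experimental references are computed exactly from
the ground-truth parameters and then perturbed with Gaussian noise of
standard deviation `sigma` (default 0.3 kcal mol$^{-1}$, a typical
experimental uncertainty for solvation free energies). All draws come from
one seeded stream; the generating spec travels with every dataset, and the
same spec regenerates it bit-for-bit.

`generate_outlier_scenario()` plants a constant water-phase energy offset
on a labelled molecule subset while the reference tables keep the clean
truth — the synthetic analogue of a class-specific force-field deficiency
such as the hydroxyl-compound offset seen in blind-challenge outliers.

What the generator does *not* emulate: correlations between components of
real molecules, conformer sets that differ physically between solvents,
non-Gaussian experimental error, and any quantum-chemical or
integral-equation physics. Passing recovery tests therefore demonstrate the
correctness of the estimation machinery under the stated noise model, not
the physical accuracy of the correction on real chemistry.

## Problem sizes and verification

The test suite exercises parameter recovery at $n \in \{50, 200, 500\}$
molecules with 20 replicates at noise 0.3 kcal mol$^{-1}$ — sizes chosen so
the whole suite runs in a few minutes while the shrinking of the recovery
error with $n$ is clearly resolved. Noiseless datasets must reproduce their
generating parameters to $10^{-4}$ and their stored observables to
$10^{-10}$, and the nonlinear fit must agree with the closed-form
least-squares oracle to $10^{-8}$ on single-state data. The packaged
per-compound prediction table reproduces the published evaluation
statistics at printed precision, including the leave-one-out isolation of
the SM15 outlier (signed error $-1.36$; RMSE 0.2 over the remaining ten
compounds).

## Known limitations

* The published *training-set* statistics and parameter values for the
  octanol models cannot be recomputed here: they require the Minnesota
  Solvation Database experimental values together with the corresponding
  upstream component energies, neither of which is redistributable with the
  package. `fit_correction_params()` documents this as an optional
  validation path for users who hold both.
* Neutral species only: no ionic corrections are exercised
  ($c_q$ is carried for API completeness), and no pH-dependent
  distribution coefficients are computed.
* No molecular structure handling of any kind — inputs begin and end at
  energy components.
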