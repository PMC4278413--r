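---
title: "Ensemble model selection for circadian control of CBF3 transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble model selection for circadian control of CBF3 transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbfclock)
```

## The scientific question

*CBF3* (*DREB1A*) heads the main cold-acclimation regulon of Arabidopsis.
Its transcription is clock-controlled: a sharp daily peak ~8 h after dawn
whose phase barely moves across photoperiods and persists in constant
light. Several clock components have been proposed as its direct
regulators — activation by the morning factors LHY/CCA1, repression by the
day-phased pseudo-response regulators (PRR9, PRR7, NI as the PRR5 proxy),
or repression by evening components (TOC1, the LUX–ELF3–ELF4 Evening
Complex). `cbfclock` discriminates among these hypotheses by fitting an
ensemble of candidate transcription submodels to multi-photoperiod
expression data, ranking them by corrected AIC, and stress-testing the
winners with in-silico genetics and cold-pulse gating experiments.

## The model

### Clock driver

The *CBF3* submodel consumes time courses of six clock regulator species.
The default driver is deliberately phenomenological: each wild-type
species is a smooth von-Mises-shaped 24-h bump

$$x(t) = a\,\exp\{\kappa[\cos(2\pi (t-\phi)/24) - 1]\},$$

with peak phase $\phi$ (hours after dawn), sharpness $\kappa$ and
amplitude $a$ set in `clock_config()`. Defaults encode the canonical
phase ordering: LHY/CCA1 at ZT1 (broad, $\kappa = 1$ — LHY protein
persists well into the day), PRR9/PRR7/NI in sequence through the day at
ZT3/6/9 ($\kappa = 2$), TOC1 near dusk at ZT13 ($\kappa = 1.5$), and EC
activity centred at ZT23 with $\kappa = 1.5$, so that it spans late night
across dawn and falls below 25% of its maximum through the afternoon.
These are tunable configuration values, not mechanistic claims; the
submodel only needs regulator waveforms with the right phases and widths.

Two consequences of this choice matter for interpretation:

* **Photoperiod invariance.** The surrogate waveforms are identical in
  every regime, including constant light — the experimental observation
  for *CBF3* itself. Free-running period drift of a real clock in
  constant light is deliberately out of scope, so effects that depend on
  clock phase drift in LL (e.g. the documented ~4 h constant-light delay
  of fitted EC-only variants relative to the data peak) are only
  partially reproduced: the EC-only variant shows the delay because its
  repression window cannot open before ZT~11, but the EC+LHY variant,
  which can sculpt its peak onto ZT8 with the declining LHY wave, does
  not.
* **Mutant knock-on effects are configuration, not mechanism.**
  `standard_genotypes()` encodes *lhy cca1* (LHY/CCA1 knocked out),
  *ni prr7 prr9* (those three knocked out, LHY/CCA1 amplitude doubled —
  the day PRRs repress *LHY/CCA1* transcription), *toc1* (TOC1 out) and
  *lux* (EC out, LHY/CCA1 amplitude ×0.3, since EC mutants have low LHY).
  All multipliers are exposed in the genotype objects.

An SBML import path (`read_sbml_clock()`) can replace the surrogate: it
reads a restricted SBML Level 3 subset (species, parameters, reactions
with MathML kinetic laws, rate rules), integrates it with `deSolve`, and
maps declared model species onto the six regulator roles.

### CBF3 transcription submodel

mRNA obeys

$$\frac{dC}{dt} = v_{\max} \prod_{A}\frac{A^n}{A^n + K_A^n}
 \prod_{R}\frac{K_R^n}{K_R^n + R^n} \; - \; d\,C,$$

one independent Hill term per regulator sharing a fixed exponent
($n = 2$ by default, configurable but never fitted). This multiplicative
form reproduces the free-parameter accounting that the ensemble
comparison relies on: $2 + (\text{number of regulators})$ parameters, so
3 for a single-regulator variant and 4 for two. Clock species regulate
transcription only — there is no CBF3 protein variable, no feedback onto
the clock, and no regulated decay.

The ensemble (`cbf_ensemble()`) contains 13 variants: all combinations of
EC/TOC1 repression with optional LHY/CCA1 activation, the single-regulator
variants, EC activation as a control, and the joint day-PRR repression
variants (NI+PRR7+PRR9, alone or under LHY activation). The two joint-PRR
variants are the only members exceeding three regulators (5 and 6 free
parameters under the counting rule); each PRR term keeps its own
half-saturation constant, the direct extension of the per-regulator
pattern.

### Numerics

Because the clock inputs are prescribed functions of time, the mRNA ODE
is linear, and `simulate_cbf3()` integrates it with an exact
exponential-integrator step assuming piecewise-linear production on a
fine internal grid (default 0.05 h). The result is non-negative by
construction and, in the tests, agrees with an independent fixed-step
RK4 reference at 0.001 h to better than $10^{-4}$ relative error across
all 13 architectures. The initial condition is the instantaneous balance
point $C(0) = p(0)/d$, and the first 24 h of every simulation are treated
as an entrainment transient and discarded from all analyses.

## Synthetic data

The generator (`generate_dataset()`) emulates the statistical structure
of the diurnal microarray series this analysis is designed around, since
the original series is not redistributable here:

* a raised-cosine peak centred at ZT8, full width at half maximum 4 h,
  on a baseline of 5% of peak height — the "sharp peak" phenotype;
* identical waveform in 8L/16D, 12L/12D, 16L/8D and 24L/0D — phase
  robustness across photoperiods;
* sampling every 4 h over 0–48 h (13 points × 4 regimes = 52 points),
  a standard diurnal microarray design;
* additive Gaussian noise, SD 10% of peak, truncated at zero
  (microarray-scale noise; the original error model is unprinted).

All of these are configuration knobs with the listed defaults. What the
generator does **not** emulate: replicate structure, probe-level effects,
normalisation artefacts, and any dependence of waveform shape on
photoperiod. Tests passing on these data therefore demonstrate that the
selection machinery recovers the right architecture *under the stated
waveform phenotype*, not that it would do so on any real microarray
series.

## Fitting and selection

Each architecture is fitted by minimising the pooled sum of squared
residuals with model output and data each scaled to unit maximum within a
regime. The normalisation reflects that microarray units are arbitrary
and that the parameter counts admit no free scale: fits are scale-free,
which also means $v_{\max}$ is identified only up to that scale.

The optimiser is a seeded Latin-hypercube multi-start (default 24
restarts; starting points drawn in seeded blocks of 8 so restart
sequences are nested and the best cost is non-increasing in the number of
restarts) over log-spaced bounds — $10^{-3}..10^{3}$ for $v_{\max}$ and
each $K$, $0.05..5\,\mathrm{h^{-1}}$ for $d$ — with chained Nelder–Mead
refinement in $\log_{10}$ space (the simplex is restarted from its own
optimum up to five times, which escapes the collapsed-simplex stagnation
NM is prone to in ill-conditioned valleys). Ties between restarts break
to the lowest restart index; everything is reproducible bit-for-bit for
a fixed seed.

Scores are the standard small-sample corrected AIC computed from the RSS
under a Gaussian likelihood with profiled variance; the variance counts
as one parameter, so $k = k_{\text{free}} + 1$ for every model and the
shared offset cancels in comparisons. One pooled score is computed per
model across all four regimes. Akaike weights are computed stably after
subtracting the minimum score. Absolute score values are
convention-dependent — they move with the dataset, the residual
normalisation and the pooling choice — so ranking and weight structure
are the meaningful outputs.

## In-silico experiments

* `peak_phase()` — argmax over the final full cycle, modulo 24; flat
  trajectories signal a classed "arrhythmic" condition rather than
  returning a number.
* `mutant_fold_change()` — mutant and wild type simulated with identical
  fitted parameters in constant light; the statistic is the ratio of
  final-cycle peak mRNA. Class thresholds (abolished < 0.05, reduced
  < 0.5, wild-type-like 0.5–2, elevated > 2) are configuration. A
  peak ratio (rather than mean or point ratio) is used because the
  comparisons it reproduces are plotted as constant-light waveforms; an
  arrhythmic mutant falls back to its mean level and is flagged.
* `cold_gating_profile()` — five-fold pulses at ZT0,4,...,20 after
  subjective dawn in constant light. Via-LHY pulses multiply the LHY/CCA1
  waveform for 4 h from pulse onset (the experimental sampling
  granularity; pulse duration is configuration); direct pulses multiply
  the mRNA state at the pulse instant. Induction is read as the maximum
  pulsed mRNA within 4 h of onset, mirroring short cold-exposure
  transcript measurements; profiles are normalised to unit maximum by
  default. With the fitted top model, via-LHY gating peaks at ZT0–4
  while direct induction necessarily tracks the ambient waveform and
  peaks at ZT8 — the signature separating a clock-internal cold signal
  from an external one.

## Problem sizes and reproducibility

The default analysis — 52 data points, 13 architectures × 24 restarts,
0.05 h integration step — completes in about a minute on one CPU; the
package test-suite property checks (integrator-oracle agreement across
the ensemble, noiseless parameter recovery for every architecture, pulse
identities and monotonicity) run in a few minutes. `run_selection()`
writes every artifact (per-regime CSVs, per-fit JSON and restart traces,
the selection table, a manifest with config hash and per-file checksums)
and is bit-identical under a fixed configuration; the master seed
propagates as dataset seed and per-architecture fitting seeds
(`seed + position`).

## Known limitations

* The surrogate clock does not free-run, so constant-light phenotypes
  that depend on clock phase drift are only partially expressed (see
  above); with an SBML clock model supplied, this limitation lifts.
* Mutant knock-on effects are first-order configuration (amplitude
  scalings), not emergent network behaviour; fold-change magnitudes for
  strongly repressed wild-type baselines can saturate at the fitting
  bounds and should be read as order-of-magnitude.
* The multiplicative Hill form with a fixed, shared exponent is the
  minimal transcription model consistent with the free-parameter
  accounting the ensemble comparison is built on; richer forms
  (interaction terms, fitted exponents, regulated decay) are excluded by
  design, and the exponent convention ($n = 2$) follows the Arabidopsis
  clock-model lineage.
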