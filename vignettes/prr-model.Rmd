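---
title: "A stochastic model of PCNA ubiquitylation in budding-yeast post replication repair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic model of PCNA ubiquitylation in budding-yeast post replication repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prrsim)
library(dplyr)
```

## The biological question

When UV light damages DNA, replicative polymerases stall at the lesions.
Budding yeast tolerates (rather than repairs) such lesions through Post
Replication Repair (PRR), and the routing decision inside PRR is written on
the sliding clamp PCNA: mono-ubiquitylation of PCNA at K164 recruits
translesion polymerases (potentially mutagenic bypass), while K63-linked di-
and tri-ubiquitylation promotes error-free template switching. `prrsim`
implements a mechanistic stochastic model of exactly this decision layer —
the enzymatic cascade that conjugates one, two or three ubiquitins to
lesion-stalled PCNA — together with the calibration, simulation, observable
and sensitivity machinery needed to compare it with western-blot time
courses.

## The reaction network

The model is a mass-action network of 23 molecular species and 25
irreversible reactions (`prr_species()`, `prr_reactions()`), organised in
four functional modules:

1. **Lesion recognition and mono-ubiquitylation** (reactions 1–10). A free
   lesion `L` converts PCNA to the stalled clamp `PCNA_on`; the Rad18 dimer
   docks on it, recruits ubiquitin-charged Rad6 (`Rad6:U`), and the ubiquitin
   is transferred to the clamp (`PCNA_on:U`).
2. **Di-ubiquitylation** (11–17). The pre-formed Ubc13:Mms2 heterodimer
   charges with ubiquitin, joins Rad5 bound to mono-ubiquitylated PCNA, and
   extends the chain (`PCNA_on:U:U`).
3. **Tri-ubiquitylation** (18–22). The same cycle adds a third moiety
   (`PCNA_on:U:U:U`); the chain is capped there because longer chains are
   rare after UV damage and not reproducibly detectable.
4. **Signal switch-off** (23–25). A generic first-order step converts each
   ubiquitylated isoform to the absorbing `PCNA_off`, releasing its
   ubiquitins back into the free pool (recycling). The molecular mechanism of
   switch-off is not characterised; the step phenomenologically reproduces
   the observed signal decay.

Model assumptions worth making explicit:

* **Step-wise chain growth** — one ubiquitin per enzymatic cycle, as shown by
  in vitro reconstitution of the E2/E3 reactions.
* **Pre-formed Ubc13:Mms2** — the complex-formation sub-module changes
  nothing dynamically, so the E2 heterodimer starts pre-assembled with copy
  number `min(Ubc13, Mms2)` in the nucleus (193).
* **Closed totals** — there is no synthesis or degradation in the network,
  matching experiments done under cycloheximide (protein synthesis blocked).
  Consequently seven weighted species sums (total PCNA trimers, total
  ubiquitin counting free, carrier-bound and conjugated pools, total Rad6,
  Rad18, Rad5, Ubc13:Mms2, and total lesions free or carried) are exact
  invariants; `validate_conservation()` checks them structurally and the
  test suite asserts them along simulated trajectories.
* **Rad18 starts monomeric** (206 copies); dimers only arise through the
  dimerization reaction.

## Parameterisation

**Copy numbers.** Whole-cell copy numbers come from curated proteome
databases (`prr_protein_amounts()`). Proteins present in both nucleus and
cytoplasm (Rad6, Ubc13, Mms2, ubiquitin) are scaled by the nuclear volume
fraction — 7% of cell volume in exponentially growing yeast — assuming
uniform distribution; nucleus-resident proteins (Rad5, Rad18, PCNA) are not
scaled. Scaling rounds to the nearest molecule, which reproduces all the
published nuclear amounts (Rad6 194, Ubc13 628, Mms2 193, ubiquitin 8698).
PCNA is counted in functional homotrimers (7480).

**Stochastic constants** are per-second under the stochastic
chemical-kinetics convention (propensity = constant × combinatorial reactant
count) for both reaction orders; no volume rescaling is applied to the
bimolecular constants, which are taken as published. The only
literature-measured rate is the chain-extension catalytic rate
K~cat~ = 3.0 min^−1^, which for a first-order step converts directly to
`3/60 = 0.05` s^−1^ (`kcat_to_stochastic_constant()`); the remaining
constants were calibrated against 5 J/m² time courses by the model's
original development and are carried here verbatim.

**UV dose → lesion count.** Two published dose–response datasets of
(CPD + 6-4 photoproduct) counts per genome are shipped as
`dose_lesion_data()`. Each is fitted by least squares through the origin
(`fit_through_origin()`, slope = Σxy/Σx²), giving 200.248 and 222.22
lesions per J/m². `chi2_cross_validate()` scores each slope on the *other*
dataset with the Pearson statistic Σ(obs−pred)²/pred and keeps the slope
that generalises better — the 200.248 coefficient. Two numerical caveats are
deliberate and documented rather than hidden:

* The published χ² magnitudes are not reproduced by this (or several other
  standard) χ² forms; the original formula is unspecified. Only the
  *selection outcome* is part of the tested contract.
* `lesions_for_dose()` rounds to nearest. This reproduces the published
  lesion estimates at 5–50 J/m² exactly (1001, 2002, 4005, 6007, 10012) but
  gives 15019 at 75 J/m² where the published table prints 15018
  (200.248 × 75 = 15018.6, an apparent round-down). The built-in
  `high_dose_75` scenario uses the published 15018 as its input.

## Simulation engines

`simulate_ssa()` is an exact Gillespie direct-method implementation;
`simulate_tau_leaping()` is an explicit tau-leaping engine with the
Cao–Gillespie–Petzold step-size selection. Both are compiled and draw all
randomness from R's RNG, so a seed fully determines a trajectory; ensembles
derive run seeds as `base_seed + run_index - 1` and reproducibility is part
of the contract. Sampling uses last-value-before-t (piecewise-constant)
interpolation on the requested grid; the default grid is the experimental
lane schedule 0, 3 min, 30 min, 1–5 h.

Tau-leaping control parameters (all user-settable): error bound
`eps = 0.03`, critical-reaction threshold `n_critical = 10` (a reaction
within 10 firings of exhausting a reactant fires one at a time, which is
what prevents negative counts), and an SSA fallback whenever the selected
leap — including the expected time to the next critical event — is shorter
than 10 expected SSA steps, taken in batches of 100 exact steps.

An honest performance note: this network mixes very fast association steps
(constants of 10^5^) with copy numbers of order 1–100, so the leap-size
control keeps the engine in its exact-stepping regime for most of a
canonical trajectory; tau-leaping genuinely accelerates only the
large-copy-number phases (for example the initial E2 charging, or toy
systems with thousands of molecules, where the test suite verifies its
moments against SSA and against closed-form death-process statistics).
Stiffness is handled through the critical-reaction partition rather than
implicit methods, which is adequate at these copy numbers. The practical
cost of a 5-hour trajectory rises steeply with dose — at high dose most
clamps are stalled and the fast dock/undock cycles of the Rad18 dimer
dominate the event count — which is why the heavier checks below use
reduced run counts or horizons.

## Observables: what a blot sees

A species' band on a denaturing SDS-PAGE blot is determined by the number of
ubiquitins *covalently conjugated* to the clamp, because non-covalent
partners (the Rad18 dimer, Rad5, charged Ubc13:Mms2) dissolve in SDS.
`classify_isoform()` therefore maps each species to
free / unmodified / mono / di / tri / off by its `conjugated_ub` count, and
carrier-bound ubiquitin riding on Rad6 or Ubc13:Mms2 inside a complex does
not shift the band. Whether the original figure pipeline summed the
enzyme-bound intermediates into each isoform band is not stated anywhere;
the covalent-counting rule is the biologically forced resolution and is the
documented convention here.

Two representations mirror the published comparison strategies:
`units_representation()` (UR) gives absolute molecule counts per channel
with across-run mean and standard deviation (channel sums are accumulated
per run, so the dispersion is the true dispersion of the sum);
`normalized_representation()` (NR) divides mono/di/tri by their total,
flagging times whose total modified signal is below a detection threshold
(default 0; a positive value emulates the blot detection floor, which in the
wet protocol sits near the 5 J/m² acute-dose signal). "Poly-ubiquitylated"
always means di + tri summed. NR discards scale, so UR→NR is not invertible.

## Parameter sweeps and sensitivity screening

`parameter_sweep()` varies exactly one target at a time: stochastic
constants log-uniformly over three orders of magnitude either side of the
reference (7 samples by default), initial amounts linearly from 0 to twice
the reference (9 samples by default, spanning deletion to 2-fold
overexpression), with `n_replicates = 10` runs per value by default to tame
stochastic fluctuation.

`elementary_effects()` implements the Morris screening method over the
reaction constants, on a `p = 4` level grid in log10-factor space spanning
two orders of magnitude below to two above each reference value, with
`r = 10` trajectories and jump `delta = p/(2(p-1))` by default (the original
study names the method but not its settings; these are standard choices and
all configurable). Elementary effects are defined per unit change of
log10(constant) because the interval spans four decades. The screened output
is not pinned down in the source study either ("amounts of mono- and
poly-ubiquitylated PCNA"); this implementation computes both a
near-peak point statistic (30 min by default) and the area under the curve
over the horizon, for the mono and poly channels, and reports a μ*-ranking
for each. The Morris estimator itself is validated in the test suite against
a brute-force full-factorial enumeration of elementary effects on an
interacting two-factor toy.

## The synthetic blot generator

`generate_blot()` emulates the densitometry readout so the whole pipeline
can be exercised without wet data: per replicate and band,
`intensity = gain × molecules × LogNormal(mean 1, cv) + background`, with
amounts under the detection threshold leaving background-only bands, and an
optional film-saturation ceiling (off by default). Multiplicative lognormal
noise is the natural model for densitometry, whose error scales with band
intensity; the original protocol reports no noise model, so `noise_cv = 0.2`
is the default replicate scatter — a value typical of triplicate blot
quantification. The default synthetic grid includes the 3-minute early-peak
lane. `ratios_from_blot()` quantifies in the same order as the experimental
protocol: background-subtract, normalise to the unmodified-PCNA band of the
same lane (this loading normalisation cancels algebraically in the final
ratios when gain is uniform — a tested identity), normalise mono/di/tri to
sum to one per replicate, then average across replicates.

With zero noise and background the chain
ensemble → UR → blot → ratios reproduces `normalized_representation()`
exactly, and with noise the replicate means converge to the truth as the
noise vanishes; both are asserted in the tests. The
parameter-recovery check uses the *population* replicate-level dispersion
for its 3σ/√3 interval: with only three replicates a sample-sd interval is a
Student-t with two degrees of freedom, whose 3-sigma coverage is ~90% per
cell, so sample-based intervals cannot meet a 95% joint bar even in
principle — a point worth remembering when reading triplicate blot error
bars.

## Problem sizes and numerical choices in the checks

The test suite asserts, among others: exact reproduction of the calibration
coefficients, lesion estimates, nuclear amounts and the K~cat~ conversion;
conservation and non-negativity along full 5-hour trajectories of both
engines; engine agreement on a 10×-down-scaled network (pools ÷10,
50 lesions, 250 runs per engine over a 10-minute window at three sample
times); the low-dose switch-off (1001 lesions, 100 runs: mean total
modified PCNA at 5 h strictly below its time-course maximum, itself an
interior peak); the high-dose plateau (15018 lesions, 4 runs with the final hour sampled
every 150 s: each isoform channel's half-hour window average changes by
<5% across the final hour — window averaging is used because single-time
ensemble means fluctuate by ~10% at affordable run counts); monotonicity of peak mono- and
poly-ubiquitylation in initial ubiquitin over the reduced grid
{870, 8698, 17396} molecules at 4005 lesions over a 2-hour window; and the
synthetic-blot identities above. These sizes are the package's own choices
balancing statistical resolution against the cost of exact simulation at
each condition; the full-size figure-level runs (100-run ensembles over 5 h
at every published dose, the 5-point ubiquitin sweep) are available through
`run_scenario()`.

## Known limitations

* The model stops at the ubiquitylation decision layer: no NER chemistry, no
  downstream TLS polymerase switching or template-switching intermediates,
  no K107 ubiquitylation or K127 SUMOylation, no chromatin
  loading/unloading of PCNA.
* It describes the in vivo readout well only below roughly 30 J/m²; at
  higher doses the simulated isoforms saturate to a plateau while wild-type
  cells (with functional NER) diverge — that mismatch is a finding about
  NER/PRR crosstalk, not a target the model should be tuned to.
* The switch-off module is phenomenological by construction.
* The synthetic blot emulates noise, background, gain and detection floor,
  but not gel artefacts, molecular-weight ladders or film saturation
  curves; passing round-trip tests therefore demonstrates pipeline
  correctness, not wet-lab realism.
* SBML export is not provided; the JSON serialization
  (`write_network_json()`) is the interchange format.

## A worked low-dose run

```{r example, eval = FALSE}
net <- build_prr_network(uv_dose = 5)            # 1001 lesions
ens <- run_ensemble(net, n_runs = 100, method = "ssa", base_seed = 1)
ur <- units_representation(ens)
nr <- normalized_representation(ur)
autoplot(ens)

# compare against a synthetic triplicate blot of the same truth
blot <- generate_blot(ur, blot_params(noise_cv = 0.2, n_replicates = 3),
                      seed = 7)
compare_series(nr, ratios_from_blot(blot))$mean_dev
```
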