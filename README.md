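# prrsim

Stochastic modelling of PCNA ubiquitylation in the budding-yeast Post
Replication Repair (PRR) pathway.

## The problem

UV light leaves lesions (cyclobutane pyrimidine dimers and 6-4
photoproducts) on DNA. During S phase the replication fork stalls at a
lesion, and *Saccharomyces cerevisiae* tolerates the damage through PRR: the
sliding clamp PCNA, stalled at the lesion, is ubiquitylated at K164.
**Mono**-ubiquitylation (by the E2 Rad6 with the E3 Rad18) routes bypass to
translesion synthesis — potentially mutagenic — while K63-linked **di/tri**
ubiquitylation (by Ubc13:Mms2 with Rad5) routes it to error-free template
switching. The balance of mono- vs poly-ubiquitylated PCNA over the hours
after irradiation is therefore the readout of the pathway decision, and it
is measurable as band ratios on a western blot.

`prrsim` is for systems biologists who want to simulate and interrogate that
decision layer quantitatively. It provides:

* the mechanistic mass-action network — 23 species, 25 reactions — of PCNA
  mono-, di- and tri-ubiquitylation with nuclear copy numbers
  (`build_prr_network()`, `prr_species()`, `prr_reactions()`,
  `validate_conservation()`);
* the UV-dose → lesion-count calibration: through-origin least squares
  (slope Σxy/Σx²) on two published dose–response datasets, χ²
  cross-dataset model selection, and the dose-to-lesion table
  (`fit_through_origin()`, `chi2_cross_validate()`, `lesions_for_dose()`);
* exact Gillespie SSA and Cao–Gillespie–Petzold tau-leaping engines in
  compiled code, with seeded ensembles (`simulate_ssa()`,
  `simulate_tau_leaping()`, `run_ensemble()`);
* blot-style observables: isoform channels by covalently conjugated
  ubiquitin count, the units (absolute molecules) and normalized (ratio)
  representations, and series comparison (`units_representation()`,
  `normalized_representation()`, `compare_series()`);
* one-at-a-time parameter sweeps and Morris elementary-effects sensitivity
  screening (`parameter_sweep()`, `elementary_effects()`);
* a synthetic western-blot generator with lognormal densitometry noise,
  background and detection floor, plus the quantification chain back to
  ratios (`generate_blot()`, `ratios_from_blot()`);
* figure-level scenario runner writing reproducible CSV/plot bundles
  (`run_scenario()`, `prr_scenarios()`).

The kinetic core: a reaction with stochastic constant *c* has propensity
*c·n<sub>A</sub>* (first order), *c·n<sub>A</sub>n<sub>B</sub>* (bimolecular)
or *c·n<sub>A</sub>(n<sub>A</sub>−1)/2* (homodimerization), and trajectories
of the jump process are sampled exactly (SSA) or by Poisson leaps with
critical-reaction partitioning (tau-leaping). See the methods vignette
(`vignettes/prr-model.Rmd`) for the model assumptions, parameter
provenance, and numerical choices.

## A worked example

Five J/m² of UV-C corresponds to ~1001 genomic lesions under the selected
calibration. Simulate a 100-run ensemble over the experimental 5-hour
course and look at the modified-PCNA channels:

```r
library(prrsim)

calibrate_dose_response()
#> <prr_calibration> dose -> lesion linear fits (through origin)
#> # A tibble: 2 × 4
#>   source coefficient  chi2 selected
#>   <chr>        <dbl> <dbl> <lgl>
#> 1 B66           222.  366. FALSE
#> 2 B65           200.  261. TRUE
#> selected coefficient: 200.2485 lesions per J/m^2

net <- build_prr_network(uv_dose = 5)        # L = 1001 lesions
ens <- run_ensemble(net, n_runs = 100, method = "ssa", base_seed = 1)
ur  <- units_representation(ens)
subset(ur, channel %in% c("mono", "di", "tri") & time %in% c(1800, 18000))
```

```
#> # A tibble: 6 × 5
#>    time channel  mean   std provenance
#>   <dbl> <chr>   <dbl> <dbl> <chr>
#> 1  1800 mono    14.3   3.52 simulated
#> 2  1800 di      19.4   4.71 simulated
#> 3  1800 tri     39.4   5.61 simulated
#> 4 18000 mono     2.28  1.54 simulated
#> 5 18000 di       3.41  1.82 simulated
#> 6 18000 tri      6.72  2.46 simulated
```

At this low dose the signal peaks around 30 minutes (mono ≈ 14, di ≈ 19,
tri ≈ 39 molecules per nucleus on average) and has largely switched off by
5 hours — the clamp pool is progressively converted to the absorbing
`PCNA_off` state as lesions are bypassed, reproducing the decay seen on
blots. The poly (di+tri) signal dominating mono reflects the error-free
branch carrying most of the bypass at low dose. `autoplot(ens)` draws the
isoform time courses with their stochastic fluctuation bands, and

```r
nr <- normalized_representation(ur)
blot <- generate_blot(ur, blot_params(noise_cv = 0.2, n_replicates = 3), seed = 7)
compare_series(nr, ratios_from_blot(blot))$mean_dev
#> [1] 0.01844425
```

compares the simulated isoform ratios with a synthetic triplicate blot of
the same ground truth (mean absolute ratio deviation ≈ 0.02 at 20% band
noise).

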