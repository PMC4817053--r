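# oxiquant

Quantitative analysis of site-specific protein oxidation and its
functional consequences, from mass-spectrometric and colorimetric data.

Reactive oxygen species oxidize proteins at specific residues —
methionine to methionine sulfoxide (+15.995 Da), cysteine to higher
oxidation states — and those modifications may alter a protein's
conformational ensemble and catalytic activity. oxiquant implements the
full analytical chain needed to quantify this for a peptide-level
workflow, built around the 125-residue phosphohistidine phosphatase
PHPT1 as the motivating system:

* **Peptide chemistry** — monoisotopic/average masses from elemental
  composition, residue modifications (phospho, mono/di/tri-oxidation,
  carbamidomethyl) and terminal groups (succinyl, *p*-nitroanilide),
  H⁺/Na⁺/K⁺ adduct m/z, b/y fragment ions with the −64 Da CH₄SO loss of
  oxidized Met and the −80/−98/−116 Da losses of phosphohistidine, and
  in-silico tryptic digestion.
* **Oxidation stoichiometry (`oxquant`)** — extracted ion chromatograms
  (XICs) at ±5 ppm on monoisotopic and A+1 peaks, trapezoidal AUC with
  rule-based peak windows, oxidized : non-oxidized ratios per replicate,
  fold changes vs control with a homoscedastic two-tailed t-test
  (fold = mean ratio / mean control ratio), plus whole-protein
  oxidized/non-oxidized intensity ratios and max-normalized per-site
  mod/base summaries.
* **Phosphatase activity (`activity`)** — direct-infusion time courses
  of the six-peak set m/z 691/713/729 (substrate product) and
  771/793/809 (phosphopeptide), 5-minute spectral averaging,
  adduct-summed phospho : non-phospho ratios, and fold change of the
  phosphorylation level `f = r/(1+r)` against an untreated control,
  reported as −log₁₀(fold).
* **Ensemble discriminability (`ensembles`)** — Kabsch least-squares
  superposition to a reference structure and a per-residue statistic η:
  the cross-validated balanced accuracy of a regularized linear
  discriminant separating two ensembles' frames (0.5 = chance, 1 =
  disjoint), with center-of-mass deviations and a configurable flag
  threshold (default η ≥ 0.69, the conventional 1 Å equivalence point).
* **Michaelis–Menten kinetics (`kinetics`)** — Beer–Lambert conversion
  (ε = 17.8 mM⁻¹cm⁻¹, path length from well geometry), most-linear-window
  initial velocities, nonlinear least-squares fits of
  v = V·S/(Kₘ+S) with 95% CIs, k_cat = V/[E], and fold-change
  comparisons between treatments.
* **Synthetic data (`synth`)** — seeded generators for every input
  (LC-MS oxidation pairs, infusion decays, Gaussian conformational
  clouds, pNPP progress curves), each emitting the ground truth needed
  to validate the downstream estimate.

Everything is tidyverse-native: functions take data frames, return
tibbles, compose with the pipe, and fitted objects support
`tidy()`/`glance()`/`autoplot()`.

## Worked example

```r
library(oxiquant)

# The infusion-assay substrate and its phosphohistidine form
substrate <- parse_peptide("Suc-AHPF-pNA")
substrate
#> <peptide> Suc-AHPF-pNA
#>   monoisotopic 690.2762 Da; average 690.71 Da
phospho <- apply_modification(substrate, "ph", 2)
round(c(H = adduct_mz(phospho, "H"), Na = adduct_mz(phospho, "Na"),
        K = adduct_mz(phospho, "K")), 2)
#>      H     Na      K
#> 771.25 793.23 809.21
```

The three adduct m/z are the phosphopeptide peaks the infusion assay
watches (nominal 771/793/809); the substrate's own adducts sit at
691/713/729.

```r
# Site-specific oxidation: simulate 3 control + 3 treated LC-MS runs
# whose true oxidized:non-oxidized odds differ 41-fold, then recover
# that fold change from 5-ppm XICs
sc <- run_oxidation_scenario(ox_odds = c(control = 0.01, `1mM` = 0.41),
                             seed = 42)
sc$report
#> # A tibble: 2 × 6
#>   group   truth_fold recovered_fold relative_error      p_value significant
#> 1 control          1            1          0       1            FALSE
#> 2 1mM             41           40.8       -0.00523 0.0000000387 TRUE

# Phosphatase activity: noise-free infusion with k = ln(100)/10 per min
act <- run_activity_scenario(seed = 42)
act$at_10min
#> # A tibble: 3 × 5
#>   arm            k fraction_at_10min fold_decrease expected_fold_decrease
#> 1 control   0                0.375            1                      1
#> 2 treated   0.461            0.00375        100                    100
#> 3 denatured 0.0461           0.237            1.58                   1.58
```

The treated enzyme erases 99% of the phosphorylation in 10 minutes
(fold decrease 100, −log₁₀ = 2); the heat-denatured arm retains partial
activity, sitting between control and treated.

```r
# Kinetics: simulated pNPP progress curves over 0.8-40 mM substrate
sim <- simulate_pnpp_progress(pnpp_sim_config(noise_sd = 0.005), seed = 42)
fit <- fit_progress_curves(sim$curves)
fit
#> <mm_fit> Michaelis-Menten fit
#>   Km   = 5.038 mM (95% CI 4.867 - 5.209)
#>   Vmax = 0.01003 mM/min (95% CI 0.009921 - 0.01013)
#>   kcat = 4.775 min^-1 at [E] = 2.1 uM
```

The fit recovers the generator truth (Kₘ = 5 mM, V = 0.01 mM/min)
within 1%; `tidy(fit)` returns the parameter table, `autoplot(fit)` the
saturation curve.

## Documentation

The methods vignette (`vignettes/oxidation-analysis.Rmd`) describes the
models, the estimator design choices (integration windows, tolerance
defaults, the η definition, the initial-velocity rule), what the
synthetic generators do and do not emulate, and known limitations.
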