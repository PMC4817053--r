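---
title: "Quantifying protein oxidation and its functional consequences with oxiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein oxidation and its functional consequences with oxiquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxiquant)
```

## The problem

Reactive oxygen species oxidize proteins at specific residues —
methionine to methionine sulfoxide (+15.995 Da), cysteine to sulfenic,
sulfinic and sulfonic acids — and those modifications can change a
protein's structure and enzymatic activity. oxiquant packages the
quantitative machinery needed to ask, for a small enzyme such as the
125-residue phosphohistidine phosphatase PHPT1, three linked questions:

1. **Where and how much is the protein oxidized?** Site-specific
   oxidation stoichiometry from high-mass-accuracy LC-MS, via extracted
   ion chromatograms (XICs) of the oxidized and non-oxidized forms of
   each tryptic peptide.
2. **Does oxidation change catalytic activity?** A direct-infusion
   mass-spectrometric assay that watches a phosphohistidine peptide
   substrate being dephosphorylated in real time, and a colorimetric
   pNPP assay yielding Michaelis–Menten constants.
3. **Does oxidation change the conformational ensemble?** A
   per-residue "discriminability" statistic comparing two structural
   ensembles after least-squares superposition.

Every stage is paired with a synthetic-data generator that records its
own ground truth, so each estimator in the package is continuously
exercised against known answers.

## Peptide chemistry

All masses are computed from elemental composition using hard-coded
monoisotopic masses (5+ decimals) and IUPAC standard atomic weights, so
monoisotopic and average masses always describe the same molecule.
Charging uses the proton mass (1.007276 Da), not the hydrogen-atom
mass, and sodium/potassium adducts use the cation mass (neutral atom
minus one electron). Heavy-isotope peaks are placed at a fixed
+1.00336/z per isotope index (the ¹³C-dominated A+1 spacing); full
isotope fine structure is deliberately not modelled because the XIC
workflow only ever targets the monoisotopic and A+1 peaks.

The worked reference molecule throughout is the chromogenic
phosphatase substrate succinyl-Ala-His-Pro-Phe-*p*-nitroanilide
("Suc-AHPF-pNA"), whose phosphohistidine form is the substrate of the
infusion assay:

```{r}
substrate <- parse_peptide("Suc-AHPF-pNA")
substrate
phospho <- apply_modification(substrate, "ph", 2)
c(MH = adduct_mz(phospho, "H"), MNa = adduct_mz(phospho, "Na"),
  MK = adduct_mz(phospho, "K"))
```

Fragment ions (b/y series at charge 1) carry neutral-loss companion
peaks when asked: the −63.998 Da methanesulfenic-acid loss diagnostic
of oxidized methionine, and the −80/−98/−116 Da phosphate losses
characteristic of the acid-labile phosphohistidine P–N bond. Tryptic
digestion follows the standard rule — cleave after Lys/Arg, suppressed
before Pro — since the peptide-level workflow expects tryptic peptides
with up to one missed cleavage.

## XIC-based oxidation stoichiometry

For each site, the oxidized and non-oxidized species of the same
peptide backbone are extracted at a ±5 ppm tolerance on their
monoisotopic and A+1 m/z, integrated, and summarized as an
oxidized : non-oxidized AUC ratio per replicate. Group means of these
ratios give fold changes against the control group, with a two-tailed
homoscedastic Student t-test across replicates.

Two numerical choices deserve comment:

* **Integration window.** Bench software integrates peaks under manual
  cursor control; reproducibility requires a rule. The default window
  is the XIC apex extended on both sides until intensity falls to 1% of
  the apex. Explicit windows can be supplied instead.
* **Undefined ratios.** A replicate whose non-oxidized AUC is zero gets
  an `NA` ratio and a warning, and is excluded from the group mean —
  exclusion is conservative and leaves a visible trace, whereas
  imputation would manufacture information.

The LC-MS generator draws Gaussian elution peaks for both species (the
sulfoxide eluting slightly earlier, as on reversed phase), jitters
centroid m/z with a 1.5 ppm standard deviation, applies 5%
multiplicative intensity noise, and sprinkles low-level background
centroids. Its ground truth is exact: the injected AUC ratio of each
replicate equals the configured odds. What it does *not* emulate —
co-eluting interferences, isotope-envelope overlap, ionization
suppression, cross-run retention drift — bounds what a passing
recovery test shows about real data: the estimator is unbiased and
precise when the signal model holds, not that the signal model always
holds.

## The direct-infusion activity assay

The assay tracks six peaks per scan: nominal m/z 691/713/729
(substrate product, H⁺/Na⁺/K⁺) and 771/793/809 (phosphorylated
substrate). Spectra are averaged over left-closed right-open 5-minute
windows (0–5, 5–10, …), peaks are matched at ±0.3 m/z — a
unit-resolution tolerance appropriate to infusion peak lists and
deliberately separate from the 5 ppm LC-MS tolerance — and the
adduct-summed phospho : non-phospho intensity ratio is computed per
window.

**Fold changes are computed on the phosphorylation level, not on the
raw ratio.** Dephosphorylation converts substrate into product: as the
phospho peaks shrink, the product peaks grow. The intensity ratio
`r = P/N` therefore falls faster than the chemistry: with an initial
phosphorylated fraction f₀ = 0.375 decaying as f(t) = f₀·e^(−kt), the
ratio falls 159-fold over a window in which the phosphorylation level
falls 100-fold. The level `f = r/(1+r)` is the quantity whose
first-order decay matches the enzymology, so
`activity_fold_change()` reports fold = f/f̄(control) and
−log₁₀(fold), alongside the raw-ratio series for inspection. The
control reference is the mean over all control windows (the first,
dead-time-affected window is included by default; `t0` can exclude
it).

The infusion generator conserves intensity (conversion moves counts
from the phospho to the product family, never destroys them), supports
an in-source phosphate-loss fraction that transfers phospho signal to
product peaks in every scan — biasing the measured level low by a
factor (1 − s) that cancels exactly in fold changes — and optional
per-adduct rate multipliers for the observation that sodium and
potassium adducts can convert more slowly than the protonated form.
The default initial fraction 0.375 is the midpoint of the 35–40% yield
typical of aqueous phosphoramidate synthesis of phosphohistidine
peptides.

## Ensemble discriminability

Two conformational ensembles (e.g. oxidized vs non-oxidized, 3001
frames each from 150 ns of sampling at 50 ps, endpoints inclusive) are
first least-squares superposed onto a common reference with the Kabsch
algorithm — always a proper rotation — to remove whole-molecule
rotation and translation. Then, residue by residue, a discriminability
score η asks how well the two ensembles can be told apart at that
position.

**Definition used here.** η is the cross-validated balanced accuracy
of a ridge-regularized linear discriminant trained to label frames by
ensemble, using the residue's Cartesian coordinates as features
(stratified 5-fold CV, averaged over shuffled repetitions, seeded).
This is a reimplementation choice made deliberately and documented
prominently: it satisfies the properties that matter — η is bounded,
sits at 0.5 (chance) for identical ensembles, rises monotonically with
ensemble difference, and approaches 1 for disjoint ensembles — and for
isotropic Gaussian clouds it converges to the Bayes rate, e.g.
η ≈ Φ(1) ≈ 0.84 at a mean separation of twice the per-coordinate SD.
The conventional threshold η = 0.69, calibrated elsewhere as
equivalent to a 1 Å center-of-mass deviation, is exposed as a
configurable flag threshold (`eta_crit`), not rederived: that
calibration depends on the original ensembles, which are not inputs
here.

The generator draws per-residue isotropic Gaussian clouds (default
1 Å SD) around a deterministic helical reference, displacing a
configurable set of residues — frames are independent draws, not
dynamics, so passing calibration tests certifies the statistic, not
any force field. Null calibration at full scale (125 residues × 3001
frames, identical distributions) keeps every residue's η below 0.69.

## Colorimetric Michaelis–Menten kinetics

Absorbance at 405 nm converts to product concentration by Beer–Lambert
with ε = 17.8 mM⁻¹cm⁻¹ and a path length computed from well geometry
(volume/(πr²); 100 µl in a 4 mm-radius well gives 0.199 cm). Initial
velocities are the slope of the most linear portion of each progress
curve, operationalized as follows: all contiguous windows of 5–11
samples are scored by linear-fit R²; among windows within 0.02 of the
best R² — indistinguishable in linearity at plate-reader noise — the
earliest, then longest, window wins. The earliest-tie preference is
the initial-rate convention (least substrate depletion); the length
cap bounds depletion bias on slow curves. Window and R² are reported
with each velocity. The estimator is invariant to constant absorbance
offsets, so blank subtraction is immaterial.

Velocities at ≥3 substrate concentrations (default grid 0.8–40 mM
pNPP) are fitted to v = Vmax·S/(Km+S) by Levenberg–Marquardt least
squares; 95% CIs come from the linearized covariance (the delta
method, matching the commercial defaults such data are usually fitted
with), and kcat = Vmax/[E] with [E] defaulting to 2.1 µM. A velocity
vector that is constant across the grid carries no Km information; the
fit then returns Vmax as the mean velocity with an unbounded Km CI and
a `saturated` flag rather than failing obscurely. The progress-curve
generator integrates the Michaelis–Menten rate with substrate
depletion (0.01-min steps), so the initial-velocity estimator is
always tested against realistically curved data; recovery of (Km,
Vmax) within 5% at 0.005 AU absorbance noise is part of the test
suite. Fold-change comparisons between two fits propagate CIs on the
log scale.

## Scenario defaults and problem sizes

The `run_*_scenario()` functions reproduce each analysis end-to-end on
synthetic data at desk scale: 3 replicates per treatment group for the
oxidation scenario (control odds 0.01 with 9-, 26- and 41-fold dose
groups), a 30-minute infusion sampled every 10 s with 5-minute windows
for the activity scenario (treated rate ln(100)/10 min⁻¹, denatured
arm at 10% of it), and 125-residue × 3001-frame ensembles with a
shifted loop at residues 29–39 for the discriminability scenario.
Every report embeds the seed, a configuration hash and the package
version; reruns with the same seed are identical.

## Known limitations

* The XIC module quantifies configured species; it does not identify
  peptides, localize modifications, or estimate FDR — that is database
  search software's role upstream.
* Infusion intensity summation uses monoisotopic peaks only; isotope
  envelopes of the six species are not summed.
* η values are classifier-dependent by construction; the 0.69
  threshold is a convention carried over, not a package-derived
  constant.
* Initial-rate kinetics ignore substrate depletion in the estimator
  (it is modelled in the generator); global progress-curve fitting and
  inhibition models are out of scope.
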