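---
title: "Field-based 3D-QSAR and binding-affinity correlation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-based 3D-QSAR and binding-affinity correlation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldqsar)
```

## What this package models

`fieldqsar` implements the classical field-based 3D-QSAR workflow for a
*congeneric series*: a set of analogues sharing one scaffold, pre-aligned in a
common 3D frame, each with a measured pIC50 (−log10 molar IC50). The premise
of CoMFA/CoMSIA-style modelling is that, once the common scaffold is
superimposed, differences in activity are explained by differences in the
noncovalent fields the substituents project into the space around the
molecules. The package samples those fields on a lattice, relates them to
activity by partial least squares (PLS), validates the model internally and
externally, screens compounds through a leverage-based applicability domain,
and maps the model back onto 3D space as StDev\*Coeff contours. A separate
post-processing layer handles binding-free-energy bookkeeping: pIC50↔ΔG
conversion, linear interaction energy (LIE) and MM-PB/GBSA term assembly, and
experimental-versus-computed correlations with bootstrap standard errors.

Alignment, conformer generation, docking, and molecular dynamics are out of
scope: molecules arrive pre-aligned with partial charges, and energy tables
arrive computed. The package consumes those inputs; it does not produce them.

## Fields

Both field families are evaluated on a shared rectangular lattice
(`build_grid`), default spacing 2.0 Å, margin 4.0 Å beyond the union bounding
box of all molecules, origin anchored at the integer-Å floor so grids are
exactly reproducible.

**CoMFA (probe interaction energies).** At each lattice point an sp3-carbon-like
probe (radius 1.52 Å, charge +1 e) feels

* a steric Lennard-Jones energy
  $E_S(q) = \sum_i \varepsilon_i^* \left[ (R_i^*/r_{iq})^{12} - 2 (R_i^*/r_{iq})^{6} \right]$
  with $R_i^* = r_{\mathrm{vdw},i} + r_{\mathrm{probe}}$ and
  $\varepsilon_i^* = \sqrt{\varepsilon_i\,\varepsilon_{\mathrm{probe}}}$, and
* a Coulomb energy with distance-dependent dielectric
  $E_E(q) = 332.0636 \sum_i q_i q_{\mathrm{probe}} / r_{iq}^2$.

Both are truncated to ±30 kcal/mol. A probe exactly on an atom center counts
as inside the atom (steric = +30). Points whose *untruncated* steric energy
exceeds +30 kcal/mol for a molecule are flagged *sterically excluded* for that
molecule; the electrostatic value there is meaningless and is replaced by the
column mean over the non-excluded molecules when the descriptor matrix is
assembled — the behaviour long established in the originating implementations.

**CoMSIA (Gaussian similarity indices).** The hard LJ wall makes CoMFA fields
jagged near the molecular surface; CoMSIA instead uses
$A_k(q) = -\sum_i w_{\mathrm{probe},k}\, w_{ik}\, e^{-\alpha r_{iq}^2}$
with attenuation α = 0.3 Å⁻² and no distance cutoff. Per-atom weights
$w_{ik}$ are the cubic van der Waals radius (steric, S), the partial charge
(electrostatic, E), an atom-typed lipophilicity increment (hydrophobic, H),
and binary donor/acceptor indicators (D, A). The attenuation factor is
sometimes printed as σ in application papers; it is the exponential α of the
original method, with r in Å, and we use that convention.

**Frozen parameter tables.** Van der Waals radii are Bondi values; LJ well
depths are GAFF-like per-element values; hydrophobicity increments follow
Ghose–Crippen-style signs (apolar carbon/halogen positive, polar heteroatoms
and their hydrogens negative). The probe well depth (0.086 kcal/mol) is a
choice, not a published constant of the method. Donors are hydrogens within
1.3 Å of N/O; acceptors are all N/O — deliberately simple, geometry-based
typing that needs no bond table.

**Charges.** File-provided partial charges always win (MOL2 charge column, or
a `PARTIAL_CHARGES` data field in SDF). When a file carries none, a fallback
rule assigns residual-electronegativity charges (Pauling χ difference from
the molecular mean, scaled to ~0.1 e magnitudes, zero-sum). This is a crude
stand-in documented here precisely so nobody mistakes it for a
Gasteiger-class method: real studies should supply charges.

## Descriptor matrix and preprocessing

Columns are (lattice point × field kind). Preprocessing order is fixed:
first electrostatic imputation at sterically excluded points, then a
minimum-σ column filter dropping columns whose standard deviation over the
molecules falls below 2.0 kcal/mol (CoMFA kinds) or 0.05 similarity units
(CoMSIA kinds). The filter and the imputation means are computed **once on
the training set** and frozen: test compounds and design candidates are
projected through `apply_matrix_template`, never re-filtered, so the model's
descriptor space is immutable after training.

Within one field block no per-column autoscaling is applied (the CoMFA
convention — spatial contrast between columns *is* the signal). When several
field kinds enter one model, each block is divided by the pooled standard
deviation of its centered entries, so no kind dominates merely by its units.
This block-scaling choice is recorded in the fitted model and undone when
coefficients are reported on the raw descriptor scale.

## PLS, cross-validation, model selection

`fit_pls` is NIPALS PLS1 on the centered (block-scaled) matrix. Training
statistics use the classical definitions: r² = 1 − RSS/SS_tot,
SEE = √(RSS/(n−A−1)), F = (r²/A)/((1−r²)/(n−A−1)) for A components.

`loo_q2` computes PRESS(a) by genuinely refitting n leave-one-out models per
component count (centering and block scales are re-derived inside each fold;
the column set is not). Then q²(a) = 1 − PRESS(a)/SS_tot and
SEP(a) = √(PRESS(a)/(n−a−1)). The optimal number of components maximises q²,
ties broken toward fewer components, scan capped at 6 — the conventional
upper bound for series of this size — and additionally at (rank − 1) of the
centered matrix so degenerate single-field blocks are scanned only as far as
they can support. `bootstrap_r2` refits on row resamples (default 100),
redrawing degenerate resamples, and reports the mean and SD of resample r².

`field_combination_search` evaluates all 2ᵏ−1 non-empty subsets of the
candidate CoMSIA kinds by LOO q² on a shared pre-filtered matrix, ranking by
q², then fewer fields, then fewer components — the standard
permutation-combination protocol for choosing a CoMSIA descriptor subset.

A note on the F statistic: published model tables in this field occasionally
print F values that are not consistent with the standard formula above at
the stated n, r² and component count. `fieldqsar` implements the standard
formula and makes no attempt to reverse-engineer alternative conventions.

## Validation metrics

`regression_metrics` implements the Golbraikh–Tropsha/Roy family with the
through-origin conventions spelled out in its documentation: slopes k and
k′, through-origin determination coefficients r₀² and r′₀², and
r_m² = r²(1 − √(max(r² − r₀², 0))) with the difference clipped at zero so the
root stays real on adversarial inputs. Several r₀² variants circulate in the
literature; the definitions here are fixed and tested, which matters more
than which variant a given paper used. χ² uses |ŷ| in the denominator; on
pIC50 scales (5–9) this is benign. The internal block is computed on fitted
training predictions (not LOO predictions) — the common convention when a
published table does not say which was used.

`external_metrics` provides r_pred² = Q_F1² (training-mean reference), Q_F2²
(test-mean reference), Q_F3² (mean-squared-error ratio) and the concordance
correlation coefficient Q_ccc, which unlike Pearson r penalises location and
scale bias. `threshold_check` applies the published acceptance bounds
(q² > 0.5, r² > 0.6, r_pred² > 0.6, 0.85 ≤ k, k′ ≤ 1.15, |r₀²−r′₀²| < 0.3,
(r²−r₀²)/r² < 0.1, r_m² family > 0.5, χ² < 1, RMSE < 0.5); metrics without a
hard published bound are reported but marked "not evaluated".

## Applicability domain

Leverage is computed in latent space: h_i = 1/n + t_iᵀ(TᵀT)⁻¹t_i over the
training score matrix T; test compounds are projected against the same T.
The warning leverage is the standard Williams-plot h\* = 3(p+1)/n with
p = number of latent components, and standardized residuals use the
degrees-of-freedom-corrected training error (an essentially exact fit is
treated as having zero residuals rather than 0/0). A compound is in-domain
iff h ≤ h\* and |standardized residual| ≤ 3. Published Williams plots
sometimes quote h\* values that do not follow from 3(p+1)/n at the stated n
and component count; this package reports only the formula value.

## Contours

`stdev_coeff` multiplies each active column's standard deviation by its PLS
coefficient, both in the model's scaled space so kinds are comparable.
`extract_contours` thresholds the signed distribution per field kind at the
80th/20th percentiles by default (the customary favored/disfavored levels —
application papers rarely state theirs); favored points must additionally be
strictly positive and disfavored strictly negative, so an all-zero map yields
empty sets and the two sets are always disjoint. Exports: OpenDX scalar
grids per field kind and PDB pseudo-atoms (residues `FAV`/`DIS`) for viewer
overlay.

## Binding-affinity post-processing

`pic50_to_dg` uses ΔG = −RT ln(10)·pIC50 with R = 1.98720425×10⁻³
kcal/(mol·K), default T = 300 K (an MD thermostat's target). Published
ΔG_EXP tables sometimes imply a slightly different effective temperature
(RT·ln10 ≈ 1.381 corresponds to ≈302 K), which is why T is configurable.
`lie_energy` is ΔG = ½ΔE_cou + ½ΔE_vdW over bound→unbound changes;
`mmpbsa_total` is ΔE_vdW + ΔE_ELE + ΔE_GB + ΔE_SA − TΔS, cross-checked
against the ΔE_MM + ΔG_sol − TΔS grouping. `correlate` drops excluded
complexes and incomplete pairs listwise, then reports Pearson R with a
bootstrap standard error (default 1000 resamples, degenerate resamples
redrawn and counted).

The package ships the eight-complex wild-type/mutant kinase energy table it
was developed against (`flt3_binding_energies()`). Recomputing the
correlations over the seven wild-type complexes reproduces the published
FEP coupling exactly at two decimals (0.71) and the MM-PB/GBSA and rupture
force couplings within ±0.02 of the printed values (0.92, −0.55) — the small
differences being rounded-input effects. The printed LIE coupling (0.60) is
*not* recoverable from the rounded table: the recomputation gives ≈0.49.
Whether the original value used unrounded inputs or a different pairing is
unknowable from the table alone; `fieldqsar` reports the recomputed value
and flags the discrepancy rather than adjusting anything toward the print.

## The synthetic series: what it emulates, what it does not

Real congeneric series with published coordinates are rare, so the package
generates its own (`generate_series`): a rigid, planar, pteridinone-like
fused bicycle (fixed coordinates — every analogue is born aligned), three
substitution sites, and an eight-member substituent library (H, methyl,
ethyl, methoxy, amino, hydroxyl, chloro, trifluoromethyl pseudo-groups with
fixed local geometry and frozen charges). Default 35 compounds, unique
substitution patterns sampled under seed.

The planted truth is a linear function of CoMSIA field values at one probe
point per site — computed by the *same* field code the pipeline uses, so the
generator plants exactly the kind of signal the method assumes: bulk favored
at R1 and R3 (+1.0 each on S), bulk mildly penalised at R2 (−0.4 on S) and
hydrophobicity favored at R2 (+3.0 on H). The H weight is larger because the
hydrophobic similarity index spans about a third of the steric one's range
over this library, and because steric and hydrophobic bulk are strongly
collinear (r ≈ 0.77 at R2): the weights equalise the variance each planted
channel contributes so that a correct method must keep both fields. These
weights were fixed at design time as part of the generator's definition.

The noiseless signal is affinely mapped onto the target span (default
pIC50 5.26–8.80), Gaussian noise (default σ = 0.3 log units) is added, and
the noisy vector is rescaled onto the span once more so the generated series
attains the stated range exactly. σ remains interpretable in log-activity
units to within the small second rescale.

`split_train_test` ranks by activity, cuts tertiles, and samples the test
picks (default 9 of 35) proportionally across tertiles under seed — the
low/medium/high stratified protocol, guaranteeing both sets span the
activity range.

What passing on this system shows: the pipeline recovers a planted linear
field–activity relationship of realistic size, noise and collinearity, and
the combination search identifies which property channels carry signal. What
it does not show: robustness to alignment error, conformational flexibility,
tautomers, charge-model artefacts, or activity cliffs — none of which the
generator emulates. Results on the synthetic series are a correctness
check, not a claim about prospective performance on real chemistry.

`generate_energy_table` draws (experimental, computed) pairs from a
bivariate normal with a requested population correlation, for testing the
correlation and bootstrap machinery at scale.

## Numerical choices and degenerate inputs

* CoMFA truncation ±30 kcal/mol; r² floored at 10⁻¹² Å² (probe on an atom).
* NIPALS stops with an explicit rank error when the residual covariance
  collapses (‖Xᵀy‖ < 10⁻¹²).
* Degenerate descriptor matrices (every column filtered) raise an error;
  all-excluded electrostatic columns become NA and are filtered.
* Ties in ONC selection go to fewer components; ties in the combination
  ranking to fewer fields, then fewer components.
* Zero-variance activity vectors, singular TᵀT, and sub-minimal sample
  sizes raise immediate, named errors rather than propagating NaN.
* All stochastic operations (bootstraps, generators, splits) take explicit
  seeds and are exactly reproducible.

## Problem sizes used by the shipped tests

The test suite and the reproduction script run the full pipeline on the
35-compound synthetic series (26/9 split) over ten generator seeds, the
field-combination search over all 31 subsets of five kinds, LOO at up to six
components, 20–100 bootstrap resamples in tests (1000 in the script's
correlation block), and a 5000-row synthetic energy table for the
correlation-recovery check. These sizes exercise every code path at the
scale the method is designed for — field-based QSAR is a small-n method —
while keeping the whole suite fast.

## Known limitations

* No alignment: garbage in, garbage out if the input frames differ.
* The fallback charge rule is deliberately primitive; supply real charges.
* CoMFA electrostatic imputation uses training column means; other
  implementations offer more elaborate schemes (we do not).
* No region focusing, H-bond CoMFA variants, SAMPLS, or progressive
  scrambling; no Y-randomisation beyond the permutation checks in the tests.
* The hydrophobicity increments are atom-typed constants, not a fitted
  logP decomposition.
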