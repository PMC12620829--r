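---
title: "Model and methods behind adasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind adasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adasim)
```

# The problem

Anti-drug antibodies (ADA) against protein therapeutics can accelerate
drug clearance and erode efficacy, but ADA positivity alone is a poor
predictor of clinical relevance: many ADA-positive patients keep normal
drug exposure. `adasim` simulates both layers at once — whether ADA
form, and whether they matter for pharmacokinetics — in virtual
clinical trials, and summarises the second question with the molar
ratio of the peak total ADA concentration to the drug concentration the
same subject would have had without ADA ([ADA]:[Drug]).

# Model structure

## Minimal PBPK

The drug distributes over plasma, a lymph-node compartment, and a
lumped tissue split into vascular, endosomal and interstitial spaces.
Transport is plasma flow between plasma and the tissue vascular space,
and convective lymph flow across the capillary wall with a vascular
reflection coefficient $\sigma_v$ (flux $Q_{lymph}(1-\sigma_v)C_v$),
returning to plasma through interstitium and lymph node at $Q_{lymph}$.
Elimination is a single linear plasma clearance (subject-specific);
the endosomal space is structural and exchanges with the vascular
space at first-order rates. FcRn recycling and target-mediated
disposition are deliberately not modelled: clearance values are meant
to be fitted to clinical PK, which absorbs those processes for the
mAb-like molecules the package targets. Subcutaneous dosing is a
first-order depot receiving the bioavailable fraction; infusions are
zero-order inputs; IV boluses are state jumps between integration
segments (the solver never steps across a discontinuity, and sampling
exactly at a dose time reports the pre-dose trough).

Internal units are nM and hours throughout; mg doses and ng/mL assay
thresholds are converted at the boundary via molecular weight. The
lymph-node inflow/outflow topology and the reflection coefficient are
not identifiable from plasma PK; the defaults
(`physiology_parameters()`) are documented assumptions for a 70 kg
adult and can be overridden or sampled.

## Immune response

The humoral cascade lives in the lymph node and blood: immature
dendritic cells mature under antigen stimulus (plus a small
constitutive flux that maintains a baseline mature pool), drug-specific
naive CD4+ T cells are activated per epitope by

$$D_{epitope} = \frac{ID_m}{ID_m + T_{tot}}\cdot\frac{S}{S + K_{Ag,N}},
 \qquad S = DC_{uptake}\cdot AgVS \cdot
 \sum_{alleles}\left(\frac{100}{EL_{rank}} - 1\right)^2 ,$$

where $AgVS$ is the drug concentration in the tissue vascular space
and the sum runs over the elution ranks of that epitope for the
alleles the subject expresses (homozygous loci contribute an allele
once; allele–epitope pairs missing from the rank table contribute
nothing, equivalent to the maximal rank of 100). The leading term is
read as the fraction $ID_m/(ID_m+T_{tot})$ — a dendritic-cell
availability factor bounded by one; an unbounded product would be
dimensionally inconsistent with a saturating activation function.
Whether the allele sum should span all six expressed class II
specificities or only the locus of each prediction is ambiguous; all
expressed specificities are used.

Activated T cells proliferate logistically with a rate gated by a
steeper (squared) saturation in the same presented-antigen signal,
$S^2/(S^2 + (0.75\,K_{Ag,N})^2)$: subjects whose HLA genotype gives a
strong presentation signal expand clones, subjects below the gate do
not, which reproduces the carrier/non-carrier dichotomy seen with
risk-allele-restricted epitopes. B-cell activation requires antigen in
blood and only a trace of cognate T help (small half-constant), while
B-cell clonal expansion requires an expanded T compartment (large
half-constant). This split produces two regimes observed in ADA
assays: a low-level "trickle" of ADA near the assay detection limit in
subjects without T-cell expansion, and a full plasma-cell response in
subjects with expansion. Short- and long-lived plasma cells secrete a
lumped IgG ADA pool (150 kDa) that binds free drug 1:1
($k_{on}/k_{off}$); the complex is cleared at $k_{IC}$ and the drug
mass balance reflects the loss. Methotrexate co-medication follows a
closed-form two-compartment oral PK model and multiplies the T-cell
proliferation rate by the inhibitory Emax factor
$1 - I_{max}c/(IC_{50}+c)$ with the default $IC_{50}$ of 283 nM.

The cell-lineage rate constants are structural stand-ins, assumed
rather than taken from a single literature source (`immune_rates()`
documents each). They were chosen once so that a strongly presented
epitope set seroconverts a typical subject within about four weeks of
repeated dosing, a weakly presented set does not drive clonal
expansion, and the joint behaviour of the shipped scenarios reproduces
the qualitative exposure-impact fingerprints that motivate the
[ADA]:[Drug] metric (see below). `K_{Ag,N}` defaults to a value in the
sensitive range of the shipped scenarios; `calibrate_k_ag_n()` refits
it to observed incidences by RMSE minimisation, which is how the
constant is meant to be set against real data.

## Decoupled limits

With the immune module switched off, an empty epitope list, or zero
dendritic-cell uptake, the cascade cannot leave its initial state and
the drug kinetics decouple exactly. These limits are routed through
the identical PK-only integration path, so "immune off" and
`simulate_pk_only()` agree bit for bit rather than to solver
tolerance; the paired PK-only run of every trial subject uses the
same physiology, clearance and genotype by construction.

# Virtual trials

A virtual population (default n = 250) samples per-subject physiology
and clearance from lognormal distributions parameterised by mean and
CV (so the arithmetic mean and CV match the configuration exactly;
CV = 0 degenerates to the mean), and an HLA class II genotype — two
independent draws per locus (DRB1 allele, DQ and DP haplotypes) from a
frequency table, allowing homozygosity. Frequency tables aggregate
study-level data by sample-size-weighted averaging followed by
per-locus renormalisation; whether a residual "other alleles" class
should be carried instead of renormalising is not determinable from
typical published tables, and renormalisation was chosen.

Each subject is simulated twice (full and PK-only) on the union of the
ADA and PK sampling grids. ADA positivity requires the total ADA
concentration (free plus complexed, as a binding assay would see) to
strictly exceed the assay threshold at at least one sampled ADA time;
concentrations between sampling times are ignored. The threshold
defaults to the FDA minimum recommended sensitivity of 100 ng/mL when
a study-specific value is not configured. The exposure impact verdict
compares free plasma drug at the final sampling time between
ADA-positive and ADA-negative subjects with a two-sided Wilcoxon
rank-sum test (exact for small tie-free groups, tie-corrected normal
approximation with continuity correction otherwise): "impact" requires
both p < 0.05 and a lower ADA-positive median, so a significant
*increase* is never read as impact; fewer than two ADA-positive
subjects (a configurable minimum chosen so the comparison has any
variance) yields "not assessable".

The [ADA]:[Drug] ratio divides the maximum total ADA over the sampled
ADA times (assay realism; the continuous maximum is not observable) by
the PK-only free plasma drug at the final ADA sampling time, both in
nM. It is 0 when ADA never form and +Inf (flagged) if the PK-only
concentration is zero. `dose_adjustment_scan()` reruns the same
population under twice the dose amount and half the dosing interval
and reports the fraction of subjects with ratio > 1 under each label
(`Study Dose`, `2xDose`, `2xFreq`).

# Synthetic scenarios and what they do (and do not) show

All tests and examples run on fully synthetic inputs
(`fixture_scenario()`): a random 89-residue sequence, a toy
self-proteome, an allele-structured elution-rank table, and a
placeholder HLA frequency table with the 11 DRB1 / 6 DQ / 6 DP
structure of the common class II reference set. The rank tables put a
minority of "presenter" alleles at the strong end of each scenario's
band ((0.1, 2] for `high_risk_drug`, [20, 100] for `low_risk_drug`),
because real class II predictions are allele-structured and this is
what makes ADA risk genotype-dependent. The high-risk drug is a
100 mg SC Q2W mAb-like compound; the low-risk drug is dosed at 300 mg
Q2W with lower clearance (a high-exposure regimen) and carries a
higher drug-specific naive T-cell precursor frequency, the kind of
compound-specific input an experimental package would supply.

Under the shipped seeds the high-risk scenario produces roughly 70–80%
incidence with an impact verdict and ratios spanning about four orders
of magnitude, and the low-risk scenario roughly 20% incidence of
low-level ADA with a no-impact verdict and all ratios far below 1.
Subjects with ratio < 0.3 lose at most a fraction of a percent of
trough exposure, while subjects with ratio > 1 lose most of it — the
two fingerprints the ratio metric is designed to separate. Passing
these checks shows the machinery is internally consistent and the
metric behaves as intended on data whose ground truth is known; it
does not validate predictions for real compounds, which require real
NetMHCIIpan-style rank tables, measured uptake and precursor
frequencies, fitted clearances and population HLA frequencies.

# Numerical choices

The coupled 18-state system is integrated with `deSolve::lsoda`
(compiled right-hand side; an R reference implementation is
cross-checked against it in the tests) at rtol 1e-8 and atol 1e-10,
with bolus doses applied as state jumps between integration segments.
Transient solver undershoot below zero is clamped inside the
right-hand side before computing fluxes, and outputs are floored at
zero. Methotrexate concentrations enter as a closed-form forcing
(eigen-decomposition of the linear PK system, superposed over doses)
rather than extra states. `calibrate_k_ag_n()` pre-screens a log-space
grid, zooms once around the bracketing minimum (the objective is
stepwise for finite cohorts, which defeats plain golden-section
search), and polishes with `optimize`; simulated incidence is monotone
non-increasing in the constant when positivity is driven by expanded
responses, so recovery is well-posed. Tests and the acceptance script
use 250-subject trials (the default trial size) for study-level
quantities and 40–100 subjects for property checks; a paired
250-subject trial takes on the order of seconds.

# Known limitations

Bivalent ADA binding, affinity maturation, isotype switching,
regulatory T cells, immune-complex-enhanced presentation and
target-mediated disposition are out of scope. The immune rate table is
a calibrated structural stand-in, not a measured parameter set; only
the activation function, the methotrexate model, the trial design
logic and the ratio metric carry quantitative meaning independent of
it. Exact-substring self-filtering is a deliberate, reproducible
surrogate for an alignment screen against the human proteome; users
with real BLAST output can supply a pre-filtered candidate list
instead.
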