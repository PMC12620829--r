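# adasim

Quantitative systems pharmacology simulation of anti-drug antibody
(ADA) formation against protein therapeutics, and of its impact on
drug exposure, in virtual clinical trials.

ADA positivity does not always translate into loss of drug exposure.
`adasim` couples a minimal physiologically based pharmacokinetic
(PBPK) model — plasma, lymph node, and a lumped tissue with vascular,
endosomal and interstitial spaces — to a mechanistic ODE model of the
humoral immune response: dendritic cells, drug-specific CD4+ T and B
lineages, plasma cells, ADA secretion, and 1:1 ADA–drug complex
formation and clearance. T-cell activation by each selected epitope is
driven by MHC class II elution-rank scores restricted to the alleles a
virtual subject carries:

    D = ID_m / (ID_m + T_tot) * S / (S + K_Ag_N),
    S = DC_uptake * AgVS * sum_alleles (100 / EL_rank - 1)^2

with `AgVS` the drug concentration in the tissue vascular space (nM).
Methotrexate co-medication inhibits T-cell proliferation through an
inhibitory Emax model (default IC50 283 nM). For every subject the
trial engine runs the full model and a paired PK-only simulation on
the same parameter set, classifies ADA positivity against an assay
threshold (default 100 ng/mL, the FDA minimum recommended
sensitivity), tests for an exposure impact with a Wilcoxon rank-sum
comparison of free drug at the final sampling time, and computes the
**[ADA]:[Drug] molar ratio** — peak total ADA (nM) over the drug
concentration (nM) the subject would have had without ADA — the
model-informed metric separating clinically relevant immunogenicity
(ratio above ~1) from inconsequential ADA.

The sequence pipeline enumerates all 15-mer candidate peptides from a
protein sequence or eluted-peptide list, removes candidates occurring
verbatim in a self-proteome, and greedily selects up to five
non-overlapping epitopes with the lowest (strongest) elution rank
across the HLA reference set. Virtual populations sample lognormal
physiology/clearance and HLA class II genotypes (11 DRB1 alleles, 6 DQ
and 6 DP haplotypes) from study-size-weighted frequency tables.

## Worked example

Everything below is fully synthetic and seeded
(`fixture_scenario()` builds the drug, rank table, HLA table, regimen
and sampling schedule; no external data are needed).

```r
library(adasim)

sc  <- fixture_scenario("high_risk_drug")       # 100 mg SC Q2W, strong epitopes
pop <- scenario_population(sc, n = 250, seed = 1)
tr  <- run_trial(pop, sc$drug, sc$regimen, sc$schedule, seed = 1)
tr
#> <ada_trial> synthetic high-risk mAb: 250 subjects (0 failed)
#>   ADA incidence: 74.0% (threshold 100 ng/mL)
#>   exposure impact: impact (Wilcoxon p = <2e-16)
#>   max [ADA]:[Drug] ratio: 2.65
summary(tr)
#> Virtual trial of synthetic high-risk mAb (n = 250, 0 solver failures)
#>   ADA incidence:        74.0%
#>   exposure verdict:     impact (p = 1.94e-20)
#>   median free drug:     ADA+ 2.46 / ADA- 121 nM
#>   [ADA]:[Drug] > 1:     53.6% of subjects
#>   ratio quantiles:
#>      0%     25%     50%     75%    100%
#> 0.00299 0.00608 1.09000 1.41000 2.65000
```

74% of subjects seroconvert; those whose ADA exceed the molar drug
concentration (ratio > 1) lose most of their trough exposure (median
free drug 2.5 vs 121 nM), while ADA-positive subjects with ratio
below 0.3 lose under 1%. `plot(tr)` draws the fingerprint (free drug
at the final sampling time against the ratio, ADA-positive subjects in
red, paired PK-only concentrations in grey).

Dose adjustment as a mitigation strategy — same population, doubled
dose or doubled frequency:

```r
dose_adjustment_scan(scenario_population(sc, n = 100, seed = 1),
                     sc$drug, sc$regimen, sc$schedule, seed = 1)
#>      regimen fraction_ratio_gt_1
#> 1 Study Dose                0.48
#> 2     2xDose                0.08
#> 3     2xFreq                0.04
```

Both adjustments shrink the fraction of subjects whose ADA exceed the
molar drug concentration, because the expanded ADA response saturates
while exposure doubles.

A command-line interface mirroring the R functions is installed at
`inst/cli/adasim` (subcommands `fixtures`, `epitopes`, `population`,
`simulate`, `analyze`, `scan-dose`; `--seed`, `--config`, `--out`).

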