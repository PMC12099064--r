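# seqMSI

Microsatellite instability (MSI) calling from amplicon sequencing of a
mononucleotide marker panel, and concordance analysis against mismatch
repair (MMR) protein immunohistochemistry (IHC).

MMR deficiency testing of tumours is the entry point to Lynch syndrome
screening. IHC of the four MMR proteins (MLH1, PMS2, MSH2, MSH6) is the
clinical standard; sequencing-based MSI analysis is the scalable functional
alternative: MMR-deficient tumours accumulate deletions in mononucleotide
microsatellites, visible as shifted repeat-length spectra in deep amplicon
sequencing. seqMSI is for bioinformaticians and method developers who want
the complete desk side of such an assay — extraction, scoring, simulation
and evaluation — as a reproducible, testable package.

## What it implements

**From reads to spectra.** `extractSpectra()` assigns each FASTQ read to at
most one panel marker by exact flank anchoring (forward or reverse
complement) and records the number of complete repeat-unit copies between
the anchors. `qcPass()` applies the clinical depth rule: median per-marker
depth ≥ 100 (lower-median convention).

**The MSI score.** For each marker, two features: the deletion frequency
(fraction of reads below the sample-specific reference length) and the
allelic bias (concentration of deletion reads on one length — clonal
deletions are unimodal, PCR stutter is dispersed). With Beta class
conditionals fitted per marker (`fitMsiModel()`), the score is the
naive Bayes log Bayes factor

```
S = prior log odds + Σ_markers Σ_features [ log f(x | MSI-H) − log f(x | MSS) ]
```

`S > 0` calls MSI-high, `S < 0` calls microsatellite stable (MSS); scores
inside a confirmation band (default ±5) require a repeat assay, and
conflicting repeats yield an `uncertain` call with the score set to 0
(`classifyMsi()`).

**Synthetic cohorts.** `simulateCohort()` generates seeded cohorts with
deletion-biased geometric-tail PCR stutter, a clonal somatic deletion allele
(default fraction 0.35 in MSI-H samples), an attenuated "MSH6-like" subclass
mimicking isolated MSH6 deficiency, Poisson depths (default 2000×), and
IHC-style truth annotations. `emitReads()` writes FASTQ that inverts exactly
through `extractSpectra()`.

**Concordance statistics.** `deriveMmrClass()` (heterodimer-aware IHC
logic), `diagnosticSummary()` (cross-tabulation, sensitivity/specificity
with exact CIs), `clopperPearson()`, `fisherExact2x2()`, `fisherExactRxC()`
(full enumeration with an explicit budget — no silent approximation),
`mannWhitney()`, `kruskalWallis()`, `rocAuc()`.

## Worked example

Train on one seeded synthetic cohort split, score held-out samples:

```r
library(seqMSI)
panel <- defaultPanel()     # 14 synthetic poly-A markers, ref lengths 18-27
sim <- simulateCohort(simulationConfig(seed = 42, n_mss = 10, n_msih = 6,
                                       n_msh6like = 2, depth_mean = 2000),
                      panel)
train <- c(1:5, 11:15)      # 5 MSS + 5 MSI-H
model <- fitMsiModel(sim$spectra[train], sim$truth$true_class[train], panel)
res <- scoreCohort(sim$spectra[c(6:10, 16:18)], model, panel)
res$true_class <- sim$truth$true_class[c(6:10, 16:18)]
res
#>   sample_id msi_score   qc  call needs_repeat true_class
#> 1      S006  -14361.7 TRUE   MSS        FALSE        MSS
#> 2      S007  -14241.1 TRUE   MSS        FALSE        MSS
#> 3      S008  -14206.5 TRUE   MSS        FALSE        MSS
#> 4      S009  -14334.6 TRUE   MSS        FALSE        MSS
#> 5      S010  -14493.4 TRUE   MSS        FALSE        MSS
#> 6      S016   10076.2 TRUE MSI-H        FALSE      MSI-H
#> 7      S017   -1701.1 TRUE   MSS        FALSE  MSH6-like
#> 8      S018   -1789.7 TRUE   MSS        FALSE  MSH6-like
```

Every MSS and MSI-H sample is called correctly and with high confidence —
the deletion features separate sharply at 2000× depth. The two MSH6-like
samples score far closer to zero than the MSS samples and are called MSS:
the attenuated instability of isolated MSH6 deficiency, which commonly
misclassifies as MSS in practice, emerges from the reduced clonal deletion
fraction alone.

The package also ships the reference screening cohort's published
cross-tabulations (107 consecutive sebaceous tumours) and recomputes their
headline statistics:

```r
st <- referenceStatistics()
st$concordance$sensitivity
#> sensitivity 83% (40/48, CI 70-93%)   # MSI-H among conclusive MMR-deficient
st$tumour_type_fisher$p_value
#> [1] 0.004736238                      # IHC class x tumour type, 3x3 exact
```

A command-line front end (`inst/scripts/seqmsi`, or `msiCli()` in R) exposes
`simulate`, `extract`, `train`, `score`, `concord` and `refcheck`
subcommands with conventional exit codes.

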