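---
title: "Scoring microsatellite instability from amplicon spectra: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring microsatellite instability from amplicon spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqMSI)
```

# The problem

Mismatch repair (MMR) deficiency is the tumour biomarker that triggers Lynch
syndrome screening. The clinical standard is immunohistochemistry (IHC) of
the four MMR proteins (MLH1, PMS2, MSH2, MSH6); microsatellite instability
(MSI) analysis is the functional alternative: MMR-deficient tumours
accumulate deletions in mononucleotide repeats, which amplicon sequencing of
a small marker panel can detect at high depth. seqMSI implements the full
desk side of such an assay: converting reads to per-marker repeat-length
spectra, scoring samples with a naive Bayes classifier, and quantifying
concordance with IHC.

# From reads to spectra

Reads are assigned to markers by exact flank anchoring: a read (or its
reverse complement) belongs to the first panel marker whose 5' flank occurs
in it with the 3' flank downstream. The repeat length recorded is the number
of *complete* repeat-unit copies immediately after the 5' flank — partial
trailing units are ignored so lengths are always in whole units, which keeps
the definition identical across mono- and dinucleotide markers. Reads
matching no marker are counted as unassigned, so read totals are conserved.

Exact substring anchoring is a deliberate design choice: it is deterministic,
dependency-free and exactly invertible against the read emitter
(`extractSpectra(emitReads(s)) == s`), which makes the extraction layer
testable to equality. It does not tolerate sequencing errors inside a flank;
a production deployment would align reads instead. The scoring layer is
agnostic to the origin of spectra and accepts the spectra TSV from any
upstream extractor.

Sample QC follows clinical practice: a sample passes when the median
per-marker depth is at least 100. With an even marker count the *lower*
median (the lower of the two central order statistics) is used — the
conservative choice, and one that must be fixed for reproducibility: with
half the markers at high depth and half dropped out, the lower median is 0
and the sample fails QC.

# The MSI score

Two features summarise each marker's spectrum:

* **deletion frequency** — the fraction of reads with repeat length strictly
  below the sample-specific reference length;
* **allelic bias** — among deletion reads, the fraction carrying the single
  most frequent deleted length. A clonal somatic deletion is unimodal (bias
  near 1); PCR stutter spreads across lengths (low bias).

The sample-specific reference length is the modal observed length when that
mode is within one unit of the panel reference, otherwise the panel
reference. This tolerates germline length polymorphism (±1 unit) without
absorbing genuine somatic deletions, which in MMR-deficient tumours are
typically several units. Modal ties are broken towards the length closest to
the panel reference, then towards the longer allele.

The classifier is naive Bayes with Beta class conditionals. For each marker
$m$, class $c \in \{\mathrm{MSS}, \mathrm{MSI\text{-}H}\}$ and feature
$f \in \{\text{del\_freq}, \text{allelic\_bias}\}$ a Beta$(\alpha_{mcf},
\beta_{mcf})$ density is fitted by the method of moments on training values
shrunk into the open unit interval by $x \mapsto (xn + 0.5)/(n+1)$, $n$ the
class sample count. The MSI score of a sample is the natural-log Bayes
factor

$$ S = \log\frac{P(\text{prior MSI-H})}{P(\text{prior MSS})} + \sum_{m}
\sum_{f} \left[ \log f_{m,\mathrm{MSI\text{-}H}}(x_{mf}) -
\log f_{m,\mathrm{MSS}}(x_{mf}) \right]. $$

$S > 0$ favours MSI-H, $S < 0$ favours MSS. Markers with zero depth are
simply omitted — under naive Bayes, missing evidence marginalises out
cleanly. Numerical safeguards: densities are floored at $10^{-300}$ before
the log, and features are always shrunk away from $\{0,1\}$ (at scoring
time, each class's density is evaluated at the value shrunk with that
class's training count, the same transform used in fitting; this keeps the
label-swap symmetry $S \mapsto -S$ exact when class sizes are equal).

Design notes on genuinely open choices:

* *Density family.* Beta conditionals over (deletion frequency, allelic
  bias) are the natural exponential-family choice for proportions and match
  the additive signed-score behaviour of the clinical assay; a joint model
  of the two features was rejected to keep training stable at clinical
  cohort sizes.
* *Method of moments, not maximum likelihood.* Closed form, no iteration or
  convergence failures; when the moment solution is invalid (variance at
  least mean·(1−mean), including the degenerate zero-variance case) the cell
  falls back to the uninformative Beta(1,1), which contributes nothing to
  the score — a conservative failure mode.

## Calls, the confirmation band and the repeat rule

Clinically, scores near 0 are not trusted: scores within a confirmation band
(default half-width 5 on the log-Bayes-factor scale) require a repeat assay.
The decision rule implemented by `classifyMsi()`:

* QC failure → call `fail`, always.
* $|S| \ge$ band → call by sign, no repeat needed.
* $|S| <$ band → repeat requested. A repeat score of the same sign confirms
  the call; a conflicting (opposite-signed or zero) repeat yields
  `uncertain` with the reported score set to 0. We apply the conflict rule
  whatever the repeat's magnitude — an opposite-signed repeat outside the
  band still indicates an unstable measurement. A score of exactly 0 with
  no repeat is `uncertain`.

The band half-width is a tunable parameter: its clinical value was
established on the training scale of a colorectal-cancer-trained model, and
an independently trained model (as here) produces scores on its own scale.
All classification guarantees in this package are therefore stated in terms
of call semantics, not absolute score values.

# The synthetic cohort generator

No public training cohort accompanies the assay, so the package treats the
trained model as an exchangeable input and ships a seeded generator whose
defaults define the study conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `depth_mean` | 2000 | Poisson mean per-marker read depth (the assay's design depth) |
| `stutter_rate` | 0.002/unit | per-unit slippage probability per read |
| `somatic_fraction` | 0.35 | clonal fraction of the somatic deletion allele in MSI-H |
| `msh6_fraction_multiplier` | 0.35 | attenuation of the somatic fraction in the MSH6-like class |
| `somatic_del_units` | 3 | somatic deletion size, repeat units |
| `n_mss`, `n_msih`, `n_msh6like` | 50 / 30 / 10 | cohort composition |

Each read draws its template (reference allele, or the somatic deletion
allele at the clonal fraction), then PCR stutter removes $D$ units:
$D = 0$ with probability $(1-r)^{L}$ for a template of $L$ units and stutter
rate $r$; otherwise $D$ is 1 plus a Geometric(0.5) tail, truncated at the
template length. Stutter is deletion-only — the dominant error mode for
mononucleotide repeats; insertion stutter, flank sequencing errors, FFPE
artifacts and tumour-purity gradients are deliberately not modelled. The
somatic fraction of 0.35 represents a typical tumour-cell content after
macrodissection with a heterozygous clonal deletion; the MSH6-like
multiplier reproduces the attenuated instability of isolated MSH6
deficiency (redundancy between the MutSα and MutSβ heterodimers), whose
hallmark — lower MSI scores, frequent misclassification as MSS — the
simulated class reproduces qualitatively.

Simulated samples also carry IHC-style truth annotations so the concordance
layer can be exercised end to end: MSS samples retain all four proteins,
MSH6-like samples show isolated MSH6 loss, and MSI-H samples draw a staining
pattern from the empirical distribution of MMR-deficient patterns in the
reference cohort (MSH2/MSH6 co-loss the majority; MLH1/PMS2-family patterns
next; the isolated-MSH6 rows are reserved for the MSH6-like class so the
class semantics stay disjoint).

What passing the synthetic tests shows — and what it does not: the default
cohort is strongly separated (deletion fractions of ~0.37 vs ~0.04 at 2000×
depth), so perfect recovery there demonstrates the correctness of the
plumbing and the internal consistency of features, model and decision rule,
not clinical sensitivity on borderline real specimens, where tumour content,
stutter dispersion and marker informativeness all vary.

# The concordance toolkit

IHC truth enters as per-protein statuses; `deriveMmrClass()` maps them to a
class with the precedence *uninterpretable → NA*, else *any loss → MMRd*,
else *any equivocal → equivocal*, else *MMRp*. Loss outranking equivocal
matters: equivocal MLH1 staining with clear PMS2 loss is MMR-deficient (the
MutLα heterodimer logic), not equivocal.

Sensitivity and specificity of MSI calling take IHC as the reference and are
computed on conclusively classified samples only: equivocal/NA IHC and
uncertain/failed MSI calls are excluded from the denominators (but retained
in the cross-tabulation, which always conserves counts). Exact
Clopper–Pearson intervals (Beta-quantile closed form) accompany every
proportion.

The exact tests are implemented to fixed contracts: the r×c Fisher test
enumerates *all* tables with the observed margins and sums multivariate
hypergeometric probabilities not exceeding the observed table's (relative
tolerance $10^{-7}$ guards float comparison), refusing tables with total
count above the enumeration budget (200) rather than silently switching to
an approximation. The 2×2 case defers to the standard conditional-MLE
implementation in `stats`, with the zero-margin convention $p = 1$. The
Mann–Whitney test is exact for combined samples of at most 12 without ties
and otherwise uses the tie- and continuity-corrected normal approximation;
Kruskal–Wallis uses the χ² approximation throughout (standard practice; an
exact version is out of scope, and all-identical input returns H = 0,
p = 1 rather than a division by zero). ROC AUC is the Mann–Whitney
pair-counting statistic with ties counted half.

On the shipped reference-cohort tables (a consecutive sebaceous-tumour
screening series, n = 107), `referenceStatistics()` recomputes sensitivity
40/48 = 83% (CI 70–93%), specificity 52/52 = 100% (CI 93–100%), MMR
deficiency 49/104 = 47.1%, and the tumour-type association p = 4.74×10⁻³.
Two reporting notes: the 3×3 construction of the tumour-type table (keeping
the equivocal row, dropping the NA row) is the one consistent with the
printed p-value — a 2×3 deficient-vs-rest collapse gives a much larger p;
and the Clopper–Pearson lower bound for 49/104 computes to 37.25%, which
rounds to 37.2% where the reference reports 37.3% — a sub-tenth-of-a-point
rounding difference we report as computed.

# Problem sizes and determinism

Everything stochastic is seeded: the cohort generator takes an explicit
seed, and the test suite and acceptance script fix theirs. The default
synthetic experiment (90 samples × 14 markers at 2000× depth, a 25+15
train / 50 test split) runs in a few seconds; the r×c enumeration handles
the 3×3, n = 104 reference table in well under a second. The enumeration
budget, band width, QC threshold and confidence level are all exposed as
parameters with the clinical defaults.

# Known limitations

* Flank anchoring requires error-free flanks; it substitutes for, and does
  not claim equivalence to, alignment-based extraction of real reads.
* The shipped 14-marker panel is synthetic (the clinical panel's loci are
  not public); real deployments supply their own panel TSV and trained
  model.
* Scores from an independently trained model are not on the clinical score
  scale, so the published per-group score medians and ROC AUC of the
  reference assay are not reproducible desk-side and are not targeted.
* The simulator omits insertion stutter, flank errors and purity gradients;
  the MSH6-like class is a one-parameter attenuation, not a mechanistic
  model of MutSβ redundancy.
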