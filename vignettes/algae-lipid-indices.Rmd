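---
title: "Methods: fatty acid indices and antioxidant assay reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fatty acid indices and antioxidant assay reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algaeLipids)
```

This vignette is the package's own account of the methods it implements:
the models, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the design was genuinely open.

## Fatty acid nomenclature

FAME tables name fatty acids with the shorthand
`C<carbons>:<doubleBonds> [∆p1,p2,…] [(ω-n)]`. ∆ positions are
carboxyl-numbered (1-based) double-bond start positions; the ω class counts
from the methyl terminus with the terminal carbon as 1, so when a ∆ list is
present the two annotations are redundant: ω = carbons − max(∆).
`parseFaLabel()` enforces that redundancy instead of exploiting it — an ω
tag contradicting the ∆ list is a consistency error, never silently
corrected, because such a contradiction signals a transcription mistake in
the source table. Typographic decoration (superscript carets around ∆
lists, glyph and spacing variants) is stripped before parsing; it is
transport noise, not chemistry.

Labels with unsaturation but no ∆ list and no ω tag (they occur in real
tables, e.g. an unpositioned `C16:1`) are retained as distinct,
unpositioned species: they count toward MUFA/PUFA totals but never toward
ω-class sums, since their ω class is unknowable from the label. An ω tag
without a ∆ list is accepted as authoritative. Out of scope by design:
cis/trans isomerism, branched chains, and oxygenated fatty acids.

## Class sums and nutritional indices

`classSummary()` sums relative abundances over saturation classes and over
ω-3/ω-6 PUFA. The ω-6/ω-3 ratio is reported absent (`NA`) when no ω-3 PUFA
is detected — never 0 or infinity.

`nutritionalIndices()` computes the Ulbricht–Southgate atherogenicity and
thrombogenicity indices and the
hypocholesterolemic/hypercholesterolemic ratio:

$$AI = \frac{C12{:}0 + 4\,C14{:}0 + C16{:}0}
            {\Sigma MUFA + \Sigma\omega6 + \Sigma\omega3}, \qquad
  TI = \frac{C14{:}0 + C16{:}0 + C18{:}0}
            {0.5\,\Sigma MUFA + 0.5\,\Sigma\omega6 + 3\,\Sigma\omega3 +
             \Sigma\omega3/\Sigma\omega6},$$

$$h/H = \frac{C18{:}1\omega9 + C18{:}2\omega6 + C18{:}3\omega3 +
              C20{:}4\omega6 + C20{:}5\omega3}{C14{:}0 + C16{:}0}.$$

Decisions worth recording:

* **Denominators use ΣMUFA + Σω6 + Σω3, not ΣPUFA.** PUFA of other ω
  classes (ω-1, ω-4, ω-5 occur in diatoms) are excluded, consistent with
  the ∑(n−6)/∑(n−3) symbols of the canonical formulas.
* **Closure before indexing.** The TI ratio term Σω3/Σω6 is dimensionless
  while every other term carries the profile's scale, so TI as written is
  only well defined on percentages closed to 100. `nutritionalIndices()`
  therefore closes each profile internally, which also makes all three
  indices exactly invariant under uniform rescaling of the abundances.
* **Degenerate denominators yield absent values.** Σω3 = 0 makes the TI
  ratio term 0 (not undefined); Σω6 = 0 with Σω3 > 0 makes TI absent; a
  zero h/H denominator makes h/H absent.
* **Rounding only at presentation**, half away from zero
  (`roundHalfUp()`), matching how such tables are printed; all internal
  arithmetic is at full precision.
* **Index tables aggregate per replicate**: indices are computed per
  replicate and then averaged (sample SD, n − 1). The alternative — the
  index of the mean profile — differs in the second decimal for skewed
  replicate distributions; both are available (apply
  `nutritionalIndices()` to a mean profile for the latter).

The packaged seven-species fixture ships as printed, including a blank
C16:0 cell for *Chlorella vulgaris* that its own class sums show to be an
omission of roughly 17 %. The cell is carried as 0 and the species flagged
`complete_profile = FALSE` in `indexTable()`; patching a published table
is not this package's call to make. `normalizeProfiles()` (the explicit
closure step for replicate data) rejects profiles summing outside
[95, 105] for the same reason: a sum that far from 100 indicates a missing
or non-compositional column, and that *C. vulgaris* column is deliberately
rejected rather than silently rescaled.

## Antioxidant assay reduction

The DPPH/ABTS reduction assumes the standard plate layout: radical blanks
(radical + solvent), sample wells (sample + radical), sample controls
(sample + solvent, correcting intrinsic colour), and a Trolox standard
series. Inhibition at a reading is

$$\mathrm{Inhibition\%} =
  \frac{Abs_{radical} - (Abs_{sample} - Abs_{control})}{Abs_{radical}}
  \times 100,$$

with the grouping chosen so the colour control corrects the sample reading
— standard practice for both assays. Inhibition may be negative
(pro-oxidant behaviour or noise) and is clipped only at presentation.

ICx comes from ordinary least squares of mean inhibition on concentration
(`estimateICx()`), exactly as the protocol states — no four-parameter
logistic is fitted. Defaults and parameters:

* **Time point 120 min** (end of incubation); earlier readings are
  retained for QC only and selected by nearest-time matching.
* **Inhibition level is a per-assay parameter**: 50 % for ABTS and 20 %
  for DPPH by default, reflecting that weakly scavenging lipid extracts
  often reach only 20 % inhibition of DPPH at testable concentrations.
* **Replicates are averaged before regression**, matching triplicate
  mean ± SD reporting; per-replicate curves can be built by subsetting the
  plate if SD propagation is wanted.
* An IC outside the tested concentration range is returned but flagged
  `extrapolated`; a slope that is zero or negative (below 1e-10 in
  absolute terms, the numerical tolerance for "flat") is a no-convergence
  error, not a number.

Trolox equivalents are `TE = 1000 · IC_Trolox / IC_sample` (µmol Trolox
per g extract), enforced to compare the same assay and the same inhibition
level. A useful internal consistency property follows: `TE · IC_sample`
is one assay-wide constant (1000 · IC_Trolox), which the test suite checks
on the packaged published result pairs.

## Statistics

* **glog transform**: `log2((x + sqrt(x² + λ²))/2)`, the
  variance-stabilizing generalized logarithm for zero-containing data.
  λ defaults to the smallest positive value in the matrix (recorded in the
  output), a common metabolomics convention; it is configurable because
  the choice is conventional, not derived.
* **PCA** on the column-centered, *unscaled* glog matrix — unit-variance
  scaling would double-transform already variance-stabilized values.
  Component signs are fixed by making each loading vector's
  largest-magnitude entry positive, so results are platform-deterministic.
  A single-distinct-row input yields zero informative components rather
  than an error.
* **Clustering**: Euclidean distance, Ward linkage (`hclust` method
  `"ward.D2"`, Ward's criterion on Euclidean distances); both
  configurable. Leaves are ordered lexicographically before the distance
  computation so ties break deterministically. Trees export to Newick via
  `ape` for interoperability.
* **Kruskal–Wallis + Dunn**: tie-corrected omnibus H via
  `stats::kruskal.test`; Dunn's pairwise z on the joint ranking is
  implemented in the package (with the Σ(t³−t) tie correction) and
  cross-checked in the tests against a brute-force rank oracle.
  Multiplicity correction is Benjamini–Hochberg by default with
  Benjamini–Yekutieli by flag, applied over all pairs of one variable.
  Groups with fewer than two values are excluded from the post-hoc with a
  warning.
* **Letters use the inverted convention** in which a letter *shared* by
  two groups marks a *significant* pair (q < 0.05) — the convention of the
  tables this package mirrors, and the opposite of agronomy-style compact
  letter displays. The encoding round-trips: the significant-pair set is
  exactly reconstructible from the letters.
* **Correlation** reports both Pearson and Spearman coefficients, since
  published correlation claims often leave the method unstated.
* Replicate-level matrices are the default input for PCA/clustering;
  species-mean matrices are equally accepted (any numeric matrix works).

## Synthetic data: what it emulates, and what it does not

`simulateProfiles()` emulates the replicate structure of a GC-MS FAME
table: each fatty acid's mean abundance is perturbed by an independent
log-normal factor with unit mean and configurable CV (default 0.05,
n = 5 replicates — typical analytical replication for such screens), then
the replicate is closed to 100 %. Log-normal-plus-closure was chosen over
a Dirichlet model because the per-FA CV is then directly controllable,
matching tables whose SDs are roughly proportional to means. Mean rows are
closed to 100 before perturbation, so the CV → 0 limit reproduces the
(closed) means exactly. Zeros stay exactly zero: the generator never
invents a fatty acid the mean profile lacks.

Closure has a knowable statistical side effect: for an FA with share *w*
of the total, the realised CV of the closed value is attenuated by
approximately √(1 + Σⱼwⱼ² − 2w). For a dominant FA (w ≈ 0.4) this is a
~30 % attenuation; for minor FAs a slight inflation. The generator is
calibrated to the configured CV for balanced compositions, and the test
suite asserts both the calibration and the dominant-FA attenuation. Not
emulated: chromatographic co-elution, identification errors,
between-batch drift, or correlated replicate noise — so passing tests
demonstrate correct arithmetic and statistical behaviour under the stated
noise model, not robustness to instrument pathology.

`simulatePlate()` emits raw plate time-series whose final-reading truth is
linear in concentration, anchored so inhibition(trueIc) = level, with the
default slope `level/trueIc` (a truth line through the origin). Defaults
mirror the protocol the reduction expects: extract dilutions 25/125/250/500
µg/mL, Trolox 5/12.5/25/37.5 µmol/L, triplicate wells, readings every
5 min over 0–120 min, radical working solution at 0.9 AU, additive
Gaussian absorbance noise, and a 0.01 AU constant colour offset on the
controls to exercise the correction path. The kinetic shape is a
first-order exponential decay toward the final value (rate 0.3/min, making
the 120-min reading equal to the truth to machine precision); only that
final reading enters the IC estimate, so the shape is a modelling
convenience, explicitly not a contract. When a steep truth exceeds 100 %
inhibition at the highest tested concentration the object is flagged
rather than clipped — clipping would bend the linear truth and bias the
very regression the generator exists to validate.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit integer seed, and equal seeds
give byte-identical outputs (the manifest written by `runFullAnalysis()`
records seed and parameters, and contains no timestamp precisely so reruns
are byte-comparable). The validation suite uses: the packaged 7 × 32 mean
table for exact recomputation; 1000 simulated replicates per species for
index-recovery checks (1 % relative tolerance); 10 seeds × 2 truth values
for noisy IC50 recovery (0.005 AU noise, 5 % tolerance); and 5-replicate
simulations for the qualitative clustering property that the four green
(Chlorophyta) species form a clade before merging with any other phylum.

## Known limitations

* Published index tables computed from replicate-level data can differ in
  the last printed decimal from indices of mean profiles; where a source
  table's own cells are arithmetically inconsistent (the *C. vulgaris*
  C16:0 omission), this package flags rather than repairs.
* The linear dose–response model is faithful to the protocol but
  extrapolates poorly outside the tested range; the `extrapolated` flag is
  a warning, not a defence.
* PCA variance percentages of a published study are reproducible only from
  its replicate-level matrix; with species means or simulated replicates
  only qualitative structure (clade membership, phylum separation) is
  checkable, and that is what the tests assert.
* Absolute quantification (µg FA per mg biomass), internal-standard
  correction and peak integration are upstream of this package's scope.
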