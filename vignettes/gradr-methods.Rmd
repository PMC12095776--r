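---
title: "Methods: gradient-based RNA interactor prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient-based RNA interactor prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradr)
```

## The model

Molecules that are part of the same complex sediment together: on a
linear glycerol gradient their abundance profiles across the fractions
(22 by default, top to bottom) have the same shape. `gradr` scores
shape similarity between an RNA and a protein by the sample Pearson
correlation of their fraction profiles. Correlation alone is weak
evidence — many unrelated molecules share a sedimentation coefficient —
so two orthogonal layers restrict the candidate space *before* any
correlation is computed:

* **RNA-binding capacity.** In an OOPS experiment, proteins
  crosslinked to RNA partition to the organic/aqueous interphase and
  are released by RNase. A protein whose RNase+ eluate abundance
  exceeds its no-RNase control by a fold-change of at least
  `oops_fc_min` (2) at a two-tailed Student's t-test p-value of at most
  `oops_p_max` (0.05) is called an RNA-binding protein. Only
  RNA-binding proteins can be interactor candidates.
* **Shared compartment.** An RNA is assigned to cytoplasm or nucleus
  by majority of its spike-in-normalised signal; a protein is eligible
  for a compartment when it was detected there (signal > 0) in all
  replicates and is *not* at least `opposing_compartment_pct` (60)
  percent in the opposing compartment in all replicates. For nuclear
  RNAs, mitochondrial proteins are additionally removed, since a
  nuclear-mitochondrial complex is implausible and mitochondrial
  ribonucleoproteins otherwise dominate nuclear sedimentation peaks.

The surviving proteins are correlated against the query RNA's profile,
sorted by descending r, and pairs with r at least `r_min` (0.5) are the
predicted interactome. The output deliberately retains sub-threshold
rows (`passed = FALSE`) so r-versus-p scatter plots can show the full
candidate cloud.

### Assumptions

The procedure assumes (i) complex membership is reflected in
co-sedimentation — transient or sub-stoichiometric interactions that do
not survive the gradient are invisible; (ii) the OOPS filter has good
sensitivity — an interactor that fails it is unrecoverable regardless
of correlation; (iii) compartment annotations are meaningful at the
whole-cell-population level. The method proposes candidates and
machineries; it does not establish direct contact.

## Parameters

| parameter | default | unit/scale | role |
|---|---|---|---|
| `oops_fc_min` | 2 | linear fold-change | RNA-binding call |
| `oops_p_max` | 0.05 | p-value | RNA-binding call |
| `r_min` | 0.5 | Pearson r | interactor threshold |
| `opposing_compartment_pct` | 60 | percent | compartment exclusion |
| `rna_pct_cyt_min` | 50 | percent | RNA compartment call |
| `rpkm_min` | 0.5 | RPKM | expressed-RNA filter |
| `min_reads` | 10 | reads | expressed-RNA filter |
| `min_hit_bases` | 20 | bases | BLAST hit retention |
| `window_bp` | 100000 | bp | orthologous window span |
| `n_fractions` | 22 | fractions | gradient resolution |

All thresholds on fold-change, p, r and percent are inclusive
(fold-change exactly 2 passes, r exactly 0.5 passes). Both bounds
matter at the margins and the tests pin them explicitly.

## Statistical choices

**t-test form.** LFQ abundances are approximately log-normal, so the
test runs on log2-transformed values by default, in the pooled-variance
(Student) form; a Welch variant sits behind `var_equal = FALSE` and a
raw-scale mode behind `log_transform = FALSE`, since proteomics
pipelines differ on both points. Under a log-normal null the type-I
error at p <= 0.05 is calibrated (checked over 10,000 simulated null
proteins in the test suite).

**Zeros.** Zeros in replicate tables break the log transform. Two
conventions are used, matching their different origins: in
capture-style (ChIRP-MS) tables, a control group that is *entirely*
zero marks a treatment-exclusive protein, and its control mean is
artificially set to 100 so the fold-change is finite and the protein
appears in volcano plots (flagged `ctrl_imputed`); everywhere else,
individual zeros are floored at half the smallest nonzero abundance of
the table before the log transform only — the fold-change itself is
computed from the unfloored linear means, so an all-zero treatment
group yields fold-change 0 and is excluded by the fold-change gate.

**Degenerate groups.** Two constant identical groups give p = 1 by
convention; constant but different groups give p = 0. Both conventions
only matter for noise-free synthetic data.

**Fold-change direction.** Spike-in normalisation divides each
sample's RPKMs by the percentage of spike-in reads: with an equal mass
of spike-in added per sample, a sample with less endogenous RNA shows a
higher spike share and is scaled down. The opposite reading is
available via `mode = "multiply"`.

**Correlation.** Pearson r is computed on the raw linear-scale
profiles. Row-Z-scoring (used for heatmaps) is an affine transform per
profile and provably leaves Pearson r unchanged; the test suite checks
this numerically to 1e-10. Profiles with zero variance carry no shape
information: they are flagged degenerate and the pair is skipped, never
imputed. Missing fractions are refused outright — sedimentation shape
is the signal, so partial profiles would silently change what r means.

**Ties and ranks.** Candidates are sorted by descending r with ties
broken lexicographically by protein id, making ranks deterministic.

## Conservation scoring

For each (lncRNA, species) pair, BLASTN tabular hits against the target
genome are filtered to those with at least `min_hit_bases` *matched*
bases, computed as `round(align_length * pct_identity / 100)` — the
raw-alignment-length reading is available behind `mode = "length"`.
The orthologous locus is the subject window of span at most `window_bp`
whose hits jointly cover the most query sequence; candidate windows are
anchored at each hit's lower subject coordinate, an enumeration that
provably contains an optimum for union-coverage scoring (shifting a
window left until its left edge meets a hit boundary never drops a
contained hit). When hits map to multiple loci a syntenic hint, given
as a subject interval, restricts the choice to hint-overlapping
candidates. Percent base conservation weights each covered query
position by the best (highest-identity) hit covering it, avoiding
double counting across overlapping hits; an unweighted
covered-positions mode ships as well because either reading of
"percent base conservation" is defensible. Clipping of query regions
that overlap protein-coding genes is the caller's responsibility
upstream of BLAST. Species without retained hits score 0% rather than
erroring, so cross-species tables stay rectangular.

## The simulator

`simulate_cosedimentome()` generates every input table the predictor
consumes, with planted truth: complexes are Gaussian peaks over the
fractions (members share peak and width), abundances are perturbed by
multiplicative log-normal noise of sd `noise_sd`, true RNA-binding
proteins elute `oops_effect`-fold more after RNase with replicate
noise, and every entity carries 80–95% of its fractionation signal in
its home compartment. The default condition — two complexes peaking at
fractions 5 and 18 with width 1.5 over 22 fractions, 8 proteins and 3
RNAs each, one cytoplasmic and one nuclear, 30 background proteins of
which 30% are RNA binders and 20% mitochondrial, noise sd 0.1, OOPS
effect 4, three replicates — was chosen so that complexes are clearly
separated on the gradient while background proteins provide realistic
off-target correlation mass. A single integer seed drives one random
stream; identical seeds give byte-identical files.

What the simulator does **not** emulate: multimodal profiles of RNAs
shared between complexes (available explicitly via multiple complexes,
but not drawn by default), missing values and dropout typical of real
proteomics, batch effects between gradient fractions, and compositional
distortion of RPKMs. Passing the planted-truth benchmarks therefore
shows the *filter chain and ranking logic* are correct, not that the
thresholds are optimal for any real dataset.

## Problem sizes and determinism

The shipped tests run the enrichment-test null at 10,000 (acceptance)
and 4,000 (unit) simulated proteins, the correlation oracle at 1,000
random profile pairs, and the end-to-end benchmark on the default
two-complex condition (~70 entities); these sizes give stable results
while keeping the whole suite fast. All stochastic tests fix their
seeds. Each CLI stage writes a manifest with input checksums, the full
configuration and the package version, and re-running a stage on
identical inputs reproduces output files bit-identically (manifest
timestamp aside).

## Known limitations

* Recall is bounded by the OOPS filter: a true interactor that fails
  the RNA-binding call is irrecoverable (observed directly in the
  noise-grid benchmark, where OOPS misses dominate lost recall at
  noise sd 0.5).
* The RNA compartment call uses a simple majority rule on mean percent
  cytoplasmic; real annotations may come from curated sources, so the
  threshold is configurable and calls can be supplied directly to
  `combined_dataset()`.
* The per-sample-maximum reading of the minimum-read rule in the
  expressed-RNA filter is one of two defensible readings; the
  per-condition-sum alternative is `reads_rule = "sum"`.
* Correlation on 22 fractions has limited resolving power between
  complexes of similar size; the correlation matrix and its
  average-linkage clustering (distance 1 − r) are provided to inspect
  such ambiguity rather than hide it.
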