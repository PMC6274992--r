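---
title: "Gene set regularity: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene set regularity: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsreg)
```

## The model

`gsreg` quantifies how well each sample preserves the *within-gene-set
expression ordering* of a normal control cohort. For a gene set with $n$
member genes present in the data there are $\binom{n}{2}$ unordered gene
pairs. From the control cohort we build a **rank template**: for each pair
$(i, j)$ with gene $i$ lexicographically first, the template records whether
$\mathrm{rank}_i < \mathrm{rank}_j$ holds in a majority of control samples,
together with the fraction of controls supporting that majority (the
*support*, always in $[0.5, 1]$). This is the rank-matching construction of
differential rank conservation (DIRAC), reduced to a single
control-phenotype template.

The **gene set regularity (GSR) index** of a sample is the fraction of
template pairs whose ordering the sample reproduces:

$$\mathrm{GSR}(s) \;=\; \frac{1}{\binom{n}{2}}
  \sum_{i<j} \mathbf{1}\!\left[\, (r_i^s < r_j^s) = T_{ij} \,\right]$$

where $r^s$ are the sample's within-set ranks and $T_{ij}$ the template
orientation. A GSR index of 1 means the ordering is fully conserved
relative to the control majority; 0 means it is fully reversed. Because
only ranks enter, the index is invariant to any monotone transformation of
the expression values: the readers deliberately apply no normalization or
log transform.

The **functionome** of a sample is its vector of GSR indices over all gene
sets in a collection; the **immunofunctionome** is the functionome
restricted to sets whose Gene Ontology terms are offspring of *immune
system process* (GO:0002376) or *inflammatory response* (GO:0006954),
following both `is_a` and `part_of` edges, ancestors included.

Downstream, per-set deregulation is measured by the case/control ratio of
mean GSR indices and tested by a two-sided Mann-Whitney U test with BH-FDR
correction across sets within each stage group; stage rankings are
intersected (top-$k$, default $k = 75$), filtered for progressive
deterioration (significant in all stages and strictly decreasing ratio from
stage I to IV), and condensed into core elements (similarity-merged terms
found by both filters) and auxiliary elements (the symmetric difference).
Profile-level structure is assessed by hierarchical clustering of group
mean profiles and by RBF-kernel SVM classification under repeated
stratified $k$-fold cross-validation.

## Numerical and procedural choices

Several rules are under-determined by the construction above; the package
fixes them deterministically:

* **Ties.** Within a sample, tied expression values get average ranks, and
  a tied pair does not satisfy a strict "$<$". Consequently a tie fails a
  `TRUE` template entry and matches a `FALSE` one.
* **Majority splits.** With an even control count, an exact 50/50 vote is
  resolved in favor of the lexicographically first gene, so templates are
  reproducible across runs and machines.
* **Template arm.** Templates are built from *all* controls, and controls
  are scored against that same template (the simplest reading of a single
  control-population template, consistent with control means below 1).
  `reconstruct_functionome(loo_controls = TRUE)` instead scores each
  control against the template rebuilt from the other controls; see the
  calibration note below.
* **Small sets.** A set needs at least 2 member genes in the matrix;
  otherwise its column is `NA` and the set is reported as skipped — never
  zero-filled.
* **Corrected group means.** Stage groups computed against slightly
  different control gene universes are made comparable by
  $\text{corrected}_g = \text{raw}_g \cdot \bar c / c_g$, with $c_g$ the
  group's control mean and $\bar c$ the grand mean of the control means.
  This multiplicative form is a documented reconstruction: it reproduces
  all four published corrected stage means to within $\pm 0.001$ (the
  acceptance script recomputes this), and it reduces to the identity when
  the control means are equal.
* **Mann-Whitney mode.** Exact null distribution when both arms have at
  most 8 observations and no ties; otherwise the normal approximation with
  tie and continuity corrections (`stats::wilcox.test`). Degenerate input
  with a single distinct value returns $p = 1$.
* **Ranking tie-breaks.** Per-stage rankings order by ascending $p$, then
  by larger $|1 - \text{ratio}|$, then lexicographically by set id, so
  top-$k$ lists are deterministic.
* **Progressive filter.** "Significant" means $q < \alpha$ (default 0.05)
  in *all four* stages — the strictest consistent reading — and "decreasing"
  means strictly decreasing with a configurable per-step tolerance
  $\varepsilon$ (default 0). Sets with `NA` in any stage are excluded and
  counted.
* **Semantic similarity.** The similarity of two ontology terms is the
  Jaccard index of their ancestor closures (each closure including the term
  itself). This choice is deterministic, needs no external information
  content, and is symmetric with value 1 exactly on identical closures.
  Core merging links a common-side and a progressive-side term when they
  are identical or their similarity reaches $\tau = 0.5$ (configurable) and
  groups matches by single linkage, i.e. connected components of the
  thresholded similarity graph.
* **Upper-level exclusion.** "Non-specific, upper-level" terms are
  operationalized as terms whose shortest path to a root is less than
  `min_depth` (default 3). Depth is the simplest testable proxy for
  specificity and is computed on the same `is_a`/`part_of` graph.
* **Classification.** `kernlab::ksvm` with the RBF kernel, the median
  ("automatic") bandwidth heuristic and unit cost; folds are stratified by
  class so small groups never produce empty folds; AUC comes from pooled
  decision values oriented toward the positive class. For multiclass tasks
  the one-vs-one voting accuracy is reported plus per-class one-vs-rest
  AUCs computed from voting scores; these are convenience diagnostics, not
  comparable to a binary AUC. All randomness flows from one integer seed,
  making reports bit-reproducible.
* **Clustering.** Euclidean distance, average linkage, input rows sorted
  by group label first, so leaf order is deterministic. The tree is also
  exported as a Newick string.

## The synthetic cohort generator

Real multi-dataset microarray corpora cannot ship with a package, so
`synthetic_config()`/`generate_cohort()` emulate the study design: a
control cohort with a stable within-set ordering and four case groups in
which designated sets are disrupted with graded severity.

* Each gene has a log2-intensity-like baseline value (mean 8, SD 2);
  every sample adds Gaussian jitter with `noise_sd` (default 1.5). These
  values give a control cohort whose rank-conservation level — mean control
  GSR around 0.8 — is of the same order as real expression cohorts, and
  the ordinal conversion discards all other distributional detail anyway.
* Disruption is modeled as *within-set value permutation*: in each case
  sample, a fraction $\pi$ of a planted set's member genes (rounded, at
  least 2 when $\pi > 0$) have their values permuted among themselves.
  Because the GSR index responds only to ordering, this is the minimal
  faithful perturbation; mean shifts without reordering would be invisible
  by design.
* Defaults follow the validation preset: 2500 genes, 200 sets of size 10,
  40 controls, 40 cases per stage; 10 "common" sets planted at
  $\pi = 0.5$ in every stage and 10 "progressive" sets at
  $\pi = (0.50, 0.65, 0.80, 0.95)$ — strictly increasing severities
  anchored at 0.5 so that every planted set is clearly deregulated at every
  stage while the progression signal remains to be detected. A `printed`
  preset carries the published cohort sizes (34/39/695/131 cases, 136
  controls) for full-scale runs.
* Gene sets are drawn with **mutually disjoint membership** so that planted
  truth is identifiable: a disrupted gene can never leak signal into a
  nominally null set. Real GO sets overlap heavily; this is a deliberate
  simplification, and passing recovery tests therefore demonstrate correct
  mechanics, not robustness to cross-set gene sharing.
* The generator emits the same on-disk formats the readers consume
  (expression TSV, annotation TSV, GMT, truth JSON), and
  `generate_ontology()` produces a random acyclic ontology with two
  designated immune ancestors, matched gene sets and a name-consistent
  mapping, so the ontology path is testable end to end as well.

What the generator does *not* emulate: platform and batch effects,
probe-level structure, correlated noise across genes, cohort heterogeneity
of cellular composition, and overlapping set membership. Results on
synthetic data validate the pipeline's statistics and bookkeeping, not its
behavior on any particular real cohort.

## A calibration note on the null distribution

The rank template is *estimated from the control cohort*, and the same
cohort forms the control arm of every Mann-Whitney comparison. Scores are
therefore not independent across samples: all case scores share the
estimated template, and in-sample control scores carry a small optimism
(each control voted into the majority it is scored against). At the
validation preset's cohort size (40 controls) this inflates the fraction of
null sets reaching $p < 0.05$ slightly above the nominal 0.05 — the
acceptance script reports the measured rate. The effect shrinks as the
control cohort grows, and it disappears entirely when both arms are scored
against a template from an independent cohort. The leave-one-out option
removes the location bias of the control arm but not the shared-template
dependence, so it does not restore nominal calibration either; it is
offered for analyses where the control-arm optimism itself is the concern.
In practice this means small-cohort per-set p-values should be read as
slightly anti-conservative, and q-value thresholds as approximate.

## Problem sizes used in the test suite

The shipped tests exercise: exhaustive-oracle comparisons on fixtures with
up to 4 genes and 6 controls (including all $2^P$ template assignments);
1000 random tie-free samples for the bounds and reversal identities;
planted-truth recovery on ten cohorts of the default preset; a
five-point disruption grid with 20 replicates; and the separable
classification fixture (50 fully disrupted sets, 20 samples per arm) with
its label-permutation null. These sizes were chosen so the whole validation
battery exercises every stage of the pipeline on a single CPU in a few
minutes.

## Known limitations

* GSR indices are blind to expression changes that preserve within-set
  ordering (a uniform shift of all member genes is invisible).
* Duplicated genes across sets induce correlated indices across columns;
  the per-set tests do not model this (and the synthetic generator
  deliberately avoids it).
* The semantic-similarity measure and the depth-based upper-level rule are
  principled stand-ins for choices the original staged analysis left
  unspecified; both are parameterized (`tau`, `min_depth`) rather than
  hard-coded.
* Per-set p-values at small control-cohort sizes are slightly
  anti-conservative, as described above.
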