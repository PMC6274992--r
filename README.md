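# gsreg — gene set regularity analysis of expression functionomes

`gsreg` is an R package for rank-conservation scoring of gene sets in
expression cohorts, built for studies that track how biological functions
*deregulate* across disease stages — the motivating case being the
deterioration of immunological functions across the four FIGO stages of
ovarian serous carcinoma, measured against normal ovarian controls. It is
aimed at transcriptomics analysts who want a single-sample, ordinal,
platform-agnostic alternative to differential-expression + enrichment
workflows.

## The statistic

For each gene set, the normal-control cohort defines a **rank template**:
for every unordered pair of member genes, the majority ordering of their
expression ranks across controls, with the fraction of controls supporting
it. The **gene set regularity (GSR) index** of a sample is the fraction of
template pair orderings the sample reproduces,

```
GSR(s) = (1 / C(n,2)) * Σ_{i<j} 1[ (r_i^s < r_j^s) = T_ij ]   ∈ [0, 1]
```

— 1 when the within-set ordering is fully conserved, 0 when fully
reversed. This is a single-template variant of differential rank
conservation (DIRAC). The per-sample vector of GSR indices over a
collection is the **functionome**; restricted to Gene Ontology offspring of
*immune system process* (GO:0002376) and *inflammatory response*
(GO:0006954) it is the **immunofunctionome**.

On top of the index the package implements the full staged inference:
control-averaged correction of group means, per-set Mann-Whitney tests with
BH-FDR, deterministic significance rankings, top-k cross-stage
intersection (full Venn partition), progressive-deregulation filtering
(significant in all stages, strictly decreasing case/control ratio from
stage I to IV), core/auxiliary element extraction by ontology semantic
similarity, hierarchical clustering of group profiles, and RBF-SVM
classification with repeated stratified cross-validation. A synthetic
cohort generator with planted, graded rank-order disruption makes every
stage testable without any external data.

## Worked example

The published corrected stage means are reproduced directly from the
printed raw group means by the control-average correction:

```r
library(gsreg)
corrected_group_means(c(0.6195, 0.6021, 0.5748, 0.5588),   # case means I–IV
                      c(0.6461, 0.6459, 0.6518, 0.6486))   # control means
#> [1] 0.6214177 0.6041508 0.5715371 0.5583692
```

matching the published 0.6214 / 0.6041 / 0.5715 / 0.5583 to the printed
precision: the stepwise decrease from stage I to IV is the quantitative
signature of progressive functional deterioration.

A full synthetic study, end to end:

```r
cfg <- synthetic_config(n_genes = 1000, n_sets = 80, set_size = c(10, 10),
                        n_planted_common = 8, n_planted_progressive = 8,
                        n_controls = 30, n_cases = rep(30, 4), seed = 42)
cohort <- generate_cohort(cfg)
bundle <- gsr_pipeline(cohort$expression, cohort$annotation,
                       cohort$collection, k_top = 20, cv_repeats = 5,
                       seed = 42)

bundle$group_means
#> # A tibble: 4 × 7
#>   group    case_mean case_sd control_mean control_sd corrected_case_mean  p_value
#> 1 stageI       0.759   0.106        0.801     0.0845               0.759 3.07e-41
#> 2 stageII      0.755   0.109        0.801     0.0845               0.755 8.87e-49
#> 3 stageIII     0.748   0.121        0.801     0.0845               0.748 1.29e-50
#> 4 stageIV      0.743   0.129        0.801     0.0845               0.743 5.43e-54
```

Group mean GSR decreases monotonically with stage (the planted severities
increase), every stage differs significantly from control, and — because
all four stages share one control pool here — the corrected means equal the
raw means. The progressive filter recovers exactly the eight planted
progressive sets:

```r
bundle$progressive
#> [1] "SET_025" "SET_028" "SET_035" "SET_040" "SET_049" "SET_050" "SET_057" "SET_075"
sort(cohort$truth$set_id[cohort$truth$class == "progressive"])
#> [1] "SET_025" "SET_028" "SET_035" "SET_040" "SET_049" "SET_050" "SET_057" "SET_075"
```

the stage-vs-control SVM separates perfectly on this fixture,

```r
glance(bundle$cv$stageIV_vs_control)[c("accuracy_mean", "auc_mean")]
#> # A tibble: 1 × 2
#>   accuracy_mean auc_mean
#> 1             1        1
```

and the group dendrogram recovers stage adjacency:

```r
bundle$dendrogram$newick
#> [1] "((stageI:0.117,stageII:0.117):0.078,(stageIII:0.118,stageIV:0.118):0.078);"
```

`autoplot()` methods exist for deregulation tables, Venn partitions,
CV reports and dendrograms; `plot_gsr_histogram()` draws the per-stage
GSR distributions against the controls. `write_gsr_bundle()` emits every
artifact (TSV/JSON/Newick) under fixed names.

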