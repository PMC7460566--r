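# profilex

Stepwise extraction of informative gene expression profiles from a
two-class expression matrix (e.g. healthy vs. tumor), for analysts who need
a compact, class-separating, mutually correlated gene set — typically as
the starting point for gene-regulatory-network reconstruction or a
diagnostic signature.

Given a preprocessed (rma-level) samples × genes matrix
*e<sub>ij</sub>* ∈ ℝ<sup>n×m</sup> with known binary labels, the package
chains four stages:

1. **Filtering.** Per-gene variance, mean absolute expression and
   James–Stein shrinkage Shannon entropy; three boundaries advance together
   over a linear grid (variance/mean up, entropy down) and the kept set is
   fixed at the first minimum of the composite cluster-validity criterion

   *QC<sub>int</sub> = K(K−1) QC<sub>W</sub>² / ((N−K) QC<sub>B</sub>²)*,

   where *QC<sub>W</sub>* is the mean correlation distance
   (*d = 1 − r*) of samples to their class centres and *QC<sub>B</sub>*
   the distance between centres — the WB-index combined multiplicatively
   with the reciprocal Calinski–Harabasz ratio, minimised at the best
   configuration.
2. **Clustering.** Level-wise binary SOTA (self-organizing tree) clustering
   of the kept gene profiles under correlation distance: every leaf splits
   once per level (≤ 2<sup>L</sup> clusters at level L), deterministically;
   per level, the cluster whose genes best separate the classes (minimal
   *QC<sub>int</sub>* in sample space) is selected.
3. **Classification.** Stratified 60/40 split; logistic regression,
   linear-kernel SVM (CV-tuned cost), CART and a 10-tree random forest on
   each selected cluster, scored by accuracy, precision, recall, F-measure,
   Matthews correlation coefficient and Mann–Whitney AUC.
4. **Fuzzy fusion.** A Mamdani system (min activation, max accumulation,
   centroid defuzzification, complete 8-rule majority base) fuses the
   SVM/CART/RF outputs into a crisp final state FS ∈ [0, 1]; FS ≥ 0.5 is
   called tumor.

A seeded synthetic-data generator with planted correlated blocks, chaotic
noise genes and low-expression genes makes the whole pipeline testable
without any external data.

## Worked example

```r
library(profilex)

sim <- generate_synthetic(synth_config(seed = 2))
sim$dataset
#> expression_dataset: 100 samples x 200 genes

rep <- run_pipeline(sim$dataset, sim$labels, max_level = 2, seed = 2)
rep
#> pipeline_report: filter kept 29 genes (step 8); levels 1..2; chosen level 1 (20 genes)

rep$selection
#>   level cluster n_genes     qc_int selectable
#> 1     1       1      20 0.06741737       TRUE
#> 2     2       1      15 0.11211977       TRUE

rep$metrics[rep$metrics$level == rep$chosen_level, ]
#>   level classifier n_genes    AC    PR   RC     F   MCC   AUC
#> 1     1        glm      20 0.875 0.895 0.85 0.872 0.751 0.882
#> 2     1        svm      20 0.975 1.000 0.95 0.974 0.951 0.998
#> 3     1       cart      20 0.850 0.889 0.80 0.842 0.704 0.845
#> 4     1         rf      20 0.925 0.947 0.90 0.923 0.851 0.950

rep$fusion
#>   level n_genes   AC  PR  RC     F   MCC   AUC
#> 1     1      20 0.95 1.0 0.9 0.947 0.905 0.984
#> 2     2      15 0.90 0.9 0.9 0.900 0.800 0.948
```

Reading this: the boundary scan kept 29 of 200 genes (all planted
informative ones — the 100 noise/low genes are gone); the level-1 cluster
of 20 genes separates the classes best (*QC<sub>int</sub>* = 0.067); on
the 40 held-out samples the SVM reaches 0.975 accuracy and the fused
decision 0.95 with perfect precision. The fused level-1 F-measure (0.947)
exceeds level 2's, so level 1 is the chosen final cluster and
`rep$chosen_genes` its gene list.

The fusion itself is a one-liner: three classifier probabilities in, one
crisp state out —

```r
fs <- fuzzy_infer(default_fuzzy_system(), 0.9, 0.8, 0.7)
round(fs, 3); final_class(fs)
#> [1] 0.858
#> [1] 1
```

A thin command-line front-end ships in `inst/cli/profilex.R`
(`run` and `simulate` subcommands) for shell use; the functions above are
the primary interface. The methods vignette
(`vignettes/profile-extraction.Rmd`) documents the model, the parameter
defaults and the generator's assumptions.

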