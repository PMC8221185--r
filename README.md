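# mstnet

Dynamic brain-network analysis for trial-structured multichannel
electrophysiology: phase-lag-index connectivity in sequential 100-ms
windows, maximum-spanning-tree backbones, tree-topology statistics, a
dissimilarity-gated Wilcoxon/FDR comparison of conditions, and
single-trial SVM classification — plus a coupled-oscillator signal
generator with planted coupling topologies so the whole pipeline is
testable without any recordings.

## The method

For every trial, frequency band and post-stimulus window, the package:

1. **Preprocesses** epochs: common average reference, zero-phase
   4th-order Butterworth band-pass (delta 0.5–4, theta 4–8, alpha 8–12,
   beta 13–30, gamma 31–46 Hz by default), baseline correction over
   −200–0 ms, and slicing of the 0–500 ms span into five 100-ms windows
   T1–T5.
2. **Estimates connectivity** with the phase lag index. With
   instantaneous phases φ from the analytic signal (Hilbert transform),

       PLI = | mean_k sgn( sin(φ_a(t_k) − φ_b(t_k)) ) |  ∈ [0, 1],

   with sgn(0) = 0, so zero-lag synchronization (volume conduction)
   contributes nothing.
3. **Extracts the backbone**: the maximum spanning tree (Kruskal on
   descending PLI weights) of each channels × channels adjacency, and
   its measure suite — diameter D, leaf fraction L_f, maximum
   betweenness MaxBC, maximum degree MaxK, tree hierarchy
   Th = L/(2·m·MaxBC), mean edge PLI, per-node degree and betweenness
   (m = N−1 links; degree-type measures are normalized by m,
   betweenness by (N−1)(N−2)/2). A line tree and a star tree are the
   two extremes: raw MaxK/leaves/D are 2/2/(N−1) and (N−1)/(N−1)/2.
4. **Gates by tree dissimilarity**: per cell, a reference tree is built
   from the trial-averaged adjacency of the reference ("scrambled")
   condition, each trial's tree is scored by

       S_n/m = (1/N) Σ_i log10 | S_n(i) / S_m(i) |,

   S_k(i) the sum of reciprocal-PLI distances from node i to its tree
   neighbours, and the two contrast conditions are compared by Wilcoxon
   rank-sum with Benjamini–Hochberg correction over the band × window
   grid. Only passing cells enter measure testing.
5. **Selects features and classifies**: per measure, rank-sum + BH over
   the grid (× nodes for nodal measures); significant features are
   concatenated per trial and fed to an RBF-kernel SVM under 5×5-fold
   stratified cross-validation (z-scoring fitted on training folds),
   reporting accuracy, sensitivity, specificity and ROC AUC, with a raw
   time-segment feature baseline for comparison.

## Worked example

```r
library(mstnet)

nch <- 12
plan <- list(
  face  = list(gamma = list("2" = star_coupling(nch))),
  ketch = list(gamma = list("2" = chain_coupling(nch))))
cfg <- synth_config(n_subjects = 1, trials_per_condition = 300,
                    n_channels = nch,
                    band_plan = list(theta = c(4, 8), gamma = c(31, 46)),
                    coupling_plan = plan, seed = 11)

ep  <- baseline_correct(generate_dataset(cfg))
st  <- connectivity_stack(ep, cfg$band_plan)
mst <- mst_stack(st)
di  <- dissimilarity_table(st, mst, reference_condition = "scrambled")
gate <- gate_by_dissimilarity(di, c("face", "ketch"))
subset(gate, pass)
#>    band window        p_raw        p_adj direction pass
#> 4 gamma      2 5.165507e-13 5.165507e-12        -1 TRUE
```

The gate finds exactly the planted (gamma, T2) cell. Measure selection
then flags the star-vs-chain signature with the expected signs — the
star condition has the higher leaf fraction and maximum degree and the
shorter diameter:

```r
tab <- mst_measure_table(mst)
sel <- select_features(tab, gate, c("face", "ketch"))
subset(as.data.frame(sel), is.na(node))[, c(1:3, 6:8)]
#>          measure  band window        p_adj direction significant
#> 1       diameter gamma      2 2.934266e-07        -1        TRUE
#> 2  leaf_fraction gamma      2 1.043986e-09         1        TRUE
#> 3         max_bc gamma      2 3.007460e-09         1        TRUE
#> 4     max_degree gamma      2 2.459748e-14         1        TRUE
#> 5 tree_hierarchy gamma      2 2.978236e-02         1        TRUE
#> 6        mst_pli gamma      2 5.233851e-07        -1        TRUE
```

Feeding the selected features of an independent planted set (coupling
in T2 and T3, 500 trials per class) to the cross-validated SVM yields

```r
#> <classification_report> accuracy 0.9360 | sensitivity 0.8908 |
#>   specificity 0.9812 | AUC 0.9758
```

i.e. near-perfect single-trial discrimination of the planted
topologies, while the raw time-segment baseline stays near chance.
`run_pipeline()` (or `inst/scripts/run_pipeline.R` with a YAML config)
orchestrates all stages and writes per-stage CSV/JSON artifacts with a
reproducible run manifest.

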