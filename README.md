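# adipobranch

Bifurcating trajectory analysis of early adipocyte differentiation.

## What this is for

Human adipose stem and progenitor cells differentiating in vitro split
from a common progenitor (P) population into two fates: an **adipogenic**
branch (U; *ADIPOQ*, *PPARG*, lipid and mitochondrial metabolism) and a
**structural** branch of SWAT-like cells (L; extracellular matrix,
*DCN*-type markers). `adipobranch` packages the computational workflow for
characterizing such a bifurcation in droplet scRNA-seq data:

* QC filtering of UMI count matrices (strict rules: < 200 or > 9,000
  detected genes, > 120,000 UMIs, > 8% mitochondrial when enabled; genes
  in < 3 cells), log normalization to 10,000 transcripts, covariate
  residualization;
* a simplified bifurcation inference (PCA → k-means → minimum spanning
  tree, with cell-level discriminant refinement) and **stretched
  pseudotime** mapping every root-to-leaf path onto 0–100;
* branch × pseudotime-decile stratification (30 strata);
* a spline likelihood-ratio test for **branch-dependent genes**
  (full model `~ ns(t) * branch` vs reduced `~ ns(t)`), BH q-values,
  a q < 0.05 & |log2FC| > 0.3 filter, and kinetic clustering (k = 6);
* kernel-smoothed per-branch curves and **divergence-point detection**:
  the pseudotime at which a gene's expression separates between branches,
  with the requirement that the divergence is maintained to the end;
* brown/white adipocyte **signature deconvolution** per stratum
  (two-component constrained least squares);
* cumulative hypergeometric **gene-set enrichment** with the directional
  z-score `(up − down) / sqrt(count)`;
* **kNN label transfer** on a joint PCA embedding with vote-fraction
  confidences;
* the **nuclei dot-counting** image algorithm (multi-Otsu background
  removal, 8-connectivity components, knee-point maximum-size gate).

A first-class synthetic-data module (`simulate_bifurcation()`,
`simulate_mixture()`, `simulate_dot_image()`) plants full ground truth —
true branches, pseudotimes, divergence times, kinetic archetypes, mixture
fractions, dot counts — so the entire pipeline is testable offline.

## Worked example

```r
library(adipobranch)

sim <- simulate_bifurcation(sim_config(n_cells = 2000, n_genes = 600, seed = 1))
sim$counts
#> count_matrix: 2000 cells x 600 genes (10 mitochondrial)

qc   <- qc_filter(sim$counts, qc_thresholds(apply_mito_filter = FALSE))
norm <- normalize_log(qc$counts)
res  <- residualize(norm, cell_qc_stats(qc$counts)[, c("umi_total", "mito_fraction")])

tg   <- sim$truth$gene
traj <- infer_bifurcation(
  res,
  root_cells   = sim$meta$cell_id[sim$meta$t_true < 10],
  marker_genes = tg$gene_id[tg$is_branch_gene & tg$favored %in% "U"],
  seed = 1)
table(traj$branch)
#>   L   P   U
#> 604 810 586

traj <- stretch_pseudotime(traj)
range(traj$pseudotime_stretched)
#> [1]   0 100

length(unique(stratify_deciles(traj)$stratum))
#> [1] 30

bt  <- fit_branch_test(norm, traj)
sig <- filter_branch_genes(bt)          # q < 0.05 and |log2FC| > 0.3
length(sig)
#> [1] 111
```

Of the 118 planted branch genes, 111 survive the significance/effect
filter, and 91.5% of cells carry their true branch label (the remaining
errors sit in the information-poor window just after the split). Smoothing
and divergence calling on the significant genes:

```r
curves <- smooth_branch_curves(norm, traj, genes = sig)
calls  <- detect_divergence(curves, delta = 0.25, mode = "sign-tail")
head(calls[order(calls$t_star), c("gene_id", "favored_branch", "t_star", "max_gap")], 3)
#>    gene_id favored_branch   t_star   max_gap
#> 3    G0013              L 17.37374 0.7281964
#> 14   G0045              L 17.37374 0.6041203
#> 22   G0073              L 17.37374 0.8520692
```

`t_star` is the estimated onset of divergence on the stretched 0–100
scale; onsets earlier than the observable window (the two fates only
exist after the split) are clamped to its extrapolated start, which is
where these early-diverging genes accumulate. `favored_branch` names the
branch with the higher maintained expression, and `max_gap` the largest
log-expression separation over the validated tail. The default
`mode = "strict"` instead reports the time the gap first reaches `delta`
and stays there — the literal "maintained divergence" rule, used to
reject genes whose curves cross back.

One call runs everything and writes CSV/JSON outputs plus a hash manifest:

```r
run_pipeline(default_config(out_dir = "run1", seed = 1))
```

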