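# clonodyn

Clonal dynamics of paired-chain single-cell TCR repertoires.

In single-cell studies of inflamed or autoimmune tissue, T cells descended
from one clone carry identical TCR rearrangements, so paired CDR3α/CDR3β
sequences act as lineage barcodes. `clonodyn` turns those barcodes into two
per-sample statistics and everything needed around them:

* **Clonal expansion** of a subtype *S*: with *N* TCR-informative cells in
  *S* and clonal clonotypes *i = 1..k* of per-subtype size *nᵢ* (a cell is
  clonal when its clonotype is seen in ≥ 2 cells sample-wide),

  `expansion(S) = Σᵢ nᵢ / N ∈ [0, 1]`

* **Clonal transition** between subtypes *A* and *B*: over clonotypes
  present in both,

  `transition(A, B) = Σᵢ (nᵢ,A + nᵢ,B) / (N_A + N_B)`

  — symmetric, in [0, 1], and evidence that cells of one state
  differentiated into the other.

Group means of these values feed a subtype × group heatmap and a transition
network whose edges can be flagged as *exclusive* to one cohort arm (positive
mean transition in exactly one group). The package also provides:

* readers/writers for 10x-style MTX count matrices, V(D)J contig CSVs, cell
  metadata TSVs, and a Cytoscape-importable edge list — all deterministic;
* the per-sample QC chain (gene prevalence ≥ 3 cells; 500–8000 detected
  features; 98th-percentile UMI cut; doublet-flag removal; >15% mito / >40%
  ribo / >3% hemoglobin filters; gene-set exclusion) with a telescoping
  report;
* log-normalization plus a from-first-principles Wilcoxon rank-sum test
  (exact for small samples) driving marker detection (Bonferroni p < 0.05,
  log2FC > 0.25, >25% expressed) and DEG screening (fold > 2 or > 1.5,
  >10% expressed);
* per-sample, compartment-relative cell-type proportions with Wilcoxon /
  Welch-t group comparisons and Spearman frequency correlation;
* a multi-sample cohort simulator with complete ground truth (planted clone
  structure, shared clones, markers, QC violators, doublets) that every
  statistic is validated against.

Everything is tidyverse-shaped: tabular inputs and outputs are tibbles,
results chain with the pipe, fitted objects have `tidy()`/`glance()` methods
and `autoplot()` figures. Count matrices are sparse `Matrix::dgCMatrix`.

## Worked example

Simulate a small two-arm cohort with Trm→Teff clonotype sharing planted only
in the disease arm, assemble clonotypes, and compute the two statistics:

```r
library(clonodyn)

cfg <- sim_config(groups = c(GD = 4L, control = 4L),
                  cells_per_sample = 500L, seed = 42L)
cohort <- simulate_cohort(cfg)
glance(cohort)
#> # A tibble: 1 × 5
#>   n_samples n_cells n_tcr_cells n_doublets n_contigs
#>       <int>   <int>       <int>      <int>     <int>
#> 1         8    4304        2017        304      4012

assignments <- assemble_clonotypes(cohort$chains,
                                   cohort$meta[!cohort$meta$doublet_flag, ])
summarize_expansion(clonal_expansion(assignments))
#> # A tibble: 10 × 4
#>    subtype group   mean_expansion n_samples
#>    <chr>   <chr>            <dbl>     <int>
#>  1 Teff    GD               0.598         4
#>  2 Teff    control          0.610         4
#>  3 Tem     GD               0.413         4
#>  4 Tem     control          0.404         4
#>  5 Tex     GD               0.276         4
#>  6 Tex     control          0.190         4
#>  7 Trm     GD               0.257         4
#>  8 Trm     control          0.196         4
#>  9 naive   GD               0             4
#> 10 naive   control          0             4

transition_network(summarize_transitions(clonal_transitions(assignments)))
#> # A tibble: 1 × 5
#>   subtype_a subtype_b weight_GD weight_control exclusive_to
#>   <chr>     <chr>         <dbl>          <dbl> <chr>
#> 1 Teff      Trm           0.239              0 GD
```

Reading the output: mean expansion tracks the simulator's planted clonal
mass per subtype (0.6 in Teff down to 0 in naive; chain dropout shaves a
little off), and the only clonotype-sharing edge is Teff–Trm, flagged as
exclusive to the `GD` arm — exactly the planted cross-subtype clones.
`autoplot()` on the two summary objects draws the heatmap and the network;
`write_edge_list()` exports the network for Cytoscape.

The full pipeline (simulate → QC → markers → clonotypes → composition) runs
as one call, writing deterministic TSVs plus an MD5 manifest:

```r
run_pipeline(pipeline_config(outdir = "my_run", seed = 11L))
```

A thin CLI wrapper over the same stages lives at `inst/scripts/clonodyn`
(`clonodyn run-all --outdir my_run --seed 11`).

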