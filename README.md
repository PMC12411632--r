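# clonodyn

Clonotype dynamics and interferon-module analysis for paired single-cell
RNA + TCR repertoire cohorts.

## What this package is for

Longitudinal single-cell studies of relapsing autoimmune disease — systemic
lupus erythematosus (SLE) being the motivating case — sample patients before
a flare (BF) and at the flare (FL), profiling both gene expression
(scRNA-seq) and paired-chain T cell receptors (scTCR-seq) in the same cells.
Three questions drive the analysis:

1. **Which T cell clones expand at the flare, and what do they become?**
   Cells are collapsed into clonotypes from their paired α/β chains; clones
   that grow at least twofold (or appear de novo) with at least three flare
   cells are classified as flare-expanded, and their cell-subtype fates
   (e.g. naive → effector memory) are tracked.
2. **How does the repertoire's shape change?** Shannon entropy
   (−Σ pᵢ ln pᵢ) summarises clonal diversity, the top-10 clonotype
   proportion summarises dominance, and the Morisita–Horn index
   (2Σxᵢyᵢ / [(Σxᵢ²/X² + Σyᵢ²/Y²)·XY]) measures repertoire overlap between
   samples.
3. **Which interferon-stimulated genes act in which cell types?** Per
   cell-type log₂ fold-change profiles of a 100-gene IFN panel are
   partitioned into modules by K-means with silhouette-based selection of
   K, and per-cell module scores (bin-matched-control gene-set averages,
   z-scored) quantify module activity across groups and timepoints.

Around this core sit the standard supports: 10x-style MTX / contig-CSV /
AIRR-TSV readers, cell QC (>500 detected genes, <5% mitochondrial UMIs,
platelet-marker exclusion), a rank-sum differential-expression test with
the fold-change > 1.25 and BH-adjusted p < 10⁻⁶ significance conjunction,
per-sample cell-type composition statistics, and a staged `run_pipeline()`
driver with a reproducibility manifest.

Because real cohorts of this kind are access-restricted, the package ships
a first-class synthetic-cohort generator (`sim_config()` /
`simulate_cohort()`) that emulates the full study design — BF/FL pairs,
group-specific composition, power-law repertoires with planted expansions,
negative-binomial expression with planted cell-type-specific module
activation — and returns the planted ground truth, so every stage of the
analysis is testable end to end.

## Worked example

```r
library(clonodyn)
library(dplyr)

cfg <- sim_config(n_patients = 2, n_controls = 2, n_cells_per_sample = 1000,
                  n_genes_total = 300, frac_chain_dropout = 0.05, seed = 42)
cohort <- simulate_cohort(cfg)
calls  <- call_clonotypes(cohort$contigs)
calls
#> Clonotype calls: 3207 cells from 3381 barcodes (key mode: genes_plus_cdr3aa )
#>   removed contigs: low confidence 0 | non-productive 0 | non-alpha/beta 0 | secondary chain 0
#>   unpaired barcodes dropped: 174
```

174 of 3381 T cells lost a chain to the simulated 5% dropout (plus cells
whose partner chain was never emitted) and are removed by the
paired-chain rule. Per-patient CD8 repertoire statistics:

```r
cd8  <- filter(cohort$meta, cell_type %in% c("CD8 naive", "CD8 Tem"))
prof <- repertoire_from_calls(calls, cd8, c("patient_id", "timepoint"))
repertoire_metrics(filter(prof, !is.na(timepoint)))
#>   patient_id timepoint n_cells n_clonotypes shannon top_n_proportion
#> 1 P01        BF            335          293    5.62           0.0896
#> 2 P01        FL            368          290    5.46           0.177
#> 3 P02        BF            334          282    5.54           0.117
#> 4 P02        FL            364          273    5.34           0.212
```

Both patients show the flare signature: entropy falls (5.62 → 5.46,
5.54 → 5.34) and the share held by the ten largest clones roughly doubles.
Expansion classification recovers every planted clone:

```r
expn <- classify_expansion_cohort(calls, cohort$meta,
                                  cell_types = c("CD8 naive", "CD8 Tem"))
glance(expn)
#>   n_clonotypes n_expanded n_de_novo n_fold n_excluded_min_cells
#> 1          599         10         4      6                   24
```

10 clonotypes are called expanded (4 de novo, 6 by fold increase) —
exactly the 2 × 5 planted per patient; 24 would-be expansions with fewer
than three flare cells were gated out as spurious. `fate_table()` then
crosses each expanded clone's BF subtype distribution with its FL one,
`module_scores()` + `compare_expanded_scores()` contrast module activity
between expanded and non-expanded cells, and `run_pipeline(run_config(...))`
executes the whole chain from files on disk to TSV/JSON artifacts.

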