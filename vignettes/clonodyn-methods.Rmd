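---
title: "Methods: clonotype dynamics and interferon modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonotype dynamics and interferon modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical procedures implemented in
**clonodyn**, the choices made where the design was genuinely open, and the
limits of what the synthetic validation can show.

## Clonotype calling

Cells are collapsed to paired-αβ clonotypes by four ordered rules applied to
the contig table: (1) contigs not flagged high-confidence are dropped; (2)
when a cell carries several contigs of one chain, only the highest-UMI
contig survives; (3) cells lacking either a TRA or a TRB are dropped; (4)
the surviving chain pair defines the clonotype key.

Decisions taken here:

* **Productivity.** 10x's filtered contig convention treats non-productive
  rearrangements as noise; `call_clonotypes()` therefore also requires
  `productive == TRUE` by default. `require_productive = FALSE` applies the
  literal four rules for users whose input is already productive-only.
* **Key mode.** The field-standard clonotype definition includes both CDR3
  amino-acid sequences alongside the V(D)J genes
  (`genes_plus_cdr3aa`, the default). A `genes_only` mode implements the
  narrower V/D/J-only key. The mode used is recorded in every output; the
  two are *not* interchangeable and results must cite the mode.
* **Tie-breaking.** Equal-UMI contigs are ordered lexicographically by
  `(cdr3_nt, v_gene)` before truncation, making the caller invariant to
  input row order; ties are counted in the filter report.
* **Scope of identity.** The clonotype key is a pure function of the two
  chains. Clonotype-level comparisons are only ever made within a patient
  (expansion) or through abundance-overlap statistics (Morisita–Horn);
  clone identity is never merged across patients.

## Repertoire statistics

Diversity is Shannon entropy over clonotype proportions, computed on **cell
counts per clonotype** (not UMIs), natural log by default (the base is an
argument and is recorded as an attribute). Dominance is the summed
proportion of the `n = 10` largest clones, with deterministic lexicographic
selection among tied clones. Overlap is the Morisita–Horn index over the
union of clonotype keys; it is symmetric, bounded in [0, 1], and invariant
to proportional scaling of either repertoire.

Entropy is depth-sensitive; no rarefaction is applied by default because
the analysis compares within-patient samples of similar size.
`subsample_repertoire()` provides seeded subsampling to a common depth for
unequal comparisons.

## Expansion classification

For one patient's baseline (BF) and flare (FL) CD8 repertoires, a clonotype
is **expanded** when (a) its flare count is at least `fold_threshold = 2`
times its baseline count, or it is absent at baseline; (b) it has at least
`min_flare_cells = 3` flare cells; and (c) under
`require_proportional = TRUE`, its within-repertoire proportion also
increased. The count fold and proportion fold are both emitted so either
reading of "fold increase" is auditable; the minimum-cell gate applies only
to would-be expansions (status `excluded_min_cells`) and never converts a
genuinely unexpanded clone's label. The fold could alternatively be defined
on proportions; the package computes counts as primary and proportions as
the separate conjunct, and reports both, rather than guessing a single
intent.

Fate tables attribute each expanded clonotype one unit of mass, split
across (BF subtype × FL subtype) pairs proportionally to its cell counts —
clonotype-level weighting prevents one hyper-expanded clone from dominating
the transition structure. A cell-weighted variant
(`weighting = "cell"`) is available.

## Interferon module discovery and scoring

The per-cell-type log₂ fold-change profile normalizes counts to
counts-per-10k (linear scale), averages within (cell type × group), and
takes `log2((mean_SLE + ε) / (mean_CTL + ε))` with ε = 0.01 for
finiteness. Note that library-size normalization slightly deflates the
apparent fold change of planted effects: elevating 50 of ~1500 genes
twofold grows the library by a few percent, so a true two-fold effect
appears as log₂FC ≈ 0.9 rather than 1.0 at cohort scale.

Gene modules are found by K-means (Euclidean, on the raw log₂FC rows, no
row scaling) with `n_restarts = 50` random initializations per K, keeping
the lowest within-cluster sum of squares; K is selected by maximum mean
silhouette width over `k_range = 2:8`. Base R's `kmeans()` with many random
restarts is used rather than a k-means++ initializer: on ~100-row profiles
the restarts achieve the same robustness without hand-rolling an
initializer. Labels are renumbered C1, C2, … by descending cluster size so
the labelling is deterministic; an all-identical profile is rejected as
having no cluster structure. At the default planted effect size the
silhouette curve is nearly flat between K = 4 and K = 5 on full-cohort
profiles (per-gene fold-change noise can split one module); the controlled
planted-profile benchmark with between/within separation ≥ 5 recovers the
planted K essentially always, and users should inspect
`silhouette_by_k` rather than trusting the argmax blindly.

Module scores are the mean normalized log1p expression of a gene set,
minus the mean of an expression-bin-matched control set (24 bins, up to
100 control genes drawn per set gene, seeded), then z-scored across cells —
the standard single-cell module-score construction. A `control = FALSE`
mode gives the plain aggregated mean; the mode is recorded in the result.
A zero-variance module scores 0 for all cells rather than NaN.

## Differential expression and composition

DE between two groups is a per-gene Mann–Whitney test on normalized log1p
expression. The original analysis context uses a model-based single-cell
test; the distribution-free rank test is a deliberate, documented
substitute — it is assumption-light, and the extreme significance
conjunction (fold change strictly > 1.25 **and** BH-adjusted p strictly
< 10⁻⁶) dominates the operating characteristics. Fold change is computed
on linear normalized means with ε = 0.01. BH adjustment is the standard
step-up procedure (`stats::p.adjust`), validated in the test suite against
a from-definition oracle on all permutations of up to six p values.

Composition tests compare per-sample cell-type fractions between groups by
Mann–Whitney with BH across types — samples, not cells, are the
independent units, avoiding pseudoreplication. Subtype ratios
(e.g. ABC / memory B) are per-sample with zero-denominator samples
excluded and logged.

## Quality control

Cells are kept when detected genes (≥1 UMI) are **strictly greater than**
500, mitochondrial UMI fraction (genes matching `^MT-`, case-insensitive)
is **strictly below** 5%, and no platelet marker (PPBP, PF4, NRGN) is
expressed above 0 counts. Rules are evaluated on the original matrix, not
sequentially; a multiply-failing cell is attributed to the first failing
rule in the order genes → mito → platelet. If no mitochondrial genes are
present the rule is skipped with a warning recorded in the report. The
variable-feature blacklist (TCR-variable, Ig-variable, ribosomal,
mitochondrial, dissociation-stress genes) ships with a stand-in core
stress-gene list (immediate-early and heat-shock genes); supply the exact
published signature when matching a specific study.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design: `n_patients = 4` SLE
patients with BF + FL samples, `n_controls = 4` single-sample controls,
`n_cells_per_sample = 2000`, and group-specific cell-type fractions in
which effector-memory CD8 T cells and atypical B cells are enriched in SLE.

* **Repertoires.** Clone sizes are i.i.d. from a truncated discrete power
  law P(s) ∝ s^(−3.5) on 1…15 — a steep law placing most clones at sizes
  1–2, consistent with the singleton-dominated shape of peripheral TCR
  repertoires. The exponent is a modeling choice (the clone-size
  distribution is not parameterized by the study design) fixed a priori.
  Non-planted clones keep their baseline count at flare; planted clones
  take exactly `expansion_fold = 4` times their baseline count (de novo
  clones: 0 baseline, 6 flare cells) and switch phenotype naive → Tem.
  Because counts are constructed rather than resampled, the planted set
  coincides exactly with the set satisfying the expansion rule on true
  counts, giving an unambiguous ground truth.
* **Chains.** Each clonotype deterministically encodes (patient, lineage,
  index) into its CDR3 in a 20-letter amino-acid alphabet, so keys are
  unambiguous and never collide across patients. Noise is injected as
  configured fractions of cells missing one chain, carrying a 1-UMI
  secondary α chain, or carrying a high-UMI decoy contig flagged
  low-confidence (which must be removed by rule 1 *before* the max-UMI
  rule sees it).
* **Expression.** Per-cell library sizes are lognormal (mean 2500, sdlog
  0.25); per-gene relative abundances are skewed gamma draws;
  counts are negative binomial with shared dispersion 0.5; module genes
  are elevated by exp(δ) with δ = ln 2 in the designated cell types of SLE
  cells only. Mitochondrial genes carry a fixed 2.5% of the library so the
  QC rule operates in a realistic regime; platelet markers are absent (no
  platelets are simulated — the platelet rule is exercised on constructed
  fixtures in the tests).

What the generator does **not** emulate: V(D)J recombination statistics,
somatic hypermutation, batch effects, ambient RNA, doublets, cell-type
misannotation, or partial phenotype switching of expanded clones. Passing
the planted-truth benchmarks therefore demonstrates correctness of the
*computational* pipeline under its stated model, not robustness to every
artifact of real droplet data.

## Problem sizes and determinism

The validation suite runs multi-seed benchmarks at deliberately desk-scale
sizes: expansion recovery and diversity direction use 20 seeds of
2-patient cohorts with 1500 cells per sample (≈525 baseline CD8 cells per
patient, above the 500-cell floor at which the recovery guarantees are
stated); module-K recovery uses 50 seeds of 100-gene planted profiles; the
score-calibration checks use cohorts of ≥2000 cells. Every stochastic
stage takes an explicit seed, simulation is bit-reproducible for a fixed
configuration, and the staged pipeline writes byte-identical artifacts
across reruns at a fixed seed (the manifest timestamp aside).

## Known limitations

* The Mann–Whitney DE substitute does not model dropout or cellular
  detection rates; genes expressed in very few cells are underpowered
  relative to hurdle-model tests.
* Silhouette-based K selection is only as sharp as the separation in the
  fold-change profile; report the silhouette curve, not just K.
* Expansion classification treats observed counts as exact; no sampling
  uncertainty is propagated, matching the rule-based definition rather
  than a model-based test for clonal growth.
* Morisita–Horn between very shallow repertoires is noisy; interpret
  cross-sample similarity heatmaps with repertoire sizes in hand.
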