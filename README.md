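# loopregnet

Multi-omics integration for case/control epigenome panels: one control cell
line against a panel of N tumour-derived lines profiled with peak-based
assays (histone ChIP-seq, ATAC-seq, CUT&RUN), promoter-anchored HiChIP
loops, and RNA-seq. The package implements the presence/absence logic that
turns such a panel into a regulatory story: which chromatin regions and
loops are specific to the control or recurrently acquired by the cases,
which genes change expression in *every* case line, and which transcription
factors plausibly drive those changes.

It is aimed at computational biologists who already have per-sample peak
calls (BED), loop calls (BEDPE with counts and FDR), a count matrix and
motif models, and want the downstream integration — not at read-level
processing (alignment, peak calling and loop calling are out of scope).

## The statistics at the core

**Differential regions by quantifier rules.** A boundary sweep partitions
the union of all per-sample peaks into maximal segments of constant
per-sample presence (≥ 1 bp overlap). With control presence C ∈ {0, 1} and
case presence count m out of n:

- lost (control-specific): C = 1 and m = 0,
- gained (case-recurrent): C = 0 and m ≥ k (default k/n = 10/15),
- shared: present in every sample; anything else is *other*.

The same machinery supports two control slots (e.g. two normal cell types)
and other k-of-n rules, such as k/n = 6/13 for TF-binding panels.

**Differential loops.** Loop calls are filtered (count ≥ 2, FDR < 0.01,
span ≥ 5 kb), anchors are unified across samples by single-linkage merging
(gap ≤ 500 bp), and unified loops get per-sample counts. Lost: control
count ≥ 2 and all case counts 0; gained: control count 0 and count ≥ 2 in
≥ 8 of 14 cases. Loops are classed P-P / P-E / E-E by promoter-window
(TSS ± 2 kb) overlap of their anchors; a loop is *multi-anchor* when an
anchor is used by two or more loops (hubs = connected components with ≥ 2
loops); spans (anchor midpoint distance) of lost vs gained loops are
compared with a two-sided Welch t-test.

**Core DEGs.** Each case line is compared to the control (median-of-ratios
normalization; variance-moderated t on log2 normalized counts as a
documented stand-in for a negative-binomial Wald test), a gene is
significant at p < 0.01 AND BH-FDR < 0.01, and the core DEG set is the
intersection of the N per-line significant sets.

**Regulatory network.** PWMs are scanned by log-odds score
`sum(log2(p_b / bg_b))` on both strands; motif enrichment in gained regions
vs background regions uses the exact hypergeometric upper tail with BH
correction; key TFs are enriched motifs whose own gene is a core DEG;
TF→target edges arise from motif hits inside gained regions, assigned to
the nearest TSS (proximal < 2 kb / distal); the spatial coupling of a motif
pair is the per-region minimum midpoint distance, compared target vs
background by a two-sided Wilcoxon test.

Every stage is testable without external data through a deterministic
synthetic-data generator (`generate_synthetic_study()`) that plants ground
truth with the study's design parameters: lost loops with median span
254 kb vs gained 114 kb, 85% of gained loops promoter-promoter and
organized in hubs, 100 core DEGs at |log2FC| = 2 with NB dispersion 0.05
and 3 replicates/line, motif pairs spaced 56 bp in target promoters vs a
median of 124 bp in background promoters, and a 47-target TF sharing 33
targets (70.2%) with its partner.

## Worked example

```r
library(loopregnet)
cfg <- synth_config(seed = 1, preset = "tiny")   # 2 x 2 Mb toy study
res <- run_pipeline(pipeline_config(outdir = "toy_run", synth = cfg))
```

The run writes per-stage files (segments.bed, de_results.tsv,
unified_loops.tsv, motif_hits.bed, tf_target_edges.tsv, key_tfs.tsv, ...)
plus `report.json` under `toy_run/`. The report for this seed prints:

```
regions: lost 12 gained 34 shared 160
core DEGs: 40 from 15 pairwise comparisons
loops: lost 15 gained 24
gained P-P fraction: 0.8333333
median span lost/gained (bp): 257481 / 112041  p = 5.88e-08
key TFs: g0083, g0093
common-target fraction: 66.7 %
motif pair medians (target/background): 56 / 124 bp, p = 9.64e-06
```

Reading: of the consensus segments, 12 are control-specific and 34
case-recurrent; 40 genes are differentially expressed in all 15 case
lines; lost loops are long-range (~257 kb) and gained loops short-range
(~112 kb); 83% of gained loops connect two promoters; both planted TFs are
recovered (motif enriched in gained regions and themselves core DEGs);
their motifs sit 56 bp apart at common-target promoters versus 124 bp in
background promoters. Every number equals the generator's planted truth —
that is the point of the synthetic preset.

A thin CLI wrapper is installed at `inst/cli/loopregnet.R`
(`synth` and `run-all` subcommands).

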