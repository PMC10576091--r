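---
title: "Methods: presence/absence integration of regions, loops, expression and motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence/absence integration of regions, loops, expression and motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the tunable parameters, the design choices
made where the design was genuinely open, and what the planted-truth test
suite does and does not demonstrate about real data.

## Study design and coordinate conventions

The package targets a one-control / N-case panel design: a normal cell
type as reference and many tumour-derived lines as cases, each profiled
with peak-based chromatin assays, promoter-anchored loops and RNA-seq.
All genomic coordinates are 0-based half-open (BED convention) everywhere
inside the package; GTF input (1-based closed) is converted at the parser
boundary and nowhere else. Output files are sorted by chromosome in byte
order so that repeated runs are bit-stable regardless of locale.

## Differential regions by multi-sample segmentation

`atomic_segments()` performs a boundary sweep: every peak start and end
across all samples becomes a breakpoint, yielding maximal segments on
which per-sample presence (defined as at least 1 bp of overlap) is
constant. This is the multi-intersection view of a panel of peak sets —
the union of the segments equals the union of all inputs, a conservation
property the tests check, and a per-base brute-force oracle reproduces the
segmentation exactly on random instances.

`classify_segments()` applies quantifier rules to the presence vectors:

* **lost** — present in every control slot, absent in all cases;
* **gained** — absent in every control slot, present in at least *k* of
  *n* cases (default 10 of 15);
* **shared** — present in every sample; the remainder is **other**.

Decisions taken where the underlying convention is ambiguous:

* *Presence* means ≥ 1 bp overlap; no overlap fraction is imposed, which
  matches the semantics of multi-intersection tooling.
* Rules are evaluated at the segment level, not the whole-peak level, so a
  case peak partially overlapping a control peak splits into a shared part
  and a differential part.
* `min_width` defaults to 1 bp (no width filtering) and is configurable;
  adjacent same-label segments are merged before filtering.
* The rule object is parameterized as k-of-n with any number of control
  slots, so a two-control design (e.g. TF-binding panels requiring absence
  in both normal lines, presence in ≥ 6 of 13 cases) reuses the same code.

TSS annotation is strand-aware (TSS = 5' end of the gene model), distance
is zero for intervals containing the TSS and otherwise the gap from the
nearest interval edge, and the proximal/distal boundary is a symmetric
TSS ± 2 kb window. Symmetry is a choice: the source convention ("< 2 kb
from the TSS") does not state sidedness, and symmetric windows are the
common default of annotation tools. Nearest-gene ties break to the
lexicographically smallest gene id, making annotation deterministic.

## Differential loops

Loop calls are first filtered per sample — support count ≥ 2, FDR < 0.01
where an FDR column exists (skipped with a warning otherwise), span
≥ 5 kb — and only then unified, so a call failing significance in one
sample never contributes counts to a unified loop.

**Span.** A loop's span is the distance between anchor midpoints (floor
division). The alternatives (inner or outer span) depend on anchor widths,
which differ between samples and callers; midpoint distance is invariant
under symmetric anchor widening and is the convention recorded in every
output.

**Anchor unification.** Single-linkage merging of anchor intervals with a
maximum gap of 500 bp (configurable). Single linkage is transitive by
design: chains of near-adjacent anchors collapse into one anchor, which is
what cross-sample loop identity requires when each caller jitters anchor
boundaries. Within-sample duplicate calls mapping to one unified pair have
their counts summed (conservative toward presence). A loop absent from a
sample's file has implicit count 0.

**Differential rules.** lost: control count ≥ 2 and every case count
exactly 0; gained: control count 0 and count ≥ 2 in ≥ 8 of 14 cases;
shared requires the control and ≥ k cases to pass the presence count. The
count thresholds and k are configuration fields.

**Classes and hubs.** An anchor is a promoter anchor when it overlaps any
TSS ± 2 kb window; loop classes are P-P (both anchors), P-E (one), E-E
(none, distal-distal). Multi-anchor loops share an anchor with another
loop (degree ≥ 2 in the anchor graph); hubs are connected components with
at least two loops. Lost vs gained span distributions are summarized by
median and IQR and compared with a two-sided Welch t-test; when several
marks or conditions are analysed the caller adjusts that family of
p-values with `bh_adjust()`.

## Expression: the stand-in DE engine and the core intersection

Counts are filtered at a minimum row sum of 10, normalized by
median-of-ratios size factors (reference = per-gene geometric mean over
samples, computed on genes positive everywhere), and each case line is
tested against the control.

The package deliberately does not reimplement a negative-binomial Wald
test. The default engine fits a linear model to `log2(normalized + 1)` per
gene and moderates the per-gene variance by empirical-Bayes shrinkage
across the transcriptome (limma's `lmFit`/`eBayes`). The moderation
matters: with three replicates per side, a plain per-gene Welch t-test has
about 74% power at p < 0.01 for a 4-fold change at NB dispersion 0.05, and
an intersection over 15 comparisons then retains almost nothing
(0.74^15 ≈ 1%). Sharing variance information across genes — the same
reason NB engines share dispersion estimates — restores per-comparison
power to the level the intersection design presupposes, while keeping the
decision structure identical: per-gene log2 fold change (computed from
mean normalized counts with a 0.5 pseudo-count), p-value, BH q-value
within the comparison, and the dual threshold p < 0.01 AND q < 0.01. A
plain Welch engine remains available (`engine = "welch"`), and the engine
label is recorded in the result metadata so no output can be mistaken for
an NB Wald fit. Externally computed DE tables in the same schema can be
intersected directly.

FDR is computed within each pairwise comparison (not globally): each
comparison is its own multiple-testing family, mirroring per-comparison DE
runs. The core DEG set is the strict intersection across all comparisons;
`rule = "at_least_k"` relaxes this when wanted. Exclusive membership
patterns over the union are reported UpSet-style.

Signature distances are Euclidean distances between samples over a gene
subset of a log-scale expression matrix, with average-linkage clustering
for a deterministic leaf order; `log2(normalized + 1)` stands in for a
regularized log transform and is recorded as such.

## Regulatory network

PWM scanning scores every window on both strands with the log-odds score
in bits; windows containing N are skipped; the minus strand is scanned via
the reverse-complemented matrix so coordinates always refer to the plus
strand. The default threshold is 80% of a motif's maximum attainable
score, configurable and recorded. Known-motif scanning with explicit PWMs
replaces de-novo motif discovery (out of scope): the downstream logic
needs reproducible hit positions for named TFs.

Enrichment counts a region as a carrier when a hit lies fully inside it
and tests carriers among targets vs background with the exact
hypergeometric upper tail, BH-adjusted across motifs. The background is an
explicit argument (background regions overlapping targets are excluded
automatically); the pipeline uses the shared (non-differential) regions of
the same assay, whose width distribution matches the differential regions
by construction in the synthetic study, so no additional width-matched
subsampling is applied there. Key TFs must satisfy both conditions: motif
enrichment p below the threshold and the TF's own gene in the core DEG
set.

TF→target edges require a hit inside a gained region; the target is the
gene with the nearest TSS to the hit midpoint (ties within 1 bp each
receive an edge; beyond that, lexicographic tie-break), and the
proximal/distal zone uses the same 2 kb cutoff. A containment audit
(every edge's hit inside its evidence region) runs on every call. The
motif-pair distance of two TFs is, per region containing both motifs, the
minimum over hit pairs of the absolute midpoint distance; targets and
background are compared by a two-sided Wilcoxon test. The exact
permutation mode is used automatically up to a combined n of 20 (it
enumerates the U distribution and is therefore oracle-checkable, including
under ties); larger samples use the tie-corrected normal approximation
with continuity correction. Both modes exist because small region sets are
common in this analysis and the exactness cutoff is a documented choice.
P-values are reported as computed, never truncated.

## The synthetic study: what it emulates and what it does not

`generate_synthetic_study()` plants, deterministically per seed:

* a toy genome (default 2 chromosomes × 5 Mb, 400 genes on a jittered
  grid, GC 0.41; `tiny` preset 2 × 2 Mb, 160 genes) — roughly 1/500 of a
  mammalian genome, keeping end-to-end runs under a minute;
* peaks: shared everywhere, 40 lost (control-only), 60 gained in k ~
  Uniform{10..15} random cases (k drawn per region to exercise the rule
  boundary), widths 600–1500 bp, placed on a collision-free slot grid;
  optional jitter and case-dropout noise (defaults 0: the noise-free
  setting is the primary validation surface);
* loops: 50 lost with span median 254 kb, 80 gained with span median
  114 kb (log-normal factors, sdlog 0.35, constructed so the planted
  sample median is exact), 85% of gained loops P-P and grouped into hubs
  of 2–4 loops sharing a promoter anchor, 86.6% of lost loops involving
  an enhancer anchor; per-sample junk calls that must die in the
  significance filters;
* counts: NB(μ, dispersion 0.05) with log-normal base means (log-mean
  log 200, log-sd 1), 100 core DEGs shifted ±2 log2 units in all 15
  lines, 30 sporadic DEGs shifted in only 2–5 lines (they must not reach
  the core), 3 replicates per line;
* motifs: two 12-bp consensi written into promoter peaks — spaced exactly
  56 bp (midpoint to midpoint) at the 33 common-target promoters, single
  motifs at A-only (14) and B-only (15) target promoters, and pairs with
  an exact sample median of 124 bp at 100 background promoters. All
  chance occurrences of either consensus (both strands) are scrubbed from
  the genome first and an audit verifies exclusivity, so a max-score scan
  provably returns the planted set and nothing else.

Numerical notes: NB draws use `rnbinom(mu, size = 1/dispersion)`;
promoter-anchor placement snaps to the nearest free gene TSS and then
shifts the anchor centre up to ±2 kb toward the exact target span (the
residual snap error is why realized gained-span medians sit within a few
percent of 114 kb rather than exactly on it); enhancer anchors keep ≥ 4 kb
from every TSS and ≥ 2 kb from other anchors, with a bounded nudge budget
that errors out rather than silently misplacing.

What passing the planted-truth suite shows: the rule logic, segmentation,
unification, intersection and scanning machinery are exact — precision and
recall 1 in the noise-free setting, graceful degradation under dropout.
What it does not show: robustness to realistic peak-caller noise
(irregular peak boundaries, partial overlaps), copy-number distortion of
counts, sequencing-depth imbalance, motif degeneracy, or annotation
incompleteness. Real-data use should treat the thresholds (k-of-n,
count/FDR/span filters, 2 kb window, scan threshold) as the tunable
surface they are; every one is a configuration field echoed in the run
report.

## Determinism and problem sizes

Every generator seeds its own RNG substream from the configured seed, so
outputs are byte-identical whether stages run standalone or composed, and
`run_pipeline()` reports are byte-identical across reruns (the config hash
covers thresholds, seed and input names, not output paths). The test
suite validates the statistics at small exact sizes (hypergeometric tail
against direct summation for all populations up to 30; exact Wilcoxon
against full enumeration up to combined n = 10; segmentation against a
per-base oracle on 100 kb instances) and the pipeline at the `tiny` and
default synthetic scales described above — sizes chosen so the complete
suite validates every stage in about two minutes on one core.
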