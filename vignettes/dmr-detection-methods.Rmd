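---
title: "Detecting differential 5mC and 5hmC regions with dmrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential 5mC and 5hmC regions with dmrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrkit)
```

## The problem

DNA methylation (5mC) and its oxidised form hydroxymethylation (5hmC) are
the two most abundant cytosine modifications in vertebrate genomes, and
their redistribution marks development and disease. HMST-seq measures both
simultaneously at CCGG sites through three restriction-enzyme tag
libraries; WGBS and RRBS measure bulk methylation per base but cannot
separate the two marks. In all three assays, per-site coverage is limited,
so the variation of a single CpG across samples is dominated by sampling
noise. `dmrkit` therefore tests *regions* — clusters of nearby methylated
sites inside biologically meaningful annotations — and treats sites missing
in one condition as data to be imputed rather than discarded, because a
missing level often records a genuinely unmethylated state.

## From tag counts to site levels

For HMST input, the per-site 5mC level is `BGT / HpaII` and the 5hmC level
is `MspI / BGT`. These ratios are unbounded above and are not fractions;
the conventional "significantly modified" threshold for them is a level
above 1, versus 0.5 for WGBS/RRBS fractions. Two numerical choices matter:

* **Denominator guard.** A zero denominator (e.g. HpaII = 0 at a fully
  methylated site) is replaced by `max(denominator, epsilon)` with
  `epsilon = 1` normalized tag count by default. This keeps fully
  methylated sites in the analysis — the sites most worth keeping — at the
  cost of a mild compression of very large ratios. Sites with a zero
  *numerator* are not emitted for that context, since the ratio carries no
  signal there.
* **Quantile normalization.** When tag counts are not already normalized
  across samples, each library column can be quantile-normalized: each
  sample's sorted values are replaced by the across-sample mean at the
  same rank. Samples of unequal size are interpolated onto a common
  mid-rank grid `(i - 0.5) / n`, the standard extension; ranks, and hence
  every within-sample ordering, are preserved exactly.

## Genome partition

Each refFlat transcript yields a TSS region (TSS ± 1 kb), a TES region
(TES ± 1 kb), the gene body strictly between the two flank regions, and a
strand-aware 5′-distance region 10–100 kb upstream of the TSS (on the
minus strand, upstream extends to higher coordinates). Intergenic regions
are the per-chromosome complement of all TSS/TES/gene-body regions, with
segments shorter than 2 kb discarded and segments longer than 100 kb
truncated to their first 100 kb — truncation rather than deletion
preserves coverage adjacent to genes, and a split mode tiles the whole
segment for users who want full intergenic coverage. All coordinates are
0-based half-open throughout, matching BED and the UCSC txStart/txEnd
convention, and are clipped to the chromosome bounds. Transcripts are
processed independently (refFlat is transcript-level); identical regions
from duplicate transcripts are deduplicated afterwards. A gene shorter
than the two flanks combined gets no gene body — there is no positive-
length interval strictly between its flanks — but keeps its flank regions.
5′-distance regions are deliberately *not* subtracted from intergenic
space: the intergenic class is defined only against TSS/TES/gene body, so
the two classes may overlap, and density summaries should not be read as a
partition across those two classes.

## MR search

Within one region, sites are scanned in coordinate order; a cluster breaks
wherever the gap between consecutive sites exceeds the adjacency `a`
(default 2000 bp; a gap exactly equal to `a` stays in the cluster), and
clusters below the class minimum are dropped. The minimums follow the
`mc1`/`mc2`/`mc3` convention: `mc1` (default 3) for TSS/TES, `mc2`
(default 5) for gene body, 5′-distance and intergenic, and `mc3` (default
3) for enhancer and custom classes — the binding of `mc3` to enhancers is
this package's documented choice, and `min_sites_for_class()` makes the
mapping explicit so it can be re-bound. A site inside two overlapping
regions contributes to both, since each region class is searched
independently. The window mode tiles each region from its own start into
non-overlapping `window_size` windows (region-anchored rather than
genome-anchored tiling — the choice keeps windows comparable across
regions of one class); it suits dense WGBS data where adjacency clustering
would fuse everything.

Suggested presets: HMST `a = 2000`, `mc1 = 3`, `mc2 = 5`; RRBS `a = 200`,
all minimums 2, same-trend on, T-test; WGBS window mode with 200 bp
windows, `mc1 = 3`, `mc2 = 5`.

## Pairing, imputation and testing

Case and control MRs share a locus when their bounding intervals overlap
by at least one base inside the same parent region; all transitively
overlapping MRs on either side merge into one paired locus, which also
gives replicate samples a natural treatment — each replicate contributes
one aligned level vector over the union of positions, and the vectors are
concatenated per condition before testing. Positions unobserved in a
condition are imputed: zeros by default (a plausible real unmethylated
state), the MR median, or the nearest observed neighbour (ties resolved to
the lower coordinate).

The default test is the Wilcoxon rank-sum. Its P-value is computed two
ways:

* **Exact enumeration** when the MR has fewer than 10 sites
  (`nx < exact_threshold`, counted on the union position set). The null
  distribution of the rank-sum over all `choose(nx + ny, nx)` assignments
  of the pooled mid-ranks is built by the shift algorithm — a
  generating-function dynamic programme over integer-doubled ranks — which
  equals literal enumeration but runs in polynomial time, handles ties
  through mid-ranks, and the two-sided P-value is the doubled smaller
  tail, capped at 1 (the convention that matches the approximation it
  hands over to). The distribution's counts stay exact in double precision
  whenever `choose(nx+ny, nx) < 2^53`, which always holds on the exact
  path.
* **Normal approximation with tie and continuity correction** otherwise,
  via `stats::wilcox.test(exact = FALSE)`.

An alternative joint gate (`min(nx, ny) < 10 && nx + ny < 20`) is
available behind `joint_exact_rule` but is not the default; the default
gate uses the MR site count alone. The T-test (pooled variance; P = 1 by
convention for zero-variance input) and the two-sample KS test are
alternatives suited to WGBS-scale data. With the same-trend gate
(`isST = 1`) a pair is tested only if both conditions' *original* level
sequences are same-trend — all nonzero signs of consecutive differences
identical; zero differences never veto. Originals are used because imputed
zeros would spuriously break otherwise monotone trends. Gating happens
before testing (the condition reads as MR admissibility, not a
post-filter).

P-values are thresholded at `alpha = 0.05` by default, optionally after
Benjamini–Hochberg adjustment computed globally across the full record
list of one context — a single global FDR is the interpretable quantity
when region classes are later re-aggregated, though it is a choice the
interface exposes rather than a forced one.

## Direction

`rratio = (μ_case − μ_control) / ((μ_case + μ_control) / 2)` on the
medians of the **original** levels only — imputation never moves the
direction estimate. Positive means hypermethylated, negative
hypomethylated; both medians zero gives 0 and the label `none`. The
statistic is antisymmetric under swapping the conditions.

## Summaries

* **Relative density**: sites with level strictly above the threshold
  (1 for HMST, 0.5 for WGBS/RRBS) per megabase of each class's merged
  footprint. Per-Mb normalization is this package's labelled convention —
  "relative density" needs a unit, and footprint length is the
  denominator that makes classes of very different extent comparable.
* **Direction percentages**: hyper and hypo shares per class; rows sum to
  100 and classes without DMRs are absent rather than zero-filled.
* **Meta-profile**: each gene's TSS, body and TES are rescaled to three
  fixed sub-axes of 100 bins each (configurable; 100 bins keeps the
  2 kb flank regions at 20 bp/bin, comfortably below typical CCGG
  spacing), sites are placed by transcription-direction position,
  each bin takes the nearest observed site's level (exact at observed
  points, extending at the ends), and bins are averaged over genes with at
  least one site. Smoothing is a centred moving average
  (`MA_t = (1/n) Σ_{i=−n/2..n/2} A_{t+i}`, default n = 3, even windows
  widened to odd for symmetry) followed by a 1-D Gaussian filter (default
  sigma 2 bins, kernel truncated at 4 sigma), both with reflective edge
  padding — the formula is stated without boundary treatment, and
  reflection keeps constants invariant and the output mean close to the
  input mean. Both steps are linear.
* **Per-MR plots**: diamonds for original levels, circles for imputed
  ones, case and control in separate colours, titled
  `chrom:start:end:strand:gene p=…`; every figure has a sibling TSV of
  exactly the plotted values, so figures are regenerable from exports
  alone.

## Pipeline and determinism

Eight stages (`qc`, `annotate_genome`, `preprocess`, `find_mrs`,
`prepare_dmr`, `dmr_search`, `annotate_dmrs`, `summarize`) run
individually or via `run_pipeline()`; a JSON manifest records the
parameter snapshot, input digests and completed stages, so re-runs skip
finished stages and any parameter change invalidates the bookkeeping. The
three heavy stages shard by chromosome across `n_cpus` workers
(chromosomes are the natural independent unit here); every table is
canonically sorted and numbers are printed with fixed formatting before
writing, so serial and parallel runs are byte-identical. The statistical
stages draw no random numbers at all — only fixture generation consumes
the seed, which the manifest records.

## What the synthetic generator emulates — and what it does not

`generate_fixtures()` builds a small genome (3 chromosomes of 1 Mb, 20
genes each by default) and writes HMST tag counts by inverse-ratio
construction: per-site levels are drawn first (Gaussian around a
per-region baseline uniform on 0.5–1.5, noise sd 0.2, truncated at zero)
and encoded as `HpaII ~ U(5, 20)`, `BGT = 5mC · HpaII`,
`MspI = 5hmC · BGT`, so the ratio computation recovers the planted levels
exactly. A quarter of TSS loci receive a mean shift of 0.6 — three times
the noise scale, a strong but realistic promoter-scale effect — with
random hyper/hypo sign, independently per context, and the planted loci
are written to a truth table. `simulate_paired_loci()` generates the same
level model directly at the paired-MR stage (8–15 sites per locus) for
calibration of the tests in isolation.

What the generator does **not** emulate: spatially correlated methylation
along a locus (sites are independent given the baseline), coverage-
dependent level precision, bisulfite conversion error, strand asymmetries,
or CCGG positional bias. Passing the recovery and calibration checks
therefore shows the statistical machinery is correct under its stated
model, not that real data meets those assumptions — on real data the
effective per-locus correlation typically inflates variance relative to
this model, and P-values should be read accordingly.

Problem sizes used by the test-suite and acceptance checks — 2000 paired
loci for calibration, 500 random configurations for the clustering
oracle, roughly a thousand small-sample cases for the exact-test oracle,
and a 2–3 chromosome pipeline run — are chosen so the whole suite
completes in about a minute while keeping Monte-Carlo error well inside
the asserted bounds.

## Known limitations

* Coverage is not propagated into the tests; a beta-binomial model that
  weights sites by depth would be the natural extension.
* The exact path's gate uses the printed single-sided rule (`nx < 10`);
  the control-side count does not gate the default path.
* Multiple testing is corrected per context over all classes jointly;
  per-class FDR control would need the records split before
  `call_dmrs()`.
* WGBS/RRBS level files carry no read counts, so the QC stage can report
  only site counts for them.
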