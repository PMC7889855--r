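---
title: "Regulatory hubs: from CTCF loops to putative causal elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulatory hubs: from CTCF loops to putative causal elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Disease-risk variants identified by GWAS mostly fall in non-coding DNA, inside
linkage-disequilibrium (LD) blocks that may contain many regulatory elements
and no obvious target gene. One emerging model of transcriptional regulation
holds that genes are controlled within *regulatory hubs*: sets of genomic
regions held in spatial proximity by chains of CTCF-mediated chromatin loops,
inside which many enhancers and promoters interact. Under that model, the
question "which gene does this risk variant regulate?" becomes: find the hub
the LD block belongs to, then ask which elements in the hub explain the
expression of which hub genes.

`hublinker` implements that computation as a reusable, testable pipeline:

1. **Consensus peaks.** Per-sample CTCF (and ATAC) peak calls are merged into
   candidate regions; a region is a *consensus peak* when at least a
   threshold fraction (default 60%) of the group's samples have a peak
   overlapping it.
2. **Loop filtering.** CTCF-HiChIP loops are kept only when they have at
   least 2 supporting reads and both anchors land on consensus peaks.
3. **Hub discovery.** Loop anchors are merged into disjoint nodes; each loop
   is an edge. Starting from an LD block, everything it touches, everything
   those regions touch, "and so forth" is exactly transitive closure, so a
   hub is the connected component of the anchor graph containing the block.
   LD blocks touching no anchor are *inactive* and reported as such.
4. **Membership.** Hub genes are those whose promoter window (TSS ± 2 kb by
   default) overlaps an anchor region or a seed LD block; hub ATAC peaks are
   consensus regions under the same test. Elements inside the LD block
   itself are always scoreable even if they miss every anchor.
5. **Per-gene model.** For each hub gene *i* with expression
   $Y_i$ (log~2~ CPM), the candidate features are the expression of the
   other hub genes $Y_t$ ($t = 1..T$, target excluded) and the accessibility
   $A_p$ of the hub's ATAC peaks ($p = 1..P$):
   $$Y_i \sim \sum_{t}^{T} Y_t + \sum_{p}^{P} A_p$$
   All-relevant feature selection (a Boruta-style shadow-feature algorithm
   over random-forest importance) decides which features carry information
   about $Y_i$. Because the selector is stochastic, it is run 50 times and
   only features confirmed in at least 95% of runs are retained.
6. **Causal assignment.** Retained features lying within a risk LD block
   become *putative causal elements*; every gene whose model retained such
   an element becomes its *putative target gene*.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `consensus_threshold` | 0.6 | fraction of samples | consensus peak rule |
| `min_reads` | 2 | reads | loop support filter |
| `min_cpm`, `min_samples` | 1, 5 | CPM, samples | expressed-gene filter |
| `promoter_pad` | 2000 | bp | promoter half-width around the TSS |
| `anchor_pad` | 0 | bp | optional slack around anchors before overlap |
| `prior` (log-CPM) | 0.5 | pseudo-count | finiteness at zero counts |
| `n_runs` | 50 | runs | stability repetitions per gene |
| `retention_fraction` | 0.95 | fraction of runs | stability retention rule |
| `alpha` | 0.05 | level | per-iteration binomial decision test |
| `n_trees` | 100 | trees | forest size per Boruta iteration |
| `max_iterations` | 100 | iterations | per-run budget; undecided ends Tentative |

The promoter half-width of 2 kb is the common regulatory-genomics convention
for "promoter"; nothing in the hub definition depends on it strongly, and it
is exposed as a flag. `anchor_pad` defaults to 0 because overlap is defined
as ≥ 1 shared bp under 0-based half-open coordinates — bookended regions do
not overlap — and any padding belongs to an explicit, visible knob rather
than the overlap primitive.

## Numerical and procedural choices

* **"At least 60%" / "at least 95%" are exact rational comparisons.** 3 of 5
  samples passes 0.6, 48 of 50 runs passes 0.95, 47 of 50 fails. The
  implementation compares counts against `ceiling(frac * n - 1e-9)`; the
  tiny guard only absorbs binary-float artifacts such as
  `0.6 * 5 == 3.0000000000000004`.
* **Consensus support is counted per merged region**, not per base: the
  candidate regions are the merged union of all samples' peaks, and the
  support of a candidate is the number of distinct samples with ≥ 1 bp of
  overlap. This matches the consensus semantics of replicate-peak tooling
  and yields stable region boundaries. Where per-sample calls coincide in
  coordinates (the regime the test oracles use), region-level and per-base
  counting provably agree; with chained partial overlaps they can differ,
  which is why the merge happens *before* counting, deterministically.
* **Boruta details.** Each iteration appends a permuted shadow copy of every
  active feature (padded to at least five shadows), fits a
  100-tree random forest (impurity importance, single-threaded, seeded), and
  scores a hit for each undecided feature beating the best shadow. Decisions
  use a two-sided binomial test on hit counts at level `alpha`, corrected
  twice: Bonferroni across the *full* candidate feature set (correcting only
  across the still-undecided features would let the last lucky survivor
  confirm against a trivial threshold), and `alpha/iteration` for testing
  the same feature at every iteration (the sequential-testing control of
  shadow-feature selectors; without it a constant-level test applied
  repeatedly is anti-conservative). Zero-variance features
  are auto-rejected with a log message. A run is fully deterministic given
  `(design, seed, params)`; stability run *r* uses `base_seed + r`, so any
  single run can be re-executed from the log.
* **"Significant in at least 95% of runs" counts Confirmed only.** Features
  still Tentative when the iteration budget ends do not count; this is the
  conservative reading, switchable via `count_tentative = TRUE`.
* **Element naming.** Elements overlapping a gene span take the gene's id
  (leftmost start wins ties, with a log note); intergenic elements are named
  `Peak_<k>` by 0-based position in the coordinate-sorted consensus list.
  Names are labels for reporting, never keys.
* **LD-block membership is any-overlap** (≥ 1 bp), both for seeding hubs and
  for calling an element "within" a block; strict containment is available
  via `contained = TRUE`. The underlying definitions in the field are
  ambiguous, so both are exposed and the default is the more inclusive one,
  consistent between the two places it is used.
* **Inter-chromosomal loops are accepted**: nothing in the hub definition
  forbids a component spanning chromosomes.
* **Library sizes** default to the column sums of the supplied count matrix.
  When the matrix is genome-wide this is the standard CPM denominator; for
  hub-scale extracts an externally computed `lib_sizes` vector can be
  supplied to keep fidelity to genome-wide normalisation.
* **Expressed-gene filter:** CPM ≥ 1 in ≥ 5 samples, applied to genes before
  they can serve as response or feature. (Published uses of this rule have
  quoted slightly different genome-wide totals in different sections; the
  filter here is the explicit rule, not any quoted total.)

## The synthetic-data generator

`simulate_bundle()` produces a complete desk-scale input bundle with known
ground truth; its defaults *are* the package's reference study conditions:

* 20 matched samples with both RNA-seq and ATAC-seq;
* 2 hubs, each a chain of 4 anchors (one chromosome per hub), chained by
  **two loops per adjacent anchor pair** — a loop observed in more than one
  sample — so the planted connectivity survives the ≥ 2-read filter despite
  the `1 + Poisson(mean − 1)` read-support draw;
* 4 genes and 6 ATAC peaks per hub; 4 planted element→gene links at
  β = 2 (log~2~ expression units per unit latent accessibility), with the
  planted peaks and one decoy peak placed inside the hub's active LD block;
* one active LD block per hub plus as many inactive blocks again, the
  latter overlapping no anchor;
* per-sample peak drop-out at rate 0.1 (coordinates otherwise exact);
* latent accessibility $a_{ps} \sim N(\mu_p, 1)$; latent log-expression is
  baseline plus $\beta$ times the *centred* accessibility of planted peaks
  plus $N(0, 0.5)$ noise — centring simply absorbs $\beta\mu_p$ into the
  baseline so simulated expression stays in a realistic log-CPM range;
* counts observed as negative binomial with mean $2^{\text{latent}}$ scaled
  by a per-sample depth factor, dispersion 0.1;
* 100 background genes and 40 background peaks outside all hubs. The
  background matters: CPM normalisation divides by column sums, and with
  only a handful of genes a single strongly-driven gene would move every
  other gene's log-CPM, manufacturing compositional correlations that
  genome-wide normalisation never shows. A fifth of background genes are
  near-silent so the expressed filter has something to remove.

Everything derives from one master seed through named sub-streams
(loops, CTCF drop-out, ATAC drop-out, latent variables, counts), so a stage
can be regenerated in isolation and identical configurations give
byte-identical bundles on disk.

**What the generator does not emulate:** real peak-width and loop-length
distributions, coordinate jitter between replicate peak calls, GC/mappability
artifacts, correlated accessibility between neighbouring elements,
trans-effects, or confounding covariates (batch, age, treatment). Passing
tests on this generator therefore demonstrate the *computational* contract —
each stage does what it claims on data with the assumed statistical
structure — not that the biological assumptions hold in any real cohort.

`simulate_selection_design()` is a smaller benchmark for the selection stage
alone: 20 samples, 12 independent standard-normal features of which 3 drive
the response at β = 2 noise-SDs. The test suite scores the stability
selector on 10 such replicates (planted-feature sensitivity and decoy false
retention) and on 50 permuted-response null datasets (how often the retained
set is empty) — these are the problem sizes the suite runs, and the measured
values are what the acceptance report recomputes.

## Known limitations

* **All-relevant selection is not causal discovery.** With 20 samples the
  sampling correlation between an unrelated peak and a gene has standard
  deviation ≈ 0.24, so |r| ≈ 0.5 associations arise by chance; an
  all-relevant selector rightly calls such a feature informative *in that
  dataset*, and repeating the selector 50 times on the same data removes
  only algorithmic randomness, not sampling noise. The same mechanism means
  a minority of pure-noise datasets contain a feature correlated strongly
  enough by chance to be retained through the full stability filter.
  Emitted element→gene pairs are therefore *putative*: on the reference
  bundle the pipeline recovers all planted links, but typically also emits
  one or two chance-association pairs. A larger cohort, not more selector
  runs, is what shrinks this.
* Consensus support counting is region-level by design; pathological
  chained-overlap geometries can retain bases a per-base rule would drop.
* The per-gene models treat other genes' expression and peak accessibility
  symmetrically as features; retained gene-features are reported like any
  other element (named by their gene), with no directionality claim.
* Differential expression, peak calling, loop calling and LD-block
  construction are upstream of this package and are consumed as inputs.
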