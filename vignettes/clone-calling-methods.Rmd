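---
title: "Methods: clone detection from multiplexed sgRNA barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone detection from multiplexed sgRNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescreen)
```

## The model

In a high-MOI single-cell CRISPR screen every cell integrates a set of
sgRNAs, and all descendants of an infected founder inherit that set. The
guide complement of a cell is therefore a clonal barcode. `clonescreen`
formalizes "same clone" as a hypergeometric question: if cell 1 carries `n`
of the `M` library guides and cell 2 carries `N`, and the two cells were
unrelated, the number of shared guides `X` would follow
`Hypergeometric(M, n, N)`. The clonality evidence is the survival
probability `P(X >= x)` at the observed overlap `x`.

Two numerical points matter:

* **Log space throughout.** With `M ~ 20,000` and `n = N ~ 30`, clonal
  pairs routinely reach p-values of 10^-30 and far below. All p-values are
  computed and carried as `log10 p` via the log-space hypergeometric
  survival function (`stats::phyper(log.p = TRUE)`, itself built on
  log-gamma), and never exponentiated below the representable range. The
  test suite validates the implementation against an independent oracle:
  exhaustive enumeration of all `C(M, N)` draws for every library size up
  to 12.
* **The test convention** is `P(X >= x)`: an overlap of zero has p = 1
  (`log10 p = 0`), and the statistic is monotone non-increasing in the
  overlap.

## Guide detection: the saturation-curve knee

Raw per-cell guide UMI vectors mix genuinely expressed guides (tens of
UMIs) with ambient molecules (1–2 UMIs spread over many guides). Detection
sorts a cell's guides by UMI count (ties broken by guide id), forms the
cumulative UMI fraction curve, and takes as the knee the index maximizing
the distance between the curve and the chord joining its endpoints. Guides
up to the knee — plus any guide tied with the knee's UMI value, which makes
the result independent of input order — are retained. Zero-UMI guides are
never retained, an all-zero cell yields an empty set (carried through and
reported, never silently dropped), and a single expressed guide is always
kept. The detector is pluggable (`method =` accepts a function), since
knee-finding conventions vary.

The knee is meaningful only when a low-count background exists: on a
homogeneous count vector with no ambient tail the maximal-distance point
sits mid-curve and would cut genuine guides. This is why the simulator
plants ambient noise by default (below), mirroring real droplet data.

## Grouping cells into clones

Clones are grown by a single agglomerative pass over a clone dictionary.
For each cell, the overlap test is run against every clone already in the
dictionary; with a Bonferroni-corrected threshold of `alpha = 0.05`, the
cell

* founds a new clone when it matches none (so non-clonal cells end up as
  singleton clones, and an empty guide set founds a singleton, never a
  doublet);
* joins the unique matching clone;
* is flagged a likely **doublet** and excluded from all clones when it
  matches more than one distinct clone — a droplet containing two cells
  carries the union of two clonal barcodes.

Three design choices here were genuinely open:

**Comparison target.** A clone is represented by its founder cell (the
dictionary semantics; cost `O(cells x clones)`). A strict mode
(`compare = "members"`) tests against every member and accepts a cell on
any significant match; on well-separated clones the two agree, and the
suite checks that.

**Iteration order** (default `order = "umi_asc"`, ascending total guide
UMI, ties by barcode). The result of any agglomerative pass depends on the
order, so it is fixed, logged, and configurable. Ascending order is the
default because inline doublet flagging requires a doublet's two parent
clones to exist in the dictionary *before* the doublet is tested: doublets
carry roughly twice the guide material of a single cell, so visiting cells
from least to most guide content defers exactly the multiplet-like barcodes
to the end. With the opposite order a doublet founds a clone whose founder
spans both parents, the parents merge into it, and doublet detection
collapses — easily reproduced on simulated data.

**The Bonferroni denominator.** The corrected cutoff of 0.05 needs a count
of tests, but the number of tests performed depends on how many clones
exist when each cell is visited, which depends on the threshold itself. The
default (`bonferroni = "tests"`) resolves this as a fixed point: the first
pass uses `n_cells` as the denominator, each subsequent pass reuses the
previous pass's actual test count, and iteration stops when the assignment
is unchanged (at most 4 passes; in practice 2–3). The denominator actually
used is stored on the result and logged by the pipeline. A simpler fixed
mode (`cells x final clone count`) is available. Because clonal overlap
p-values sit many orders of magnitude below any plausible threshold, the
partition is insensitive to the denominator; the machinery exists so the
cutoff is principled and auditable rather than load-bearing.

"High-confidence non-clonal" cells (`classify_nonclonal`) are singletons
whose best overlap p-value against *every other cell* fails even an
uncorrected 0.05 — deliberately stricter than merely failing the corrected
clone test.

## The simulator and what it does (not) emulate

`sim_config()` defaults are the study conditions used throughout the test
suite: library size `M = 20139`, `k = 30` guides per cell, clonal cells
drawing `round(r * k)` guides (`r = 0.75`; round-half-to-even, so 22 of 30 —
documented because 22.5 rounds differently under other conventions) from
their clone's founder set and the rest uniformly from the library;
non-clonal cells draw `k` uniform guides. True-guide UMIs are negative
binomial with mean 15; ambient noise adds Poisson(100) guide species per
cell at 1–2 UMIs.

Two generator parameters deserve justification:

* **UMI dispersion 0.1** (variance `mu + 0.1 mu^2`). At dispersion 0.5 the
  low tail of the count distribution is heavy enough that ~7% of true
  guides land at <= 2 UMIs — indistinguishable from ambient molecules by
  *any* threshold filter — and no detector can retain >= 90% of planted
  guides. At 0.1 the planted and ambient populations separate cleanly and
  knee detection retains ~95% of true guides with mean UMI ~15 per detected
  guide, matching the clean per-cell detection the method presumes.
  Dispersion is configurable for studying noisier capture.
* **Expression depth** (`simulate_expression_with_cnv`): baseline gene
  means are log-normal around 8 UMIs/gene (`sdlog = 0.5`, NB dispersion
  0.15), i.e. ~16,000 UMIs per cell over a 2000-gene panel — the regime of
  droplet data restricted to robustly detected genes, which is exactly what
  the 10%-of-cells expression filter produces. Copy-number segments
  multiply the means of genes inside a chromosome interval by a
  fold-change (0.5 = monoallelic loss, 1.5 = gain) in the cells of one
  clone.

What the simulation does **not** emulate: guide-capture dropout correlated
with cell state, index-hopping between libraries, clone-specific
proliferation (clone sizes are uniform by default; configurable), CRISPRi
effects of the guides themselves, and transcriptome-wide covariance beyond
per-gene negative binomial noise. Passing recovery tests on this generator
therefore shows the algorithm is correct under its stated model, not that
real data meet the model; the accession-scale summary statistics quoted in
published screens are not reproducible from simulation and are not asserted
anywhere in the suite.

Problem sizes in the test suite were chosen to exercise the study-scale
conditions while keeping the default run light: clone-recovery acceptance
runs 2000 cells x 20,139 guides across 5 seeds; CNV recovery runs 150 cells
x 2000 genes across 20 seeds; DE calibration runs 400 cells x 1000 genes
with 20 null groups.

## Power analysis

`power_log10_pvalue(M, k, r)` evaluates the overlap test at the assumed
overlap `round(r * k)` between two cells both carrying `k` guides —
detectability of clones as a function of experiment design. Along the
library-size axis the surface is always monotone non-increasing. Along the
guides-per-cell axis, two caveats are documented rather than hidden:

* on a unit-step `k` axis the rounded overlap does not advance at every
  step, producing small upward plateaus; a step of `1/r` (2 at `r = 0.75`)
  advances the overlap each step;
* in the **saturated corner** — `k` an appreciable fraction of `M` (smallest
  libraries, largest guide loads) — the tail threshold `round(r * k)` grows
  more slowly than the draw sizes and `P(X >= round(r*k))` genuinely
  increases with `k`. This is a property of the hypergeometric, not of the
  implementation; the corresponding acceptance check asserts global
  monotonicity over `M in [100, 20000]` and is expected to fail in that
  corner, while monotonicity holds throughout the `k << M` regime every
  practical screen occupies.

Exposing `r` as a free argument covers sensitivity of the surface to the
assumed sharing fraction; the surface is monotone in `r`.

## Copy-number profiles from expression

The CNV module follows the standard z-score visualization: counts-per-
million per cell (each cell scaled to 10^6; zero-depth cells excluded with
a warning), genes expressed in fewer than 10% of cells removed (boundary
kept), per-gene z-scores across cells with the sample standard deviation
(denominator `n - 1`; zero-variance genes are excluded with a warning
rather than set to 0, keeping the per-gene mean-0/sd-1 invariant exact),
genes ordered by (chromosome rank, start) with chromosome order defaulting
to 1..22, X, Y. Clone profiles are per-gene means of member-cell z-scores;
coherent runs of negative (positive) values indicate segmental loss
(gain). Coordinates are normalized internally to 0-based half-open: BED is
consumed natively and GTF converted on read, so both encodings of the same
genes order identically.

`call_cnv_segments` (centered rolling mean crossing a cutoff; window 25
genes, cutoff 0.3 by default) is labeled exploratory: it picks regions to
inspect and to overlap with labeled gene lists (`overlap_labeled_genes`),
and is not a statistical CNV caller — no HMM, no allele-specific inference,
no segment significance. Heatmap exports carry raw z-values; clipping is a
display option only.

## Region-level DE and the Significance Score

Cells are grouped per perturbed region (a cell belongs to every region it
carries a detected guide for). For a region's group, each gene is tested by
a hypergeometric draw on UMIs: universe = all UMIs in all cells, marked =
the gene's UMIs, drawn = the group's UMIs; the depletion tail gives the
down-regulation p, the enrichment tail the up-regulation p, and the smaller
tail sets the direction. An alternative formulation (cell-level
expressed/not-expressed contingency) exists in the literature; the UMI-draw
version is the implemented default and is isolated behind
`gene_observed_pvalue` so the contingency variant can be swapped in.

The background repeats the identical computation for random cell groups of
matched size, summarizing the directional log10 p per gene by its mean
(median available). The **Significance Score** is observed log10 p minus
background log10 p; random groups inherit everything that is *not* the
perturbation — depth, expression skew, and crucially clonal substructure of
the universe — so the subtraction cancels clone-driven pseudo-signal. The
`signed_score` flips the sign for up-regulated genes so Manhattan-style
exports show down-regulation below zero. Backgrounds are deterministic
under a seed; the default randomization count is 10,000, while the test
suite runs at 200 with planted-hit rankings already stable at that depth
(checked against 400).

## Known limitations

* Clone calls depend on detection quality; heavily under-sequenced guide
  libraries (mean UMI per guide near the ambient level) defeat both the
  knee filter and, eventually, the overlap test.
* The founder-comparison pass is order-dependent by construction; the
  order is fixed and logged, but a pathological order (doublet-like cells
  first) degrades doublet flagging, which is why the default defers them.
* Doublets merging two cells of the *same* clone are indistinguishable
  from ordinary members and are absorbed silently — by construction, not
  by failure.
* The DE background assumes random groups of matched size are exchangeable
  with the region group under the null; group-size-correlated covariates
  (cell quality, cycle) are not modeled.
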