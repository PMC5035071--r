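---
title: "Predicting enhancers from low-methylated regions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enhancers from low-methylated regions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lmrsvm` learns a cell-type-specific enhancer classifier from the DNA
sequence of low-methylated regions (LMRs) and scans a genome with it. This
vignette is the package's own account of the model: its assumptions, its
tunable parameters, the numerical choices made where the design was open,
and what the bundled simulator does and does not establish about real data.

## The learning problem

LMRs called from a WGBS methylation profile are candidate distal regulatory
elements, but only a small subset can be anchored to experimentally
validated enhancers. There is no per-cell-type gold standard, so a plain
supervised formulation is unavailable. The package instead treats the LMR
set as *unlabeled* and converts anchor resemblance into graded confidence:

- **RP** (reliable positives): LMRs ranking in the top δ quantiles of a
  density fitted on the anchor LMRs in k-mer space;
- **LP** (likely positives): the middle of the ranking;
- **LN** (likely negatives): the bottom quantiles (default cutoff 0.15;
  0.11 is a sensible alternative for fibroblast-like profiles);
- **RN** (reliable negatives): random loci that avoid exons, LMRs and
  assembly gaps, matched per chromosome in count and length to the LMRs.

The classifier is a soft-margin linear SVM whose misclassification penalty
depends on the set:

$$\min_{w,b,\xi}\ \tfrac12\lVert w\rVert^2
  + C_{+}^{RP}\!\!\sum_{i\in RP}\!\xi_i + C_{+}^{LP}\!\!\sum_{i\in LP}\!\xi_i
  + C_{-}^{LN}\!\!\sum_{i\in LN}\!\xi_i + C_{-}^{RN}\!\!\sum_{i\in RN}\!\xi_i$$

subject to $y_i(w^\top x_i+b)\ge 1-\xi_i$, $\xi_i\ge 0$, with $y_i=+1$ on
RP ∪ LP. The orderings $C_{+}^{RP}\ge C_{+}^{LP}$ and
$C_{-}^{RN}\ge C_{-}^{LN}$ encode that mislabeling a reliable sequence
costs more than mislabeling a likely one; `wsvm_weights()` enforces them.

Assumptions worth stating plainly: (i) enhancer identity is partly legible
from local 5-mer composition; (ii) the anchor LMRs are a representative,
if small, sample of the cell type's enhancers; (iii) random exon-free loci
are overwhelmingly non-enhancers. All three are approximations — (iii) in
particular means a few RN sequences are mislabeled true enhancers, which
the finite $C_{-}^{RN}$ tolerates.

## Sequence representation

`encode_kmers()` counts every overlapping window of length k (default 5,
1,024 features) on the forward strand and divides by the total count, so
vectors are composition profiles independent of sequence length. Windows
containing N are skipped; a sequence with no valid window is flagged
invalid rather than silently zeroed. Reverse-complement collapsing is
available (`canonical = TRUE`, 512 features) but off by default: the
method counts plain occurrences, and strand-collapsing is left as an
experiment. k is a genuine dial — 4⁶ = 4,096 features already outgrows a
few hundred training sequences — and 5 balances expressiveness against the
training-set sizes this protocol produces.

## Density ranking

The anchor set is typically ~10–150 sequences while the feature space has
1,024 dimensions, so a kernel density estimate in raw k-mer space would be
degenerate. `fit_kmer_density()` therefore:

1. projects the anchors onto their leading principal components, keeping
   the smallest number that explains ≥ 95% of variance (`var_explained`,
   optionally capped by `max_dim`);
2. fits a product-Gaussian KDE in that space with a per-dimension
   Silverman bandwidth, $h_j = s_j\,(4/((p+2)m))^{1/(p+4)}$ for $m$
   anchors in $p$ dimensions;
3. floors bandwidths at $10^{-8}\max(1, \max_j s_j)$ so duplicate-anchor
   and zero-variance inputs stay finite (with a warning rather than an
   error).

Queries are mapped through the stored centering and rotation, evaluated
with a log-sum-exp accumulation, and floored at the smallest positive
double — densities are strictly positive and finite by construction.
`rank_by_density()` sorts ascending, assigns ranks 1..n and quantiles
rank/n, and breaks ties deterministically by (density, chromosome, start),
so refits on identical input are bit-stable. Only the rank order feeds the
pipeline; mode-based cluster labels are deliberately not computed, because
partitioning consumes nothing but the quantile.

## Partitioning and the background set

Boundary semantics are explicit: quantile ≥ δ is RP ("top δ quantiles"
inclusive), quantile < the LN cutoff is LN, the remainder LP. On an exact
quantile grid i/n these rules give exact set sizes, which the tests assert.

`generate_negatives()` places one random locus per LMR on the same
chromosome with the same length, by rejection sampling against (a) the
exclusion track (exons plus the LMRs themselves), (b) previously placed
negatives, and (c) any N in the extracted sequence. Rejected placements
are resampled rather than dropped, preserving the count invariant; an
interval that cannot be placed within `max_tries` raises an error naming
the chromosome and length. Self-overlap among negatives is forbidden by
default for cleanliness — a plain coordinate shuffle does not guarantee
this — and can be relaxed with `allow_self_overlap = TRUE`.

## Solving the weighted SVM

The dual problem — minimize $\tfrac12\alpha^\top Q\alpha - \mathbf 1^\top
\alpha$ with $y^\top\alpha=0$ and $0\le\alpha_i\le C_i$ — is solved by
sequential minimal optimization in compiled code (`src/wsvm_solver.cpp`):

- working sets are chosen second-order (the maximal violator paired with
  the partner giving the steepest feasible decrease), which converges
  reliably where first-order maximal-violating-pair selection can stall on
  degenerate faces;
- the stop rule is the violation surrogate $m(\alpha)-M(\alpha)\le$ `tol`,
  which bounds every sample's KKT residual by `tol`; training defaults to
  `tol = 1e-8` (the pipeline uses `1e-6`, ample for a sign decision);
- the gradient is refreshed from scratch every 10⁵ iterations so
  incremental rounding cannot accumulate over long runs;
- the kernel matrix is cached up to n = 6,000 (288 MB) and computed
  column-wise on demand beyond that;
- the bias is the mean of $-y_iG_i$ over free support vectors, or the
  midpoint of the violation bounds if none is free.

With all four penalties equal the problem is a standard C-SVM, and the
test suite certifies agreement with an independently solved dual QP to
1e-6 in decision values, plus KKT residuals below 1e-6 on random weighted
instances. Slacks are retrievable from the fitted object (`m$xi`), and
`glance()` reports the gap, iteration count and convergence flag.

## Model selection

`select_wsvm()` evaluates every (δ, weight-profile) pair by stratified
5-fold cross-validation. Design choices the protocol leaves open:

- **Pooled counts.** The cross-validated TP/FN/PP are pooled over folds
  (micro-averaged) before computing recall, precision and F. With RP sets
  of a dozen sequences, per-fold F-scores are too noisy to average.
- **Stratification.** Folds preserve RP/LP/LN/RN proportions; fold
  assignment is seeded and reproducible.
- **Top-F group.** "The models with the best F-scores" is quantified as
  every survivor within 0.005 (absolute) of the maximum (`tie_tol`);
  within the group the highest precision wins, and residual ties go to
  the lexicographically smallest (δ, C_RP, C_LP, C_LN, C_RN).
- **Coverage constraint.** Each candidate is retrained on all data and
  scanned over a designated proxy chromosome; candidates covering more
  than `coverage_cap` (default 0.05, with 0.10/0.15 as the usual looser
  presets) are excluded before the F comparison. Full-retrain coverage is
  used because per-fold scans would quintuple the cost for a quantity the
  cap only needs approximately.
- **Grids.** The default δ grid is {0.90, 0.95, 0.99} and the default
  weight grid holds three profiles, (10, 1, 1, 10), (50, 5, 1, 25) and
  (100, 10, 5, 50), spanning mild to strong emphasis on the reliable
  sets. The original protocol's exact grid is not published; these grids
  are this package's choice and are fully configurable.

Note that the F-score here is not a generalization estimate: LP contains
unknown negatives, so pooled recall is structurally pessimistic. F and
precision are *relative* selection signals, which is all the protocol
requires.

## Scanning and merging

`scan_genome()` tiles each chromosome from position 0 with `window` = 2 kb
steps of 500 bp; a trailing partial window is not emitted (the tiling
phase is unspecified in the protocol; 0 is the natural choice). Windows
whose sequence has no valid k-mer — assembly-gap deserts — are flagged
non-callable and scored −∞ rather than treated as confident negatives.

`merge_windows()` groups positive windows into connected components under
overlap-or-adjacency and reports each component's union span as one
enhancer. "Separating at negatively scored windows" is under-specified
when windows overlap; the implemented rule cuts between two consecutive
positive members only when a fully negative callable window lies between
them and no positive member spans that window's midpoint. Geometrically
this can only trigger for adjacency-linked positives (e.g. positives at 0
and 2,000 with the window at 1,000 negative), exactly the situation the
sliding geometry produces. Both behaviors ship
(`split_at_negative = TRUE`/`FALSE`) and both are tested. Each enhancer's
representative is its highest-scoring member window, leftmost on ties;
representatives, not concatenated spans, feed all validation statistics,
because a long merged span trivially lands near some marker.

## Validation rules

Distances in the validation rules are **edge** distances with overlap
counting as zero, and thresholds are inclusive ("within 1 kb" admits
exactly 1,000 bp). The alternative center-point metric is available by
flag (`mode = "center"`) and is also what the TSS-distance *plots* use,
following the convention that distribution plots measure from sequence
centers. TSS inputs are 1 bp points; a BED of gene bodies should be
collapsed beforehand. The true-positive-marker track keeps only DHS /
p300 / TF peaks whose nearest-TSS edge distance exceeds 1 kb (markers on
chromosomes without any TSS are retained — distance +∞). Categories are
assigned in fixed order: validated (TPM ≤ 1 kb), then misclassified
(TSS ≤ 2.5 kb), then unknown; the six marker states partition the
validated set, with `p300+/-DHS` absorbing both p300-only and p300+DHS.
`two_proportion_ztest()` provides the pooled-variance z-test used for
comparing overlap proportions; its z² equals the uncorrected chi-square
statistic, which the tests cross-check against `prop.test()`.

## The simulator: what it emulates, and what it does not

`sim_config()` freezes a desk-scale study condition: three 400 kb
chromosomes (1.2 Mb total), background bases i.i.d. at GC 0.41 (the
genomic level), one 3 kb N gap, and 15 planted enhancers of 1.2–2 kb whose
sequences receive one of four GC-rich 6-mer motif words at 80% of
opportunities spaced every 20 bp. The rationale for the key defaults:

- **Enhancer count and length.** The protocol's own 5% coverage cap is
  part of the study conditions; a fixture whose true enhancers (plus the
  ≥ 2 kb minimum footprint of a window-based detection) exceeded the cap
  would make correct models inadmissible by construction. Fifteen
  enhancers of ~1.6 kb put truth at 2% of the genome and a perfect
  detection at ~3.5–4%, inside the cap with realistic headroom.
- **LMR geometry.** 240 LMRs, a quarter centred on enhancers, log-normal
  lengths with median ~650 bp clipped to 300–2,200 bp. Training
  sequences and 2 kb scan windows must see comparable motif densities for
  a threshold learned on one to transfer to the other — in real data the
  same transfer is implicit in LMRs tracking enhancer extents.
- **Motif planting.** Motif words at 80% of 20 bp-spaced opportunities
  put ~24% of enhancer bases in motif, a strong but not degenerate k-mer
  signal; the spec of the generator is that planted enhancers be
  separable in k-mer space, which the tests assert directly
  (enhancer-to-background centroid distance well above
  background-to-background).
- **Companion tracks.** Markers sit on enhancers at rates 0.9 (DHS), 0.6
  (p300) and 0.5 (TF) with 30 background peaks per track; TSSs keep a
  3 kb margin from enhancers; 60% of enhancers carry a CAGE-style
  interval and 80% a short conserved segment, over a dense background of
  400 random conserved segments. These rates echo the qualitative
  structure of real marker co-occurrence (DHS nearly ubiquitous at active
  enhancers, p300 and TF partial).
- The validated-anchor track covers 40% of enhancers with 200 bp
  primer-like flanks; in a null (zero-enhancer) configuration random
  LMRs stand in so the ranking stage still runs and learns nothing.

What the simulator does **not** emulate: real genomic base composition
(isochores, CpG islands, repeats), the diffuse and partially redundant
sequence code of real enhancers (as opposed to literal motif planting),
methylation measurement noise and LMR-calling artifacts, chromatin
context, and marker peaks with realistic width/score distributions.
Passing the end-to-end recovery test therefore shows the machinery is
correct and the protocol coherent — ranking finds the planted signal, the
selection rule behaves, scanning recovers what was planted — not that the
method attains any particular accuracy on a real genome.

## Problem sizes and runtime

The test suite and the acceptance script run the full pipeline on the
1.2 Mb default fixture (about ten seconds on one CPU), certify the solver
against a dual-QP oracle on twenty random instances up to n = 200,
d = 50, check the encoder against dictionary counting on 1,000 random
sequences of 10–3,000 bp, verify shuffled negatives on 1,000 intervals
over a 2 Mb genome, and audit the 3 × 3 selection grid exhaustively.
These sizes were chosen so the pipeline's combinatorics (multiple
chromosomes, multi-window enhancers, marker co-occurrence, an N gap) are
all exercised while any stage remains re-runnable interactively.

## Known limitations

- The density rank treats the anchor KDE as unimodal evidence; with very
  heterogeneous anchor sets a mode-aware treatment might rank better.
- The F-score used in selection is not comparable across δ values in any
  absolute sense (the positive set itself changes with δ); it is used
  strictly as the protocol's relative criterion.
- Linear kernels only; the weight grid is small by default and should be
  widened for serious use.
- GC-matched negatives (a documented alternative that trades sensitivity
  for precision) are not the default; construct them by passing a custom
  template to `generate_negatives()` if wanted.
- Genome scans encode every window independently; for chromosome-scale
  genomes a streaming implementation would be preferable to holding all
  window vectors at once.
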