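---
title: "Methods: promoter-centered interaction calling and enhancer-gene linking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-centered interaction calling and enhancer-gene linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promloop)
```

## The problem

Promoter-capture proximity-ligation assays (PLAC-seq / HiChIP with an
H3K4me3 antibody) enrich chromatin contacts anchored at gene promoters.
The analytical task is to decide which 10-kb bin pairs carry more read
pairs than the assay's systematic biases explain, and then to interpret the
significant promoter-distal contacts: are the distal anchors enriched for
regulatory chromatin, how is CTCF motif orientation arranged across the two
anchors, and which accessible elements behave like enhancers of the genes
they touch?  `promloop` implements this pipeline end to end, with a
synthetic-data generator that plants known interactions, motif orientations
and enhancer-gene links so every stage can be validated offline against
ground truth.

## The count model

Within each library, the genome is tiled with 10-kb bins and bin pairs are
classified against replicated H3K4me3 peaks: *AND* (both bins contain a
peak), *XOR* (exactly one), *NOT* (neither).  Overlap means at least one
base pair under 0-based half-open (BED) coordinates.  Only AND and XOR
pairs with at least one read pair are modeled -- a pair is unobservable
otherwise -- so the natural noise model is a **zero-truncated (positive)
Poisson**: a Poisson count conditioned on being $\ge 1$.

For a pair with covariates $c$ (effective fragment size, GC content,
mappability, ChIP enrichment, $\log_{10}$ genomic distance) the rate is
log-linear, $\mu = \exp(c^\top\beta)$, and the likelihood contribution is

$$\ell_i(\beta) = x_i\log\mu_i - \mu_i - \log\left(1 - e^{-\mu_i}\right) - \log x_i!$$

`ztp_glm()` maximizes this by Fisher scoring with the analytic score
$C^\top(x - m(\mu))$, where $m(\mu) = \mu/(1-e^{-\mu})$ is the truncated
mean, and expected-information weights $w = m(1+\mu-m)$ (the truncated
variance).  A step-halving guard keeps the log-likelihood monotone; the
fit stops when its relative change drops below $10^{-8}$ (100 iterations
maximum, an error beyond that).  Covariates are z-scored internally for
conditioning and coefficients are reported on both scales.  Separate fits
are run for the AND and XOR sets: ChIP enrichment affects the two sets
differently.

Significance of an observed count $x$ uses the conditional upper tail

$$p = \frac{1 - \sum_{k=0}^{x-1} e^{-\mu}\mu^k / k!}{1 - e^{-\mu}},$$

evaluated in log space (`ztp_pvalue()`), so that $x=1$ carries no evidence
($p = 1$) and extreme counts do not underflow.  Calls require
Benjamini-Hochberg $q < 0.01$ (pooled across autosomes within a set
label), a normalized contact frequency $\mathrm{NCF} = x/\mu \ge 2$, and a
1D distance between 20 kb and 1 Mb, with the distance filter applied
before multiple testing.  AND-set calls are promoter-to-promoter (P2P),
XOR-set calls promoter-to-nonpromoter (P2N).

Because the ZTP tail is discrete, null p-values are super-uniform and the
realized false-discovery proportion sits below the nominal level; the
acceptance suite verifies both.

### Detection power

Power is dictated by the realized BH cutoff and the background rate.
Self-consistently, the cutoff is roughly
$\mathrm{fdr}\times\pi_\text{planted}\times\text{power}$, so with 1% of
pairs planted at fold 4 over backgrounds averaging 3 counts the smallest
callable count is 12-13 and per-pair power is the ZTP tail above it.  With
distance-decayed rates most pairs sit below the average rate, and measured
sensitivity at fold 4 is about 0.26, rising above 0.9 at fold 6.  The test
suite asserts agreement between empirical sensitivity and this analytic
value rather than a fixed aspiration, and separately that the
false-discovery proportion stays below 5% in that regime.

## Library QC, merging and depth balancing

`qc_metrics()` computes, after dropping alternative and mitochondrial
contigs: `trans_ratio` (inter-chromosomal / all unique pairs; pass
$< 0.40$), `long_cis_ratio` (intra pairs spanning $> 1$ kb / all intra;
pass $> 0.50$) and `FRiP` (valid short-range pairs -- opposite strands,
intra, $\le 1$ kb -- with an end in an H3K4me3 peak, over all valid
short-range pairs; pass $> 0.075$).  Replicates are merged by summing
bin-pair counts, and cross-sample comparability is restored by
per-chromosome downsampling of AND+XOR counts to the minimum across
samples, thinning individual read pairs without replacement
(hypergeometric at the bin-pair level).  For cross-sample analyses the
AND/XOR universes can be recomputed against the interval union of all
samples' H3K4me3 peaks (`union_peak_relabel()`); ChIP-enrichment
covariates remain sample-specific, since enrichment is a property of each
library rather than of the union annotation.

## Enrichment against distance-matched controls

For P2N calls, the promoter-interacting (distal) bin at promoter $+d$ is
matched with the bin at promoter $-d$; pairs whose reflection leaves the
chromosome are dropped on both sides, keeping the design matched.  Distal
bins interacting with several promoters are counted once by default
(configurable).  Peak enrichment asks whether a region contains the
midpoint $\lfloor(start+end)/2\rfloor$ of at least one peak (floor for
determinism); chromatin-state enrichment compares base-pair overlap,
$\mathrm{fold} = \mathrm{bp}(fg \cap S)/\mathrm{bp}(ctrl \cap S)$.
Across samples, folds are tested against 1 with a two-tailed one-sample
t-test and BH adjustment; zero-variance fold vectors are reported as
$p = \mathrm{NA}$ and excluded from the adjustment rather than fabricating
significance.

## CTCF orientation

Each CTCF peak takes the strand of its highest-scoring motif hit (ties:
higher score, then leftmost start, then `+`), peaks without motifs are
excluded, and anchors are `forward`/`reverse` when all contained peaks
agree, `dual` when strands mix, `none` otherwise.  Interactions are
classified by bound ends (P2P: both / one-sided / neither; P2N: both /
P-side only / N-side only / neither).  Convergence analysis keeps
interactions whose two anchors are both unambiguous, orders anchors by
coordinate, and labels (+,-) convergent, (-,+) divergent, same-strand
tandem; counts are tested against the random-orientation null
$(1/4, 1/4, 1/2)$ -- the null is not dictated by the data, so the
uniform-strand benchmark is the natural reference.  Promoter direction
bias cross-tabulates promoter-anchor orientation (forward / reverse /
dual) against upstream/downstream partner position and applies a
chi-square test of independence without Yates correction.

## Enhancer-gene linking

From P2N calls, every accessible (ATAC) peak overlapping the distal bin is
paired with every gene whose H3K4me3-marked TSS lies in the promoter bin,
deduplicated at the (cCRE, gene) level.  H3K27ac is counted in a 2-kb
window around each cCRE center (read midpoints; the center uses floor on
even widths), columns are scaled to a common library size and
quantile-normalized to the mean-of-sorted-columns reference with ties
broken by first occurrence -- making the identical-sorted-multiset
invariant exact.  Each pair's Spearman correlation across the sample panel
(22 samples in the reference design) uses average ranks and the
t-approximation for its two-sided p-value; pairs with positive correlation
and BH $q < 0.05$ are flagged cEnhancer-gene pairs.  Constant vectors are
excluded, not imputed.

Supporting analyses: the closest-promoter baseline assigns each cCRE to
its nearest TSS (multi-TSS genes represented by their highest-H3K27ac
TSS), restricted to 20 kb-1 Mb to match the interacting pairs;
signal-matched controls draw non-cEnhancer cCREs from 100 equal-frequency
H3K27ac bins, preserving the per-bin histogram exactly and reporting any
shortfall instead of backfilling; `kmeans_profiles()` clusters
$\log_2(x+1)$ H3K27ac profiles (pseudocount 1 keeps zeros finite) with
seeded restarts and relabels clusters by decreasing mean signal;
reporter-assay validation reports both the rate $n_+/(n_+ + n_-)$ and the
$n_+{:}n_-$ ratio, because both summaries are in common use, with 2x2
chi-square comparisons; and conservation is the per-base mean of a scored
interval track with uncovered bases at 0.

## The synthetic-data generator

`simulate_study()` produces all pipeline inputs with known truth:

* **Genome and peaks.**  Identical-length chromosomes (default 2 x 10 Mb,
  at least 2 Mb so the full distance range fits), 10-kb bins, H3K4me3
  peaks wholly inside a chosen set of promoter bins with one gene TSS
  inside each peak, CTCF peaks each carrying exactly one oriented motif,
  ATAC peaks, and a 15-state segmentation tiling each chromosome (segment
  lengths in 200-bp steps, geometric with mean ~1 kb).  When requested,
  segments inside planted distal anchor bins adopt the enhancer state with
  a configurable probability, giving state-enrichment tests a positive
  control.
* **Contacts.**  Bin-level covariates (effective fragment size, GC,
  mappability as uniforms/betas; ChIP enrichment as a log-scale normal,
  higher at promoter bins) average into pair covariates; rates follow
  $\mu \propto \exp(\beta^\top c)\, d^{-\alpha}$ with default effects
  $(0.5, 0.3, 0.4, 0.8)$ and $\alpha = 1$, the standard power-law contact
  decay -- the decay exponent is a free parameter of the generator, not an
  empirical constant.  Expectations are thinned so their genome-wide sum
  equals the configured depth, a planted fraction is multiplied by the
  planted fold, Poisson counts are drawn, and pairs with $\ge 1$ count are
  emitted -- conditional on emission the counts are exactly
  zero-truncated Poisson, i.e. the caller's model is correctly specified.
  Note the planted-pair oracle: planting scales the pre-truncation rate,
  so the emitted mean is $m(\mathrm{fold}\cdot\mu)$, which approaches
  $\mathrm{fold}\cdot m(\mu)$ only when truncation is negligible.
* **Reads.**  Multinomial composition over inter-chromosomal, short-cis
  (valid: opposite strands, $\le 1$ kb, optionally placed inside peaks)
  and long-cis pairs, so QC metrics have known expectations.
* **Expression panel.**  Element H3K27ac counts are lognormal with
  sample-specific library factors; planted elements follow a latent
  cross-sample activity.  A planted gene's FPKM is a strictly monotone
  function (exp of normal scores) of its element's *normalized* H3K27ac
  row plus Gaussian log-scale noise $\sigma$ (`link_noise_sd`).  At
  $\sigma = 0$ the downstream Spearman correlation is exactly 1; the
  default $\sigma = 0.72$ targets a population rank correlation near 0.8
  via $\rho_S = (6/\pi)\operatorname{asin}(r/2)$ with
  $r = 1/\sqrt{1+\sigma^2}$.  Defining the link on the normalized scale is
  deliberate: the planted relationship is the one the method estimates,
  and it stays exactly recoverable in the noiseless limit regardless of
  library-size distortions.

What the generator does *not* emulate: sequence-level reads, restriction
fragments, diploid structure, unequal chromosome lengths, correlated decoy
expression programs, and peak-calling noise (peak sets are taken as
given).  Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
artifact of real libraries.

## Numerical choices and degenerate inputs

Log-space tails (`ppois(..., log.p = TRUE)` minus `log(-expm1(-mu))`)
avoid underflow to $x = 200$, $\mu \in [0.1, 50]$ and beyond; `log.p`
returns tails smaller than double precision.  Zero counts, empty
libraries, zero-total panel columns, zero-length elements and
rank-deficient covariates raise immediate, named errors.  Empty call
tables propagate as empty results.  `kmeans` with $k$ equal to the row
count returns the trivial partition directly (base `kmeans` refuses it).
Seeds are explicit arguments everywhere randomness exists; a fixed
configuration and seed reproduce every output byte for byte, which the
acceptance suite checks by hashing two complete pipeline runs.

## Problem sizes used in validation

The packaged checks run at desk scale: calibration of the caller uses two
6-Mb chromosomes (~18,000 XOR pairs) over 20 seeds, coefficient recovery
uses 50,000 pairs, the enrichment null uses 100 seeds of 120 matched bins,
link calling uses 300-element panels over 20 seeds, and the acceptance
script scales the caller's calibration up to ~175,000 XOR candidate pairs
per replicate on a 4 x 25 Mb genome, with background rates averaging ~3
counts per pair.  These sizes were chosen to make Monte-Carlo standard
errors small relative to the tested tolerances.

## Known limitations

The caller fits a single pooled regression per set label with a
log-distance covariate rather than stratifying by distance; a spline or
stratified fit could absorb non-power-law decay in real libraries (the
formula argument of `map_interactions()` accepts such terms).  The
Spearman p-value uses the t-approximation, slightly liberal at very small
panels (the suite quantifies this against exact permutation at $n = 7$).
Validation-rate and conservation analyses treat tested reporter elements
and conservation tracks as given inputs.  Sex-chromosome calling is
intentionally out of scope.
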