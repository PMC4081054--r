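---
title: "Calling rare CNVs from exome read depth with a negative binomial HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling rare CNVs from exome read depth with a negative binomial HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbcnv)
```

## The problem

Exome sequencing covers the genome in small, disjoint capture targets.
The number of reads overlapping a target tracks the underlying copy
number — a heterozygous deletion roughly halves coverage, a single-copy
duplication raises it by half — but the signal sits on top of strong
target- and sample-specific biases (GC content, capture efficiency,
sequencing run). Samples processed together are highly correlated with
one another, and this correlation is the resource the method exploits:
for each test sample, well-matched reference samples define what its
coverage *should* look like at every target under the diploid state, and
systematic departures over runs of consecutive targets are candidate
copy number variants (CNVs).

`nbcnv` models read counts directly as overdispersed counts (negative
binomial, NB) rather than through a Gaussian approximation of
normalized coverage. At exome-typical depth the NB model retains power
for short events — particularly small deletions, where discreteness and
skew matter most.

## The read-count model

Let $K_{ij}$ be the read count of sample $j$ at target $i$. We assume
$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \sigma^2_{ij})$ and estimate both
moments from reference samples:

1. **Aggregate normalization.** Every reference sample's counts are
   scaled so its total count over all targets equals the test sample's
   total (`normalize_to_sample()`). Library size drops out.
2. **Reference weighting.** The test sample's count vector is regressed
   on the normalized reference vectors by non-negative least squares
   (`nnls_weights()`). References sharing the test sample's systematic
   biases receive high coefficients; unrelated batches get ~0. Because
   all columns share one aggregate count the coefficients sum to
   (approximately) 1; they are renormalized to sum to exactly 1 and used
   as weights $w_k$. The NNLS solution is computed with a Lawson–Hanson
   active-set solver on the normal equations, which gives the same
   fitted vector as tall-matrix solvers at a fraction of the cost; with
   near-duplicate reference columns the split of weight among them is
   solver-dependent, so only the fitted moments are contract-tested.
   The effective number of references is $1/\sum_k w_k^2$.
3. **Weighted moments.** $\mu_{ij} = \sum_k w_k \tilde K_{ik}$ and the
   raw variance is the reliability-weights unbiased estimator
   $\sum_k w_k (\tilde K_{ik} - \mu_{ij})^2 / (1 - \sum_k w_k^2)$,
   which reduces to the classical unbiased variance under equal
   weights. If a single reference carries essentially all weight the
   variance is flagged undefined and only the floor below is used.
4. **Variance floor.** The raw variance at a single target is noisy
   (the effective number of references is often 10–30). Across targets,
   variance grows curvilinearly with mean depth and rises at both GC
   extremes, so we pool information by regressing
   $\log(\text{variance}+1)$ on a penalized-spline additive model in
   $\log(\text{mean}+1)$ and GC (`fit_variance_trend()`, via mgcv), and
   floor every per-target variance at the larger of the back-transformed
   prediction $s^2_{ij}$ and the mean itself (the Poisson floor):
   $\sigma^2_{ij} = \max(\text{raw}, \mu_{ij}, s^2_{ij})$. The log
   scale is a deliberate choice: variances span several orders of
   magnitude, and fitting them on the raw scale lets a handful of deep
   targets dominate the smooth. The floor is applied unconditionally —
   conservative, in that it can only widen the model — rather than only
   at low effective reference numbers.

The NB size parameter follows as $z_{ij} = \mu_{ij}^2 /
(\sigma^2_{ij} - \mu_{ij})$; where flooring leaves
$\sigma^2_{ij} = \mu_{ij}$ the size is flagged infinite and emission
probabilities fall back to Poisson. All-zero targets get $\mu = 0$ with
a small $\varepsilon = 10^{-3}$ emission mean so log-likelihoods stay
finite.

## Segmentation and genotyping

A three-state hidden Markov model (deletion / diploid / duplication)
runs along each chromosome's targets. Emissions under copy number $c$
scale both the mean and the size by $c/2$ (so a deletion has mean
$\mu/2$, size $z/2$); the size scales with the mean because empirically
the two are roughly proportional. Transitions attenuate with the
genomic gap $d$ between consecutive targets: with $f = e^{-d/D}$ and
$q = 1/T$, a CNV state persists with probability $f(1-q)$ and otherwise
relaxes toward the stationary diploid-centred row $(p,\,1-2p,\,p)$. The
defaults $p = 10^{-8}$, $T = 6$ targets and $D = 70\,000$ bases are the
conventional exome-HMM settings, kept for comparability with
Gaussian-model callers. The exact matrix (documented at
`transition_matrix()`) is a reconstruction — the row mixes the
persistence term with the stationary row in proportion $f : 1-f$ — and
is the single most consequential modelling choice the package freezes;
its rows are row-stochastic for every $d$ and collapse to the
stationary row as $d \to \infty$. The Viterbi path (ties broken toward
diploid, then deletion) is segmented into maximal non-diploid runs, the
calls.

Each call, and any (sample, region, type) triple, receives two
Phred-scaled interval qualities computed from constrained forward
passes over the chromosome: with $P_{\text{none}}$ the probability that
*no* target in the region occupies the event state (restricted
likelihood over paths avoiding the state, divided by the unrestricted
likelihood),

$$SQ = -10\log_{10} P_{\text{none}}, \qquad
  NQ = -10\log_{10}(1 - P_{\text{none}}),$$

so that before capping (at 99) the two are exact Phred complements. SQ
is evidence the event is present; NQ is evidence the region is clean.

Integer copy numbers compare per-region NB likelihoods for copies 1 and
0 (deletions) or 3–6 (duplications), scaling $\mu$ and $z$ by $c/2$.
Copy 0 uses a flat Poisson background with mean $\lambda_0 = 0.2$ reads
per target — the residual level observed at truly zero-copy loci, a
platform-specific constant exposed in the configuration. Because
homozygous deletions and multi-copy duplications are rare, a
non-baseline copy number is accepted only when its likelihood ratio
over the single-copy event exceeds 1000.

Samples whose biases no reference can match accumulate spurious calls;
any sample with more than $N_{\max} = 50$ calls has all its calls
removed and is reported. The `mds_batches()` diagnostic embeds samples
in 2D from the inverse of the sample covariance matrix; the inverse is
normalized to partial correlations and the dissimilarity
$1 - |\text{partial correlation}|$ is fed to classical scaling. The
normalization matters: raw inverse-covariance entries are dominated by
per-sample precision scale, and scaling them away is what makes batch
clusters visible in the embedding. Samples whose best pairwise
correlation is low are flagged — they are poor candidates for
reference-based calling.

Sex chromosomes are excluded by default: with mixed-sex cohorts the
diploid baseline does not hold there, and no dosage correction is
attempted.

## Trio analysis

Given parent–proband trios, a parental call (above a quality threshold)
is **transmitted** if the proband's SQ over the same region and type
exceeds the proband's NQ, **not transmitted** if SQ < NQ, and
**uncertain** (excluded) on exact ties. The per-pair transmission ratio
is transmitted / (transmitted + not transmitted); under Mendelian
inheritance of real calls the median over pairs converges to 50% as the
quality threshold rises, which makes the ratio a specificity instrument
that needs no external truth set. A proband call is **de novo** at
threshold $t$ when its SQ exceeds $t$ and *both* parents' NQ over the
region exceeds $t$; the count of such calls should fall to zero as $t$
rises. "Applicable" scores are type-matched throughout (a deletion call
is scored against deletion-type SQ/NQ). Regions are scored exactly as
called in the parent (for transmission) or the child (for de novo),
without re-segmentation.

## The synthetic cohort generator

`simulate_cohort()` emulates the data features the model relies on:

* per-target baseline rates lognormal around the median depth with
  log-sd `rate_sd = 1` — real capture designs span roughly two orders
  of magnitude of mean coverage, and it is precisely this spread that
  makes samples highly correlated across targets;
* batch structure: each batch has its own per-target multiplicative
  bias (lognormal, log-sd `batch_sd = 0.3`), shared by its samples.
  This produces clearly separated clusters in the MDS diagnostic whose
  within-batch correlation approaches the ceiling set by the counting
  noise, $\approx 1/(1 + 1/z)$ — about 0.985 at $z = 70$ and 0.995 at
  $z = 200$. The generic single-batch default `size = 200` (variance
  ~1.5× Poisson at depth 100) represents a well-matched same-platform
  batch, consistent with the >0.99 pairwise correlations such batches
  show in practice;
* per-sample lognormal library-size factors (log-sd 0.1), removed
  downstream by aggregate normalization;
* GC per target from a Beta distribution centred on 0.45, optionally
  coupled to dispersion (`gc_variance = TRUE` inflates dispersion
  fourfold at GC < 0.3 or > 0.6) so the variance-trend fit has GC
  signal to recover — off by default;
* spiked CNVs redraw counts with the mean scaled by $c/2$ (copy 0:
  Poisson(0.2)), recorded in a truth table sufficient to compute exact
  sensitivity and specificity of any downstream run.

`simulate_trios()` builds father/mother/proband cohorts, spikes
heterozygous deletions or duplications (equally likely) of 3–8 targets
into parents, transmits each independently with probability 0.5 (by
default), and optionally adds de novo events in probands. Family
members land in different batches; events within a family are placed
non-overlapping with a two-target margin.

What the generator does *not* emulate: alignment and duplicate
artifacts, capture-kit lot differences beyond a single multiplicative
bias per batch, dosage-biased GC waves within a sample, common CNVs
segregating across families, sex chromosomes, and mosaic or fractional
copy states. Passing tests on simulated cohorts therefore demonstrate
the estimator and segmentation machinery under the model's own
assumptions — not robustness to every artifact of real exome data.

## Problem sizes and study design

The trio specificity study used in the tests and the acceptance script
simulates 50 trios (150 samples) at depth 100, NB size 70, 3 batches,
with 16 parental CNVs of 3–8 targets per parent over 18,000 targets,
and evaluates transmission at SQ ≥ 60 and de novo status at threshold
90. Family members are kept out of each other's reference panels
(`pedigree_exclusions()`): a relative shares the tested CNV about half
the time, and leaving them in the panel inflates the reference variance
precisely at event regions — measurably biasing which parental calls
clear the quality threshold and depressing child classification. Two
further numbers deserve justification:

* **Event load and target count.** At NB size 70 the per-target
  log-likelihood ratio of a heterozygous deletion is ~5 nats against a
  ~20-nat prior penalty, so only events of ≥ 5–6 targets reliably clear
  SQ 60, and duplications (whose evidence per target is ~60% of a
  deletion's) rarely do. A median of per-pair ratios is only a stable
  statistic when pairs average several eligible events, so each parent
  carries 16 spiked CNVs; the target count is then set so that
  CNV-carrying cells remain ~0.5% of the reference panel, at which
  level the spiked events barely perturb reference variance
  estimation. Real cohorts are sparser still (tens of CNV calls
  against ~190,000 targets); the density here is a desk-scale
  compromise, biased toward realism in the contamination fraction
  rather than in the per-sample event count.
* **Dispersion.** Size 70 for the trio study is a deliberately noisy,
  multi-batch setting; the single-batch default is 200. Under size 70
  the pipeline's own estimation noise (weighted-variance sampling error
  interacting with the max-flooring, plus the ~1.5% reference
  contamination) inflates realized variance-to-mean ratios from the
  ideal 2.4 to ~3.1 at depth 100, which is the dominant power cost for
  short events; this is a property of the method, reproduced rather
  than patched here.

Smaller fixtures in the unit tests (20–30 samples, 200–500 targets)
exercise the same code paths; the variance-trend fit requires at least
200 targets by default (configurable) and warns below 16 samples.

## Numerical choices and degeneracies

* All chain computations are in log space; no scaling tricks are
  needed at exome chain lengths.
* Viterbi ties break deterministically toward diploid, then deletion,
  then duplication, so outputs are byte-identical across runs.
* Inter-target distance is `start[i+1] − end[i]`, floored at zero for
  overlapping targets; chromosomes are processed independently.
* The restricted forward pass zeroes the forbidden state inside the
  region only; SQ/NQ complementarity then holds by construction, and
  capping (default 99) is applied last.
* Zero-total reference samples are dropped with a warning; an all-zero
  NNLS solution falls back to uniform weights with a warning.
* `gc` values missing or NaN (e.g. all-N targets) are imputed with the
  cohort median for the variance-trend fit.
* Variance-trend predictions are clamped to the training hull of
  (log-mean, GC) before back-transforming, so extrapolation cannot run
  away.

## Known limitations

* Calls are target-resolution; no breakpoint refinement and no merging
  across a diploid gap.
* The NB model is estimated per (target, sample) pair independently;
  no explicit GC correction of counts is applied (the GC signal enters
  only through the variance floor).
* Samples uncorrelated with every reference cannot be called reliably;
  the N_max filter removes them, and the MDS diagnostic should be
  consulted before trusting calls on outlier samples.
* Transmission analysis scores the parent's called region in the child
  verbatim; a partially transmitted or re-segmented event in the child
  can depress child SQ.
* The homozygous-deletion background mean (0.2) is platform-specific
  and should be re-estimated for other platforms, e.g. from female Y
  coverage or known null loci.
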