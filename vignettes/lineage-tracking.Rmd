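---
title: "Tracking clonal lineages through a fermentation season"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking clonal lineages through a fermentation season}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagetrace)
```

## The problem

Industrial bioethanol fermentation maintains a ~10^17-cell *S. cerevisiae*
population for an 8-month season, growing ~10% every 12 hours and recycled
by centrifugation between batches. The population reproduces asexually, so
its genetic diversity is organized into clonal lineages: nested clades of a
phylogeny, each the descendants of one cell. Two kinds of sequencing see
this population from complementary angles. Whole-population metagenomes
taken through the season measure per-site alternate-allele frequencies of
the pooled DNA without any isolation bias, but cannot by themselves say
which alleles travel together. Whole-genome sequencing of picked clonal
isolates reveals the linkage — which alleles co-occur in one genome — but
samples the population sparsely and non-quantitatively.

`lineagetrace` combines the two: clones define the lineages and their
diagnostic alleles; metagenomes supply the quantitative time series from
which each lineage's frequency trajectory is inferred.

## Data model

All tabular data are long tibbles. A variant table has one row per site and
sample with the alternate-allele read count `x` and total depth `d`
(reference + alternate counts, the convention used by AD-style fields from
haplotype-based callers); allele frequency is `x/d`. Only biallelic SNPs are
used: sites with more than one alternate allele are dropped at ingestion
rather than split, and entries with `d = 0` are kept but treated as masked,
never as frequency zero. Coordinates stay 1-based throughout; no coordinate
arithmetic is performed, so no half-open convention is needed.

## Stage 1: ploidy

These populations mix diploid and triploid strains, and ploidy changes what
a heterozygous site looks like: a diploid's allele-frequency spectrum peaks
at 0, 1/2 and 1, a triploid's at 0, 1/3, 2/3 and 1. `classify_ploidy()`
turns that visual signature into a likelihood comparison. For each
informative site (depth ≥ 10, `0 < x < d`), both ploidy models assign an
equal-weight binomial mixture likelihood over their copy fractions,
error-adjusted via `p = g(1−e) + (1−g)e`; summed log-likelihoods are
compared and the sign of the difference is the call.

Two modeling points deserve emphasis:

* **The 0 and 1 mixture components are kept in both models** even though the
  spectrum is restricted to intermediate frequencies. At 25× depth with a
  0.5% error rate, roughly 12% of homozygous sites leak one or two error
  reads and enter the spectrum near frequency 0.04 or 0.96. A model with
  only heterozygous components must explain such a site with its nearest
  peak — 1/3 fits a frequency of 0.04 far better than 1/2 does — so
  thousands of leaked sites would systematically push every call toward
  triploid. The shared boundary components absorb them symmetrically.
* **Gates, not guesses.** Clones with fewer than 50 informative sites are
  returned as `NA` with reason `"insufficient data"`; calls with
  `|Δlog L| < 10` carry a low-confidence flag. Ploidies above 3 are not
  modeled (only 2n and 3n occur in these populations); an out-of-model clone
  surfaces as a low-confidence call rather than a wrong confident one.

## Stage 2: genotypes

Given its ploidy, each clone's per-site alternate copy number `c ∈
{0, …, ploidy}` gets a binomial likelihood `Binom(x; d, p_c)` with
`p_c = (c/ploidy)(1−e) + (1−c/ploidy)e`, normalized under a uniform prior
over states. The maximum a posteriori state is kept when depth ≥ 8 and its
posterior ≥ 0.95; otherwise the call is missing. Missing calls are tolerated
downstream (the marker rules budget for them) rather than imputed. The
uniform prior is the deliberately neutral choice; with ≥ 20× depth the
likelihood dominates it anyway.

Depth limits what is knowable here: at 25× the triploid 1/3-versus-2/3
decision is occasionally wrong *with high posterior confidence* (a 3σ count
fluctuation), at a rate of a few per thousand calls. This matters downstream
because a single confident miscall in any clade member disqualifies that
marker site for the whole clade.

## Stage 3: the lineage model

Every internal node and tip of the clone phylogeny is a candidate lineage. A
site is a **synapomorphic marker** of a clade when all non-missing members
share one identical copy fraction `g > 0`, all non-missing non-members have
`g = 0`, and missingness among members and among non-members is each ≤ 20%.
The constant-copy-number requirement is what makes the metagenomic expectation
linear: a marker at copy fraction `g_m` in a lineage at genome-copy frequency
`F` appears at allele frequency `g_m · F`.

Markers are polarized on the alternate allele only (`g > 0` inside, `g = 0`
outside). Sites whose shared state would be the reference allele are simply
not usable as markers; this loses marker density, never correctness, and
avoids the ambiguity of re-polarizing against an outgroup. Clades with fewer
than 10 qualifying markers are discarded (recorded with reasons); 10 markers
at ~90× metagenomic depth average binomial noise down to a standard error of
about `sqrt(p(1−p)/(10·90·g²))` ≈ 0.02 on a frequency scale. Sites that
qualify for no clade — homoplasies, recombination remnants, miscalls — are
reported as unassigned, never fatal. In the rare case (possible only through
missing calls) that one site qualifies for several clades, it is assigned to
the smallest, the most specific hypothesis consistent with the pattern.
Singleton (single-clone) lineages are allowed but flagged: their markers may
include clone-private artifacts.

## Stage 4: frequency inference

At each timepoint the package maximizes the binomial marker log-likelihood
jointly over all lineage frequencies under the nesting constraints
(`F ∈ [0,1]`; sister sums ≤ parent; top-level sum ≤ 1). Numerical choices:

* **Stick-breaking reparameterization.** Each lineage takes a fraction
  `u ∈ (0,1)` of its parent's not-yet-allocated mass; the feasible set
  becomes the unit box, on which `L-BFGS-B` runs unconstrained (box bounds
  `1e-7`). The expected frequency is clamped to `[ε, 1−ε]`, ε = 0.002 by
  default, so boundary evaluations stay finite and stray error reads at
  absent markers are not infinitely surprising.
* **Multi-start plus coordinate polish.** The first start is the pooled
  closed-form estimate per lineage, `Σx / Σ(d·g)`, projected onto the
  feasible set (children raised into parents bottom-up, overflowing sibling
  groups rescaled top-down); the remaining starts (default 5 total) are
  random feasible points from a seeded generator. The best optimum is then
  refined by cyclic one-dimensional line searches in the stick coordinates,
  which escape the plateaus the map can create when a parent's stick is near
  zero (all descendant gradients vanish there).
* **Markers with depth < 10 at a timepoint are skipped for that timepoint
  only**; a lineage with no usable markers at a timepoint is flagged
  unidentifiable and pinned to the minimum the constraints force (the sum of
  its children) rather than silently estimated.
* Timepoints are fitted independently — no smoothing, no selection
  coefficients — and a per-timepoint failure leaves other timepoints
  untouched.

Estimates report inclusive frequencies `F`, exclusive frequencies
`E = F − Σ(children)`, and the residual `R = 1 − Σ(top-level F)`; `Σ E + R
= 1` at every timepoint. The residual is a real quantity, not an error term:
it is the population fraction never represented among sequenced clones.

Frequencies are genome-copy (DNA) fractions, because that is what reads
measure; a triploid lineage contributes 1.5× the DNA of a diploid at equal
cell counts. `as_cell_fractions()` converts post hoc by dividing exclusive
fractions by ploidy and renormalizing, but it is not the default, and the
residual's ploidy must then be assumed (default 2).

## The season simulator

`simulate_season()` generates complete synthetic seasons for validation:

* a lineage tree with `n_founders` top-level lineages (the first is the
  starter; later founders invade at random times) and further lineages
  attached within founder subtrees — ploidy is constant within a founder
  subtree, so planted markers always satisfy the constant-copy rule;
* per-lineage markers at copy fractions valid for the subtree's ploidy;
* background sites of three classes: *ancestral heterozygous* sites
  (heterozygous in every founder, giving clones the genome-wide intermediate
  allele-frequency spectrum real isolates show — in mixed-ploidy populations
  these are never clean synapomorphies and end up unassigned), *homoplasic*
  sites (carried by several but not all founders, violating the clade
  pattern by construction), and a *zero-frequency pool* from which each
  sampled clone receives a few private mutations;
* trajectories by discrete-time logistic competition — exclusive masses
  multiplied by `exp(s_l)` per step and renormalized, entrants inserted at a
  small initial frequency — with optional Wright–Fisher multinomial jitter
  (off by default, so truth is deterministic given the seed);
* clone sampling at ~25× and metagenome sampling at ~90× mean depth
  (Poisson per site) with binomial counts at error-mixed expected
  frequencies, matching the study scale of ~26×/~87×, and a per-read error
  rate of 0.002.

The default clone-sampling plan (`"coverage"`) picks 4 clones per lineage at
timepoints where the lineage is alive, guaranteeing every lineage is
represented — the regime the recovery analyses assume; `"proportional"`
draws clones by exclusive frequency (residual draws are redrawn), emulating
realistic sparse picking, and is what the rarefaction analysis stresses.

What the simulator does **not** emulate: linked read structure and mapping
artifacts, site-specific error rates, de novo mutation accumulation during
the season, recombination, aneuploidy, and bacterial contamination. Passing
the validation suite therefore demonstrates correctness of the inference
given approximately binomial sampling noise — the noise model the method
assumes — not robustness to every pathology of real sequencing data.

## Validation and chosen problem sizes

The test suite validates each stage against independent oracles: the
genotype posterior against direct enumeration with explicit log-factorials
(1e-12 in log space); the optimizer against an exhaustive grid search at
0.005 resolution for instances of up to three lineages (within 1e-3 log
units, 25 seeded instances — feasible because the likelihood is separable,
so the grid tabulates one curve per lineage); ploidy calls against simulated
truth (100% over 50 seeded replicates at ≥ 20× with ≥ 500 informative
sites, including error-leaked homozygous sites); and the full pipeline
against simulated seasons.

Reference recovery scenario: 8 lineages (mixed 2n/3n), 20 markers each, 15
timepoints, 100× metagenome depth, ε = 0.002; across 10 seeds the
inclusive-frequency RMSE stays below 0.05 (typically ~0.005). Robustness to
unsampled diversity is checked two ways: paired simulations in which an
extra unmodeled lineage is carved out of the residual (at 2000× depth, so
systematic bias is separated from sampling noise; modeled estimates move
< 0.01 in mean absolute value), and model-ablation in the acceptance script
(dropping one top-level lineage's subtree from the model moves the remaining
estimates by well under 0.01). The rarefaction analysis re-runs the whole
pipeline on clone subsets (5 versus 40 clones, 10 subsampling seeds) and
requires recovery error non-increasing in clone count in at least 8 of 10
seeds.

Some tests scale the simulated genome down (600–1200 background sites
instead of the default ~4840) to keep replicated end-to-end runs small;
background-site count affects only ploidy/genotyping workload, not the
marker model, so this does not change what the tests demonstrate. The
marker-recovery example uses 60× clones: near the triploid 1/3-versus-2/3
boundary, shallow clones produce occasional confident miscalls, and a single
one disqualifies a marker for its whole clade — at 25–40× that intrinsic
ambiguity, not the model construction, caps per-clade marker recovery.

## Known limitations

* Markers are alternate-allele polarized; lineages defined only by
  reference-state alleles are invisible.
* A lineage none of whose clones were sequenced cannot be tracked (its mass
  lands in the residual, by design); a lineage whose clade in the clone tree
  coincides with another's (e.g. a parent whose every sampled clone passed
  through one child) is merged with it.
* Confident genotype miscalls at shallow clone depth remove markers clade-wide;
  deep clades with many members are the most exposed.
* The binomial noise model ignores overdispersion from mapping and
  library artifacts; ε absorbs some of it, but heavy-tailed sites will
  locally distort estimates.
* No dynamics are inferred: trajectories are per-timepoint estimates, and
  smoothing or selection inference is intentionally out of scope.
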