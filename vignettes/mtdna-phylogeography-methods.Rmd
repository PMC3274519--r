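---
title: "Models and methods behind mitopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mitopop analyses a single non-recombining locus — in practice mitochondrial
cytochrome *b* — sampled from many small localities of a structured
population. This vignette explains the models the package implements, the
choices made where conventions diverge, and what the simulation-based tests
do and do not establish.

## Haplotypes, sites, and distances

Haplotype identity is exact string equality over the full alignment after
case normalisation. We deliberately do not merge sequences that differ only
at ambiguous positions: a mismatch tolerance would make haplotype counts
depend on an arbitrary threshold, and the statistics downstream (haplotype
diversity, Fu's Fs) are defined on exact allele classes. The cost is that a
sequence with an `N` can form a spurious extra haplotype; with Sanger-grade
mitochondrial data this is rare.

Site classification calls a column variable iff at least two distinct
unambiguous bases occur; columns that are entirely gap/`N` are excluded and
logged rather than counted as conserved. Substitution-class totals consider
every unordered pair of distinct observed bases at a variable site —
purine–purine and pyrimidine–pyrimidine pairs are transitions, the rest
transversions. This convention is parsimony-free and deterministic, and on
two-state sites (the overwhelming majority in intraspecific data) it is
exactly the obvious count. Both ts/tv and tv/ts are reported; the headline
`ratio_reported` is ts/tv, the orientation a transition-biased mitochondrial
locus actually has. Weighting in the classification uses haplotype sample
counts, so collapsing cannot change singleton/parsimony-informative totals
relative to the raw alignment.

The K2P distance uses pairwise deletion: a site enters a pair's comparison
iff both sequences carry an unambiguous base there. This is the default of
the standard distance tools and the only policy that keeps each pair's
estimate independent of unrelated sequences' missingness. Saturation (a
logarithm argument at or below zero) is reported as `NaN` with an explicit
flag, never silently truncated.

## Diversity

Haplotype diversity uses the unbiased estimator $Hd = \frac{n}{n-1}(1 -
\sum_i p_i^2)$; with 134 haplotypes among 201 sequences this is the form
that yields values just below 1, matching how such studies report Hd.
Nucleotide diversity is the mean over pairs of (differences / comparable
sites), consistent with the pairwise-deletion policy; $\bar k$ is the mean
raw difference count, the quantity the demographic machinery consumes.

## Median-joining networks

The network stage implements the Bandelt–Forster–Röhl median-joining
iteration on the variable, fully unambiguous columns:

1. build the $\varepsilon$-relaxed minimum spanning network (MSN) over the
   current node set under the weighted Hamming distance — by default
   transversions cost 5 and transitions 1, the weighting appropriate when
   the observed ts/tv ratio is around 5;
2. for triples of nodes joined through the MSN, form quasi-medians
   (majority state per site; three-way ties expand to the observed state
   combinations, capped at 27 per triple);
3. insert new medians whose connection cost is within $\varepsilon$ of the
   round's minimum; drop unobserved nodes with fewer than three links;
   iterate to a fixpoint (an iteration cap turns pathological
   non-convergence into an error, and a cap of 10× the observed haplotype
   count bounds median growth).

With the maximum-parsimony option the converged network is pruned to
links and medians lying on *some* minimum-cost spanning subgraph of the
observed haplotypes (exact subset search up to 14 medians, greedy
cost-neutral removal beyond). Because ties are broken lexicographically
everywhere, output is deterministic. Two cost notions coexist: the pruned
network is the **union** of all optimal connections, so its total edge sum
can exceed `min_cost`, the cost of one optimal connection — `min_cost` is
the number to compare against an exact Steiner computation.

A known limitation, documented deliberately: with $\varepsilon = 0$ the
median-joining heuristic is not guaranteed to reach the global Steiner
optimum. On coalescent-generated (genealogical) data at the scales we test
(≤ 6 haplotypes, ≤ 6 variable sites) it attains the exact optimum in every
case we fuzz; on uniformly random, saturation-grade strings it can miss by
a few percent. Raising $\varepsilon$ recovers completeness at exponential
cost, which is why $\varepsilon$ is exposed in `network_config()`.

## AMOVA and Fst

The hierarchical analysis of molecular variance partitions pairwise
differences into among-group, among-population-within-group and
within-population components using Excoffier-style sums of squares with
unequal-size coefficients. The inter-individual distance is the **raw
pairwise difference count** — the conventional "number of differences"
choice for haplotype data — rather than a model-corrected distance; at
intraspecific divergences the two are nearly proportional and the raw count
is the reproducible default. Negative variance components are reported as
computed: they are a known feature of method-of-moments AMOVA and clamping
them would bias the Φ-statistics.

Each Φ-statistic gets its own permutation scheme: individuals among
populations anywhere (Φ_ST), individuals among populations within their
group (Φ_SC), whole populations among groups (Φ_CT). P-values are
one-tailed with the (b+1)/(m+1) correction, so they are never exactly zero.
At low polymorphism the permuted statistic takes few distinct values and
ties push p-values toward 1 — the test stays valid (size at most nominal)
but conservative; its null distribution is uniform in the usual sense only
when the data are variable enough for the statistic to be effectively
continuous.
When a scheme has one population per group the among-populations stratum
has zero degrees of freedom and the analysis reduces explicitly to the
two-level case (Φ_ST = Φ_CT), rather than emitting 0/0. Pairwise Fst is the
two-population Φ_ST with individuals permuted between the pair.

## Mismatch distributions and the sudden-expansion model

The observed spectrum is the relative frequency of pairwise difference
counts. The sudden-expansion expectation is
$$F_i(\tau, \theta_0, \theta_1) = \hat F_i(\theta_1) + e^{-\tau}
\sum_{j=0}^{i} \frac{\tau^j}{j!}\left[\hat F_{i-j}(\theta_0) -
\hat F_{i-j}(\theta_1)\right], \qquad
\hat F_i(\theta) = \frac{\theta^i}{(\theta+1)^{i+1}},$$
the transient-phase formula for a population that jumped from $\theta_0$ to
$\theta_1$ at $\tau$ mutational time units before present. Two numerical
notes: the truncated tail mass is folded into the last class so the
expectation is a distribution over the observed classes; and the formula
itself can dip marginally below zero in extreme parameter corners (it is an
approximation, verified here against a direct-summation reference) — the
package clips at zero and renormalises, which is invisible at realistic
parameter values.

Fitting minimises the sum of squared deviations over classes, with a
$(\tau, \theta_0)$ grid seed, $\theta_1$ profiled on a log scale, and a
box-constrained quasi-Newton refinement; $\theta_1$ is capped at $10^5$
(effectively infinite post-expansion size). Goodness of fit (SSD,
Harpending's raggedness $rg = \sum_i (x_i - x_{i-1})^2$) is assessed by a
parametric bootstrap: samples are simulated from the fitted expansion with
the package's own coalescent, refitted (warm-started from the parent fit),
and p is the fraction of simulated statistics at or above the observed one.
τ confidence intervals are percentile intervals of the refitted τ values,
95% by default. Bootstrap replicates default to 1,000 in the pipeline
(200 in the fast paths), configurable up to the conventional 10,000.

## Neutrality tests

**Fu's Fs** uses the Ewens sampling distribution of the haplotype count:
$\Pr(K = k \mid \theta, n) = |s(n,k)|\,\theta^k / \theta^{(n)}$ with
unsigned Stirling numbers of the first kind computed by a log-space dynamic
program (exact to n = 200 and beyond without overflow; rows are memoized).
With $\hat\theta = \bar k$, $S' = \Pr(K \ge k_{obs})$ and
$F_s = \ln(S'/(1-S'))$. The p-value is the fraction of neutral constant-size
coalescent simulations (infinite sites, rate $\hat\theta$) with simulated
Fs at or below the observed. A property users must know: under the null the
simulated tail probability is *not* uniform at the nominal 5% point — the
originating analysis itself recommends rejecting at 2% for a 5%-level test,
and our calibration experiment reproduces exactly that ≈2× inflation. The
package reports raw p-values and leaves the cutoff to the user.

**R2** contrasts per-sequence singleton loads with $\bar k$:
$R_2 = \sqrt{\tfrac1n \sum_i (U_i - \bar k/2)^2}\,/\,S$. Singletons are
folded: a site contributes where its minority base has frequency exactly
one, attributed to the carrier of that base. The null is conditioned on the
observed S (fixed-S coalescent, mutations placed proportional to branch
length), matching the statistic's published convention; its p-values are
uniform under the null to Kolmogorov–Smirnov precision in our calibration
runs.

Both nulls run on an infinite-sites engine that never builds sequences
(edge/descendant bookkeeping only), which is what makes 500 × 200
calibration experiments affordable on one CPU.

## Dating expansions

The conversion from mutational time to years inverts $\tau = 2ut$ with
$u = 2 \mu L g$: $\mu$ is the per-site per-lineage yearly substitution rate
obtained from a dated clade split as $\mu = d_{K2P} / (2T)$ (two lineages
each accumulate half the divergence), $L$ the locus length, $g$ the
generation time in years. This internal calibration avoids importing a rate
from other taxa; its cost is that dating uncertainty in the calibrating
split propagates linearly into every expansion date. The map is linear in
τ, so CI bounds transform identically; results are reported in Mya at
three decimals, the conventional precision.

## The coalescent simulator

All time is kept in units of $2N$ generations of the reference
(present-day) population and exposed only through $(\theta, \tau)$, so no
absolute population size is ever assumed. Branch lengths scale to
mutational units by $\theta/2$; a sudden expansion of age τ is a size
change at scaled time $\tau/\theta_1$; a two-deme split merges lineages at
$\tau_{split}/\theta$, with optional symmetric migration. Mutation is
finite-sites over L positions with transition:transversion odds κ:1
(default 5.33), so synthetic data exercise multiple hits and K2P
saturation handling; `fixed_S` conditions on an exact mutation count for
fixed-S nulls. Same seed, same output, byte for byte.

`make_study_like_dataset()` emulates the sampling design the package
targets: two clades split deeply (stem lengths chosen so between-clade K2P
lands near 3%), each split into two subgroups (≈2%), each subgroup a recent
sudden expansion (θ0 = 1, θ1 = 50, τ = 5), 92 samples scattered over ~43
populations of 1–4 individuals. Subgroup sizes 40/12/16/24 are a ~46%
scale-down of a typical such study's 94/24/30/50, keeping every stage
affordable in tests. What it does **not** emulate: sequencing error,
ambiguity codes, uneven spatial sampling, isolation-by-distance within
subgroups, or selection — so passing tests demonstrate algorithmic
correctness and statistical calibration under the stated models, not
robustness to those real-data features.

## Problem sizes used by the test suite

The statistical acceptance experiments use the sizes that keep a full run
in the tens of minutes on one CPU: 500 replicates × 200
permutations/simulations for p-value calibration, 2,000 coalescent
replicates for the E[S]/E[k̄] checks, and 50 replicates × 200 bootstraps
for τ-recovery against a ≥80% CI-coverage requirement.
Exact-oracle checks (AMOVA enumeration, Dreyfus–Wagner Steiner search,
Kruskal MSTs) run at ≤ 12 sequences / ≤ 6 haplotypes where exhaustive
computation is feasible.

## Known limitations

* Median-joining optimality is heuristic at $\varepsilon = 0$ (see above).
* The mismatch machinery implements the demographic (sudden) expansion
  model only — no spatial-expansion variant, no Bayesian skyline.
* AMOVA assumes the raw-difference distance; other distances can be
  supplied as a matrix but are not the tested path.
* Fu's Fs p-values inherit the statistic's non-nominal tail behaviour;
  interpret 0.02 < p < 0.05 with care.
* The simulator's two-deme model supports one split; arbitrary topologies
  are composed by grafting expansions onto stem lineages, as the study-like
  generator does.
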