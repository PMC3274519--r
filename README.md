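# mitopop

Population-genetic analysis of single-locus (mitochondrial) alignments, built
for phylogeographic studies of structured, recently expanded populations —
the classic small-mammal cytochrome-*b* setting: a few hundred sequences from
many small localities, nested in clades and subclades, with demographic
expansion signatures to date.

The package covers the full analysis chain as composable functions plus a
pipeline driver:

* **Haplotypes and sites** — exact-match haplotype collapsing with
  per-population counts; conserved/variable/singleton/parsimony-informative
  site classification; transition/transversion totals.
* **Distances** — Kimura 2-parameter distances with pairwise deletion,
  d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q), with explicit saturation flags;
  raw difference counts; between-group means.
* **Diversity** — haplotype diversity Hd = n/(n−1)·(1 − Σp²), nucleotide
  diversity π, segregating sites S, mean pairwise differences k̄.
* **Median-joining networks** — the Bandelt–Forster–Röhl iteration over an
  ε-relaxed minimum spanning network with quasi-median insertion, weighted
  substitution classes (transversion 5 : transition 1 by default), and
  maximum-parsimony (Steiner) pruning; GraphML/DOT/TSV export.
* **Structure** — hierarchical AMOVA (Φ_ST, Φ_SC, Φ_CT with level-appropriate
  permutation tests) and pairwise Fst from raw difference counts.
* **Demography** — mismatch distributions fitted to the sudden-expansion
  model F_i(τ, θ0, θ1) with SSD and Harpending's raggedness (parametric
  bootstrap p-values and τ CIs); Fu's Fs via the Ewens distribution of the
  haplotype count (log-space Stirling numbers); Ramos-Onsins & Rozas's R2
  with fixed-S coalescent nulls; expansion dating t = τ/(2u) with
  u = 2µLg calibrated from a dated clade divergence (µ = d/2T).
* **Coalescent simulator** — constant-size, sudden-expansion and two-deme
  split demographies with transition-biased finite-sites mutation; powers
  the null distributions, bootstraps and a study-like synthetic data set, so
  every stage is testable offline.

## Worked example

```r
library(mitopop)

# a packaged synthetic data set emulating a two-clade, four-subclade
# phylogeography (92 sequences x 1,140 bp, ~43 populations)
fx <- make_study_like_dataset(seed = 11)

haps <- collapse_haplotypes(fx$alignment, fx$popmap)
print(haps)
#> HaplotypeTable: 75 haplotypes, 92 samples, 43 populations

dm  <- distance_matrix(fx$alignment, model = "raw")
res <- amova(dm, fx$popmap, n_perm = 1000, seed = 1)
print(res)
#> AMOVA (popmap groups)
#>   sigma2: among groups 12.5661 (79.85%), among pops 0.0546 (0.35%), within pops 3.1156 (19.80%)
#>   Phi_ST = 0.8020 (p = 0.000999), Phi_SC = 0.0172 (p = 0.2428), Phi_CT = 0.7985 (p = 0.000999)

# date a fitted expansion age with a divergence-calibrated rate:
# between-clade K2P 3.1%, split age 0.62 Mya, 1,140 bp, 1 yr/generation
cal <- rate_calibration(0.031, 0.62e6, L = 1140, generation_years = 1)
date_expansion(4.389, cal, tau_ci = c(3.172, 5.389))
#> Expansion time: 0.039 Mya (0.028-0.047)
```

`Phi_CT = 0.80` says 80% of molecular variance lies among the four subclades
— strong geographic structure; the dating call converts an expansion age of
τ = 4.389 mutational units into 0.039 Mya (CI 0.028–0.047), i.e. a
late-Pleistocene expansion.

The same chain runs end-to-end from files:

```r
run_pipeline(list(fasta = "seqs.fasta", popmap = "popmap.tsv",
                  out_dir = "results", seed = 1,
                  calibration = list(clade_divergence_k2p = 0.031,
                                     divergence_time_years = 620000)))
```

writing diversity/AMOVA/Fst/demography TSV tables, the network as
GraphML/DOT, and a JSON run log. A thin command-line wrapper with
per-stage subcommands lives at `inst/cli/mitopop.R`.

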