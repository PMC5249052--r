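---
title: "Models and methods in botryphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in botryphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

botryphylo infers the geographic origin and dispersal history of a clade
from aligned mitochondrial haplotype sequences sampled across populations
nested in regions. This vignette documents the models, the parameters
that matter, the numerical choices, and what the synthetic-data tests do
and do not demonstrate.

## Data model

The unit of data is an equal-length alignment (default 524 bp, the
classic mtCOI barcode fragment) plus a two-level map: each sample belongs
to one population, each population to one region per grouping scheme.
Haplotypes are defined by exact string identity on the trimmed alignment.
Sequences containing ambiguity (`N`/`-`) are merged into an unambiguous
haplotype when they match it at every resolved site, and kept distinct
otherwise; this keeps haplotype counts stable without inventing variants.
All site indices are 0-based internally and 1-based in reports.

## Diversity and neutrality statistics

Per population (only populations with more than 3 sequences, the
conventional inclusion rule for these surveys):

* nucleotide diversity π: mean proportion of differing sites over all
  unordered pairs, with ambiguous positions excluded *pairwise* rather
  than by complete deletion — sparse data keep their information;
* Watterson's θ~w~ = S/(a₁L), a₁ = Σ 1/i, the segregating-sites
  estimator of 2N~e~μ for a haploid maternal locus;
* haplotype diversity Hd = n/(n−1)(1 − Σ p²);
* Tajima's D = (k̄ − S/a₁)/√(e₁S + e₂S(S−1)) with the 1989 constants.
  Its significance is assessed by simulation: 1,000 neutral constant-size
  coalescent replicates conditioned on n with θ set to the Watterson
  estimate, two-sided at α = 0.05. The simulation route was chosen
  because the commonly used desktop programs do not document their test;
  it reuses the package's own coalescent machinery under an
  infinite-sites approximation, which is accurate at mtCOI diversity
  levels.
* Fu's F~s~ = ln(S′/(1−S′)), S′ = Pr(K ≥ k~obs~) under the Ewens sampling
  formula with θ = k̄; the distribution of K is computed exactly from
  unsigned Stirling numbers of the first kind in log space (stable to
  n in the hundreds). The boundary cases S′ ∈ {0,1} are reported as
  signed infinities with an `extreme` flag.
* R₂ = √((1/n)Σ(Uᵢ − k̄/2)²)/S, where Uᵢ counts the sites at which
  sequence *i* carries a base found in no other sequence.

A note on the null expectation of D: even under a strictly neutral
constant-size coalescent its mean is slightly negative in finite samples
(we measure −0.05 to −0.14 across sample sizes and θ; an independent
simulator agrees). The calibration test therefore runs at n = 20,
θ~locus~ ≈ 10, where that intrinsic offset is small relative to the
Monte-Carlo band of 500 replicates.

## AMOVA and F-statistics

Molecular variance is partitioned from an inter-individual distance
matrix by the nested sums-of-squares construction, with unequal-sample
size coefficients, giving components σ²ₐ (among regions), σ²~b~ (among
populations within regions) and σ²~c~ (within populations), and the
fixation indices F~CT~, F~SC~, F~ST~. The default distance is allele
identity (0/1 by haplotype), which yields conventional F-statistics;
site-difference distances (Φ-statistics) are an option. Negative
components are retained and flagged rather than truncated, matching
standard practice. P-values use the three canonical permutation schemes
(samples among populations among groups; samples among populations
within groups; whole populations among groups), with the unbiased
estimator p = (#{perm ≥ obs} + 1)/(n~perm~ + 1) and a default of 1,023
permutations — a deliberate default where the exact counts used by
desktop packages are unstated. Pairwise F~ST~ p-values are corrected with
the Benjamini–Yekutieli step-up (valid under arbitrary dependence),
via `stats::p.adjust`.

## Median-joining networks

The network construction alternates two steps to a fixpoint: (i) build
the ε-relaxed minimum spanning network — a pair is linked when its
Hamming distance is within ε of the minimax (bottleneck) path distance,
computed from a Prim MST and Kruskal-style agglomeration; (ii) for every
triple of nodes with at least two links among them, propose the per-site
consensus (median); add the median that most reduces total network
length, breaking ties lexicographically on the sequence string so output
is deterministic; prune unsampled nodes of degree ≤ 1. ε defaults to 0.
Ambiguous bases are treated as missing with pairwise exclusion.
Three-way consensus ties are resolved in favour of the state minimising
added length, then lexicographically.

Two idealised properties sometimes claimed for such networks — that the
final graph contains the sampled-haplotype MSN as a subgraph, and that
its total length never exceeds the sampled-haplotype MST length — do not
hold in general: with tied distances the MSN carries reticulate
co-minimal links (three haplotypes pairwise two steps apart through
disjoint site pairs already exceed the MST, and no median helps), and a
profitable median deliberately replaces MSN links by shorter star edges.
What the construction does guarantee, and what the tests assert, is that
the output *is* the ε-MSN over its final node set and that adding
medians only ever shortens the network.

## Ancestral locations on a fixed tree

Ancestral-region reconstruction treats location as a discrete trait
evolving by a symmetric K-state CTMC with uniform stationary frequencies
(instantaneous rate r/(K−1) to each alternative state) along a supplied
rooted tree — by default a UPGMA tree over haplotype distances. The
switch rate is fitted by maximum likelihood; because the rate profile
can plateau at high rates, the optimiser brackets the optimum on a
40-point log grid before the local golden-section search. Marginal node
posteriors come from the up–down (outside) algorithm under a uniform
root prior, with per-node rescaling for numerical stability.

This is an empirical-Bayes, fixed-tree stand-in for a full joint
Bayesian tree-and-trait analysis: it estimates the same scientific
quantity (node location posteriors) at desk scale and testable accuracy,
but ignores phylogenetic uncertainty; its numbers are comparable to a
posterior-tree analysis only qualitatively.

## Coalescent scenario simulation

Demographic scenarios are population trees with optional unsampled
("ghost") populations, divergence events (all lineages move
daughter→parent backward in time) and admixture events (each lineage in
the target goes to source A with probability r~a~, else B). Within a
population, pairs coalesce at rate C(k,2)/N~e~ per generation with
exponential waiting times — a continuous-time approximation that is
standard and negligibly biased at the N~e~ of interest. N~e~ counts
*gene copies* of the haploid maternal locus, so E[T₂] = N~e~
generations. A scenario is invalid if lineages are left stranded with no
path to a common ancestor.

Sequences evolve down the genealogy under HKY+I: a fraction I of sites
never mutates; the rest evolve at rate μ/(1−I) per site so the locus-wide
mean rate is μ. Transition probabilities use the exact HKY matrix
exponential; per branch, the number of changed sites is drawn binomially
from 1 − P~ss~(t), which is fast when branches are short.

Priors are uniform with the order constraints t₄ > t₃, t₄ > t₂,
t₃ ≥ t₂ enforced by rejection. Defaults: N~e~ ∈ [10, 2×10⁵] (alternate
maximum 6×10⁵ for the sensitivity re-analysis), times ∈ [10, 10⁵]
generations, r~a~ ∈ [0.001, 0.999], μ ∈ [10⁻⁸, 10⁻⁶] per site per
generation, κ ∈ [0.05, 20], I ∈ [0, 0.9] — all configurable.

`builtin_scenarios()` encodes the named dispersal hypotheses for the two
clades (Pacific-ancestral histories with and without a ghost lineage and
Atlantic intermediates for clade A; English-Channel-France ancestral
with a ghost, plus England- and Mediterranean-ancestral alternates for
clade E). Only the histories described in words are encoded; further
topologies are user-definable.

## ABC model choice and the scenario tournament

The summary-statistic vector holds, per group: haplotype count,
segregating sites, private segregating sites (segregating within the
group, monomorphic outside), mean and variance of pairwise differences,
and Tajima's D; per group pair: mean between-group pairwise differences
and two-population F~ST~. Undefined entries (D with S = 0 or n < 4,
F~ST~ with n < 2) are imputed as 0 with a paired indicator column, so the
vector length is fixed and no simulation is discarded.

Scenario choice standardises the statistics, projects onto linear
discriminant axes fitted to the scenario labels, retains the fraction
(default 1%) of simulations nearest the observed point, fits a
multinomial logistic regression of scenario on the LDA coordinates over
the retained set, and reads the posterior probabilities at the observed
point; 95% CIs come from bootstrap over the retained set (default 500
resamples) — a documented internal choice where the reference desktop
implementation leaves its CI method unpublished. A pure rejection method
(retained-set frequencies) is available and agrees in ranking on
separable problems. Parameter estimation applies the local-linear
regression adjustment to the retained draws, with a ridge fallback for
collinear statistics; bias, RMSE and interval coverage are estimated
from pseudo-observed reference-table rows.

The tournament mirrors the two-round protocol: per ancestral set, the
top scenario advances together with every scenario whose 95% CI overlaps
the top's, provided no selected scenario overlaps an unselected one
(otherwise the overlap set is flagged undecidable); the selected
scenarios from all sets are then pooled and recompared, with a
head-to-head third round if the top CIs still overlap; the final
comparison is repeated under the alternate N~e~ maximum and both winners
reported.

Reference tables default to desk scale (10³–10⁴ rows per scenario in
tests and the acceptance script; the protocol's original scale is 10⁶).
CI widths shrink with table size, and on a two-scenario toy with
disjoint N~e~ priors the machinery recovers the generating scenario in
well over 80% of pseudo-observed datasets at 5×10³ rows per scenario.

## The synthetic-study generator

`generate_study()` emulates the sampling design of the motivating
surveys: 4 regions and 14 (clade-E-like) or 29 (clade-A-like)
populations, per-population sample sizes drawn log-uniformly in [1, 41]
(skewed, like real marina sampling), 524-bp sequences, and a recorded
truth (template, scenario, parameter draw, sizes, seed) sufficient to
regenerate the dataset bit-for-bit. Populations subdivide a region's
sample only nominally — within-region structure is *not* simulated — so
synthetic AMOVAs concentrate variance among regions and within
populations, not among populations within regions. Note the log-uniform
size law makes expected totals ≈150 (clade-E-like) rather than the
~300 of the field data; the skew was judged more important to preserve
than the total.

The default demography is a fixed reference draw chosen once for
realism: μ = 10⁻⁷ per site per generation, κ = 4, I = 0.5, all
N~e~ = 5×10⁴ gene copies, divergence times 5×10³/10⁴/3×10⁴ generations.
At n ≈ 200 and L = 524 this yields ~20–50 haplotypes, Hd ≈ 0.8–0.9 and
π below 1% — the observed mtCOI scale — with region-level F~CT~ near
0.1. Passing `draw = "prior"` samples the demography from the full
prior instead; such draws are frequently far more diverse than real
data, which is exactly what the ABC prior is designed to cover.

What passing tests on synthetic data show: the statistics match
independent oracles; the simulator is internally calibrated (E[T₂],
uniform marginals, constraint satisfaction); scenario recovery works
when scenarios are separable. What they do not show: robustness to
sequencing error, chimeras, alignment artefacts, within-region
population structure, or selection on mtCOI — none of which the
generator emulates.

## Numerical and design choices

* Haplotype identity is exact string match; ambiguity merging as above.
* Distances: Hamming with pairwise exclusion of ambiguous sites.
* Permutation p-values: add-one estimator; default 1,023 permutations.
* Median tie-breaks: lexicographic; output is order-invariant up to
  median relabelling.
* LDA singularities fall back to the standardised-statistic space with a
  warning; scenarios absent from a retained set get probability 0 with a
  warning.
* The problem sizes used by the tests and the acceptance script
  (reference tables of 10³–10⁴ rows, 500–2,000 coalescent replicates,
  199–1,023 permutations) were chosen as the smallest sizes at which the
  checked properties are statistically decisive.

## Command-line use

`run_pipeline()` executes the full analysis (statistics → structure →
network → ancestral locations → ABC tournament) from one YAML
configuration with a single master seed and per-stage substreams, writes
per-stage CSV/GraphML/JSON outputs and an md5-stamped manifest, and
leaves completed-stage outputs intact on later failure.
`inst/scripts/botryphylo.R` is a thin Rscript wrapper
(`botryphylo.R run --config run.yaml`). For the ABC stage the observed
data are subsampled to a per-region cap (default 12) and simulations are
conditioned on that sample configuration, keeping desk-scale runtimes.
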