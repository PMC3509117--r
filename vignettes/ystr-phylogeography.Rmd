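---
title: "Models and methods for Y-STR haplotype phylogeography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for Y-STR haplotype phylogeography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrhap)
```

# The setting

Y-chromosome short tandem repeat (Y-STR) loci mutate by gaining or losing
one repeat unit at a time, at rates orders of magnitude above SNPs. Within
a SNP-defined haplogroup, the vector of repeat counts across 15–17 loci —
the haplotype — therefore accumulates resolvable variation on historical
timescales, which is what makes it usable for three questions at once:
how diverse is each population (how old is its expansion), how far apart
are populations, and when did a diaspora's founders leave their source.

`ystrhap` implements that battery over plain data frames: one row per
sampled man, a `population` column, optionally a `group` column, and one
integer column per locus. The panel is simply the set of locus columns;
`derive_analysis_panel()`/`apply_panel_rules()` reduce a raw 17-locus
Yfiler table to the 15 analysis loci by dropping the multicopy pair
DYS385a/b (whose alleles cannot be assigned to a chromosome copy, so step
distances are undefined) and replacing DYS389II by DYS389II − DYS389I
(the genotyped DYS389II fragment contains DYS389I, so subtracting avoids
double-counting mutations). Both rules are conventional Yfiler practice
and both are configurable; there is no universally agreed 15-locus
subset, so the choice is documented rather than asserted.

Missing repeat values disqualify an individual (dropped with a warning;
a strict mode errors), because every statistic below assumes complete
haplotypes. Intermediate (non-integer) alleles are rejected outright:
they cannot be placed on the single-step mutational ladder.

# Pairwise metrics

Three comparisons between haplotypes `a` and `b` are used, selected by a
`metric` argument wherever it matters:

* `allele` — number of differing loci. The default for mean pairwise
  differences within (`PiX`) and between (`PiXY`) populations, matching
  the "number of pairwise differences" convention of standard haplotype
  software, and for the haplotype-level AMOVA.
* `step` — `Σ|aᵢ − bᵢ|`, the minimum number of single-step mutations.
  Used for network branch lengths, AMD and the ρ statistic.
* `squared` — `Σ(aᵢ − bᵢ)²`, the stepwise-mutation-model (SMM) metric,
  linear in time in expectation; used for Rst and TD/ASD dating.

Published tables rarely state which convention they used; where we had to
pick a default (`allele` for MPD/PiXY, `step` for AMD) the alternative
remains one argument away, and the package's own validation relies on
oracles rather than on any printed value.

# Diversity statistics

Haplotype diversity uses the unbiased estimator
`HD = n/(n−1)·(1 − Σpᵢ²)` with Nei's sampling variance

```
V(HD) = 2/(n(n−1)) · { 2(n−2)·(Σp³ − (Σp²)²) + Σp² − (Σp²)² }
```

For MPD two dispersion conventions are implemented. The default,
`sd_method = "empirical"`, is the sample SD of the metric over the
C(n, 2) unordered pairs: it describes the spread of the
pairwise-difference distribution, is defined for any metric, and is the
only convention that depends on the data beyond (n, MPD).
`sd_method = "tajima"` gives the total (sampling + stochastic) variance
of the mean, `V = (3n(n+1)·π + 2(n²+n+3)·π²) / (11(n²−7n+6))`, the
estimator-theoretic convention of classical software. Since the two
answer different questions ("how variable are pairs" vs "how uncertain is
the mean"), both are exposed; reports state which was used.

The modal haplotype is the most frequent whole haplotype, ties broken by
the lexicographically smallest repeat vector so results are
reproducible. The per-locus mode (`per_locus = TRUE`) is a different
object — the componentwise most common allele, which need not be an
observed haplotype — and is the right centre for expansion dating (see
below). AMD is the mean metric distance of individuals from whichever
reference is supplied.

# Distances, AMOVA and ordination

`(δμ)²` is the mean over loci of the squared difference in mean repeat
count; under the SMM its expectation grows as `2μt` per locus with
divergence time `t`, which the test suite verifies by simulation.

AMOVA follows the distance-matrix formulation: pairwise metric values are
treated as squared Euclidean distances, sums of squared deviations are
obtained as `SS(set) = Σ_{i<j∈set} d²ᵢⱼ / |set|`, and variance components
come from equating observed to expected mean squares for the nested
design, with the standard unbalanced-design coefficients. The one-level
design yields `Φ_ST`; the two-level design (populations in groups) also
yields `Φ_CT` and `Φ_SC`. Focal-versus-source comparisons in
`run_full_analysis()` are two-level AMOVAs (focal populations = one
group) reporting `Φ_ST`, with `Φ_CT` carried alongside, since a single
"Fst" per comparison is ambiguous between the two. Pairwise Rst is the
two-population `Φ_ST` under the `squared` metric (Slatkin's estimator);
negative estimates — pure sampling noise around zero differentiation —
are clamped to zero in matrices, with raw values retained in an
attribute. Permutation p-values (individuals permuted across populations,
seeded) are available but deliberately not part of any table
reproduction.

Ordination is classical (Torgerson) metric MDS via double-centering and
eigendecomposition. The full eigenvalue spectrum is kept on the result:
distance structure that no Euclidean configuration can represent shows up
as negative eigenvalues, and `glance()` reports that mass rather than
hiding it.

# Haplotype networks

The network machinery treats STR characters as ordered multistate, with
per-locus weights (default 10 per locus, the convention of the networking
software used throughout this literature) multiplying `|Δrepeats|`.

`build_minimum_spanning_network()` returns the union of all minimum
spanning trees: a link `(u, v)` of length `d` survives iff `d` equals the
minimax path weight between `u` and `v` (computed by a Floyd-type sweep),
relaxed to `d ≤ minimax + ε` for tolerance `ε ≥ 0`. `ε = 0` is the
default; raising it (in units of weighted steps) admits near-minimal
links.

`build_median_joining_network()` iterates: build the spanning network;
for every triplet of nodes with at least two links among them compute the
quasi-median (per-locus median of the three repeat vectors); add it as an
inferred node when connecting the triplet through it is strictly cheaper
than the best pairwise connection (`Σ_l w_l(max_l − min_l)` against the
two smallest pairwise distances); repeat until no new vectors appear,
with an iteration cap that errors rather than spinning. Haplotypes and
candidate medians are processed in lexicographic order, so networks are
byte-reproducible. Inferred nodes that end as leaves are discarded.

`mp_prune()` implements maximum-parsimony cleaning exactly: it
enumerates subsets of median vectors, finds the minimum total length of a
tree within the network spanning all observed haplotypes, and keeps
precisely the links (and medians) that occur in some minimum spanning
tree of some optimal subset. Exact enumeration is exponential in the
number of medians, so it is capped (default 16 medians) and errors past
the cap instead of silently approximating; the test suite checks it
against an independent all-spanning-trees search on small instances.
Observed haplotypes are never deleted and pruning never disconnects the
network (violations are internal errors, not warnings).

**Founder clusters.** Historically this step is done by eye on the
plotted network. `extract_founder_clusters()` makes it deterministic:
root nodes are, in order of preference, nodes carrying both focal and
source individuals; focal nodes directly linked to a source node; else
the focal nodes at minimal network distance from any source node. Each
focal node is assigned to the root reachable by the shortest network path
passing through no other root, with distance-then-identifier
tie-breaking. A manual node-to-cluster table overrides the rule, so a
published clustering can be reproduced exactly when one is available.

For founder-cluster work at realistic sample sizes the spanning network
is the recommended substrate: the quantities that feed dating are
member-to-root step distances along the network, and inferred median
vectors lie on geodesics, so they do not change those sums; they multiply
node counts (hundreds of medians on a deep, diverse dataset) without
adding dating information. The full median-joining construction remains
the right object for display and for sparse datasets, and is what
`run_full_analysis()` builds.

# Dating

`dating_params()` carries the three conversion constants: `μ = 6.9×10⁻⁴`
per locus per generation — the evolutionary effective Y-STR rate
conventionally paired with `g = 25` years per generation — and the locus
count `L` (15 by default). The effective-rate convention is a modelling
choice: substituting a faster germline pedigree rate is a one-argument
change and rescales all ages downward proportionally.

The ρ statistic is the mean step distance of cluster members from the
root; `t = ρ/(L·μ)` generations. Its SD follows the
independent-branches (star) form `√(Σdᵢ)/n` when computed from raw
haplotypes, and the branch-sharing-aware form
`√(Σ_e m_e²·l_e)/n` — summing over the edges of the shortest-path tree
from the root, with `m_e` members descending through an edge of `l_e`
steps — when computed from a network cluster. TD dating uses
`ASD = mean_{i,l}(rᵢₗ − founderₗ)²`, `t = ASD/μ` generations, with the
across-locus SD of per-locus ASD (divided by √L) as its uncertainty;
under the SMM, ASD is exactly linear in time (the displacement variance
equals the mutation count expectation), which makes TD the less biased of
the two at depth.

Two conventions deliberately mirror founder-analysis tables:
`founder_age_summary()` averages cluster ages and averages cluster SDs
(unweighted), with inverse-variance weighting as an option; and
`group_expansion_age()` roots each population at its **per-locus** modal
haplotype. The latter matters: in an old population nearly every whole
haplotype is a singleton, so "the most frequent haplotype" degenerates to
an arbitrary tie-break, while the componentwise mode sits at the centre
of the radiation and dates it stably.

**Known bias.** ρ counts net steps, not mutations: two mutations at one
locus cancel with probability one half. The exact expectation of the
observed distance per locus is the mean absolute value of a symmetric
Skellam displacement, `λe^{-λ}(I₀(λ)+I₁(λ))` at mutation load `λ = μt`,
which is below `λ` by roughly `λ/2`. At founder depths (≈ 56 generations,
λ ≈ 0.04) this is negligible; at expansion depths of hundreds of
generations it shaves 10–20 % off ρ-based ages. The package does not
correct for it — matching the field's practice — but the simulator makes
it visible, and deep absolute ages should be read accordingly. The test
suite asserts recovery of simulated times within two reported standard
errors, where this bias comfortably fits at the depths tested; it
asserts only orderings for deep expansion ages.

# The simulator

`simulate_star_population()` draws, per individual and locus, a
Poisson(μt) number of ±1 steps (a star genealogy: private branches, no
shared drift). `simulate_coalescent_population()` draws a Kingman
genealogy at rate `k(k−1)/(2Ne)` and mutates along branches, giving the
shared-branch variance structure real samples have. Repeat counts are
unconstrained during simulation and floored at 1 only on output (with a
warning) — range constraints would break the linearity that the
estimators assume, and the defaults never approach the floor.

`simulate_roma_scenario()` composes these into the study design the
package targets: two source populations (n = 64 and 43) expanding in star
fashion for 642 and 998 generations (16.05 and 24.95 thousand years at
25 y/gen), their founders separated by 400 generations of divergence from
a common base haplotype of 14 repeats at 15 loci; and three focal
populations (n = 21, 41, 76) founded 56 generations (1400 years) ago from
1, 2 and 2 haplotypes drawn from the first source population's sample.
These defaults are the package's fixed reference conditions — sample
sizes and time depths chosen to match the scale of published
haplogroup-founder studies — and the ground truth (founders, times,
per-individual founder assignment) is returned alongside the data.

What the simulator does **not** emulate: admixture after founding,
population growth curves (star vs coalescent are the two extremes
offered), locus-specific mutation rates, multi-step mutations, and
genotyping artefacts. Passing recovery tests on this model therefore
demonstrates estimator correctness under the SMM, not robustness to
model misspecification.

Determinism is strict throughout: every simulation accepts a seed,
derives any sub-streams from it, and restores the caller's RNG state.

# Numerical and degenerate-input policy

* Estimators requiring variation (`HD`, `MPD`, variance, AMOVA's
  within-population component) error below their minimum n instead of
  returning NaN; monomorphic inputs return exact zeros where the
  definition allows.
* Ties are always broken lexicographically (modal haplotypes, node
  processing order, root assignment), never by hash or input order.
* Floating-point comparisons in network construction use a 10⁻⁹ slack on
  integer-valued weighted distances.
* Negative variance components and Rst values are reported raw in result
  objects and clamped only in exported matrices.

# Problem sizes used in validation

The shipped tests validate AMOVA/Rst against a brute-force
sums-of-squares oracle on 200 random small datasets (≤ 4 populations × ≤ 6
individuals), maximum-parsimony pruning against exhaustive
spanning-structure search on 25 networks of at most six nodes, ρ/TD
recovery on 100 star replicates of n = 200 at t = 100 generations,
founding-age recovery on 50 scenario replicates, and MDS against known
planar configurations at numerical precision. These sizes were chosen so
the full suite runs in about a minute while keeping Monte-Carlo standard
errors well below the effect sizes being asserted.

# Limitations

* Reproduction of any specific published table requires that study's
  genotype matrix; summary statistics are not invertible, and this
  package ships none of that data.
* Exact maximum-parsimony pruning is exponential in median vectors;
  beyond the cap the unpruned network is the product.
* ρ-based deep ages inherit the saturation bias described above.
* AMOVA significance is by permutation only; no analytic distribution is
  attempted.
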