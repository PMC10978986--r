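---
title: "Methods: genome-resolved co-activity and community cross-feeding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-resolved co-activity and community cross-feeding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coactomics)
```

This vignette explains the models behind each pipeline stage, the
parameters that matter, the numerical conventions, and — importantly —
what the synthetic-data module does and does not emulate, hence what a
green test suite does and does not show about real ocean data.

## 1. Genome catalogue

Quality classes follow the standard single-copy-marker conventions for
assembled genomes: HQ (completeness >= 0.90, contamination <= 0.05), MHQ
(>= 0.75, <= 0.10), MQ (>= 0.50, <= 0.25), LQ otherwise. All thresholds
are inclusive, matching the "at least" phrasing such rules are stated
with. LQ genomes are retained in tables but excluded downstream.

Species dereplication takes *precomputed* ANI and alignment-coverage
matrices (no sequence comparison happens here) and runs two-step
single-linkage clustering: connected components of the graph with edges
where ANI >= 0.90 and coverage >= 0.60, then, within each component,
components at ANI >= 0.95. Single linkage mirrors the graph-component
behaviour of the two-pass dereplication tools this emulates. The cluster
representative maximizes `completeness - 5 * contamination` — a widely
used dereplication default; the weight is exposed
(`quality_weight`) because the underlying principle is only "most
complete, least contaminated". Ties break by larger genome, then
lexicographic id, so representative choice is deterministic.

Bacterial and archaeal reference trees are built independently, so the
catalogue joins them through a new root with a total bridge of 0.122
substitutions/site. Whether that constant is one branch or two is
immaterial for every downstream use (only path lengths matter); we split
it 0.061 + 0.061. Patristic distances and mean pairwise community
distance are plain branch-length sums; a precomputed cophenetic matrix
can be passed when typing many communities.

## 2. Meta-omics activity profiling

The printed identity formula `(NM - XN)/L` is a **mismatch** fraction
(edit distance minus ambiguous reference bases, over read length).
Reading it literally as an identity would make the "identity >= 95%"
filter unsatisfiable for good alignments, so the package defines
`identity = 1 - (NM - XN)/L`; the filter keeps records with MAPQ >= 20
and identity >= 0.95, both inclusive. Alignment spans are 0-based
half-open.

Depth is total aligned bases over genome length; breadth is the fraction
of positions covered at least once (overlapping spans counted once). A
genome is *observed* in a sample when its metagenomic breadth is at
least 0.30. Activity is the ratio of metatranscriptomic to metagenomic
depth; no activity threshold is applied, so 0 is a valid activity. Both
the abundance and the activity matrix mask cells keyed on **metagenomic**
breadth: activity needs its metagenomic denominator, and occurrence is
defined on the metagenome. Genomes observed in fewer than
`n_obs_min = 10` samples are dropped, independently per layer.

"Per 1 M base pairs" normalization is ambiguous between genome-length
and sequencing-effort scaling; since depth already divides by genome
length, the package normalizes by total mapped sample megabases
(cross-sample effort), with `normalization = "none"` available. Note
that the CLR transform makes per-sample scale factors irrelevant for
network inference, so this choice only affects reported abundances.

CLR: per sample, zeros among observed values are replaced by half the
smallest non-zero observed value in that sample (adaptive pseudo-count),
then values are logged and centred to zero mean over observed genomes.
Masked cells stay `NA` and are excluded from every statistic.

## 3. Network inference

Edges are direct associations surviving conditional-independence
pruning. Stage 0 keeps pairs whose Pearson correlation (on the CLR
matrix, pairwise-complete samples, at least `n_obs_min = 10` shared
observations) is significant under the Fisher z test
`z = atanh(r) * sqrt(n - k - 3)` at `alpha = 0.01` (the inference
tool's significance default is not exported; 0.01 is this package's
default and exposed). For k = 1..`max_k` (default 3), each surviving
edge is tested against conditioning subsets drawn from the current
neighbourhoods of its endpoints (PC-stable: neighbourhoods are
snapshotted per level); one non-significant test removes the edge and is
recorded in an audit table, so every absence is attributable. Surviving
edges carry the partial correlation given the largest certifying
conditioning set. Partial correlations are computed by inverting the
covariance submatrix; collinear conditioning sets raise an error at the
operation level and are skipped (non-informative) inside the search.

Because the original tool's local-to-global heuristics are not published
at procedure level, this PC-stable variant is a documented
simplification. `conditioning = "exhaustive"` (all subsets of all other
variables up to `max_k`) provides the small-instance surface on which
the procedure provably equals a brute-force conditioning oracle — the
default neighbourhood-restricted search can only retain a superset of
those edges, since it sees fewer removing tests.

**A structural caveat on latent-factor cliques.** If k genomes co-vary
through one shared latent factor, any pair is conditionally independent
given a third member; the maximum partial correlation given one sibling
is 0.25 (at the optimal noise level), given three siblings 0.13. At
desk-scale sample sizes (tens of samples) such edges are *correctly*
pruned. Pairs have no sibling proxy, so two-member planted communities
are the canonical recoverable unit; the end-to-end pipeline plants pairs
by default, and larger plans are supported but their intra-community
edges should be expected to thin out with increasing size. This is a
property of conditional-independence networks, not an implementation
artifact.

## 4. Markov clustering

MCL runs on the positive-weight subgraph: flow interpretation requires
non-negative similarities, so negative edges are dropped for clustering
(kept in the network and all sign-based summaries); folding them in by
absolute value is available (`negative = "absolute"`). Self-loops equal
each node's maximum incident weight (standard regularization; exposed).
Expansion 2, inflation 1.5, pruning threshold 1e-5, convergence when the
maximum entry change falls below 1e-8; non-convergence within
`max_iter = 200` is an error with diagnostics. Clusters are the
connected components of the converged flow's support; size-1 clusters
are reported separately as singletons.

## 5. Constraint-based scores

Toy models use a shared ~13-metabolite universe (glucose/acetate carbon,
five amino acids, thiamine, ribose, plus inorganic ammonium, phosphate,
water, CO2) with one biomass precursor per planted auxotrophy, keeping
exhaustive oracles tractable. Exchange reactions use the `EX_`
convention (negative flux = uptake). Inorganic environment metabolites
are always open and excluded from minimal-media candidates and from all
cross-feeding records — mirroring the practice of excluding inorganics
so that phosphate/iron-style essential uptake does not swamp biotic
exchanges.

Growth is the flux-balance LP optimum of the biomass reaction reaching
`g_min = 1e-4` flux units ("non-zero growth" needs a numeric floor;
exposed). For communities, growth means simultaneous growth of every
member (biomass lower bounds `g_min`, feasibility test). The LP engine
is a dense two-phase primal simplex (`src/simplex.cpp`) with Dantzig
pricing, a Bland anti-cycling fallback, and bounds handled as explicit
slack rows after shifting fluxes to non-negative form — problems here
have tens of rows, where a dense tableau is the simplest robust choice.

Minimal media are *all* inclusion-minimal subsets of the organic
candidates supporting growth, by exhaustive lattice search with superset
pruning (candidate count guarded at 20); `weighting = "molweight"`
selects the media with the smallest total molecular weight among the
inclusion-minimal ones. The published component-score formulas are
delegated by their sources to solver-level MILP enumeration, so this
package pins *operational* definitions with oracle tests instead:

* `MRO = sum_{i<j} |M_i ∩ M_j| / sum_{i<j} min(|M_i|, |M_j|)`, with
  `M_i` the union of species i's minimal media (species in isolation).
* `MIP = |smallest private-mode community medium| - |smallest
  shared-mode community medium|`; private mode gives each member its own
  extracellular compartment, so MIP counts metabolites spared by
  exchange and is non-negative by construction.
* `SCS(d, r)`: fraction of inclusion-minimal donor sets (subsets of the
  community whose joint growth with r on the medium rescues r)
  containing d; 0 when r grows alone. Requiring *all* members of the
  rescuing set to grow follows the "non-zero growth of all community
  species" framing.
* `MUS(m, r)`: fraction of r's inclusion-minimal organic uptake sets —
  within the community environment (medium plus whatever other members
  can secrete) — containing m.
* `MPS(m, d)`: 1 if d can secrete m at non-zero flux on the medium
  (producibility; no growth requirement on the donor), else 0.
* `SMETANA = SCS * MUS * MPS` per (donor, receiver, metabolite); the
  community sum is normalized by `N(N-1)/2`.

The default medium for detailed scoring is the smallest shared-mode
community minimal medium (the community-specific minimal medium
convention), overridable. Communities beyond 6 members are refused —
the enumeration is exact, not heuristic.

Transporters: reactions with transport annotations (or spanning
compartments unannotated, mapped to "other") are tabulated into nine
mechanism classes; reversible transporters are duplicated into import
and export rows. A transporter is *active* when at least one gene in
its rule is transcribed, regardless of AND/OR structure. Metabolite
categorization is a total table lookup with an "uncategorized" fallback.

## 6. Community typing

Null thresholds come from random communities sampled uniformly without
replacement from the network genome pool, with sizes resampled from the
observed co-active size multiset (the size distribution of the original
random communities is not recorded; a uniform size range is available
behind `size_range`). Quantiles use linear interpolation (type 7), fixed
for reproducibility. "Smaller than 95% of random communities" is read as
below the 5th percentile (strict), "above 95%" as above the 95th
percentile (strict), giving the four LPD/HPD x LCP/HCP quadrants.

The functional Gini uses the bias-corrected denominator
`2 n (n - 1) mean(x)` so that the verbal endpoints are exactly
attainable: equal capitals give 0 and a single functional holder gives
exactly 1 (the raw n^2 form is available via `corrected = FALSE`).
Capitals count occurring KOs (present in >= 1 member) carried by each
member. Expressed-mode Jaccard restricts KO sets to those detected in at
least 10 samples.

Because toy-model SMETANA scores are ratios of small integers, the null
score distribution at desk scale is discrete; the calibration tests
therefore use a model pool designed to diversify the score lattice
(helper prototroph donors, dependents with one or two auxotrophies, and
alternative precursor routes that split minimal uptake sets), and the
acceptance checks allow the tail probabilities a wider Monte-Carlo band
than a continuous null would need. Real genome-scale models produce
near-continuous scores and would not show this artifact.

## 7. What the synthetic world does and does not emulate

The generators plant: per-category gene counts following
`log10(y) = log10(c) + beta log10(x) + N(0, sigma)` noise (counts
rounded half away from zero; zeros excluded from fits since the law is
linear in log space and no pseudo-count is prescribed); log-uniform
genome sizes spanning at least one order of magnitude; random
bifurcating domain trees; compositional coverage tables closed to a
fixed per-sample depth total; co-activity induced on the *activity*
layer through a shared lognormal latent factor with per-member loadings
and lognormal noise, while metagenomic depths stay only weakly
structured (co-abundance and co-activity are distinct signals); breadth
above the detection rule for planted members in their support samples;
alignment records with consistent `0 <= XN <= NM <= L` fields and truth
labels; ANI matrices with within-cluster >= 0.95 over >= 0.60 coverage
and between-cluster <= 0.90; toy models with planted obligate or
facultative cross-feedings plus prototroph controls.

They do **not** emulate: read-level sequences (no FASTQ), environmental
covariates, phylogenetically structured co-activity (tree and activity
are independent), realistic activity noise (the lognormal latent-factor
model is a stand-in, not a claim about field data), genome-scale
metabolic network topology, or taxonomy. Passing tests therefore
demonstrate correctness of the *computations* and recoverability of
*planted* structure at desk scale — not that the method's assumptions
hold in the ocean.

## 8. Problem sizes and determinism

The test suite and acceptance script run end-to-end worlds of 30 genomes
by 40 samples with three planted co-active pairs; scaling-law checks use
500 genomes (slope recovery) and 50 x 120-genome scans (enrichment
power); network calibration uses 100 x 20-variable noise draws and 100
causal-chain draws at n = 500; typing calibration classifies 1000 null
draws against thresholds from 110 (memoized over the ~200 distinct
communities of an 11-model pool). Every generator accepts a seed and is
deterministic under it (RNG state is saved and restored, so generators
do not disturb the caller's stream); network inference and MCL iterate
in sorted, stable order, so whole-pipeline runs are reproducible from a
single integer.

## 9. Known limitations

* The PC-stable variant is not the original local-to-global algorithm;
  edge sets can differ from it, and only the exhaustive mode is
  oracle-exact.
* Exact enumeration bounds everything: 20 medium candidates, 6 community
  members. The package refuses, rather than approximates, beyond them.
* MRO/MIP/SCS/MUS/MPS are operational definitions pinned by oracle
  tests; bit-compatibility with external MILP-based implementations is
  not claimed (denominator conventions in particular may differ).
* Latent-factor cliques of size >= 3 are intentionally not recoverable
  as cliques at small n (Section 3); recovery claims are for pairs.
* The heterogeneous/meta-variable handling of the original network tool
  and time-series or latent-variable causal discovery are out of scope.
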