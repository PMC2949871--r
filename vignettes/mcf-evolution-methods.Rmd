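---
title: "Methods: region composition, selection and substrate proxies for the mitochondrial carrier family"
author: "mcfevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region composition, selection and substrate proxies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcfevo)
```

## The scientific setting

Mitochondrial carriers (the SLC25 family, ~44 members in human) share a
conserved architecture: six transmembrane alpha-helices (TR1..TR6) around a
central translocation channel, with the loops between odd helix pairs
(loop1, loop3, loop5) facing the mitochondrial matrix and the termini plus
loops 2 and 4 facing the cytosol. Each helix can be halved vertically into a
cytosol-facing (UP) and matrix-facing (DOWN) part, giving four quadrant
composites — `TR_UP135`, `TR_UP246`, `TR_DOWN135`, `TR_DOWN246` — plus the
aggregates `TR`, `TR_UP`, `TR_DOWN`, `LOOP135`, `NCLOOP24`. The matrix ends
of the odd helices carry the Px(D/E)xx(K/R) signature motifs that line the
conical substrate pit (`CPR`); conserved proline/glycine hinges sit near the
midpoints of the even helices.

The package asks, on this coordinate system, the questions a molecular-
evolution study of the family asks: does the hydrophobic fraction of
specific helix faces rise across metazoan evolutionary phases (invertebrates
`Non-ver`, vertebrate ectotherms `Ver-eco`, vertebrate endotherms
`Ver-endo`)? Is the family under purifying selection? Where did gene
duplications occur? Do the substrate-facing motifs stay conserved, and how
old are the substrate clusters?

## The region model

A `topology_model` is pure data: six helix column intervals, a split column
per helix, loop intervals that tile the remaining columns, and three motif
anchors. Coordinates are 1-based inclusive alignment columns; reported
motif positions are 1-based ungapped residue positions, so residues of
specific carriers remain addressable. Helix boundaries for a real alignment
differ between curation choices, so they ship as an editable YAML fixture
rather than constants; the default 200-column layout (20-column helices,
12-column loops, 10-column termini, midpoint splits) is the shape the
synthetic generator emits.

Two conventions are worth stating because they are genuinely open:

* **UP/DOWN split.** The vertical halving point of a helix is not uniquely
  defined; the default is the geometric midpoint (`ceiling((a+b)/2)` is the
  first DOWN-side column for odd helices), overridable per helix for users
  who prefer hinge-anchored splits (the P-G "level 1" plane sits near the
  midpoint anyway).
* **Orientation.** Odd helices run cytosol to matrix, even helices the
  reverse; the model records which half of each helix is UP, defaulting to
  this alternating pattern.

Partitioning excludes gaps from region residue strings but keeps per-residue
column provenance, so reassembly is exact (a tested invariant) and a region
is "present" as soon as one residue survives; gap-only regions are flagged,
never silently counted as zero.

## Composition statistics

Residue classes are a disjoint cover of the 20 amino acids, shipped as data
(default: hydrophobic A,V,L,I,M,F,W,C; charged D,E,K,R,H; turn G,P,S,N;
hydrophilic T,Q,Y) because published hydropathy tables differ; every
statistic takes the scheme as a parameter and the tests also run synthetic
schemes.

Two designs are implemented:

1. **Phase comparison with selected species** — per-sequence class
   proportions in a region, compared across phases by classic one-way
   ANOVA (`stats::oneway.test`, equal variances) followed by Holm–Šidák
   step-down decisions (`p` ranked, the k-th smallest compared against
   `1 - (1-alpha)^(1/(m-k+1))`, stopping at the first failure).
2. **Pooled resampling ECDFs** — the mean class proportion of
   `sample_size` sequences drawn without replacement from a phase pool,
   repeated `replicates` times; defaults 132 and 132 (44 carriers times 3
   species). The empirical cumulative distribution of replicate means is
   the phase-separation display, and the exact sup-distance between two
   such ECDFs (`ecdf_ks_distance`) the separation measure. Sampling
   without replacement is deliberate: with pools of 160–210 against a
   sample of 132 the two modes differ materially; a with-replacement flag
   exists.

**Calibration.** Replicate means from subsampling one pool concentrate
around that pool's own mean (standard deviation roughly the per-sequence
spread over `sqrt(132)`, shrunk further by the finite-population
correction), so a two-sample KS *test* applied to two pools' replicate-mean
ECDFs is drastically anticonservative — in simulation it rejects a true
null most of the time. The calibrated pool comparison therefore runs the KS
statistic on the *per-sequence* proportions, with a permutation p-value
(region proportions are heavily tied, which makes the asymptotic p-value
conservative). One further subtlety: phase pools contain orthologs of the
same carrier subfamilies, so sequences are clustered by family and plain
permutation is again miscalibrated; `ks_pool_test` accepts subfamily labels
and permutes pool membership within families, which matches how the pools
are assembled and makes the test exact under the generator's null
(measured rejection ≈ 0.05 at the nominal 5% level over 200 seeds).
Replicate-mean ECDFs remain the effect-size and display device.

Sequence identity of a region is the mean over all unordered pairs of the
percentage of matching columns, excluding both-gap columns and counting a
single-gap column as a mismatch (the convention is recorded on the result;
identity-to-a-reference is a different statistic and not what is computed
here). For pools mixing unrelated subfamilies the meaningful quantity is
the within-subfamily (ortholog) mean, which the analysis scripts report.

## Packing

Helix packing values are per-residue compactness measures from
occluded-surface analyses of membrane proteins. The published per-residue
table is not redistributed; the package ships a clearly labelled
*synthetic* table (`packing_values_synthetic.tsv`) with plausible
magnitudes, and all tests use synthetic tables, so the statistic stays
exact and the data honest. Because "the mean packing of a pool" is
ambiguous for ragged pools, `mean_packing` reports any of three
aggregations — grand mean over residues, mean of per-sequence means, mean
of per-subfamily means — which coincide on balanced gap-free pools.

## Selection

Pairwise dN/dS uses the Nei–Gojobori (1986) pathway method: per-codon
synonymous site fractions (averaged over the two sequences), observed
differences averaged over all orderings of the changed positions, and the
Jukes–Cantor correction `d = -3/4 log(1 - 4p/3)` applied to both
proportions. Conventions that the original leaves open are fixed as
follows and mirrored exactly by the brute-force enumeration oracle in the
test suite: mutational pathways through stop codons are excluded with
weights renormalised (if no pathway survives, all are used and the case is
flagged by construction); site counting likewise excludes changes to stop
codons and renormalises the per-position fractions, so synonymous plus
nonsynonymous sites always total three per codon. Gapped codon columns are
dropped pairwise; proportions at or above 3/4 saturate the correction and
are flagged rather than returned as numbers; `omega` is flagged undefined
when `dS = 0`. Two properties of the estimator are worth knowing: a single
synonymous codon difference in a very short sequence saturates the
correction (pS can exceed 1), and double synonymous hits within one codon
can yield a small positive pathway-averaged dN even when no nonsynonymous
substitution ever occurred — both are mathematics, not bugs, and both are
pinned by tests.

The branch-site test for positive selection is consumed, not fitted: given
the log-likelihoods of the null (foreground omega fixed at 1) and
alternative models, `2*lambda` is compared against the critical value of
the 50:50 mixture of a point mass at zero and chi-square with one degree of
freedom — `c` solves `0.5 * P(chisq_1 > c) = alpha`, giving 2.71 at 5% and
5.41 at 1%. Negative `2*lambda` is clipped to zero and flagged;
significance is strict exceedance.

## Trees and duplications

Distances are Poisson-corrected protein distances, `-log(1 - p)` on the
differing fraction of compared columns, with saturated pairs flagged.
Neighbor joining is implemented in the package because a deterministic
tie rule is part of its contract: among minimal `Q` entries the pair with
the lowest row then column index joins, negative branch lengths are clamped
to zero and counted, and the final three lineages get the closed-form star
resolution. On additive matrices the result is exact (tested to 1e-9
against the generating tree, and cross-checked topologically against
`ape::nj` on random matrices). Bootstrap support is column resampling with
a seed, annotated via `ape::prop.clades`.

Duplications are detected by species overlap on a rooted tree: an internal
node whose two child clades share at least one species is a duplication,
and it is *accepted* when both emerging orthologous subfamilies span at
least two species. Rooting is the user's decision (midpoint rooting is one
flag away but a logged choice, since the detection outcome depends on it);
polytomies are resolved arbitrarily and flagged.

## Substrate proxies

The three conical-pit motifs are located per odd helix by searching
`P.[DE]..[KR]` within a window of ±10 ungapped residues around the
configured anchor; the nearest match start wins, ties going left. The
18-residue concatenation (the "mark sequence") is the substrate-selectivity
proxy; missing motifs yield placeholders and an explicit incompleteness
flag. Logo-level similarity is made quantitative as the mean per-column
Jensen–Shannon divergence (base 2) between position frequency matrices:
0 for identical column distributions, 1 for disjoint residue usage.

Carrier-cluster age averages `log10` of the `k = 10` smallest E-values per
carrier, then averages carriers within a cluster; exponent averaging is the
geometric-mean reading that `10^-x` notation implies. Short lists use all
values with a warning; `E = 0` is clipped to a configurable floor exponent
(default −180) and flagged. The metric is a relative ordering — more
negative means older — not a calibrated date.

## The synthetic-data generator

`generate_mcf_pools` emits the three phase pools under a fully known model,
with defaults chosen once to mirror the study conditions: 44 carrier
subfamilies; pool sizes 192 (`Non-ver`), 164 (`Ver-eco`), 208 (`Ver-endo`),
assembled species-major so the last species of a phase may lack some
carriers, as real curated pools do; background hydrophobic fraction 0.40 in
helices and 0.25 in loops (uniform within residue class); substitution
probability 0.10 per site between a family ancestor and each ortholog;
motif conservation 1.0.

Design points that matter for interpreting results:

* **One root ancestor per subfamily, shared by all phases.** The phase
  pools hold orthologs of the same carriers, so family identity is a
  *paired* effect across phases. This is what makes a family-stratified
  permutation test exact under the null; with independent per-phase
  ancestors the pools would genuinely differ at the family level and every
  honest test would reject.
* **Enrichment is a marginal lift with an exact region-level target.**
  `delta` is the increase in expected hydrophobic proportion of a whole
  enriched region (`TR_DOWN135` and `TR_UP246` in the vertebrate phases).
  Constrained columns — motif P/(D,E)/(K,R) positions and the P/G hinges —
  cannot be hydrophobic, and the motif x-positions are deliberately left at
  background so mark sequences stay comparable across phases; the boost on
  the remaining helix columns is inflated accordingly, and the realized
  phase difference equals `delta` exactly in expectation (a tested
  invariant, and the reason `delta` up to about 0.24 is feasible at the
  default background).
* **Substitution noise redraws from the site's own distribution**, which
  preserves marginals exactly; hinges never mutate, motif-constrained
  positions stay within pattern with probability `motif_conservation`.

What the generator does **not** emulate: indels and alignment uncertainty,
site-specific conservation profiles and rate heterogeneity (ortholog
identity is therefore flat across regions, unlike real carriers where the
transmembrane core is the most conserved), between-family homology
(subfamily representatives are unrelated random sequences, so deep nodes of
an all-family tree carry no signal and low bootstrap support), and
substrate-cluster structure in the sequences themselves (cluster ages come
from a separate E-value exponent generator). Passing tests therefore
validate the statistics and their calibration, not the biological claims on
real data.

The codon simulator is a minimal thinned Markov jump process: uniform
single-nucleotide proposals at rate 1 per site for time `t`, synonymous
changes always accepted, nonsynonymous with probability `omega`, stops
never — adequate for estimator-recovery tests, not a named codon model.
The duplication-tree generator plants events at pairwise non-nested
internal nodes of a random species tree (no losses); nested histories are
not modelled because, without losses, an event below a duplication would be
copied into both paralog subtrees and the planted-event count would become
ambiguous.

## Numerical choices and problem sizes

Every stochastic function takes and records an integer seed; reruns are
bit-identical. ECDFs are `stats::ecdf` step functions; KS distances are
computed exactly at the jump points. The mixture critical value solves its
defining equation to better than 1e-8 via `stats::qchisq`. Degenerate
inputs return flagged values, not silent defaults: empty regions give
flagged `NA` proportions, an all-identical ANOVA returns `F = 0, p = 1`
with a degeneracy flag, saturated distances return `Inf` with a saturation
attribute.

The shipped analyses and checks use problem sizes chosen to make every
statistic's sampling error small relative to the effects probed while
remaining quick on a laptop: full-size phase pools (192/164/208 sequences
of 200 columns) wherever the study design itself is the point, 132×132
resampling, 200 generator seeds for the null-calibration experiment,
400-codon pairs (30–60 replicates) for estimator recovery, and 100 planted
trees for the duplication benchmark.

## Limitations

The NG86 estimator is the package's built-in dN/dS method; it preserves
the qualitative regime (strong purifying selection, omega far below 1) but
is not the Yang–Nielsen (2000) counting method, which weights codon
frequencies and transition/transversion bias — the estimator interface is
a single function boundary, so a yn00-compatible backend can be slotted in.
Branch-site model likelihoods must come from an external optimiser; only
the decision rule is applied here. Rooting choices materially affect
duplication counts and are logged rather than optimised. The packing table
shipped is synthetic; conclusions about real compactness require the
user's preferred published table.
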