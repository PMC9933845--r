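---
title: "Likelihood-based phylogenetic placement with phyplace: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based phylogenetic placement with phyplace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyplace)
```

`phyplace` places aligned query sequences onto a fixed backbone phylogeny
by maximum likelihood, optionally through a divide-and-conquer layer that
restricts the likelihood search to a subtree around the query's nearest
leaf. This vignette is the package's own account of the underlying models
and algorithms, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the places where a
design decision had to be made.

## The substitution model

All likelihoods use the generalized time-reversible (GTR) model with
discrete-Gamma rate heterogeneity. The instantaneous rate matrix is

$$Q_{ij} = s_{ij}\,\pi_j \quad (i \ne j),$$

with six symmetric exchangeabilities $s_{ij}$ (order AC, AG, AT, CG, CT,
GT; GT is fixed at 1 when estimated, the standard identifiable
parameterization), stationary frequencies $\pi$, and the diagonal set so
rows sum to zero. $Q$ is rescaled so $-\sum_i \pi_i Q_{ii} = 1$: one unit
of branch length is one expected substitution per site at stationarity.

Rate heterogeneity across sites uses $k$ equal-probability categories of a
mean-one Gamma distribution with shape $\alpha$; each category's rate is
the *mean* of its Gamma slice (not the median), which preserves the mean
substitution rate exactly. The default $k = 4$ is the field convention;
the per-category rates satisfy $\bar r = 1$ to machine precision.

Transition probabilities $P(t) = e^{Qt}$ are computed through the
symmetrized eigendecomposition
$D_\pi^{1/2} Q D_\pi^{-1/2} = V \Lambda V^\top$, so
$P(t) = A\,e^{\Lambda t}B$ with $A = D_\pi^{-1/2}V$ and
$B = V^\top D_\pi^{1/2}$. The symmetric form keeps the decomposition
numerically stable for any admissible $\pi$ (which is why empirical base
frequencies carry a pseudocount of 0.5 per state: zero frequencies would
break it). Tiny negative entries produced by round-off in the composite
transform are clipped at zero.

## Likelihood computation and the two-directional cache

`compute_loglikelihood()` is standard Felsenstein pruning: leaves
contribute indicator vectors (gap, `N`, `?`, and IUPAC ambiguity codes
contribute ones over their compatible states — missing data), internal
nodes multiply their children's transformed partials, and per-site values
average the $k$ categories with equal weights. Identical alignment columns
are collapsed into weighted site patterns first; this is exact and is the
single most effective speedup on real-sized alignments.

Underflow protection is per node, per site pattern, and per category: when
the maximum state entry of a partial falls below $10^{-100}$ the column is
renormalized and the log factor accumulated, so likelihoods remain finite
on large trees — precisely the regime where naive implementations start
returning `-Inf`.

`compute_edge_partials()` adds the pre-order direction: for every node,
the conditional likelihood of *the rest of the tree* seen from its parent.
For a reversible model, combining the two directions across any edge
reproduces the total log-likelihood (the pulley principle), which the test
suite verifies edge by edge. The payoff is that the likelihood of any
*modified* edge — a new branch length, or a query attached at an interior
point — costs O(sites × categories) instead of a full tree traversal. The
inner kernels live in `src/kernels.cpp` (RcppArmadillo) with hand-fused
per-column loops; on one core the computation is memory-bound, so avoiding
intermediate matrices matters more than FLOP counts.

## Branch-length and model-parameter estimation

`optimize_branch_lengths()` is coordinate ascent: each branch is optimized
by Brent's method on $[10^{-8}, 20]$ expected substitutions/site (zero is
excluded to keep $P(t)$ nondegenerate; 20 is effectively saturation).
Within a sweep all branches are optimized against the current cache and
proposed jointly; if the joint update ever overshoots (it rarely does),
the sweep falls back to sequential updates with a fresh cache per branch,
which cannot decrease the likelihood. Accepted log-likelihoods are
therefore monotone, which is asserted in the tests. Sweeps stop when the
total improves by less than `tol` (default $10^{-4}$ log units, maximum 50
sweeps with a warning).

`estimate_model_parameters()` mirrors the numeric-parameter estimation
stage that external tools (RAxML, FastTree) perform in production
placement pipelines, as a functional stand-in on a fixed topology: base
frequencies are empirical (counts over non-gap, non-ambiguous characters
plus the 0.5 pseudocount); exchangeabilities (5 free, GT-normalized) and
$\alpha$ (searched in $[0.01, 100]$ on the log scale) are fitted by
Nelder-Mead on the log scale, interleaved with branch-length sweeps for
`rounds = 2` outer rounds. No claim of numeric equality with any external
binary is made — the contract is stated through recovery experiments on
simulated data: with 16 taxa and 20,000 sites the median relative
branch-length error is well under 10% and a 4× inflated AG exchangeability
is recovered as the largest.

## Placement

`place_query()` scores the attachment of the query on *every* backbone
edge. The geometry on an edge of length $b$ has two parameters: the distal
offset $x \in [0, b]$, measured from the child (leafward) endpoint, and
the pendant branch length $p \in [10^{-8}, 5]$. Writing $D$ for the
child-side partial, $U$ for the parent-side partial, and $q$ for the query
leaf vector, the per-site likelihood of the extended tree is

$$\ell = \sum_a \pi_a\,[P(x)D]_a\,[P(b-x)U]_a\,[P(p)q]_a,$$

evaluated from the cache without rebuilding the tree. Each edge runs a
2-D coordinate ascent (Brent in $x$, then in $p$), initialized at
$x = b/2$, $p = 0.1$, for at most `optimize_iters = 5` rounds or until a
round improves by less than $10^{-4}$. Two engineering details:

- Edges whose score after the first round is more than 60 log units below
  the running best stop refining early. Such edges cannot influence the
  argmax in practice and are excluded from the softmax anyway (the
  reported `like_weight_ratio` drops scores below best − 50 to avoid
  underflow).
- The winning edge is re-polished at full resolution
  ($x$ to $10^{-5} b$, $p$ to $10^{-7}$) so the reported geometry is
  accurate even though the search over non-winning edges is coarse.

Near-ties ($|\Delta\log L| < 10^{-9}$) break toward the smaller edge
number, making results deterministic. The optimizer's contract is stated
via an oracle: on small instances the chosen edge matches the argmax of a
dense 21 × 21 grid over $(x, p)$ per edge, and the attachment score itself
equals the full pruning likelihood of the explicitly reconstructed
extended tree to $10^{-8}$.

`like_weight_ratio` is a softmax over per-edge *optimized* scores, not a
Bayesian integral over placements; it should be read as a relative
likelihood weight, not a posterior probability.

## The divide-and-conquer layer

`scampp_place()` composes four steps:

1. **Nearest leaf.** Normalized Hamming distance (p-distance) between the
   query and every backbone leaf, counting only columns where both
   sequences are non-gap; pairs with no comparable column score 1. The
   mutual-non-gap convention is a deliberate choice: fragmentary queries
   are mostly gaps, and counting gap mismatches would let gap count
   dominate the signal.
2. **Subtree extraction.** The `B` leaves with the smallest branch-length
   path distance from the seed leaf (ties by label) induce the placement
   subtree; degree-2 nodes are suppressed with branch lengths summed.
   Branch-length distance (rather than topological edge count) is the
   default because branch lengths carry the evolutionary signal the
   nearest-leaf heuristic exploits; a `distance_mode` switch provides the
   topological alternative. The default `B = 2000` follows the
   recommendation established for this family of methods; at desk scale
   any `B ≥ n` reduces the pipeline *exactly* to full placement, which the
   tests assert to $10^{-6}$ log units.
3. **Placement in the subtree**, reusing the backbone's model parameters
   without re-estimation (the subtree inherits the backbone's "reference
   package"; re-fitting on a biased leaf sample would only add variance).
4. **Back-mapping.** Each subtree edge records the ordered backbone edge
   segments it compresses (child end first). The subtree distal offset is
   walked along those segments; a point landing exactly on a segment
   boundary belongs to the more parentward segment with distal length 0.
   Segment sums equal compressed lengths to $10^{-9}$, and each backbone
   edge appears in at most one segment list.

## Evaluation machinery

Placement accuracy is measured topologically. A tree's non-trivial
bipartitions are canonicalized as the split side not containing the
lexicographically smallest leaf; `fn_missing_branches(reference,
estimated)` counts reference splits absent from the estimated tree (the FN
half of Robinson–Foulds), after restricting the reference to the estimated
tree's leaves. The **delta error** of a placement is the FN count of the
placed tree (against the reference restricted to backbone leaves plus the
query) minus the FN count of the backbone (against the reference minus the
query). It is always non-negative and is zero exactly when the query lands
on the edge its reference position induces.

`leave_one_out_experiment()` samples queries without replacement (seeded),
prunes each from the tree (suppressing the degree-2 node, summing
lengths), optionally cuts the query to a fragmentary protocol, places it
back, and reports per-query records with the mean delta error and its
standard error ($s/\sqrt{n}$).

**Fragmentary protocols.** For a query of ungapped length `lo`, the
fragment length is drawn from $N(0.25\,lo, 60)$ (low) or $N(0.10\,lo, 10)$
(high), in basepairs, rounded and clamped to $[1, lo]$. The length model
and both parameter pairs are protocol constants. The starting position is
stated to be normally distributed but its parameters are not fixed by the
protocol's description; this package centers it — start
$\sim N((lo-L)/2, \sigma)$, clamped so the fragment fits — which keeps
fragments unbiased along the sequence while honoring the stated spread.
Fragments are cut in ungapped coordinates and re-expressed in alignment
columns by gapping everything outside the fragment, since queries enter
the pipeline pre-aligned.

## The synthetic-data generator

`simulate_tree()` draws a Yule (pure-birth) topology and rescales branch
lengths so the mean root-to-tip path is 0.5 expected substitutions/site —
a moderately diverged backbone where placement is informative but not
trivial. `simulate_alignment()` draws root states from $\pi$, assigns each
site a Gamma category, and evolves states down the tree with
$P(t \cdot r)$; the output is ungapped.

What this emulates: substitution-driven divergence under the exact model
family the likelihood machinery assumes, at controllable size. What it
does not: indels and alignment error (real backbone alignments are
estimated, with gaps and misaligned regions), model misspecification
(real data never evolved under GTR+Γ), rate variation along the tree, and
backbone trees with topological error. Green tests on this generator
therefore demonstrate the *correctness of the algorithms* under their own
assumptions — oracle equality, exact reductions, contract invariants —
not field accuracy on biological data. The one protocol component taken
from the evaluation literature verbatim (fragmentary read-length cutting)
is exercised on the generator's full-length queries.

Experiment sizes used by the packaged tests were chosen to make each
property statistically decisive at desk scale: 100 random instances for
the likelihood oracle (≤ 5 leaves, ≤ 4 sites, random GTR+Γ, including gaps
and ambiguity codes), 25 instances for the placement grid oracle, 50
30-leaf instances for the `B ≥ n` reduction, 600 leave-one-out placements
for the delta-error contract, 20 replicates of 16 taxa × 20,000 sites for
parameter recovery, 20,000 draws per fragment protocol, and one 200-leaf
backbone with 100 full-length and 100 high-fragmentary leave-one-out
queries for the end-to-end directional check (full-length mean delta error
below 0.5; fragmentation never decreases it).

## Numerical choices and degenerate inputs

- State order is fixed as A, C, G, T everywhere.
- Scaling threshold $10^{-100}$ per node/site/category; log factors
  accumulate exactly.
- Branch-length bracket $[10^{-8}, 20]$; pendant bracket $[10^{-8}, 5]$.
- Zero-length edges are legal; the distal search degenerates gracefully
  (no search when $b \le 10^{-12}$).
- All-gap queries are rejected as uninformative; a query whose label
  collides with a backbone leaf is an error.
- Missing branch lengths in Newick input are read as 0 with a warning;
  negative or non-finite lengths are errors.
- Edge numbers are assigned canonically — post-order with children
  ordered by their smallest descendant leaf label (byte order) — so
  numbering is a pure function of the labeled topology, invariant to the
  child order of the input file and stable across serializations.
- Alignment pattern compression keys include any query rows that will be
  scored against the cache, so compressed placement is exact, not
  approximate.

## Known limitations

- Topology inference is out of scope: the backbone topology is fixed
  everywhere; only numeric parameters are estimated.
- Nucleotide data only; no proportion-of-invariant-sites mixture, no
  amino-acid or codon models.
- `like_weight_ratio` is likelihood-based, not a posterior.
- Placement scales as O(edges × sites × categories) per query with the
  default exhaustive edge scan; the divide-and-conquer layer is the
  intended route for large backbones.
- Each query is placed independently; batched amortization of subtree
  extraction across queries sharing a seed leaf is not implemented.
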