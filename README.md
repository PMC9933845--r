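# phyplace

Maximum-likelihood phylogenetic placement with a divide-and-conquer layer,
in R.

## The problem

Phylogenetic placement inserts *query* sequences, one at a time, into an
existing *backbone tree* whose leaves carry a fixed multiple sequence
alignment. It is the workhorse for updating large reference phylogenies and
for taxonomically characterizing reads from environmental samples. The most
accurate placement methods are likelihood-based: given numeric model
parameters estimated on the backbone (branch lengths in expected
substitutions per site, and a GTR+Γ substitution model), the query is
attached to the edge that maximizes the probability that the resulting tree
generated the query sequence. Direct maximum-likelihood placement scores
every edge of the backbone, which becomes numerically fragile and expensive
on very large trees; a divide-and-conquer strategy instead selects a small
*placement subtree* around the query's nearest leaf, places the query
within it, and maps the chosen edge back onto the backbone.

`phyplace` implements the whole pipeline as a self-contained toolkit:

- **GTR+Γ model** — rate matrix `Q` (normalized so branch lengths are
  expected substitutions/site), stationary frequencies π, discrete-Gamma
  rate categories (equal-probability slice means), transition probabilities
  `P(t) = exp(Qt)` via the reversible eigendecomposition.
- **Likelihood engine** — Felsenstein pruning with per-site underflow
  scaling, two-directional (post-order + pre-order) conditional likelihood
  caches so any edge can be scored in O(sites), branch-length optimization
  by per-edge Brent searches, and numeric-parameter estimation
  (empirical base frequencies, exchangeabilities, Γ shape) on a fixed
  topology.
- **Placement** — per-edge coordinate ascent over the attachment geometry:
  the distal offset `x ∈ [0, edge length]` (measured from the child end)
  and the pendant branch length `p`; the reported `like_weight_ratio` is
  the softmax weight of the winning edge among all per-edge optimized
  log-likelihoods.
- **SCAMPP layer** — nearest leaf by normalized Hamming distance
  (p-distance over mutually non-gap columns), extraction of the `B`-leaf
  placement subtree (default `B = 2000`) with a segment mapping that
  records how each compressed subtree edge subdivides into backbone edges,
  and exact back-mapping of the subtree placement.
- **Evaluation** — non-trivial bipartitions, missing-branch (FN) counts,
  **delta error** (the increase in missing branches caused by adding the
  query; always ≥ 0), leave-one-out experiments, and the fragmentary-query
  protocols that cut queries to read-like lengths
  (`N(0.25·lo, 60 bp)` low, `N(0.10·lo, 10 bp)` high, for original
  ungapped length `lo`).
- **Synthetic data** — Yule trees rescaled to a target mean root-to-tip
  height and GTR+Γ sequence simulation, so every stage is testable without
  external datasets.

File formats: FASTA alignments, Newick trees, jplace v3 placement files
(with the pplacer-style five-field layout), and a small JSON model-parameter
file.

## Worked example

Simulate a 50-leaf backbone, hold one leaf out, and place it back:

```r
library(phyplace)
set.seed(1)

model <- gtr_gamma_model(c(1.2, 3, 0.8, 1.1, 3.5, 1),
                         c(0.3, 0.2, 0.2, 0.3), alpha = 1)
tree  <- simulate_tree(50)                      # Yule, mean height 0.5
aln   <- simulate_alignment(tree, model, 1000)  # GTR+Gamma, no indels

query    <- "t7"
backbone <- assign_edge_numbers(ape::drop.tip(tree, query))

pl <- place_query(backbone, model, aln, query)
pl
#> Placement of 't7': edge 32, distal 0.0328818, pendant 0.0347632, logL -26586.9455, LWR 1.0000
```

The query attaches to backbone edge 32 at distal offset 0.033 (from the
edge's leafward end) with a pendant branch of 0.035 substitutions/site; the
likelihood weight ratio 1.00 says this edge carries essentially all of the
softmax weight over candidate edges. The same placement through the
divide-and-conquer route, restricted to the 20 leaves nearest the query:

```r
scampp_place(query, backbone, model, aln, config = scampp_config(B = 20))
#> Placement of 't7': edge 32, distal 0.0332684, pendant 0.032676, logL -11558.6273, LWR 1.0000
```

Same edge and near-identical geometry; the log-likelihood is smaller in
magnitude because it is evaluated on the 20-leaf subtree. Scoring the
placement against the
true tree:

```r
placed <- phyplace:::attach_query_to_tree(backbone, query, pl$edge_number,
                                          pl$distal_length, pl$pendant_length)
delta_error(tree, backbone, placed, query)$delta
#> [1] 0
```

A delta error of 0 means adding the query introduced no new missing
branches relative to the true tree. `leave_one_out_experiment()` automates
this over many queries and reports the mean delta error with its standard
error; `write_jplace()` writes placements to a jplace file.

A command-line wrapper is installed with the package
(`exec/phyplace` in the source tree):

```sh
phyplace simulate --leaves 50 --sites 1000 --seed 7 --output sim
phyplace eval-loo --tree sim.nwk --alignment sim.fasta \
    --model sim.model.json --n-queries 20 --seed 7 --output loo.tsv
```

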