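#' Non-trivial bipartitions of a tree
#'
#' Every internal edge of an unrooted tree splits the leaf set in two; this
#' returns those splits, canonicalized as the side not containing the
#' lexicographically smallest label (sorted, pasted with `|`). Trivial
#' splits (singleton or full set) are excluded, and the two rooted edges
#' incident to a degree-2 root contribute the same unrooted split once.
#'
#' @param tree A `"phylo"` tree.
#' @param leaf_universe Optional label set; when given, the tree is first
#'   restricted to it. Defaults to the tree's own leaves.
#' @return Character vector (a set) of canonical split keys.
#' @export
bipartitions <- function(tree, leaf_universe = NULL) {
  if (!is.null(leaf_universe)) {
    tree <- restrict_to_leaves(tree, intersect(tree$tip.label, leaf_universe))
  }
  n <- length(tree$tip.label)
  if (n < 4L) return(character(0))
  universe <- tree$tip.label
  smallest <- min_label(universe)
  kids <- children_list(tree)
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- tree$tip.label[i]
  splits <- character(0)
  for (v in postorder_nodes(tree)) {
    if (v <= n) next
    below[[v]] <- unlist(below[kids[[v]]], use.names = FALSE)
    if (v == n + 1L) next  # root has no edge
    size <- length(below[[v]])
    if (size < 2L || size > n - 2L) next
    side <- below[[v]]
    if (smallest %in% side) side <- setdiff(universe, side)
    splits <- c(splits, paste(side[order(side, method = "radix")],
                              collapse = "|"))
  }
  unique(splits)
}

#' Missing-branch (false negative) count
#'
#' Number of non-trivial bipartitions of the reference tree absent from the
#' estimated tree, after restricting the reference to the estimated tree's
#' leaf set (suppressing degree-2 nodes). This is the FN half of the
#' Robinson-Foulds comparison.
#'
#' @param reference Reference `"phylo"` tree (may contain extra leaves).
#' @param estimated Estimated `"phylo"` tree.
#' @return Integer count of missing branches.
#' @export
fn_missing_branches <- function(reference, estimated) {
  extra <- setdiff(estimated$tip.label, reference$tip.label)
  if (length(extra) > 0L) {
    stop("estimated tree has leaves not in the reference: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  ref <- restrict_to_leaves(reference, estimated$tip.label)
  if (!setequal(ref$tip.label, estimated$tip.label)) {
    stop("leaf sets differ after restriction")  # nocov
  }
  length(setdiff(bipartitions(ref), bipartitions(estimated)))
}

#' Delta error of one placement
#'
#' The increase in the number of missing branches incurred by placing the
#' query into the backbone: `FN(reference restricted to backbone leaves +
#' query, placed) - FN(reference restricted to backbone leaves, backbone)`.
#' Always non-negative, and zero when the query is placed on the edge its
#' reference position induces.
#'
#' @param reference_with_query Reference tree containing the backbone
#'   leaves and the query.
#' @param backbone Backbone tree (without the query).
#' @param placed Backbone tree with the query attached on one edge.
#' @param query_name The query leaf label.
#' @return List with `fn_before`, `fn_after`, and `delta` (integer `>= 0`).
#' @export
delta_error <- function(reference_with_query, backbone, placed, query_name) {
  if (!query_name %in% reference_with_query$tip.label) {
    stop("query '", query_name, "' missing from the reference tree")
  }
  if (!query_name %in% placed$tip.label) {
    stop("query '", query_name, "' missing from the placed tree")
  }
  fn_before <- fn_missing_branches(reference_with_query, backbone)
  fn_after <- fn_missing_branches(reference_with_query, placed)
  list(fn_before = fn_before, fn_after = fn_after,
       delta = fn_after - fn_before)
}

# ---- fragmentary-query protocol --------------------------------------------

#' Fragmentary-query protocols
#'
#' The two read-length protocols used to cut full-length queries into
#' fragments: the fragment length is drawn from a normal distribution whose
#' mean is a fraction of the query's original (ungapped) length `lo` --
#' `N(0.25 * lo, 60 bp)` for the low-fragmentary protocol and
#' `N(0.10 * lo, 10 bp)` for the high-fragmentary protocol -- rounded to
#' the nearest integer and clamped to `[1, lo]`. The starting position is
#' drawn from a centered normal `N((lo - L) / 2, sigma)`, clamped so the
#' fragment stays within the sequence.
#'
#' @param level `"low"` (fraction 0.25, sigma 60) or `"high"` (fraction
#'   0.10, sigma 10).
#' @param fraction,sigma Override the protocol parameters directly.
#' @return A `fragment_protocol` object.
#' @export
fragment_protocol <- function(level = c("low", "high"), fraction = NULL,
                              sigma = NULL) {
  level <- match.arg(level)
  defaults <- list(low = list(fraction = 0.25, sigma = 60),
                   high = list(fraction = 0.10, sigma = 10))[[level]]
  if (is.null(fraction)) fraction <- defaults$fraction
  if (is.null(sigma)) sigma <- defaults$sigma
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(level = level, fraction = fraction, sigma = sigma),
            class = "fragment_protocol")
}

#' Sample clamped fragment lengths
#'
#' Draws `n` fragment lengths for an original length `lo` under a protocol:
#' `round(rnorm(n, fraction * lo, sigma))` clamped to `[1, lo]`. Uses R's
#' global random number generator (seed with [set.seed()]).
#'
#' @param n Number of draws.
#' @param lo Original (ungapped) sequence length.
#' @param protocol A [fragment_protocol()].
#' @return Integer vector of lengths.
#' @export
sample_fragment_lengths <- function(n, lo, protocol = fragment_protocol("low")) {
  stopifnot(inherits(protocol, "fragment_protocol"), lo >= 1)
  len <- round(stats::rnorm(n, mean = protocol$fraction * lo,
                            sd = protocol$sigma))
  pmin(pmax(len, 1), lo)
}

#' Cut a fragment from an ungapped sequence
#'
#' Samples a fragment length and a (normally distributed, centered) start
#' position, and returns the contiguous substring. Clamping absorbs
#' extreme draws, so this never fails.
#'
#' @param sequence Ungapped sequence string (`lo = nchar(sequence) >= 1`).
#' @param protocol A [fragment_protocol()].
#' @return List with `fragment` (string), `start` (1-based), `length`.
#' @export
make_fragment <- function(sequence, protocol = fragment_protocol("low")) {
  lo <- nchar(sequence)
  stopifnot(lo >= 1)
  len <- sample_fragment_lengths(1L, lo, protocol)
  start0 <- round(stats::rnorm(1, mean = (lo - len) / 2, sd = protocol$sigma))
  start0 <- min(max(start0, 0), lo - len)
  list(fragment = substr(sequence, start0 + 1L, start0 + len),
       start = start0 + 1L, length = len)
}

#' Cut a fragment in aligned coordinates
#'
#' Applies [make_fragment()] to the ungapped content of an aligned row and
#' re-expresses the result in the alignment's columns: columns outside the
#' fragment become gaps.
#'
#' @param row Aligned sequence string (may contain gaps).
#' @param protocol A [fragment_protocol()].
#' @return Aligned sequence string of the same width with the fragment's
#'   columns retained.
#' @export
fragment_aligned_row <- function(row, protocol = fragment_protocol("low")) {
  chars <- strsplit(row, "")[[1]]
  pos <- which(chars != "-")
  if (length(pos) == 0L) stop("cannot fragment an all-gap row")
  frag <- make_fragment(paste(chars[pos], collapse = ""), protocol)
  keep <- pos[seq.int(frag$start, frag$start + frag$length - 1L)]
  out <- rep("-", length(chars))
  out[keep] <- chars[keep]
  paste(out, collapse = "")
}

# ---- leave-one-out experiments ---------------------------------------------

#' Leave-one-out placement experiment
#'
#' Samples `n_queries` leaves without replacement; for each, prunes the
#' leaf from the tree (suppressing the degree-2 node and summing branch
#' lengths), optionally cuts the query to a fragmentary protocol, places it
#' back with the chosen method, and computes the delta error against the
#' original tree as reference. Model parameters are supplied by the caller
#' and reused across queries (the backbone's numeric parameters).
#'
#' @param tree Edge-numbered backbone `"phylo"` tree (also the reference).
#' @param alignment Alignment covering all leaves.
#' @param model A [gtr_gamma_model()].
#' @param method `"full"` (placement on every backbone edge) or `"scampp"`
#'   (divide-and-conquer placement with subtree size `B`).
#' @param B Placement subtree size when `method = "scampp"`.
#' @param n_queries Number of leaves to hold out (default 200, capped at
#'   the leaf count).
#' @param seed Optional integer seed for query sampling and fragment draws.
#' @param protocol Optional [fragment_protocol()]; `NULL` places the
#'   full-length query.
#' @param optimize_iters,tol Passed to [place_query()].
#' @return A `delta_error_report`: data frame of per-query records
#'   (`query_name`, `fn_before`, `fn_after`, `delta`, `edge_number`,
#'   `log_likelihood`) with `mean_delta` and `se_delta` attributes.
#' @export
leave_one_out_experiment <- function(tree, alignment, model,
                                     method = c("full", "scampp"),
                                     B = 2000L, n_queries = 200L,
                                     seed = NULL, protocol = NULL,
                                     optimize_iters = 5L, tol = 1e-4) {
  method <- match.arg(method)
  tree <- require_edge_numbers(tree)
  n <- length(tree$tip.label)
  if (n_queries > n) stop("n_queries exceeds the number of leaves")
  if (n <= 4L) stop("tree too small for leave-one-out (need > 4 leaves)")
  if (!is.null(seed)) set.seed(seed)
  queries <- sample(tree$tip.label, n_queries)
  records <- vector("list", n_queries)
  for (i in seq_along(queries)) {
    q <- queries[i]
    backbone <- prune_leaf(tree, q)
    qrow <- get_row(alignment, q)
    if (!is.null(protocol)) qrow <- fragment_aligned_row(qrow, protocol)
    aln_q <- alignment
    aln_q$seqs[[q]] <- qrow
    pl <- if (method == "full") {
      place_query(backbone, model, aln_q, q,
                  optimize_iters = optimize_iters, tol = tol)
    } else {
      scampp_place(q, backbone, model, aln_q, config = scampp_config(B),
                   optimize_iters = optimize_iters, tol = tol)
    }
    placed <- attach_query_to_tree(backbone, q, pl$edge_number,
                                   pl$distal_length, pl$pendant_length)
    de <- delta_error(tree, backbone, placed, q)
    records[[i]] <- data.frame(query_name = q, fn_before = de$fn_before,
                               fn_after = de$fn_after, delta = de$delta,
                               edge_number = pl$edge_number,
                               log_likelihood = pl$log_likelihood,
                               stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, records)
  class(report) <- c("delta_error_report", "data.frame")
  attr(report, "mean_delta") <- mean(report$delta)
  attr(report, "se_delta") <- stats::sd(report$delta) / sqrt(nrow(report))
  attr(report, "method") <- if (method == "scampp") paste0("scampp(B=", B, ")") else "full"
  report
}

#' @export
print.delta_error_report <- function(x, ...) {
  cat("Leave-one-out delta-error report (", attr(x, "method"), "): ",
      nrow(x), " queries\n", sep = "")
  cat(sprintf("  mean delta error: %.4f +/- %.4f (SE)\n",
              attr(x, "mean_delta"), attr(x, "se_delta")))
  NextMethod()
}

# ---- synthetic data ---------------------------------------------------------

#' Simulate a Yule backbone tree
#'
#' Draws a pure-birth (Yule) tree and rescales branch lengths so the mean
#' root-to-tip path equals `height` expected substitutions per site
#' (default 0.5, a moderately diverged backbone). Uses R's global RNG.
#'
#' @param n_leaves Number of leaves (`>= 4`). Leaves are labeled
#'   `t1..tn`.
#' @param birth_rate Yule birth rate (default 1; affects only the shape of
#'   node depths before rescaling).
#' @param height Target mean root-to-tip path length.
#' @return An edge-numbered `"phylo"` tree.
#' @export
simulate_tree <- function(n_leaves, birth_rate = 1, height = 0.5) {
  if (n_leaves < 4L) stop("n_leaves must be >= 4")
  tree <- ape::rphylo(n_leaves, birth = birth_rate, death = 0)
  depths <- ape::node.depth.edgelength(tree)[seq_len(n_leaves)]
  tree$edge.length <- tree$edge.length * (height / mean(depths))
  assign_edge_numbers(tree)
}

#' Simulate sequences along a tree
#'
#' Evolves ungapped DNA down the tree under the model: root states are
#' drawn from the stationary frequencies, each site is assigned one Gamma
#' rate category, and states mutate along each branch with the transition
#' probabilities `P(t * rate)`. No indels are introduced.
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @param model A [gtr_gamma_model()].
#' @param n_sites Number of alignment columns (`>= 1`).
#' @return An [aligned_seqs()] with one row per leaf.
#' @export
simulate_alignment <- function(tree, model, n_sites) {
  stopifnot(inherits(model, "gtr_gamma"), n_sites >= 1)
  n <- length(tree$tip.label)
  n_all <- n + tree$Nnode
  root <- n + 1L
  cat_of_site <- sample.int(model$n_categories, n_sites, replace = TRUE)
  states <- matrix(NA_integer_, nrow = n_all, ncol = n_sites)
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE, prob = model$pi)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; v <- tr$edge[i, 2L]; t <- tr$edge.length[i]
    for (c in seq_len(model$n_categories)) {
      sites <- which(cat_of_site == c)
      if (length(sites) == 0L) next
      P <- transition_matrix(model, t, model$rates[c])
      ps <- states[p, sites]
      for (s in 1:4) {
        idx <- sites[ps == s]
        if (length(idx) > 0L) {
          states[v, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                       prob = P[s, ])
        }
      }
    }
  }
  seqs <- apply(states[seq_len(n), , drop = FALSE], 1L,
                function(z) paste(DNA_STATES[z], collapse = ""))
  names(seqs) <- tree$tip.label
  aligned_seqs(seqs)
}

#' Simulate a complete placement instance
#'
#' Convenience generator for tests and examples: a Yule tree plus a
#' GTR+Gamma alignment simulated on it.
#'
#' @inheritParams simulate_tree
#' @inheritParams simulate_alignment
#' @param model Model to simulate under (default: a moderately skewed GTR
#'   with Gamma shape 1).
#' @return List with `tree`, `alignment`, `model`.
#' @export
simulate_instance <- function(n_leaves, n_sites, model = NULL,
                              birth_rate = 1, height = 0.5) {
  if (is.null(model)) {
    model <- gtr_gamma_model(c(1.2, 3, 0.8, 1.1, 3.5, 1),
                             c(0.3, 0.2, 0.2, 0.3), alpha = 1)
  }
  tree <- simulate_tree(n_leaves, birth_rate, height)
  aln <- simulate_alignment(tree, model, n_sites)
  list(tree = tree, alignment = aln, model = model)
}
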