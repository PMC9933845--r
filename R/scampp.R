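#' SCAMPP configuration
#'
#' Parameters of the divide-and-conquer placement layer: the placement
#' subtree size `B` (number of leaves retained around the query's nearest
#' leaf; default 2000) and the distance used to select those leaves
#' (branch-length path distance by default, or topological edge count).
#'
#' @param B Placement subtree size, `>= 3` (default 2000).
#' @param distance_mode `"branch_length"` (path distance in expected
#'   substitutions/site) or `"topological"` (edge count).
#' @return A `scampp_config` object.
#' @export
scampp_config <- function(B = 2000L, distance_mode = c("branch_length",
                                                       "topological")) {
  B <- as.integer(B)
  if (is.na(B) || B < 3L) stop("B must be >= 3")
  structure(list(B = B, distance_mode = match.arg(distance_mode)),
            class = "scampp_config")
}

#' Nearest backbone leaf by normalized Hamming distance
#'
#' Returns the leaf minimizing the p-distance to the query: mismatches
#' divided by compared sites, comparing only columns where both sequences
#' are non-gap (so fragmentary queries are not dominated by their gap
#' count). Pairs with zero comparable columns score 1. Ties are broken
#' toward the lexicographically smaller label.
#'
#' @param query_row Aligned query sequence string (backbone column space).
#' @param alignment An [aligned_seqs()] with the leaf rows.
#' @param leaf_labels Candidate leaf labels.
#' @return The selected leaf label.
#' @export
hamming_nearest_leaf <- function(query_row, alignment, leaf_labels) {
  if (length(leaf_labels) == 0L) stop("empty leaf set")
  qv <- strsplit(toupper(query_row), "")[[1]]
  if (length(qv) != alignment$L) {
    stop("query length does not match alignment width")
  }
  m <- alignment_matrix(subset_alignment(alignment, leaf_labels))
  qmat <- matrix(qv, nrow = nrow(m), ncol = alignment$L, byrow = TRUE)
  both <- (m != "-") & (qmat != "-")
  comp <- rowSums(both)
  mism <- rowSums((m != qmat) & both)
  d <- ifelse(comp == 0, 1, mism / comp)
  ord <- order(d, leaf_labels, method = "radix")
  leaf_labels[ord[1L]]
}

#' Extract a placement subtree around a seed leaf
#'
#' Selects the `min(B, n)` leaves closest to `seed_leaf` (single-source
#' path distances on the tree; ties broken by label), restricts the
#' backbone to those leaves, and suppresses the resulting degree-2 nodes by
#' summing branch lengths. The returned mapping records, for every subtree
#' edge, the ordered backbone edge segments it compresses (from the child
#' end to the parent end), which is what allows a placement inside the
#' subtree to be mapped back onto the backbone. With `B >= n` the subtree
#' is identical to the backbone and every segment list is a singleton.
#'
#' @param tree Edge-numbered backbone `"phylo"` tree.
#' @param seed_leaf Label of the leaf to grow the subtree around.
#' @param B Number of leaves to retain (`>= 3`).
#' @param distance_mode See [scampp_config()].
#' @return List with `subtree` (edge-numbered `"phylo"`) and `mapping`
#'   (a `subtree_mapping`).
#' @export
extract_placement_subtree <- function(tree, seed_leaf, B,
                                      distance_mode = c("branch_length",
                                                        "topological")) {
  tree <- require_edge_numbers(tree)
  distance_mode <- match.arg(distance_mode)
  n <- length(tree$tip.label)
  if (!seed_leaf %in% tree$tip.label) {
    stop("seed leaf '", seed_leaf, "' not in tree")
  }
  B <- as.integer(B)
  if (B < 3L) stop("B must be >= 3")

  dtree <- tree
  if (distance_mode == "topological") {
    dtree$edge.length <- rep(1, nrow(tree$edge))
  }
  d <- node_path_distances(dtree, seed_leaf)[seq_len(n)]
  ord <- order(d, tree$tip.label, method = "radix")
  kept_labels <- tree$tip.label[ord[seq_len(min(B, n))]]
  kept_ids <- match(kept_labels, tree$tip.label)

  n_all <- n + tree$Nnode
  kids <- children_list(tree)
  par <- parent_vec(tree)
  bl <- length_above(tree)
  enum <- integer(n_all)
  enum[tree$edge[, 2L]] <- tree$edge_number

  cnt <- integer(n_all)
  cnt[kept_ids] <- 1L
  po <- postorder_nodes(tree)
  for (v in po) {
    if (v > n) cnt[v] <- sum(cnt[kids[[v]]])
  }
  retained <- logical(n_all)
  retained[kept_ids] <- TRUE
  for (v in seq.int(n + 1L, n_all)) {
    retained[v] <- sum(cnt[kids[[v]]] > 0L) >= 2L
  }

  # parent-in-restriction and compressed edge segments, walking rootward
  ret_nodes <- which(retained)
  sub_parent <- integer(n_all)   # 0 = restriction root
  seg_list <- vector("list", n_all)
  for (v in ret_nodes) {
    w <- v
    edges <- integer(0)
    lens <- numeric(0)
    repeat {
      p <- par[w]
      if (p == 0L) { sub_parent[v] <- 0L; break }  # reached backbone root
      edges <- c(edges, enum[w])
      lens <- c(lens, bl[w])
      if (retained[p]) { sub_parent[v] <- p; break }
      w <- p
    }
    if (sub_parent[v] > 0L) {
      seg_list[[v]] <- data.frame(edge_number = edges, length = lens)
    }
  }
  # exactly one retained node has no retained ancestor: the restriction root
  roots <- ret_nodes[sub_parent[ret_nodes] == 0L]
  stopifnot(length(roots) == 1L)
  sub_root <- roots

  # build the subtree phylo: tips first (backbone tip-id order), root next
  ret_tips <- ret_nodes[ret_nodes <= n]
  ret_ints <- c(sub_root, setdiff(ret_nodes[ret_nodes > n], sub_root))
  m <- length(ret_tips)
  subid <- integer(n_all)
  subid[ret_tips] <- seq_len(m)
  subid[ret_ints] <- m + seq_along(ret_ints)
  nonroot <- setdiff(ret_nodes, sub_root)
  edge_mat <- cbind(subid[sub_parent[nonroot]], subid[nonroot])
  edge_len <- vapply(nonroot, function(v) sum(seg_list[[v]]$length), numeric(1))
  subtree <- structure(list(edge = edge_mat, edge.length = edge_len,
                            tip.label = tree$tip.label[ret_tips],
                            Nnode = length(ret_ints)),
                       class = "phylo")
  subtree <- ape::reorder.phylo(subtree, "cladewise")
  subtree <- assign_edge_numbers(subtree)

  # key segment lists by the subtree's canonical edge numbers
  sub_enum <- integer(m + length(ret_ints))
  sub_enum[subtree$edge[, 2L]] <- subtree$edge_number
  segments <- stats::setNames(
    lapply(nonroot, function(v) seg_list[[v]]),
    as.character(sub_enum[subid[nonroot]]))

  mapping <- structure(list(leaf_set = kept_labels, segments = segments),
                       class = "subtree_mapping")
  list(subtree = subtree, mapping = mapping)
}

#' @export
print.subtree_mapping <- function(x, ...) {
  nseg <- vapply(x$segments, nrow, integer(1))
  cat("Subtree mapping: ", length(x$leaf_set), " leaves, ",
      length(x$segments), " subtree edges compressing ", sum(nseg),
      " backbone edges\n", sep = "")
  invisible(x)
}

#' Map a subtree placement back onto the backbone
#'
#' Walks the compressed edge's backbone segments from the child end,
#' accumulating length until the subtree `distal_length` is reached, and
#' emits the containing backbone edge with the residual as the backbone
#' `distal_length`. Pendant length and log-likelihood carry over unchanged.
#' A distal point falling exactly on a segment boundary is assigned to the
#' more parentward (rootward) segment with `distal_length` 0.
#'
#' @param subtree_placement A [placement()] on the subtree.
#' @param mapping The `subtree_mapping` from [extract_placement_subtree()].
#' @return A [placement()] on the backbone.
#' @export
map_placement_to_backbone <- function(subtree_placement, mapping) {
  stopifnot(inherits(subtree_placement, "placement"),
            inherits(mapping, "subtree_mapping"))
  segs <- mapping$segments[[as.character(subtree_placement$edge_number)]]
  if (is.null(segs)) {
    stop("subtree edge ", subtree_placement$edge_number, " not in mapping")
  }
  total <- sum(segs$length)
  rem <- subtree_placement$distal_length
  if (rem > total + 1e-9) {
    stop("distal length ", rem, " exceeds compressed edge length ", total)
  }
  rem <- min(rem, total)
  nseg <- nrow(segs)
  for (i in seq_len(nseg)) {
    li <- segs$length[i]
    if (rem <= li - 1e-9) {
      return(remap_placement(subtree_placement, segs$edge_number[i], rem))
    }
    if (rem <= li + 1e-9) {
      if (i == nseg) {
        return(remap_placement(subtree_placement, segs$edge_number[i], li))
      }
      rem <- 0
    } else {
      rem <- rem - li
    }
  }
  stop("internal error: distal walk did not terminate")  # nocov
}

remap_placement <- function(pl, edge_number, distal) {
  placement(query_name = pl$query_name, edge_number = edge_number,
            distal_length = distal, pendant_length = pl$pendant_length,
            log_likelihood = pl$log_likelihood,
            like_weight_ratio = pl$like_weight_ratio)
}

#' Divide-and-conquer placement of one query
#'
#' The full SCAMPP pipeline for a single query: find the nearest backbone
#' leaf by normalized Hamming distance, extract the placement subtree of
#' size `B` around it, run maximum-likelihood placement within the subtree
#' (reusing the backbone's model parameters without re-estimation), and map
#' the chosen edge and its branch subdivision back onto the backbone. With
#' `B >= n` this reduces exactly to [place_query()] on the full backbone.
#'
#' @inheritParams place_query
#' @param config A [scampp_config()].
#' @return A [placement()] on the backbone tree.
#' @export
scampp_place <- function(query_name, tree, model, alignment,
                         config = scampp_config(), optimize_iters = 5L,
                         tol = 1e-4) {
  tree <- require_edge_numbers(tree)
  if (query_name %in% tree$tip.label) {
    stop("query '", query_name, "' is already a backbone leaf")
  }
  qrow <- get_row(alignment, query_name)
  seed <- hamming_nearest_leaf(qrow, alignment, tree$tip.label)
  ext <- extract_placement_subtree(tree, seed, config$B,
                                   distance_mode = config$distance_mode)
  subpl <- place_query(ext$subtree, model, alignment, query_name,
                       optimize_iters = optimize_iters, tol = tol)
  map_placement_to_backbone(subpl, ext$mapping)
}
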