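#' Read a Newick tree
#'
#' Reads a phylogeny from a Newick file into an [ape::read.tree()] `"phylo"`
#' object, validates it (unique leaf labels, finite non-negative branch
#' lengths), replaces missing branch lengths with 0 (with a warning), and
#' assigns canonical edge numbers (see [assign_edge_numbers()]).
#'
#' @param path Path to a Newick file.
#' @return A `"phylo"` object carrying an `edge_number` component: one
#'   integer per row of `tree$edge`, numbering edges `0..E-1`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  read_newick_text(txt)
}

read_newick_text <- function(txt) {
  check_balanced_parens(txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("Newick parse error")
  validate_tree(tree)
}

check_balanced_parens <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("Newick parse error: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of input")
  }
  invisible(TRUE)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; setting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths read as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0")
  }
  assign_edge_numbers(tree)
}

#' Write a Newick tree
#'
#' @param tree A `"phylo"` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 17)
  invisible(path)
}

#' Assign canonical edge numbers
#'
#' Numbers the `E` edges of the tree `0..E-1` by a canonical post-order
#' traversal in which the children of every node are visited in
#' lexicographic (byte) order of their smallest descendant leaf label. The
#' numbering is therefore a deterministic function of the labeled topology
#' and is invariant to the child ordering of the input file, which makes
#' jplace edge references stable across serializations.
#'
#' @param tree A `"phylo"` object.
#' @return The tree with an `edge_number` integer vector parallel to the
#'   rows of `tree$edge`.
#' @export
assign_edge_numbers <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- children_list(tree)
  # smallest descendant leaf label per node, computed children-first
  small <- character(n + tree$Nnode)
  small[seq_len(n)] <- tree$tip.label
  for (v in postorder_nodes(tree)) {
    if (v > n) small[v] <- min_label(small[kids[[v]]])
  }
  # iterative DFS avoids deep recursion on large trees
  number_of_child <- iterative_canonical_postorder(tree, kids, small)
  tree$edge_number <- unname(number_of_child[tree$edge[, 2L]] - 1L)
  tree
}

iterative_canonical_postorder <- function(tree, kids, small) {
  n <- length(tree$tip.label)
  root <- n + 1L
  number_of_child <- integer(n + tree$Nnode)
  counter <- 0L
  # stack of (node, next-child index); children pre-sorted
  sorted_kids <- kids
  for (v in seq.int(n + 1L, n + tree$Nnode)) {
    ch <- kids[[v]]
    sorted_kids[[v]] <- ch[order(small[ch], method = "radix")]
  }
  stack <- integer(0)
  state <- integer(n + tree$Nnode)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    if (v <= n || state[v] >= length(sorted_kids[[v]])) {
      # finished: assign number to v's edge
      stack <- stack[-length(stack)]
      if (v != root) {
        number_of_child[v] <- counter + 1L
        counter <- counter + 1L
      }
    } else {
      state[v] <- state[v] + 1L
      stack <- c(stack, sorted_kids[[v]][state[v]])
    }
  }
  number_of_child
}

min_label <- function(x) x[order(x, method = "radix")][1L]

# ---- traversal helpers ------------------------------------------------------

children_list <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  kids
}

parent_vec <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  par <- integer(n_all)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

# branch length of the edge above each node (0 for the root)
length_above <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  bl <- numeric(n_all)
  bl[tree$edge[, 2L]] <- tree$edge.length
  bl
}

# nodes in postorder (children before parents), tips included, root last
postorder_nodes <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  c(tr$edge[, 2L], length(tree$tip.label) + 1L)
}

# edge row index by child node id
edge_row_of_child <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  idx <- integer(n_all)
  idx[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  idx
}

# child node id for a given canonical edge number
child_of_edge_number <- function(tree, edge_number) {
  i <- match(edge_number, tree$edge_number)
  if (is.na(i)) stop("edge number ", edge_number, " not in tree")
  tree$edge[i, 2L]
}

require_edge_numbers <- function(tree) {
  if (is.null(tree$edge_number)) tree <- assign_edge_numbers(tree)
  tree
}

# ---- tree surgery -----------------------------------------------------------

# Attach a query tip onto edge `edge_number` at `distal` from the child end
# with a pendant branch of length `pendant`. Returns a new phylo (edge
# numbers are NOT carried over; renumber if needed).
attach_query_to_tree <- function(tree, query_name, edge_number, distal, pendant) {
  tree <- require_edge_numbers(tree)
  n <- length(tree$tip.label)
  row <- match(edge_number, tree$edge_number)
  if (is.na(row)) stop("edge number ", edge_number, " not in tree")
  b <- tree$edge.length[row]
  if (distal < -1e-9 || distal > b + 1e-9) {
    stop("distal length ", distal, " outside edge of length ", b)
  }
  distal <- min(max(distal, 0), b)
  if (query_name %in% tree$tip.label) {
    stop("query '", query_name, "' is already a leaf of the tree")
  }
  # Re-index: tips 1..n stay, new query tip = n+1, internal j -> j+1,
  # new attachment node = n + Nnode + 2.
  old_edge <- tree$edge
  shift <- function(v) ifelse(v > n, v + 1L, v)
  e1 <- shift(old_edge[, 1L])
  e2 <- shift(old_edge[, 2L])
  p <- e1[row]; v <- e2[row]
  u <- n + tree$Nnode + 2L
  q <- n + 1L
  new_edge <- rbind(
    cbind(e1[-row], e2[-row]),
    c(p, u), c(u, v), c(u, q))
  new_len <- c(tree$edge.length[-row], b - distal, distal, pendant)
  out <- list(edge = new_edge, edge.length = new_len,
              tip.label = c(tree$tip.label, query_name),
              Nnode = tree$Nnode + 1L)
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  out <- ape::reorder.phylo(out, "cladewise")
  out
}

# Drop one leaf, suppressing the resulting degree-2 node and summing the two
# merged branch lengths (ape::drop.tip does exactly this).
prune_leaf <- function(tree, label) {
  if (!label %in% tree$tip.label) stop("leaf '", label, "' not in tree")
  if (length(tree$tip.label) <= 4L) stop("cannot prune below 4 leaves")
  out <- ape::drop.tip(tree, label, collapse.singles = TRUE)
  assign_edge_numbers(out)
}

# Restrict a tree to a leaf set (topology-only use: bipartition comparison).
restrict_to_leaves <- function(tree, labels) {
  drop <- setdiff(tree$tip.label, labels)
  if (length(setdiff(labels, tree$tip.label)) > 0L) {
    stop("labels not in tree: ",
         paste(setdiff(labels, tree$tip.label), collapse = ", "))
  }
  if (length(drop) == 0L) return(tree)
  ape::keep.tip(tree, labels)
}

# Single-source path distances (sum of branch lengths) from one leaf to all
# nodes, via DFS over the undirected adjacency. O(n).
node_path_distances <- function(tree, from_leaf) {
  n <- length(tree$tip.label)
  n_all <- n + tree$Nnode
  src <- match(from_leaf, tree$tip.label)
  if (is.na(src)) stop("leaf '", from_leaf, "' not in tree")
  adj <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1L]; b <- tree$edge[i, 2L]; w <- tree$edge.length[i]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist <- rep(NA_real_, n_all)
  dist[src] <- 0
  stack <- src
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    nb <- adj[[v]]
    for (j in seq_len(NROW(nb))) {
      w <- nb[j, 1L]
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + nb[j, 2L]
        stack <- c(stack, w)
      }
    }
  }
  dist
}
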