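# Programmatic fixtures: everything is generated in code at test time.

# Random GTR+Gamma model with moderate parameter ranges.
random_model <- function(n_categories = sample(1:4, 1)) {
  x <- stats::runif(4, 0.5, 2)
  gtr_gamma_model(stats::runif(6, 0.3, 3), x / sum(x),
                  alpha = stats::runif(1, 0.3, 3),
                  n_categories = n_categories)
}

# Random rooted binary tree with uniform branch lengths and canonical edge
# numbers.
random_tree <- function(n, min_bl = 0.02, max_bl = 0.6) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, min_bl, max_bl))
  assign_edge_numbers(tr)
}

# Random alignment over given labels; optionally sprinkles gaps/ambiguity.
random_alignment <- function(labels, L, gap_prob = 0) {
  chars <- c("A", "C", "G", "T")
  if (gap_prob > 0) chars <- c(chars, "-", "N")
  probs <- if (gap_prob > 0) {
    c(rep((1 - gap_prob) / 4, 4), gap_prob / 2, gap_prob / 2)
  } else rep(0.25, 4)
  seqs <- vapply(labels, function(l) {
    paste(sample(chars, L, replace = TRUE, prob = probs), collapse = "")
  }, "")
  aligned_seqs(seqs)
}

# Simulated instance plus one extra leaf held out as an aligned query.
instance_with_query <- function(n_leaves, n_sites, model = NULL) {
  inst <- simulate_instance(n_leaves + 1L, n_sites, model = model)
  q <- sample(inst$tree$tip.label, 1L)
  backbone <- phyplace:::prune_leaf(inst$tree, q)
  list(reference = inst$tree, backbone = backbone, query = q,
       alignment = inst$alignment, model = inst$model)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
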