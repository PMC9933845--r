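# Independent oracles used to validate the likelihood and evaluation
# machinery: brute-force enumeration over ancestral states with dense
# matrix exponentials (Matrix::expm), bipartitions via ape::prop.part, and
# a from-scratch jplace reparser.

# Brute-force GTR+Gamma tree log-likelihood: sums over every assignment of
# states to internal nodes, per site and per rate category. Exponential-
# time; only for tiny trees. Independent of the pruning/eigendecomposition
# code path.
oracle_loglik <- function(tree, model, aln) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  root <- n + 1L
  edges <- tree$edge
  lens <- tree$edge.length
  rows <- lapply(tree$tip.label, function(l) strsplit(aln$seqs[[l]], "")[[1]])
  states <- c("A", "C", "G", "T")
  allowed <- function(ch) {
    map <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                N = states, `-` = states, `?` = states)
    match(map[[ch]], states)
  }
  grid <- as.matrix(expand.grid(rep(list(1:4), m)))
  total <- 0
  for (site in seq_len(aln$L)) {
    site_like <- 0
    for (ci in seq_len(model$n_categories)) {
      r <- model$rates[ci]
      Ps <- lapply(seq_len(nrow(edges)), function(i) {
        as.matrix(Matrix::expm(model$Q * lens[i] * r))
      })
      cat_like <- 0
      for (g in seq_len(nrow(grid))) {
        st <- grid[g, ]
        state_of <- function(v) st[v - n]
        p <- model$pi[state_of(root)]
        for (i in seq_len(nrow(edges))) {
          pa <- state_of(edges[i, 1L])
          ch <- edges[i, 2L]
          p <- p * if (ch <= n) {
            sum(Ps[[i]][pa, allowed(rows[[ch]][site])])
          } else {
            Ps[[i]][pa, state_of(ch)]
          }
        }
        cat_like <- cat_like + p
      }
      site_like <- site_like + cat_like / model$n_categories
    }
    total <- total + log(site_like)
  }
  total
}

# Non-trivial splits via ape::prop.part (clade enumeration), canonicalized
# the same way as the package but through an independent code path.
oracle_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4L) return(character(0))
  smallest <- sort(tree$tip.label, method = "radix")[1L]
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (i in seq_along(parts)) {
    tips <- tree$tip.label[parts[[i]]]
    if (length(tips) < 2L || length(tips) > n - 2L) next
    side <- if (smallest %in% tips) setdiff(tree$tip.label, tips) else tips
    out <- c(out, paste(sort(side, method = "radix"), collapse = "|"))
  }
  unique(out)
}

# Second jplace parser: JSON via jsonlite plus a regex walk of the tree
# string; recovers tip label -> edge number and the placement rows.
reparse_jplace <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tstr <- doc$tree
  mm <- gregexpr("([A-Za-z0-9_.]+):([0-9.eE+-]+)\\{([0-9]+)\\}", tstr)[[1]]
  tips <- integer(0)
  for (i in seq_along(mm)) {
    frag <- substr(tstr, mm[i], mm[i] + attr(mm, "match.length")[i] - 1L)
    parts <- regmatches(frag,
                        regexec("([A-Za-z0-9_.]+):([0-9.eE+-]+)\\{([0-9]+)\\}",
                                frag))[[1]]
    tips[parts[2]] <- as.integer(parts[4])
  }
  rows <- lapply(doc$placements, function(entry) {
    p <- entry$p[[1]]
    data.frame(name = entry$nm[[1]][[1]],
               edge_num = as.integer(p[[1]]), likelihood = p[[2]],
               like_weight_ratio = p[[3]], distal_length = p[[4]],
               pendant_length = p[[5]], stringsAsFactors = FALSE)
  })
  list(version = doc$version, fields = unlist(doc$fields),
       tip_edges = tips, placements = do.call(rbind, rows))
}

# Canonical unrooted split of one edge (used for rooting-invariance checks).
edge_split <- function(tree, edge_number) {
  n <- length(tree$tip.label)
  i <- match(edge_number, tree$edge_number)
  v <- tree$edge[i, 2L]
  tips <- if (v <= n) tree$tip.label[v] else ape::extract.clade(tree, v)$tip.label
  smallest <- sort(tree$tip.label, method = "radix")[1L]
  side <- if (smallest %in% tips) setdiff(tree$tip.label, tips) else tips
  paste(sort(side, method = "radix"), collapse = "|")
}
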