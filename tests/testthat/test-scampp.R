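test_that("Hamming nearest leaf uses p-distance over mutually non-gap columns", {
  aln <- aligned_seqs(c(a = "ACGTAC", b = "ACGTAA", c = "TTTTTT"))
  expect_equal(hamming_nearest_leaf("ACGTAA", aln, c("a", "b", "c")), "b")
  # gap columns are excluded from the comparison
  aln2 <- aligned_seqs(c(a = "ACGT", b = "AGGT"))
  expect_equal(hamming_nearest_leaf("AC-T", aln2, c("a", "b")), "a")
  # equidistant leaves resolve to the lexicographically smaller label
  aln3 <- aligned_seqs(c(z = "AAAA", b = "AAAT", c = "AAAG"))
  expect_equal(hamming_nearest_leaf("AAAC", aln3, c("z", "b", "c")), "b")
  expect_error(hamming_nearest_leaf("AAAA", aln3, character(0)), "empty")
})

test_that("an all-gap overlap counts as maximally distant", {
  aln <- aligned_seqs(c(a = "AC--", b = "--GT"))
  # query overlaps only a: distance 0 to a, no comparable site with b
  expect_equal(hamming_nearest_leaf("AC--", aln, c("a", "b")), "a")
})

test_that("subtree extraction with B >= n is the identity with singleton mappings", {
  set.seed(501)
  tr <- random_tree(12)
  ext <- extract_placement_subtree(tr, tr$tip.label[1], 50)
  expect_setequal(ext$subtree$tip.label, tr$tip.label)
  key <- function(t) sort(vapply(seq_len(nrow(t$edge)), function(i) {
    paste0(edge_split(t, t$edge_number[i]), "=", t$edge_number[i], "@",
           round(t$edge.length[i], 12))
  }, ""))
  expect_identical(key(ext$subtree), key(tr))
  for (seg in ext$mapping$segments) expect_equal(nrow(seg), 1L)
})

test_that("subtree extraction compresses paths and conserves branch lengths", {
  ct <- phyplace:::read_newick_text("((a:1,b:1):1,(c:1,(d:1,e:1):1):1);")
  ex <- extract_placement_subtree(ct, "a", 3)
  expect_setequal(ex$subtree$tip.label, c("a", "b", "c"))
  nseg <- vapply(ex$mapping$segments, nrow, integer(1))
  expect_equal(sort(unname(nseg)), c(1L, 1L, 1L, 2L))
  # the compressed edge toward c sums its two backbone segments
  two <- ex$mapping$segments[[names(nseg)[nseg == 2L]]]
  child <- phyplace:::child_of_edge_number(ex$subtree,
                                           as.integer(names(nseg)[nseg == 2L]))
  expect_equal(ex$subtree$tip.label[child], "c")
  expect_equal(sum(two$length), 2)

  # conservation + uniqueness of backbone edges across all mappings
  set.seed(502)
  tr <- random_tree(100)
  for (B in c(10, 37, 80)) {
    ex <- extract_placement_subtree(tr, tr$tip.label[3], B)
    all_edges <- unlist(lapply(ex$mapping$segments, `[[`, "edge_number"))
    expect_equal(anyDuplicated(all_edges), 0L)
    for (enum in names(ex$mapping$segments)) {
      seg <- ex$mapping$segments[[enum]]
      i <- match(as.integer(enum), ex$subtree$edge_number)
      expect_equal(sum(seg$length), ex$subtree$edge.length[i],
                   tolerance = 1e-9)
    }
  }
})

test_that("selected leaf sets grow monotonically with B", {
  set.seed(503)
  tr <- random_tree(60)
  seed <- tr$tip.label[10]
  prev <- extract_placement_subtree(tr, seed, 5)$mapping$leaf_set
  for (B in c(10, 20, 40, 60)) {
    cur <- extract_placement_subtree(tr, seed, B)$mapping$leaf_set
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_error(extract_placement_subtree(tr, "nope", 10), "not in tree")
  expect_error(extract_placement_subtree(tr, seed, 2), ">= 3")
})

test_that("placements map back through compressed edges by segment walking", {
  mk <- function(segs) structure(list(leaf_set = character(0),
                                      segments = segs),
                                 class = "subtree_mapping")
  segs <- list(`0` = data.frame(edge_number = c(7L, 3L),
                                length = c(0.4, 0.6)))
  pl <- function(d) placement("q", 0L, d, 0.02, -10, 0.5)
  m1 <- map_placement_to_backbone(pl(0.5), mk(segs))
  expect_equal(m1$edge_number, 3L)
  expect_equal(m1$distal_length, 0.1, tolerance = 1e-12)
  expect_equal(m1$pendant_length, 0.02)
  expect_equal(m1$log_likelihood, -10)
  # exact boundary goes to the parentward segment with distal 0
  m2 <- map_placement_to_backbone(pl(0.4), mk(segs))
  expect_equal(m2$edge_number, 3L)
  expect_equal(m2$distal_length, 0)
  # the far end of the last segment stays on it
  m3 <- map_placement_to_backbone(pl(1.0), mk(segs))
  expect_equal(m3$edge_number, 3L)
  expect_equal(m3$distal_length, 0.6)
  expect_error(map_placement_to_backbone(pl(1.2), mk(segs)), "exceeds")
  expect_error(map_placement_to_backbone(placement("q", 5L, 0, 0, -1),
                                         mk(segs)), "not in mapping")
  # identity mapping passes the placement through unchanged
  ident <- mk(list(`4` = data.frame(edge_number = 9L, length = 0.3)))
  m4 <- map_placement_to_backbone(placement("q", 4L, 0.12, 0.05, -2, 0.8),
                                  ident)
  expect_equal(m4$edge_number, 9L)
  expect_equal(m4$distal_length, 0.12)
})

test_that("scampp with B >= n reduces exactly to full placement", {
  set.seed(504)
  for (rep in 1:3) {
    iq <- instance_with_query(15, 200)
    full <- place_query(iq$backbone, iq$model, iq$alignment, iq$query)
    sc <- scampp_place(iq$query, iq$backbone, iq$model, iq$alignment,
                       config = scampp_config(2000))
    expect_equal(sc$edge_number, full$edge_number)
    expect_lt(abs(sc$log_likelihood - full$log_likelihood), 1e-6)
    expect_equal(sc$distal_length, full$distal_length, tolerance = 1e-9)
  }
})

test_that("restricted scampp placement stays on valid backbone edges", {
  set.seed(505)
  inst <- simulate_instance(60, 200)
  for (rep in 1:5) {
    q <- sample(inst$tree$tip.label, 1)
    backbone <- phyplace:::prune_leaf(inst$tree, q)
    pl <- scampp_place(q, backbone, inst$model, inst$alignment,
                       config = scampp_config(15))
    i <- match(pl$edge_number, backbone$edge_number)
    expect_false(is.na(i))
    expect_lte(pl$distal_length, backbone$edge.length[i] + 1e-9)
    expect_gte(pl$distal_length, 0)
  }
})

test_that("scampp placement beats placement on a random edge", {
  set.seed(506)
  inst <- simulate_instance(50, 300)
  deltas_scampp <- numeric(0)
  deltas_random <- numeric(0)
  for (q in sample(inst$tree$tip.label, 12)) {
    backbone <- phyplace:::prune_leaf(inst$tree, q)
    pl <- scampp_place(q, backbone, inst$model, inst$alignment,
                       config = scampp_config(25))
    placed <- phyplace:::attach_query_to_tree(backbone, q, pl$edge_number,
                                              pl$distal_length,
                                              pl$pendant_length)
    deltas_scampp <- c(deltas_scampp,
                       delta_error(inst$tree, backbone, placed, q)$delta)
    rand_edge <- sample(backbone$edge_number, 1)
    i <- match(rand_edge, backbone$edge_number)
    placed_r <- phyplace:::attach_query_to_tree(
      backbone, q, rand_edge, backbone$edge.length[i] / 2, 0.1)
    deltas_random <- c(deltas_random,
                       delta_error(inst$tree, backbone, placed_r, q)$delta)
  }
  expect_lte(mean(deltas_scampp), mean(deltas_random))
})
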