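test_that("bipartitions enumerate non-trivial splits canonically", {
  q <- phyplace:::read_newick_text("((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(bipartitions(q), "c|d")
  star <- phyplace:::read_newick_text("(a:1,b:1,c:1,d:1,e:1);")
  expect_length(bipartitions(star), 0L)
  cat5 <- phyplace:::read_newick_text("((((a:1,b:1):1,c:1):1,d:1):1,e:1);")
  expect_length(bipartitions(cat5), 2L)
  tri <- phyplace:::read_newick_text("((a:1,b:1):1,c:1);")
  expect_length(bipartitions(tri), 0L)

  # matches the independent clade-based enumeration on random trees
  set.seed(601)
  for (i in 1:6) {
    tr <- random_tree(sample(5:8, 1))
    expect_setequal(bipartitions(tr), oracle_bipartitions(tr))
  }
})

test_that("missing-branch counts behave like the FN half of Robinson-Foulds", {
  set.seed(602)
  tr <- random_tree(8)
  expect_equal(fn_missing_branches(tr, tr), 0L)
  star <- phyplace:::read_newick_text(
    paste0("(", paste0(tr$tip.label, ":1", collapse = ","), ");"))
  expect_equal(fn_missing_branches(tr, star), length(bipartitions(tr)))

  ref <- phyplace:::read_newick_text("((a:1,b:1):1,(c:1,d:1):1,e:1);")
  est <- phyplace:::read_newick_text("((a:1,c:1):1,(b:1,d:1):1,e:1);")
  expect_equal(fn_missing_branches(ref, est),
               length(setdiff(oracle_bipartitions(ref),
                              oracle_bipartitions(est))))

  # symmetric FN counts sum to phangorn's Robinson-Foulds distance
  for (i in 1:4) {
    t1 <- random_tree(9)
    t2 <- ape::rtree(9, tip.label = sample(t1$tip.label))
    rf <- as.numeric(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
    expect_equal(fn_missing_branches(t1, t2) + fn_missing_branches(t2, t1),
                 rf)
  }

  extra <- random_tree(6)
  expect_error(fn_missing_branches(extra,
                                   phyplace:::read_newick_text(
                                     "((x:1,y:1):1,(z:1,w:1):1);")),
               "not in the reference")
})

test_that("delta error is zero for the induced edge and non-negative elsewhere", {
  set.seed(603)
  for (rep in 1:5) {
    ref <- random_tree(8)
    q <- sample(ref$tip.label, 1)
    backbone <- phyplace:::prune_leaf(ref, q)
    deltas <- vapply(backbone$edge_number, function(e) {
      i <- match(e, backbone$edge_number)
      placed <- phyplace:::attach_query_to_tree(
        backbone, q, e, backbone$edge.length[i] / 2, 0.1)
      delta_error(ref, backbone, placed, q)$delta
    }, numeric(1))
    expect_true(all(deltas >= 0))
    expect_equal(min(deltas), 0)
  }
  ref <- random_tree(8)
  expect_error(delta_error(ref, ref, ref, "notaleaf"), "missing")
})

test_that("fragment protocols match their stated normal length models", {
  low <- fragment_protocol("low")
  expect_equal(low$fraction, 0.25)
  expect_equal(low$sigma, 60)
  high <- fragment_protocol("high")
  expect_equal(high$fraction, 0.10)
  expect_equal(high$sigma, 10)
  expect_error(fragment_protocol("low", fraction = 2), "fraction")

  set.seed(604)
  lens <- sample_fragment_lengths(4000, 1000, low)
  expect_true(all(lens >= 1 & lens <= 1000))
  expect_equal(mean(lens), 250, tolerance = 0.02)
  expect_equal(sd(lens), 60, tolerance = 0.05)
})

test_that("fragments are contiguous, clamped, and deterministic under a seed", {
  seqs <- paste(rep("ACGT", 250), collapse = "")
  set.seed(605)
  f1 <- make_fragment(seqs, fragment_protocol("low"))
  set.seed(605)
  f2 <- make_fragment(seqs, fragment_protocol("low"))
  expect_identical(f1, f2)
  expect_equal(nchar(f1$fragment), f1$length)
  expect_identical(f1$fragment,
                   substr(seqs, f1$start, f1$start + f1$length - 1L))

  # aligned-coordinate masking keeps the fragment columns and gaps the rest
  row <- "AC-GT-ACGTAC-GTACGT"
  set.seed(606)
  masked <- fragment_aligned_row(row, fragment_protocol("high"))
  expect_equal(nchar(masked), nchar(row))
  keep <- which(strsplit(masked, "")[[1]] != "-")
  orig <- which(strsplit(row, "")[[1]] != "-")
  expect_true(all(keep %in% orig))
  expect_true(all(diff(match(keep, orig)) == 1))  # contiguous in ungapped coords
})

test_that("leave-one-out experiments are seeded, contract-conforming, and B=n-reducible", {
  set.seed(607)
  inst <- simulate_instance(12, 200)
  rep1 <- leave_one_out_experiment(inst$tree, inst$alignment, inst$model,
                                   method = "full", n_queries = 6, seed = 42)
  expect_equal(nrow(rep1), 6L)
  expect_true(all(rep1$delta >= 0))
  expect_true(all(rep1$fn_after >= rep1$fn_before))
  rep2 <- leave_one_out_experiment(inst$tree, inst$alignment, inst$model,
                                   method = "full", n_queries = 6, seed = 42)
  expect_identical(rep1$delta, rep2$delta)
  expect_identical(rep1$query_name, rep2$query_name)
  rep3 <- leave_one_out_experiment(inst$tree, inst$alignment, inst$model,
                                   method = "scampp", B = 12, n_queries = 6,
                                   seed = 42)
  expect_identical(rep3$delta, rep1$delta)
  expect_identical(rep3$edge_number, rep1$edge_number)
  expect_equal(attr(rep1, "se_delta"),
               sd(rep1$delta) / sqrt(6), tolerance = 1e-12)
  expect_error(leave_one_out_experiment(inst$tree, inst$alignment,
                                        inst$model, n_queries = 99),
               "exceeds")
})

test_that("simulated Yule trees have the requested size, height, and determinism", {
  set.seed(608)
  tr <- simulate_tree(50)
  expect_equal(length(tr$tip.label), 50L)
  expect_equal(nrow(tr$edge), 2 * 50 - 2)  # rooted binary
  depths <- ape::node.depth.edgelength(tr)[1:50]
  expect_equal(mean(depths), 0.5, tolerance = 1e-9)
  set.seed(123)
  t1 <- simulate_tree(20)
  set.seed(123)
  t2 <- simulate_tree(20)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(simulate_tree(3), ">= 4")
})

test_that("sequence simulation respects degenerate branch lengths and stationarity", {
  m <- gtr_gamma_model(c(1.5, 2.5, 0.8, 1.2, 3, 1),
                       c(0.35, 0.15, 0.2, 0.3), alpha = 1)
  tr <- phyplace:::read_newick_text("((a:0,b:0):0,(c:0,d:0):0);")
  set.seed(609)
  aln <- simulate_alignment(tr, m, 200)
  expect_equal(length(unique(unname(aln$seqs))), 1L)

  tr2 <- phyplace:::read_newick_text("((a:0.4,b:0.4):0.2,(c:0.3,d:0.3):0.3);")
  set.seed(610)
  aln2 <- simulate_alignment(tr2, m, 50000)
  for (leaf in c("a", "d")) {
    chars <- strsplit(aln2$seqs[[leaf]], "")[[1]]
    freq <- table(factor(chars, levels = c("A", "C", "G", "T"))) / 50000
    expect_true(all(abs(as.numeric(freq) - m$pi) < 0.01))
  }
})
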