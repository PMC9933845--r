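test_that("FASTA alignments parse, normalize case, and reject invalid input", {
  f <- write_lines_tmp(c(">a", "ACGT", ">b", "AC-T"), ".fasta")
  aln <- read_fasta_alignment(f)
  expect_equal(labels(aln), c("a", "b"))
  expect_equal(aln$L, 4L)
  expect_equal(aln$seqs[["b"]], "AC-T")

  f2 <- write_lines_tmp(c(">a desc text", "acgt"), ".fasta")
  expect_equal(read_fasta_alignment(f2)$seqs[["a"]], "ACGT")

  f3 <- write_lines_tmp(c(">a", "ACGT", ">b", "ACG"), ".fasta")
  expect_error(read_fasta_alignment(f3), "ragged.*'b'")
  f4 <- write_lines_tmp(c(">a", "ACGT", ">a", "ACGT"), ".fasta")
  expect_error(read_fasta_alignment(f4), "duplicate")
  f5 <- write_lines_tmp(character(0), ".fasta")
  expect_error(read_fasta_alignment(f5), "empty")
  expect_error(read_fasta_alignment(tempfile()), "not found")

  # round trip, including multi-line wrapping
  set.seed(201)
  aln2 <- random_alignment(sprintf("s%02d", 1:8), 203, gap_prob = 0.1)
  out <- tempfile(fileext = ".fasta")
  write_fasta_alignment(aln2, out, width = 60)
  expect_identical(read_fasta_alignment(out)$seqs, aln2$seqs)
})

test_that("Newick reading validates structure and round-trips exactly", {
  f <- write_lines_tmp("((a:1,b:2):0.5,c:3);", ".nwk")
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  internal_child <- tr$edge[, 2L] > length(tr$tip.label)
  expect_equal(tr$edge.length[internal_child], 0.5)

  expect_warning(phyplace:::read_newick_text("((a,b),c);"), "branch lengths")
  tr0 <- suppressWarnings(phyplace:::read_newick_text("((a,b),c);"))
  expect_true(all(tr0$edge.length == 0))
  expect_error(phyplace:::read_newick_text("((a:1,b:2:0.5,c:3);"),
               "unclosed")
  expect_error(phyplace:::read_newick_text("(a:1,b:2)):0.5;"), "position")
  expect_error(phyplace:::read_newick_text("((a:1,a:2):0.5,c:3);"),
               "duplicate")

  set.seed(202)
  tr <- simulate_tree(50)
  f1 <- tempfile(); f2 <- tempfile()
  write_newick(tr, f1)
  tr2 <- read_newick(f1)
  write_newick(tr2, f2)
  expect_identical(readLines(f1), readLines(f2))
  key1 <- sort(paste(tr$edge_number, tr$edge.length))
  key2 <- sort(paste(tr2$edge_number, tr2$edge.length))
  expect_equal(key1, key2, tolerance = 1e-12)
})

test_that("edge numbering is canonical: postorder, idempotent, rotation-invariant", {
  tr <- phyplace:::read_newick_text("((a:1,b:1):1,c:1);")
  enum_of <- function(tree, tip) {
    tree$edge_number[match(match(tip, tree$tip.label), tree$edge[, 2L])]
  }
  parent_edge <- tr$edge_number[tr$edge[, 2L] > length(tr$tip.label)]
  expect_lt(enum_of(tr, "a"), parent_edge)
  expect_lt(enum_of(tr, "b"), parent_edge)

  expect_identical(assign_edge_numbers(tr)$edge_number, tr$edge_number)

  # all child-order rotations of one labeled 5-leaf topology give the same
  # numbering of the same unrooted edges
  rotations <- c("((a:1,b:2):3,(c:4,(d:5,e:6):7):8);",
                 "((b:2,a:1):3,(c:4,(e:6,d:5):7):8);",
                 "(((d:5,e:6):7,c:4):8,(a:1,b:2):3);",
                 "((c:4,(d:5,e:6):7):8,(b:2,a:1):3);")
  keys <- lapply(rotations, function(txt) {
    tr <- phyplace:::read_newick_text(txt)
    k <- vapply(seq_len(nrow(tr$edge)), function(i) {
      edge_split_all <- edge_split(tr, tr$edge_number[i])
      paste0(edge_split_all, "=", tr$edge_number[i], "@",
             tr$edge.length[i])
    }, "")
    sort(k)
  })
  for (i in 2:length(keys)) expect_identical(keys[[i]], keys[[1]])
})

test_that("jplace output is valid version 3 and survives an independent reparse", {
  set.seed(203)
  tr <- random_tree(8)
  pl <- placement("q1", edge_number = 3L, distal_length = 0.01234,
                  pendant_length = 0.567, log_likelihood = -1234.5,
                  like_weight_ratio = 0.9)
  f <- tempfile(fileext = ".jplace")
  write_jplace(tr, list(pl), f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(doc$version, 3L)
  expect_equal(unlist(doc$fields),
               c("edge_num", "likelihood", "like_weight_ratio",
                 "distal_length", "pendant_length"))
  expect_length(doc$placements, 1L)
  expect_length(doc$placements[[1]]$p[[1]], 5L)

  re <- reparse_jplace(f)
  expect_equal(re$placements$edge_num, 3L)
  expect_equal(re$placements$pendant_length, 0.567)
  expect_equal(re$placements$distal_length, 0.01234)
  # every tip edge number recovered from the tree string matches the
  # canonical numbering
  for (tip in names(re$tip_edges)) {
    v <- match(tip, tr$tip.label)
    expect_equal(re$tip_edges[[tip]],
                 tr$edge_number[match(v, tr$edge[, 2L])])
  }

  f2 <- tempfile(fileext = ".jplace")
  write_jplace(tr, list(), f2)
  doc2 <- jsonlite::fromJSON(f2, simplifyVector = FALSE)
  expect_length(doc2$placements, 0L)

  bad <- placement("q", edge_number = 999L, distal_length = 0,
                   pendant_length = 0, log_likelihood = 0)
  expect_error(write_jplace(tr, list(bad), tempfile()), "unknown edge")
})

test_that("model files round-trip and validate their fields", {
  jc <- gtr_gamma_model(rep(1, 6), rep(0.25, 4), alpha = 2.5,
                        n_categories = 4)
  f <- tempfile(fileext = ".json")
  write_model_file(jc, f)
  back <- parse_model_file(f)
  expect_equal(back$pi, jc$pi, tolerance = 1e-12)
  expect_equal(back$alpha, jc$alpha)
  expect_equal(back$n_categories, jc$n_categories)

  m <- gtr_gamma_model(c(1.17, 2.9345, 0.771, 1.33, 3.001, 1),
                       c(0.21, 0.27, 0.24, 0.28), alpha = 0.73)
  write_model_file(m, f)
  back <- parse_model_file(f)
  expect_equal(unname(back$exchangeabilities),
               unname(m$exchangeabilities), tolerance = 1e-12)
  expect_equal(back$pi, m$pi, tolerance = 1e-12)
  expect_equal(back$Q, m$Q, tolerance = 1e-12)

  writeLines(jsonlite::toJSON(list(exchangeabilities = rep(1, 6),
                                   base_freqs = c(0.3, 0.3, 0.3, 0.3),
                                   gamma_shape = 1, n_categories = 4),
                              auto_unbox = TRUE), f)
  expect_error(parse_model_file(f), "sum to 1")
  writeLines(jsonlite::toJSON(list(exchangeabilities = rep(1, 6),
                                   base_freqs = rep(0.25, 4),
                                   n_categories = 4), auto_unbox = TRUE), f)
  expect_error(parse_model_file(f), "gamma_shape")
})
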