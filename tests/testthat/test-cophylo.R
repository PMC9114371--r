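test_that("neighbor joining reconstructs an additive 4-taxon matrix exactly", {
  ids <- LETTERS[1:4]
  d <- matrix(4, 4, 4, dimnames = list(ids, ids))
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  diag(d) <- 0
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  # split {A,B}|{C,D}: internal branch 2, pendant branches 1
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 1, 2))
  truth <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(robinson_foulds(tr, truth)$rf, 0L)
})

test_that("neighbor joining solves the 3-taxon star in closed form", {
  ids <- c("A", "B", "C")
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3, dimnames = list(ids, ids))
  tr <- nj_tree(d)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["A"]], 0.5)  # (dAB + dAC - dBC)/2
  expect_equal(el[["B"]], 1.5)
  expect_equal(el[["C"]], 2.5)
})

test_that("neighbor joining validates its input and clamps negative branches", {
  ids <- c("A", "B", "C")
  asym <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3, 3, dimnames = list(ids, ids))
  expect_error(nj_tree(asym), class = "validation_error")
  diag_bad <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 1), 3, 3, dimnames = list(ids, ids))
  expect_error(nj_tree(diag_bad), class = "validation_error")
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(ids[1:2], ids[1:2]))),
               class = "validation_error")
  # near-degenerate distances produce negative estimates that get clamped
  d <- matrix(c(0, 0.1, 5, 5,
                0.1, 0, 5, 5,
                5, 5, 0, 9.95,
                5, 5, 9.95, 0), 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- suppressMessages(nj_tree(d))
  expect_true(all(tr$edge.length >= 0))
})

test_that("NJ is consistent for additive distances from random trees", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    truth <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(truth)
    rec <- nj_tree(d)
    expect_equal(robinson_foulds(rec, truth)$rf, 0L)
  }
})

test_that("Robinson-Foulds distance satisfies identity, symmetry and NNI cases", {
  t1 <- parse_newick("(((A,B),C),D,E);")
  expect_equal(robinson_foulds(t1, t1), list(rf = 0L, normalized = 0, n_leaves = 5L))

  t2 <- parse_newick("(((A,C),B),D,E);")  # one NNI away
  rf <- robinson_foulds(t1, t2)
  expect_equal(rf$rf, 2L)
  expect_equal(rf$normalized, 0.5)
  expect_identical(robinson_foulds(t2, t1)$rf, rf$rf)

  star <- parse_newick("(A,B,C,D,E);")
  rf2 <- robinson_foulds(t1, star)
  expect_equal(rf2$rf, 2L)
  expect_equal(rf2$normalized, 0.5)

  t3 <- parse_newick("((A,B),(C,F),E);")
  expect_error(robinson_foulds(t1, t3), class = "label_error")
})

test_that("Newick writing is canonical and round-trip stable", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  nw <- write_newick(tr)
  expect_identical(nw, "((A:1.000000,B:1.000000):1.000000,C:2.000000);")
  # rotated input serialises to the same bytes
  tr_rot <- parse_newick("(C:2,(B:1,A:1):1);")
  expect_identical(write_newick(tr_rot), nw)
  # round trip preserves topology and branch lengths
  back <- parse_newick(nw)
  expect_identical(write_newick(back), nw)

  expect_error(parse_newick("(A,B"), class = "parse_error")
  expect_error(parse_newick("((A,B),(A,C));"), class = "parse_error")

  set.seed(62)
  for (i in 1:10) {
    t <- ape::rtree(sample(4:10, 1))
    rt <- parse_newick(write_newick(t))
    expect_equal(robinson_foulds(rt, t)$rf, 0L)
    expect_equal(sort(rt$edge.length), sort(round(t$edge.length, 6)))
  }
})

test_that("symbiont leaves map onto host species for tree comparison", {
  map <- data.frame(strain_id = c("S1", "S2", "S3", "S4"),
                    host_species = c("H1", "H2", "H2", "H3"),
                    host_taxon = c("H1", "H2", "H2", "H3"),
                    stringsAsFactors = FALSE)
  tr <- parse_newick("((S1:1,S2:1):1,(S3:1,S4:1):1);")
  mapped <- map_symbiont_leaves(tr, map)
  expect_setequal(mapped$tip.label, c("H1", "H2", "H3"))
  # S2 < S3 lexicographically, so S2 represents H2
  expect_true("H2" %in% mapped$tip.label)
  host_tr <- parse_newick("((H1:1,H2:1):1,H3:2);")
  expect_silent(robinson_foulds(mapped, host_tr))

  bad <- parse_newick("((S1:1,S9:1):1,S4:2);")
  expect_error(map_symbiont_leaves(bad, map), class = "label_error")
})
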