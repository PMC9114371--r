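test_that("pairwise identity follows the stated gap conventions", {
  for (mode in c("all", "exclude_either", "exclude_both"))
    expect_equal(pairwise_identity("ACGT", "ACGT", mode), 1.0)
  expect_equal(pairwise_identity("AC-GT", "AC-GA", "all"), 0.8)
  expect_equal(pairwise_identity("AC-GT", "AC-GA", "exclude_either"), 0.75)
  expect_equal(pairwise_identity("AC-GT", "AC-GA", "exclude_both"), 0.75)
  expect_true(is.na(pairwise_identity("----", "----", "exclude_either")))
  expect_equal(pairwise_identity("----", "----", "all"), 1.0)  # gap-gap matches
  expect_equal(pairwise_identity("NN", "NN", "all"), 1.0)      # N-N matches
  expect_error(pairwise_identity("ACG", "AC"), class = "alignment_shape_error")
})

test_that("similarity matrices are symmetric and match direct computation", {
  m <- similarity_matrix(c(x = "AAAA", y = "AAAA", z = "TTTT"))
  expect_equal(m$values["x", "y"], 1.0)
  expect_equal(m$values["x", "z"], 0.0)
  expect_equal(m$values["y", "z"], 0.0)
  expect_true(all(diag(m$values) == 1))
  expect_error(similarity_matrix(c(x = "ACGT")), class = "insufficient_input_error")
})

test_that("similarity matrices agree with the per-column oracle and are permutation invariant", {
  set.seed(31)
  for (rep in 1:25) {
    recs <- random_alignment(sample(3:6, 1), sample(20:80, 1))
    for (mode in c("all", "exclude_either", "exclude_both")) {
      m <- similarity_matrix(recs, mode)
      for (i in seq_along(recs)) for (j in seq_along(recs)) {
        expect_identical(m$values[i, j],
                         oracle_identity(recs[[i]], recs[[j]], mode))
      }
      perm <- sample(length(recs))
      m2 <- similarity_matrix(recs[perm], mode)
      expect_identical(m2$values[names(recs), names(recs)], m$values)
    }
  }
})

test_that("gap modes coincide on gap-free sequences", {
  set.seed(32)
  for (rep in 1:10) {
    recs <- random_alignment(3, 50, gap_prob = 0, n_prob = 0.05)
    vals <- lapply(c("all", "exclude_either", "exclude_both"),
                   function(mode) similarity_matrix(recs, mode)$values)
    expect_identical(vals[[1]], vals[[2]])
    expect_identical(vals[[1]], vals[[3]])
  }
})

test_that("per-gene pair similarity skips missing or undefined genes", {
  g1 <- make_gene("g1", x = "AAAA", y = "AAAA")
  g2 <- make_gene("g2", x = "CCCC", y = "CCCC")
  v <- per_gene_pair_similarity(list(g2, g1), "x", "y")
  expect_equal(unname(v), c(1.0, 1.0), ignore_attr = TRUE)
  expect_equal(names(v), c("g1", "g2"))  # lexicographic gene order
  expect_equal(attr(v, "n_skipped"), 0L)

  g3 <- make_gene("g3", x = "GGGG")
  v2 <- per_gene_pair_similarity(list(g1, g2, g3), "x", "y")
  expect_length(v2, 2L)
  expect_equal(attr(v2, "n_skipped"), 1L)

  expect_error(per_gene_pair_similarity(list(g3), "x", "y"),
               class = "empty_comparison_error")
  expect_error(per_gene_pair_similarity(list(g1), "x", "x"),
               class = "validation_error")
})

test_that("summary statistics use sample sd and interpolated quartiles", {
  s <- summary_stats(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(s$q25, 0.175)
  expect_equal(s$q50, 0.25)
  expect_equal(s$q75, 0.325)

  s2 <- summary_stats(c(0.8, 0.9, 1.0))
  expect_equal(s2$mean, 0.9)
  expect_equal(s2$sd, 0.1)
  expect_equal(s2$min, 0.8)
  expect_equal(s2$max, 1.0)

  s3 <- summary_stats(0.5)
  expect_equal(s3$n, 1L)
  expect_true(is.na(s3$sd))
  expect_equal(c(s3$q25, s3$q50, s3$q75), rep(0.5, 3))

  s4 <- summary_stats(rep(0.7, 5))
  expect_equal(s4$sd, 0)
  expect_equal(c(s4$min, s4$q25, s4$q50, s4$q75, s4$max), rep(0.7, 5))

  expect_error(summary_stats(numeric(0)), class = "empty_input_error")
})

test_that("cross-group statistics summarise the block and its row maxima", {
  recs <- c(a1 = "A", a2 = "A", b1 = "A", b2 = "A")  # placeholder ids
  m <- structure(list(ids = names(recs),
                      values = matrix(1, 4, 4, dimnames = list(names(recs), names(recs))),
                      gap_mode = "all"),
                 class = "similarity_matrix")
  m$values["a1", "b1"] <- m$values["b1", "a1"] <- 0.9
  m$values["a1", "b2"] <- m$values["b2", "a1"] <- 0.8
  m$values["a2", "b1"] <- m$values["b1", "a2"] <- 0.9
  m$values["a2", "b2"] <- m$values["b2", "a2"] <- 0.7
  cg <- cross_group_stats(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(cg$overall_mean, 0.825)
  expect_equal(cg$overall_min, 0.7)
  expect_equal(cg$overall_max, 0.9)
  expect_equal(cg$row_max_mean, 0.9)
  expect_equal(cg$row_max_mode, 0.9)

  one <- cross_group_stats(m, "a1", "b2")
  expect_equal(one$overall_mean, 0.8)
  expect_equal(one$row_max_mode, 0.8)

  expect_error(cross_group_stats(m, c("a1", "b1"), c("b1", "b2")),
               class = "validation_error")
})

test_that("row-max mode breaks ties toward the smaller value", {
  ids <- c("a1", "a2", "b1", "b2")
  vals <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  vals["a1", "b1"] <- vals["b1", "a1"] <- 0.92
  vals["a2", "b2"] <- vals["b2", "a2"] <- 0.95
  m <- structure(list(ids = ids, values = vals, gap_mode = "all"),
                 class = "similarity_matrix")
  cg <- cross_group_stats(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(cg$row_max_mode, 0.92)  # 0.92 and 0.95 each occur once
})
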