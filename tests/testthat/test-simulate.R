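test_that("Yule host trees have the requested shape and are seed-reproducible", {
  tr <- simulate_host_tree(3, 1, seed = 1)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)
  expect_true(ape::is.ultrametric(tr))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)

  a <- simulate_host_tree(9, 2, seed = 77)
  b <- simulate_host_tree(9, 2, seed = 77)
  expect_identical(write_newick(a), write_newick(b))
  expect_false(identical(write_newick(a),
                         write_newick(simulate_host_tree(9, 2, seed = 78))))

  expect_error(simulate_host_tree(2, 1, 1), class = "validation_error")
  expect_error(simulate_host_tree(5, 0, 1), class = "validation_error")
})

test_that("waiting time from root to second split follows the pure-birth law", {
  # with 2 extant lineages the wait to the next split is Exp(2 * birth_rate)
  birth <- 1.5
  waits <- vapply(1:300, function(i) {
    tr <- simulate_host_tree(3, birth, seed = 10000 + i, normalize_height = FALSE)
    nt <- ape::node.depth.edgelength(tr)
    internal_times <- sort(nt[4:5])
    internal_times[2] - internal_times[1]
  }, numeric(1))
  expected <- 1 / (2 * birth)
  se <- sd(waits) / sqrt(length(waits))
  expect_lt(abs(mean(waits) - expected), 3 * se)
})

test_that("a cophylogeny without host shifts reproduces the host tree exactly", {
  ht <- simulate_host_tree(10, 1, seed = 3)
  co <- simulate_cophylogeny(ht, 0, seed = 1)
  expect_equal(nrow(co$events), 0L)
  expect_equal(robinson_foulds(co$tree, ht)$rf, 0L)
  d1 <- ape::cophenetic.phylo(co$tree)
  d2 <- ape::cophenetic.phylo(ht)
  expect_equal(d1[rownames(d2), colnames(d2)], d2, tolerance = 1e-10)
})

test_that("a forced host shift sets the donor-recipient symbiont distance to twice its age", {
  ht <- simulate_host_tree(8, 1, seed = 5)
  # use a pair whose host lineages split at the root, so they are distinct
  # lineages at every event time
  nt <- ape::node.depth.edgelength(ht)
  mr <- ape::mrca(ht)
  mt <- matrix(nt[mr], nrow(mr), ncol(mr))
  basal <- which(mt == min(mt), arr.ind = TRUE)[1, ]
  donor <- ht$tip.label[basal[1]]
  recip <- ht$tip.label[basal[2]]
  for (t_ev in c(0.5, 0.8, 0.95)) {
    fe <- data.frame(time = t_ev, donor = donor, recipient = recip)
    co <- simulate_cophylogeny(ht, 0, seed = 1, forced_events = fe)
    d <- ape::cophenetic.phylo(co$tree)
    expect_equal(d[donor, recip], 2 * (1 - t_ev), tolerance = 1e-10)
  }
  # recipient's original coalescences are replaced by the donor's lineage
  fe <- data.frame(time = 0.9, donor = donor, recipient = recip)
  co <- simulate_cophylogeny(ht, 0, seed = 1, forced_events = fe)
  d <- ape::cophenetic.phylo(co$tree)
  dh <- ape::cophenetic.phylo(ht)
  others <- setdiff(ht$tip.label, c(donor, recip))
  for (x in others)
    expect_equal(d[recip, x], max(dh[donor, x], 2 * (1 - 0.9)), tolerance = 1e-10)
})

test_that("host-shift event counts follow the Poisson mean", {
  ht <- simulate_host_tree(6, 1, seed = 11)
  L <- sum(ht$edge.length)
  lambda <- 0.8
  counts <- vapply(1:300, function(i) {
    nrow(simulate_cophylogeny(ht, lambda, seed = 5000 + i)$events)
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - lambda * L), 3 * se)
  # events respect tree bounds and donor != recipient
  co <- simulate_cophylogeny(ht, 2, seed = 123)
  if (nrow(co$events) > 0) {
    expect_true(all(co$events$time >= 0 & co$events$time <= 1))
    expect_true(all(co$events$donor_host != co$events$recipient_host))
  }
})

test_that("sequence evolution is seeded, aligned, and frozen at rate zero", {
  tr <- simulate_host_tree(5, 1, seed = 9)
  g1 <- evolve_sequences(tr, 3, 120, 0.3, seed = 4)
  g2 <- evolve_sequences(tr, 3, 120, 0.3, seed = 4)
  expect_identical(g1, g2)
  expect_equal(vapply(g1, `[[`, integer(1), "n_columns"), rep(120L, 3))
  expect_setequal(names(g1[[1]]$records), tr$tip.label)

  frozen <- evolve_sequences(tr, 2, 80, 0, seed = 4)
  for (g in frozen) {
    expect_equal(length(unique(g$records)), 1L)
    expect_equal(pairwise_identity(g$records[[1]], g$records[[2]]), 1.0)
  }
})

test_that("generated datasets are complete, readable and reproducible", {
  cfg <- simulation_config(n_hosts = 6, n_genes = 6, gene_length = 120,
                           dropout_prob = 0, seed = 8)
  out1 <- file.path(tempdir(), "ds_a")
  out2 <- file.path(tempdir(), "ds_b")
  d1 <- generate_dataset(cfg, out1)
  d2 <- generate_dataset(cfg, out2)
  for (f in c("host.nwk", "symbiont.nwk", "events.tsv", "strain_host_map.tsv",
              "config.json"))
    expect_true(file.exists(file.path(out1, f)))
  expect_length(list.files(file.path(out1, "symbiont_genes")), 6L)
  expect_length(list.files(file.path(out1, "host_genes")), 6L)
  # every FASTA parses with no warnings
  for (f in list.files(file.path(out1, "symbiont_genes"), full.names = TRUE))
    expect_no_warning(read_fasta_alignment(f))
  # bit-for-bit reproducibility from (config, seed)
  for (f in list.files(out1, recursive = TRUE)) {
    expect_identical(readChar(file.path(out1, f), file.size(file.path(out1, f))),
                     readChar(file.path(out2, f), file.size(file.path(out2, f))),
                     info = f)
  }
})

test_that("gene dropout matches its binomial mean", {
  cfg <- simulation_config(n_hosts = 40, n_genes = 50, gene_length = 30,
                           host_subst_rate = 0.1, dropout_prob = 0.02, seed = 13)
  out <- file.path(tempdir(), "ds_drop")
  d <- generate_dataset(cfg, out)
  counts <- table(unlist(lapply(d$symb_genes, function(g) names(g$records))))
  mean_recovered <- mean(counts)
  se <- sqrt(50 * 0.02 * 0.98) / sqrt(40)
  expect_lt(abs(mean_recovered - 49), 3 * se)
})

test_that("shift-pair selection returns distant, isolated, disjoint pairs", {
  found <- FALSE
  for (s in 1:10) {
    ht <- simulate_host_tree(12, 1, seed = 200 + s)
    pairs <- pick_shift_pairs(ht, n_pairs = 3)
    if (is.null(pairs)) next
    found <- TRUE
    expect_equal(nrow(pairs), 3L)
    all_leaves <- c(pairs$donor, pairs$recipient)
    expect_equal(anyDuplicated(all_leaves), 0L)
    nt <- ape::node.depth.edgelength(ht)
    mr <- ape::mrca(ht)
    idx <- cbind(match(pairs$donor, ht$tip.label),
                 match(pairs$recipient, ht$tip.label))
    expect_true(all(1 - nt[mr[idx]] > 0.35))
  }
  expect_true(found)
})
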