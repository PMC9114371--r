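# Independent oracles and fixture builders used across tests.

# Per-column counting oracle for pairwise identity: a deliberately naive
# character-by-character loop, kept independent of the package's vectorised
# implementation.
oracle_identity <- function(a, b, gap_mode = "all") {
  av <- strsplit(a, NULL)[[1L]]
  bv <- strsplit(b, NULL)[[1L]]
  stopifnot(length(av) == length(bv))
  n_match <- 0L
  denom <- 0L
  for (i in seq_along(av)) {
    drop_col <- switch(gap_mode,
      all            = FALSE,
      exclude_either = av[i] == "-" || bv[i] == "-",
      exclude_both   = av[i] == "-" && bv[i] == "-")
    if (drop_col) next
    denom <- denom + 1L
    if (av[i] == bv[i]) n_match <- n_match + 1L
  }
  if (denom == 0L) NA_real_ else n_match / denom
}

random_alignment <- function(n_seq, n_col, gap_prob = 0.15, n_prob = 0.05) {
  alphabet <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_seq), function(i) {
    chars <- sample(alphabet, n_col, replace = TRUE)
    r <- runif(n_col)
    chars[r < gap_prob] <- "-"
    chars[r >= gap_prob & r < gap_prob + n_prob] <- "N"
    paste(chars, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("seq%02d", seq_len(n_seq))
  seqs
}

make_gene <- function(gene_id, ...) {
  gene_alignment(gene_id, c(...))
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# slope through the origin (least squares), used for clock-ratio recovery
origin_slope <- function(x, y) sum(x * y) / sum(x * x)

# simulate one codiverging host/symbiont dataset and return per-pair JC
# distances from the concatenated alignments
jc_pair_distances <- function(tree, n_genes, gene_length, rate, seed) {
  genes <- evolve_sequences(tree, n_genes, gene_length, rate, seed)
  concat <- concatenate_by_id(genes)
  sim <- similarity_matrix(concat)
  d <- jc_distance(sim$values)
  d[upper.tri(d)]
}

# run the similarity -> classification stages on one simulated replicate
# with forced recent host shifts; returns list(flagged, truth) of host-pair
# keys "Ha|Hb" (sorted)
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

hs_replicate <- function(seed, n_hosts = 12L, n_genes = 50L, gene_length = 900L,
                         host_rate = 0.5, clock_c = 0.5, shift_age = 0.02) {
  tree_seed <- seed
  repeat {
    ht <- simulate_host_tree(n_hosts, 1, tree_seed)
    pairs <- pick_shift_pairs(ht, n_pairs = 3L)
    if (!is.null(pairs)) break
    tree_seed <- tree_seed + 1000L
  }
  fe <- data.frame(time = 1 - shift_age, donor = pairs$donor,
                   recipient = pairs$recipient)
  co <- simulate_cophylogeny(ht, 0, seed = seed, forced_events = fe)
  host_genes <- evolve_sequences(ht, n_genes, gene_length, host_rate, seed + 1L)
  symb_genes <- evolve_sequences(co$tree, n_genes, gene_length,
                                 clock_c * host_rate, seed + 2L)
  host_sim <- similarity_matrix(concatenate_by_id(host_genes))
  symb_sim <- similarity_matrix(concatenate_by_id(symb_genes))
  labs <- ht$tip.label
  cmb <- utils::combn(labs, 2L)
  per_pair <- data.frame(symb_id_a = cmb[1L, ], symb_id_b = cmb[2L, ],
                         host_a = cmb[1L, ], host_b = cmb[2L, ],
                         symb_mean = symb_sim$values[cbind(cmb[1L, ], cmb[2L, ])],
                         host_mean = host_sim$values[cbind(cmb[1L, ], cmb[2L, ])],
                         stringsAsFactors = FALSE)
  det <- detect_all(per_pair)
  hs <- det$calls[det$calls$label == "host_shift", ]
  list(flagged = sort(pair_key(hs$host_a, hs$host_b)),
       truth = sort(pair_key(pairs$donor, pairs$recipient)))
}
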