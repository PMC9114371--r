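# Host-symbiont coevolution simulator.
#
# Host phylogenies follow a seeded pure-birth (Yule) process; the symbiont
# tree starts as an exact copy of the host tree (strict codivergence) and
# host-shift events, drawn from a Poisson process over the tree, replace the
# recipient host's symbiont lineage with the donor's at the event time.
# Sequences evolve along either tree under Jukes-Cantor without indels, so
# the true alignment is positional identity and every downstream stage can
# be validated against ground truth. Time is measured from the root; by
# default the host tree is rescaled to height 1 and all rates are per unit
# height.

#' Simulate a pure-birth (Yule) host tree
#'
#' Starts from the root split with two lineages at time 0; each of k extant
#' lineages splits after an exponential wait with total rate
#' `k * birth_rate` until `n_hosts` lineages exist, plus one final waiting
#' time to the present. Leaves are labelled `H1..Hn`.
#'
#' @param n_hosts Number of extant host species (>= 3).
#' @param birth_rate Speciation rate per lineage per unit time (> 0).
#' @param seed Integer seed; the same seed reproduces the tree exactly.
#' @param normalize_height Rescale branch lengths so the root-to-tip height
#'   is 1 (default `TRUE`).
#' @return A rooted ultrametric binary `phylo` tree.
#' @export
simulate_host_tree <- function(n_hosts, birth_rate = 1, seed, normalize_height = TRUE) {
  if (n_hosts < 3L)
    hs_stop("n_hosts must be at least 3", "validation_error")
  if (!(birth_rate > 0))
    hs_stop("birth_rate must be positive", "validation_error")
  with_seed(seed, {
    root <- n_hosts + 1L
    next_internal <- n_hosts + 2L
    node_time <- numeric(2L * n_hosts - 1L)
    par <- rep(root, 2L)   # parent node of each active lineage
    st <- c(0, 0)          # time each active lineage started
    edges <- matrix(0L, 0L, 2L)
    elen <- numeric(0)
    t <- 0
    k <- 2L
    while (k < n_hosts) {
      t <- t + stats::rexp(1L, k * birth_rate)
      i <- sample.int(k, 1L)
      m <- next_internal
      next_internal <- next_internal + 1L
      node_time[m] <- t
      edges <- rbind(edges, c(par[i], m))
      elen <- c(elen, t - st[i])
      par <- c(par[-i], m, m)
      st <- c(st[-i], t, t)
      k <- k + 1L
    }
    t_end <- t + stats::rexp(1L, n_hosts * birth_rate)
    for (i in seq_len(n_hosts)) {
      edges <- rbind(edges, c(par[i], i))
      elen <- c(elen, t_end - st[i])
    }
    tree <- structure(list(edge = edges, edge.length = elen,
                           tip.label = paste0("H", seq_len(n_hosts)),
                           Nnode = n_hosts - 1L),
                      class = "phylo")
    tree <- stats::reorder(tree, "cladewise")
    if (normalize_height) tree$edge.length <- tree$edge.length / t_end
    attr(tree, "height") <- if (normalize_height) 1 else t_end
    tree
  })
}

# edge index whose branch is ancestral to `leaf_label` at time `t`
edge_at_time <- function(tree, tp, tc, leaf_label, t) {
  node <- match(leaf_label, tree$tip.label)
  if (is.na(node))
    hs_stop(sprintf("unknown leaf label '%s'", leaf_label), "label_error")
  e <- which(tree$edge[, 2L] == node)
  repeat {
    if (tp[e] <= t) return(e)
    node <- tree$edge[e, 1L]
    e <- which(tree$edge[, 2L] == node)
    if (length(e) == 0L)
      hs_stop(sprintf("event time %g precedes the root", t), "validation_error")
  }
}

# smallest leaf label descending from the child node of edge e
edge_label <- function(tree, e) {
  tips <- unlist(phangorn::Descendants(tree, tree$edge[e, 2L], type = "tips"))
  lex_sort(tree$tip.label[tips])[1L]
}

#' Simulate a symbiont cophylogeny with host-shift events
#'
#' The symbiont genealogy is the host tree except at host-shift events: at
#' each event the recipient host lineage's symbiont is replaced by a copy of
#' the donor's, so the recipient's prior symbiont divergence (from the event
#' back) follows the donor lineage. Random events arrive as a Poisson
#' process with rate `hs_rate_lambda` per unit branch length; explicit
#' events can be forced via `forced_events`. With no events the symbiont
#' tree is identical to the host tree.
#'
#' @param host_tree Rooted ultrametric binary `phylo` (see
#'   [simulate_host_tree()]).
#' @param hs_rate_lambda Host-shift rate per unit branch length (>= 0).
#' @param seed Integer seed for the Poisson draw.
#' @param forced_events Optional data.frame with columns `time`, `donor`,
#'   `recipient` (leaf labels); the event transfers the donor lineage's
#'   symbiont into the recipient lineage at `time`.
#' @return List with `tree` (symbiont `phylo`, leaf labels matching the
#'   host tree), `events` (data.frame `time`, `donor_host`,
#'   `recipient_host`) and `height`.
#' @export
simulate_cophylogeny <- function(host_tree, hs_rate_lambda = 0, seed = 1L,
                                 forced_events = NULL) {
  stopifnot(inherits(host_tree, "phylo"))
  if (hs_rate_lambda < 0)
    hs_stop("hs_rate_lambda must be non-negative", "validation_error")
  nt <- ape::node.depth.edgelength(host_tree)
  n <- length(host_tree$tip.label)
  H <- max(nt[seq_len(n)])
  if (max(abs(nt[seq_len(n)] - H)) > 1e-6 * max(H, 1))
    hs_stop("host tree must be ultrametric", "validation_error")
  E <- host_tree$edge
  tp <- nt[E[, 1L]]
  tc <- nt[E[, 2L]]

  ev <- data.frame(time = numeric(0), donor_edge = integer(0),
                   recipient_edge = integer(0), donor_host = character(0),
                   recipient_host = character(0), stringsAsFactors = FALSE)
  if (hs_rate_lambda > 0) {
    ev_rand <- with_seed(seed, {
      L <- sum(host_tree$edge.length)
      nev <- stats::rpois(1L, hs_rate_lambda * L)
      out <- NULL
      if (nev > 0L) {
        de <- sample.int(nrow(E), nev, replace = TRUE, prob = host_tree$edge.length)
        tt <- tp[de] + stats::runif(nev) * (tc[de] - tp[de])
        re <- integer(nev)
        for (i in seq_len(nev)) {
          alive <- setdiff(which(tp <= tt[i] & tt[i] < tc), de[i])
          re[i] <- if (length(alive) == 1L) alive else alive[sample.int(length(alive), 1L)]
        }
        out <- data.frame(time = tt, donor_edge = de, recipient_edge = re,
                          stringsAsFactors = FALSE)
      }
      out
    })
    if (!is.null(ev_rand)) {
      ev_rand$donor_host <- vapply(ev_rand$donor_edge, function(e) edge_label(host_tree, e), character(1))
      ev_rand$recipient_host <- vapply(ev_rand$recipient_edge, function(e) edge_label(host_tree, e), character(1))
      ev <- rbind(ev, ev_rand)
    }
  }
  if (!is.null(forced_events) && nrow(forced_events) > 0L) {
    stopifnot(all(c("time", "donor", "recipient") %in% names(forced_events)))
    for (i in seq_len(nrow(forced_events))) {
      t <- forced_events$time[i]
      de <- edge_at_time(host_tree, tp, tc, forced_events$donor[i], t)
      re <- edge_at_time(host_tree, tp, tc, forced_events$recipient[i], t)
      if (de == re)
        hs_stop("donor and recipient occupy the same lineage at the event time",
                "validation_error")
      ev <- rbind(ev, data.frame(time = t, donor_edge = de, recipient_edge = re,
                                 donor_host = forced_events$donor[i],
                                 recipient_host = forced_events$recipient[i],
                                 stringsAsFactors = FALSE))
    }
  }
  ev <- ev[order(ev$time), , drop = FALSE]

  # backward sweep: trace which host lineage carries each sampled symbiont;
  # two symbionts coalesce the moment they occupy the same host lineage
  Tco <- matrix(NA_real_, n, n)
  cl <- seq_len(n)                       # cluster id per tip
  cloc <- integer(n)                     # current edge per cluster id
  for (i in seq_len(n)) cloc[i] <- which(E[, 2L] == i)
  merge_at <- function(ids, t) {
    if (length(ids) < 2L) return(invisible())
    for (a in ids) for (b in ids) if (a < b) {
      ta <- which(cl == a); tb <- which(cl == b)
      Tco[ta, tb] <<- t
      Tco[tb, ta] <<- t
    }
    keep <- min(ids)
    cl[cl %in% ids] <<- keep
    invisible()
  }
  internal <- (n + 1L):(n + host_tree$Nnode)
  moments <- rbind(
    data.frame(time = nt[internal], type = "node", idx = internal),
    if (nrow(ev) > 0L) data.frame(time = ev$time, type = "event", idx = seq_len(nrow(ev))))
  # descending time; events strictly inside branches come before the node
  # that opens their branch, so at ties events are processed first
  moments <- moments[order(-moments$time, moments$type == "node"), , drop = FALSE]
  for (r in seq_len(nrow(moments))) {
    tmom <- moments$time[r]
    if (moments$type[r] == "event") {
      e <- ev[moments$idx[r], ]
      ids <- unique(cl)
      movers <- ids[cloc[ids] == e$recipient_edge]
      cloc[movers] <- e$donor_edge
      merge_at(ids[cloc[ids] == e$donor_edge |
                     (ids %in% movers)], tmom)
    } else {
      v <- moments$idx[r]
      ce <- which(E[, 1L] == v)
      pe <- which(E[, 2L] == v)
      if (length(pe) == 0L) pe <- 0L     # root sentinel
      ids <- unique(cl)
      movers <- ids[cloc[ids] %in% ce]
      cloc[movers] <- pe
      merge_at(unique(cl)[cloc[unique(cl)] == pe], tmom)
    }
  }
  diag(Tco) <- H
  D <- 2 * (H - Tco)
  diag(D) <- 0
  dimnames(D) <- list(host_tree$tip.label, host_tree$tip.label)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  sym_tree <- ape::as.phylo(hc)
  list(tree = sym_tree,
       events = ev[, c("time", "donor_host", "recipient_host"), drop = FALSE],
       height = H)
}

#' Evolve gene alignments along a tree under Jukes-Cantor
#'
#' Independent genes; uniform root base composition; substitutions per
#' branch follow the JC69 transition probabilities at
#' `subst_rate * branch_length` expected substitutions per site. No indels,
#' so the simulated sequences are already aligned.
#'
#' @param tree `phylo` with branch lengths.
#' @param n_genes Number of independent genes.
#' @param gene_length Sites per gene.
#' @param subst_rate Substitutions per site per unit branch length (>= 0).
#' @param seed Integer seed.
#' @return List of [gene_alignment()] objects with gene ids
#'   `gene001, gene002, ...`.
#' @export
evolve_sequences <- function(tree, n_genes, gene_length, subst_rate, seed) {
  stopifnot(inherits(tree, "phylo"), n_genes >= 1L, gene_length >= 1L,
            subst_rate >= 0)
  with_seed(seed, {
    lapply(seq_len(n_genes), function(i) {
      gid <- sprintf("gene%03d", i)
      if (subst_rate == 0) {
        root <- paste(sample(c("A", "C", "G", "T"), gene_length, replace = TRUE),
                      collapse = "")
        recs <- stats::setNames(rep(root, length(tree$tip.label)), tree$tip.label)
      } else {
        dat <- phangorn::simSeq(tree, l = gene_length, rate = subst_rate)
        m <- toupper(as.character(dat))
        recs <- stats::setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
        recs <- recs[tree$tip.label]
      }
      gene_alignment(gid, recs)
    })
  })
}

#' Simulator configuration
#'
#' Defaults emulate the study conditions the package is designed around:
#' ~50 single-copy genes of ~900 aligned sites per strain with a small gene
#' dropout probability (incomplete ortholog recovery), a host tree of
#' height 1, host genes evolving fast enough that distantly related hosts
#' share 45-75\% identity, and symbiont genes on a proportional clock at
#' half the host rate, so codiverging symbiont pairs stay below the
#' host-shift call threshold.
#'
#' @param n_hosts Number of host species (>= 3).
#' @param birth_rate Yule speciation rate.
#' @param hs_rate_lambda Host-shift rate per unit symbiont branch length.
#' @param n_genes Genes per strain (default 50).
#' @param gene_length Aligned sites per gene (default 900).
#' @param host_subst_rate Host substitutions/site per unit tree height.
#' @param clock_ratio_c Symbiont rate as a multiple of the host rate.
#' @param dropout_prob Per-strain, per-gene probability that the gene is not
#'   recovered (default 0.02).
#' @param seed Integer seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_hosts = 10L, birth_rate = 1, hs_rate_lambda = 0,
                              n_genes = 50L, gene_length = 900L,
                              host_subst_rate = 0.5, clock_ratio_c = 0.5,
                              dropout_prob = 0.02, seed = 1L) {
  if (n_hosts < 3L || n_genes < 1L || gene_length < 1L)
    hs_stop("n_hosts >= 3, n_genes >= 1 and gene_length >= 1 required",
            "validation_error")
  if (birth_rate <= 0 || hs_rate_lambda < 0 || host_subst_rate < 0 ||
      clock_ratio_c <= 0 || dropout_prob < 0 || dropout_prob >= 1)
    hs_stop("invalid rate parameter", "validation_error")
  structure(list(n_hosts = as.integer(n_hosts), birth_rate = birth_rate,
                 hs_rate_lambda = hs_rate_lambda, n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 host_subst_rate = host_subst_rate,
                 clock_ratio_c = clock_ratio_c, dropout_prob = dropout_prob,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

drop_records <- function(genes, prob) {
  lapply(genes, function(g) {
    keep <- stats::runif(length(g$records)) >= prob
    if (sum(keep) < 2L) return(g)  # a gene must keep at least one comparable pair
    gene_alignment(g$gene_id, g$records[keep])
  })
}

#' Generate a complete synthetic host-symbiont dataset on disk
#'
#' Simulates the host tree, the symbiont cophylogeny with host shifts, and
#' per-gene alignments for hosts (rate `host_subst_rate`) and symbionts
#' (rate `clock_ratio_c * host_subst_rate` on the symbiont tree), applies
#' gene dropout, and writes everything under `out_dir`: one FASTA per gene
#' in `host_genes/` and `symbiont_genes/`, `host.nwk`, `symbiont.nwk`,
#' `events.tsv`, `strain_host_map.tsv` and a `config.json` echo. Symbiont
#' strains are labelled `S1..Sn`, one per host `H1..Hn`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if missing).
#' @param host_tree Optional pre-simulated host tree (overrides the seeded
#'   Yule draw), e.g. to force events between chosen leaves.
#' @param forced_events Optional forced host-shift events, see
#'   [simulate_cophylogeny()].
#' @return Invisibly, a list with the simulated objects and file paths.
#' @export
generate_dataset <- function(config, out_dir, host_tree = NULL,
                             forced_events = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(host_tree))
    host_tree <- simulate_host_tree(config$n_hosts, config$birth_rate, config$seed)
  coph <- simulate_cophylogeny(host_tree, config$hs_rate_lambda,
                               seed = config$seed + 1L,
                               forced_events = forced_events)
  host_genes <- evolve_sequences(host_tree, config$n_genes, config$gene_length,
                                 config$host_subst_rate, config$seed + 2L)
  symb_tree <- coph$tree
  strain_of <- stats::setNames(paste0("S", sub("^H", "", host_tree$tip.label)),
                               host_tree$tip.label)
  symb_tree$tip.label <- unname(strain_of[symb_tree$tip.label])
  symb_genes <- evolve_sequences(symb_tree, config$n_genes, config$gene_length,
                                 config$clock_ratio_c * config$host_subst_rate,
                                 config$seed + 3L)
  if (config$dropout_prob > 0) {
    dropped <- with_seed(config$seed + 4L, {
      list(symb = drop_records(symb_genes, config$dropout_prob),
           host = drop_records(host_genes, config$dropout_prob))
    })
    symb_genes <- dropped$symb
    host_genes <- dropped$host
  }

  sdir <- file.path(out_dir, "symbiont_genes")
  hdir <- file.path(out_dir, "host_genes")
  dir.create(sdir, showWarnings = FALSE)
  dir.create(hdir, showWarnings = FALSE)
  for (g in symb_genes)
    write_fasta(g$records, file.path(sdir, paste0(g$gene_id, ".fasta")))
  for (g in host_genes)
    write_fasta(g$records, file.path(hdir, paste0(g$gene_id, ".fasta")))
  write_newick(host_tree, file.path(out_dir, "host.nwk"))
  write_newick(symb_tree, file.path(out_dir, "symbiont.nwk"))
  utils::write.table(coph$events, file.path(out_dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(strain_id = unname(strain_of),
                    host_species = names(strain_of),
                    host_taxon = names(strain_of),
                    stringsAsFactors = FALSE)
  utils::write.table(map, file.path(out_dir, "strain_host_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(host_tree = host_tree, symbiont_tree = symb_tree,
                 events = coph$events, strain_host_map = map,
                 symb_genes = symb_genes, host_genes = host_genes,
                 paths = list(out_dir = out_dir, symbiont_genes = sdir,
                              host_genes = hdir)))
}

#' Choose host pairs suitable for forced host-shift events
#'
#' Selects disjoint leaf pairs that are (a) mutually distant — their
#' divergence predates the present by at least `min_pair_age`, so the host
#' identity of each pair falls below the informative threshold by the JC
#' closed form — and (b) isolated — each chosen leaf's closest relative
#' diverged at least `min_isolation_age` ago, so a shift into or out of the
#' leaf cannot make any *other* pair's symbionts similar enough to be
#' flagged. Pairs are picked greedily, oldest divergence first.
#'
#' @param host_tree Ultrametric `phylo`.
#' @param n_pairs Number of disjoint pairs wanted.
#' @param min_pair_age Minimum age (time before present) of each pair's
#'   common ancestor.
#' @param min_isolation_age Minimum age of each chosen leaf's most recent
#'   divergence from any other leaf.
#' @return data.frame with columns `donor`, `recipient`, or `NULL` if the
#'   tree does not admit `n_pairs` such pairs.
#' @export
pick_shift_pairs <- function(host_tree, n_pairs = 3L, min_pair_age = 0.35,
                             min_isolation_age = 0.2) {
  stopifnot(inherits(host_tree, "phylo"))
  nt <- ape::node.depth.edgelength(host_tree)
  n <- length(host_tree$tip.label)
  H <- max(nt[seq_len(n)])
  parent <- host_tree$edge[match(seq_len(n), host_tree$edge[, 2L]), 1L]
  iso <- H - nt[parent]
  cand <- which(iso > min_isolation_age)
  if (length(cand) < 2L * n_pairs) return(NULL)
  mr <- ape::mrca(host_tree)
  pairs <- utils::combn(cand, 2L)
  age <- H - nt[mr[cbind(pairs[1L, ], pairs[2L, ])]]
  keep <- age > min_pair_age
  pairs <- pairs[, keep, drop = FALSE]
  age <- age[keep]
  ord <- order(-age)
  chosen <- matrix(integer(0), 2L, 0L)
  used <- integer(0)
  for (k in ord) {
    p <- pairs[, k]
    if (any(p %in% used)) next
    chosen <- cbind(chosen, p)
    used <- c(used, p)
    if (ncol(chosen) == n_pairs) break
  }
  if (ncol(chosen) < n_pairs) return(NULL)
  data.frame(donor = host_tree$tip.label[chosen[1L, ]],
             recipient = host_tree$tip.label[chosen[2L, ]],
             stringsAsFactors = FALSE)
}
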