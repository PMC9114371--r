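# Distance trees, Newick I/O, and symbiont-host tree incongruence.
#
# Trees are ape "phylo" objects throughout. Neighbor-joining on
# 1 - similarity serves as the distance-tree stand-in where users have no
# externally inferred phylogeny; incongruence between symbiont and host
# trees is quantified by the Robinson-Foulds bipartition distance.

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining agglomeration on a symmetric, zero-diagonal
#' distance matrix (typically 1 - similarity). Negative branch-length
#' estimates are clamped to zero; the clamped total is available as the
#' `negative_branch_deficit` attribute and reported via a message.
#'
#' @param distances Square symmetric numeric matrix with zero diagonal and
#'   at least 3 taxa, or a [stats::dist] object.
#' @param ids Taxon labels; defaults to the matrix dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(distances, ids = NULL) {
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
  if (!is.null(ids)) dimnames(distances) <- list(ids, ids)
  if (is.null(rownames(distances)))
    hs_stop("distance matrix needs taxon labels (ids or dimnames)",
            "validation_error")
  n <- nrow(distances)
  if (n < 3L)
    hs_stop("neighbor joining needs at least 3 taxa", "validation_error")
  if (max(abs(distances - t(distances))) > 1e-8)
    hs_stop("distance matrix must be symmetric", "validation_error")
  if (max(abs(diag(distances))) > 1e-8)
    hs_stop("distance matrix must have a zero diagonal", "validation_error")
  tr <- ape::nj(distances)
  neg <- tr$edge.length < 0
  deficit <- sum(-tr$edge.length[neg])
  if (deficit > 0) {
    tr$edge.length[neg] <- 0
    message(sprintf("clamped %d negative branch length(s), total deficit %.3g",
                    sum(neg), deficit))
  }
  attr(tr, "negative_branch_deficit") <- deficit
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of non-trivial bipartitions, treating both trees as
#' unrooted; normalised by `2(n - 3)` for `n >= 4` leaves (0 by definition
#' for `n <= 3`).
#'
#' @param t1,t2 `phylo` trees with identical leaf label sets.
#' @return List with `rf` (integer), `normalized` (fraction in \[0, 1\]) and
#'   `n_leaves`.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    hs_stop("trees must share an identical leaf label set", "label_error")
  u1 <- ape::unroot(t1)
  u2 <- ape::unroot(t2)
  rf <- as.integer(phangorn::RF.dist(u1, u2, check.labels = TRUE))
  n <- length(t1$tip.label)
  normalized <- if (n >= 4L) rf / (2 * (n - 3)) else 0
  list(rf = rf, normalized = normalized, n_leaves = n)
}

#' Parse a Newick string or file
#'
#' @param text Newick string, or the path of a file containing one.
#' @return A `phylo` tree.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    suppressWarnings(
      if (file.exists(text) && !grepl("\\(", text)) ape::read.tree(text)
      else ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    hs_stop("malformed Newick input", "parse_error")
  if (anyDuplicated(tr$tip.label))
    hs_stop("duplicate leaf labels in Newick input", "parse_error")
  tr
}

#' Write a tree as canonical Newick
#'
#' Children are ordered by their smallest descendant leaf label and branch
#' lengths written with 6 decimals, so equal trees serialise to identical
#' bytes regardless of input rotation.
#'
#' @param tree A `phylo` tree.
#' @param path Optional output file; if `NULL` the string is returned.
#' @param digits Decimals for branch lengths (default 6).
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL, digits = 6L) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- rep(NA_real_, max(tree$edge))
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2L]] <- tree$edge.length
  min_label <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    labs <- vapply(kids[[as.character(node)]], min_label, character(1))
    labs[lex_order(labs)][1L]
  }
  fmt <- function(node) {
    body <- if (node <= n) {
      tree$tip.label[node]
    } else {
      ch <- kids[[as.character(node)]]
      ch <- ch[lex_order(vapply(ch, min_label, character(1)))]
      paste0("(", paste(vapply(ch, fmt, character(1)), collapse = ","), ")")
    }
    if (!is.na(elen[node])) body <- paste0(body, sprintf(":%.*f", digits, elen[node]))
    body
  }
  root <- n + 1L
  out <- paste0(fmt(root), ";")
  if (!is.null(path)) {
    writeLines(out, path, sep = "\n")
    return(invisible(out))
  }
  out
}

#' Match symbiont tree leaves to host species for tree comparison
#'
#' Robinson-Foulds comparison needs identical leaf sets: symbiont strain
#' leaves are relabelled by their host species via the strain-host map, and
#' when several strains map to the same host only the lexicographically
#' smallest strain is kept.
#'
#' @param symb_tree `phylo` with strain-labelled leaves.
#' @param strain_host_map data.frame from [read_strain_host_map()].
#' @return `phylo` with host-species leaf labels, one leaf per host.
#' @export
map_symbiont_leaves <- function(symb_tree, strain_host_map) {
  stopifnot(inherits(symb_tree, "phylo"))
  idx <- match(symb_tree$tip.label, strain_host_map$strain_id)
  if (anyNA(idx))
    hs_stop(sprintf("strain(s) missing from the map: %s",
                    paste(symb_tree$tip.label[is.na(idx)], collapse = ", ")),
            "label_error")
  hosts <- strain_host_map$host_species[idx]
  drop <- character(0)
  for (h in unique(hosts[duplicated(hosts)])) {
    strains <- lex_sort(symb_tree$tip.label[hosts == h])
    drop <- c(drop, strains[-1L])
  }
  if (length(drop) > 0L)
    symb_tree <- ape::drop.tip(symb_tree, drop)
  idx <- match(symb_tree$tip.label, strain_host_map$strain_id)
  symb_tree$tip.label <- strain_host_map$host_species[idx]
  symb_tree
}
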