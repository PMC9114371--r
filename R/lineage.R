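# Identical-sequence collapsing and divergence-threshold lineage clustering.
#
# Assemblies of the same symbiont lineage from different host populations
# often yield byte-identical concatenated ortholog sequences; these are
# collapsed to a single representative before tree building. Strains are
# then grouped into lineages: single-linkage connected components of the
# graph whose edges join pairs with divergence (1 - similarity) strictly
# below a threshold.

#' Collapse identical concatenated sequences
#'
#' Groups sequence ids whose concatenated sequences are byte-identical and
#' keeps the lexicographically smallest id of each group as representative.
#' Idempotent: re-collapsing the representatives changes nothing.
#'
#' @param concat A `concat_alignment` (or named character vector of
#'   sequences).
#' @return Object of class `identical_groups`: list with `groups` (list of
#'   character vectors, each sorted; groups ordered by representative) and
#'   `representatives` (character vector, one per group).
#' @export
collapse_identical <- function(concat) {
  records <- if (inherits(concat, "concat_alignment")) concat$records else concat
  if (length(records) < 1L)
    hs_stop("no records to collapse", "empty_input_error")
  groups <- split(names(records), factor(unname(records), levels = unique(unname(records))))
  groups <- lapply(unname(groups), lex_sort)
  reps <- vapply(groups, `[[`, character(1), 1L)
  ord <- lex_order(reps)
  structure(list(groups = groups[ord], representatives = reps[ord]),
            class = "identical_groups")
}

#' @export
print.identical_groups <- function(x, ...) {
  cat(sprintf("<identical_groups> %d ids in %d groups\n",
              length(unlist(x$groups)), length(x$groups)))
  invisible(x)
}

#' Cluster strains into lineages below a divergence threshold
#'
#' Single-linkage clustering on the similarity graph: ids are joined
#' whenever their divergence (1 - similarity) is strictly below
#' `max_divergence`, and lineages are the connected components. Undefined
#' similarities are treated as above-threshold (no edge) with a message.
#'
#' @param mat A `similarity_matrix`.
#' @param max_divergence Divergence threshold in (0, 1); default `2e-4`,
#'   i.e. 0.02 percent.
#' @return Object of class `lineage_clustering`: `clusters` (list of sorted
#'   character vectors, ordered by smallest member), `max_divergence`,
#'   `linkage = "single"`.
#' @export
cluster_lineages <- function(mat, max_divergence = 2e-4) {
  stopifnot(inherits(mat, "similarity_matrix"))
  if (!(max_divergence > 0 && max_divergence < 1))
    hs_stop("max_divergence must lie in (0, 1)", "validation_error")
  div <- 1 - mat$values
  n_na <- sum(is.na(div[upper.tri(div)]))
  if (n_na > 0L)
    message(sprintf("%d undefined similarity value(s) treated as above threshold", n_na))
  adj <- !is.na(div) & div < max_divergence
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  clusters <- split(mat$ids, comp$membership)
  clusters <- lapply(unname(clusters), lex_sort)
  firsts <- vapply(clusters, `[[`, character(1), 1L)
  structure(list(clusters = clusters[lex_order(firsts)],
                 max_divergence = max_divergence,
                 linkage = "single"),
            class = "lineage_clustering")
}

#' @export
print.lineage_clustering <- function(x, ...) {
  cat(sprintf("<lineage_clustering> %d ids in %d lineages (max divergence %g, %s linkage)\n",
              length(unlist(x$clusters)), length(x$clusters),
              x$max_divergence, x$linkage))
  invisible(x)
}

#' Draw one representative per lineage
#'
#' A seeded uniform draw from each cluster; the same seed always returns the
#' same selection.
#'
#' @param clustering A `lineage_clustering`.
#' @param seed Integer seed.
#' @return Character vector of representatives, one per cluster.
#' @export
select_representatives <- function(clustering, seed) {
  stopifnot(inherits(clustering, "lineage_clustering"))
  if (length(clustering$clusters) == 0L) return(character(0))
  with_seed(seed, vapply(clustering$clusters, function(cl) {
    if (length(cl) == 1L) cl else cl[sample.int(length(cl), 1L)]
  }, character(1)))
}

#' Write lineage clusters as TSV
#'
#' Columns `cluster_index`, `member_id`, `is_representative` (0/1).
#'
#' @param clustering A `lineage_clustering`.
#' @param representatives Character vector from [select_representatives()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lineages <- function(clustering, representatives, path) {
  stopifnot(inherits(clustering, "lineage_clustering"),
            length(representatives) == length(clustering$clusters))
  df <- do.call(rbind, lapply(seq_along(clustering$clusters), function(i) {
    members <- clustering$clusters[[i]]
    data.frame(cluster_index = i, member_id = members,
               is_representative = as.integer(members == representatives[i]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
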