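# Pairwise identity under explicit gap conventions, per-gene similarity
# vectors, and descriptive statistics.
#
# Similarity is the fraction of identical aligned columns. Three gap
# conventions are supported:
#   all            - every column counts; a column matches iff the two
#                    characters are equal (gap/gap and N/N both match).
#   exclude_either - columns gapped in either sequence are dropped first.
#   exclude_both   - only columns gapped in both sequences are dropped.
# The "all" mode is the default and mirrors similarity matrices computed on
# full alignments with gaps retained.

GAP_MODES <- c("all", "exclude_either", "exclude_both")

identity_from_chars <- function(av, bv, gap_mode) {
  keep <- switch(gap_mode,
    all            = rep(TRUE, length(av)),
    exclude_either = av != "-" & bv != "-",
    exclude_both   = !(av == "-" & bv == "-"))
  denom <- sum(keep)
  if (denom == 0L) return(NA_real_)
  sum(av[keep] == bv[keep]) / denom
}

#' Pairwise identity of two aligned sequences
#'
#' Fraction of identical columns between two equal-length aligned sequences
#' under the chosen gap convention. Returns `NA` when no columns remain in
#' the denominator (e.g. two all-gap sequences under `exclude_either`).
#'
#' @param a,b Aligned sequences (equal-length strings).
#' @param gap_mode One of `"all"` (default), `"exclude_either"`,
#'   `"exclude_both"`.
#' @return A fraction in \[0, 1\], or `NA` if undefined.
#' @examples
#' pairwise_identity("AC-GT", "AC-GA")                    # 0.8
#' pairwise_identity("AC-GT", "AC-GA", "exclude_either")  # 0.75
#' @export
pairwise_identity <- function(a, b, gap_mode = c("all", "exclude_either", "exclude_both")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b))
    hs_stop(sprintf("sequence lengths differ (%d vs %d)", nchar(a), nchar(b)),
            "alignment_shape_error")
  if (nchar(a) == 0L)
    hs_stop("sequences are empty", "empty_input_error")
  identity_from_chars(strsplit(a, NULL)[[1L]], strsplit(b, NULL)[[1L]], gap_mode)
}

#' Pairwise similarity matrix of an alignment
#'
#' Computes all unordered pairwise identities among aligned sequences.
#'
#' @param records Named character vector of equal-length aligned sequences
#'   (at least two), or a `concat_alignment` / `gene_alignment`.
#' @param gap_mode Gap convention, see [pairwise_identity()].
#' @return An object of class `similarity_matrix`: list with `ids`, `values`
#'   (symmetric numeric matrix, `NA` where undefined) and `gap_mode`.
#' @export
similarity_matrix <- function(records, gap_mode = c("all", "exclude_either", "exclude_both")) {
  gap_mode <- match.arg(gap_mode)
  if (inherits(records, "concat_alignment") || inherits(records, "gene_alignment"))
    records <- records$records
  if (length(records) < 2L)
    hs_stop("similarity_matrix needs at least two sequences",
            "insufficient_input_error")
  lens <- nchar(records)
  if (any(lens != lens[1L]))
    hs_stop("sequences must have equal length", "alignment_shape_error")
  m <- seq_char_matrix(records)
  n <- nrow(m)
  ids <- names(records)
  vals <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  gap <- m == "-"
  for (i in seq_len(n)) {
    for (j in i:n) {
      keep <- switch(gap_mode,
        all            = TRUE,
        exclude_either = !(gap[i, ] | gap[j, ]),
        exclude_both   = !(gap[i, ] & gap[j, ]))
      if (isTRUE(keep)) {
        v <- mean(m[i, ] == m[j, ])
      } else {
        denom <- sum(keep)
        v <- if (denom == 0L) NA_real_ else sum(m[i, keep] == m[j, keep]) / denom
      }
      vals[i, j] <- vals[j, i] <- v
    }
  }
  structure(list(ids = ids, values = vals, gap_mode = gap_mode),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d ids, gap_mode=%s\n", length(x$ids), x$gap_mode))
  invisible(x)
}

#' Write a similarity matrix as CSV
#'
#' Fractions at 6 decimals; undefined entries as `NA`.
#'
#' @param mat A `similarity_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_similarity_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "similarity_matrix"))
  out <- format(round(mat$values, 6), nsmall = 6, trim = TRUE)
  out[is.na(mat$values)] <- "NA"
  df <- data.frame(id = mat$ids, out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene similarity vector for one strain pair
#'
#' For each gene alignment containing both identifiers, the pairwise
#' identity of the pair; genes missing either identifier or yielding an
#' undefined identity are skipped and counted in the `n_skipped` attribute.
#' Values follow lexicographic `gene_id` order.
#'
#' @param genes List of [gene_alignment()] objects.
#' @param id_a,id_b Distinct sequence identifiers.
#' @param gap_mode Gap convention, see [pairwise_identity()].
#' @return Named numeric vector (names are gene ids) with attribute
#'   `n_skipped`.
#' @export
per_gene_pair_similarity <- function(genes, id_a, id_b,
                                     gap_mode = c("all", "exclude_either", "exclude_both")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(length(genes) >= 1L)
  if (identical(id_a, id_b))
    hs_stop("id_a and id_b must differ", "validation_error")
  gids <- vapply(genes, `[[`, character(1), "gene_id")
  genes <- genes[lex_order(gids)]
  vals <- numeric(0)
  skipped <- 0L
  for (g in genes) {
    if (!(id_a %in% names(g$records)) || !(id_b %in% names(g$records))) {
      skipped <- skipped + 1L
      next
    }
    v <- pairwise_identity(g$records[[id_a]], g$records[[id_b]], gap_mode)
    if (is.na(v)) {
      skipped <- skipped + 1L
    } else {
      vals <- c(vals, stats::setNames(v, g$gene_id))
    }
  }
  if (length(vals) == 0L)
    hs_stop(sprintf("no gene contains both '%s' and '%s' with a defined identity",
                    id_a, id_b), "empty_comparison_error")
  attr(vals, "n_skipped") <- skipped
  vals
}

#' Descriptive statistics of a similarity vector
#'
#' Mean, sample standard deviation (denominator n-1; `NA` for a single
#' value), extremes and quartiles by linear interpolation between order
#' statistics — the usual descriptive-statistics convention for per-gene
#' similarity tables.
#'
#' @param values Non-empty numeric vector of fractions.
#' @return Object of class `summary_stats`: list with `n`, `mean`, `sd`,
#'   `min`, `q25`, `q50`, `q75`, `max`.
#' @export
summary_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || all(is.na(values)))
    hs_stop("cannot summarise an empty vector", "empty_input_error")
  values <- values[!is.na(values)]
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(n = length(values),
                 mean = mean(values),
                 sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
                 min = min(values),
                 q25 = q[1L], q50 = q[2L], q75 = q[3L],
                 max = max(values)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "<summary_stats> n=%d mean=%.4f sd=%s min=%.4f q25=%.4f q50=%.4f q75=%.4f max=%.4f\n",
    x$n, x$mean, ifelse(is.na(x$sd), "NA", sprintf("%.4f", x$sd)),
    x$min, x$q25, x$q50, x$q75, x$max))
  invisible(x)
}

#' Cross-group block statistics of a similarity matrix
#'
#' Statistics of the rectangular block of similarities between two disjoint
#' id groups: overall mean/min/max, and the mean and mode of the per-row
#' maxima (each group-A member's best match in group B). The mode is taken
#' after rounding to 2 decimal places in percent; ties break toward the
#' smallest value.
#'
#' @param mat A `similarity_matrix`.
#' @param group_a,group_b Disjoint, non-empty character vectors of ids
#'   present in `mat`.
#' @return Object of class `cross_group_stats`: `overall_mean`,
#'   `overall_min`, `overall_max`, `row_max_mean`, `row_max_mode`
#'   (fractions).
#' @export
cross_group_stats <- function(mat, group_a, group_b) {
  stopifnot(inherits(mat, "similarity_matrix"))
  if (length(group_a) == 0L || length(group_b) == 0L)
    hs_stop("both groups must be non-empty", "validation_error")
  if (length(intersect(group_a, group_b)) > 0L)
    hs_stop("groups must be disjoint", "validation_error")
  missing <- setdiff(c(group_a, group_b), mat$ids)
  if (length(missing) > 0L)
    hs_stop(sprintf("ids not in matrix: %s", paste(missing, collapse = ", ")),
            "validation_error")
  block <- mat$values[group_a, group_b, drop = FALSE]
  row_max <- apply(block, 1L, max, na.rm = TRUE)
  rounded <- round(row_max * 100, 2)
  tab <- table(rounded)
  best <- max(tab)
  mode_pct <- min(as.numeric(names(tab)[tab == best]))
  structure(list(overall_mean = mean(block, na.rm = TRUE),
                 overall_min = min(block, na.rm = TRUE),
                 overall_max = max(block, na.rm = TRUE),
                 row_max_mean = mean(row_max),
                 row_max_mode = mode_pct / 100),
            class = "cross_group_stats")
}
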