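# Aligned-FASTA input/output and supermatrix concatenation.
#
# Sequences are stored as plain uppercase character strings over the
# six-letter alphabet {A, C, G, T, N, -}; any other symbol (including U and
# IUPAC ambiguity codes) is mapped to N on input so that identity counting
# downstream is exact character equality.

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct a per-gene alignment object
#'
#' A `gene_alignment` holds the aligned sequences of one single-copy
#' ortholog: a named character vector of equal-length uppercase strings over
#' `{A,C,G,T,N,-}` plus the gene identifier.
#'
#' @param gene_id Single string naming the gene.
#' @param records Named character vector of aligned sequences; names are the
#'   strain/sequence identifiers and must be unique.
#' @return An object of class `gene_alignment` with fields `gene_id`,
#'   `records` and `n_columns`.
#' @export
gene_alignment <- function(gene_id, records) {
  if (length(records) == 0L)
    hs_stop("alignment has no records", "empty_input_error")
  if (is.null(names(records)) || anyNA(names(records)) || any(names(records) == ""))
    hs_stop("all records must be named", "validation_error")
  if (anyDuplicated(names(records)))
    hs_stop(sprintf("duplicate sequence id '%s' in gene '%s'",
                    names(records)[duplicated(names(records))][1L], gene_id),
            "duplicate_id_error")
  len <- nchar(records)
  if (any(len != len[1L])) {
    bad <- names(records)[which(len != len[1L])[1L]]
    hs_stop(sprintf("record '%s' in gene '%s' has length %d, expected %d",
                    bad, gene_id, nchar(records[[bad]]), len[1L]),
            "alignment_shape_error")
  }
  if (len[1L] == 0L)
    hs_stop(sprintf("gene '%s' has zero alignment columns", gene_id),
            "empty_input_error")
  structure(list(gene_id = as.character(gene_id),
                 records = records,
                 n_columns = unname(len[1L])),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d sequences x %d columns\n",
              x$gene_id, length(x$records), x$n_columns))
  invisible(x)
}

#' Read an aligned FASTA file as a gene alignment
#'
#' Sequences are uppercased; characters outside `{A,C,G,T,N,-}` are replaced
#' by `N` with a warning reporting the replacement count. Header lines are
#' truncated at the first whitespace.
#'
#' @param path Path to an aligned FASTA file.
#' @param gene_id Gene identifier; defaults to the file name without
#'   extension.
#' @return A [gene_alignment()].
#' @export
read_fasta_alignment <- function(path,
                                 gene_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path))
    hs_stop(sprintf("file not found: %s", path), "io_error")
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    hs_stop(sprintf("no FASTA records in %s", path), "empty_input_error")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  n_bad <- sum(nchar(seqs)) - sum(nchar(gsub("[^ACGTN-]", "", seqs)))
  if (n_bad > 0L) {
    seqs <- gsub("[^ACGTN-]", "N", seqs)
    warning(sprintf("%s: %d non-DNA character(s) replaced with N", path, n_bad))
  }
  names(seqs) <- ids
  gene_alignment(gene_id, seqs)
}

#' Write sequences to FASTA
#'
#' Writes a named character vector of sequences as FASTA with fixed line
#' wrapping and LF line endings. Round-trip stable with
#' [read_fasta_alignment()].
#'
#' @param records Named character vector of sequences (non-empty).
#' @param path Output file path.
#' @param line_width Sequence characters per line (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  if (length(records) == 0L)
    hs_stop("no records to write", "empty_input_error")
  stopifnot(line_width >= 1L)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  for (i in seq_along(records)) {
    s <- records[[i]]
    starts <- seq(1L, nchar(s), by = line_width)
    lines <- substring(s, starts, pmin(starts + line_width - 1L, nchar(s)))
    writeLines(c(paste0(">", names(records)[i]), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Joins gene alignments by sequence identifier into one concatenated
#' alignment with a partition map. Genes are always concatenated in
#' lexicographic `gene_id` order, so the result is independent of input
#' order. The identifier universe is the union of identifiers across genes;
#' strains missing from a gene are either padded with gaps (`pad_gaps`,
#' default, keeping the maximum possible number of genes per strain) or
#' dropped from the result entirely (`drop_strain`).
#'
#' @param genes List of [gene_alignment()] objects with unique `gene_id`s.
#' @param missing_policy `"pad_gaps"` or `"drop_strain"`.
#' @return An object of class `concat_alignment` with fields `records`
#'   (named character vector), `partitions` (data.frame `gene_id`, `start`,
#'   `end`; 0-based half-open) and `total_length`.
#' @export
concatenate_by_id <- function(genes, missing_policy = c("pad_gaps", "drop_strain")) {
  missing_policy <- match.arg(missing_policy)
  if (length(genes) == 0L)
    hs_stop("no gene alignments supplied", "empty_input_error")
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_alignment")))
  gids <- vapply(genes, `[[`, character(1), "gene_id")
  if (anyDuplicated(gids))
    hs_stop("gene_ids must be unique", "duplicate_id_error")
  genes <- genes[lex_order(gids)]

  all_ids <- lex_sort(unique(unlist(lapply(genes, function(g) names(g$records)))))
  if (missing_policy == "drop_strain") {
    keep <- Reduce(intersect, lapply(genes, function(g) names(g$records)), all_ids)
    if (length(keep) == 0L)
      hs_stop("drop_strain left no sequence present in every gene",
              "empty_result_error")
    all_ids <- lex_sort(keep)
  }

  pieces <- lapply(genes, function(g) {
    out <- g$records[all_ids]
    out[is.na(out)] <- strrep("-", g$n_columns)
    unname(out)
  })
  records <- do.call(paste0, pieces)
  names(records) <- all_ids

  lens <- vapply(genes, `[[`, integer(1), "n_columns")
  ends <- cumsum(lens)
  partitions <- data.frame(gene_id = vapply(genes, `[[`, character(1), "gene_id"),
                           start = c(0L, ends[-length(ends)]),
                           end = ends,
                           stringsAsFactors = FALSE)
  structure(list(records = records,
                 partitions = partitions,
                 total_length = unname(ends[length(ends)])),
            class = "concat_alignment")
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("<concat_alignment> %d sequences x %d columns (%d genes)\n",
              length(x$records), x$total_length, nrow(x$partitions)))
  invisible(x)
}

#' Extract one gene's columns from a concatenated alignment
#'
#' @param concat A `concat_alignment`.
#' @param gene_id Gene to slice out.
#' @return Named character vector of the gene's columns for every strain.
#' @export
slice_gene <- function(concat, gene_id) {
  stopifnot(inherits(concat, "concat_alignment"))
  i <- match(gene_id, concat$partitions$gene_id)
  if (is.na(i))
    hs_stop(sprintf("gene '%s' not in partition map", gene_id), "validation_error")
  substr(concat$records, concat$partitions$start[i] + 1L, concat$partitions$end[i])
}

#' Write a partition map as TSV
#'
#' Columns `gene_id`, `start`, `end` with 0-based half-open coordinates.
#'
#' @param concat A `concat_alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_partition_map <- function(concat, path) {
  stopifnot(inherits(concat, "concat_alignment"))
  utils::write.table(concat$partitions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a strain-to-host mapping table
#'
#' Expects a TSV with header `strain_id`, `host_species`, `host_taxon`.
#' Every strain must map to exactly one host species.
#'
#' @param path Path to the TSV file.
#' @return data.frame with those three character columns.
#' @export
read_strain_host_map <- function(path) {
  if (!file.exists(path))
    hs_stop(sprintf("strain-host map not found: %s", path), "configuration_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("strain_id", "host_species", "host_taxon")
  if (!identical(names(df)[seq_along(need)], need))
    hs_stop(sprintf("strain-host map must have header '%s'",
                    paste(need, collapse = "\\t")), "configuration_error")
  if (anyDuplicated(df$strain_id))
    hs_stop("strain_id values must be unique in the strain-host map",
            "validation_error")
  df[need]
}
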