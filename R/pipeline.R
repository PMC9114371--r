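# End-to-end pipeline: concatenation -> similarity -> dedup -> lineages ->
# per-pair statistics -> host-shift calls -> NJ trees -> RF, with a full
# artifact bundle and manifest.

#' Pipeline configuration
#'
#' @param symb_gene_dir Directory of per-gene symbiont FASTA alignments.
#' @param host_gene_dir Directory of per-gene host FASTA alignments.
#' @param strain_host_map Path to the strain-host TSV
#'   (see [read_strain_host_map()]).
#' @param out_dir Output directory.
#' @param gap_mode Gap convention for similarity, see [pairwise_identity()].
#' @param max_divergence Lineage clustering threshold (default 2e-4).
#' @param thresholds A [threshold_config()].
#' @param n_boot Bootstrap resamples for per-pair confidence intervals.
#' @param seed Integer seed (representative selection, bootstrap).
#' @param verbose Log stage progress to standard error.
#' @return Object of class `run_config`.
#' @export
run_config <- function(symb_gene_dir, host_gene_dir, strain_host_map, out_dir,
                       gap_mode = "all", max_divergence = 2e-4,
                       thresholds = threshold_config(), n_boot = 1000L,
                       seed = 1L, verbose = TRUE) {
  for (p in c(symb_gene_dir, host_gene_dir)) {
    if (!dir.exists(p))
      hs_stop(sprintf("[config] gene directory not found: %s", p),
              "configuration_error")
  }
  if (!file.exists(strain_host_map))
    hs_stop(sprintf("[config] strain-host map not found: %s", strain_host_map),
            "configuration_error")
  stopifnot(inherits(thresholds, "threshold_config"))
  structure(list(symb_gene_dir = symb_gene_dir, host_gene_dir = host_gene_dir,
                 strain_host_map = strain_host_map, out_dir = out_dir,
                 gap_mode = gap_mode, max_divergence = max_divergence,
                 thresholds = thresholds, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

read_gene_dir <- function(dir, stage) {
  files <- lex_sort(list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  if (length(files) == 0L)
    hs_stop(sprintf("[%s] no FASTA files in %s", stage, dir),
            "data_validation_error")
  lapply(files, read_fasta_alignment)
}

subset_similarity <- function(mat, ids) {
  structure(list(ids = ids, values = mat$values[ids, ids, drop = FALSE],
                 gap_mode = mat$gap_mode),
            class = "similarity_matrix")
}

#' Run the full host-shift detection pipeline
#'
#' Reads per-gene symbiont and host alignments plus the strain-host map,
#' then: concatenates each set into a supermatrix, computes concatenated
#' similarity matrices, collapses identical symbiont sequences, clusters the
#' remaining strains into lineages and draws one representative per lineage,
#' computes per-gene similarity statistics for every representative pair and
#' the corresponding host pair, classifies each pair
#' (host shift / codivergence / uninformative), calibrates the symbiont/host
#' clock ratio from the codiverging pairs, builds neighbor-joining trees
#' from 1 - similarity and measures their Robinson-Foulds incongruence.
#' All artifacts are written under `config$out_dir` together with
#' `report.tsv` and a JSON manifest (parameters, seed, file checksums).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every intermediate object
#'   (`symb_concat`, `host_concat`, `symb_sim`, `host_sim`,
#'   `identical_groups`, `clustering`, `representatives`, `pair_stats`,
#'   `calls`, `hs_host_fraction`, `clock`, `trees`, `rf`, `report`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(stage) {
    if (config$verbose)
      message(sprintf("[%s] +%.1fs", stage,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  log_stage("read")
  symb_genes <- read_gene_dir(config$symb_gene_dir, "read")
  host_genes <- read_gene_dir(config$host_gene_dir, "read")
  map <- read_strain_host_map(config$strain_host_map)

  log_stage("concat")
  symb_concat <- concatenate_by_id(symb_genes, "pad_gaps")
  host_concat <- concatenate_by_id(host_genes, "pad_gaps")

  log_stage("similarity")
  symb_sim <- similarity_matrix(symb_concat, config$gap_mode)
  host_sim <- similarity_matrix(host_concat, config$gap_mode)

  log_stage("collapse")
  ident <- collapse_identical(symb_concat)

  log_stage("lineages")
  rep_sim <- subset_similarity(symb_sim, ident$representatives)
  clustering <- cluster_lineages(rep_sim, config$max_divergence)
  reps <- select_representatives(clustering, config$seed)

  log_stage("pairs")
  host_of <- stats::setNames(map$host_species, map$strain_id)
  if (anyNA(host_of[reps]))
    hs_stop("[pairs] representative strain missing from the strain-host map",
            "data_validation_error")
  pair_stats <- list()
  rows <- list()
  if (length(reps) >= 2L) {
    cmb <- utils::combn(lex_sort(reps), 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1L, k]; b <- cmb[2L, k]
      ha <- host_of[[a]]; hb <- host_of[[b]]
      if (ha == hb) next  # same host species: no host comparison exists
      sv <- per_gene_pair_similarity(symb_genes, a, b, config$gap_mode)
      hv <- per_gene_pair_similarity(host_genes, ha, hb, config$gap_mode)
      ss <- summary_stats(sv)
      hs <- summary_stats(hv)
      ci <- bootstrap_mean_ci(sv, config$n_boot, config$seed + k)
      pair_stats[[length(pair_stats) + 1L]] <-
        list(symb_pair = c(a, b), host_pair = c(ha, hb),
             symb_stats = ss, host_stats = hs,
             symb_values = sv, host_values = hv, ci = ci)
      rows[[length(rows) + 1L]] <-
        data.frame(symb_id_a = a, symb_id_b = b, host_a = ha, host_b = hb,
                   symb_mean = ss$mean, host_mean = hs$mean,
                   ci_low = ci[["low"]], ci_high = ci[["high"]],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    hs_stop("[pairs] no representative pair with distinct host species",
            "data_validation_error")
  per_pair <- do.call(rbind, rows)

  log_stage("detect")
  det <- detect_all(per_pair, config$thresholds)
  calls <- det$calls
  codiv <- calls$label == "codivergence"
  clock <- NULL
  calls$expected_symb_similarity <- NA_real_
  if (any(codiv)) {
    clock <- calibrate_clock_ratio(data.frame(
      host_divergence = 1 - calls$host_mean[codiv],
      symb_divergence = 1 - calls$symb_mean[codiv]))
    calls$expected_symb_similarity <-
      expected_symb_similarity(1 - calls$host_mean, clock)
  }
  calls <- calls[, c("symb_id_a", "symb_id_b", "host_a", "host_b",
                     "symb_mean", "host_mean", "expected_symb_similarity",
                     "label", "ci_low", "ci_high")]

  log_stage("trees")
  trees <- list(symbiont = NULL, host = NULL)
  rf <- NULL
  hosts <- unique(host_of[reps])
  if (length(reps) >= 3L && length(hosts) >= 3L) {
    d_symb <- 1 - symb_sim$values[reps, reps, drop = FALSE]
    diag(d_symb) <- 0
    trees$symbiont <- nj_tree(d_symb)
    d_host <- 1 - host_sim$values[hosts, hosts, drop = FALSE]
    diag(d_host) <- 0
    trees$host <- nj_tree(d_host)
    mapped <- map_symbiont_leaves(trees$symbiont, map)
    rf <- robinson_foulds(mapped, trees$host)
  }

  log_stage("write")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_similarity_matrix(symb_sim, file.path(out, "simmatrix_symbiont.csv"))
  write_similarity_matrix(host_sim, file.path(out, "simmatrix_host.csv"))
  write_partition_map(symb_concat, file.path(out, "partitions_symbiont.tsv"))
  write_partition_map(host_concat, file.path(out, "partitions_host.tsv"))
  ident_df <- do.call(rbind, lapply(seq_along(ident$groups), function(i) {
    data.frame(group_index = i, member_id = ident$groups[[i]],
               is_representative = as.integer(ident$groups[[i]] == ident$representatives[i]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(ident_df, file.path(out, "identical_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_lineages(clustering, reps, file.path(out, "lineages.tsv"))
  calls_out <- calls
  for (col in c("symb_mean", "host_mean", "expected_symb_similarity",
                "ci_low", "ci_high"))
    calls_out[[col]] <- sprintf("%.6f", calls_out[[col]])
  utils::write.table(calls_out, file.path(out, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(trees$symbiont)) {
    write_newick(trees$symbiont, file.path(out, "symbiont_nj.nwk"))
    write_newick(trees$host, file.path(out, "host_nj.nwk"))
    utils::write.table(data.frame(rf = rf$rf, normalized = rf$normalized,
                                  n_leaves = rf$n_leaves),
                       file.path(out, "rf.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- data.frame(
    key = c("n_symbiont_strains", "n_host_species", "n_symbiont_genes",
            "n_host_genes", "n_identical_groups", "n_lineages",
            "n_pairs_classified", "n_host_shift_calls", "hs_host_fraction",
            "clock_ratio", "rf", "rf_normalized", "gap_mode",
            "max_divergence", "symb_min_similarity", "host_max_similarity",
            "seed"),
    value = c(length(symb_concat$records), length(host_concat$records),
              length(symb_genes), length(host_genes),
              length(ident$groups), length(clustering$clusters),
              nrow(calls), sum(calls$label == "host_shift"),
              det$hs_host_fraction,
              if (is.null(clock)) NA else signif(clock$ratio_c, 6),
              if (is.null(rf)) NA else rf$rf,
              if (is.null(rf)) NA else signif(rf$normalized, 6),
              config$gap_mode, config$max_divergence,
              config$thresholds$symb_min_similarity,
              config$thresholds$host_max_similarity, config$seed),
    stringsAsFactors = FALSE)
  utils::write.table(report, file.path(out, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- lex_sort(setdiff(list.files(out, recursive = TRUE), "manifest.json"))
  manifest <- list(
    package = "hostshiftr",
    version = as.character(utils::packageVersion("hostshiftr")),
    seed = config$seed,
    parameters = list(gap_mode = config$gap_mode,
                      max_divergence = config$max_divergence,
                      symb_min_similarity = config$thresholds$symb_min_similarity,
                      host_max_similarity = config$thresholds$host_max_similarity,
                      n_boot = config$n_boot),
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(file.path(out, f))))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(symb_concat = symb_concat, host_concat = host_concat,
                 symb_sim = symb_sim, host_sim = host_sim,
                 identical_groups = ident, clustering = clustering,
                 representatives = reps, pair_stats = pair_stats,
                 calls = calls, hs_host_fraction = det$hs_host_fraction,
                 clock = clock, trees = trees, rf = rf, report = report,
                 manifest = manifest))
}

#' Render a descriptive-statistics table for species pairs
#'
#' One column block per species pair with Host and Symbiont sub-columns;
#' rows `n_genes`, `Mean`, `Std`, `Min`, `25%`, `50%`, `75%`, `Max`;
#' percentages with two decimals, `NA` where a statistic is undefined.
#'
#' @param summaries Non-empty list; each element a list with `label`
#'   (string), `host` and `symb` ([summary_stats()] objects).
#' @return data.frame with a `statistic` column plus two columns per pair.
#' @export
render_pair_table <- function(summaries) {
  if (length(summaries) == 0L)
    hs_stop("no summaries to render", "empty_input_error")
  pct <- function(x) if (is.na(x)) "NA" else sprintf("%.2f%%", 100 * x)
  col_for <- function(st) c(as.character(st$n), pct(st$mean), pct(st$sd),
                            pct(st$min), pct(st$q25), pct(st$q50),
                            pct(st$q75), pct(st$max))
  out <- data.frame(statistic = c("n_genes", "Mean", "Std", "Min",
                                  "25%", "50%", "75%", "Max"),
                    stringsAsFactors = FALSE)
  for (s in summaries) {
    out[[paste0(s$label, ".Host")]] <- col_for(s$host)
    out[[paste0(s$label, ".Symbiont")]] <- col_for(s$symb)
  }
  out
}
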