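# Host-shift classification: contrast symbiont and host per-gene similarity
# under a proportional molecular clock.
#
# Vertically transmitted endosymbionts codiverge with their hosts, so under
# a clock the symbiont divergence of a host pair is proportional to the host
# divergence. A symbiont pair that is far more similar than its host pair
# can only be explained by recent horizontal transfer (a host shift): there
# is no vertical route between distantly related hosts. Host pairs that are
# themselves very similar are uninformative, because vertical transmission
# through a recent common ancestor, hybridisation or introgression cannot be
# excluded.

#' Decision thresholds for host-shift classification
#'
#' `symb_min_similarity` is the minimum mean symbiont similarity required to
#' call a host shift; `host_max_similarity` is the maximum mean host
#' similarity at which the host pair is still considered distant enough to
#' be informative. Defaults (0.93 / 0.80) reflect the observed separation
#' between shifted symbiont lineages (93-99.9% similar) and their distantly
#' related hosts (60-80% similar).
#'
#' @param symb_min_similarity Fraction in (0, 1); default 0.93.
#' @param host_max_similarity Fraction in (0, 1); default 0.80.
#' @return Object of class `threshold_config`.
#' @export
threshold_config <- function(symb_min_similarity = 0.93, host_max_similarity = 0.80) {
  if (!(symb_min_similarity > 0 && symb_min_similarity < 1) ||
      !(host_max_similarity > 0 && host_max_similarity < 1))
    hs_stop("thresholds must lie in (0, 1)", "validation_error")
  structure(list(symb_min_similarity = symb_min_similarity,
                 host_max_similarity = host_max_similarity),
            class = "threshold_config")
}

stats_mean <- function(x) {
  if (inherits(x, "summary_stats")) x$mean
  else if (is.numeric(x) && length(x) == 1L) as.numeric(x)
  else summary_stats(x)$mean
}

#' Classify one host pair as host shift, codivergence or uninformative
#'
#' Pure function of the two mean similarities and the thresholds:
#' host mean above `host_max_similarity` -> `"uninformative"` (hosts too
#' close to discriminate vertical from horizontal transfer); otherwise
#' symbiont mean at or above `symb_min_similarity` -> `"host_shift"`;
#' otherwise `"codivergence"`.
#'
#' @param symb_stats,host_stats [summary_stats()] objects, per-gene
#'   similarity vectors, or single mean fractions.
#' @param thresholds A [threshold_config()].
#' @return `"host_shift"`, `"codivergence"` or `"uninformative"`.
#' @examples
#' classify_pair(0.9851, 0.4836)  # "host_shift"
#' @export
classify_pair <- function(symb_stats, host_stats, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  symb_mean <- stats_mean(symb_stats)
  host_mean <- stats_mean(host_stats)
  if (host_mean > thresholds$host_max_similarity) "uninformative"
  else if (symb_mean >= thresholds$symb_min_similarity) "host_shift"
  else "codivergence"
}

#' Calibrate the symbiont/host clock ratio
#'
#' The clock ratio c is the symbiont divergence accumulated per unit host
#' divergence under codivergence. It is estimated as the median of
#' `symb_divergence / host_divergence` over reference codiverging pairs.
#'
#' @param reference_pairs data.frame (or 2-column matrix) with columns
#'   `host_divergence` and `symb_divergence`.
#' @return Object of class `clock_model` with field `ratio_c`.
#' @export
calibrate_clock_ratio <- function(reference_pairs) {
  if (is.matrix(reference_pairs))
    reference_pairs <- data.frame(host_divergence = reference_pairs[, 1L],
                                  symb_divergence = reference_pairs[, 2L])
  stopifnot(all(c("host_divergence", "symb_divergence") %in% names(reference_pairs)))
  ok <- reference_pairs$host_divergence > 0
  if (!any(ok))
    hs_stop("all host divergences are zero; cannot calibrate clock ratio",
            "calibration_error")
  ratio <- stats::median(reference_pairs$symb_divergence[ok] /
                           reference_pairs$host_divergence[ok])
  structure(list(ratio_c = ratio), class = "clock_model")
}

#' Expected symbiont similarity under codivergence
#'
#' Linear clock expectation: `max(0, 1 - ratio_c * host_divergence)`,
#' reported alongside each call as the similarity a codiverging symbiont
#' pair would show.
#'
#' @param host_divergence Fractions in \[0, 1\] (vectorised).
#' @param clock A `clock_model` from [calibrate_clock_ratio()].
#' @return Expected symbiont similarity fractions.
#' @export
expected_symb_similarity <- function(host_divergence, clock) {
  stopifnot(inherits(clock, "clock_model"),
            all(host_divergence >= 0 & host_divergence <= 1))
  pmax(0, 1 - clock$ratio_c * host_divergence)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Seeded and reproducible percentile interval over resampled means.
#'
#' @param values Non-empty numeric vector.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 1000L, seed = 1L, level = 0.95) {
  if (length(values) == 0L)
    hs_stop("cannot bootstrap an empty vector", "empty_input_error")
  if (n_boot < 100L)
    hs_stop("n_boot must be at least 100", "validation_error")
  means <- with_seed(seed, {
    idx <- matrix(sample.int(length(values), length(values) * n_boot, replace = TRUE),
                  nrow = n_boot)
    rowMeans(matrix(values[idx], nrow = n_boot))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
  c(low = ci[1L], high = ci[2L])
}

#' Classify every host pair and summarise the host-shift fraction
#'
#' Applies [classify_pair()] to each row and reports, in percent with one
#' decimal, the fraction of distinct host species that appear in at least
#' one host-shift call.
#'
#' @param per_pair data.frame with columns `symb_id_a`, `symb_id_b`,
#'   `host_a`, `host_b`, `symb_mean`, `host_mean` (means as fractions).
#' @param thresholds A [threshold_config()].
#' @return List with `calls` (the input plus a `label` column) and
#'   `hs_host_fraction` (percent, one decimal).
#' @export
detect_all <- function(per_pair, thresholds = threshold_config()) {
  need <- c("symb_id_a", "symb_id_b", "host_a", "host_b", "symb_mean", "host_mean")
  stopifnot(is.data.frame(per_pair), all(need %in% names(per_pair)),
            nrow(per_pair) >= 1L)
  labels <- mapply(function(s, h) classify_pair(s, h, thresholds),
                   per_pair$symb_mean, per_pair$host_mean)
  calls <- per_pair
  calls$label <- unname(labels)
  species <- unique(c(per_pair$host_a, per_pair$host_b))
  hs_rows <- calls$label == "host_shift"
  flagged <- unique(c(calls$host_a[hs_rows], calls$host_b[hs_rows]))
  frac <- round(100 * length(flagged) / length(species), 1)
  list(calls = calls, hs_host_fraction = frac)
}
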