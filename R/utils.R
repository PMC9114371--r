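# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' seeded operations never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# classed conditions so callers/tests can distinguish failure modes
hs_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hostshiftr_error")))
}

# locale-independent lexicographic sort (C collation via radix)
lex_sort <- function(x) sort(x, method = "radix")

lex_order <- function(x) order(x, method = "radix")

# split sequences into a character matrix, one row per sequence
seq_char_matrix <- function(records) {
  chars <- strsplit(unname(records), NULL)
  matrix(unlist(chars), nrow = length(records), byrow = TRUE,
         dimnames = list(names(records), NULL))
}

#' Jukes-Cantor expected identity and distance
#'
#' Under the JC69 model, two sequences separated by `d` expected
#' substitutions per site are identical at a site with probability
#' 1/4 + (3/4) exp(-4 d / 3). `jc_distance` is the inverse map from an
#' observed identity fraction back to an evolutionary distance.
#'
#' @param d Non-negative numeric vector of distances (substitutions/site).
#' @param identity Numeric vector of identity fractions in (1/4, 1].
#' @return Numeric vector: expected identity in \[1/4, 1\] or distance >= 0
#'   (`NaN` where identity <= 1/4, beyond JC saturation).
#' @examples
#' jc_expected_identity(0)     # 1
#' jc_expected_identity(0.5)   # ~0.635
#' jc_distance(jc_expected_identity(0.2))
#' @export
jc_expected_identity <- function(d) {
  stopifnot(is.numeric(d), all(d >= 0))
  0.25 + 0.75 * exp(-4 * d / 3)
}

#' @rdname jc_expected_identity
#' @export
jc_distance <- function(identity) {
  stopifnot(is.numeric(identity), all(identity <= 1))
  p <- 1 - identity
  -0.75 * log(1 - 4 * p / 3)
}
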