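#' @importFrom rlang abort warn %||%
#' @importFrom stats pt median setNames
NULL

#' Column-wise medians of a numeric matrix
#'
#' Fast path used by the enrichment bootstrap: a single radix sort orders
#' entries within columns, so no per-column R call is needed.
#'
#' @param m numeric matrix.
#' @return numeric vector of length `ncol(m)`.
#' @keywords internal
#' @noRd
col_medians <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(as.numeric(m[1L, ]))
  s <- matrix(m[order(col(m), m, method = "radix")], nrow = n)
  h <- n %/% 2L
  if (n %% 2L == 1L) s[h + 1L, ] else (s[h, ] + s[h + 1L, ]) / 2
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement between two labellings of the
#' same entities; 1 means identical partitions, 0 is the chance level.
#'
#' @param a,b vectors of cluster labels (any atomic type), equal length.
#' @return a single number in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Derive n child seeds (< 2^31) from one parent seed without disturbing the
# caller's RNG state.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Run code under a seed when one is given, otherwise use the current stream.
with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
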