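#' Multivariate random forest proximity for guided clustering
#'
#' Guided clustering combines the binary map matrix with matched expression
#' profiles. Each tree of the forest recursively splits the set of mRNAs on
#' a map-matrix column (miRNA): the mRNAs targeted by that miRNA form one
#' child, the rest the other. Candidate columns are scored by the drop in
#' expression-space node homogeneity, and at each node only a random subset
#' of `num_cov` columns is screened. Two mRNAs are proximal in one tree if
#' they share a terminal node; the forest proximity is the mean of that
#' indicator over `n_trees` trees, and `1 - proximity` is the guided
#' dissimilarity.
#'
#' @name mrf
NULL

#' Expression-space homogeneity of a node
#'
#' Sum over the node's members of the squared Euclidean distance between
#' each member's expression vector and the node's per-condition mean vector.
#' Zero iff all members share one expression profile.
#'
#' @param expr_rows numeric matrix, one row per member, one column per
#'   condition.
#' @return a non-negative number.
#' @export
node_homogeneity <- function(expr_rows) {
  expr_rows <- as.matrix(expr_rows)
  n <- nrow(expr_rows)
  if (n == 0L) abort("node homogeneity is undefined for an empty node")
  # sum((x - xbar)^2) = sum(x^2) - n * sum(xbar^2), per condition
  max(0, sum(expr_rows^2) - n * sum(colMeans(expr_rows)^2))
}

#' Score one candidate split of a tree node
#'
#' Splitting node members on map column `covariate` sends the targeted
#' members to one child and the rest to the other; the score is the drop in
#' homogeneity `S(parent) - S(child1) - S(child2)` (never negative). The
#' split is inadmissible — score `NA` — when either child is empty or
#' smaller than `node_size`.
#'
#' @param members integer row indices of the node's members (row bootstrap
#'   may repeat an index).
#' @param covariate map-matrix column index.
#' @param map a [map_matrix()].
#' @param expr an [expression_matrix()] row-aligned with `map`.
#' @param node_size minimum admissible child size.
#' @return the score, or `NA_real_` for an inadmissible split.
#' @export
split_score <- function(members, covariate, map, expr, node_size = 1L) {
  if (length(members) < 2L) abort("a node needs >= 2 members to be split")
  targeted <- unclass(map)[members, covariate] == 1
  n1 <- sum(targeted)
  n2 <- length(members) - n1
  if (n1 == 0L || n2 == 0L || n1 < node_size || n2 < node_size) {
    return(NA_real_)
  }
  e <- unclass(expr)[members, , drop = FALSE]
  node_homogeneity(e) -
    node_homogeneity(e[targeted, , drop = FALSE]) -
    node_homogeneity(e[!targeted, , drop = FALSE])
}

#' Grow one multivariate regression tree
#'
#' Recursive splitting from a root holding `rows` (all map rows by default).
#' At each node `num_cov` distinct columns are drawn uniformly without
#' replacement and the admissible split with the highest score is taken
#' (ties broken uniformly at random); a node with at most `node_size`
#' members, or no admissible sampled split, is terminal. Uses the current
#' RNG stream.
#'
#' @inheritParams split_score
#' @param num_cov number of candidate columns screened per node; default
#'   `round(sqrt(ncol(map)))`.
#' @param rows row indices at the root (duplicates allowed, for row
#'   bootstrap).
#' @return a nested list of nodes; each node has `members`, and either
#'   `terminal = TRUE` or `split` (the column index) plus `left`/`right`
#'   subtrees (`left` = targeted members).
#' @export
grow_tree <- function(map, expr, node_size = 5L, num_cov = NULL, rows = NULL) {
  X <- ncol(map)
  num_cov <- num_cov %||% max(1L, round(sqrt(X)))
  if (num_cov > X) abort("num_cov cannot exceed the number of map columns")
  rows <- rows %||% seq_len(nrow(map))
  mapv <- unclass(map)
  exprv <- unclass(expr)

  build <- function(members) {
    if (length(members) <= node_size) {
      return(list(members = members, terminal = TRUE))
    }
    cand <- sample.int(X, num_cov)
    scores <- vapply(cand, function(h) {
      split_score(members, h, map, expr, node_size)
    }, numeric(1L))
    ok <- !is.na(scores)
    if (!any(ok)) return(list(members = members, terminal = TRUE))
    best <- max(scores[ok])
    tied <- cand[ok & scores >= best - 1e-12 * max(1, abs(best))]
    h <- tied[sample.int(length(tied), 1L)]
    targeted <- mapv[members, h] == 1
    list(members = members, terminal = FALSE, split = h,
         left = build(members[targeted]),
         right = build(members[!targeted]))
  }
  build(rows)
}

# Assign every map row to a terminal node of a tree by traversal; returns an
# integer label per row. Works whether or not the tree was grown on a
# bootstrap sample of the rows.
terminal_labels <- function(tree, map) {
  mapv <- unclass(map)
  labels <- integer(nrow(mapv))
  counter <- 0L
  descend <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (isTRUE(node$terminal)) {
      counter <<- counter + 1L
      labels[idx] <<- counter
      return(invisible())
    }
    targeted <- mapv[idx, node$split] == 1
    descend(node$left, idx[targeted])
    descend(node$right, idx[!targeted])
    invisible()
  }
  descend(tree, seq_len(nrow(mapv)))
  labels
}

#' Forest proximity matrix
#'
#' Grows `n_trees` trees with independent covariate-sampling streams derived
#' from `seed` and returns the mean same-terminal-node indicator: entry
#' \[a, b\] is the fraction of trees in which rows a and b end in the same
#' terminal node (diagonal all 1).
#'
#' @inheritParams grow_tree
#' @param n_trees number of trees in the forest.
#' @param seed integer seed for the forest.
#' @param row_bootstrap draw each tree's training rows with replacement
#'   (off by default: randomness then comes only from covariate
#'   subsampling).
#' @return a symmetric matrix with class `proximity_matrix`, entries in
#'   \[0, 1\], labelled by the map row identifiers.
#' @export
forest_proximity <- function(map, expr, n_trees = 100L, node_size = 5L,
                             num_cov = NULL, seed = NULL,
                             row_bootstrap = FALSE) {
  stopifnot(n_trees >= 1L)
  if (nrow(map) != nrow(expr) || !identical(rownames(map), rownames(expr))) {
    abort("map and expression inputs must be row-aligned (see align_entities)")
  }
  Y <- nrow(map)
  tree_seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1L),
                             n_trees)
  prox <- matrix(0, Y, Y)
  for (g in seq_len(n_trees)) {
    lab <- withr::with_seed(tree_seeds[g], {
      rows <- if (row_bootstrap) sample.int(Y, Y, replace = TRUE) else NULL
      tree <- grow_tree(map, expr, node_size = node_size, num_cov = num_cov,
                        rows = rows)
      terminal_labels(tree, map)
    })
    prox <- prox + outer(lab, lab, "==")
  }
  prox <- prox / n_trees
  dimnames(prox) <- list(rownames(map), rownames(map))
  class(prox) <- c("proximity_matrix", class(prox))
  prox
}

#' Guided dissimilarity from a proximity matrix
#'
#' Elementwise `1 - proximity`: zero diagonal, symmetric, range \[0, 1\].
#'
#' @param prox a `proximity_matrix` from [forest_proximity()].
#' @return a labelled symmetric dissimilarity matrix.
#' @export
guided_dissimilarity <- function(prox) {
  stopifnot(inherits(prox, "proximity_matrix"))
  d <- 1 - unclass(prox)
  diag(d) <- 0
  d
}

#' @export
print.proximity_matrix <- function(x, ...) {
  cat(sprintf("forest proximity matrix: %d entities, mean off-diagonal %.3f\n",
              nrow(x), mean(unclass(x)[upper.tri(x)])))
  invisible(x)
}
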