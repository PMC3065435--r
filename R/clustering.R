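#' Unguided dissimilarity: Euclidean distance between binary map profiles
#'
#' The unguided route clusters entities on the Euclidean distance between
#' their binary map-matrix profiles — rows (target profiles of mRNAs) or
#' columns (regulator profiles of miRNAs).
#'
#' @param map a [map_matrix()].
#' @param axis `"rows"` for mRNAs, `"cols"` for miRNAs.
#' @return a labelled symmetric dissimilarity matrix with zero diagonal.
#' @export
unguided_dissimilarity <- function(map, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  profiles <- if (axis == "rows") unclass(map) else t(unclass(map))
  as.matrix(stats::dist(profiles, method = "euclidean"))
}

#' Cluster-set container
#'
#' A partition of entities into K clusters, as produced by [pam_cluster()]
#' or [hclust_cluster()]. `tidy()` returns the per-entity assignment table,
#' `glance()` one row of bookkeeping (cluster count, mean cluster size,
#' singleton count).
#'
#' @param assignments named vector (entity id -> cluster label in 1..K) or a
#'   two-column data frame (`id`, `cluster`).
#' @param K requested number of clusters.
#' @param medoid_ids medoid entity ids, one per cluster (PAM only).
#' @param method `"unguided"`, `"guided"`, or `NA`.
#' @param algorithm `"pam"` or `"hclust"`.
#' @return an object of class `cluster_set`.
#' @export
cluster_set <- function(assignments, K, medoid_ids = NULL,
                        method = NA_character_, algorithm = "pam") {
  if (is.data.frame(assignments)) {
    tab <- tibble::as_tibble(assignments[c("id", "cluster")])
  } else {
    tab <- tibble::tibble(id = names(assignments),
                          cluster = as.integer(assignments))
  }
  if (anyDuplicated(tab$id)) abort("each entity must be assigned exactly once")
  if (!is.null(medoid_ids) && !all(medoid_ids %in% tab$id)) {
    abort("medoids must be members of the clustered entities")
  }
  structure(
    list(assignments = tab, K = as.integer(K), medoid_ids = medoid_ids,
         method = method, algorithm = algorithm),
    class = "cluster_set"
  )
}

#' Partition entities around medoids (PAM / k-medoids)
#'
#' Kaufman-Rousseeuw PAM (greedy BUILD then SWAP until no swap lowers the
#' total dissimilarity to medoids), run on an arbitrary dissimilarity via
#' the \pkg{cluster} package. The algorithm is deterministic; `seed` is
#' accepted for interface stability but not consumed.
#'
#' @param d labelled symmetric dissimilarity matrix (or `dist`).
#' @param K number of clusters, `1 <= K <=` number of entities.
#' @param seed unused (PAM is deterministic).
#' @param method clustering route label carried into the result
#'   (`"unguided"` or `"guided"`).
#' @return a [cluster_set()] with medoids.
#' @export
pam_cluster <- function(d, K, seed = NULL, method = NA_character_) {
  d <- stats::as.dist(d)
  Z <- attr(d, "Size")
  if (K < 1L || K > Z) abort(sprintf("K must be in 1..%d, got %s", Z, K))
  ids <- attr(d, "Labels") %||% as.character(seq_len(Z))
  if (K == Z) {
    # every entity is its own medoid; cluster::pam requires K < Z
    return(cluster_set(setNames(seq_len(Z), ids), K = K, medoid_ids = ids,
                       method = method, algorithm = "pam"))
  }
  fit <- cluster::pam(d, k = K, diss = TRUE, keep.diss = FALSE)
  cluster_set(fit$clustering, K = K, medoid_ids = fit$medoids,
              method = method, algorithm = "pam")
}

#' Agglomerative hierarchical comparator
#'
#' Merges under average (default) or complete linkage and cuts the tree at
#' K clusters; provided as the comparator clustering algorithm.
#'
#' @inheritParams pam_cluster
#' @param linkage `"average"` or `"complete"`.
#' @return a [cluster_set()] (no medoids).
#' @export
hclust_cluster <- function(d, K, linkage = c("average", "complete"),
                           method = NA_character_) {
  linkage <- match.arg(linkage)
  d <- stats::as.dist(d)
  Z <- attr(d, "Size")
  if (K < 1L || K > Z) abort(sprintf("K must be in 1..%d, got %s", Z, K))
  tree <- stats::hclust(d, method = linkage)
  cluster_set(stats::cutree(tree, k = K), K = K, medoid_ids = NULL,
              method = method, algorithm = "hclust")
}

#' Extract member ids of each cluster
#'
#' @param x a `cluster_set`.
#' @param min_size drop clusters smaller than this.
#' @return a named list of id vectors, one per cluster label.
#' @export
cluster_members <- function(x, min_size = 1L) {
  stopifnot(inherits(x, "cluster_set"))
  members <- split(x$assignments$id, x$assignments$cluster)
  members[lengths(members) >= min_size]
}

#' @exportS3Method generics::tidy
#' @rdname cluster_set
#' @param x a `cluster_set`.
#' @param ... unused.
tidy.cluster_set <- function(x, ...) {
  dplyr::mutate(x$assignments,
                is_medoid = .data$id %in% (x$medoid_ids %||% character(0)))
}

#' @exportS3Method generics::glance
#' @rdname cluster_set
glance.cluster_set <- function(x, ...) {
  sizes <- table(x$assignments$cluster)
  tibble::tibble(
    K = x$K,
    n_entities = nrow(x$assignments),
    n_clusters = length(sizes),
    mean_cluster_size = nrow(x$assignments) / x$K,
    n_singletons = sum(sizes == 1L),
    method = x$method,
    algorithm = x$algorithm
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("cluster_set: %d entities in %d clusters (K = %d, %s, %s)\n",
              g$n_entities, g$n_clusters, g$K, x$algorithm,
              x$method %||% "?"))
  invisible(x)
}
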