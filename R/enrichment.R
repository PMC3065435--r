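#' Cluster enrichment score
#'
#' Tightness of a cluster in map space: the componentwise median of the
#' members' binary map profiles is the cluster centre, and the score is the
#' mean Euclidean distance of the members to that centre. Zero iff all
#' member profiles are identical; small scores mean the members share their
#' predicted regulators.
#'
#' @param profiles numeric matrix of member map profiles (one row per
#'   member).
#' @return a non-negative number.
#' @export
enrichment_score <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n == 0L) abort("enrichment score is undefined for an empty cluster")
  centre <- col_medians(profiles)
  mean(sqrt(rowSums((profiles - rep(centre, each = n))^2)))
}

#' Bootstrap test of one cluster's enrichment
#'
#' Draws `B` random clusters of the observed size from the universe
#' (without replacement within a draw), computes their enrichment scores,
#' and counts `w1`, the number of random scores less than or equal to the
#' observed score. The cluster is enriched when `w1 / B < alpha` (strict).
#'
#' @param members entity ids of the cluster.
#' @param map a [map_matrix()] whose rows are the clustered entities.
#' @param B bootstrap replicates.
#' @param alpha significance level.
#' @param universe ids eligible for random draws; defaults to all map rows.
#' @param seed optional integer seed.
#' @param cluster_label label carried into the result.
#' @return a one-row tibble: `cluster`, `size`, `es`, `w1`, `n_random`,
#'   `p_boot`, `enriched`.
#' @export
bootstrap_enrichment <- function(members, map, B = 100L, alpha = 0.05,
                                 universe = rownames(map), seed = NULL,
                                 cluster_label = NA) {
  stopifnot(B >= 1L)
  n_k <- length(members)
  if (n_k > length(universe)) {
    abort("cluster size exceeds the sampling universe")
  }
  mapv <- unclass(map)
  obs <- enrichment_score(mapv[members, , drop = FALSE])
  uni_idx <- match(universe, rownames(mapv))
  if (anyNA(uni_idx)) abort("universe ids must be rows of the map matrix")
  rand <- with_opt_seed(seed, vapply(seq_len(B), function(b) {
    enrichment_score(mapv[sample(uni_idx, n_k), , drop = FALSE])
  }, numeric(1L)))
  w1 <- sum(rand <= obs)
  tibble::tibble(cluster = cluster_label, size = n_k, es = obs, w1 = w1,
                 n_random = as.integer(B), p_boot = w1 / B,
                 enriched = w1 / B < alpha)
}

#' Test every cluster of a cluster set for enrichment
#'
#' Clusters of size one cannot be co-targeted groups and are excluded from
#' the testable total; with `keep_singletons = TRUE` (miRNA mode — a single
#' miRNA can still regulate many mRNAs) they are retained untested and
#' flagged. `Pr_enrich` is the fraction of testable (size > 1) clusters
#' declared enriched.
#'
#' @param clusters a [cluster_set()].
#' @inheritParams bootstrap_enrichment
#' @param keep_singletons retain size-1 clusters untested instead of
#'   dropping them.
#' @return an object of class `enrichment_eval`: per-cluster tibble plus
#'   `pr_enrich`, `n_total`, `n_enrich`.
#' @export
evaluate_cluster_set <- function(clusters, map, B = 100L, alpha = 0.05,
                                 universe = rownames(map),
                                 keep_singletons = FALSE, seed = NULL) {
  stopifnot(inherits(clusters, "cluster_set"))
  members <- cluster_members(clusters)
  sizes <- lengths(members)
  if (all(sizes <= 1L)) {
    abort("no clusters of size > 1: nothing is testable for enrichment")
  }
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1L),
                        length(members))
  rows <- purrr::imap(members, function(ids, lab) {
    i <- match(lab, names(members))
    if (length(ids) > 1L) {
      bootstrap_enrichment(ids, map, B = B, alpha = alpha,
                           universe = universe, seed = seeds[i],
                           cluster_label = lab) |>
        dplyr::mutate(tested = TRUE, retained = .data$enriched)
    } else if (keep_singletons) {
      tibble::tibble(cluster = lab, size = 1L, es = 0, w1 = NA_integer_,
                     n_random = NA_integer_, p_boot = NA_real_,
                     enriched = NA, tested = FALSE, retained = TRUE)
    } else {
      tibble::tibble(cluster = lab, size = 1L, es = 0, w1 = NA_integer_,
                     n_random = NA_integer_, p_boot = NA_real_,
                     enriched = NA, tested = FALSE, retained = FALSE)
    }
  })
  results <- dplyr::bind_rows(rows)
  n_total <- sum(results$tested)
  n_enrich <- sum(results$enriched[results$tested])
  structure(
    list(results = results, pr_enrich = n_enrich / n_total,
         n_total = n_total, n_enrich = n_enrich, B = as.integer(B),
         alpha = alpha, members = members),
    class = "enrichment_eval"
  )
}

#' Sweep the cluster count K and select it by Pr_enrich
#'
#' Clusters the dissimilarity at every K in the grid, evaluates enrichment,
#' and selects the K with the highest Pr_enrich (smallest K on ties).
#'
#' @param d labelled symmetric dissimilarity matrix.
#' @param map a [map_matrix()] providing the profiles scored by the
#'   enrichment statistic (rows must cover the clustered ids).
#' @param K_grid integer vector of cluster counts to try.
#' @inheritParams evaluate_cluster_set
#' @param algorithm `"pam"` or `"hclust"`.
#' @param linkage linkage for the hclust comparator.
#' @param method route label (`"unguided"`/`"guided"`) carried through.
#' @return an object of class `enrichment_sweep`: the per-K table, the
#'   selected K, its `cluster_set` and `enrichment_eval`.
#' @export
sweep_k <- function(d, map, K_grid, B = 100L, alpha = 0.05,
                    universe = rownames(map), keep_singletons = FALSE,
                    algorithm = c("pam", "hclust"),
                    linkage = "average", method = NA_character_,
                    seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (length(K_grid) == 0L) abort("K_grid must be non-empty")
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1L),
                        length(K_grid))
  fits <- purrr::map(seq_along(K_grid), function(i) {
    K <- K_grid[i]
    cs <- if (algorithm == "pam") {
      pam_cluster(d, K, method = method)
    } else {
      hclust_cluster(d, K, linkage = linkage, method = method)
    }
    ev <- evaluate_cluster_set(cs, map, B = B, alpha = alpha,
                               universe = universe,
                               keep_singletons = keep_singletons,
                               seed = seeds[i])
    list(clusters = cs, evaluation = ev)
  })
  tab <- purrr::map2_dfr(fits, K_grid, function(f, K) {
    tibble::tibble(K = as.integer(K), n_total = f$evaluation$n_total,
                   n_enrich = f$evaluation$n_enrich,
                   pr_enrich = f$evaluation$pr_enrich,
                   n_singletons = sum(lengths(f$evaluation$members) == 1L))
  })
  best <- which(tab$pr_enrich == max(tab$pr_enrich))
  sel <- best[which.min(tab$K[best])]
  structure(
    list(table = tab, selected_K = tab$K[sel],
         clusters = fits[[sel]]$clusters,
         evaluation = fits[[sel]]$evaluation,
         method = method, algorithm = algorithm, B = as.integer(B),
         alpha = alpha),
    class = "enrichment_sweep"
  )
}

#' Ids of clusters carried into the module step
#'
#' Enriched size > 1 clusters, plus untested singletons when they were
#' retained (miRNA mode).
#'
#' @param x an `enrichment_eval` or `enrichment_sweep`.
#' @return named list of member-id vectors.
#' @export
retained_clusters <- function(x) {
  if (inherits(x, "enrichment_sweep")) x <- x$evaluation
  stopifnot(inherits(x, "enrichment_eval"))
  keep <- x$results$cluster[x$results$retained]
  x$members[as.character(keep)]
}

#' @exportS3Method generics::tidy
tidy.enrichment_eval <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.enrichment_eval <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_enrich = x$n_enrich,
                 pr_enrich = x$pr_enrich, B = x$B, alpha = x$alpha)
}

#' @exportS3Method generics::tidy
tidy.enrichment_sweep <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.enrichment_sweep <- function(x, ...) {
  sel <- x$table[x$table$K == x$selected_K, ]
  dplyr::mutate(sel, method = x$method, algorithm = x$algorithm,
                B = x$B, alpha = x$alpha)
}

#' @export
print.enrichment_eval <- function(x, ...) {
  cat(sprintf(
    "enrichment: %d/%d testable clusters enriched (Pr_enrich = %.3f, B = %d)\n",
    x$n_enrich, x$n_total, x$pr_enrich, x$B))
  invisible(x)
}

#' @export
print.enrichment_sweep <- function(x, ...) {
  cat(sprintf("Pr_enrich sweep over K = {%s}; selected K = %d (Pr_enrich = %.3f)\n",
              paste(x$table$K, collapse = ", "), x$selected_K,
              max(x$table$pr_enrich)))
  invisible(x)
}
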