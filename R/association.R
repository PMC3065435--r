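#' Linear association between one miRNA and one mRNA
#'
#' Ordinary least squares of the mRNA's log2 fold-changes `u` on the
#' miRNA's `v`: `u = alpha + beta * v`. The slope is tested with a t-test
#' on `T - 2` degrees of freedom, two-sided or one-sided (`"negative"` for
#' the repression-direction alternative `beta < 0`, the pipeline default;
#' `"positive"` for indirect relationships). A perfect fit gives p = 0 with
#' a warning; a constant `v` leaves the slope inestimable and the pair is
#' never associated.
#'
#' @param v numeric miRNA fold-change vector (length T >= 3).
#' @param u numeric mRNA fold-change vector, same length.
#' @param direction `"negative"`, `"two_sided"`, or `"positive"`.
#' @param alpha_level pair-level significance level.
#' @param predicted is the pair in the map matrix? The associated flag
#'   requires it.
#' @return a one-row tibble: `predicted`, `alpha_hat`, `beta_hat`, `t_stat`,
#'   `p_value`, `estimable`, `associated`.
#' @export
fit_pair <- function(v, u, direction = c("negative", "two_sided", "positive"),
                     alpha_level = 0.05, predicted = TRUE) {
  direction <- match.arg(direction)
  if (length(v) != length(u)) abort("u and v must have equal length")
  if (length(v) < 3L) abort("at least 3 conditions are needed (df = T - 2 >= 1)")
  fits <- fit_all_pairs(
    expression_matrix(matrix(v, 1L, dimnames = list("v", NULL))),
    expression_matrix(matrix(u, 1L, dimnames = list("u", NULL))),
    direction = direction, alpha_level = alpha_level
  )
  tibble::tibble(predicted = predicted, alpha_hat = fits$alpha_hat[1L],
                 beta_hat = fits$beta_hat[1L], t_stat = fits$t_stat[1L],
                 p_value = fits$p_value[1L], estimable = fits$estimable[1L],
                 associated = predicted & fits$associated[1L])
}

#' Fit the pair model for every miRNA x mRNA combination
#'
#' Closed-form OLS vectorised over all pairs; the workhorse behind the
#' module association counts and their bootstrap.
#'
#' @param mirna_expr miRNA [expression_matrix()] (X x T).
#' @param mrna_expr mRNA [expression_matrix()] (Y x T), same conditions.
#' @inheritParams fit_pair
#' @return an object of class `pair_fits`: X x Y matrices `alpha_hat`,
#'   `beta_hat`, `t_stat`, `p_value`, logical `estimable` and `associated`
#'   (association here means a significant slope in the requested
#'   direction; the map-matrix predicted filter is applied downstream).
#' @export
fit_all_pairs <- function(mirna_expr, mrna_expr,
                          direction = c("negative", "two_sided", "positive"),
                          alpha_level = 0.05) {
  direction <- match.arg(direction)
  V <- unclass(mirna_expr)
  U <- unclass(mrna_expr)
  if (ncol(V) != ncol(U)) abort("matched inputs must share their conditions")
  T_n <- ncol(V)
  if (T_n < 3L) abort("at least 3 conditions are needed (df = T - 2 >= 1)")
  df <- T_n - 2L
  X <- nrow(V)
  Y <- nrow(U)
  Vc <- V - rowMeans(V)
  Uc <- U - rowMeans(U)
  sxx <- rowSums(Vc^2)                    # per miRNA
  syy <- rowSums(Uc^2)                    # per mRNA
  sxy <- Vc %*% t(Uc)                     # X x Y cross-products
  estimable <- sxx > 0
  beta <- sxy / ifelse(sxx > 0, sxx, NA_real_)
  alpha_hat <- rowMeans(U)[col(beta)] - beta * rowMeans(V)[row(beta)]
  rss <- pmax(0, rep(syy, each = X) - beta^2 * sxx)
  se <- sqrt(rss / df / sxx)
  t_stat <- beta / se
  perfect <- estimable & se == 0
  if (any(perfect)) {
    t_stat[perfect] <- sign(beta[perfect]) * Inf
    warn(sprintf("%d pair fit(s) had zero residual variance; p set to 0",
                 sum(perfect)))
  }
  p <- switch(direction,
    two_sided = 2 * pt(-abs(t_stat), df),
    negative = pt(t_stat, df),
    positive = pt(t_stat, df, lower.tail = FALSE)
  )
  dn <- list(rownames(V), rownames(U))
  dimnames(beta) <- dimnames(alpha_hat) <- dimnames(t_stat) <- dimnames(p) <- dn
  assoc <- !is.na(p) & p < alpha_level
  assoc[!estimable, ] <- FALSE
  structure(
    list(alpha_hat = alpha_hat, beta_hat = beta, t_stat = t_stat,
         p_value = p, estimable = matrix(estimable, X, Y, dimnames = dn),
         associated = assoc, direction = direction,
         alpha_level = alpha_level, df = df),
    class = "pair_fits"
  )
}

#' @exportS3Method generics::tidy
tidy.pair_fits <- function(x, ...) {
  tibble::tibble(
    mirna_id = rep(rownames(x$beta_hat), times = ncol(x$beta_hat)),
    mrna_id = rep(colnames(x$beta_hat), each = nrow(x$beta_hat)),
    alpha_hat = as.vector(x$alpha_hat),
    beta_hat = as.vector(x$beta_hat),
    t_stat = as.vector(x$t_stat),
    p_value = as.vector(x$p_value),
    estimable = as.vector(x$estimable),
    associated = as.vector(x$associated)
  )
}

#' @export
print.pair_fits <- function(x, ...) {
  cat(sprintf(
    "pair fits: %d miRNAs x %d mRNAs, %s test at alpha = %g (df = %d)\n",
    nrow(x$beta_hat), ncol(x$beta_hat), x$direction, x$alpha_level, x$df))
  invisible(x)
}

#' Count associated predicted pairs between two clusters
#'
#' `Assoc(m, n)`: the number of (miRNA in cluster m, mRNA in cluster n)
#' pairs that are both predicted in the map matrix and have a significant
#' slope in the requested direction.
#'
#' @param mirna_ids,mrna_ids cluster member ids.
#' @param map a [map_matrix()].
#' @param fits a `pair_fits` object covering the members.
#' @return a non-negative integer.
#' @export
module_assoc_count <- function(mirna_ids, mrna_ids, map, fits) {
  if (length(mirna_ids) == 0L || length(mrna_ids) == 0L) {
    abort("clusters must be non-empty")
  }
  A <- fits$associated[mirna_ids, mrna_ids, drop = FALSE]
  P <- t(unclass(map))[mirna_ids, mrna_ids, drop = FALSE]
  sum(A & P == 1)
}

#' Bootstrap test of one module's association count
#'
#' Draws `B` random mRNA clusters of the observed size from the universe
#' (without replacement within a draw) and counts `w2`, the number of
#' random clusters whose association count with the same miRNA cluster is
#' greater than or equal to the observed count. The module is significant
#' when `w2 / B < alpha` (strict).
#'
#' @param mirna_ids miRNA cluster member ids.
#' @param observed_count observed `Assoc(m, n)`.
#' @param n_gene size of the mRNA cluster.
#' @param map a [map_matrix()].
#' @param fits a `pair_fits` object.
#' @param mrna_universe ids eligible for random draws (all map rows by
#'   default).
#' @param B bootstrap replicates.
#' @param alpha module-level significance level.
#' @param seed optional integer seed.
#' @return a list: `w2`, `p_boot = w2 / B`, `significant`.
#' @export
bootstrap_module_test <- function(mirna_ids, observed_count, n_gene, map,
                                  fits, mrna_universe = rownames(map),
                                  B = 100L, alpha = 0.05, seed = NULL) {
  if (n_gene > length(mrna_universe)) {
    abort("mRNA cluster size exceeds the sampling universe")
  }
  # predicted-and-associated indicator restricted to the miRNA cluster
  AP <- fits$associated[mirna_ids, mrna_universe, drop = FALSE] &
    t(unclass(map))[mirna_ids, mrna_universe, drop = FALSE] == 1
  col_tot <- colSums(AP)
  n_uni <- length(mrna_universe)
  rand <- with_opt_seed(seed, vapply(seq_len(B), function(b) {
    sum(col_tot[sample.int(n_uni, n_gene)])
  }, numeric(1L)))
  w2 <- sum(rand >= observed_count)
  list(w2 = w2, p_boot = w2 / B, significant = w2 / B < alpha)
}

#' Identify potentially regulatory miRNA-mRNA modules
#'
#' Evaluates every pairing of a retained miRNA cluster with a retained mRNA
#' cluster: counts the associated predicted pairs, bootstrap-tests the
#' count against random mRNA clusters of the same size, and computes each
#' member miRNA's targeting fraction of the mRNA cluster. A module is
#' potentially regulatory when the bootstrap test is significant and every
#' member miRNA targets more than `majority_threshold` of the mRNA cluster.
#'
#' @param mirna_clusters,mrna_clusters named lists of member-id vectors
#'   (see [retained_clusters()]), or `cluster_set` objects.
#' @param map a [map_matrix()] (mRNAs x miRNAs) covering the members.
#' @param mirna_expr,mrna_expr matched [expression_matrix()] objects.
#' @inheritParams fit_pair
#' @param alpha module-level bootstrap significance level.
#' @param majority_threshold targeting fraction every miRNA must strictly
#'   exceed.
#' @param B bootstrap replicates per module.
#' @param mrna_universe ids for random mRNA clusters (all map rows by
#'   default).
#' @param bh_adjust also report Benjamini-Hochberg adjusted bootstrap
#'   p-values across the candidate modules (off by default; the regulatory
#'   flag always uses the unadjusted test).
#' @param seed optional integer seed.
#' @return an object of class `mirmod_modules`: a tibble with one row per
#'   candidate module (`mirna_cluster`, `mrna_cluster`, `n_mir`, `n_gene`,
#'   `assoc_count`, `w2`, `p_boot`, `significant`, `min_targeting`,
#'   `regulatory`, list-columns of member ids and per-miRNA targeting
#'   fractions), with the `pair_fits` attached.
#' @export
identify_modules <- function(mirna_clusters, mrna_clusters, map, mirna_expr,
                             mrna_expr,
                             direction = c("negative", "two_sided", "positive"),
                             alpha_level = 0.05, alpha = 0.05,
                             majority_threshold = 0.5, B = 100L,
                             mrna_universe = rownames(map),
                             bh_adjust = FALSE, seed = NULL) {
  direction <- match.arg(direction)
  if (inherits(mirna_clusters, "cluster_set")) {
    mirna_clusters <- cluster_members(mirna_clusters)
  }
  if (inherits(mrna_clusters, "cluster_set")) {
    mrna_clusters <- cluster_members(mrna_clusters)
  }
  if (length(mirna_clusters) == 0L || length(mrna_clusters) == 0L) {
    abort("at least one cluster is required on each side")
  }
  fits <- fit_all_pairs(mirna_expr, mrna_expr, direction = direction,
                        alpha_level = alpha_level)
  tmap <- t(unclass(map))
  grid <- tidyr::expand_grid(m = seq_along(mirna_clusters),
                             n = seq_along(mrna_clusters))
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1L),
                        nrow(grid))
  rows <- purrr::pmap(list(grid$m, grid$n, seeds), function(m, n, s) {
    mir <- mirna_clusters[[m]]
    gene <- mrna_clusters[[n]]
    count <- module_assoc_count(mir, gene, map, fits)
    boot <- bootstrap_module_test(mir, count, length(gene), map, fits,
                                  mrna_universe = mrna_universe, B = B,
                                  alpha = alpha, seed = s)
    targeting <- rowMeans(tmap[mir, gene, drop = FALSE])
    tibble::tibble(
      mirna_cluster = names(mirna_clusters)[m] %||% as.character(m),
      mrna_cluster = names(mrna_clusters)[n] %||% as.character(n),
      n_mir = length(mir), n_gene = length(gene),
      assoc_count = count, w2 = boot$w2, n_random = as.integer(B),
      p_boot = boot$p_boot, significant = boot$significant,
      min_targeting = min(targeting),
      regulatory = boot$significant && all(targeting > majority_threshold),
      mirna_ids = list(mir), mrna_ids = list(gene),
      targeting_fraction = list(targeting)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (bh_adjust) {
    out$p_boot_bh <- stats::p.adjust(out$p_boot, method = "BH")
  }
  structure(
    list(modules = out, fits = fits, direction = direction,
         alpha_level = alpha_level, alpha = alpha,
         majority_threshold = majority_threshold, B = as.integer(B)),
    class = "mirmod_modules"
  )
}

#' @exportS3Method generics::tidy
tidy.mirmod_modules <- function(x, ...) x$modules

#' @exportS3Method generics::glance
glance.mirmod_modules <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$modules),
    n_significant = sum(x$modules$significant),
    n_regulatory = sum(x$modules$regulatory),
    direction = x$direction, alpha_level = x$alpha_level,
    alpha = x$alpha, majority_threshold = x$majority_threshold, B = x$B
  )
}

#' Per-pair edge list for the regulatory modules
#'
#' Flat (miRNA, mRNA) edges of the predicted pairs inside regulatory
#' modules, with their fitted slope and p-value; suitable for network
#' tools.
#'
#' @param x a `mirmod_modules` object.
#' @param regulatory_only keep only regulatory modules (default).
#' @return a tibble: `module_id`, `mirna_id`, `mrna_id`, `beta_hat`,
#'   `p_value`, `associated`.
#' @export
module_edges <- function(x, regulatory_only = TRUE) {
  stopifnot(inherits(x, "mirmod_modules"))
  mods <- x$modules
  if (regulatory_only) mods <- mods[mods$regulatory, ]
  if (nrow(mods) == 0L) {
    return(tibble::tibble(module_id = character(), mirna_id = character(),
                          mrna_id = character(), beta_hat = numeric(),
                          p_value = numeric(), associated = logical()))
  }
  purrr::pmap_dfr(
    list(mods$mirna_cluster, mods$mrna_cluster, mods$mirna_ids,
         mods$mrna_ids),
    function(mc, nc, mir, gene) {
      tidyr::expand_grid(mirna_id = mir, mrna_id = gene) |>
        dplyr::mutate(
          module_id = paste0(mc, ":", nc),
          beta_hat = x$fits$beta_hat[cbind(mirna_id, mrna_id)],
          p_value = x$fits$p_value[cbind(mirna_id, mrna_id)],
          associated = x$fits$associated[cbind(mirna_id, mrna_id)],
          .before = 1L
        ) |>
        dplyr::relocate("module_id")
    })
}

#' @export
print.mirmod_modules <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "miRmR modules: %d candidates, %d significant, %d regulatory (%s, alpha = %g)\n",
    g$n_candidates, g$n_significant, g$n_regulatory, x$direction, x$alpha))
  invisible(x)
}
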