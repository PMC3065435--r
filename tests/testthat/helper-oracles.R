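# Fixture builders and independent oracles used across the suite.

# small labelled map matrix from a plain 0/1 matrix
mk_map <- function(values, rids = NULL, cids = NULL) {
  rids <- rids %||% sprintf("g%02d", seq_len(nrow(values)))
  cids <- cids %||% sprintf("m%02d", seq_len(ncol(values)))
  map_matrix(matrix(values, nrow(values), ncol(values),
                    dimnames = list(rids, cids)))
}

mk_expr <- function(values, rids = NULL) {
  rids <- rids %||% sprintf("g%02d", seq_len(nrow(values)))
  expression_matrix(matrix(values, nrow(values), ncol(values),
                           dimnames = list(rids, NULL)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- PAM oracle: exhaustive enumeration of medoid sets ------------------

# total cost of serving all points from the given medoids
pam_cost_of <- function(d, medoid_idx) {
  sum(apply(d[, medoid_idx, drop = FALSE], 1L, min))
}

# optimal K-medoid cost by brute force (Z small)
pam_brute_cost <- function(d, K) {
  Z <- nrow(d)
  combos <- utils::combn(Z, K)
  min(apply(combos, 2L, function(m) pam_cost_of(d, m)))
}

# cost of a fitted cluster_set on dissimilarity d (labelled)
pam_fit_cost <- function(d, cs) {
  pam_cost_of(d[cs$assignments$id, cs$assignments$id],
              match(cs$medoid_ids, cs$assignments$id))
}

# --- exhaustive-split regression tree oracle ----------------------------

# Mirrors the stated growth rule but screens every covariate; returns the
# list of terminal member sets (sorted for comparison). Assumes no score
# ties between covariates that induce different partitions.
exhaustive_tree_terminals <- function(map, expr, node_size) {
  mapv <- unclass(map)
  out <- list()
  recurse <- function(members) {
    if (length(members) <= node_size) {
      out[[length(out) + 1L]] <<- sort(members)
      return(invisible())
    }
    scores <- vapply(seq_len(ncol(mapv)), function(h) {
      split_score(members, h, map, expr, node_size)
    }, numeric(1L))
    if (all(is.na(scores))) {
      out[[length(out) + 1L]] <<- sort(members)
      return(invisible())
    }
    h <- which.max(scores)
    targeted <- mapv[members, h] == 1
    recurse(members[targeted])
    recurse(members[!targeted])
    invisible()
  }
  recurse(seq_len(nrow(mapv)))
  out[order(vapply(out, `[`, numeric(1L), 1L))]
}

tree_terminals <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (isTRUE(node$terminal)) {
      out[[length(out) + 1L]] <<- sort(node$members)
    } else {
      walk(node$left); walk(node$right)
    }
  }
  walk(tree)
  out[order(vapply(out, `[`, numeric(1L), 1L))]
}

# map with no duplicate or complementary columns (so the exhaustive oracle
# and the randomised tree cannot disagree through partition-equivalent ties)
random_tree_instance <- function(Y, X, seed) {
  withr::with_seed(seed, {
    repeat {
      vals <- matrix(rbinom(Y * X, 1L, 0.5), Y, X)
      keys <- apply(vals, 2L, paste, collapse = "")
      comp <- apply(1L - vals, 2L, paste, collapse = "")
      if (anyDuplicated(c(keys)) == 0L && !any(keys %in% comp)) break
    }
    list(map = mk_map(vals), expr = mk_expr(matrix(runif(Y * 3), Y)))
  })
}

# --- OLS oracle via stats::lm -------------------------------------------

lm_pair_oracle <- function(v, u) {
  fit <- stats::lm(u ~ v)
  s <- summary(fit)$coefficients
  list(alpha = s[1L, 1L], beta = s[2L, 1L], t = s[2L, 3L],
       p_two = s[2L, 4L],
       p_neg = stats::pt(s[2L, 3L], df = length(v) - 2L),
       p_pos = stats::pt(s[2L, 3L], df = length(v) - 2L, lower.tail = FALSE))
}

# --- planted-module matching --------------------------------------------

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# does each planted module have a matching regulatory module (Jaccard >= 0.5
# on both sides), and how many reported regulatory modules match nothing?
match_planted <- function(reg, truth) {
  matched <- vapply(seq_len(nrow(truth)), function(k) {
    if (nrow(reg) == 0L) return(FALSE)
    any(vapply(seq_len(nrow(reg)), function(r) {
      jaccard(reg$mirna_ids[[r]], truth$mirna_ids[[k]]) >= 0.5 &&
        jaccard(reg$mrna_ids[[r]], truth$mrna_ids[[k]]) >= 0.5
    }, logical(1L)))
  }, logical(1L))
  reg_matched <- vapply(seq_len(nrow(reg)), function(r) {
    any(vapply(seq_len(nrow(truth)), function(k) {
      jaccard(reg$mirna_ids[[r]], truth$mirna_ids[[k]]) >= 0.5 &&
        jaccard(reg$mrna_ids[[r]], truth$mrna_ids[[k]]) >= 0.5
    }, logical(1L)))
  }, logical(1L))
  list(recall_ok = all(matched), n_false = sum(!reg_matched))
}

# ARI of the recovered mRNA partition restricted to planted members
planted_ari <- function(run, truth) {
  cs <- tidy(run$mrna$sweep$clusters)
  planted <- unlist(truth$modules$mrna_ids)
  truth_lab <- rep(seq_len(nrow(truth$modules)),
                   lengths(truth$modules$mrna_ids))
  adjusted_rand_index(truth_lab, cs$cluster[match(planted, cs$id)])
}
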