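test_that("enrichment score is the mean distance to the median profile", {
  expect_equal(enrichment_score(rbind(c(1, 0), c(1, 0), c(1, 0))), 0)
  # median profile (1, 0.5); both members at distance 0.5
  expect_equal(enrichment_score(rbind(c(1, 0), c(1, 1))), 0.5)
  expect_equal(enrichment_score(matrix(c(1, 0, 1), 1)), 0)    # singleton
  expect_error(enrichment_score(matrix(numeric(), 0, 3)), "empty")

  # permutation invariance, and zero iff all profiles identical
  withr::with_seed(12, p <- matrix(rbinom(40, 1, 0.5), 8))
  expect_equal(enrichment_score(p), enrichment_score(p[sample(8), ]))
  if (nrow(unique(p)) > 1L) expect_gt(enrichment_score(p), 0)
})

test_that("enrichment bootstrap handles the extreme statistics", {
  withr::with_seed(13, {
    vals <- matrix(rbinom(200, 1, 0.5), 20)
    vals[1:4, ] <- rep(vals[1L, ], each = 4)     # four identical rows
  })
  map <- mk_map(vals)
  ids <- rownames(map)

  # observed ES = 0 in a heterogeneous universe: no random cluster ties it
  res <- bootstrap_enrichment(ids[1:4], map, B = 50L, seed = 1L)
  expect_equal(res$es, 0)
  expect_equal(res$w1, 0L)
  expect_true(res$enriched)

  # the whole universe as the cluster: every draw reproduces it
  res2 <- bootstrap_enrichment(ids, map, B = 50L, seed = 2L)
  expect_equal(res2$w1, 50L)
  expect_false(res2$enriched)

  expect_error(bootstrap_enrichment(c(ids, "extra"), map, B = 10L),
               "exceeds")
})

test_that("cluster-set evaluation computes Pr_enrich over testable clusters", {
  # 4 tight duplicate-triple clusters, 1 deliberately loose cluster of
  # mutually distant rows, 2 singletons
  blocks <- lapply(1:4, function(k) {
    v <- rep(0, 12); v[(3 * k - 2):(3 * k)] <- 1
    rbind(v, v, v)
  })
  loose <- rbind(c(rep(1, 6), rep(0, 6)), c(rep(0, 6), rep(1, 6)),
                 rep(c(1, 0), 6))
  vals <- do.call(rbind, c(blocks, list(loose), list(diag(12)[1:2, ])))
  map <- mk_map(vals)
  assign <- rep(1:7, c(3, 3, 3, 3, 3, 1, 1))
  cs <- cluster_set(setNames(assign, rownames(map)), K = 7L)

  ev <- evaluate_cluster_set(cs, map, B = 100L, seed = 5L)
  expect_equal(ev$n_total, 5L)
  expect_equal(ev$n_enrich, 4L)
  expect_equal(ev$pr_enrich, 0.8)
  expect_false(any(tidy(ev)$retained[!tidy(ev)$tested]))

  # miRNA mode: singletons ride along untested
  ev2 <- evaluate_cluster_set(cs, map, B = 100L, keep_singletons = TRUE,
                              seed = 5L)
  expect_equal(ev2$n_total, 5L)                  # singletons never counted
  sing <- tidy(ev2)[tidy(ev2)$size == 1L, ]
  expect_true(all(!sing$tested & sing$retained))
  expect_equal(length(retained_clusters(ev2)), 4L + 2L)

  # identical seed reproduces the evaluation bit-exactly
  ev3 <- evaluate_cluster_set(cs, map, B = 100L, seed = 5L)
  expect_identical(tidy(ev), tidy(ev3))

  all_single <- cluster_set(setNames(1:12, rownames(map)[1:12]), K = 12L)
  expect_error(evaluate_cluster_set(all_single, map), "nothing is testable")
})

test_that("K sweep selects the best Pr_enrich, smallest K on ties", {
  # single-K grid: that K is selected
  withr::with_seed(14, vals <- matrix(rbinom(64, 1, 0.5), 16))
  vals <- vals[rep(1:4, each = 4), ]             # 4 groups of 4 duplicates
  map <- mk_map(vals)
  d <- unguided_dissimilarity(map, "rows")
  s1 <- sweep_k(d, map, K_grid = 3L, B = 50L, seed = 3L)
  expect_equal(s1$selected_K, 3L)

  # K = 4 and K = 8 both split into duplicate groups (ES = 0 everywhere),
  # so Pr_enrich ties at 1 and the smaller K wins
  s2 <- sweep_k(d, map, K_grid = c(8L, 4L), B = 50L, seed = 4L)
  expect_equal(max(s2$table$pr_enrich), 1)
  expect_equal(s2$table$pr_enrich[s2$table$K == 4L],
               s2$table$pr_enrich[s2$table$K == 8L])
  expect_equal(s2$selected_K, 4L)
})

test_that("planted co-targeting clusters are detected as enriched", {
  hits <- 0L
  for (seed in 1:20) {
    tr <- simulate_modules(synthetic_spec(
      Y = 100L, X = 20L, n_modules = 1L, module_mirna_sizes = 5L,
      module_mrna_sizes = 30L, seed = seed))
    res <- bootstrap_enrichment(tr$modules$mrna_ids[[1L]], tr$map,
                                B = 100L, seed = 1000L + seed)
    hits <- hits + res$enriched
  }
  expect_gte(hits, 19L)
})
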