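test_that("node homogeneity is the squared spread around the mean profile", {
  expect_equal(node_homogeneity(matrix(c(3, 1, 4), 1)), 0)     # single row
  expect_equal(node_homogeneity(rbind(c(1, 2), c(1, 2))), 0)   # no spread
  expect_equal(node_homogeneity(rbind(0, 10)), 50)             # 25 + 25
  # brute-force formula on a random fixture
  withr::with_seed(5, e <- matrix(rnorm(21), 7))
  brute <- sum(apply(e, 1L, function(x) sum((x - colMeans(e))^2)))
  expect_equal(node_homogeneity(e), brute)
})

test_that("split scores follow the homogeneity drop and admissibility rules", {
  map <- mk_map(cbind(c(0, 0, 1, 1), c(1, 1, 1, 1)))
  expr <- mk_expr(matrix(c(0, 0, 10, 10), 4))
  # S(parent) = 100, both children pure
  expect_equal(split_score(1:4, 1L, map, expr, node_size = 1L), 100)
  # covariate targeting every member: empty child
  expect_true(is.na(split_score(1:4, 2L, map, expr, node_size = 1L)))
  # children of size 2 and 2 are inadmissible at node_size 3
  expect_true(is.na(split_score(1:4, 1L, map, expr, node_size = 3L)))
  expect_error(split_score(1L, 1L, map, expr), ">= 2")
})

test_that("tree growth obeys the stopping rule and finds separating splits", {
  # too few members: root is terminal
  small <- mk_map(cbind(c(1, 0), c(0, 1)))
  tree <- grow_tree(small, mk_expr(matrix(c(0, 5), 2)), node_size = 5L)
  expect_true(tree$terminal)

  # two expression blocks, each tagged by a dedicated covariate
  map <- mk_map(cbind(c(1, 1, 1, 0, 0, 0), c(0, 1, 0, 1, 0, 1)))
  expr <- mk_expr(matrix(c(0, 0, 0, 9, 9, 9), 6))
  withr::with_seed(1, {
    tree <- grow_tree(map, expr, node_size = 1L, num_cov = 2L)
  })
  expect_false(tree$terminal)
  expect_identical(tree$split, 1L)
  expect_setequal(tree$left$members, 1:3)
  expect_setequal(tree$right$members, 4:6)

  # identical expression everywhere: every defined score is 0, still splits
  flat <- mk_expr(matrix(1, 6, 2))
  withr::with_seed(2, tflat <- grow_tree(map, flat, node_size = 1L,
                                         num_cov = 2L))
  expect_false(tflat$terminal)

  # children partition the parent at every split
  check_partition <- function(node) {
    if (isTRUE(node$terminal)) return(invisible())
    expect_setequal(c(node$left$members, node$right$members), node$members)
    check_partition(node$left)
    check_partition(node$right)
  }
  check_partition(tree)
})

test_that("tree with all covariates matches the exhaustive-split oracle", {
  for (seed in c(3, 17, 29, 41, 53)) {
    inst <- random_tree_instance(Y = 12, X = 6, seed = seed)
    withr::with_seed(seed + 100, {
      tree <- grow_tree(inst$map, inst$expr, node_size = 2L, num_cov = 6L)
    })
    expect_identical(tree_terminals(tree),
                     exhaustive_tree_terminals(inst$map, inst$expr, 2L))
  }
})

test_that("forest proximity is a well-formed similarity", {
  inst <- random_tree_instance(Y = 15, X = 5, seed = 8)
  prox <- forest_proximity(inst$map, inst$expr, n_trees = 25L,
                           node_size = 3L, seed = 99L)
  p <- unclass(prox)
  expect_equal(diag(p), setNames(rep(1, 15), rownames(inst$map)))
  expect_identical(p, t(p))
  expect_true(all(p >= 0 & p <= 1))

  # a single tree gives a 0/1 indicator
  p1 <- unclass(forest_proximity(inst$map, inst$expr, n_trees = 1L,
                                 node_size = 3L, seed = 7L))
  expect_true(all(p1 %in% c(0, 1)))
})

test_that("inseparable duplicate entities always share a terminal node", {
  # rows 1 and 2 have identical map profiles and identical expression: no
  # covariate can ever place them in different children
  vals <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0), c(1, 1, 0),
                c(0, 0, 1), c(0, 1, 1))
  expr <- mk_expr(matrix(c(1, 1, 5, 2, 8, 3), 6))
  prox <- forest_proximity(mk_map(vals), expr, n_trees = 40L,
                           node_size = 1L, num_cov = 2L, seed = 3L)
  expect_equal(unclass(prox)[1L, 2L], 1)
})

test_that("proximities from independent forests agree within Monte Carlo error", {
  inst <- random_tree_instance(Y = 14, X = 6, seed = 21)
  p1 <- unclass(forest_proximity(inst$map, inst$expr, n_trees = 200L,
                                 node_size = 3L, seed = 1L))
  p2 <- unclass(forest_proximity(inst$map, inst$expr, n_trees = 200L,
                                 node_size = 3L, seed = 2L))
  expect_lt(max(abs(p1 - p2)), 3 * sqrt(0.25 / 200))
})

test_that("guided dissimilarity is the proximity complement", {
  prox <- structure(matrix(c(1, 0.25, 0.25, 1), 2,
                           dimnames = list(c("a", "b"), c("a", "b"))),
                    class = c("proximity_matrix", "matrix", "array"))
  d <- guided_dissimilarity(prox)
  expect_equal(d["a", "b"], 0.75)
  expect_equal(diag(d), c(a = 0, b = 0))

  full <- forest_proximity(mk_map(diag(4)), mk_expr(matrix(1:8, 4)),
                           n_trees = 5L, node_size = 2L, seed = 1L)
  expect_equal(unclass(guided_dissimilarity(full)) + unclass(full),
               matrix(1, 4, 4, dimnames = dimnames(full)),
               ignore_attr = FALSE)
})
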