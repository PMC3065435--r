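test_that("an exact line is recovered with a saturated test", {
  expect_warning(f <- fit_pair(1:5, c(5, 4, 3, 2, 1)), "residual")
  expect_equal(f$beta_hat, -1)
  expect_equal(f$alpha_hat, 6)
  expect_equal(f$p_value, 0)
  expect_true(f$associated)
})

test_that("closed-form OLS matches the lm oracle to 1e-10", {
  for (seed in c(1, 8, 15, 22, 30)) {
    withr::with_seed(seed, {
      T_n <- sample(4:8, 1L)
      v <- rnorm(T_n)
      u <- 0.7 - 1.3 * v + rnorm(T_n, sd = 0.5)
    })
    o <- lm_pair_oracle(v, u)
    f2 <- fit_pair(v, u, direction = "two_sided")
    expect_equal(f2$beta_hat, o$beta, tolerance = 1e-10)
    expect_equal(f2$alpha_hat, o$alpha, tolerance = 1e-10)
    expect_equal(f2$t_stat, o$t, tolerance = 1e-10)
    expect_equal(f2$p_value, o$p_two, tolerance = 1e-10)
    expect_equal(fit_pair(v, u, "negative")$p_value, o$p_neg,
                 tolerance = 1e-10)
    expect_equal(fit_pair(v, u, "positive")$p_value, o$p_pos,
                 tolerance = 1e-10)
  }
})

test_that("vectorised pair fits agree with per-pair fits", {
  withr::with_seed(19, {
    V <- mk_expr(matrix(rnorm(15), 3), rids = c("mA", "mB", "mC"))
    U <- mk_expr(matrix(rnorm(20), 4), rids = sprintf("g%d", 1:4))
  })
  fits <- fit_all_pairs(V, U, direction = "two_sided")
  for (i in 1:3) {
    for (j in 1:4) {
      o <- lm_pair_oracle(unclass(V)[i, ], unclass(U)[j, ])
      expect_equal(fits$beta_hat[i, j], o$beta, tolerance = 1e-10)
      expect_equal(fits$p_value[i, j], o$p_two, tolerance = 1e-10)
    }
  }
})

test_that("direction and estimability constraints hold", {
  # constant miRNA: inestimable, never associated
  f <- fit_pair(rep(2, 5), rnorm(5))
  expect_false(f$estimable)
  expect_false(f$associated)
  expect_error(fit_pair(1:2, 1:2), "at least 3")

  # with direction = negative, no non-negative slope is ever associated
  withr::with_seed(23, {
    V <- mk_expr(matrix(rnorm(40), 8), rids = sprintf("m%d", 1:8))
    U <- mk_expr(matrix(rnorm(50), 10), rids = sprintf("g%d", 1:10))
  })
  fits <- fit_all_pairs(V, U, direction = "negative", alpha_level = 0.4)
  expect_false(any(fits$associated[fits$beta_hat >= 0]))
  # one-sided p-values complement each other
  pos <- fit_all_pairs(V, U, direction = "positive")
  expect_equal(fits$p_value + pos$p_value,
               matrix(1, 8, 10, dimnames = dimnames(pos$p_value)))
})

test_that("null pair p-values are uniform at the nominal level", {
  withr::with_seed(31, {
    V <- mk_expr(matrix(rnorm(100 * 5), 100), rids = sprintf("m%d", 1:100))
    U <- mk_expr(matrix(rnorm(100 * 5), 100), rids = sprintf("g%d", 1:100))
  })
  fits <- fit_all_pairs(V, U, direction = "two_sided")
  p <- as.vector(fits$p_value)                     # 10,000 null pairs
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(p)) + 0.002)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("association counts respect prediction and significance level", {
  withr::with_seed(37, {
    V <- mk_expr(matrix(rnorm(25), 5), rids = sprintf("m%d", 1:5))
    U <- mk_expr(matrix(rnorm(40), 8), rids = sprintf("g%d", 1:8))
    map <- mk_map(matrix(rbinom(40, 1, 0.5), 8),
                  rids = rownames(U), cids = rownames(V))
  })
  # monotone non-increasing in alpha_level
  counts <- vapply(c(0.01, 0.05, 0.2, 0.5), function(a) {
    fits <- fit_all_pairs(V, U, direction = "two_sided", alpha_level = a)
    module_assoc_count(rownames(V), rownames(U), map, fits)
  }, numeric(1L))
  expect_true(all(diff(counts) >= 0))

  # no predicted pairs: count 0
  empty <- mk_map(matrix(0, 8, 5), rids = rownames(U), cids = rownames(V))
  fits <- fit_all_pairs(V, U)
  expect_equal(module_assoc_count(rownames(V), rownames(U), empty, fits), 0)

  # everything predicted and perfectly anti-linear: maximal count
  v1 <- mk_expr(matrix(c(0.2, -1, 0.5, 1.4, -0.8), 1L), rids = "m1")
  Uanti <- mk_expr(do.call(rbind, lapply(1:4, function(j) {
    j - 2 * unclass(v1)[1L, ]
  })), rids = sprintf("g%d", 1:4))
  full <- mk_map(matrix(1, 4, 1), rids = rownames(Uanti), cids = "m1")
  suppressWarnings(fa <- fit_all_pairs(v1, Uanti, direction = "negative"))
  expect_equal(module_assoc_count("m1", rownames(Uanti), full, fa), 4)
})

test_that("module bootstrap handles extreme observed counts", {
  withr::with_seed(41, {
    V <- mk_expr(matrix(rnorm(25), 5), rids = sprintf("m%d", 1:5))
    U <- mk_expr(matrix(rnorm(100), 20), rids = sprintf("g%d", 1:20))
    map <- mk_map(matrix(rbinom(100, 1, 0.3), 20),
                  rids = rownames(U), cids = rownames(V))
  })
  fits <- fit_all_pairs(V, U)
  b0 <- bootstrap_module_test(rownames(V), 0L, 5L, map, fits, B = 50L,
                              seed = 1L)
  expect_equal(b0$w2, 50L)
  expect_false(b0$significant)

  bmax <- bootstrap_module_test(rownames(V), 10000L, 5L, map, fits,
                                B = 50L, seed = 2L)
  expect_equal(bmax$w2, 0L)
  expect_true(bmax$significant)
})

test_that("module identification applies the majority-targeting filter", {
  # one miRNA, strongly anti-correlated with a 5-gene cluster but predicted
  # to target only 2 of them (40% < majority threshold); a wide mRNA
  # universe keeps random clusters from reproducing both predicted pairs
  T_n <- 6L
  withr::with_seed(43, v <- rnorm(T_n))
  U <- mk_expr(do.call(rbind, lapply(1:60, function(j) {
    -2 * v + rnorm(T_n, sd = 0.05)
  })), rids = sprintf("g%d", 1:60))
  V <- mk_expr(matrix(v, 1L), rids = "mirA")
  vals <- matrix(0, 60, 1, dimnames = list(rownames(U), "mirA"))
  vals[c("g1", "g2"), 1L] <- 1
  map <- map_matrix(vals)
  mods <- identify_modules(list(c1 = "mirA"), list(n1 = sprintf("g%d", 1:5)),
                           map, V, U, B = 50L, seed = 9L)
  m <- tidy(mods)
  expect_true(m$significant)          # 2 associated predicted pairs beat null
  expect_equal(m$min_targeting, 0.4)
  expect_false(m$regulatory)

  # identical seeds give bit-identical module tables
  mods2 <- identify_modules(list(c1 = "mirA"), list(n1 = sprintf("g%d", 1:5)),
                            map, V, U, B = 50L, seed = 9L)
  expect_identical(tidy(mods), tidy(mods2))
})
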