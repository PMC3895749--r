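test_that("protected division is total", {
  expect_equal(protected_divide(6, 3), 2)
  expect_equal(protected_divide(5, 0), 1)
  expect_equal(protected_divide(0, 0), 1)
  expect_equal(protected_divide(c(6, 5, 0), c(3, 0, 0)), c(2, 1, 1))
  expect_equal(protected_divide(1, 1e-12), 1)   # near-zero guard
  expect_equal(protected_divide(1, 1e-6), 1e6)
})

test_that("random trees respect the configured depth range and function set", {
  cfg <- gp_config(init_depth = c(2, 6), max_depth = 12)
  set.seed(31)
  depths <- replicate(500, tree_depth(random_tree(cfg, n_variables = 4)))
  expect_true(all(depths >= 2 & depths <= 6))

  add_only <- gp_config(function_set = "add")
  set.seed(32)
  for (i in 1:20) {
    tr <- random_tree(add_only, 3)
    expect_true(all(tr$code[tr$code > 0] == 1L))
  }
  # no ephemeral constants when disabled
  novar <- gp_config(constant_range = NULL)
  set.seed(33)
  for (i in 1:20) expect_false(any(random_tree(novar, 3)$code == 0L))
  # identical RNG state gives the identical tree
  set.seed(34)
  t1 <- random_tree(cfg, 4)
  set.seed(34)
  t2 <- random_tree(cfg, 4)
  expect_identical(t1, t2)
})

test_that("tree evaluation matches an independent interpreter", {
  t_div <- parse_tree("div(x1, x2)", 2)
  expect_equal(evaluate_tree(t_div, matrix(c(8, 20), 1)), 0.4)
  t_const <- parse_tree("0.7", 1)
  expect_equal(evaluate_tree(t_const, matrix(1:5)), rep(0.7, 5))
  t_guard <- parse_tree("div(x1, sub(x2, x2))", 2)
  expect_equal(evaluate_tree(t_guard, matrix(rnorm(10), 5, 2)), rep(1, 5))

  cfg <- gp_config()
  set.seed(35)
  X <- matrix(runif(60), 20, 3)
  for (i in 1:100) {
    tr <- random_tree(cfg, 3)
    expect_equal(evaluate_tree(tr, X), oracle_eval_tree(tr, X))
  }
  expect_error(evaluate_tree(parse_tree("add(x1, x5)", 5), X),
               "unbound|malformed")
})

test_that("fitness reports rmse and the zero-variance correlation convention", {
  f <- fitness(c(1, 2, 3), c(1, 2, 3))
  expect_equal(f$rmse, 0)
  expect_equal(f$pearson_r, 1)
  expect_equal(fitness(c(2, 2, 2), c(1, 5, 3))$pearson_r, 0)
  f2 <- fitness(c(1, 0), c(0, 1))
  expect_equal(f2$rmse, 1)
  expect_equal(f2$pearson_r, -1)
  expect_error(fitness(1:3, 1:4), "equal-length")
  expect_error(fitness(1, 1), "equal-length")
  expect_equal(fitness(c(Inf, 1), c(0, 1))$rmse, Inf)
})

test_that("serialization round-trips structure and constants", {
  cfg <- gp_config()
  set.seed(36)
  for (i in 1:50) {
    tr <- random_tree(cfg, 5)
    back <- parse_tree(tree_to_string(tr), 5)
    expect_identical(back$code, tr$code)
    expect_equal(back$value[!is.na(back$value)],
                 tr$value[!is.na(tr$value)], tolerance = 1e-10)
  }
  tr <- parse_tree("add(x1, 0.5)", 2)
  expect_equal(tree_depth(tr), 2)
  expect_equal(tree_size(tr), 3)
  expect_equal(tree_variables(tr), 1L)
  expect_equal(tree_to_infix(tr), "(x1 + 0.5)")
  expect_error(parse_tree("add(x1", 2), "parse error at position")
  expect_error(parse_tree("add(x1, x2) junk", 2), "trailing")
  expect_error(parse_tree("add(x1, x9)", 2), "out of range")
  expect_error(parse_tree("frob(x1, x2)", 2), "unknown token")
})

test_that("evolution recovers a planted linear target and is deterministic", {
  set.seed(37)
  X <- matrix(runif(100), 50, 2)
  colnames(X) <- c("x1", "x2")
  y <- X[, 1]
  cfg <- gp_config(generations = 100, stop_rmse = 1e-9, seed = 91)
  res <- evolve(cfg, X, y)
  expect_lte(res$train_fitness$rmse, 0.01)
  expect_true(all(diff(res$trajectory) <= 1e-12))
  res2 <- evolve(cfg, X, y)
  expect_identical(tree_to_string(res$best_tree),
                   tree_to_string(res2$best_tree))
  expect_identical(res$trajectory, res2$trajectory)
})

test_that("division-only search solves an exact ratio quickly", {
  set.seed(38)
  X <- matrix(runif(80, 0.1, 1), 40, 2)
  y <- X[, 1] / X[, 2]
  cfg <- gp_config(generations = 50, function_set = "div",
                   constant_range = NULL, stop_rmse = 1e-9, seed = 12)
  res <- evolve(cfg, X, y)
  expect_lt(res$train_fitness$rmse, 1e-6)
})

test_that("degenerate targets and depth limits are handled", {
  set.seed(39)
  X <- matrix(runif(20), 10, 2)
  expect_warning(res <- evolve(tiny_gp(seed = 1), X, rep(0.3, 10)),
                 "constant target")
  expect_true(length(res$warnings) > 0)
  # max depth respected through evolution
  cfg <- gp_config(population_size = 50, generations = 10, max_depth = 7,
                   init_depth = c(2, 4), seed = 3)
  res2 <- evolve(cfg, X, runif(10))
  expect_lte(tree_depth(res2$best_tree), 7)
  expect_error(evolve(cfg, X, runif(9)), "match")
})
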