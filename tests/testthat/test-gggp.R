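test_that("crossover preserves grammar validity and swaps subtrees", {
  g <- default_grammar(2)
  sin_x1 <- make_node("s", make_node("expr",
    make_node("pre", make_node("sin")),
    make_node("expr", make_node("var", make_node("x_1")))))
  cos_x2 <- make_node("s", make_node("expr",
    make_node("pre", make_node("cos")),
    make_node("expr", make_node("var", make_node("x_2")))))
  set.seed(14)
  seen <- character(0)
  for (k in 1:200) {
    kids <- crossover_trees(sin_x1, cos_x2, g)
    expect_true(validate_tree(g, kids[[1]]))
    expect_true(validate_tree(g, kids[[2]]))
    seen <- union(seen, vapply(kids, function(tr)
      sent_key(tree_yield(tr)), character(1)))
  }
  # the var-level swap produces sin x_2 / cos x_1 among the outcomes
  expect_true("sin x_2" %in% seen)
  expect_true("cos x_1" %in% seen)
  # self-crossover keeps the yield when the swapped subtrees are identical
  kids <- crossover_trees(sin_x1, sin_x1, g)
  expect_equal(tree_yield(kids[[1]]), tree_yield(sin_x1))
  expect_equal(tree_yield(kids[[2]]), tree_yield(sin_x1))
})

test_that("mutation keeps trees valid and within the depth cap", {
  g <- default_grammar(2)
  x1 <- make_node("s", make_node("expr", make_node("var", make_node("x_1"))))
  set.seed(15)
  for (k in 1:100) {
    mt <- mutate_tree(x1, g, depth_cap = 10)
    expect_true(validate_tree(g, mt))
    expect_lte(tree_depth(mt), 10)
  }
  # leaf mutation of the variable slot can only yield x_1 or x_2
  leaf_results <- character(0)
  set.seed(16)
  for (k in 1:200) {
    mt <- mutate_tree(x1, g, depth_cap = 4)  # cap forces leaf-level edits
    leaf_results <- union(leaf_results, sent_key(tree_yield(mt)))
  }
  expect_true(all(leaf_results %in% c("x_1", "x_2")))
  expect_setequal(leaf_results, c("x_1", "x_2"))
})

test_that("fitness of a zero-coefficient model is the constant-predictor RMSE", {
  dat <- toy_expr_data()
  cd <- real_to_complex(dat, "embed")
  tr <- make_node("s", make_node("expr", make_node("var", make_node("x_2"))))
  p <- gggp_params(parsimony = 0, regulator_penalty = 0)
  f <- fitness_of(list(tree = tr, coefs = 0 + 0i), target = 1, cd, p)
  obs <- dat$values[1, ]
  expect_equal(f, sqrt(mean((obs - obs[1])^2)), tolerance = 1e-10)
})

test_that("fitness is invariant to relabeling of non-target genes", {
  set.seed(20)
  t <- seq(0, 5, by = 0.25)
  v <- rbind(0.5 + 0.3 * cos(t), 0.4 + 0.2 * sin(t), 0.6 + 0.1 * sin(2 * t))
  x <- expression_matrix(v)
  cd <- real_to_complex(x, "embed")
  tr2 <- make_node("s", make_node("expr", make_node("var", make_node("x_2"))))
  tr3 <- make_node("s", make_node("expr", make_node("var", make_node("x_3"))))
  p <- gggp_params()
  f1 <- fitness_of(list(tree = tr2, coefs = 0.3 + 0.1i), 1, cd, p)
  # swap genes 2 and 3 in the data and reference the relabeled variable
  cd_swap <- cd
  cd_swap$values <- cd$values[c(1, 3, 2), ]
  f2 <- fitness_of(list(tree = tr3, coefs = 0.3 + 0.1i), 1, cd_swap, p)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("a model fitted to its own noise-free data has near-zero fitness", {
  sys <- random_system(2, edge_density = 1e-9, terms_per_gene = c(1, 1),
                       n_points = 40, readout_bounds = c(0.02, 0.98),
                       min_amplitude = 0.1, max_tries = 500, seed = 301)
  dat <- simulate_grn(sys$system, sys$z0, n_points = 40, normalize = FALSE)
  cd <- real_to_complex(dat, "embed")
  p <- gggp_params(parsimony = 0, regulator_penalty = 0)
  for (i in 1:2) {
    mo <- sys$system$models[[i]]
    ctx <- cvgrn:::fitness_context(i, cd, p)
    prog <- cvgrn:::compile_terms(mo$terms)
    f <- cvgrn:::ctx_fitness(ctx, prog, mo$signs * mo$coefs, 0)
    expect_lt(f, 1e-2)
  }
})

test_that("evolution bookkeeping: trace, determinism, zero generations", {
  dat <- toy_expr_data()
  cd <- real_to_complex(dat, "embed")
  p <- gggp_params(population = 12, generations = 6, cfa_every = 3,
                   cfa = cfa_params(population = 8, iterations = 5),
                   seed = 42)
  res <- evolve_gene(1, cd, p)
  expect_lte(length(res$trace), p$generations + 1)
  expect_true(all(diff(res$trace) <= 0))
  expect_true(is.finite(res$fitness))
  expect_true(validate_tree(default_grammar(2), res$individual$tree))
  res2 <- evolve_gene(1, cd, p)
  expect_identical(model_to_string(res2$model), model_to_string(res$model))
  expect_identical(res2$fitness, res$fitness)
  p0 <- p; p0$generations <- 0L
  res0 <- evolve_gene(1, cd, p0)
  expect_length(res0$trace, 1)
  expect_true(is.finite(res0$fitness))
})

test_that("population closure: all evolved individuals stay grammatical", {
  g <- default_grammar(3)
  set.seed(77)
  pool <- replicate(30, random_derivation(g, 6), simplify = FALSE)
  for (k in 1:300) {
    i <- sample(30, 2)
    kids <- crossover_trees(pool[[i[1]]], pool[[i[2]]], g)
    mt <- mutate_tree(kids[[1]], g)
    expect_true(validate_tree(g, kids[[1]]) && validate_tree(g, kids[[2]]) &&
                validate_tree(g, mt))
    expect_lte(tree_depth(mt), 10)
    pool[[i[1]]] <- mt
  }
})
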