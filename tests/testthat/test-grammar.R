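test_that("default grammar satisfies the quadruple invariants", {
  g <- default_grammar(3)
  expect_length(intersect(g$nonterminals, g$terminals), 0)
  expect_true(all(g$start %in% g$nonterminals))
  expect_true(all(vapply(g$productions, function(p)
    p$lhs %in% g$nonterminals, logical(1))))
  expect_true(all(vapply(g$productions, function(p)
    all(p$rhs %in% c(g$nonterminals, g$terminals)), logical(1))))
  expect_true(all(is.finite(g$min_depth[g$nonterminals])))
  expect_error(default_grammar(0), "m must be")
  # m = 1: the var production derives exactly x_1
  sents <- enumerate_sentences(default_grammar(1), 4)
  expect_equal(vapply(sents, sent_key, character(1)), "x_1")
})

test_that("the single-variable grammar derives sin z + cos z - z", {
  g <- eq6_grammar()
  tr <- fig9_tree()
  expect_true(validate_tree(g, tr))
  expect_equal(tree_yield(tr), c("sin", "z", "+", "cos", "z", "-", "z"))
  usage <- production_usage(tr)
  expect_equal(sum(usage == "expr -> expr op expr"), 2)
  expect_equal(sum(usage == "expr -> pre expr"), 2)
  expect_equal(sum(usage == "expr -> var"), 3)
  expect_equal(sum(usage == "var -> z"), 3)
  expect_equal(sum(usage == "s -> expr"), 1)
  # the same structure over gene variables is a sentence of the full grammar
  g6 <- default_grammar(6)
  tr6 <- fig9_tree("x_1")
  expect_true(validate_tree(g6, tr6))
  expect_equal(tree_yield(tr6), c("sin", "x_1", "+", "cos", "x_1", "-", "x_1"))
})

test_that("random derivations are valid, bounded and reproducible", {
  g <- default_grammar(2)
  # minimal depth forces the shortest derivation s -> expr -> var -> x_k
  set.seed(4)
  short <- random_derivation(g, 4)
  expect_equal(tree_depth(short), 4L)
  expect_true(sent_key(tree_yield(short)) %in% c("x_1", "x_2"))
  expect_error(random_derivation(g, 3), "minimal completion depth")
  set.seed(11)
  a <- replicate(5, tree_yield(random_derivation(g, 8)), simplify = FALSE)
  set.seed(11)
  b <- replicate(5, tree_yield(random_derivation(g, 8)), simplify = FALSE)
  expect_identical(a, b)
  set.seed(2)
  trees <- replicate(500, random_derivation(g, 6), simplify = FALSE)
  expect_true(all(vapply(trees, validate_tree, logical(1), grammar = g)))
  expect_true(all(vapply(trees, tree_depth, integer(1)) <= 6))
  # every observed yield is in the exhaustive depth-6 sentence set
  sents <- vapply(enumerate_sentences(g, 6), sent_key, character(1))
  expect_true(all(vapply(trees, function(tr) sent_key(tree_yield(tr)),
                         character(1)) %in% sents))
})

test_that("validate_tree rejects malformed trees", {
  g <- default_grammar(2)
  expect_false(validate_tree(g, make_node("expr")))      # nonterminal leaf
  expect_false(validate_tree(g, make_node("nope")))      # unknown symbol
  bad <- make_node("s", make_node("op", make_node("+"))) # wrong production
  expect_false(validate_tree(g, bad))
})

test_that("sentence enumeration matches an independent oracle and is monotone", {
  for (m in 1:2) {
    g <- default_grammar(m)
    for (d in 4:5) {
      mine <- sort(vapply(enumerate_sentences(g, d), sent_key, character(1)))
      ref <- sort(oracle_sentences(g, d))
      expect_equal(mine, ref, info = sprintf("m=%d depth=%d", m, d))
    }
  }
  g <- default_grammar(2)
  s4 <- vapply(enumerate_sentences(g, 4), sent_key, character(1))
  s5 <- vapply(enumerate_sentences(g, 5), sent_key, character(1))
  s6 <- vapply(enumerate_sentences(g, 6), sent_key, character(1))
  expect_true(all(s4 %in% s5))
  expect_true(all(s5 %in% s6))
  expect_true("x_1 + x_2" %in% s5)
  expect_true("cos x_2" %in% s5)
  expect_error(enumerate_sentences(g, 8, cap = 100), "cap")
})

test_that("yield length equals leaf count", {
  g <- default_grammar(3)
  set.seed(5)
  for (k in 1:20) {
    tr <- random_derivation(g, 7)
    leaves <- sum(vapply(cvgrn:::flatten_tree(tr), `[[`, logical(1), "leaf"))
    expect_length(tree_yield(tr), leaves)
  }
})

test_that("grammar files round-trip through the plain-text format", {
  g <- default_grammar(2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_grammar(g, path)
  g2 <- read_grammar(path)
  expect_equal(g2$start, g$start)
  expect_setequal(g2$terminals, g$terminals)
  expect_equal(sort(vapply(enumerate_sentences(g2, 5), sent_key, character(1))),
               sort(vapply(enumerate_sentences(g, 5), sent_key, character(1))))
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("a b c", bad)
  expect_error(read_grammar(bad), "malformed")
})
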