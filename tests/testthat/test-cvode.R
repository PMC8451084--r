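sos_x6_model <- function() {
  cvode_model(
    target = 6,
    coefs = c(complex(real = 0.0461, imaginary = 0.0237),
              complex(real = 0.2843, imaginary = 0.0345)),
    signs = c(1, -1),
    terms = list(
      list(kind = "binary", op = "*",
           left = list(kind = "var", index = 3L),
           right = list(kind = "var", index = 2L)),
      list(kind = "binary", op = "*",
           left = list(kind = "binary", op = "*",
                       left = list(kind = "var", index = 6L),
                       right = list(kind = "var", index = 6L)),
           right = list(kind = "var", index = 6L))),
    m = 6)
}

test_that("derivation trees decode to signed-sum models", {
  # single variable: one term
  t1 <- make_node("s", make_node("expr", make_node("var", make_node("x_1"))))
  m1 <- from_derivation(t1, 1 + 0i)
  expect_length(m1$terms, 1)
  expect_equal(eval_model(m1, 0.7 + 0i), 0.7 + 0i)
  # sin x + cos x - x: three terms, signs + + -
  m3 <- from_derivation(fig9_tree("x_1"), rep(1 + 0i, 3))
  expect_length(m3$terms, 3)
  expect_equal(m3$signs, c(1, 1, -1))
  expect_equal(eval_model(m3, 0 + 0i), 1 + 0i)  # sin 0 + cos 0 - 0
  expect_error(from_derivation(fig9_tree("x_1"), c(1, 2)), "does not match")
  # term count equals the top-level split of random trees
  g <- default_grammar(2)
  set.seed(8)
  for (k in 1:25) {
    tr <- random_derivation(g, 7)
    spine_terms <- function(node) {
      while (length(node$children) == 1L) node <- node$children[[1L]]
      if (length(node$children) == 3L) {
        op <- tree_yield(node$children[[2L]])
        if (op %in% c("+", "-"))
          return(spine_terms(node$children[[1L]]) +
                 spine_terms(node$children[[3L]]))
      }
      1L
    }
    expect_equal(n_terms(tr), spine_terms(tr))
  }
})

test_that("model evaluation matches hand arithmetic and is linear in beta", {
  m6 <- sos_x6_model()
  v <- eval_model(m6, rep(1 + 0i, 6))
  expect_equal(v, complex(real = -0.2382, imaginary = -0.0108),
               tolerance = 1e-12)
  expect_equal(extract_regulators(m6), c(2L, 3L, 6L))
  zero <- m6; zero$coefs[] <- 0 + 0i
  expect_equal(eval_model(zero, runif(6) + 1i * runif(6)), 0 + 0i)
  expect_error(eval_model(m6, c(NA, rep(1 + 0i, 5))), "NA")
  # linearity in the coefficient vector
  set.seed(3)
  for (k in 1:10) {
    st <- complex(real = runif(6), imaginary = runif(6))
    b1 <- complex(real = rnorm(2), imaginary = rnorm(2))
    b2 <- complex(real = rnorm(2), imaginary = rnorm(2))
    ma <- m6; ma$coefs <- b1
    mb <- m6; mb$coefs <- b2
    mc <- m6; mc$coefs <- b1 + b2
    expect_equal(eval_model(mc, st), eval_model(ma, st) + eval_model(mb, st),
                 tolerance = 1e-12)
  }
})

test_that("compiled term programs agree with the reference evaluator", {
  g <- default_grammar(3)
  set.seed(21)
  for (k in 1:30) {
    tr <- random_derivation(g, 7)
    mo <- from_derivation(tr, rep(1 + 0i, n_terms(tr)), m = 3)
    prog <- cvgrn:::compile_terms(mo$terms)
    st <- complex(real = runif(3, -1, 1), imaginary = runif(3, -1, 1))
    ref <- vapply(mo$terms, function(tm) cvgrn:::eval_expr_r(tm, st),
                  complex(1))
    got <- cpp_eval_terms(prog$code, prog$starts, prog$lens, st, 1e-6)
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("protected division is finite and continuous at the threshold", {
  expect_equal(protected_div(1 + 0i, 2 + 0i), 0.5 + 0i)
  eps <- 1e-6
  expect_equal(protected_div(3 + 0i, 0 + 0i, eps), (3 + 0i) / eps)
  # just above vs just below the threshold differ by a bounded factor
  above <- protected_div(1 + 0i, complex(real = 1.01e-6), eps)
  below <- protected_div(1 + 0i, complex(real = 0.99e-6), eps)
  expect_lt(Mod(above / below), 1.05)
  expect_gt(Mod(above / below), 0.95)
  # direction of the denominator is preserved
  d <- protected_div(1 + 0i, complex(real = 0, imaginary = 1e-9), eps)
  expect_equal(Arg(d), -pi / 2, tolerance = 1e-12)
})

test_that("decoupled RK4 integration reproduces closed forms", {
  # zero model: constant trajectory
  cd <- complex_mat(matrix(0.4 + 0i, 1, 5), times = 0:4)
  zero <- cvode_model(target = 1, coefs = 0 + 0i,
                      terms = list(list(kind = "var", index = 1L)), m = 1)
  tr <- integrate_decoupled(zero, cd)
  expect_equal(unname(as.complex(tr)), rep(0.4 + 0i, 5))
  # dZ/dt = iZ from 1+0i to t = pi gives -1 (e^{i pi})
  rot <- cvode_model(target = 1, coefs = 0 + 1i,
                     terms = list(list(kind = "var", index = 1L)), m = 1)
  cd2 <- complex_mat(matrix(1 + 0i, 1, 2), times = c(0, pi))
  z <- integrate_decoupled(rot, cd2, substeps = 1000)
  expect_lt(Mod(z[2] - (-1 + 0i)), 1e-6)
  # order-4 convergence against the exact solution e^{it}
  cd3 <- complex_mat(matrix(1 + 0i, 1, 2), times = c(0, 2))
  e1 <- Mod(integrate_decoupled(rot, cd3, substeps = 4)[2] - exp(2i))
  e2 <- Mod(integrate_decoupled(rot, cd3, substeps = 8)[2] - exp(2i))
  expect_gt(e1 / e2, 10)
  expect_lt(e1 / e2, 25)
})

test_that("decoupled integration agrees with a fine-step Euler oracle", {
  t <- seq(0, 5, by = 0.5)
  vals <- rbind(0.5 + 0.3 * cos(t) + 0.1i * sin(t),
                0.6 + 0.2 * sin(t) - 0.05i * cos(t))
  cd <- complex_mat(vals, times = t)
  b <- c(complex(real = 0.4, imaginary = 0.2),
         complex(real = -0.3, imaginary = 0.1))
  mo <- cvode_model(target = 1, coefs = b,
                    terms = list(
                      list(kind = "unary", op = "sin",
                           child = list(kind = "var", index = 2L)),
                      list(kind = "binary", op = "*",
                           left = list(kind = "var", index = 1L),
                           right = list(kind = "var", index = 2L))),
                    m = 2)
  got <- integrate_decoupled(mo, cd, substeps = 4)
  # hand-coded right-hand side, independent integrator
  rhs <- function(st) b[1] * sin(st[2]) + b[2] * st[1] * st[2]
  ref <- euler_decoupled(rhs, cd, target = 1, steps_per_interval = 4000L)
  expect_lt(max(Mod(as.complex(got) - ref)), 1e-4)
})

test_that("real coefficients on real data stay on the real slice", {
  t <- seq(0, 4, by = 0.25)
  vals <- rbind(0.5 + 0.3 * cos(t) + 0i, 0.6 + 0.2 * sin(t) + 0i)
  cd <- complex_mat(vals, times = t)
  mo <- cvode_model(target = 1, coefs = c(-0.5 + 0i),
                    terms = list(list(kind = "var", index = 2L)), m = 2)
  tr <- integrate_decoupled(mo, cd)
  expect_lt(max(abs(Im(tr))), 1e-12)
})

test_that("regulator extraction matches a leaf scan of the yield", {
  g <- default_grammar(4)
  set.seed(33)
  for (k in 1:25) {
    tr <- random_derivation(g, 7)
    mo <- from_derivation(tr, rep(1 + 0i, n_terms(tr)), m = 4)
    toks <- tree_yield(tr)
    ref <- sort(unique(as.integer(sub("^x_", "", toks[grepl("^x_", toks)]))))
    expect_equal(extract_regulators(mo), ref)
  }
})

test_that("divergent models trip the guard", {
  cd <- complex_mat(matrix(0.5 + 0i, 1, 40), times = 0:39)
  blow <- cvode_model(target = 1, coefs = 50 + 0i,
                      terms = list(list(kind = "var", index = 1L)), m = 1)
  tr <- integrate_decoupled(blow, cd, div_limit = 1e6)
  expect_true(attr(tr, "diverged"))
  expect_true(any(is.na(tr)))
})
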