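# CVODE models: one target gene's equation dZ_i/dt = sum_k beta_k e_k(Z),
# with complex coefficients beta_k and expression terms e_k decoded from a
# derivation tree.  Expressions are small ASTs; the integration hot path
# compiles them to postfix programs executed in C++.

cv_var <- function(index) list(kind = "var", index = as.integer(index))
cv_unary <- function(op, child) list(kind = "unary", op = op, child = child)
cv_binary <- function(op, left, right)
  list(kind = "binary", op = op, left = left, right = right)

var_index_of <- function(symbol, var_names = NULL) {
  if (!is.null(var_names)) {
    i <- match(symbol, var_names)
    if (!is.na(i)) return(i)
  }
  if (grepl("^x_[0-9]+$", symbol))
    return(as.integer(sub("^x_", "", symbol)))
  if (!is.null(var_names))
    stop(sprintf("unknown variable terminal '%s'", symbol))
  1L  # single-variable grammars (e.g. terminal 'z') map to gene 1
}

# Convert a derivation subtree rooted at an expr-like node into an AST.
# Shapes recognised: unit chains (s -> expr, expr -> var, var -> x_k,
# pre -> sin), (pre expr) unary nodes and (expr op expr) binary nodes.
derivation_to_ast <- function(node, var_names = NULL) {
  nk <- length(node$children)
  if (nk == 0L) return(cv_var(var_index_of(node$symbol, var_names)))
  if (nk == 1L) return(derivation_to_ast(node$children[[1L]], var_names))
  if (nk == 2L) {
    op <- tree_yield(node$children[[1L]])
    if (length(op) != 1L || !(op %in% c("sin", "cos")))
      stop("unsupported unary operator in derivation tree")
    return(cv_unary(op, derivation_to_ast(node$children[[2L]], var_names)))
  }
  if (nk == 3L) {
    op <- tree_yield(node$children[[2L]])
    if (length(op) != 1L || !(op %in% c("+", "-", "*", "/")))
      stop("unsupported binary operator in derivation tree")
    return(cv_binary(op, derivation_to_ast(node$children[[1L]], var_names),
                     derivation_to_ast(node$children[[3L]], var_names)))
  }
  stop("unsupported derivation tree shape")
}

# Split the top-level additive structure of a derivation tree into signed
# terms: the tree is read as a flat signed sum, '-' flipping the sign of
# everything to its right operand.  Returns list of list(sign, node).
split_signed_terms <- function(tree) {
  out <- list()
  walk <- function(node, sign) {
    while (length(node$children) == 1L) node <- node$children[[1L]]
    if (length(node$children) == 3L) {
      op <- tree_yield(node$children[[2L]])
      if (length(op) == 1L && op %in% c("+", "-")) {
        walk(node$children[[1L]], sign)
        walk(node$children[[3L]], if (op == "-") -sign else sign)
        return(invisible(NULL))
      }
    }
    out[[length(out) + 1L]] <<- list(sign = sign, node = node)
    invisible(NULL)
  }
  walk(tree, 1)
  out
}

#' Number of top-level additive terms of a derivation tree
#'
#' @param tree a derivation tree over the expression grammar.
#' @return integer count of `+`/`-` separated top-level operands.
#' @export
n_terms <- function(tree) length(split_signed_terms(tree))

#' Decode a derivation tree into a CVODE model
#'
#' The top-level `+`/`-` operands of the tree become the model terms
#' \eqn{e_k}; `coefficients[k]` is the complex coefficient of term k, and the
#' `-` signs of the flat sum are kept as a separate sign vector so the
#' effective model is \eqn{\sum_k s_k \beta_k e_k(Z)}.
#'
#' @param tree a derivation tree (root `s` or `expr`).
#' @param coefficients complex vector, one entry per top-level term.
#' @param var_names optional character vector mapping variable terminals to
#'   gene indices (defaults to the `x_k` naming).
#' @param target target gene index stored in the model (default `NA`).
#' @param m number of genes; defaults to the largest referenced index.
#' @return an object of class `"cvode_model"` with fields `target`, `coefs`,
#'   `signs`, `terms` (list of expression ASTs) and `m`.
#' @export
from_derivation <- function(tree, coefficients, var_names = NULL,
                            target = NA_integer_, m = NULL) {
  parts <- split_signed_terms(tree)
  coefficients <- as.complex(coefficients)
  if (length(coefficients) != length(parts))
    stop(sprintf("coefficient vector length %d does not match term count %d",
                 length(coefficients), length(parts)))
  terms <- lapply(parts, function(p) derivation_to_ast(p$node, var_names))
  signs <- vapply(parts, `[[`, numeric(1), "sign")
  cvode_model(target = target, coefs = coefficients, signs = signs,
              terms = terms, m = m)
}

#' Construct a CVODE model from coefficients and expression ASTs
#'
#' @param target target gene index (may be `NA`).
#' @param coefs complex coefficient vector (finite).
#' @param signs numeric vector of +1/-1 term signs (defaults to all +1).
#' @param terms list of expression ASTs.
#' @param m gene count; defaults to the largest referenced variable index.
#' @return object of class `"cvode_model"`.
#' @export
cvode_model <- function(target = NA_integer_, coefs, signs = NULL, terms,
                        m = NULL) {
  coefs <- as.complex(coefs)
  if (is.null(signs)) signs <- rep(1, length(coefs))
  if (length(terms) < 1L) stop("a model needs at least one term")
  if (length(coefs) != length(terms) || length(signs) != length(terms))
    stop("coefs, signs and terms must have equal length")
  if (any(!is.finite(Re(coefs))) || any(!is.finite(Im(coefs))))
    stop("coefficients must be finite")
  vars <- sort(unique(unlist(lapply(terms, expr_vars))))
  if (is.null(m)) m <- max(vars, if (is.na(target)) 0L else target)
  if (any(vars > m)) stop("variable index exceeds gene count m")
  structure(list(target = as.integer(target), coefs = coefs,
                 signs = as.numeric(signs), terms = terms, m = as.integer(m)),
            class = "cvode_model")
}

expr_vars <- function(ast) {
  switch(ast$kind,
         var = ast$index,
         unary = expr_vars(ast$child),
         binary = c(expr_vars(ast$left), expr_vars(ast$right)))
}

#' Regulators referenced by a CVODE model
#'
#' The gene indices whose variables appear anywhere in the model's terms.
#' A gene j in this set means "gene j regulates the model's target".
#'
#' @param model a `"cvode_model"`.
#' @return sorted integer vector of gene indices.
#' @export
extract_regulators <- function(model) {
  sort(unique(unlist(lapply(model$terms, expr_vars))))
}

#' Protected complex division
#'
#' Returns `a/b` when `|b| >= eps`; otherwise divides by `eps` times the
#' unit-phase direction of `b` (or by `eps` itself when `b == 0`).  Keeps
#' evolved quotient expressions finite on data normalized to \[0, 1\].
#'
#' @param a,b complex scalars or vectors (recycled).
#' @param eps protection threshold (> 0).
#' @return complex result of the protected quotient.
#' @export
protected_div <- function(a, b, eps = 1e-6) {
  stopifnot(eps > 0)
  a <- as.complex(a); b <- as.complex(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  mb <- Mod(b)
  small <- mb < eps
  denom <- b
  denom[small & mb > 0] <- eps * (b[small & mb > 0] / mb[small & mb > 0])
  denom[small & mb == 0] <- complex(real = eps)
  a / denom
}

# Reference (pure R) recursive evaluator used by eval_model and as the
# cross-check for the compiled C++ path.
eval_expr_r <- function(ast, state, eps = 1e-6) {
  switch(ast$kind,
         var = state[[ast$index]],
         unary = if (ast$op == "sin") sin(eval_expr_r(ast$child, state, eps))
                 else cos(eval_expr_r(ast$child, state, eps)),
         binary = {
           l <- eval_expr_r(ast$left, state, eps)
           r <- eval_expr_r(ast$right, state, eps)
           switch(ast$op, "+" = l + r, "-" = l - r, "*" = l * r,
                  "/" = protected_div(l, r, eps))
         })
}

#' Evaluate a CVODE model at a complex state
#'
#' Computes \eqn{\sum_k s_k \beta_k e_k(Z)} with complex arithmetic and
#' protected division.
#'
#' @param model a `"cvode_model"`.
#' @param state complex vector of length >= the model's gene count.
#' @param eps protected-division threshold.
#' @return a complex scalar.
#' @examples
#' g <- default_grammar(1)
#' set.seed(1)
#' t1 <- random_derivation(g, 6)
#' m1 <- from_derivation(t1, rep(1 + 0i, n_terms(t1)))
#' eval_model(m1, 0.3 + 0i)
#' @export
eval_model <- function(model, state, eps = 1e-6) {
  state <- as.complex(state)
  if (any(is.na(state)))
    stop("state contains NA/NaN values")
  if (length(state) < model$m) stop("state shorter than gene count")
  vals <- vapply(model$terms, function(tm) eval_expr_r(tm, state, eps),
                 complex(1))
  sum(model$signs * model$coefs * vals)
}

# ---- compilation to postfix programs ------------------------------------

op_codes <- c("var" = 1L, "sin" = 2L, "cos" = 3L,
              "+" = 4L, "-" = 5L, "*" = 6L, "/" = 7L)

ast_to_code <- function(ast) {
  switch(ast$kind,
         var = c(1L, ast$index - 1L),
         unary = c(ast_to_code(ast$child), op_codes[[ast$op]], 0L),
         binary = c(ast_to_code(ast$left), ast_to_code(ast$right),
                    op_codes[[ast$op]], 0L))
}

compile_terms <- function(terms) {
  codes <- lapply(terms, ast_to_code)
  lens <- vapply(codes, length, integer(1))
  list(code = as.integer(unlist(codes)),
       starts = as.integer(cumsum(c(0L, lens[-length(lens)]))),
       lens = as.integer(lens))
}

compile_model <- function(model) {
  prog <- compile_terms(model$terms)
  prog$scoefs <- as.complex(model$signs * model$coefs)
  prog
}

#' Decoupled RK4 integration of one gene's model over observed data
#'
#' Integrates the target gene's equation with the classic fourth-order
#' Runge-Kutta scheme over the sample grid of `cdata`.  Non-target gene
#' values entering the right-hand side are linearly interpolated from the
#' observed complex data at the intermediate stage times; the initial value
#' is the observed complex value of the target gene at the start of the
#' range.  If the state magnitude exceeds `div_limit` the integration is
#' aborted and the remaining trajectory is `NA` (divergence guard).
#'
#' @param model a `"cvode_model"` with `target` set.
#' @param cdata a `"complex_matrix"` (see [real_to_complex()]).
#' @param from,to sample index range (defaults: whole series).
#' @param substeps RK4 substeps per sample interval.
#' @param eps protected-division threshold.
#' @param div_limit divergence guard on `|Z|`.
#' @return complex vector of length `to - from + 1` (the trajectory at the
#'   sample times), with attribute `"diverged"`.
#' @export
integrate_decoupled <- function(model, cdata, from = 1L, to = NULL,
                                substeps = 4L, eps = 1e-6, div_limit = 1e6) {
  stopifnot(inherits(cdata, "complex_matrix"))
  n <- ncol(cdata$values)
  if (is.null(to)) to <- n
  from <- as.integer(from); to <- as.integer(to)
  if (from < 1L || to > n || to <= from)
    stop("invalid index range")
  if (is.na(model$target) || model$target < 1L ||
      model$target > nrow(cdata$values))
    stop("model target index out of range")
  times <- cdata$times[from:to]
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  grid <- stage_grid(cdata, from, to, substeps)
  prog <- compile_model(model)
  res <- cpp_rk4_decoupled(prog$code, prog$starts, prog$lens, prog$scoefs,
                           model$target - 1L, grid$sgrid, grid$hsub,
                           as.integer(substeps),
                           cdata$values[model$target, from],
                           eps, div_limit)
  traj <- res$traj
  names(traj) <- format(times, trim = TRUE)
  attr(traj, "diverged") <- res$diverged
  traj
}

# Interpolate the observed complex data on the RK4 half-step stage grid.
stage_grid <- function(cdata, from, to, substeps) {
  times <- cdata$times[from:to]
  dts <- diff(times)
  hsub <- dts / substeps
  qt <- unlist(lapply(seq_along(dts), function(k)
    times[k] + dts[k] * seq(0, length.out = 2L * substeps,
                            by = 1 / (2 * substeps))))
  qt <- c(qt, times[length(times)])
  vals <- cdata$values[, from:to, drop = FALSE]
  m <- nrow(vals)
  sgrid <- matrix(complex(1), m, length(qt))
  for (i in seq_len(m)) {
    sgrid[i, ] <- complex(real = approx(times, Re(vals[i, ]), xout = qt)$y,
                          imaginary = approx(times, Im(vals[i, ]), xout = qt)$y)
  }
  list(sgrid = sgrid, hsub = hsub)
}

# ---- rendering -----------------------------------------------------------

format_complex <- function(z, digits = 6) {
  sprintf("(%s%s%si)", format(Re(z), digits = digits),
          ifelse(Im(z) < 0, " - ", " + "),
          format(abs(Im(z)), digits = digits))
}

ast_to_string <- function(ast, var_names = NULL) {
  nm <- function(i) if (is.null(var_names)) paste0("x_", i) else var_names[i]
  switch(ast$kind,
         var = nm(ast$index),
         unary = paste0(ast$op, "(", ast_to_string(ast$child, var_names), ")"),
         binary = paste0("(", ast_to_string(ast$left, var_names), " ",
                         ast$op, " ", ast_to_string(ast$right, var_names), ")"))
}

#' Render a CVODE model as an infix string
#'
#' @param model a `"cvode_model"`.
#' @param var_names optional gene names used for the variables.
#' @param digits significant digits for the complex coefficients.
#' @return a single string like
#'   `"dx_2/dt = (0.5 + 0.1i)*x_1 - (1 - 0i)*sin(x_2)"`.
#' @export
model_to_string <- function(model, var_names = NULL, digits = 6) {
  lhs <- if (is.na(model$target)) "dZ/dt"
         else paste0("d", if (is.null(var_names)) paste0("x_", model$target)
                          else var_names[model$target], "/dt")
  parts <- vapply(seq_along(model$terms), function(k) {
    paste0(if (model$signs[k] < 0) " - " else if (k == 1L) "" else " + ",
           format_complex(model$coefs[k], digits), "*",
           ast_to_string(model$terms[[k]], var_names))
  }, character(1))
  paste0(lhs, " = ", paste(parts, collapse = ""))
}

#' @export
print.cvode_model <- function(x, ...) {
  cat(model_to_string(x), "\n")
  invisible(x)
}

#' Bundle per-gene CVODE models into a system
#'
#' @param models list with exactly one `"cvode_model"` per gene, in gene
#'   order (model k must have target k).
#' @return object of class `"cvode_system"`.
#' @export
cvode_system <- function(models) {
  targets <- vapply(models, function(mo) mo$target, integer(1))
  if (!identical(targets, seq_along(models)))
    stop("model k must have target k, for k = 1..m")
  structure(list(models = models, m = length(models)),
            class = "cvode_system")
}

#' @export
print.cvode_system <- function(x, ...) {
  cat(sprintf("<cvode system> %d genes\n", x$m))
  for (mo in x$models) cat("  ", model_to_string(mo), "\n", sep = "")
  invisible(x)
}
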