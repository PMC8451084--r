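# Shared fixtures and independent oracles used across the test files.

make_node <- function(symbol, ...) {
  structure(list(symbol = symbol, children = list(...)),
            class = "derivation_tree")
}

# Minimal single-variable grammar over terminal `z`:
# s -> expr; expr -> expr op expr | pre expr | var; pre -> sin|cos;
# op -> +|-; var -> z.
eq6_grammar <- function() {
  cvode_grammar(
    nonterminals = c("s", "expr", "op", "pre", "var"),
    terminals = c("sin", "cos", "+", "-", "z"),
    productions = list(
      list(lhs = "s", rhs = "expr"),
      list(lhs = "expr", rhs = c("expr", "op", "expr")),
      list(lhs = "expr", rhs = c("pre", "expr")),
      list(lhs = "expr", rhs = "var"),
      list(lhs = "pre", rhs = "sin"),
      list(lhs = "pre", rhs = "cos"),
      list(lhs = "op", rhs = "+"),
      list(lhs = "op", rhs = "-"),
      list(lhs = "var", rhs = "z")),
    start = "s")
}

# Derivation tree of "sin z + cos z - z": ((sin z + cos z) - z).
fig9_tree <- function(var = "z") {
  ex_var <- function() make_node("expr", make_node("var", make_node(var)))
  ex_pre <- function(fn) make_node("expr", make_node("pre", make_node(fn)),
                                   ex_var())
  sum_ <- make_node("expr", ex_pre("sin"), make_node("op", make_node("+")),
                    ex_pre("cos"))
  make_node("s", make_node("expr", sum_, make_node("op", make_node("-")),
                           ex_var()))
}

# Multiset of productions used by a tree, as "lhs -> rhs" strings.
production_usage <- function(tree) {
  out <- character(0)
  walk <- function(node) {
    if (length(node$children) == 0L) return(invisible(NULL))
    kids <- vapply(node$children, function(ch) ch$symbol, character(1))
    out <<- c(out, paste(node$symbol, "->", paste(kids, collapse = " ")))
    for (ch in node$children) walk(ch)
  }
  walk(tree)
  sort(out)
}

sent_key <- function(s) paste(s, collapse = " ")

# Second, independent implementation of bounded-depth sentence enumeration:
# enumerates complete derivations via expand.grid over child alternatives
# (no memoization, no sharing with the package's recursive-set algorithm).
oracle_sentences <- function(g, max_depth) {
  expand_sym <- function(sym, budget) {
    if (sym %in% g$terminals) {
      if (budget < 1L) return(list())
      return(list(sym))
    }
    if (budget < 2L) return(list())  # a nonterminal needs at least one level
    out <- list()
    for (p in g$productions) {
      if (p$lhs != sym) next
      kid_opts <- lapply(p$rhs, expand_sym, budget = budget - 1L)
      if (any(vapply(kid_opts, length, integer(1)) == 0L)) next
      grid <- expand.grid(lapply(kid_opts, seq_along))
      for (r in seq_len(nrow(grid))) {
        out[[length(out) + 1L]] <- unlist(lapply(seq_along(kid_opts),
          function(j) kid_opts[[j]][[grid[r, j]]]))
      }
    }
    out
  }
  res <- list()
  for (s in g$start) res <- c(res, expand_sym(s, max_depth))
  unique(vapply(res, sent_key, character(1)))
}

# Wrap a complex value matrix as the package's complex-data container.
complex_mat <- function(values, times = NULL, mode = "embed",
                        gene_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(times)) times <- seq_len(ncol(values)) - 1
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  out <- structure(list(gene_ids = gene_ids, times = as.numeric(times),
                        values = values),
                   class = "complex_matrix")
  attr(out, "mode") <- mode
  out
}

# Independent fine-step forward-Euler integrator for a hand-coded RHS
# f(z_target, state_vector) with non-target genes linearly interpolated.
euler_decoupled <- function(rhs, cdata, target, steps_per_interval = 400L) {
  times <- cdata$times
  vals <- cdata$values
  interp <- function(tt) {
    vapply(seq_len(nrow(vals)), function(i)
      complex(real = approx(times, Re(vals[i, ]), xout = tt)$y,
              imaginary = approx(times, Im(vals[i, ]), xout = tt)$y),
      complex(1))
  }
  z <- vals[target, 1L]
  out <- z
  for (k in seq_len(length(times) - 1L)) {
    h <- (times[k + 1L] - times[k]) / steps_per_interval
    tt <- times[k]
    for (s in seq_len(steps_per_interval)) {
      st <- interp(tt)
      st[target] <- z
      z <- z + h * rhs(st)
      tt <- tt + h
    }
    out <- c(out, z)
  }
  out
}

# A small, well-behaved 2-gene dataset on [0,1]: smooth damped oscillations.
toy_expr_data <- function(n = 30L, dt = 0.25) {
  t <- (seq_len(n) - 1) * dt
  v <- rbind(0.5 + 0.3 * cos(t) * exp(-0.05 * t),
             0.5 + 0.25 * sin(0.8 * t) * exp(-0.03 * t))
  expression_matrix(v, c("g1", "g2"), t)
}
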