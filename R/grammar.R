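# Context-free grammar machinery: the genotype space of the structure search
# is the set of derivation trees of a small expression grammar.

new_node <- function(symbol, children = list()) {
  structure(list(symbol = symbol, children = children),
            class = "derivation_tree")
}

#' Construct a context-free grammar
#'
#' A grammar is the quadruple (N, T, P, S) of nonterminals, terminals,
#' productions and start symbols.  Constraints checked at construction:
#' N and T are disjoint, every start symbol is a nonterminal, every
#' production maps a nonterminal to a sequence of known symbols, and every
#' nonterminal is productive (can derive a terminal-only string in finite
#' depth).
#'
#' @param nonterminals character vector of nonterminal symbol names.
#' @param terminals character vector of terminal symbol names.
#' @param productions list of productions, each `list(lhs =, rhs =)` with
#'   `lhs` a nonterminal and `rhs` a character vector of symbols.
#' @param start character vector of start symbols (subset of
#'   `nonterminals`).
#' @return an object of class `"cvode_grammar"`.
#' @seealso [default_grammar()], [random_derivation()], [enumerate_sentences()]
#' @export
cvode_grammar <- function(nonterminals, terminals, productions, start) {
  nonterminals <- as.character(nonterminals)
  terminals <- as.character(terminals)
  start <- as.character(start)
  if (length(intersect(nonterminals, terminals)) > 0L)
    stop("nonterminals and terminals must be disjoint")
  if (!all(start %in% nonterminals))
    stop("every start symbol must be a nonterminal")
  if (length(start) < 1L) stop("at least one start symbol is required")
  for (p in productions) {
    if (!is.character(p$lhs) || length(p$lhs) != 1L || !(p$lhs %in% nonterminals))
      stop("production lhs must be a single nonterminal")
    if (length(p$rhs) < 1L || !all(p$rhs %in% c(nonterminals, terminals)))
      stop(sprintf("production '%s -> %s' uses unknown symbols",
                   p$lhs, paste(p$rhs, collapse = " ")))
  }
  g <- structure(list(nonterminals = nonterminals, terminals = terminals,
                      productions = productions, start = start),
                 class = "cvode_grammar")
  md <- min_depths(g)
  if (any(!is.finite(md[nonterminals])))
    stop(sprintf("unproductive nonterminal(s): %s",
                 paste(nonterminals[!is.finite(md[nonterminals])],
                       collapse = ", ")))
  g$min_depth <- md
  g
}

# Minimal completion depth per symbol: a terminal completes at depth 1; a
# nonterminal needs 1 + min over its productions of the deepest rhs symbol.
min_depths <- function(g) {
  md <- stats::setNames(rep(Inf, length(g$nonterminals)), g$nonterminals)
  md <- c(md, stats::setNames(rep(1, length(g$terminals)), g$terminals))
  repeat {
    changed <- FALSE
    for (p in g$productions) {
      cand <- 1 + max(md[p$rhs])
      if (cand < md[[p$lhs]]) {
        md[[p$lhs]] <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  md
}

#' Default expression grammar over m gene variables
#'
#' Nonterminals are `{s, expr, op, pre, var}`; terminals are the unary
#' functions `sin`, `cos`, the binary operators `+ - * /` and the gene
#' variables `x_1 ... x_m`.  Integer powers are expressed as repeated `*`.
#'
#' @param m number of genes (>= 1).
#' @return a [cvode_grammar()] object.
#' @examples
#' g <- default_grammar(2)
#' tree_yield(random_derivation(g, max_depth = 6))
#' @export
default_grammar <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1)
    stop("m must be a single integer >= 1")
  m <- as.integer(m)
  vars <- paste0("x_", seq_len(m))
  prods <- c(
    list(list(lhs = "s", rhs = "expr"),
         list(lhs = "expr", rhs = c("expr", "op", "expr")),
         list(lhs = "expr", rhs = c("pre", "expr")),
         list(lhs = "expr", rhs = "var"),
         list(lhs = "pre", rhs = "sin"),
         list(lhs = "pre", rhs = "cos"),
         list(lhs = "op", rhs = "+"),
         list(lhs = "op", rhs = "-"),
         list(lhs = "op", rhs = "*"),
         list(lhs = "op", rhs = "/")),
    lapply(vars, function(v) list(lhs = "var", rhs = v))
  )
  cvode_grammar(nonterminals = c("s", "expr", "op", "pre", "var"),
                terminals = c("sin", "cos", "+", "-", "*", "/", vars),
                productions = prods, start = "s")
}

# Restrict the var productions of a default-style grammar to a subset of
# gene indices (used by the synthetic generator to force regulator sets).
restrict_variables <- function(g, indices) {
  keep <- paste0("x_", indices)
  prods <- Filter(function(p) p$lhs != "var" || p$rhs %in% keep,
                  g$productions)
  cvode_grammar(g$nonterminals, g$terminals, prods, g$start)
}

productions_of <- function(g, sym) {
  Filter(function(p) p$lhs == sym, g$productions)
}

#' Draw a random derivation tree
#'
#' Expands symbols top-down.  At each nonterminal a production is chosen
#' uniformly among those that can still complete within the remaining depth
#' budget, which guarantees termination.  Randomness comes from the current
#' R random number stream, so results are reproducible under [set.seed()].
#'
#' @param grammar a [cvode_grammar()].
#' @param max_depth maximum tree depth (root has depth 1, terminal leaves
#'   count); must be at least the minimal completion depth of the start
#'   symbol (4 for [default_grammar()]).
#' @param start start symbol; by default drawn uniformly from the grammar's
#'   start set.
#' @return a derivation tree (class `"derivation_tree"`).
#' @export
random_derivation <- function(grammar, max_depth = 6L, start = NULL) {
  md <- grammar$min_depth
  if (is.null(start)) {
    start <- if (length(grammar$start) == 1L) grammar$start
             else sample(grammar$start, 1L)
  }
  max_depth <- as.integer(max_depth)
  if (md[[start]] > max_depth)
    stop(sprintf("max_depth = %d is below the minimal completion depth %d",
                 max_depth, as.integer(md[[start]])))
  expand <- function(sym, budget) {
    if (sym %in% grammar$terminals) return(new_node(sym))
    prods <- productions_of(grammar, sym)
    ok <- vapply(prods, function(p) all(md[p$rhs] <= budget - 1L), logical(1))
    prods <- prods[ok]
    p <- if (length(prods) == 1L) prods[[1L]]
         else prods[[sample.int(length(prods), 1L)]]
    new_node(sym, lapply(p$rhs, expand, budget = budget - 1L))
  }
  expand(start, max_depth)
}

#' Validate a derivation tree against a grammar
#'
#' Returns `TRUE` iff every leaf carries a terminal symbol and every internal
#' node's (symbol, children-symbols) pair matches a production.  Never
#' raises; malformed trees yield `FALSE`.
#'
#' @param grammar a [cvode_grammar()].
#' @param tree a derivation tree.
#' @return logical scalar.
#' @export
validate_tree <- function(grammar, tree) {
  check <- function(node) {
    if (!is.list(node) || is.null(node$symbol)) return(FALSE)
    if (length(node$children) == 0L)
      return(node$symbol %in% grammar$terminals)
    if (!(node$symbol %in% grammar$nonterminals)) return(FALSE)
    kids <- vapply(node$children, function(ch) ch$symbol, character(1))
    hit <- any(vapply(productions_of(grammar, node$symbol),
                      function(p) identical(unname(p$rhs), unname(kids)),
                      logical(1)))
    hit && all(vapply(node$children, check, logical(1)))
  }
  isTRUE(check(tree))
}

#' Yield (terminal leaf sequence) of a derivation tree
#'
#' @param tree a derivation tree.
#' @return character vector of terminal tokens, left to right.
#' @export
tree_yield <- function(tree) {
  if (length(tree$children) == 0L) return(tree$symbol)
  unlist(lapply(tree$children, tree_yield), use.names = FALSE)
}

#' Depth of a derivation tree
#'
#' Number of node levels: a single leaf has depth 1, the root counts, and
#' terminal leaves count.
#'
#' @param tree a derivation tree.
#' @return integer depth >= 1.
#' @export
tree_depth <- function(tree) {
  if (length(tree$children) == 0L) return(1L)
  1L + max(vapply(tree$children, tree_depth, integer(1)))
}

#' @export
print.derivation_tree <- function(x, ...) {
  cat("<derivation tree> depth", tree_depth(x), "yield:",
      paste(tree_yield(x), collapse = " "), "\n")
  invisible(x)
}

#' Enumerate all sentences derivable within a depth bound
#'
#' Exhaustively expands the grammar and returns the set of yields of all
#' complete derivations of depth <= `max_depth` (same depth convention as
#' [tree_depth()]).  Intended as a test oracle at small depth; an explosion
#' guard refuses to build more than `cap` sentences.
#'
#' @param grammar a [cvode_grammar()].
#' @param max_depth depth bound.
#' @param cap maximum number of sentences before aborting.
#' @return list of character vectors (unique token sequences).
#' @export
enumerate_sentences <- function(grammar, max_depth, cap = 25000L) {
  memo <- new.env(parent = emptyenv())
  md <- grammar$min_depth
  sents <- function(sym, budget) {
    if (sym %in% grammar$terminals) {
      if (budget < 1L) return(list())
      return(list(sym))
    }
    if (md[[sym]] > budget) return(list())
    key <- paste0(sym, "#", budget)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- list()
    for (p in productions_of(grammar, sym)) {
      parts <- lapply(p$rhs, sents, budget = budget - 1L)
      if (any(vapply(parts, length, integer(1)) == 0L)) next
      combo <- list(character(0))
      for (part in parts) {
        combo <- unlist(lapply(combo, function(pref)
          lapply(part, function(s) c(pref, s))), recursive = FALSE)
        if (length(combo) > cap)
          stop(sprintf("sentence enumeration exceeds cap = %d", cap))
      }
      out <- c(out, combo)
      if (length(out) > cap)
        stop(sprintf("sentence enumeration exceeds cap = %d", cap))
    }
    keys <- vapply(out, paste, character(1), collapse = "\r")
    out <- out[!duplicated(keys)]
    memo[[key]] <- out
    out
  }
  out <- list()
  for (s in grammar$start) out <- c(out, sents(s, as.integer(max_depth)))
  keys <- vapply(out, paste, character(1), collapse = "\r")
  out[!duplicated(keys)]
}

#' Write / read a grammar as a plain-text production file
#'
#' One production per line in the form `lhs -> sym sym ...`, alternatives on
#' separate lines.  A comment header `# start: s1 s2` records the start set;
#' if absent on read, the lhs of the first production is taken as the start
#' symbol.  Terminals are the symbols that never occur as a lhs.
#'
#' @param grammar a [cvode_grammar()].
#' @param path file path.
#' @return `read_grammar` returns a [cvode_grammar()];
#'   `write_grammar` returns `path` invisibly.
#' @export
write_grammar <- function(grammar, path) {
  lines <- c(paste("# start:", paste(grammar$start, collapse = " ")),
             vapply(grammar$productions, function(p)
               paste(p$lhs, "->", paste(p$rhs, collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_grammar
#' @export
read_grammar <- function(path) {
  lines <- trimws(readLines(path))
  start <- NULL
  hdr <- grep("^#\\s*start:", lines, value = TRUE)
  if (length(hdr) > 0L)
    start <- strsplit(sub("^#\\s*start:\\s*", "", hdr[1L]), "\\s+")[[1L]]
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  prods <- lapply(lines, function(ln) {
    toks <- strsplit(ln, "\\s+")[[1L]]
    if (length(toks) < 3L || toks[2L] != "->")
      stop(sprintf("malformed production line: '%s'", ln))
    list(lhs = toks[1L], rhs = toks[-(1:2)])
  })
  lhs <- unique(vapply(prods, `[[`, character(1), "lhs"))
  syms <- unique(unlist(lapply(prods, `[[`, "rhs")))
  if (is.null(start)) start <- lhs[1L]
  cvode_grammar(nonterminals = lhs, terminals = setdiff(syms, lhs),
                productions = prods, start = start)
}

#' @export
print.cvode_grammar <- function(x, ...) {
  cat(sprintf("<cvode grammar> %d nonterminals, %d terminals, %d productions; start: %s\n",
              length(x$nonterminals), length(x$terminals),
              length(x$productions), paste(x$start, collapse = " ")))
  invisible(x)
}
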