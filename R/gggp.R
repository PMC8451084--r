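# Grammar-guided genetic programming over derivation trees.  Individuals
# are (tree, complex coefficient vector) pairs; fitness is the
# training-window prediction RMSE of the decoded model plus a small
# parsimony term; every few generations the coefficients of the incumbent
# best structure are refined by the firefly algorithm.

#' Parameters of the GGGP structure search
#'
#' @param population population size (>= 2).
#' @param crossover_rate probability of subtree crossover per pairing.
#' @param mutation_rate probability of mutating each child.
#' @param generations generation budget.
#' @param tournament_size tournament size for parent selection.
#' @param elitism number of best individuals copied unchanged.
#' @param cfa_every run the coefficient refinement every this many
#'   generations (and always on the final best).
#' @param cfa a [cfa_params()] object for the inner coefficient search.
#' @param max_depth maximum derivation depth at initialization.
#' @param depth_cap hard depth cap after genetic operators (bloat control);
#'   operators whose output exceeds it are retried.
#' @param parsimony fitness penalty per leaf token of the tree; breaks RMSE
#'   ties in favour of smaller models.
#' @param regulator_penalty fitness penalty per distinct variable referenced
#'   by the model: a sparsity prior on the regulator set, so a spurious
#'   regulator is kept only when it improves the fit by more than this
#'   amount of RMSE.
#' @param penalty fitness assigned to divergent/non-finite models.
#' @param tol early-stopping fitness threshold.
#' @param substeps RK4 substeps per sample interval in the fitness
#'   integration.
#' @param eps protected-division threshold.
#' @param div_limit divergence guard on `|Z|` during integration.
#' @param seed optional integer seed for the whole evolution.
#' @return a list of class `"gggp_params"`.
#' @export
gggp_params <- function(population = 50L, crossover_rate = 0.9,
                        mutation_rate = 0.1, generations = 100L,
                        tournament_size = 3L, elitism = 1L, cfa_every = 5L,
                        cfa = cfa_params(), max_depth = 6L, depth_cap = 10L,
                        parsimony = 1e-4, regulator_penalty = 1e-3,
                        penalty = 1e9, tol = 1e-8,
                        substeps = 4L, eps = 1e-6, div_limit = 1e6,
                        seed = NULL) {
  stopifnot(population >= 2L, crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, generations >= 0L,
            tournament_size >= 1L, elitism >= 0L, cfa_every >= 1L,
            inherits(cfa, "cfa_params"), max_depth >= 4L,
            depth_cap >= max_depth, parsimony >= 0,
            regulator_penalty >= 0, penalty > 0,
            substeps >= 1L)
  structure(list(population = as.integer(population),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 cfa_every = as.integer(cfa_every), cfa = cfa,
                 max_depth = as.integer(max_depth),
                 depth_cap = as.integer(depth_cap), parsimony = parsimony,
                 regulator_penalty = regulator_penalty,
                 penalty = penalty, tol = tol,
                 substeps = as.integer(substeps), eps = eps,
                 div_limit = div_limit, seed = seed),
            class = "gggp_params")
}

# ---- tree utilities ------------------------------------------------------

# Flatten a tree into a list of list(path, symbol, leaf, depth); path is an
# integer vector of child indices from the root.
flatten_tree <- function(tree) {
  out <- list()
  walk <- function(node, path, depth) {
    out[[length(out) + 1L]] <<- list(path = path, symbol = node$symbol,
                                     leaf = length(node$children) == 0L,
                                     depth = depth)
    for (k in seq_along(node$children))
      walk(node$children[[k]], c(path, k), depth + 1L)
  }
  walk(tree, integer(0), 1L)
  out
}

subtree_at <- function(tree, path) {
  for (k in path) tree <- tree$children[[k]]
  tree
}

replace_at <- function(tree, path, sub) {
  if (length(path) == 0L) return(sub)
  tree$children[[path[1L]]] <-
    replace_at(tree$children[[path[1L]]], path[-1L], sub)
  tree
}

#' Subtree crossover of two derivation trees
#'
#' Swaps one subtree pair whose root nodes carry the same nonterminal
#' symbol, so both children remain valid derivations of the grammar.  The
#' crossover point in the first parent is drawn uniformly over its
#' nonterminal nodes whose symbol also occurs in the second parent; if no
#' common nonterminal exists, or every attempted swap exceeds `depth_cap`,
#' the parents are returned unchanged.
#'
#' @param a,b parent derivation trees (valid under the same grammar).
#' @param grammar the shared [cvode_grammar()].
#' @param depth_cap maximum child depth.
#' @param max_tries swap attempts before giving up.
#' @return list of two derivation trees.
#' @export
crossover_trees <- function(a, b, grammar, depth_cap = 10L, max_tries = 20L) {
  na <- Filter(function(nd) !nd$leaf, flatten_tree(a))
  nb <- Filter(function(nd) !nd$leaf, flatten_tree(b))
  sa <- vapply(na, `[[`, character(1), "symbol")
  sb <- vapply(nb, `[[`, character(1), "symbol")
  common <- intersect(sa, sb)
  if (length(common) == 0L) return(list(a, b))
  ia_pool <- which(sa %in% common)
  for (k in seq_len(max_tries)) {
    ia <- ia_pool[[sample.int(length(ia_pool), 1L)]]
    jb_pool <- which(sb == sa[ia])
    jb <- jb_pool[[sample.int(length(jb_pool), 1L)]]
    sub_a <- subtree_at(a, na[[ia]]$path)
    sub_b <- subtree_at(b, nb[[jb]]$path)
    ca <- replace_at(a, na[[ia]]$path, sub_b)
    cb <- replace_at(b, nb[[jb]]$path, sub_a)
    if (tree_depth(ca) <= depth_cap && tree_depth(cb) <= depth_cap)
      return(list(ca, cb))
  }
  list(a, b)
}

#' Point mutation of a derivation tree
#'
#' Selects one node uniformly at random.  A nonterminal node keeps its
#' symbol and has its subtree regrown from the grammar within the remaining
#' depth budget; a terminal leaf is replaced by a random terminal that is
#' derivable in the same production slot.
#'
#' @param tree a valid derivation tree.
#' @param grammar the [cvode_grammar()].
#' @param depth_cap maximum depth of the mutated tree.
#' @return a valid derivation tree.
#' @export
mutate_tree <- function(tree, grammar, depth_cap = 10L) {
  nodes <- flatten_tree(tree)
  nd <- nodes[[sample.int(length(nodes), 1L)]]
  if (!nd$leaf) {
    budget <- max(depth_cap - nd$depth + 1L,
                  as.integer(grammar$min_depth[[nd$symbol]]))
    sub <- random_derivation(grammar, budget, start = nd$symbol)
    return(replace_at(tree, nd$path, sub))
  }
  if (length(nd$path) == 0L) return(tree)  # single terminal root: nothing to vary
  parent <- subtree_at(tree, nd$path[-length(nd$path)])
  slot <- nd$path[length(nd$path)]
  kids <- vapply(parent$children, `[[`, character(1), "symbol")
  cands <- unlist(lapply(productions_of(grammar, parent$symbol), function(p) {
    if (length(p$rhs) != length(kids)) return(NULL)
    if (!all(p$rhs[-slot] == kids[-slot])) return(NULL)
    if (!(p$rhs[slot] %in% grammar$terminals)) return(NULL)
    p$rhs[slot]
  }))
  if (length(cands) == 0L) return(tree)
  new_sym <- cands[[sample.int(length(cands), 1L)]]
  replace_at(tree, nd$path, new_node(new_sym))
}

# ---- fitness -------------------------------------------------------------

# Precompute everything about (target, training data) shared across fitness
# evaluations: the interpolated stage grid, the observed real series and
# the initial complex value.
fitness_context <- function(target, cdata, params, from = 1L, to = NULL) {
  stopifnot(inherits(cdata, "complex_matrix"))
  if (is.null(to)) to <- ncol(cdata$values)
  mode <- attr(cdata, "mode")
  grid <- stage_grid(cdata, from, to, params$substeps)
  times <- cdata$times[from:to]
  zz <- cdata$values[, from:to, drop = FALSE]
  n <- length(times)
  ztar <- zz[target, ]
  dz <- complex(n)  # finite-difference derivative of the target series
  dz[1L] <- (ztar[2L] - ztar[1L]) / (times[2L] - times[1L])
  dz[n] <- (ztar[n] - ztar[n - 1L]) / (times[n] - times[n - 1L])
  if (n > 2L)
    dz[2:(n - 1L)] <- (ztar[3:n] - ztar[1:(n - 2L)]) /
      (times[3:n] - times[1:(n - 2L)])
  list(target = as.integer(target), mode = mode, sgrid = grid$sgrid,
       hsub = grid$hsub, substeps = params$substeps,
       z0 = cdata$values[target, from],
       obs = complex_to_real(cdata$values[target, from:to], mode),
       states = zz, dz = dz,
       eps = params$eps, div_limit = params$div_limit,
       penalty = params$penalty, parsimony = params$parsimony,
       regulator_penalty = params$regulator_penalty)
}

# Deterministic coefficient initialization by gradient matching: the model
# RHS is linear in the coefficients given the observed states, so a ridge
# least-squares fit of the term values against the finite-difference
# derivative of the target series gives a good starting vector long before
# the firefly refinement runs.
ls_coefs <- function(ctx, prog, signs) {
  n <- ncol(ctx$states)
  K <- length(signs)
  A <- matrix(complex(1), n, K)
  for (t in seq_len(n))
    A[t, ] <- signs * cpp_eval_terms(prog$code, prog$starts, prog$lens,
                                     ctx$states[, t], ctx$eps)
  if (any(!is.finite(Re(A)) | !is.finite(Im(A)))) return(NULL)
  H <- Conj(t(A)) %*% A + diag(1e-8, K)
  beta <- tryCatch(solve(H, Conj(t(A)) %*% ctx$dz), error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(Re(beta)) | !is.finite(Im(beta))))
    return(NULL)
  as.complex(beta)
}

ctx_fitness <- function(ctx, prog, scoefs, nleaves, nregs = 0L) {
  res <- cpp_rk4_decoupled(prog$code, prog$starts, prog$lens,
                           as.complex(scoefs), ctx$target - 1L, ctx$sgrid,
                           ctx$hsub, ctx$substeps, ctx$z0, ctx$eps,
                           ctx$div_limit)
  if (isTRUE(res$diverged)) return(ctx$penalty)
  pred <- complex_to_real(res$traj, ctx$mode)
  err <- sqrt(mean((pred - ctx$obs)^2))
  if (!is.finite(err)) return(ctx$penalty)
  err + ctx$parsimony * nleaves + ctx$regulator_penalty * nregs
}

# Build an individual: split terms, compile, set coefficients (gradient-
# matched when a context is available, otherwise random/resized).
make_individual <- function(tree, params, coefs = NULL, ctx = NULL) {
  parts <- split_signed_terms(tree)
  k <- length(parts)
  terms <- lapply(parts, function(p) derivation_to_ast(p$node))
  signs <- vapply(parts, `[[`, numeric(1), "sign")
  prog <- compile_terms(terms)
  r <- params$cfa$init_radius
  if (is.null(coefs) && !is.null(ctx)) coefs <- ls_coefs(ctx, prog, signs)
  if (is.null(coefs)) {
    coefs <- complex(real = runif(k, -r, r), imaginary = runif(k, -r, r))
  } else if (length(coefs) < k) {
    coefs <- c(coefs, complex(real = runif(k - length(coefs), -r, r),
                              imaginary = runif(k - length(coefs), -r, r)))
  } else if (length(coefs) > k) {
    coefs <- coefs[seq_len(k)]
  }
  list(tree = tree, coefs = coefs, signs = signs, terms = terms,
       prog = prog, nleaves = length(tree_yield(tree)),
       nregs = length(unique(unlist(lapply(terms, expr_vars)))),
       fitness = NA_real_)
}

eval_individual <- function(ind, ctx) {
  ind$fitness <- ctx_fitness(ctx, ind$prog, ind$signs * ind$coefs,
                             ind$nleaves, ind$nregs)
  ind
}

#' Fitness of a (tree, coefficients) individual for one target gene
#'
#' Decodes the individual into a CVODE model, integrates it decoupled over
#' the training window, converts the complex trajectory back to real with
#' the data's conversion mode and returns the RMSE against the observed
#' series of the target gene, plus `parsimony` times the leaf count.
#' Divergent or non-finite trajectories receive the penalty fitness.
#'
#' @param individual list with elements `tree` (derivation tree) and
#'   `coefs` (complex vector, one per top-level term).
#' @param target target gene index.
#' @param cdata training window as a `"complex_matrix"`.
#' @param params a [gggp_params()] object.
#' @return real fitness (lower is better).
#' @export
fitness_of <- function(individual, target, cdata, params = gggp_params()) {
  ctx <- fitness_context(target, cdata, params)
  ind <- make_individual(individual$tree, params, coefs = individual$coefs)
  ctx_fitness(ctx, ind$prog, ind$signs * ind$coefs, ind$nleaves, ind$nregs)
}

tournament_pick <- function(fitness, size) {
  idx <- sample.int(length(fitness), min(size, length(fitness)))
  idx[which.min(fitness[idx])]
}

#' Evolve the CVODE model of one target gene
#'
#' Runs grammar-guided genetic programming (tournament selection,
#' replication, subtree crossover, point mutation, elitism) over derivation
#' trees of the expression grammar.  Every new individual's coefficients are
#' initialized deterministically by gradient matching (ridge least squares
#' of its term values against the finite-difference derivative of the
#' target series), falling back to a random draw in the complex
#' initialization box when the fit is singular.  Every `cfa_every`
#' generations, and on
#' the final best individual, the firefly algorithm refits the coefficient
#' vector with the structure fixed; the incumbent coefficients seed the
#' swarm, so refinement never worsens the best fitness.
#'
#' @param target target gene index.
#' @param cdata training window as a `"complex_matrix"`
#'   (see [real_to_complex()]).
#' @param params a [gggp_params()] object.
#' @param grammar expression grammar; defaults to
#'   `default_grammar(nrow(cdata$values))`.
#' @param verbose print per-generation best fitness.
#' @return list with `model` (the best `"cvode_model"`), `fitness`,
#'   `regulators`, `trace` (best-ever fitness per generation, non-
#'   increasing) and `individual`.
#' @export
evolve_gene <- function(target, cdata, params = gggp_params(),
                        grammar = NULL, verbose = FALSE) {
  if (!is.null(params$seed)) set.seed(params$seed)
  m <- nrow(cdata$values)
  if (is.null(grammar)) grammar <- default_grammar(m)
  ctx <- fitness_context(target, cdata, params)
  np <- params$population
  pop <- lapply(seq_len(np), function(i)
    eval_individual(make_individual(
      random_derivation(grammar, params$max_depth), params, ctx = ctx), ctx))
  fits <- vapply(pop, `[[`, numeric(1), "fitness")
  bi <- which.min(fits)
  best <- pop[[bi]]
  trace <- best$fitness
  refine <- function(best) {
    obj <- function(beta) ctx_fitness(ctx, best$prog, best$signs * beta,
                                      best$nleaves, best$nregs)
    cfa <- params$cfa
    cfa$seed <- NULL  # stay on the evolution's RNG stream
    res <- cfa_optimize(obj, K = length(best$coefs), params = cfa,
                        init = matrix(best$coefs, nrow = 1L))
    if (res$fitness < best$fitness) {
      best$coefs <- res$position
      best$fitness <- res$fitness
    }
    best
  }
  gen_done <- 0L
  for (gen in seq_len(params$generations)) {
    ord <- order(fits)
    nxt <- pop[ord[seq_len(min(params$elitism, np))]]
    while (length(nxt) < np) {
      i1 <- tournament_pick(fits, params$tournament_size)
      i2 <- tournament_pick(fits, params$tournament_size)
      t1 <- pop[[i1]]$tree
      t2 <- pop[[i2]]$tree
      if (runif(1) < params$crossover_rate) {
        kids <- crossover_trees(t1, t2, grammar, params$depth_cap)
      } else {
        kids <- list(t1, t2)
      }
      for (k in 1:2) {
        if (length(nxt) >= np) break
        tr <- kids[[k]]
        if (runif(1) < params$mutation_rate)
          tr <- mutate_tree(tr, grammar, params$depth_cap)
        nxt[[length(nxt) + 1L]] <- eval_individual(
          make_individual(tr, params, ctx = ctx), ctx)
      }
    }
    pop <- nxt
    fits <- vapply(pop, `[[`, numeric(1), "fitness")
    if (min(fits) < best$fitness) best <- pop[[which.min(fits)]]
    if (gen %% params$cfa_every == 0L) {
      best <- refine(best)
      # feed the refined coefficients back into the population elite
      pop[[which.min(fits)]] <- eval_individual(
        make_individual(best$tree, params, coefs = best$coefs), ctx)
      fits <- vapply(pop, `[[`, numeric(1), "fitness")
    }
    trace <- c(trace, best$fitness)
    gen_done <- gen
    if (verbose)
      message(sprintf("gene %d gen %d best fitness %.6g", target, gen,
                      best$fitness))
    if (best$fitness < params$tol) break
  }
  if (gen_done == 0L || gen_done %% params$cfa_every != 0L) {
    best <- refine(best)  # the final best is always coefficient-refined
    trace[length(trace)] <- best$fitness
  }
  model <- cvode_model(target = target, coefs = best$coefs,
                       signs = best$signs, terms = best$terms, m = m)
  list(model = model, fitness = best$fitness,
       regulators = extract_regulators(model), trace = trace,
       individual = list(tree = best$tree, coefs = best$coefs,
                         fitness = best$fitness))
}
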