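# Complex-valued firefly algorithm: swarm optimization of a complex
# coefficient vector.  Real and imaginary parts are updated in parallel,
# i.e. the canonical firefly update is applied on the 2K-dimensional
# real/imaginary unfolding of the K complex coordinates.

#' Parameters of the complex-valued firefly algorithm
#'
#' @param population number of fireflies (>= 2).
#' @param alpha random step size (per real coordinate, uniform in
#'   `alpha * (-0.5, 0.5)`).
#' @param beta0 attractiveness at distance zero.
#' @param gamma light absorption coefficient (attraction decays as
#'   `exp(-gamma r^2)`).
#' @param iterations number of swarm iterations.
#' @param init_radius half-width of the uniform complex initialization box
#'   per coefficient: real and imaginary parts are drawn in
#'   `[-init_radius, init_radius]`.
#' @param alpha_decay optional geometric per-iteration decay factor for
#'   `alpha` (1 = no decay, the default).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return a list of class `"cfa_params"`.
#' @export
cfa_params <- function(population = 100L, alpha = 0.02, beta0 = 1.0,
                       gamma = 1.0, iterations = 50L, init_radius = 5.0,
                       alpha_decay = 1.0, seed = NULL) {
  stopifnot(population >= 2L, alpha > 0, beta0 > 0, gamma > 0,
            iterations >= 0L, init_radius > 0, alpha_decay > 0,
            alpha_decay <= 1)
  structure(list(population = as.integer(population), alpha = alpha,
                 beta0 = beta0, gamma = gamma,
                 iterations = as.integer(iterations),
                 init_radius = init_radius, alpha_decay = alpha_decay,
                 seed = seed),
            class = "cfa_params")
}

#' One firefly attraction move
#'
#' Moves firefly position `p` toward a brighter firefly at `q`:
#' `p + beta0 * exp(-gamma * r^2) * (q - p) + alpha * (u - 0.5)` applied to
#' real and imaginary parts independently, with `u ~ Uniform(0,1)` per real
#' coordinate and `r` the Euclidean distance between the real/imaginary
#' unfoldings of `p` and `q`.
#'
#' @param p,q complex position vectors of equal length.
#' @param params a [cfa_params()] object (uses `alpha`, `beta0`, `gamma`).
#' @param alpha overrides `params$alpha` (used internally for decay).
#' @return the new complex position of the moved firefly.
#' @export
firefly_move <- function(p, q, params = cfa_params(), alpha = NULL) {
  if (is.null(alpha)) alpha <- params$alpha
  K <- length(p)
  r2 <- sum(Mod(q - p)^2)
  p + params$beta0 * exp(-params$gamma * r2) * (q - p) +
    alpha * complex(real = runif(K) - 0.5, imaginary = runif(K) - 0.5)
}

#' Optimize a complex coefficient vector with the firefly algorithm
#'
#' Minimizes `objective` (a function of a complex vector of length `K`
#' returning a finite real fitness; lower is better -- brightness is the
#' negative fitness).  Each iteration, every firefly moves toward every
#' brighter one via [firefly_move()]; the currently brightest firefly
#' performs a pure random walk instead, which prevents stagnation.
#' Brightness comparisons within an iteration use the fitness values from
#' the start of the iteration, and ranking ties are broken by firefly
#' index, so a fixed seed gives a bit-identical run.
#'
#' @param objective function: complex vector of length `K` -> real.
#' @param K number of complex coefficients.
#' @param params a [cfa_params()] object.
#' @param init optional complex matrix (rows = initial positions) seeding
#'   the first fireflies; the best-ever bookkeeping includes these, so
#'   seeding the incumbent guarantees a no-worse result.
#' @return list with `position` (best-ever complex vector), `fitness`
#'   (its objective value) and `trace` (best-ever fitness per iteration,
#'   length `iterations + 1`, non-increasing).
#' @examples
#' target <- 2 - 3i
#' res <- cfa_optimize(function(c) Mod(c - target)^2, K = 1,
#'                     cfa_params(population = 40, iterations = 25, seed = 1))
#' res$position
#' @export
cfa_optimize <- function(objective, K, params = cfa_params(), init = NULL) {
  stopifnot(K >= 1L)
  if (!is.null(params$seed)) set.seed(params$seed)
  np <- params$population
  pos <- matrix(complex(real = runif(np * K, -params$init_radius,
                                     params$init_radius),
                        imaginary = runif(np * K, -params$init_radius,
                                          params$init_radius)),
                np, K)
  if (!is.null(init)) {
    init <- matrix(as.complex(init), ncol = K)
    k <- min(nrow(init), np)
    pos[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  score <- function(i, it) {
    val <- tryCatch(objective(pos[i, ]),
                    error = function(e) stop(sprintf(
                      "objective failed for firefly %d at iteration %d: %s",
                      i, it, conditionMessage(e)), call. = FALSE))
    if (!is.numeric(val) || length(val) != 1L || is.na(val))
      stop(sprintf("objective returned a non-scalar or NA for firefly %d", i))
    val
  }
  fit <- vapply(seq_len(np), score, numeric(1), it = 0L)
  bi <- which.min(fit)
  best_pos <- pos[bi, ]
  best_fit <- fit[bi]
  trace <- numeric(params$iterations + 1L)
  trace[1L] <- best_fit
  alpha <- params$alpha
  for (it in seq_len(params$iterations)) {
    fit0 <- fit
    ib <- which.min(fit0)  # ties broken by lowest index
    for (i in seq_len(np)) {
      if (i == ib) {
        pos[i, ] <- pos[i, ] + alpha * complex(real = runif(K) - 0.5,
                                               imaginary = runif(K) - 0.5)
      } else {
        for (j in seq_len(np)) {
          if (fit0[j] < fit0[i])
            pos[i, ] <- firefly_move(pos[i, ], pos[j, ], params, alpha = alpha)
        }
      }
    }
    fit <- vapply(seq_len(np), score, numeric(1), it = it)
    if (min(fit) < best_fit) {
      bi <- which.min(fit)
      best_fit <- fit[bi]
      best_pos <- pos[bi, ]
    }
    trace[it + 1L] <- best_fit
    alpha <- alpha * params$alpha_decay
  }
  list(position = best_pos, fitness = best_fit, trace = trace)
}
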