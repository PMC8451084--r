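# Network inference: the user-facing fitting function and its S3 methods.

#' Infer a gene regulatory network with complex-valued ODE models
#'
#' Fits one complex-valued ODE per gene to normalized expression time
#' series and assembles the directed network from the variables appearing
#' in each optimal model.  For every target gene the pipeline is: min-max
#' normalize (optional), convert the real data to complex values, evolve
#' the model structure by grammar-guided genetic programming with
#' firefly-refined complex coefficients on the first `n_train` time points,
#' and read off the regulators.  Held-out time points (beyond `n_train`)
#' yield a per-gene test prediction RMSE.
#'
#' @param data an [expression_matrix()] (or a plain numeric matrix, rows =
#'   genes, columns = time points).
#' @param n_train number of training time points; the default uses the
#'   whole series for training (no test window).
#' @param mode real-to-complex conversion mode, see [real_to_complex()].
#' @param normalize min-max normalize the data first.
#' @param scope normalization scope, see [normalize_expression()].
#' @param params a [gggp_params()] object controlling the search.
#' @param grammar optional custom [cvode_grammar()]; defaults to
#'   [default_grammar()] over the data's genes.
#' @param genes subset of gene indices to fit (default: all).
#' @param seed integer seed; gene i uses the derived seed `seed + i`, so
#'   per-gene runs are independent and reproducible.
#' @param verbose print per-gene progress.
#' @return an object of class `"cvgrn"`: a list with `models` (a
#'   `"cvode_system"`-like list of fitted models), `network` (gene ids and
#'   the inferred edge matrix), `fitness` and `test_rmse` per gene,
#'   `traces`, the processed `data`, `cdata`, `n_train`, `mode`, `params`
#'   and `seed`.  Methods: `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals`.
#' @examples
#' \donttest{
#' sys <- random_system(2, seed = 7, readout_bounds = c(0.02, 0.98),
#'                      n_points = 30)
#' dat <- simulate_grn(sys$system, sys$z0, n_points = 30, normalize = FALSE)
#' fit <- cvgrn(dat, n_train = 25, mode = "embed", normalize = FALSE,
#'              params = gggp_params(population = 20, generations = 5,
#'                                   cfa = cfa_params(population = 15,
#'                                                    iterations = 10)),
#'              seed = 1)
#' summary(fit)
#' }
#' @export
cvgrn <- function(data, n_train = NULL,
                  mode = c("phase45", "embed", "unit_phase"),
                  normalize = TRUE, scope = c("gene", "global"),
                  params = gggp_params(), grammar = NULL, genes = NULL,
                  seed = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (!inherits(data, "expr_matrix")) data <- expression_matrix(data)
  if (normalize) data <- normalize_expression(data, scope = match.arg(scope))
  m <- nrow(data$values)
  n <- ncol(data$values)
  if (is.null(n_train)) n_train <- n
  n_train <- as.integer(n_train)
  if (n_train < 2L || n_train > n) stop("n_train must be in 2..n")
  cdata <- real_to_complex(data, mode)
  ctrain <- if (n_train < n) split_train_test(cdata, n_train)$train else cdata
  if (is.null(grammar)) grammar <- default_grammar(m)
  if (is.null(genes)) genes <- seq_len(m)
  models <- vector("list", m)
  fitness <- test_rmse <- rep(NA_real_, m)
  traces <- vector("list", m)
  for (i in genes) {
    p_i <- params
    p_i$seed <- if (!is.null(seed)) as.integer(seed) + i else NULL
    res <- evolve_gene(i, ctrain, params = p_i, grammar = grammar,
                       verbose = verbose)
    models[[i]] <- res$model
    fitness[i] <- res$fitness
    traces[[i]] <- res$trace
    if (n_train < n) {
      traj <- integrate_decoupled(res$model, cdata, from = n_train, to = n,
                                  substeps = params$substeps,
                                  eps = params$eps,
                                  div_limit = params$div_limit)
      if (isTRUE(attr(traj, "diverged"))) {
        test_rmse[i] <- Inf
      } else {
        pred <- complex_to_real(traj, mode)[-1L]  # drop the anchor point
        test_rmse[i] <- rmse(pred, data$values[i, seq(n_train + 1L, n)])
      }
    }
    if (verbose)
      message(sprintf("gene %d/%d: fitness %.6g, regulators {%s}", i, m,
                      res$fitness, paste(res$regulators, collapse = ", ")))
  }
  edges <- do.call(rbind, c(list(matrix(integer(0), 0L, 2L)),
                            lapply(genes, function(i)
                              cbind(extract_regulators(models[[i]]), i))))
  colnames(edges) <- c("regulator", "target")
  structure(list(models = models,
                 network = list(gene_ids = data$gene_ids, edges = edges),
                 fitness = fitness, test_rmse = test_rmse, traces = traces,
                 data = data, cdata = cdata, n_train = n_train, mode = mode,
                 params = params, seed = seed, genes = genes, call = cl),
            class = "cvgrn")
}

#' @export
print.cvgrn <- function(x, ...) {
  m <- length(x$data$gene_ids)
  cat("Complex-valued ODE network inference\n")
  cat(sprintf("  %d genes, %d time points (%d training), mode '%s'\n", m,
              ncol(x$data$values), x$n_train, x$mode))
  cat(sprintf("  inferred edges: %d of %d ordered pairs\n",
              nrow(x$network$edges), m^2))
  if (any(is.finite(x$test_rmse)))
    cat(sprintf("  mean test RMSE: %.6g\n",
                mean(x$test_rmse[is.finite(x$test_rmse)])))
  invisible(x)
}

#' @export
summary.cvgrn <- function(object, ...) {
  ids <- object$data$gene_ids
  tab <- data.frame(
    gene = ids,
    regulators = vapply(seq_along(ids), function(i) {
      mo <- object$models[[i]]
      if (is.null(mo)) return(NA_character_)
      paste(ids[extract_regulators(mo)], collapse = ", ")
    }, character(1)),
    n_terms = vapply(seq_along(ids), function(i) {
      mo <- object$models[[i]]
      if (is.null(mo)) NA_integer_ else length(mo$terms)
    }, integer(1)),
    train_fitness = object$fitness,
    test_rmse = object$test_rmse)
  structure(list(table = tab, edges = object$network$edges,
                 mode = object$mode, n_train = object$n_train),
            class = "summary.cvgrn")
}

#' @export
print.summary.cvgrn <- function(x, ...) {
  cat(sprintf("Per-gene fitted CVODE models (mode '%s', %d training points)\n",
              x$mode, x$n_train))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cvgrn <- function(object, ...) {
  out <- lapply(object$models, function(mo) {
    if (is.null(mo)) return(complex(0))
    stats::setNames(mo$signs * mo$coefs,
                    vapply(mo$terms, ast_to_string, character(1),
                           var_names = object$data$gene_ids))
  })
  names(out) <- object$data$gene_ids
  out
}

#' Predict expression trajectories from a fitted cvgrn model
#'
#' Each gene's fitted equation is integrated decoupled (non-target genes
#' interpolated from the observed data) over the requested index range and
#' converted back to real values.
#'
#' @param object a fitted `"cvgrn"` object.
#' @param newdata optional `"expr_matrix"` on the same genes; processed
#'   with the fit's normalization and conversion settings.  Defaults to the
#'   fitting data.
#' @param from,to sample index range (defaults to the whole series).
#' @param ... unused.
#' @return an `"expr_matrix"` of predicted expression values.
#' @export
predict.cvgrn <- function(object, newdata = NULL, from = 1L, to = NULL, ...) {
  cdata <- if (is.null(newdata)) {
    object$cdata
  } else {
    if (!inherits(newdata, "expr_matrix")) newdata <- expression_matrix(newdata)
    real_to_complex(newdata, object$mode)
  }
  n <- ncol(cdata$values)
  if (is.null(to)) to <- n
  if (from < 1L || to > n) stop("prediction range outside the data")
  fitted_genes <- which(!vapply(object$models, is.null, logical(1)))
  pred <- matrix(NA_real_, nrow(cdata$values), to - from + 1L)
  for (i in fitted_genes) {
    traj <- integrate_decoupled(object$models[[i]], cdata, from = from,
                                to = to, substeps = object$params$substeps,
                                eps = object$params$eps,
                                div_limit = object$params$div_limit)
    pred[i, ] <- complex_to_real(traj, object$mode)
  }
  expression_matrix(pred[fitted_genes, , drop = FALSE],
                    cdata$gene_ids[fitted_genes],
                    cdata$times[from:to])
}

#' @export
residuals.cvgrn <- function(object, ...) {
  pred <- predict(object, to = object$n_train)
  obs <- object$data$values[object$genes, seq_len(object$n_train),
                            drop = FALSE]
  obs - pred$values
}

#' Plot observed and predicted expression trajectories
#'
#' One panel per gene: observed data as points, the model prediction as a
#' line, with the train/test boundary marked when a test window exists.
#'
#' @param x a fitted `"cvgrn"` object.
#' @param genes gene indices to plot.
#' @param ... passed to [plot()].
#' @export
plot.cvgrn <- function(x, genes = NULL, ...) {
  fitted_genes <- which(!vapply(x$models, is.null, logical(1)))
  if (is.null(genes)) genes <- fitted_genes
  pred <- predict(x)
  op <- par(mfrow = c(ceiling(length(genes) / 2), min(2, length(genes))),
            mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (i in genes) {
    obs <- x$data$values[i, ]
    pr <- pred$values[match(i, fitted_genes), ]
    plot(x$data$times, obs, pch = 16, cex = 0.6,
         xlab = "time", ylab = "expression",
         main = x$data$gene_ids[i],
         ylim = range(c(obs, pr), finite = TRUE), ...)
    lines(x$data$times, pr, col = "red3")
    if (x$n_train < ncol(x$data$values))
      graphics::abline(v = x$data$times[x$n_train], lty = 2, col = "grey50")
  }
  invisible(x)
}

#' Inferred edges as a data frame
#'
#' @param object a fitted `"cvgrn"` object.
#' @param names use gene names instead of indices.
#' @return data frame with columns `regulator` and `target`.
#' @export
cvgrn_edges <- function(object, names = TRUE) {
  e <- object$network$edges
  if (names && nrow(e) > 0L) {
    data.frame(regulator = object$network$gene_ids[e[, 1L]],
               target = object$network$gene_ids[e[, 2L]])
  } else {
    as.data.frame(e)
  }
}
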