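# Expression-matrix handling: construction, I/O, min-max normalization and
# the real <-> complex conversions applied before/after model fitting.

#' Construct an expression matrix
#'
#' Rows are genes, columns are time points.  Values must be finite with no
#' missing entries and the time stamps strictly increasing.
#'
#' @param values numeric m x n matrix of expression levels.
#' @param gene_ids gene names (default `g1..gm` or existing rownames).
#' @param times numeric time stamps (default existing numeric colnames, else
#'   `0..n-1` with spacing 1).
#' @return object of class `"expr_matrix"` with fields `gene_ids`, `times`,
#'   `values`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, times = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("expression values must be finite with no missing entries")
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (is.null(times)) {
    cn <- suppressWarnings(as.numeric(colnames(values)))
    times <- if (!is.null(colnames(values)) && !any(is.na(cn))) cn
             else seq_len(ncol(values)) - 1
  }
  times <- as.numeric(times)
  if (length(times) != ncol(values)) stop("times length must equal n columns")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  dimnames(values) <- list(gene_ids, format(times, trim = TRUE))
  structure(list(gene_ids = as.character(gene_ids), times = times,
                 values = values),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expression matrix> %d genes x %d time points (t = %s .. %s)\n",
              nrow(x$values), ncol(x$values), format(min(x$times)),
              format(max(x$times))))
  print(head(x$values, 6L))
  invisible(x)
}

#' Min-max normalization of an expression matrix
#'
#' Applies `g' = (g - g_min) / (g_max - g_min)` so each scope spans
#' exactly \[0, 1\].  With `scope = "gene"` (the default, standard for GRN
#' work) the minimum and maximum are taken per gene; with `"global"` over
#' the whole matrix.  A constant series (max equal to min) is mapped to all
#' zeros with a warning.
#'
#' @param x an `"expr_matrix"` (or coercible matrix).
#' @param scope `"gene"` or `"global"`.
#' @return a normalized `"expr_matrix"`.
#' @export
normalize_expression <- function(x, scope = c("gene", "global")) {
  scope <- match.arg(scope)
  if (!inherits(x, "expr_matrix")) x <- expression_matrix(x)
  v <- x$values
  if (scope == "global") {
    rng <- range(v)
    if (rng[2] == rng[1]) {
      warning("constant matrix: normalization maps all entries to 0")
      v[] <- 0
    } else v <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    for (i in seq_len(nrow(v))) {
      rng <- range(v[i, ])
      if (rng[2] == rng[1]) {
        warning(sprintf("gene '%s' is constant: normalized to all zeros",
                        x$gene_ids[i]))
        v[i, ] <- 0
      } else v[i, ] <- (v[i, ] - rng[1]) / (rng[2] - rng[1])
    }
  }
  expression_matrix(v, x$gene_ids, x$times)
}

conversion_modes <- c("phase45", "embed", "unit_phase")

#' Convert normalized real expression data to complex values
#'
#' Three invertible conversion modes are provided (the observation model
#' under which the complex-valued equations are fitted):
#' \describe{
#'   \item{`phase45` (default)}{\eqn{z = g'(\cos\pi/4 + i \sin\pi/4)}: the
#'     value becomes the modulus along the 45-degree ray.}
#'   \item{`embed`}{\eqn{z = g' + 0i}: plain real embedding.}
#'   \item{`unit_phase`}{\eqn{z = \cos(\pi g') + i\sin(\pi g')}: the value
#'     becomes a phase on the unit circle.}
#' }
#'
#' @param x an `"expr_matrix"` with values in \[0, 1\].
#' @param mode conversion mode.
#' @return object of class `"complex_matrix"` (fields `gene_ids`, `times`,
#'   `values`) with attribute `"mode"`.
#' @seealso [complex_to_real()]
#' @export
real_to_complex <- function(x, mode = c("phase45", "embed", "unit_phase")) {
  mode <- match.arg(mode)
  if (!inherits(x, "expr_matrix")) x <- expression_matrix(x)
  g <- x$values
  z <- switch(mode,
              embed = complex(real = g, imaginary = 0 * g),
              phase45 = g * complex(real = cos(pi / 4), imaginary = sin(pi / 4)),
              unit_phase = complex(real = cos(pi * g), imaginary = sin(pi * g)))
  z <- matrix(z, nrow(g), ncol(g), dimnames = dimnames(g))
  out <- structure(list(gene_ids = x$gene_ids, times = x$times, values = z),
                   class = "complex_matrix")
  attr(out, "mode") <- mode
  out
}

#' Convert complex values (data or model output) back to real
#'
#' Inverse of [real_to_complex()] for the matching mode: `embed` takes the
#' real part, `phase45` the modulus, `unit_phase` `acos(Re z)/pi` with the
#' real part clamped to \[-1, 1\] against numeric drift.
#'
#' @param z a complex vector/matrix or a `"complex_matrix"`.
#' @param mode conversion mode; defaults to the `"mode"` attribute of `z`.
#' @return real values with the shape of the input (an `"expr_matrix"` when
#'   `z` is a `"complex_matrix"`).
#' @export
complex_to_real <- function(z, mode = NULL) {
  if (is.null(mode)) mode <- attr(z, "mode")
  if (is.null(mode)) stop("conversion mode is required")
  mode <- match.arg(mode, conversion_modes)
  if (inherits(z, "complex_matrix")) {
    r <- complex_to_real(z$values, mode)
    return(expression_matrix(r, z$gene_ids, z$times))
  }
  if (any(is.na(z))) stop("complex input contains NA values")
  switch(mode,
         embed = Re(z),
         phase45 = Mod(z),
         unit_phase = acos(pmin(pmax(Re(z), -1), 1)) / pi)
}

#' Read / write an expression matrix as TSV or CSV
#'
#' Expected layout: rows are genes with the gene id in the first column;
#' the header row holds the time stamps.  The separator is inferred from the
#' file extension (`.csv` uses comma, anything else tab) unless given.
#'
#' @param path file path.
#' @param sep field separator (optional).
#' @return `read_expression` returns an `"expr_matrix"`.
#' @export
read_expression <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("expression file needs a gene id column and data columns")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate gene id '%s'", ids[duplicated(ids)][1L]))
  num <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(num), nrow(num), ncol(num)))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s'",
                 ids[bad[1L]], colnames(num)[bad[2L]]))
  }
  tn <- suppressWarnings(as.numeric(colnames(num)))
  times <- if (!any(is.na(tn))) tn else seq_len(ncol(num)) - 1
  expression_matrix(vals, ids, times)
}

#' @rdname read_expression
#' @param x an `"expr_matrix"`.
#' @param digits significant digits written (6 minimum).
#' @export
write_expression <- function(x, path, sep = NULL, digits = 8) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- data.frame(gene = x$gene_ids,
                    signif(x$values, max(digits, 6)),
                    check.names = FALSE)
  colnames(tab) <- c("gene", format(x$times, trim = TRUE))
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split an expression series into training and test windows
#'
#' Prefix/suffix split by time index, no shuffling: the first `n_train`
#' time points are the training window, the remainder the test window.
#'
#' @param x an `"expr_matrix"` or `"complex_matrix"`.
#' @param n_train number of training time points (1 < n_train < n).
#' @return list with elements `train` and `test` of the same class as `x`.
#' @export
split_train_test <- function(x, n_train) {
  n <- length(x$times)
  n_train <- as.integer(n_train)
  if (n_train <= 1L || n_train >= n)
    stop("n_train must satisfy 1 < n_train < n")
  take <- function(idx) {
    out <- structure(list(gene_ids = x$gene_ids, times = x$times[idx],
                          values = x$values[, idx, drop = FALSE]),
                     class = class(x))
    if (!is.null(attr(x, "mode"))) attr(out, "mode") <- attr(x, "mode")
    out
  }
  list(train = take(seq_len(n_train)),
       test = take(seq(n_train + 1L, n)))
}
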