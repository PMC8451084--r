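# Prediction-error and network-accuracy metrics.

#' Root-mean-square error
#'
#' @param pred,obs numeric vectors of equal length (>= 1).
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (length(pred) < 1L) stop("empty series")
  sqrt(mean((as.numeric(pred) - as.numeric(obs))^2))
}

#' Arithmetic mean of per-gene RMSE values
#'
#' Matches the "Averaged" row convention of per-gene prediction-error
#' tables: RMSE per gene over the test window, then the plain mean across
#' genes.
#'
#' @param values numeric vector of per-gene RMSE values (non-empty).
#' @return the arithmetic mean.
#' @export
mean_rmse <- function(values) {
  if (length(values) < 1L) stop("empty RMSE vector")
  mean(as.numeric(values))
}

#' Percent improvement of a new error over a baseline
#'
#' `100 * (base - new) / base`: the percentage by which `new` decreases
#' the baseline value.
#'
#' @param base baseline value (> 0).
#' @param new new value.
#' @return percent change (positive = improvement).
#' @export
percent_change <- function(base, new) {
  if (!is.numeric(base) || base <= 0) stop("base must be positive")
  100 * (base - new) / base
}

as_edge_matrix <- function(x, m) {
  if (inherits(x, "cvgrn")) x <- x$network
  if (is.list(x) && !is.null(x$edges)) x <- x$edges
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(x) || length(x) == 0L)
    return(matrix(integer(0), 0L, 2L,
                  dimnames = list(NULL, c("regulator", "target"))))
  x <- matrix(as.integer(x), ncol = 2L)
  if (any(is.na(x)) || any(x < 1L) || any(x > m))
    stop("edge indices must lie in 1..m")
  x <- unique(x)
  colnames(x) <- c("regulator", "target")
  x
}

edge_ids <- function(edges, m) (edges[, 1L] - 1L) * m + edges[, 2L]

#' Confusion counts of an inferred network against a gold standard
#'
#' Counts TP/FP/TN/FN over all `m^2` ordered gene pairs, self-loops
#' included.  Edges may be given as a two-column matrix/data frame of
#' (regulator, target) indices, a network list with an `edges` field, or a
#' fitted [cvgrn()] object.
#'
#' @param inferred inferred directed edges.
#' @param gold gold-standard directed edges.
#' @param m number of genes.
#' @return object of class `"confusion_counts"`: list with `tp`, `fp`,
#'   `tn`, `fn`, `m`.
#' @export
confusion_counts <- function(inferred, gold, m) {
  m <- as.integer(m)
  inf_ids <- edge_ids(as_edge_matrix(inferred, m), m)
  gold_ids <- edge_ids(as_edge_matrix(gold, m), m)
  tp <- length(intersect(inf_ids, gold_ids))
  fp <- length(setdiff(inf_ids, gold_ids))
  fn <- length(setdiff(gold_ids, inf_ids))
  tn <- m * m - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, m = m),
            class = "confusion_counts")
}

#' Confusion counts from summary numbers
#'
#' Builds the TP/FP/TN/FN table from the numbers typically reported for a
#' network reconstruction: the true-positive and false-positive edge counts,
#' the gold-standard size and the gene count (negatives are the remaining
#' `m^2 - |gold|` ordered pairs, self-loops included).
#'
#' @param tp true positives.
#' @param fp false positives.
#' @param n_gold number of gold-standard edges.
#' @param m number of genes.
#' @return object of class `"confusion_counts"`.
#' @export
confusion_from_counts <- function(tp, fp, n_gold, m) {
  tp <- as.integer(tp); fp <- as.integer(fp)
  n_gold <- as.integer(n_gold); m <- as.integer(m)
  fn <- n_gold - tp
  tn <- m * m - n_gold - fp
  if (fn < 0L || tn < 0L) stop("inconsistent counts")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, m = m),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d   (m = %d, %d ordered pairs)\n",
              x$tp, x$fp, x$tn, x$fn, x$m, x$m^2))
  invisible(x)
}

#' Sensitivity and specificity of a network reconstruction
#'
#' `sensitivity` is TP / (TP + FN), the fraction of true regulations
#' recovered; `specificity` is TN / (TN + FP), the fraction of
#' non-regulations correctly absent.
#'
#' @param counts a `"confusion_counts"` object.
#' @return a real value in \[0, 1\].
#' @export
sensitivity <- function(counts) {
  d <- counts$tp + counts$fn
  if (d == 0L) stop("sensitivity undefined: no positive pairs")
  counts$tp / d
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  d <- counts$tn + counts$fp
  if (d == 0L) stop("specificity undefined: no negative pairs")
  counts$tn / d
}

#' Read / write a directed edge list as two-column TSV
#'
#' Format: header line `regulator<TAB>target`, one edge per line, entries
#' either gene names or 1-based indices.
#'
#' @param path file path.
#' @param gene_ids optional gene names used to resolve names to indices on
#'   read (and to write names instead of indices).
#' @return `read_edge_list` returns an integer edge matrix.
#' @export
read_edge_list <- function(path, gene_ids = NULL) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("edge list needs two columns")
  resolve <- function(v) {
    idx <- suppressWarnings(as.integer(v))
    if (!any(is.na(idx))) return(idx)
    if (is.null(gene_ids)) stop("gene_ids required to resolve edge names")
    i <- match(v, gene_ids)
    if (any(is.na(i)))
      stop(sprintf("unknown gene '%s' in edge list", v[is.na(i)][1L]))
    i
  }
  cbind(regulator = resolve(tab[[1L]]), target = resolve(tab[[2L]]))
}

#' @rdname read_edge_list
#' @param edges two-column edge matrix (or network/`cvgrn` object).
#' @export
write_edge_list <- function(edges, path, gene_ids = NULL) {
  if (inherits(edges, "cvgrn")) {
    if (is.null(gene_ids)) gene_ids <- edges$data$gene_ids
    edges <- edges$network$edges
  }
  m <- if (is.null(gene_ids)) max(edges, 1L) else length(gene_ids)
  edges <- as_edge_matrix(edges, m)
  tab <- if (is.null(gene_ids)) {
    data.frame(regulator = edges[, 1L], target = edges[, 2L])
  } else {
    data.frame(regulator = gene_ids[edges[, 1L]],
               target = gene_ids[edges[, 2L]])
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
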