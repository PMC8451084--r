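test_that("rmse follows its definition and metric-like properties", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2), c(3, 4)), 2)            # constant offset
  expect_equal(rmse(c(0, 1), c(1, 1)), sqrt(0.5))
  expect_error(rmse(1:3, 1:2), "lengths differ")
  set.seed(6)
  for (k in 1:10) {
    a <- rnorm(8); b <- rnorm(8); c <- rnorm(8)
    expect_equal(rmse(a, b), rmse(b, a))
    expect_lte(rmse(a, c), rmse(a, b) + rmse(b, c) + 1e-12)
  }
})

test_that("averaged RMSE rows reproduce the benchmark tables", {
  sos <- read.table(system.file("extdata", "sos_rmse.tsv", package = "cvgrn"),
                    header = TRUE, sep = "\t")
  expect_equal(round(mean_rmse(sos$ode), 6), 0.074081)
  expect_equal(round(mean_rmse(sos$cvode), 6), 0.048563)
  ecoli <- read.table(system.file("extdata", "ecoli_rmse.tsv",
                                  package = "cvgrn"),
                      header = TRUE, sep = "\t")
  expect_equal(round(mean_rmse(ecoli$cvode), 6), 0.021406)
  expect_equal(mean_rmse(0.5), 0.5)
  expect_error(mean_rmse(numeric(0)), "empty")
})

test_that("percent improvement matches the reported headline numbers", {
  expect_equal(round(percent_change(0.074081, 0.048563), 1), 34.4)
  expect_equal(round(percent_change(0.274861, 0.139998), 2), 49.07)
  expect_equal(percent_change(3, 3), 0)
  expect_error(percent_change(0, 1), "positive")
})

test_that("confusion counts agree with a brute-force pair scan", {
  gold <- cbind(c(1, 2, 3), c(2, 3, 1))
  expect_equal(confusion_counts(gold, gold, 3)$fp, 0)
  expect_equal(confusion_counts(gold, gold, 3)$fn, 0)
  set.seed(31)
  for (k in 1:20) {
    m <- sample(3:6, 1)
    pick <- function() {
      n <- sample.int(m^2, 1)
      ids <- sample.int(m^2, n)
      cbind(((ids - 1) %/% m) + 1, ((ids - 1) %% m) + 1)
    }
    inf <- pick(); gld <- pick()
    cc <- confusion_counts(inf, gld, m)
    # brute-force double loop over all ordered pairs
    tp <- fp <- tn <- fn <- 0
    for (r in 1:m) for (t in 1:m) {
      in_inf <- any(inf[, 1] == r & inf[, 2] == t)
      in_gld <- any(gld[, 1] == r & gld[, 2] == t)
      if (in_inf && in_gld) tp <- tp + 1
      else if (in_inf) fp <- fp + 1
      else if (in_gld) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(tp, fp, tn, fn))
    # invariants: row sums
    expect_equal(cc$tp + cc$fn, nrow(unique(gld)))
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, m^2)
    if (cc$tp + cc$fn > 0) {
      sn <- sensitivity(cc)
      expect_true(sn >= 0 && sn <= 1)
    }
    if (cc$tn + cc$fp > 0) {
      sp <- specificity(cc)
      expect_true(sp >= 0 && sp <= 1)
    }
  }
})

test_that("sensitivity and specificity reproduce the benchmark values", {
  # SOS network, 6 genes, 7 gold edges
  sos_cvode <- confusion_from_counts(tp = 7, fp = 17, n_gold = 7, m = 6)
  expect_equal(sos_cvode$tn, 12)
  expect_equal(sos_cvode$fn, 0)
  expect_equal(sensitivity(sos_cvode), 1)
  expect_equal(round(specificity(sos_cvode), 4), 0.4138)
  sos_ode <- confusion_from_counts(tp = 5, fp = 18, n_gold = 7, m = 6)
  expect_equal(round(sensitivity(sos_ode), 4), 0.7143)
  expect_equal(round(specificity(sos_ode), 4), 0.3793)
  # E. coli network, 8 genes, 15 gold edges
  ec_cvode <- confusion_from_counts(tp = 14, fp = 20, n_gold = 15, m = 8)
  expect_equal(round(sensitivity(ec_cvode), 6), 0.933333)
  expect_equal(round(specificity(ec_cvode), 6), 0.591837)
  ec_ode <- confusion_from_counts(tp = 12, fp = 19, n_gold = 15, m = 8)
  expect_equal(sensitivity(ec_ode), 0.8)
  expect_equal(round(specificity(ec_ode), 6), 0.612245)
  # degenerate denominators raise
  none <- confusion_from_counts(tp = 0, fp = 0, n_gold = 0, m = 2)
  expect_error(sensitivity(none), "undefined")
  full <- confusion_from_counts(tp = 4, fp = 0, n_gold = 4, m = 2)
  expect_error(specificity(full), "undefined")
})

test_that("edge lists round-trip through TSV with names or indices", {
  e <- cbind(c(1L, 2L), c(2L, 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(e, path)
  expect_equal(unname(read_edge_list(path)), unname(e))
  write_edge_list(e, path, gene_ids = c("lexA", "recA"))
  back <- read_edge_list(path, gene_ids = c("lexA", "recA"))
  expect_equal(unname(back), unname(e))
  expect_error(read_edge_list(path), "gene_ids required")
})
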