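test_that("binned mutual information behaves like an information measure", {
  set.seed(61)
  lab <- rep(0:1, 500)
  x <- rnorm(1000)                    # independent of labels
  expect_lte(mutual_information(x, lab), 0.05)
  expect_gte(mutual_information(x, lab), 0)
  # binary feature identical to balanced binary labels: 1 bit
  expect_equal(mutual_information(as.numeric(lab), lab, n_bins = 2), 1)
  # hand 4-trial product distribution: 0 bits
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1), n_bins = 2), 0)
  # constant feature: single occupied bin
  expect_equal(mutual_information(rep(3, 100), rep(0:1, 50)), 0)
  expect_error(mutual_information(x, rep(1, 1000)), "distinct")
})

test_that("MI is symmetric under identical binning and explains labels fully", {
  set.seed(62)
  a <- rep(0:3, 25); b <- (a + rep(0:1, 50)) %% 4
  m1 <- mutual_information(as.numeric(a), b, n_bins = 4)
  m2 <- mutual_information(as.numeric(b), a, n_bins = 4)
  expect_equal(m1, m2, tolerance = 1e-12)
  # feature that determines balanced labels carries H(Y) = log2(K) bits
  lab4 <- rep(0:3, each = 25)
  expect_equal(mutual_information(as.numeric(lab4), lab4, n_bins = 4), 2)
})

test_that("MIBIF equals the exhaustive sort-by-MI oracle", {
  set.seed(63)
  for (rep in 1:15) {
    p <- sample(3:20, 1); n <- 80
    lab <- rep(0:1, n / 2)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + lab            # ensure some signal exists
    nkeep <- sample(1:p, 1)
    res <- mibif_select(X, lab, nkeep)
    mi <- apply(X, 2, mutual_information, labels = lab)
    oracle <- sort(order(-mi, seq_len(p))[seq_len(nkeep)])
    expect_identical(res$kept, oracle)
  }
  X <- matrix(rnorm(40 * 6), 40, 6)
  expect_identical(mibif_select(X, rep(0:1, 20), 6)$kept, 1:6)  # identity
  expect_error(mibif_select(X, rep(0:1, 20), 7), "exceeds")
})

test_that("MIBIF finds a planted informative feature among noise", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    lab <- rep(0:1, 50)
    X <- matrix(rnorm(100 * 10), 100, 10)
    planted <- 4
    X[, planted] <- X[, planted] + 2.5 * lab
    hits <- hits + (mibif_select(X, lab, 1)$kept == planted)
  }
  expect_gte(hits, 19)
})

test_that("Gini impurity and node importance match hand arithmetic", {
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(3, 3, 3, 3)), 0.75)
  # pure root split of 100 balanced-binary samples
  expect_equal(node_importance(100, 100, 0.5, 50, 0, 50, 0), 0.5)
  # split with no impurity decrease
  expect_equal(node_importance(100, 40, 0.5, 20, 0.5, 20, 0.5), 0)
  expect_error(node_importance(100, 10, 0.5, 0, 0, 10, 0.5), "zero-sample")
  expect_error(node_importance(100, 10, 0.5, 4, 0, 5, 0.5), "inconsistent")
})

test_that("tree importances accumulate the weighted Gini decreases", {
  # hand-built 7-sample problem: feature 1 separates {0} from {1,2};
  # feature 2 then separates class 1 from class 2.
  X <- cbind(c(0, 0, 0, 1, 1, 1, 1), c(5, 6, 7, 1, 1, 9, 9))
  lab <- c(0, 0, 0, 1, 1, 2, 2)
  fit <- fbacsp:::fit_cart(X, lab)
  imp <- fbacsp:::cart_importances(fit, 2)
  # root: n=7, gini = 1 - (9+4+4)/49; split on f1 -> (3 pure) + (4, gini .5)
  g_root <- 1 - (9 + 4 + 4) / 49
  c_f1 <- (7 / 7) * (g_root - (3 / 7) * 0 - (4 / 7) * 0.5)
  c_f2 <- (4 / 7) * (0.5 - 0 - 0)
  expect_equal(imp, c(c_f1, c_f2) / sum(c(c_f1, c_f2)), tolerance = 1e-10)
  expect_equal(sum(imp), 1)
  expect_true(all(imp >= 0))
})

test_that("recursive elimination keeps exactly the requested features", {
  set.seed(65)
  X <- matrix(rnorm(60 * 12), 60, 12)
  lab <- rep(0:1, 30)
  X[, 3] <- X[, 3] + 2 * lab
  res <- dt_rfe(X, lab, 5)
  expect_length(res$kept, 5)
  expect_true(all(res$kept %in% 1:12))
  expect_identical(dt_rfe(X, lab, 12)$kept, 1:12)  # identity
  expect_error(dt_rfe(X, lab, 0), ">= 1")
  expect_error(dt_rfe(X, lab, 13), "exceeds")
})

test_that("elimination retains planted informative features", {
  keep_counts <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 120
    lab <- rep(0:1, n / 2)
    X <- matrix(rnorm(n * 25), n, 25)
    for (j in 1:5) X[, j] <- X[, j] + 1.5 * lab * (j %% 2 * 2 - 1)
    res <- dt_rfe(X, lab, 8)
    sum(res$kept %in% 1:5)
  }, 0)
  expect_gte(sum(keep_counts >= 4), 8)
})

test_that("elimination is permutation-equivariant", {
  set.seed(66)
  X <- matrix(rnorm(80 * 10), 80, 10)
  lab <- rep(0:1, 40)
  X[, 2] <- X[, 2] + lab; X[, 7] <- X[, 7] - lab
  perm <- sample(10)
  r1 <- dt_rfe(X, lab, 4)
  r2 <- dt_rfe(X[, perm], lab, 4)
  expect_setequal(perm[r2$kept], r1$kept)
})

test_that("cross-validation picks the planted feature count", {
  expect_equal(choose_n_features(matrix(rnorm(200), 50, 4), rep(0:1, 25),
                                 grid = 3, seed = 1), 3)  # single candidate
  picks <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 100
    lab <- rep(0:1, n / 2)
    X <- matrix(rnorm(n * 30), n, 30)
    for (j in 1:3) X[, j] <- X[, j] + 1.3 * lab
    choose_n_features(X, lab, grid = c(1, 3, 10, 30), seed = s,
                      n_trees = 60)
  }, 0)
  expect_gte(sum(picks == 3), 8)
})

test_that("pure noise falls back to the smallest candidate", {
  set.seed(68)
  X <- matrix(rnorm(80 * 20), 80, 20)
  pick <- choose_n_features(X, rep(0:1, 40), grid = c(2, 6, 12), seed = 3,
                            n_trees = 40)
  expect_equal(pick, 2)
})

test_that("tiny classes degrade the fold count with a warning", {
  set.seed(69)
  X <- matrix(rnorm(14 * 6), 14, 6)
  lab <- c(rep(0, 11), 1, 1, 1)
  expect_warning(choose_n_features(X, lab, grid = c(2, 4), seed = 1,
                                   n_trees = 20), "folds")
})
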