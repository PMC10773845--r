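#' Mutual information between a continuous feature and class labels
#'
#' Discretizes the feature into `n_bins` equal-frequency bins and evaluates
#' `I(X;Y) = sum p(x,y) log2 p(x,y) / (p(x) p(y))` on the joint histogram
#' with the labels. Result is in bits and non-negative; a constant feature
#' (single occupied bin) gives 0.
#'
#' @param feature numeric per-trial values.
#' @param labels per-trial class labels (>= 2 distinct).
#' @param n_bins number of equal-frequency bins; default
#'   `min(10, floor(sqrt(n)))`.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(feature, labels,
                               n_bins = min(10L, floor(sqrt(length(feature))))) {
  if (length(unique(labels)) < 2L) stop("need at least 2 distinct labels")
  n_bins <- max(2L, as.integer(n_bins))
  br <- unique(stats::quantile(feature, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(0)  # constant feature
  bins <- findInterval(feature, br, rightmost.closed = TRUE, all.inside = TRUE)
  tab <- table(bins, labels)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
}

#' Best-individual-feature selection by mutual information
#'
#' Ranks the columns of one feature block by marginal mutual information
#' with the labels and keeps the top `n`; ties broken by lower column index.
#' Applied independently per (sub-band, one-vs-rest projection matrix), it
#' reduces the raw CSP feature count to `subbands * K * n`.
#'
#' @param block trials x features numeric matrix (one projection matrix's
#'   features).
#' @param labels per-trial class labels.
#' @param n number of features to keep (`n <= ncol(block)`).
#' @param n_bins passed to [mutual_information()].
#' @return A list with `kept` (ordered column indices) and `scores`
#'   (MI in bits per column).
#' @export
mibif_select <- function(block, labels, n,
                         n_bins = min(10L, floor(sqrt(nrow(block))))) {
  if (n > ncol(block)) stop("n exceeds the number of features in the block")
  if (n < 1L) stop("n must be >= 1")
  mi <- apply(block, 2L, mutual_information, labels = labels, n_bins = n_bins)
  ord <- order(-mi, seq_along(mi))
  list(kept = sort(ord[seq_len(n)]), scores = mi)
}

#' Gini impurity of a node
#'
#' `1 - sum p_k^2` for class proportions `p_k` from the given counts.
#'
#' @param label_counts non-negative class counts, total >= 1.
#' @return The impurity in `[0, 1 - 1/K]`.
#' @export
gini_impurity <- function(label_counts) {
  n <- sum(label_counts)
  if (n < 1) stop("total count must be >= 1")
  1 - sum((label_counts / n)^2)
}

#' Importance contribution of one split node
#'
#' The sample-weighted impurity decrease
#' `(N_t/N) * (gini_t - (N_tL/N_t) gini_L - (N_tR/N_t) gini_R)`.
#' A feature's importance is the sum of this quantity over the nodes that
#' split on it, normalized to sum to one over features.
#'
#' @param N total training samples.
#' @param N_t samples at the node; `N_tL + N_tR == N_t <= N`.
#' @param gini_t,gini_L,gini_R impurities of the node and its children.
#' @param N_tL,N_tR child sample counts.
#' @return The node's importance contribution.
#' @export
node_importance <- function(N, N_t, gini_t, N_tL, gini_L, N_tR, gini_R) {
  if (N_t < 1 || N_tL < 1 || N_tR < 1) stop("zero-sample node")
  if (N_tL + N_tR != N_t || N_t > N) stop("inconsistent node sample counts")
  (N_t / N) * (gini_t - (N_tL / N_t) * gini_L - (N_tR / N_t) * gini_R)
}

# Fit a Gini CART on (X, labels) with rpart: no surrogates, no competes,
# fully grown. Deterministic.
fit_cart <- function(X, labels) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$.y <- factor(labels)
  rpart::rpart(.y ~ ., data = df, method = "class",
               control = rpart::rpart.control(
                 cp = 0, minsplit = 2L, minbucket = 1L, xval = 0L,
                 maxsurrogate = 0L, usesurrogate = 0L, maxcompete = 0L))
}

# Per-feature importances of a fitted rpart tree, accumulated node-by-node
# as sample-weighted Gini decreases and normalized to sum 1.
cart_importances <- function(fit, p) {
  fr <- fit$frame
  k <- length(attr(fit, "ylevels"))
  counts <- fr$yval2[, 1L + seq_len(k), drop = FALSE]
  ids <- as.integer(rownames(fr))
  N <- fr$n[1L]
  imp <- numeric(p)
  gini_of <- function(row) gini_impurity(counts[row, ])
  for (r in seq_len(nrow(fr))) {
    v <- as.character(fr$var[r])
    if (v == "<leaf>") next
    lrow <- match(ids[r] * 2L, ids)
    rrow <- match(ids[r] * 2L + 1L, ids)
    contrib <- node_importance(N, fr$n[r], gini_of(r),
                               fr$n[lrow], gini_of(lrow),
                               fr$n[rrow], gini_of(rrow))
    j <- as.integer(sub("^f", "", v))
    imp[j] <- imp[j] + contrib
  }
  tot <- sum(imp)
  if (tot > 0) imp / tot else imp
}

# Full elimination path: drops one feature at a time down to `n_min`,
# returning the surviving (original-index) sets at every size.
rfe_path <- function(X, labels, n_min) {
  p <- ncol(X)
  current <- seq_len(p)
  sets <- list()
  sets[[as.character(p)]] <- current
  while (length(current) > n_min) {
    fit <- fit_cart(X[, current, drop = FALSE], labels)
    imp <- cart_importances(fit, length(current))
    worst <- max(which(imp == min(imp)))  # tie: drop highest feature index
    current <- current[-worst]
    sets[[as.character(length(current))]] <- current
  }
  sets
}

#' Decision-tree recursive feature elimination
#'
#' Repeatedly fits a Gini decision tree on the current feature set, drops
#' the single feature with the lowest sample-weighted impurity-decrease
#' importance (ties: the highest feature index is dropped), and stops when
#' `n_target` features remain. Deterministic.
#'
#' @param X trials x features numeric matrix.
#' @param labels per-trial class labels.
#' @param n_target number of features to keep, `1 <= n_target <= ncol(X)`.
#' @return A list with `kept` (ordered original column indices) and
#'   `scores` (final-tree importances over the kept set).
#' @export
dt_rfe <- function(X, labels, n_target) {
  if (n_target < 1L) stop("n_target must be >= 1")
  if (n_target > ncol(X)) stop("n_target exceeds the feature count")
  sets <- rfe_path(X, labels, n_target)
  kept <- sets[[as.character(n_target)]]
  fit <- fit_cart(X[, kept, drop = FALSE], labels)
  list(kept = kept, scores = cart_importances(fit, length(kept)))
}

# Stratified k-fold assignment (fold id per row), seeded.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (c in unique(labels)) {
      idx <- sample(which(labels == c))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Choose the final feature count by cross-validation
#'
#' Computes the recursive-elimination path once on the full training set,
#' then estimates stratified 5-fold cross-validated accuracy of the
#' downstream random forest for each candidate size (the path's surviving
#' set of that size). Returns the smallest candidate whose mean accuracy is
#' within one standard error of the best. When the rarest class has fewer
#' than 5 trials, the fold count degrades to the largest feasible value
#' with a warning.
#'
#' @param X trials x features numeric matrix.
#' @param labels per-trial class labels.
#' @param grid candidate feature counts (clipped to `[1, ncol(X)]`).
#' @param seed RNG seed for folds and forests.
#' @param n_folds nominal fold count.
#' @param n_trees forest size used inside the CV.
#' @return The chosen feature count.
#' @export
choose_n_features <- function(X, labels, grid = c(8, 12, 16, 24, 32, 48, 64),
                              seed = 1L, n_folds = 5L, n_trees = 100L) {
  grid <- sort(unique(pmin(as.integer(grid), ncol(X))))
  grid <- grid[grid >= 1L]
  if (length(grid) == 0L) stop("candidate grid is empty")
  if (length(grid) == 1L) return(grid)
  sets <- rfe_path(X, labels, min(grid))
  minc <- min(table(labels))
  k <- min(n_folds, minc)
  if (k < n_folds)
    warning(sprintf("rarest class has %d trials; using %d folds", minc, k))
  if (k < 2L) stop("need at least 2 trials per class for cross-validation")
  fold <- stratified_folds(labels, k, derive_seed(seed, "cv-folds"))
  acc <- matrix(NA_real_, length(grid), k)
  for (gi in seq_along(grid)) {
    keep <- sets[[as.character(grid[gi])]]
    for (f in seq_len(k)) {
      tr <- fold != f
      model <- train_forest(X[tr, keep, drop = FALSE], labels[tr],
                            n_trees = n_trees,
                            seed = derive_seed(seed, sprintf("cv-%d-%d", gi, f)))
      pred <- predict(model, X[!tr, keep, drop = FALSE])
      acc[gi, f] <- mean(pred == labels[!tr])
    }
  }
  means <- rowMeans(acc)
  ses <- apply(acc, 1L, stats::sd) / sqrt(k)
  best <- which.max(means)
  ok <- means >= means[best] - ses[best]
  grid[min(which(ok))]
}
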