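#' Train a random forest on selected features
#'
#' Bagged Gini decision trees: each tree is grown on a bootstrap row sample
#' (with replacement, full n) over a random `mtry`-feature subset per split,
#' and prediction is the majority vote with ties broken toward the lowest
#' class index. Backed by the randomForest package; the vote/tie and
#' importance contracts are enforced on top of it. Deterministic given
#' `seed`.
#'
#' @param X trials x features numeric matrix.
#' @param labels per-trial class labels (>= 2 classes).
#' @param n_trees number of trees T.
#' @param mtry features sampled per split; default `ceiling(sqrt(p))`.
#' @param bootstrap if `FALSE`, every tree sees all rows (degenerate
#'   single-tree configurations).
#' @param seed integer RNG seed.
#' @return An object of class `forest_model`.
#' @export
train_forest <- function(X, labels, n_trees = 500L, mtry = NULL,
                         bootstrap = TRUE, seed = 1L) {
  labels <- as.integer(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stop("need at least 2 classes to train a classifier")
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(X)))
  mtry <- max(1L, min(as.integer(mtry), ncol(X)))
  y <- factor(labels, levels = lev)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  rf <- with_seed(seed, randomForest::randomForest(
    x = as.data.frame(X), y = y, ntree = as.integer(n_trees), mtry = mtry,
    replace = bootstrap, sampsize = nrow(X), importance = FALSE))
  structure(list(rf = rf, levels = lev, n_trees = as.integer(n_trees),
                 mtry = mtry, seed = as.integer(seed), p = ncol(X)),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("<forest_model> %d trees, mtry %d, %d features, classes {%s}\n",
              x$n_trees, x$mtry, x$p, paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict classes or vote fractions
#'
#' @param object a `forest_model`.
#' @param newdata trials x features matrix with the training feature count.
#' @param type `"class"` (majority vote, lowest-class-index ties) or
#'   `"prob"` (per-class vote fractions).
#' @param ... unused.
#' @return Integer class labels, or a trials x classes matrix of vote
#'   fractions.
#' @export
predict.forest_model <- function(object, newdata, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  if (ncol(newdata) != object$p)
    stop(sprintf("expected %d features, got %d", object$p, ncol(newdata)))
  newdata <- as.data.frame(newdata)
  names(newdata) <- paste0("f", seq_len(ncol(newdata)))
  votes <- predict(object$rf, newdata, type = "vote", norm.votes = TRUE)
  votes <- matrix(as.numeric(votes), nrow = nrow(newdata),
                  dimnames = dimnames(votes))
  if (type == "prob") {
    colnames(votes) <- as.character(object$levels)
    return(votes)
  }
  vote_to_class(votes, object$levels)
}

#' Majority vote with lowest-class-index tie-breaking
#'
#' @param votes trials x classes matrix of (possibly tied) vote counts or
#'   fractions, columns in class-label order.
#' @param levels class labels corresponding to the columns.
#' @return Integer labels; a tie selects the lowest class index.
#' @export
vote_to_class <- function(votes, levels) {
  levels[max.col(votes, ties.method = "first")]
}

#' Gini importances of a fitted forest
#'
#' Per-feature total sample-weighted Gini impurity decrease accumulated over
#' all trees, normalized to sum to one.
#'
#' @param model a `forest_model`.
#' @return Named numeric vector of importances summing to 1 (all zero if no
#'   split was ever made).
#' @export
forest_importances <- function(model) {
  imp <- model$rf$importance[, "MeanDecreaseGini"]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  names(imp) <- paste0("f", seq_along(imp))
  imp
}

#' Out-of-bag accuracy of a fitted forest
#'
#' @param model a `forest_model`.
#' @param labels the training labels the forest was fitted on.
#' @return Fraction of out-of-bag predictions matching the labels.
#' @export
oob_accuracy <- function(model, labels) {
  pred <- model$levels[as.integer(model$rf$predicted)]
  mean(pred == as.integer(labels), na.rm = TRUE)
}
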