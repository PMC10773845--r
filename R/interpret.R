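#' Per-feature mutual-information audit
#'
#' Computes the binned mutual information (bits) between every pooled
#' pre-elimination feature and the class labels, with band/type provenance,
#' for auditing which sub-bands and which feature families (CSP vs ASP)
#' carry class information.
#'
#' @param features a pooled feature matrix carrying a `provenance`
#'   attribute, as returned by `transform_features(model, epochs,
#'   selected = FALSE)`.
#' @param labels per-trial class labels.
#' @return A data.frame with one row per feature: band edges, `type`
#'   (`"CSP"`/`"ASP"`), `index`, `label` and `mi_bits`, sorted by
#'   decreasing mutual information.
#' @export
mi_summary <- function(features, labels) {
  prov <- attr(features, "provenance")
  if (is.null(prov))
    stop("`features` must carry a provenance attribute (use transform_features(..., selected = FALSE))")
  X <- unclass_matrix(features)
  mi <- apply(X, 2L, mutual_information, labels = labels)
  out <- data.frame(low_hz = prov$low_hz, high_hz = prov$high_hz,
                    type = prov$type, index = prov$index,
                    label = prov$label, mi_bits = mi)
  out <- out[order(-out$mi_bits), ]
  rownames(out) <- NULL
  out
}

#' Exact Shapley attributions by subset enumeration
#'
#' Computes, for one sample, the exact Shapley value of each feature under
#' the coalition weighting `|S|! (p - |S| - 1)! / p!`: the value of a
#' coalition S is the model output with out-of-coalition features replaced
#' by background values, averaged over the background set. All `2^p`
#' coalitions are enumerated, so the feature count is capped (default 12).
#' Satisfies efficiency (attributions sum to prediction minus background
#' expectation), symmetry and the dummy axiom exactly.
#'
#' @param predict_fn function mapping an n x p feature matrix to n model
#'   outputs (vector) or n x m per-class scores (matrix), e.g. forest vote
#'   fractions.
#' @param sample numeric length-p feature vector to explain.
#' @param background matrix of background rows (the reference
#'   distribution).
#' @param max_features enumeration cap.
#' @return An object of class `shapley_result`: `phi` (p x outputs matrix
#'   of attributions), `baseline` (background expectation), `prediction`
#'   (model output at the sample).
#' @examples
#' f <- function(X) X[, 1] + X[, 2]
#' sh <- exact_shapley(f, c(1, 2), matrix(0, 1, 2))
#' sh$phi
#' @export
exact_shapley <- function(predict_fn, sample, background, max_features = 12L) {
  p <- length(sample)
  if (p > max_features)
    stop(sprintf(paste("exact enumeration is capped at %d features;",
                       "use a sampling approximation for larger sets"),
                 max_features))
  if (!is.matrix(background)) background <- matrix(background, ncol = p)
  if (ncol(background) != p) stop("background must have length(sample) columns")
  nb <- nrow(background)
  n_sets <- 2L^p
  # value of every coalition: rows = subsets (bitmask + 1), cols = outputs
  vals <- NULL
  for (s in 0:(n_sets - 1L)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    X <- background
    if (length(members) > 0L)
      X[, members] <- matrix(sample[members], nb, length(members),
                             byrow = TRUE)
    out <- predict_fn(X)
    v <- if (is.matrix(out)) colMeans(out) else mean(out)
    if (is.null(vals)) vals <- matrix(0, n_sets, length(v))
    vals[s + 1L, ] <- v
  }
  phi <- matrix(0, p, ncol(vals))
  lw <- lgamma(seq_len(p) + 1)  # log factorials 1!..p!
  lfact <- function(n) if (n == 0L) 0 else lw[n]
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (s in 0:(n_sets - 1L)) {
      if (bitwAnd(s, bit) != 0L) next
      size <- sum(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0L)
      w <- exp(lfact(size) + lfact(p - size - 1L) - lfact(p))
      phi[j, ] <- phi[j, ] + w * (vals[bitwOr(s, bit) + 1L, ] - vals[s + 1L, ])
    }
  }
  structure(list(phi = phi, baseline = vals[1L, ],
                 prediction = vals[n_sets, ]),
            class = "shapley_result")
}

#' @export
print.shapley_result <- function(x, ...) {
  cat(sprintf("<shapley_result> %d features x %d outputs\n",
              nrow(x$phi), ncol(x$phi)))
  cat("  efficiency residual:",
      format(max(abs(colSums(x$phi) - (x$prediction - x$baseline))),
             digits = 3), "\n")
  invisible(x)
}

#' Shapley attributions for a fitted decoder
#'
#' Convenience wrapper: explains the forest's per-class vote fractions for
#' one trial of an epoch set, using a background of training feature rows.
#'
#' @param model a fitted [fbacsp()] model whose selected feature count is
#'   within the enumeration cap.
#' @param epochs an [epoch_set()] containing the trial.
#' @param trial trial index within `epochs`.
#' @param background selected-feature background matrix; defaults to the
#'   model's training features.
#' @param max_features enumeration cap, see [exact_shapley()].
#' @return A `shapley_result` with one column per class; rows are named by
#'   the selected features' provenance labels.
#' @export
explain_trial <- function(model, epochs, trial = 1L, background = NULL,
                          max_features = 12L) {
  feats <- transform_features(model, epochs)
  if (is.null(background)) background <- model$train_features
  fn <- function(X) predict(model$forest, X, type = "prob")
  res <- exact_shapley(fn, feats[trial, ], background, max_features)
  rownames(res$phi) <- model$provenance$label[model$rfe$kept]
  colnames(res$phi) <- as.character(model$forest$levels)
  res
}
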