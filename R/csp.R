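#' Average trace-normalized class covariance
#'
#' Averages, over the selected trials, each trial's spatial cross-product
#' matrix `X X'` normalized by its trace, then adds a small ridge
#' `eps * I` with `eps = 1e-8 * trace / channels` for numerical stability.
#'
#' @param epochs an [epoch_set()].
#' @param class_mask logical per-trial mask (or trial indices) selecting the
#'   class; at least 2 trials.
#' @return A symmetric positive-definite channels x channels matrix.
#' @export
class_covariance <- function(epochs, class_mask) {
  idx <- if (is.logical(class_mask)) which(class_mask) else as.integer(class_mask)
  if (length(idx) < 2L) stop("need at least 2 trials in the class mask")
  nc <- n_channels(epochs)
  acc <- matrix(0, nc, nc)
  for (t in idx) {
    x <- epochs$data[t, , , drop = TRUE]
    if (nc == 1L) x <- matrix(x, 1L)
    cc <- tcrossprod(x)
    tr <- sum(diag(cc))
    if (tr <= 0) stop(sprintf("trial %d has zero power", t))
    acc <- acc + cc / tr
  }
  acc <- acc / length(idx)
  acc + diag(1e-8 * sum(diag(acc)) / nc, nc)
}

#' Common spatial pattern filters for a covariance pair
#'
#' Solves the generalized eigenproblem `cov_a w = lambda (cov_a + cov_b) w`
#' by whitening the composite covariance. The returned projection columns
#' simultaneously diagonalize both inputs; the two diagonalized spectra sum
#' to one componentwise. Columns are sorted by eigenvalue descending and
#' sign-fixed so each filter's largest-magnitude entry is positive.
#'
#' @param cov_a,cov_b symmetric PSD matrices of equal size.
#' @return A list with `W` (channels x channels, filters in columns) and
#'   `eigenvalues` (descending, in `[0, 1]`).
#' @export
compute_csp <- function(cov_a, cov_b) {
  if (!is.matrix(cov_a) || !is.matrix(cov_b) ||
      any(dim(cov_a) != dim(cov_b)) || nrow(cov_a) != ncol(cov_a))
    stop("cov_a and cov_b must be square matrices of the same size")
  if (max(abs(cov_a - t(cov_a))) > 1e-6 * max(1, max(abs(cov_a))) ||
      max(abs(cov_b - t(cov_b))) > 1e-6 * max(1, max(abs(cov_b))))
    stop("covariances must be symmetric")
  comp <- (cov_a + cov_b)
  ec <- eigen((comp + t(comp)) / 2, symmetric = TRUE)
  vals <- pmax(ec$values, max(ec$values) * 1e-12)
  P <- diag(1 / sqrt(vals), length(vals)) %*% t(ec$vectors)  # whitener
  S <- P %*% cov_a %*% t(P)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  W <- t(P) %*% es$vectors
  for (j in seq_len(ncol(W))) {
    m <- which.max(abs(W[, j]))
    if (W[m, j] < 0) W[, j] <- -W[, j]
  }
  list(W = W, eigenvalues = es$values)
}

#' Log-variance CSP features
#'
#' Per trial and per projection column: the log of that column's output
#' variance divided by the summed output variance over all columns of `W`.
#' Invariant to a common scaling of the trial.
#'
#' @param epochs an [epoch_set()].
#' @param W channels x m projection matrix (filters in columns).
#' @return trials x m numeric feature matrix.
#' @export
csp_features <- function(epochs, W) {
  if (nrow(W) != n_channels(epochs))
    stop("W rows must equal the number of channels")
  nt <- n_trials(epochs)
  out <- matrix(0, nt, ncol(W))
  for (t in seq_len(nt)) {
    y <- crossprod(W, epochs$data[t, , , drop = TRUE])
    v <- apply(y, 1L, stats::var)
    tot <- sum(v)
    if (tot <= 0) stop(sprintf("trial %d has zero variance under W", t))
    out[t, ] <- log(v / tot)
  }
  out
}

#' One-vs-rest CSP across a filter bank
#'
#' For each sub-band and each class c, computes CSP between the covariance
#' of class c and the covariance of all remaining trials. With K classes,
#' all channel filters are retained, so the raw feature count is
#' `subbands * K * channels`. Binary problems still emit both (mirrored)
#' one-vs-rest matrices to keep that count formula; downstream selection
#' removes the redundancy.
#'
#' @param banded a `banded_epochs` object from [apply_filterbank()].
#' @return An object of class `csp_filter_set`: per band, per class, the
#'   `compute_csp()` output.
#' @export
ovr_csp <- function(banded) {
  labels <- banded$labels
  k <- max(labels) + 1L
  if (k < 2L) stop("need at least 2 classes")
  for (c in 0:(k - 1L))
    if (sum(labels == c) < 2L)
      stop(sprintf("class %d has fewer than 2 trials", c))
  per_band <- lapply(seq_along(banded$bands), function(bi) {
    ep <- banded$bands[[bi]]
    covs <- lapply(0:(k - 1L), function(c) class_covariance(ep, labels == c))
    lapply(0:(k - 1L), function(c) {
      cov_c <- covs[[c + 1L]]
      rest <- class_covariance(ep, labels != c)
      compute_csp(cov_c, rest)
    })
  })
  structure(list(filters = per_band, n_classes = k,
                 n_channels = n_channels(banded$bands[[1L]]),
                 band_specs = banded$spec$bands),
            class = "csp_filter_set")
}

#' @export
print.csp_filter_set <- function(x, ...) {
  cat(sprintf("<csp_filter_set> %d bands x %d OVR classes x %d channel filters\n",
              length(x$filters), x$n_classes, x$n_channels))
  invisible(x)
}
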