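#' Log band-energy feature of a spatially filtered trial
#'
#' The adaptive spatial pattern feature: the natural log of the total energy
#' of the trial after projection through the weight vector,
#' `log sum_t (F . X[, t])^2`. Scaling `F` by `c > 0` shifts the feature by
#' exactly `2 log c`, which the scatter-ratio loss is invariant to.
#'
#' @param F numeric weight vector over channels (non-zero).
#' @param X channels x samples trial matrix.
#' @return The scalar log energy.
#' @export
energy_feature <- function(F, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = length(F))
  if (sum(F^2) <= 0) stop("weight vector must be non-zero")
  e <- sum(as.numeric(crossprod(F, X))^2)
  if (e <= 0) stop("filter output is identically zero; log energy undefined")
  log(e)
}

#' Within/between-class scatter ratio of scalar features
#'
#' The adaptive spatial pattern loss: the within-class sum of squares over
#' the between-class (count-weighted) sum of squares of per-trial scalar
#' features. Exactly invariant under affine maps of the features. When the
#' between-class term falls below `1e-12` (all class means equal), returns
#' the `+Inf` sentinel so optimizers avoid uninformative filters.
#'
#' @param features numeric per-trial feature values.
#' @param labels per-trial class labels (at least 2 classes present).
#' @return The scalar loss (>= 0, possibly `Inf`).
#' @export
asp_loss <- function(features, labels) {
  labels <- as.integer(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stop("asp_loss needs at least 2 classes")
  gm <- mean(features)
  within <- 0; between <- 0
  for (c in cls) {
    x <- features[labels == c]
    m <- mean(x)
    within <- within + sum((x - m)^2)
    between <- between + length(x) * (m - gm)^2
  }
  if (between < 1e-12) return(Inf)
  within / between
}

# Vectorized loss over rows of a particles x trials feature matrix.
asp_loss_rows <- function(feat_mat, labels) {
  labels <- as.integer(labels)
  cls <- sort(unique(labels))
  gm <- rowMeans(feat_mat)
  within <- numeric(nrow(feat_mat)); between <- numeric(nrow(feat_mat))
  for (c in cls) {
    sub <- feat_mat[, labels == c, drop = FALSE]
    m <- rowMeans(sub)
    within <- within + rowSums((sub - m)^2)
    between <- between + ncol(sub) * (m - gm)^2
  }
  out <- within / between
  out[!is.finite(out) | between < 1e-12] <- Inf
  out
}

# channels^2 x trials matrix of vectorized per-trial cross-products X X',
# so the energy of filter F on trial i is  vec(F F') . C[, i].
trial_crossprods <- function(epochs) {
  nc <- n_channels(epochs); nt <- n_trials(epochs)
  C <- matrix(0, nc * nc, nt)
  for (t in seq_len(nt)) {
    x <- epochs$data[t, , , drop = TRUE]
    if (nc == 1L) x <- matrix(x, 1L)
    C[, t] <- as.numeric(tcrossprod(x))
  }
  C
}

# Energies of many filters at once: columns of P are filters.
filter_energies <- function(P, C) {
  nd <- nrow(P)
  V <- P[rep(seq_len(nd), nd), , drop = FALSE] *
       P[rep(seq_len(nd), each = nd), , drop = FALSE]
  crossprod(V, C)  # particles x trials
}

#' Fit one adaptive spatial pattern filter
#'
#' Finds the spatial weight vector minimizing the scatter-ratio loss of the
#' log band-energy features over the trials of one class pair, by local-best
#' PSO over the box `[-1, 1]^channels`. The loss is invariant to positive
#' rescaling of the weights, so the returned filter is normalized to unit
#' Euclidean norm (largest-magnitude entry positive) as a canonical form.
#'
#' @param epochs an [epoch_set()] restricted to the trials of the class pair
#'   (any two or more classes present are used as-is).
#' @param cfg a [swarm_config()].
#' @param seed integer RNG seed (the fit is deterministic given it).
#' @param band optional `(low, high)` Hz pair recorded for provenance.
#' @param pair optional class-pair labels recorded for provenance.
#' @param optimizer optional replacement optimizer with the signature of
#'   [pso_optimize()] (`objective, lower, upper, cfg, seed, vectorized`);
#'   hook for experimenting with other solvers.
#' @return An object of class `asp_filter`: `weights` (unit norm),
#'   `achieved_loss` (the loss recomputed from the returned weights),
#'   `band`, `pair`, `iterations`, `loss_trace`.
#' @export
fit_asp_filter <- function(epochs, cfg = swarm_config(), seed = 1L,
                           band = NULL, pair = NULL, optimizer = pso_optimize) {
  nc <- n_channels(epochs)
  labels <- epochs$labels
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  C <- trial_crossprods(epochs)
  objective <- function(P) {
    if (is.null(dim(P))) P <- matrix(P, nc)
    E <- filter_energies(P, C)
    bad <- rowSums(E <= 0) > 0
    E[E <= 0] <- 1  # placeholder; rows flagged bad get +Inf below
    losses <- asp_loss_rows(log(E), labels)
    losses[bad] <- Inf
    losses
  }
  res <- optimizer(objective, lower = rep(-1, nc), upper = rep(1, nc),
                   cfg = cfg, seed = seed, vectorized = TRUE)
  F <- res$best_position
  nrm <- sqrt(sum(F^2))
  if (nrm <= 0) stop("optimizer returned a zero weight vector")
  F <- F / nrm
  if (F[which.max(abs(F))] < 0) F <- -F
  feats <- log(as.numeric(filter_energies(matrix(F, nc), C)))
  structure(list(weights = F, achieved_loss = asp_loss(feats, labels),
                 band = band, pair = pair, iterations = res$iterations_run,
                 loss_trace = res$loss_trace),
            class = "asp_filter")
}

#' @export
print.asp_filter <- function(x, ...) {
  bd <- if (is.null(x$band)) "" else sprintf(" %g-%g Hz", x$band[1], x$band[2])
  pr <- if (is.null(x$pair)) "" else sprintf(" pair %d/%d", x$pair[1], x$pair[2])
  cat(sprintf("<asp_filter>%s%s loss %.4g (%d channels)\n",
              bd, pr, x$achieved_loss, length(x$weights)))
  invisible(x)
}

#' Filter-bank adaptive spatial patterns
#'
#' Fits one ASP filter per (sub-band, unordered class pair), each on the
#' trials of that pair only, yielding `subbands * choose(K, 2)` filters
#' (one scalar feature each). At transform time every filter is applied to
#' every trial.
#'
#' @param banded a `banded_epochs` from [apply_filterbank()].
#' @param cfg a [swarm_config()].
#' @param seed master seed; each (band, pair) fit gets a derived seed.
#' @return A list with `filters` (list of `asp_filter`) and `layout`
#'   (data.frame of band index, band edges and class pair per filter, in
#'   the stable fit/transform order).
#' @export
fb_asp <- function(banded, cfg = swarm_config(), seed = 1L) {
  labels <- banded$labels
  k <- max(labels) + 1L
  if (k < 2L) stop("need at least 2 classes")
  pairs <- utils::combn(0:(k - 1L), 2L)
  filters <- list()
  layout <- NULL
  for (bi in seq_along(banded$bands)) {
    band <- banded$spec$bands[[bi]]
    for (pi in seq_len(ncol(pairs))) {
      a <- pairs[1L, pi]; b <- pairs[2L, pi]
      sel <- labels %in% c(a, b)
      if (!any(labels == a) || !any(labels == b))
        stop(sprintf("class pair (%d,%d) has an absent class", a, b))
      sub <- subset_trials(banded$bands[[bi]], sel, relabel = TRUE)
      sd_pair <- derive_seed(seed, sprintf("asp-b%d-p%d-%d", bi, a, b))
      filters[[length(filters) + 1L]] <-
        fit_asp_filter(sub, cfg = cfg, seed = sd_pair,
                       band = band, pair = c(a, b))
      layout <- rbind(layout, data.frame(
        band = bi, low_hz = band[1], high_hz = band[2],
        class_a = a, class_b = b))
    }
  }
  list(filters = filters, layout = layout)
}

# ASP feature matrix: apply every fitted filter to every trial of each band.
asp_feature_matrix <- function(banded, asp) {
  nt <- length(banded$labels)
  out <- matrix(0, nt, length(asp$filters))
  Cs <- lapply(banded$bands, trial_crossprods)
  for (j in seq_along(asp$filters)) {
    f <- asp$filters[[j]]
    C <- Cs[[asp$layout$band[j]]]
    e <- as.numeric(filter_energies(matrix(f$weights, length(f$weights)), C))
    if (any(e <= 0)) stop("zero filter output energy in transform")
    out[, j] <- log(e)
  }
  out
}
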