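#' Pipeline configuration
#'
#' Collects the tunable parameters of the full decoding pipeline. The
#' master `seed` given to [fbacsp()] deterministically derives every
#' component seed.
#'
#' @param bands sub-band definition, see [filter_bank_spec()].
#' @param window optional `c(start_s, end_s)` cue-locked analysis window in
#'   seconds (applied after filtering, to keep filter transients out of the
#'   window); `NULL` uses the whole trial.
#' @param reref `"auto"`, `"car"` or `"none"`, see [rereference()].
#' @param rs_db,transition_hz band-pass design parameters.
#' @param swarm a [swarm_config()] for the ASP fits.
#' @param mibif_n CSP features kept per (band, one-vs-rest matrix); clipped
#'   to the channel count.
#' @param rfe_grid candidate final feature counts for the 5-fold search.
#' @param n_features `"auto"` (cross-validated choice over `rfe_grid`) or a
#'   fixed count.
#' @param n_trees,mtry random-forest size and per-split feature sample.
#' @param cv_trees forest size used inside the feature-count
#'   cross-validation.
#' @return An `fbacsp_config` list.
#' @export
fbacsp_config <- function(bands = default_bands(), window = NULL,
                          reref = "auto", rs_db = 30, transition_hz = 2,
                          swarm = swarm_config(), mibif_n = 4L,
                          rfe_grid = c(8, 12, 16, 24, 32, 48, 64),
                          n_features = "auto", n_trees = 500L, mtry = NULL,
                          cv_trees = 100L) {
  structure(list(bands = bands, window = window, reref = reref,
                 rs_db = rs_db, transition_hz = transition_hz, swarm = swarm,
                 mibif_n = as.integer(mibif_n), rfe_grid = rfe_grid,
                 n_features = n_features, n_trees = as.integer(n_trees),
                 mtry = mtry, cv_trees = as.integer(cv_trees)),
            class = "fbacsp_config")
}

# Shared preprocessing: re-reference, filter bank, then cue-locked window.
preprocess_banded <- function(epochs, spec, reref, window) {
  ep <- rereference(epochs, reref)
  banded <- apply_filterbank(ep, spec)
  if (!is.null(window))
    banded$bands <- lapply(banded$bands, extract_window,
                           start_s = window[1], end_s = window[2])
  banded
}

# Pooled pre-RFE feature matrix + provenance from fitted artifacts.
pooled_features <- function(banded, csp_set, mibif, asp, ablation) {
  k <- if (!is.null(csp_set)) csp_set$n_classes else max(banded$labels) + 1L
  nt <- length(banded$labels)
  blocks <- list(); prov <- NULL
  for (bi in seq_along(banded$bands)) {
    band <- banded$spec$bands[[bi]]
    if (ablation != "asp_only") {
      for (c in seq_len(k)) {
        W <- csp_set$filters[[bi]][[c]]$W
        sel <- mibif[[bi]][[c]]$kept
        feats <- csp_features(banded$bands[[bi]], W)[, sel, drop = FALSE]
        blocks[[length(blocks) + 1L]] <- feats
        prov <- rbind(prov, data.frame(
          band = bi, low_hz = band[1], high_hz = band[2], type = "CSP",
          group = c - 1L, index = sel))
      }
    }
  }
  if (ablation != "csp_only") {
    blocks[[length(blocks) + 1L]] <- asp_feature_matrix(banded, asp)
    prov <- rbind(prov, data.frame(
      band = asp$layout$band, low_hz = asp$layout$low_hz,
      high_hz = asp$layout$high_hz, type = "ASP",
      group = asp$layout$class_a * 100L + asp$layout$class_b,
      index = stats::ave(seq_len(nrow(asp$layout)), asp$layout$band,
                         FUN = seq_along)))
  }
  X <- do.call(cbind, blocks)
  prov$label <- feature_labels(prov)
  structure(X, provenance = prov)
}

# Pooling order: all CSP blocks (band-major, class-minor), then all ASP
# features (band-major, pair-minor); stable across fit and transform.
feature_labels <- function(prov) {
  sprintf("FB%s %g Hz-%g Hz %d", prov$type, prov$low_hz, prov$high_hz,
          prov$index)
}

#' Fit the filter-bank adaptive + common spatial pattern decoder
#'
#' Runs the full training pipeline on labeled epochs: re-referencing,
#' nine-band (by default) zero-phase Chebyshev II filter bank, cue-locked
#' windowing, per-band one-vs-rest CSP with per-matrix mutual-information
#' screening, per-band one-vs-one adaptive spatial pattern filters fitted
#' by local-best PSO, feature pooling, decision-tree recursive feature
#' elimination with a cross-validated final count, and a random-forest
#' classifier. All randomness derives from the master `seed`; refitting
#' with the same seed reproduces the model exactly.
#'
#' @param epochs a labeled [epoch_set()] (>= 2 classes; a warning is issued
#'   below 10 trials per class).
#' @param config an [fbacsp_config()].
#' @param ablation `"full"`, `"csp_only"` (classical filter-bank CSP
#'   baseline) or `"asp_only"`.
#' @param seed master integer seed.
#' @return An object of class `fbacsp` holding every fitted artifact:
#'   filter-bank spec, CSP filter set, per-matrix MIBIF selections, ASP
#'   filters and layout, pooled-feature provenance, RFE selection, the
#'   forest, and the frozen configuration.
#' @examples
#' \donttest{
#' ep <- make_fixture("tiny-2class-3ch")
#' cfg <- fbacsp_config(mibif_n = 2, rfe_grid = c(4, 8),
#'                      swarm = swarm_config(max_iter = 30), n_trees = 100)
#' fit <- fbacsp(ep, cfg, seed = 1)
#' fit
#' }
#' @export
fbacsp <- function(epochs, config = fbacsp_config(),
                   ablation = c("full", "csp_only", "asp_only"), seed = 1L) {
  ablation <- match.arg(ablation)
  k <- n_classes(epochs)
  if (k < 2L) stop("need at least 2 classes")
  if (min(table(epochs$labels)) < 10L)
    warning("fewer than 10 trials in some class; estimates will be unstable")
  spec <- filter_bank_spec(config$bands, rs_db = config$rs_db,
                           transition_hz = config$transition_hz)
  reref <- if (identical(config$reref, "auto")) {
    if (n_channels(epochs) >= 4L) "car" else "none"
  } else config$reref
  banded <- preprocess_banded(epochs, spec, reref, config$window)
  labels <- banded$labels
  nb <- length(banded$bands)

  csp_set <- NULL; mibif <- NULL
  if (ablation != "asp_only") {
    csp_set <- ovr_csp(banded)
    n_keep <- min(config$mibif_n, csp_set$n_channels)
    mibif <- lapply(seq_len(nb), function(bi)
      lapply(seq_len(k), function(c) {
        W <- csp_set$filters[[bi]][[c]]$W
        mibif_select(csp_features(banded$bands[[bi]], W), labels, n_keep)
      }))
  }
  asp <- NULL
  if (ablation != "csp_only")
    asp <- fb_asp(banded, cfg = config$swarm,
                  seed = derive_seed(seed, "asp"))

  X <- pooled_features(banded, csp_set, mibif, asp, ablation)
  prov <- attr(X, "provenance")

  n_target <- if (identical(config$n_features, "auto")) {
    choose_n_features(X, labels, grid = config$rfe_grid,
                      seed = derive_seed(seed, "rfe-cv"),
                      n_trees = config$cv_trees)
  } else min(as.integer(config$n_features), ncol(X))
  rfe <- dt_rfe(unclass_matrix(X), labels, n_target)

  forest <- train_forest(unclass_matrix(X)[, rfe$kept, drop = FALSE], labels,
                         n_trees = config$n_trees, mtry = config$mtry,
                         seed = derive_seed(seed, "forest"))
  structure(list(
    config = config, ablation = ablation, seed = as.integer(seed),
    spec = spec, reref = reref, window = config$window,
    n_channels = n_channels(epochs), fs = epochs$fs, n_classes = k,
    csp = csp_set, mibif = mibif, asp = asp,
    provenance = prov, rfe = rfe, n_features = n_target, forest = forest,
    train_features = unclass_matrix(X)[, rfe$kept, drop = FALSE],
    train_labels = labels), class = "fbacsp")
}

unclass_matrix <- function(x) {
  attr(x, "provenance") <- NULL
  x
}

#' Extract decoder features from new epochs
#'
#' Applies the frozen preprocessing and spatial filters of a fitted model
#' to new epochs — no statistic of the new data enters any artifact, and a
#' single trial transforms identically to the same trial in a batch.
#'
#' @param model a fitted [fbacsp()] model.
#' @param epochs an [epoch_set()] with the training channel count and
#'   sampling rate.
#' @param selected if `TRUE` (default) return the RFE-selected columns the
#'   classifier consumes; if `FALSE`, the full pooled pre-RFE matrix with
#'   its provenance attribute.
#' @return A trials x features numeric matrix.
#' @export
transform_features <- function(model, epochs, selected = TRUE) {
  if (n_channels(epochs) != model$n_channels)
    stop(sprintf("expected %d channels, got %d", model$n_channels,
                 n_channels(epochs)))
  if (!isTRUE(all.equal(epochs$fs, model$fs)))
    stop(sprintf("expected fs %g, got %g", model$fs, epochs$fs))
  banded <- preprocess_banded(epochs, model$spec, model$reref, model$window)
  X <- pooled_features(banded, model$csp, model$mibif, model$asp,
                       model$ablation)
  if (!selected) return(X)
  unclass_matrix(X)[, model$rfe$kept, drop = FALSE]
}

#' @rdname fbacsp
#' @param object,x a fitted `fbacsp` model.
#' @param newdata an [epoch_set()] of trials to classify.
#' @param type `"class"` or `"prob"` (vote fractions).
#' @param ... unused.
#' @export
predict.fbacsp <- function(object, newdata, type = c("class", "prob"), ...) {
  feats <- transform_features(object, newdata)
  predict(object$forest, feats, type = match.arg(type))
}

#' Evaluate a fitted decoder on labeled test epochs
#'
#' @param model a fitted [fbacsp()] model.
#' @param test a labeled [epoch_set()].
#' @return A list with `accuracy`, `kappa` (Cohen's kappa from the marginal
#'   chance agreement) and `confusion` (predicted x true table).
#' @export
evaluate <- function(model, test) {
  pred <- predict(model, test)
  classification_metrics(pred, test$labels)
}

#' Classification metrics from predicted and true labels
#'
#' @param predicted,truth integer label vectors of equal length.
#' @return `accuracy`, Cohen's `kappa`, and the `confusion` table.
#' @export
classification_metrics <- function(predicted, truth) {
  lev <- sort(unique(c(predicted, truth)))
  pf <- factor(predicted, levels = lev)
  tf <- factor(truth, levels = lev)
  tab <- table(predicted = pf, truth = tf)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
  list(accuracy = po, kappa = kappa, confusion = tab)
}

#' @export
print.fbacsp <- function(x, ...) {
  cat(sprintf("<fbacsp> %s decoder: %d classes, %d channels @ %g Hz\n",
              x$ablation, x$n_classes, x$n_channels, x$fs))
  cat(sprintf("  %d sub-bands; pooled %d features -> %d after elimination\n",
              length(x$spec$bands), nrow(x$provenance), x$n_features))
  cat(sprintf("  forest: %d trees; master seed %d\n",
              x$forest$n_trees, x$seed))
  invisible(x)
}

#' @rdname fbacsp
#' @export
summary.fbacsp <- function(object, ...) {
  prov <- object$provenance[object$rfe$kept, , drop = FALSE]
  imp <- forest_importances(object$forest)
  out <- data.frame(label = prov$label, type = prov$type,
                    band = sprintf("%g-%g Hz", prov$low_hz, prov$high_hz),
                    rfe_score = object$rfe$scores,
                    forest_importance = as.numeric(imp))
  out <- out[order(-out$forest_importance), ]
  rownames(out) <- NULL
  structure(list(model = object, features = out,
                 oob = oob_accuracy(object$forest, object$train_labels)),
            class = "summary.fbacsp")
}

#' @export
print.summary.fbacsp <- function(x, ...) {
  print(x$model)
  cat(sprintf("  out-of-bag training accuracy: %.3f\n", x$oob))
  cat("  selected features by forest importance:\n")
  print(utils::head(x$features, 10L))
  invisible(x)
}

#' @rdname fbacsp
#' @export
coef.fbacsp <- function(object, ...) {
  list(csp = object$csp, asp = object$asp)
}

#' @rdname fbacsp
#' @export
plot.fbacsp <- function(x, ...) {
  imp <- forest_importances(x$forest)
  prov <- x$provenance[x$rfe$kept, , drop = FALSE]
  ord <- order(imp, decreasing = TRUE)
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(imp[ord]), horiz = TRUE,
                    names.arg = rev(prov$label[ord]), las = 1,
                    cex.names = 0.7, xlab = "forest Gini importance",
                    main = "Selected FBACSP features", ...)
  invisible(x)
}
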