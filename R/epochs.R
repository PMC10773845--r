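#' Labeled EEG epochs
#'
#' Container for epoched multichannel EEG: a 3-D numeric array of
#' trials x channels x samples (microvolts), one integer class label per
#' trial, and the sampling rate. Class labels are coded `0 .. K-1` and every
#' class must occur at least once.
#'
#' @param data numeric array, trials x channels x samples; all values finite.
#' @param labels integer vector of per-trial class labels in `0 .. K-1`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names optional character vector of channel identifiers.
#' @return An object of class `epoch_set`.
#' @examples
#' x <- array(rnorm(4 * 3 * 100), c(4, 3, 100))
#' ep <- epoch_set(x, labels = c(0, 0, 1, 1), fs = 100)
#' ep
#' @export
epoch_set <- function(data, labels, fs, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (trials x channels x samples)")
  storage.mode(data) <- "double"
  if (any(!is.finite(data)))
    stop("`data` contains non-finite values")
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1L])
    stop("length(labels) must equal the number of trials")
  if (any(labels < 0L))
    stop("labels must be coded 0 .. K-1")
  k <- max(labels) + 1L
  if (!all(0:(k - 1L) %in% labels))
    stop("every class in 0 .. K-1 must occur at least once")
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (!is.null(channel_names) && length(channel_names) != dim(data)[2L])
    stop("channel_names length must equal the number of channels")
  structure(
    list(data = data, labels = labels, fs = fs,
         channel_names = channel_names),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat("  classes:",
      paste(sprintf("%d (n=%d)", sort(unique(x$labels)),
                    tabulate(x$labels + 1L)[sort(unique(x$labels)) + 1L]),
            collapse = ", "), "\n")
  invisible(x)
}

n_trials   <- function(ep) dim(ep$data)[1L]
n_channels <- function(ep) dim(ep$data)[2L]
n_samples  <- function(ep) dim(ep$data)[3L]
n_classes  <- function(ep) max(ep$labels) + 1L

#' Subset trials of an epoch set
#'
#' @param ep an [epoch_set()].
#' @param i trial indices or logical mask.
#' @return An `epoch_set` with the selected trials. Relabels nothing; the
#'   subset must still contain every class unless `relabel = TRUE`.
#' @param relabel if `TRUE`, remap the surviving labels to `0 .. K'-1`
#'   preserving order (used when restricting to a class pair).
#' @export
subset_trials <- function(ep, i, relabel = FALSE) {
  dat <- ep$data[i, , , drop = FALSE]
  lab <- ep$labels[i]
  if (relabel) lab <- match(lab, sort(unique(lab))) - 1L
  epoch_set(dat, lab, ep$fs, ep$channel_names)
}

#' Write / read an epoch bundle
#'
#' On-disk interchange format: a directory holding `meta.json` (dimensions,
#' sampling rate, channel names), `labels.csv` and `data.csv`. `data.csv`
#' has one row per (trial, channel) in trial-major order and one column per
#' sample — plain text, portable, and adequate for the epoch sizes this
#' package targets.
#'
#' @param ep an [epoch_set()].
#' @param path directory to create/write.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns an
#'   `epoch_set`.
#' @export
write_epochs <- function(ep, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ep$data)
  meta <- list(trials = d[1L], channels = d[2L], samples = d[3L],
               fs = ep$fs, channel_names = ep$channel_names)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(data.frame(label = ep$labels),
                   file.path(path, "labels.csv"), row.names = FALSE)
  flat <- matrix(0, d[1L] * d[2L], d[3L])
  for (t in seq_len(d[1L]))
    flat[(t - 1L) * d[2L] + seq_len(d[2L]), ] <- ep$data[t, , ]
  utils::write.table(flat, file.path(path, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  labels <- utils::read.csv(file.path(path, "labels.csv"))$label
  flat <- as.matrix(utils::read.table(file.path(path, "data.csv"), sep = ","))
  dimnames(flat) <- NULL
  dat <- array(0, c(meta$trials, meta$channels, meta$samples))
  for (t in seq_len(meta$trials))
    dat[t, , ] <- flat[(t - 1L) * meta$channels + seq_len(meta$channels), ]
  ch <- meta$channel_names
  if (length(ch) == 0L) ch <- NULL
  epoch_set(dat, labels, meta$fs, ch)
}
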