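#' Filter-bank specification
#'
#' Defines the sub-band decomposition used throughout the pipeline. The
#' default is the canonical nine 4 Hz bands 4-8, 8-12, ..., 36-40 Hz.
#' Band-pass filters are Chebyshev type II, designed with the stopband edges
#' `transition_hz` outside the passband at `rs_db` attenuation; the filter
#' order is the smallest (up to `max_order`) whose passband gain stays at or
#' above 0.9, chosen per band at application time when `order = NULL`.
#'
#' @param bands list (or 2-column matrix) of `(low_hz, high_hz)` pairs,
#'   non-overlapping and increasing in definition order.
#' @param rs_db stopband attenuation in dB.
#' @param transition_hz transition width between passband and stopband edge, Hz.
#' @param order fixed filter order, or `NULL` to auto-select per band.
#' @param max_order cap for the order search.
#' @return An object of class `filter_bank_spec`.
#' @export
filter_bank_spec <- function(bands = default_bands(), rs_db = 30,
                             transition_hz = 2, order = NULL, max_order = 10L) {
  if (is.matrix(bands)) bands <- lapply(seq_len(nrow(bands)), function(i) bands[i, ])
  bands <- lapply(bands, as.numeric)
  lows <- vapply(bands, `[`, 0, 1L)
  highs <- vapply(bands, `[`, 0, 2L)
  if (any(lows >= highs)) stop("each band must satisfy low < high")
  if (length(bands) > 1L && any(highs[-length(bands)] > lows[-1L]))
    stop("bands must be non-overlapping in definition order")
  structure(list(bands = bands, rs_db = rs_db, transition_hz = transition_hz,
                 order = order, max_order = as.integer(max_order)),
            class = "filter_bank_spec")
}

#' @rdname filter_bank_spec
#' @export
default_bands <- function() lapply(0:8, function(i) c(4 + 4 * i, 8 + 4 * i))

#' @export
print.filter_bank_spec <- function(x, ...) {
  cat(sprintf("<filter_bank_spec> %d bands: %s Hz; Chebyshev II, Rs = %g dB\n",
              length(x$bands),
              paste(vapply(x$bands, function(b) sprintf("%g-%g", b[1], b[2]), ""),
                    collapse = ", "), x$rs_db))
  invisible(x)
}

#' Re-reference epochs
#'
#' @param epochs an [epoch_set()].
#' @param scheme `"car"` (common average reference: subtract, at every time
#'   sample, the mean across channels), `"none"`, or `"auto"` (CAR when the
#'   montage has at least 4 channels, otherwise untouched — small bipolar
#'   montages should not be re-referenced).
#' @return A re-referenced `epoch_set` of identical shape.
#' @export
rereference <- function(epochs, scheme = c("car", "none", "auto")) {
  scheme <- match.arg(scheme)
  nc <- n_channels(epochs)
  if (scheme == "auto") scheme <- if (nc >= 4L) "car" else "none"
  if (scheme == "none") return(epochs)
  if (nc < 2L) stop("common-average re-referencing needs at least 2 channels")
  dat <- epochs$data
  for (t in seq_len(n_trials(epochs))) {
    x <- dat[t, , ]
    dat[t, , ] <- x - rep(colMeans(x), each = nc)
  }
  epoch_set(dat, epochs$labels, epochs$fs, epochs$channel_names)
}

#' Extract a cue-locked time window
#'
#' Windows are half-open `[start_s, end_s)` in seconds relative to the epoch
#' start (the cue); the sample index of time t is `floor(t * fs)`.
#'
#' @param epochs an [epoch_set()].
#' @param start_s,end_s window bounds in seconds, `0 <= start_s < end_s`.
#' @return An `epoch_set` with `round((end_s - start_s) * fs)` samples.
#' @export
extract_window <- function(epochs, start_s, end_s) {
  if (start_s < 0 || start_s >= end_s)
    stop("require 0 <= start_s < end_s")
  fs <- epochs$fs
  i0 <- floor(start_s * fs) + 1L
  i1 <- floor(end_s * fs)
  if (i1 > n_samples(epochs))
    stop("window exceeds trial length")
  epoch_set(epochs$data[, , i0:i1, drop = FALSE], epochs$labels, fs,
            epochs$channel_names)
}

# Chebyshev II band-pass design for one band; order auto-selected so the
# passband gain stays >= 0.9 at the band edges (stopband fixed by rs_db).
design_band_filter <- function(low, high, fs, spec) {
  nyq <- fs / 2
  if (high >= nyq) stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)", high, nyq))
  lo_s <- max(low - spec$transition_hz, 0.05 * low)
  hi_s <- min(high + spec$transition_hz, 0.999 * nyq)
  ws <- c(lo_s, hi_s) / nyq
  orders <- if (is.null(spec$order)) 2:spec$max_order else spec$order
  flt <- NULL
  for (n in orders) {
    flt <- signal::cheby2(n, spec$rs_db, ws, type = "pass")
    h <- signal::freqz(flt, n = 1024, Fs = fs)
    inband <- h$f >= low & h$f <= high
    if (!is.null(spec$order) || min(abs(h$h[inband])) >= 0.9) break
  }
  flt
}

# Zero-phase application of a designed filter to a samples x signals matrix:
# multiply by the squared magnitude response in the frequency domain after
# reflective padding (the magnitude response of forward-backward filtering).
zero_phase_filter_mat <- function(flt, x, fs) {
  ns <- nrow(x)
  pad <- min(ns - 1L, max(32L, round(fs / 4)))
  top <- 2 * x[rep(1L, pad), , drop = FALSE] - x[(pad + 1L):2L, , drop = FALSE]
  bot <- 2 * x[rep(ns, pad), , drop = FALSE] - x[(ns - 1L):(ns - pad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  L <- nrow(xp)
  w <- 2 * pi * (0:(L - 1L)) / L
  nh <- floor(L / 2) + 1L
  h <- signal::freqz(flt, w[1:nh], Fs = 2 * pi)$h
  m2 <- abs(h)^2
  m2full <- numeric(L)
  m2full[1:nh] <- m2
  if (L > nh) m2full[(nh + 1L):L] <- rev(m2[2:(L - nh + 1L)])
  y <- Re(stats::mvfft(stats::mvfft(xp) * m2full, inverse = TRUE)) / L
  y[(pad + 1L):(pad + ns), , drop = FALSE]
}

#' Decompose epochs into filter-bank sub-bands
#'
#' Applies each band-pass of `spec` to every trial and channel with zero
#' phase, so the group delay does not shift the cue alignment.
#'
#' @param epochs an [epoch_set()].
#' @param spec a [filter_bank_spec()].
#' @return An object of class `banded_epochs`: a list with `bands` (one
#'   filtered `epoch_set` per sub-band, sharing labels and fs) and `spec`.
#' @export
apply_filterbank <- function(epochs, spec = filter_bank_spec()) {
  d <- dim(epochs$data)
  nyq <- epochs$fs / 2
  for (b in spec$bands)
    if (b[2] >= nyq)
      stop(sprintf("band %g-%g Hz reaches Nyquist (%g Hz)", b[1], b[2], nyq))
  # samples x (channels*trials) matrix, filtered once per band
  xm <- matrix(aperm(epochs$data, c(3L, 2L, 1L)), nrow = d[3L])
  out <- vector("list", length(spec$bands))
  for (bi in seq_along(spec$bands)) {
    b <- spec$bands[[bi]]
    flt <- design_band_filter(b[1], b[2], epochs$fs, spec)
    ym <- zero_phase_filter_mat(flt, xm, epochs$fs)
    dat <- aperm(array(ym, c(d[3L], d[2L], d[1L])), c(3L, 2L, 1L))
    out[[bi]] <- epoch_set(dat, epochs$labels, epochs$fs, epochs$channel_names)
  }
  structure(list(bands = out, spec = spec, labels = epochs$labels,
                 fs = epochs$fs), class = "banded_epochs")
}

#' @export
print.banded_epochs <- function(x, ...) {
  cat(sprintf("<banded_epochs> %d sub-bands of ", length(x$bands)))
  print(x$bands[[1L]])
  invisible(x)
}
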