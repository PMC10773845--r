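#' Simulation scenario for synthetic motor-imagery EEG
#'
#' Describes a generative model of epoched MI-EEG: band-limited Gaussian
#' oscillatory sources (one per channel) mixed into sensors by a random
#' full-rank matrix, plus 1/f (pink) and white sensor noise. Class effects:
#'
#' * `csp_favorable` — for class `l > 0`, the variance of source
#'   `((l - 1) mod n_channels) + 1` is multiplied by `effect_size`,
#'   imitating a direction-specific ERD/ERS contrast; the mixed image of
#'   that source is the recoverable ground-truth direction.
#' * `asp_favorable` — every trial of class `l` has its effect-band
#'   content (sources and in-band sensor noise alike) amplitude-scaled so
#'   the in-band variance is multiplied by `effect_size^(l / (K - 1))`:
#'   total band energy shifts between classes while the band's spatial
#'   covariance shape — and every scale-invariant per-direction variance
#'   ratio — is exactly unchanged, so no single discriminative direction
#'   exists. Out-of-band activity is untouched.
#' * `mixed` — both effects; `null` — label-independent data.
#'
#' `snr` is the ratio of baseline (class 0) in-band source power to total
#' sensor noise power, averaged over channels.
#'
#' @param n_channels,n_classes,trials_per_class,fs,trial_seconds geometry.
#' @param effect one of `"csp_favorable"`, `"asp_favorable"`, `"mixed"`,
#'   `"null"`.
#' @param effect_band `(low, high)` Hz pair inside `[4, 40]`.
#' @param effect_size variance (energy) ratio, > 0.
#' @param snr signal-to-noise ratio as defined above.
#' @param noise_pink,noise_white relative weights of the two noise floors.
#' @param mixing_seed seed fixing the mixing matrix (part of the scenario,
#'   not of the per-draw randomness).
#' @param mixing `"random"` (full-rank Gaussian matrix; spatially
#'   correlated background) or `"orthogonal"` (random orthonormal matrix;
#'   isotropic background, so a planted per-direction contrast is the
#'   unique discriminative direction — the configuration used for
#'   parameter-recovery checks).
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_channels = 8L, n_classes = 2L,
                         trials_per_class = 100L, fs = 128, trial_seconds = 2,
                         effect = c("asp_favorable", "csp_favorable", "mixed",
                                    "null"),
                         effect_band = c(8, 12), effect_size = 4, snr = 1,
                         noise_pink = 0.5, noise_white = 0.5,
                         mixing_seed = 1L, mixing = c("random", "orthogonal")) {
  effect <- match.arg(effect)
  mixing <- match.arg(mixing)
  stopifnot(n_channels >= 1L, n_classes >= 1L, trials_per_class >= 1L,
            effect_size > 0, snr > 0,
            effect_band[1] < effect_band[2])
  structure(list(n_channels = as.integer(n_channels),
                 n_classes = as.integer(n_classes),
                 trials_per_class = as.integer(trials_per_class),
                 fs = fs, trial_seconds = trial_seconds, effect = effect,
                 effect_band = effect_band, effect_size = effect_size,
                 snr = snr, noise_pink = noise_pink,
                 noise_white = noise_white,
                 mixing_seed = as.integer(mixing_seed), mixing = mixing),
            class = "sim_scenario")
}

# Band-limited unit-variance Gaussian process: white noise spectrally
# restricted to [low, high] Hz by zeroing out-of-band Fourier bins.
bandlimited_noise <- function(ns, fs, low, high, n_signals) {
  z <- matrix(stats::rnorm(ns * n_signals), ns, n_signals)
  Z <- stats::mvfft(z)
  freqs <- (0:(ns - 1L)) * fs / ns
  freqs <- pmin(freqs, fs - freqs)  # two-sided
  Z[freqs < low | freqs > high, ] <- 0
  x <- Re(stats::mvfft(Z, inverse = TRUE)) / ns
  sweep(x, 2L, apply(x, 2L, stats::sd), "/")
}

# 1/f-amplitude (pink) noise, unit variance per column.
pink_noise <- function(ns, fs, n_signals) {
  z <- matrix(stats::rnorm(ns * n_signals), ns, n_signals)
  Z <- stats::mvfft(z)
  freqs <- (0:(ns - 1L)) * fs / ns
  freqs <- pmin(freqs, fs - freqs)
  amp <- 1 / sqrt(pmax(freqs, fs / ns))
  amp[1L] <- 0
  x <- Re(stats::mvfft(Z * amp, inverse = TRUE)) / ns
  sweep(x, 2L, apply(x, 2L, stats::sd), "/")
}

# Split a samples x signals matrix into its [low, high] Hz component and
# the remainder (brick-wall Fourier partition).
band_split <- function(x, fs, low, high) {
  ns <- nrow(x)
  Z <- stats::mvfft(x)
  freqs <- (0:(ns - 1L)) * fs / ns
  freqs <- pmin(freqs, fs - freqs)
  inb <- freqs >= low & freqs <= high
  Zi <- Z; Zi[!inb, ] <- 0
  inside <- Re(stats::mvfft(Zi, inverse = TRUE)) / ns
  list(inside = inside, outside = x - inside)
}

# Per-class source standard-deviation multipliers (K x n_sources).
class_source_scales <- function(sc) {
  k <- sc$n_classes; ns <- sc$n_channels
  m <- matrix(1, k, ns)
  if (sc$effect %in% c("csp_favorable", "mixed")) {
    for (l in seq_len(k - 1L))
      m[l + 1L, ((l - 1L) %% ns) + 1L] <-
        m[l + 1L, ((l - 1L) %% ns) + 1L] * sqrt(sc$effect_size)
  }
  m
}

# Per-class effect-band amplitude gains (energy effect): class l scales
# in-band variance by effect_size^(l / (K - 1)).
class_trial_gains <- function(sc) {
  k <- sc$n_classes
  g <- rep(1, k)
  if (sc$effect %in% c("asp_favorable", "mixed") && k > 1L)
    g <- sqrt(sc$effect_size^((0:(k - 1L)) / (k - 1L)))
  g
}

#' Generate a synthetic epoch set
#'
#' Draws trials from the scenario's generative model. Deterministic given
#' `seed` (the mixing matrix is fixed separately by the scenario's
#' `mixing_seed`, so repeated draws share the same head geometry).
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer RNG seed.
#' @return A list with `epochs` (an [epoch_set()], trials in interleaved
#'   class order) and `truth`: the mixing matrix `A`, the unit-norm channel
#'   image `u` of the contrast source (`csp_favorable`/`mixed`), the
#'   per-class source scale matrix, and the scenario.
#' @export
generate_epochs <- function(scenario, seed = 1L) {
  sc <- scenario
  if (sc$effect_band[2] >= sc$fs / 2)
    stop("effect band reaches Nyquist")
  nsamp <- round(sc$fs * sc$trial_seconds)
  nch <- sc$n_channels
  A <- with_seed(sc$mixing_seed, {
    repeat {
      cand <- matrix(stats::rnorm(nch * nch), nch, nch)
      if (abs(det(cand)) > 1e-6) break
    }
    if (identical(sc$mixing, "orthogonal")) qr.Q(qr(cand)) else cand
  })
  scales <- class_source_scales(sc)
  gains <- class_trial_gains(sc)
  nt <- sc$trials_per_class * sc$n_classes
  labels <- rep(0:(sc$n_classes - 1L), times = sc$trials_per_class)
  dat <- array(0, c(nt, nch, nsamp))
  with_seed(seed, {
    # baseline in-band sensor power per channel (class 0, unit sources)
    base_pow <- mean(rowSums(A^2))
    noise_var <- base_pow / sc$snr
    wsum <- sc$noise_pink + sc$noise_white
    wp <- sc$noise_pink / wsum; ww <- sc$noise_white / wsum
    for (t in seq_len(nt)) {
      s <- bandlimited_noise(nsamp, sc$fs, sc$effect_band[1],
                             sc$effect_band[2], nch)
      s <- sweep(s, 2L, scales[labels[t] + 1L, ], "*")
      x <- A %*% t(s)  # channels x samples
      np <- pink_noise(nsamp, sc$fs, nch)
      nw <- matrix(stats::rnorm(nsamp * nch), nsamp, nch)
      noise <- sqrt(noise_var) * (sqrt(wp) * np + sqrt(ww) * nw)
      nsplit <- band_split(noise, sc$fs, sc$effect_band[1], sc$effect_band[2])
      g <- gains[labels[t] + 1L]
      dat[t, , ] <- g * (x + t(nsplit$inside)) + t(nsplit$outside)
    }
  })
  u <- A[, 1L] / sqrt(sum(A[, 1L]^2))
  list(epochs = epoch_set(dat, labels, sc$fs),
       truth = list(A = A, u = u, scales = scales, gains = gains,
                    scenario = sc))
}

#' Deterministic fixture epoch sets
#'
#' Small presets reused across examples and tests. `"tiny-2class-3ch"`
#' mirrors a 3-electrode bipolar montage (40 trials, 3 channels, 250 Hz,
#' 3 s, mixed effect); `"small-4class-8ch"` is a 4-class, 8-channel set
#' (60 trials, 128 Hz, 2 s, mixed effect). Identical on every call.
#'
#' @param name preset identifier.
#' @return An [epoch_set()].
#' @export
make_fixture <- function(name) {
  switch(name,
    "tiny-2class-3ch" = generate_epochs(
      sim_scenario(n_channels = 3L, n_classes = 2L, trials_per_class = 20L,
                   fs = 250, trial_seconds = 3, effect = "mixed",
                   effect_band = c(8, 12), effect_size = 4, snr = 2,
                   mixing_seed = 42L),
      seed = 42L)$epochs,
    "small-4class-8ch" = generate_epochs(
      sim_scenario(n_channels = 8L, n_classes = 4L, trials_per_class = 15L,
                   fs = 128, trial_seconds = 2, effect = "mixed",
                   effect_band = c(8, 12), effect_size = 4, snr = 2,
                   mixing_seed = 7L),
      seed = 7L)$epochs,
    stop(sprintf("unknown fixture preset '%s'", name)))
}
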