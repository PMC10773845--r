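test_that("common-average re-referencing removes the per-sample channel mean", {
  # a common constant offset vanishes entirely
  x <- array(3, c(2, 4, 20))
  ep <- epoch_set(x, c(0, 1), 100)
  out <- rereference(ep, "car")
  expect_equal(max(abs(out$data)), 0)
  # per-channel constants are centred: every time-sample's channel mean is 0
  xc <- array(0, c(2, 4, 20))
  for (c in 1:4) xc[, c, ] <- c
  outc <- rereference(epoch_set(xc, c(0, 1), 100), "car")
  expect_equal(max(abs(apply(outc$data, c(1, 3), mean))), 0, tolerance = 1e-12)
  # random trial equals brute-force mean subtraction, and CAR is idempotent
  set.seed(5)
  x2 <- array(rnorm(2 * 4 * 20), c(2, 4, 20))
  ep2 <- epoch_set(x2, c(0, 1), 100)
  out2 <- rereference(ep2, "car")
  manual <- x2
  for (t in 1:2) for (s in 1:20)
    manual[t, , s] <- x2[t, , s] - mean(x2[t, , s])
  expect_equal(out2$data, manual, tolerance = 1e-12)
  expect_equal(rereference(out2, "car")$data, out2$data, tolerance = 1e-12)
  expect_equal(max(abs(apply(out2$data, c(1, 3), mean))), 0, tolerance = 1e-12)
})

test_that("re-referencing guards small montages", {
  ep1 <- epoch_set(array(rnorm(2 * 1 * 10), c(2, 1, 10)), c(0, 1), 10)
  expect_error(rereference(ep1, "car"), "2 channels")
  ep3 <- epoch_set(array(rnorm(2 * 3 * 10), c(2, 3, 10)), c(0, 1), 10)
  expect_equal(rereference(ep3, "auto")$data, ep3$data)  # bipolar left alone
})

test_that("cue-locked windows have the arithmetic sample count", {
  ep <- epoch_set(array(rnorm(2 * 2 * 1000), c(2, 2, 1000)), c(0, 1), 250)
  w <- extract_window(ep, 0.5, 3.5)
  expect_equal(dim(w$data)[3], 750)          # 3.0 s at 250 Hz
  expect_equal(w$labels, ep$labels)
  expect_equal(extract_window(ep, 0, 4)$data, ep$data)  # identity
  ep2 <- epoch_set(array(rnorm(2 * 2 * 30), c(2, 2, 30)), c(0, 1), 100)
  expect_equal(dim(extract_window(ep2, 0.1, 0.2)$data)[3], 10)
  expect_error(extract_window(ep, 1, 5), "exceeds")
  expect_error(extract_window(ep, 2, 1), "start_s")
})

test_that("filter bank concentrates a pure tone in its matched band", {
  tt <- (0:511) / 128
  x <- array(0, c(2, 2, 512))
  for (t in 1:2) for (c in 1:2) x[t, c, ] <- sin(2 * pi * 10 * tt + c)
  ep <- epoch_set(x, c(0, 1), 128)
  bd <- apply_filterbank(ep, filter_bank_spec())
  v <- vapply(bd$bands, function(b) stats::var(b$data[1, 1, ]), 0)
  expect_gte(v[2] / sum(v), 0.90)            # 8-12 Hz band
  # non-adjacent bands reject the tone to < 1% of the matched band
  expect_true(all(v[-(1:3)] < 0.01 * v[2]))
})

test_that("filter bank is linear and annihilates zero input", {
  set.seed(9)
  mk <- function(arr) epoch_set(arr, c(0, 1), 128)
  a <- array(rnorm(2 * 2 * 256), c(2, 2, 256))
  b <- array(rnorm(2 * 2 * 256), c(2, 2, 256))
  spec <- filter_bank_spec()
  fa <- apply_filterbank(mk(a), spec)
  fb <- apply_filterbank(mk(b), spec)
  fab <- apply_filterbank(mk(2 * a - 3 * b), spec)
  for (i in c(1, 5, 9))
    expect_equal(fab$bands[[i]]$data,
                 2 * fa$bands[[i]]$data - 3 * fb$bands[[i]]$data,
                 tolerance = 1e-9)
  z <- apply_filterbank(mk(array(0, c(2, 2, 256))), spec)
  expect_true(all(vapply(z$bands, function(x) max(abs(x$data)), 0) == 0))
})

test_that("white-noise band variances scale with bandwidth", {
  set.seed(11)
  ep <- epoch_set(array(rnorm(6 * 1 * 512), c(6, 1, 512)), rep(0:1, 3), 128)
  bd <- apply_filterbank(ep, filter_bank_spec())
  v <- vapply(bd$bands, function(b) mean(apply(b$data[, 1, ], 1, stats::var)), 0)
  # all nine bands are 4 Hz wide: variances agree within Monte-Carlo error
  expect_lt(max(v) / min(v), 1.8)
})

test_that("band edges at or above Nyquist are rejected", {
  ep <- epoch_set(array(rnorm(2 * 2 * 100), c(2, 2, 100)), c(0, 1), 64)
  expect_error(apply_filterbank(ep, filter_bank_spec()), "Nyquist")
  expect_error(filter_bank_spec(list(c(12, 8))), "low < high")
  expect_error(filter_bank_spec(list(c(4, 10), c(8, 12))), "non-overlapping")
})

test_that("windowing after filtering matches filtering the window interior", {
  # smooth in-band signal: order of windowing and filtering only differs
  # near the edges
  tt <- (0:767) / 128
  x <- array(0, c(1, 1, 768))
  x[1, 1, ] <- sin(2 * pi * 10 * tt) + 0.5 * sin(2 * pi * 9 * tt + 1)
  ep <- epoch_set(x, 0, 128)
  spec <- filter_bank_spec(list(c(8, 12)))
  a <- extract_window(apply_filterbank(ep, spec)$bands[[1]], 1, 5)
  b <- apply_filterbank(extract_window(ep, 1, 5), spec)$bands[[1]]
  interior <- 33:(512 - 32)                  # >= 0.25 s from the edges
  rms <- sqrt(mean((a$data[1, 1, interior] - b$data[1, 1, interior])^2))
  expect_lt(rms / sqrt(mean(a$data[1, 1, interior]^2)), 0.05)
})
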