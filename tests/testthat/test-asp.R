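test_that("log band-energy feature matches direct summation", {
  X <- rbind(c(1, 1, 1, 1), 0, 0)
  expect_equal(energy_feature(c(1, 0, 0), X), log(4))
  set.seed(3)
  F <- rnorm(3); Xr <- matrix(rnorm(30), 3, 10)
  direct <- log(sum(vapply(1:10, function(t) sum(F * Xr[, t])^2, 0)))
  expect_equal(energy_feature(F, Xr), direct, tolerance = 1e-12)
  # positive rescaling shifts the feature by exactly 2 log c
  expect_equal(energy_feature(3 * F, Xr), energy_feature(F, Xr) + 2 * log(3),
               tolerance = 1e-12)
  expect_error(energy_feature(c(0, 0, 1), rbind(1:4, 1:4, 0)), "zero")
})

test_that("the scatter-ratio loss evaluates and degenerates as designed", {
  expect_equal(asp_loss(c(0, 2, 4, 6), c(0, 0, 1, 1)), 0.25)  # 4 / 16
  expect_equal(asp_loss(c(1, 1, 5, 5), c(0, 0, 1, 1)), 0)     # no within spread
  expect_equal(asp_loss(c(0, 2, 0, 2), c(0, 0, 1, 1)), Inf)   # equal means
  expect_error(asp_loss(c(1, 2, 3), c(0, 0, 0)), "2 classes")
  # exact affine invariance
  set.seed(12)
  x <- rnorm(30); lab <- rep(0:2, 10)
  expect_equal(asp_loss(5.5 * x - 2, lab), asp_loss(x, lab),
               tolerance = 1e-12)
})

test_that("single-channel ASP is the raw log-energy loss", {
  set.seed(2)
  x <- array(rnorm(20 * 1 * 50), c(20, 1, 50))
  x[11:20, , ] <- x[11:20, , ] * 3
  ep <- epoch_set(x, rep(0:1, each = 10), 50)
  f <- fit_asp_filter(ep, tiny_swarm(), seed = 1)
  expect_equal(abs(f$weights), 1)
  raw <- log(apply(x, 1, function(m) sum(m^2)))
  expect_equal(f$achieved_loss, asp_loss(raw, ep$labels), tolerance = 1e-10)
})

test_that("achieved loss is self-consistent and the fit deterministic", {
  g <- generate_epochs(planted_scenario(n_channels = 6, trials_per_class = 30),
                       seed = 5)
  ep <- effect_band_epochs(g)
  f1 <- fit_asp_filter(ep, tiny_swarm(), seed = 4)
  f2 <- fit_asp_filter(ep, tiny_swarm(), seed = 4)
  expect_identical(f1, f2)
  expect_equal(sqrt(sum(f1$weights^2)), 1, tolerance = 1e-12)
  feats <- vapply(seq_len(dim(ep$data)[1]), function(t)
    energy_feature(f1$weights, ep$data[t, , ]), 0)
  expect_equal(f1$achieved_loss, asp_loss(feats, ep$labels), tolerance = 1e-10)
})

test_that("amplitude rescaling of a band leaves the fitted filter unchanged", {
  g <- generate_epochs(planted_scenario(n_channels = 5, trials_per_class = 25),
                       seed = 9)
  ep <- effect_band_epochs(g)
  ep2 <- epoch_set(ep$data * 4, ep$labels, ep$fs)
  f1 <- fit_asp_filter(ep, tiny_swarm(), seed = 2)
  f2 <- fit_asp_filter(ep2, tiny_swarm(), seed = 2)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-12)
  expect_equal(f1$achieved_loss, f2$achieved_loss, tolerance = 1e-10)
})

test_that("two-channel PSO is near the grid-search oracle", {
  g <- generate_epochs(planted_scenario(n_channels = 2, trials_per_class = 40),
                       seed = 7)
  ep <- effect_band_epochs(g)
  fit <- fit_asp_filter(ep, swarm_config(), seed = 1)
  angles <- seq(0, pi, length.out = 3600)
  feats_of <- function(w) vapply(seq_len(dim(ep$data)[1]), function(t)
    energy_feature(w, ep$data[t, , ]), 0)
  grid_losses <- vapply(angles, function(a)
    asp_loss(feats_of(c(cos(a), sin(a))), ep$labels), 0)
  expect_lte(fit$achieved_loss, min(grid_losses) * 1.05)
})

test_that("permuted labels raise the achieved loss far above the planted fit", {
  planted <- numeric(4); shuffled <- numeric(4)
  for (s in 1:4) {
    g <- generate_epochs(planted_scenario(n_channels = 8,
                                          trials_per_class = 50,
                                          mixing_seed = s), seed = 40 + s)
    ep <- effect_band_epochs(g)
    planted[s] <- fit_asp_filter(ep, swarm_config(max_iter = 50),
                                 seed = s)$achieved_loss
    set.seed(90 + s)
    perm <- epoch_set(ep$data, sample(ep$labels), ep$fs)
    shuffled[s] <- fit_asp_filter(perm, swarm_config(max_iter = 50),
                                  seed = s)$achieved_loss
  }
  expect_gte(stats::median(shuffled), 5 * stats::median(planted))
})

test_that("filter-bank ASP yields subbands * C(K,2) filters", {
  ep4 <- make_fixture("small-4class-8ch")
  bd4 <- apply_filterbank(ep4, filter_bank_spec())
  asp4 <- fb_asp(bd4, tiny_swarm(), seed = 1)
  expect_length(asp4$filters, 9 * choose(4, 2))  # 54
  expect_equal(nrow(asp4$layout), 54)
  ep2 <- make_fixture("tiny-2class-3ch")
  bd2 <- apply_filterbank(ep2, filter_bank_spec())
  asp2 <- fb_asp(bd2, tiny_swarm(), seed = 1)
  expect_length(asp2$filters, 9)                 # C(2,2) = 1 pair per band
  feats <- fbacsp:::asp_feature_matrix(bd2, asp2)
  expect_equal(dim(feats), c(40L, 9L))
})
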