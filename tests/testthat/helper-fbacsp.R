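# Small shared configurations so structural tests stay fast; optimization
# quality is exercised separately at full swarm settings.
tiny_swarm <- function() swarm_config(n_particles = 12L, max_iter = 20L)

quick_cfg <- function(swarm = tiny_swarm(), mibif_n = 2L,
                      rfe_grid = c(4, 8), n_trees = 60L, cv_trees = 40L,
                      ...) {
  fbacsp_config(swarm = swarm, mibif_n = mibif_n, rfe_grid = rfe_grid,
                n_trees = n_trees, cv_trees = cv_trees, ...)
}

# Independent global-best PSO oracle sharing the package's documented RNG
# draw order (init positions, init velocities, then r1/r2 per iteration).
gbest_pso_oracle <- function(objective, lower, upper, cfg, seed) {
  nd <- length(lower)
  n <- cfg$n_particles
  vmax <- cfg$v_max_frac * (upper - lower)
  set.seed(seed)
  X <- matrix(runif(nd * n, lower, upper), nd, n)
  V <- matrix(runif(nd * n, -vmax, vmax), nd, n)
  pv <- apply(X, 2, objective)
  pp <- X
  trace <- min(pv); best <- trace; stag <- 0L
  for (t in seq_len(cfg$max_iter)) {
    w <- (cfg$w_ini - cfg$w_end) * (cfg$max_iter - (t - 1)) / cfg$max_iter +
      cfg$w_end
    g <- pp[, which.min(pv)]
    r1 <- matrix(runif(nd * n), nd, n)
    r2 <- matrix(runif(nd * n), nd, n)
    V <- w * V + cfg$c1 * r1 * (pp - X) + cfg$c2 * r2 * (g - X)
    V <- pmin(pmax(V, -vmax), vmax)
    X <- pmin(pmax(X + V, lower), upper)
    vals <- apply(X, 2, objective)
    imp <- vals < pv
    pv[imp] <- vals[imp]; pp[, imp] <- X[, imp]
    nb <- min(pv)
    stag <- if (best - nb > cfg$tol) 0L else stag + 1L
    best <- min(best, nb)
    trace <- c(trace, best)
    if (stag >= cfg$patience) break
  }
  list(best_value = best, trace = trace,
       best_position = pp[, which.min(pv)])
}

# Planted-direction scenario used by recovery checks: isotropic in-band
# background plus extra variance along one known direction.
planted_scenario <- function(n_channels = 16L, trials_per_class = 100L,
                             effect_size = 4, mixing_seed = 1L) {
  sim_scenario(n_channels = n_channels, trials_per_class = trials_per_class,
               effect = "csp_favorable", effect_size = effect_size,
               snr = 10, mixing = "orthogonal", mixing_seed = mixing_seed)
}

effect_band_epochs <- function(gen) {
  apply_filterbank(gen$epochs, filter_bank_spec(list(c(8, 12))))$bands[[1]]
}
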