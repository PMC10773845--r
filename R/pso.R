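#' Local-best particle swarm configuration
#'
#' Hyperparameters of the local-best (ring topology) particle swarm
#' optimizer. The inertia weight decreases linearly from `w_ini` to `w_end`
#' over `max_iter` iterations; each velocity component is clipped to
#' `v_max = v_max_frac * (upper - lower)` per dimension; positions are
#' clamped to the box. The social term attracts each particle to the best
#' personal best among its `k_neighbors` ring neighbours plus itself.
#'
#' @param n_particles swarm size N (>= 2).
#' @param max_iter maximum iterations G (>= 1).
#' @param c1,c2 cognitive / social learning factors.
#' @param w_ini,w_end initial and final inertia weights (`w_end <= w_ini`).
#' @param v_max_frac per-dimension speed cap as a fraction of the box width.
#' @param k_neighbors ring-neighbourhood size (1 .. N-1); `N - 1` recovers
#'   global-best PSO.
#' @param tol,patience stop early when the best-so-far value has improved by
#'   less than `tol` for `patience` consecutive iterations.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(n_particles = 40L, max_iter = 100L, c1 = 2, c2 = 2,
                         w_ini = 0.9, w_end = 0.4, v_max_frac = 0.2,
                         k_neighbors = 2L, tol = 1e-8, patience = 25L) {
  stopifnot(n_particles >= 2L, max_iter >= 1L, w_end >= 0, w_end <= w_ini,
            v_max_frac > 0, k_neighbors >= 1L, k_neighbors <= n_particles - 1L)
  structure(list(n_particles = as.integer(n_particles),
                 max_iter = as.integer(max_iter), c1 = c1, c2 = c2,
                 w_ini = w_ini, w_end = w_end, v_max_frac = v_max_frac,
                 k_neighbors = as.integer(k_neighbors), tol = tol,
                 patience = as.integer(patience)),
            class = "swarm_config")
}

#' Linearly decreasing inertia weight
#'
#' `w(t) = (w_ini - w_end) * (G - t) / G + w_end` for iteration
#' `t = 0 .. G`.
#'
#' @param t iteration index, `0 <= t <= max_iter`.
#' @param cfg a [swarm_config()].
#' @return The inertia weight at iteration `t`.
#' @export
update_inertia <- function(t, cfg) {
  g <- cfg$max_iter
  (cfg$w_ini - cfg$w_end) * (g - t) / g + cfg$w_end
}

# Ring neighbourhood of particle i (1-based): i plus its k nearest indices,
# floor(k/2) on the left and ceiling(k/2) on the right, wrapping.
ring_neighbors <- function(i, n, k) {
  left <- k %/% 2L
  right <- k - left
  idx <- c(i - seq_len(left), i, i + seq_len(right))
  ((idx - 1L) %% n) + 1L
}

#' Neighbourhood best position
#'
#' Returns the personal-best position with the lowest personal-best value
#' among particle `i`'s `k` ring neighbours plus itself; ties go to the
#' lowest particle index.
#'
#' @param pbest_pos dim x N matrix of personal-best positions.
#' @param pbest_val length-N vector of personal-best objective values.
#' @param i particle index (1-based).
#' @param k neighbourhood size.
#' @return The selected position (numeric vector).
#' @export
neighborhood_best <- function(pbest_pos, pbest_val, i, k) {
  nb <- sort(unique(ring_neighbors(i, length(pbest_val), k)))
  j <- nb[which.min(pbest_val[nb])]
  pbest_pos[, j]
}

# Evaluate the objective on a dim x N matrix of positions; returns length-N
# values with non-finite results mapped to +Inf (warned once per run).
eval_objective <- function(objective, X, vectorized, warn_env) {
  vals <- if (vectorized) as.numeric(objective(X))
          else apply(X, 2L, function(x) as.numeric(objective(x)))
  bad <- !is.finite(vals)
  if (any(bad)) {
    if (!warn_env$warned) {
      warning("objective returned non-finite values; treated as +Inf")
      warn_env$warned <- TRUE
    }
    vals[bad] <- Inf
  }
  vals
}

#' Minimize a black-box objective with local-best PSO
#'
#' Runs the linearly-decreasing-inertia, velocity-clamped particle swarm
#' with a ring-topology social term over the box `[lower, upper]^dim`.
#' Velocities update as
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (lbest - x)` with one independent
#' uniform draw per particle per dimension per attraction term, then each
#' component is clipped to `[-v_max, v_max]` and positions advance and are
#' clamped to the box. Fully deterministic given `seed`.
#'
#' @param objective function mapping a numeric vector (or, with
#'   `vectorized = TRUE`, a dim x N matrix) to objective value(s) to minimize.
#' @param lower,upper per-dimension box bounds (recycled to a common length,
#'   which sets the dimension).
#' @param cfg a [swarm_config()].
#' @param seed integer RNG seed.
#' @param vectorized if `TRUE`, `objective` is called once per iteration on
#'   the full dim x N position matrix and must return N values.
#' @return A `swarm_result` list: `best_position`, `best_value`,
#'   `loss_trace` (best-so-far after initialization and after each
#'   iteration; non-increasing), `iterations_run`.
#' @examples
#' res <- pso_optimize(function(x) sum(x^2), lower = rep(-1, 3),
#'                     upper = rep(1, 3), seed = 1)
#' res$best_value
#' @export
pso_optimize <- function(objective, lower, upper, cfg = swarm_config(),
                         seed = 1L, vectorized = FALSE) {
  nd <- max(length(lower), length(upper))
  if (nd < 1L) stop("dimension must be >= 1")
  lower <- rep_len(as.numeric(lower), nd)
  upper <- rep_len(as.numeric(upper), nd)
  if (any(lower >= upper)) stop("require lower < upper in every dimension")
  n <- cfg$n_particles
  vmax <- cfg$v_max_frac * (upper - lower)
  warn_env <- new.env(); warn_env$warned <- FALSE

  runner <- function() {
    X <- matrix(stats::runif(nd * n, lower, upper), nd, n)
    V <- matrix(stats::runif(nd * n, -vmax, vmax), nd, n)
    pb_val <- eval_objective(objective, X, vectorized, warn_env)
    pb_pos <- X
    trace <- min(pb_val)
    best_so_far <- trace
    stagnant <- 0L
    iters <- 0L
    for (t in seq_len(cfg$max_iter)) {
      w <- update_inertia(t - 1L, cfg)
      G <- vapply(seq_len(n), function(i)
        neighborhood_best(pb_pos, pb_val, i, cfg$k_neighbors), numeric(nd))
      G <- matrix(G, nd, n)
      r1 <- matrix(stats::runif(nd * n), nd, n)
      r2 <- matrix(stats::runif(nd * n), nd, n)
      V <- w * V + cfg$c1 * r1 * (pb_pos - X) + cfg$c2 * r2 * (G - X)
      V <- pmin(pmax(V, -vmax), vmax)
      X <- X + V
      X <- pmin(pmax(X, lower), upper)
      vals <- eval_objective(objective, X, vectorized, warn_env)
      better <- vals < pb_val
      pb_val[better] <- vals[better]
      pb_pos[, better] <- X[, better]
      new_best <- min(pb_val)
      stagnant <- if (best_so_far - new_best > cfg$tol) 0L else stagnant + 1L
      best_so_far <- min(best_so_far, new_best)
      trace <- c(trace, best_so_far)
      iters <- t
      if (stagnant >= cfg$patience) break
    }
    j <- which.min(pb_val)
    structure(list(best_position = pb_pos[, j], best_value = pb_val[j],
                   loss_trace = trace, iterations_run = iters),
              class = "swarm_result")
  }
  with_seed(seed, runner())
}

#' @export
print.swarm_result <- function(x, ...) {
  cat(sprintf("<swarm_result> best value %.6g after %d iterations (dim %d)\n",
              x$best_value, x$iterations_run, length(x$best_position)))
  invisible(x)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-stage seed derivation from a master seed (kept < 2^31).
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}
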