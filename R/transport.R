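#' Parameters of the two-state transport simulation
#'
#' The model lives in a disk of radius 1; time is measured in units of
#' the mean microtubule-bound lifetime, i.e. `k_unbind = 1` defines the
#' clock, and all rates and speeds are expressed in those units.
#' Mitochondria switch between a microtubule-bound state (purely radial
#' motion at the PKA-dependent drift velocity, see [drift_velocity]) and
#' a free state (isotropic diffusion with reflecting boundary).
#'
#' @param k_bind binding rate (per unit time). Default 0.025.
#' @param k_unbind unbinding rate; fixing it at 1 defines the time unit.
#' @param pka_signal dimensionless PKA pathway signal strength, `>= 0`.
#'   Default 0.7.
#' @param v_plus anterograde (outward, kinesin) speed in disk radii per
#'   unit time. Default 0.4.
#' @param v_minus retrograde (inward, dynein) speed, same units.
#'   Default 0.4.
#' @param diffusion free-state diffusion coefficient in disk radii^2 per
#'   unit time. Default 0.0008 (see the methods vignette for how this
#'   default is pinned by the drift-diffusion balance that puts the
#'   steady-state mode mid-cell at the reference parameter set).
#' @param dt time step. Must satisfy `dt * max(k_bind, k_unbind) <= 0.1`
#'   so the per-step Bernoulli switching approximates the two-state
#'   Markov process. Default 0.01.
#' @param n_mito number of walkers. Default 5000.
#' @param n_steps number of steps; `NULL` (default) runs until the
#'   mean-radius convergence criterion is met (see [run_simulation]).
#' @param seed integer RNG seed.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(k_bind = 0.025, k_unbind = 1, pka_signal = 0.7,
                       v_plus = 0.4, v_minus = 0.4, diffusion = 0.0008,
                       dt = 0.01, n_mito = 5000, n_steps = NULL, seed = 1L) {
  for (nm in c("k_bind", "k_unbind", "pka_signal", "v_plus", "v_minus",
               "diffusion")) {
    stop_if_not_scalar_num(get(nm), nm, 0)
  }
  stop_if_not_scalar_num(dt, "dt", 0, strict_min = TRUE)
  stop_if_not_scalar_num(n_mito, "n_mito", 1)
  if (dt * max(k_bind, k_unbind) > 0.1) {
    stop("dt * max(k_bind, k_unbind) must be <= 0.1 (Bernoulli switching guard)",
         call. = FALSE)
  }
  if (!is.null(n_steps)) stop_if_not_scalar_num(n_steps, "n_steps", 1)
  structure(list(k_bind = k_bind, k_unbind = k_unbind,
                 pka_signal = pka_signal, v_plus = v_plus, v_minus = v_minus,
                 diffusion = diffusion, dt = dt,
                 n_mito = as.integer(n_mito),
                 n_steps = if (is.null(n_steps)) NULL else as.integer(n_steps),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' PKA-dependent drift velocity of microtubule-bound mitochondria
#'
#' The net radial speed of a bound mitochondrion results from the
#' competition between kinesin-driven anterograde and dynein-driven
#' retrograde transport, with the PKA signal partitioning the two in a
#' saturating way:
#' `v_drift = v_plus * pka/(1 + pka) - v_minus / (1 + pka)`.
#' It increases monotonically in `pka_signal` from `-v_minus` (no PKA
#' signal, pure retrograde) toward `v_plus` (saturating signal), and is
#' 0 at `pka_signal = 1` when the two speeds are equal.
#'
#' @param pka_signal dimensionless signal strength(s), `>= 0`; vectorized.
#' @param v_plus,v_minus anterograde / retrograde speeds, `>= 0`.
#' @return drift velocity (positive = outward), same length as
#'   `pka_signal`.
#' @export
drift_velocity <- function(pka_signal, v_plus = 0.4, v_minus = 0.4) {
  if (any(!is.finite(pka_signal)) || any(pka_signal < 0)) {
    stop("'pka_signal' must be finite and >= 0", call. = FALSE)
  }
  stop_if_not_scalar_num(v_plus, "v_plus", 0)
  stop_if_not_scalar_num(v_minus, "v_minus", 0)
  (pka_signal / (1 + pka_signal)) * v_plus - v_minus / (1 + pka_signal)
}

#' Advance the walker state by one time step (reference implementation)
#'
#' Single-step R reference for the simulation kernel, used to document
#' and test the exact dynamics.  Per walker, in index order: draw one
#' uniform and switch state (`unbound -> bound` w.p. `k_bind*dt`,
#' `bound -> unbound` w.p. `k_unbind*dt`); then unbound walkers take a
#' Gaussian step per axis (sd `sqrt(2*diffusion*dt)`) with a radial
#' mirror reflection at the boundary, and bound walkers step radially by
#' `v_drift*dt` (clamped at the boundary, passing through the origin).
#' Consumes the RNG identically to the compiled loop in
#' [run_simulation], so looping this function reproduces it draw for
#' draw.
#'
#' @param state list with numeric `x`, `y` and logical `bound`, all the
#'   same length, positions inside the unit disk.
#' @param params a [sim_params].
#' @return the updated state list.
#' @export
advance_state <- function(state, params) {
  res <- cpp_advance_walkers(state$x, state$y, state$bound, 1L,
                             params$k_bind * params$dt,
                             params$k_unbind * params$dt,
                             sqrt(2 * params$diffusion * params$dt),
                             drift_velocity(params$pka_signal, params$v_plus,
                                            params$v_minus) * params$dt,
                             0L)
  list(x = res$x, y = res$y, bound = res$bound)
}

#' Run the transport simulation to steady state
#'
#' Walkers start uniformly distributed over the disk area, with bound
#' flags drawn from the stationary binding distribution
#' `k_bind / (k_bind + k_unbind)`.  If `n_steps` is set the simulation
#' runs exactly that many steps; otherwise it runs in windows of 1000
#' steps until the windowed mean radius changes by less than 0.005 for 3
#' consecutive windows, with a hard cap of 1e5 steps (non-convergence is
#' reported via `converged = FALSE` and a warning).
#'
#' @param params a [sim_params].
#' @param record_every record the population mean radius every this many
#'   steps (default 100).
#' @return an object of class `sim_result`: list with `r` (final radial
#'   distances), `bound`, `trajectory` (data.frame `step`, `mean_r`),
#'   `params`, `seed`, `n_steps_run`, `converged`.
#' @export
run_simulation <- function(params = sim_params(), record_every = 100L) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, function() {
    n <- params$n_mito
    r0 <- sqrt(runif(n))
    th0 <- runif(n, 0, 2 * pi)
    state <- list(x = r0 * cos(th0), y = r0 * sin(th0),
                  bound = runif(n) < params$k_bind / (params$k_bind + params$k_unbind))
    p_bind <- params$k_bind * params$dt
    p_unbind <- params$k_unbind * params$dt
    step_sd <- sqrt(2 * params$diffusion * params$dt)
    drift_step <- drift_velocity(params$pka_signal, params$v_plus,
                                 params$v_minus) * params$dt
    record_every <- max(1L, as.integer(record_every))

    traj_step <- integer(0)
    traj_mean <- numeric(0)
    total_steps <- 0L
    advance <- function(k) {
      res <- cpp_advance_walkers(state$x, state$y, state$bound, as.integer(k),
                                 p_bind, p_unbind, step_sd, drift_step,
                                 record_every)
      state <<- list(x = res$x, y = res$y, bound = res$bound)
      traj_step <<- c(traj_step, res$rec_step + total_steps)
      traj_mean <<- c(traj_mean, res$rec_mean)
      total_steps <<- total_steps + as.integer(k)
    }

    converged <- TRUE
    if (!is.null(params$n_steps)) {
      n_run <- params$n_steps
      advance(n_run)
    } else {
      window <- 1000L
      cap <- 100000L
      record_every <- min(record_every, window)
      window_means <- numeric(0)
      n_run <- 0L
      ok_streak <- 0L
      repeat {
        before <- length(traj_mean)
        advance(window)
        n_run <- n_run + window
        wm <- mean(traj_mean[(before + 1L):length(traj_mean)])
        window_means <- c(window_means, wm)
        k <- length(window_means)
        if (k >= 2 && abs(window_means[k] - window_means[k - 1]) < 0.005) {
          ok_streak <- ok_streak + 1L
        } else {
          ok_streak <- 0L
        }
        if (ok_streak >= 3L) break
        if (n_run >= cap) {
          converged <- FALSE
          warning("simulation did not meet the steady-state criterion within ",
                  cap, " steps", call. = FALSE)
          break
        }
      }
    }
    structure(list(r = sqrt(state$x^2 + state$y^2), bound = state$bound,
                   trajectory = data.frame(step = traj_step, mean_r = traj_mean),
                   params = params, seed = params$seed,
                   n_steps_run = n_run, converged = converged),
              class = "sim_result")
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d walkers, %d steps%s, mean radius %.4f\n",
              length(x$r), x$n_steps_run,
              if (x$converged) "" else " (NOT converged)", mean(x$r)))
  invisible(x)
}

#' Steady-state mean radius over a (PKA signal, k_bind) grid
#'
#' Runs one steady-state simulation per grid point and reports the mean
#' radial distance of the population, its Monte-Carlo standard error,
#' and the drift velocity at that point.  The same seed is reused at
#' every grid point (common random numbers) so the surface is smooth in
#' the parameters.
#'
#' @param pka_grid,kbind_grid numeric vectors of parameter values.
#' @param base_params a [sim_params] supplying all other parameters.
#' @return a data.frame with columns `pka_signal`, `k_bind`, `mean_r`,
#'   `stderr`, `v_drift`, `n_steps_run`, `converged`, one row per grid
#'   point; the matrix of mean radii (rows = `kbind_grid`, columns =
#'   `pka_grid`) is attached as attribute `"matrix"`.
#' @export
mean_position_sweep <- function(pka_grid, kbind_grid, base_params = sim_params()) {
  if (!length(pka_grid) || !length(kbind_grid)) {
    stop("parameter grids must be nonempty", call. = FALSE)
  }
  grid <- expand.grid(pka_signal = pka_grid, k_bind = kbind_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base_params
    p$pka_signal <- grid$pka_signal[i]
    p$k_bind <- grid$k_bind[i]
    res <- run_simulation(p)
    data.frame(pka_signal = p$pka_signal, k_bind = p$k_bind,
               mean_r = mean(res$r), stderr = sd(res$r) / sqrt(length(res$r)),
               v_drift = drift_velocity(p$pka_signal, p$v_plus, p$v_minus),
               n_steps_run = res$n_steps_run, converged = res$converged)
  })
  out <- do.call(rbind, rows)
  m <- matrix(out$mean_r, nrow = length(pka_grid), ncol = length(kbind_grid))
  attr(out, "matrix") <- t(m)
  dimnames(attr(out, "matrix")) <- list(k_bind = kbind_grid, pka_signal = pka_grid)
  out
}
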