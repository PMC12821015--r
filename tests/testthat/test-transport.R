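test_that("drift velocity reproduces its closed form and monotonicity", {
  expect_equal(drift_velocity(0, 0.4, 0.3), -0.3)
  expect_equal(drift_velocity(1, 0.4, 0.4), 0)
  expect_equal(drift_velocity(0.7, 0.4, 0.4), -0.12 / 1.7)
  expect_equal(drift_velocity(0.7, 0.4, 0.4), -0.0706, tolerance = 1e-3)
  pka <- seq(0, 5, by = 0.1)
  expect_true(all(diff(drift_velocity(pka, 0.4, 0.4)) > 0))
  v <- drift_velocity(c(0, 1e6), 0.4, 0.3)
  expect_true(all(v > -0.3 - 1e-12 & v < 0.4))
  expect_error(drift_velocity(-1), "pka_signal")
  expect_error(drift_velocity(1, v_plus = -0.1), "v_plus")
})

test_that("sim_params enforces the stability guard and positivity", {
  expect_error(sim_params(k_bind = -1), "k_bind")
  expect_error(sim_params(dt = 0), "dt")
  expect_error(sim_params(k_unbind = 5, dt = 0.05), "guard")
  p <- sim_params(n_steps = 100)
  expect_identical(p$n_steps, 100L)
})

test_that("single-step dynamics follow the documented rules", {
  # bound walker with v_drift = 0.1 (pka=1, v+=0.3, v-=0.1) steps radially
  p <- sim_params(k_bind = 1, k_unbind = 0, pka_signal = 1, v_plus = 0.3,
                  v_minus = 0.1, diffusion = 0, dt = 0.01)
  st <- advance_state(list(x = 0.3, y = 0.4, bound = TRUE), p)
  expect_equal(sqrt(st$x^2 + st$y^2), 0.501)
  expect_equal(atan2(st$y, st$x), atan2(0.4, 0.3))   # angle unchanged

  # retrograde through the origin: radius |r - |v|dt|, direction flipped
  pneg <- sim_params(k_bind = 1, k_unbind = 0, pka_signal = 0, v_plus = 0,
                     v_minus = 0.4, diffusion = 0, dt = 0.01)
  st2 <- advance_state(list(x = 0.001, y = 0, bound = TRUE), pneg)
  expect_equal(st2$x, -(0.004 - 0.001))
  # outward clamp at the membrane
  st3 <- advance_state(list(x = 0.9999, y = 0, bound = TRUE), p)
  expect_equal(st3$x, 1)

  # null dynamics: no diffusion, no binding -> frozen positions
  pnull <- sim_params(k_bind = 0, diffusion = 0, dt = 0.01)
  st4 <- list(x = c(0.1, -0.5), y = c(0.2, 0.1), bound = c(FALSE, FALSE))
  for (i in 1:5) st4 <- advance_state(st4, pnull)
  expect_equal(st4$x, c(0.1, -0.5))
  expect_equal(st4$y, c(0.2, 0.1))
})

test_that("compiled kernel matches the plain-R oracle draw for draw", {
  p <- sim_params(k_bind = 0.4, k_unbind = 0.6, pka_signal = 0.7,
                  v_plus = 0.4, v_minus = 0.4, diffusion = 0.05, dt = 0.1)
  init <- list(x = c(0.1, -0.4, 0.8, 0, 0.3), y = c(0.2, 0.5, -0.1, 0, -0.9),
               bound = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  set.seed(123)
  a <- init
  for (s in 1:40) a <- advance_state(a, p)
  set.seed(123)
  b <- init
  for (s in 1:40) b <- oracle_advance_step(b, p)
  expect_equal(a$x, b$x, tolerance = 1e-14)
  expect_equal(a$y, b$y, tolerance = 1e-14)
  expect_identical(as.logical(a$bound), b$bound)
})

test_that("walkers stay confined to the unit disk at every step", {
  p <- sim_params(k_bind = 0.5, k_unbind = 1, pka_signal = 3, v_plus = 0.8,
                  v_minus = 0.2, diffusion = 0.2, dt = 0.05, n_mito = 200,
                  n_steps = 500, seed = 17)
  res <- run_simulation(p)
  expect_true(all(res$r <= 1))
  st <- list(x = res$r * 0, y = res$r * 0, bound = rep(FALSE, length(res$r)))
  st$x <- sqrt(runif(200)); st$bound <- runif(200) < 0.5
  for (s in 1:50) {
    st <- advance_state(st, p)
    expect_true(all(st$x^2 + st$y^2 <= 1 + 1e-12))
  }
})

test_that("simulation results are deterministic given the seed", {
  p <- sim_params(n_mito = 300, n_steps = 400, seed = 5)
  a <- run_simulation(p)
  b <- run_simulation(p)
  expect_identical(a$r, b$r)
  expect_identical(a$trajectory, b$trajectory)
  p2 <- p; p2$seed <- 6L
  expect_false(identical(run_simulation(p2)$r, a$r))
})

test_that("unbound-only dynamics relax to the uniform-area law", {
  p <- sim_params(k_bind = 0, pka_signal = 0, diffusion = 0.0008,
                  n_mito = 2000, n_steps = 2000, seed = 13)
  res <- run_simulation(p)
  r <- sort(res$r)
  ks <- max(abs(r^2 - (seq_along(r) - 0.5) / length(r)))
  expect_lt(ks, 0.05)
  expect_equal(mean(r), 2 / 3, tolerance = 0.03)
})

test_that("strong PKA with frequent binding accumulates walkers peripherally", {
  p <- sim_params(k_bind = 1, k_unbind = 1, pka_signal = 10, v_plus = 0.4,
                  v_minus = 0.4, dt = 0.05, n_mito = 1500, n_steps = 4000,
                  seed = 23)
  expect_gt(drift_velocity(10, 0.4, 0.4), 0)
  expect_gt(mean(run_simulation(p)$r), 2 / 3)
})

test_that("halving dt leaves the steady-state mean radius stable", {
  mk <- function(dt, steps) sim_params(k_bind = 0.1, pka_signal = 2,
                                       dt = dt, n_mito = 1500,
                                       n_steps = steps, seed = 31)
  a <- run_simulation(mk(0.05, 4000))
  b <- run_simulation(mk(0.025, 8000))
  se <- sd(a$r) / sqrt(length(a$r))
  expect_lt(abs(mean(a$r) - mean(b$r)), 3 * se)
})

test_that("the mean-position sweep uses common random numbers and reports a matrix", {
  base <- sim_params(n_mito = 400, n_steps = 600, seed = 3)
  sw <- mean_position_sweep(c(0.5, 2), c(0, 0.05), base)
  expect_equal(nrow(sw), 4L)
  m <- attr(sw, "matrix")
  expect_equal(dim(m), c(2L, 2L))
  # the k_bind = 0 row is exactly flat under common random numbers:
  # binding never fires, so the pka value never enters the dynamics
  expect_equal(m["0", "0.5"], m["0", "2"])
  expect_error(mean_position_sweep(numeric(0), 1, base), "nonempty")
})
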