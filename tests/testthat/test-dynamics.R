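p <- default_parameters()

test_that("spatial diffusion: eigenmode decay, mass conservation, stability refusal", {
  g <- make_grids(p, 30, 7)
  # constant density is a fixed point
  nc <- array(2, c(g$nx, g$ny, g$ny))
  dt <- 0.5 * g$dx^2 / (2 * p$beta_n)
  expect_equal(diffusion_step_x(nc, dt, p$beta_n, g), nc)

  # discrete cosine eigenmode decays by the closed-form amplification factor
  k <- 3
  mode <- cos(k * pi * g$x / g$L)
  n <- array(rep(mode, g$ny^2), c(g$nx, g$ny, g$ny))
  n1 <- diffusion_step_x(n, dt, p$beta_n, g)
  amp <- 1 - 2 * p$beta_n * dt * (1 - cos(k * pi * g$dx / g$L)) / g$dx^2
  expect_equal(n1, amp * n, tolerance = 1e-12)

  # zero-flux + symmetric stencil: mass conserved to round-off
  set.seed(11)
  nr <- array(runif(g$nx * g$ny^2), c(g$nx, g$ny, g$ny))
  st0 <- make_state(0, nr, rep(1e-6, g$nx), rep(1e-5, g$nx), rep(1e-8, g$nx), g)
  m0 <- total_mass(st0, g)
  n2 <- diffusion_step_x(nr, dt, p$beta_n, g)
  st1 <- make_state(0, n2, rep(1e-6, g$nx), rep(1e-5, g$nx), rep(1e-8, g$nx), g)
  expect_lt(abs(total_mass(st1, g) - m0) / m0, 1e-12)

  # steps beyond the stability bound are refused with the admissible dt
  expect_error(diffusion_step_x(nr, 10 * g$dx^2 / p$beta_n, p$beta_n, g),
               "admissible")
})

test_that("trait diffusion: fixed points, separability, spreading", {
  g <- make_grids(p, 12, 15)
  dt <- 0.5 * g$dy^2 / (4 * p$theta)
  nc <- array(1.5, c(g$nx, g$ny, g$ny))
  expect_equal(diffusion_step_y(nc, dt, p$theta, g), nc)

  # separable profile: the x-dependence passes through untouched
  xprof <- exp(-g$x / g$L)
  bump <- outer(exp(-(g$y - 0.5)^2 / 0.02), exp(-(g$y - 0.5)^2 / 0.02))
  n <- outer(xprof, bump)
  n1 <- diffusion_step_y(n, dt, p$theta, g)
  expect_equal(n1[5, , ] / xprof[5], n1[9, , ] / xprof[9], tolerance = 1e-12)

  # trait variance grows monotonically under pure mutation
  w2 <- outer(g$wy, g$wy)
  vary <- function(sl) {
    m <- sum(w2 * sl * rep(g$y, g$ny)) / sum(w2 * sl)
    sum(w2 * sl * (rep(g$y, g$ny) - m)^2) / sum(w2 * sl)
  }
  v <- numeric(5); sl <- n[5, , ]
  for (s in 1:5) {
    v[s] <- vary(sl)
    full <- array(rep(as.vector(sl), each = g$nx), c(g$nx, g$ny, g$ny))
    sl <- diffusion_step_y(full, dt, p$theta, g)[1, , ]
  }
  expect_true(all(diff(v) > 0))
})

test_that("implicit reaction step divides by (1 - dt R) and approximates the exponential", {
  g <- make_grids(p, 8, 7)
  n <- initial_cell_density(g)
  S_o <- rep(2.08e-6, g$nx); S_g <- rep(1e-5, g$nx); S_l <- rep(1e-8, g$nx)
  dt <- 1e4
  out <- reaction_step(n, S_o, S_g, S_l, dt, p, g)
  # independent assembly of R from the scalar fitness API
  w2 <- outer(g$wy, g$wy)
  for (i in c(1, 5)) for (j in c(1, 4)) for (k in c(1, 7)) {
    rho_i <- sum(w2 * n[i, , ])
    R <- fitness(S_o[i], S_g[i], S_l[i], rho_i, g$y[j], g$y[k], p)
    expect_equal(out[i, j, k], n[i, j, k] / (1 - dt * R), tolerance = 1e-12)
  }
  # overly large steps are refused, naming the admissible step
  expect_error(reaction_step(n, S_o, S_g, S_l, 1e10, p, g), "admissible")
})

test_that("reaction-only crowding dynamics reproduce the logistic decay exactly", {
  # with rho frozen per step, the implicit map is rho_{m+1} = rho_m/(1 + dt k rho_m),
  # i.e. 1/rho grows linearly: the discrete solution IS the logistic closed form
  g <- make_grids(p, 6, 5)
  S_o <- rep(0, g$nx); S_g <- rep(0, g$nx); S_l <- rep(1e-8, g$nx)  # no growth
  # concentrate all mass at the penalty-free node (y1 = 0, y2 = 1)
  n_init <- array(0, c(g$nx, g$ny, g$ny))
  n_init[, 1, g$ny] <- 1 / (g$wy[1] * g$wy[g$ny])   # rho = 1 at every x
  horizon <- 2e9                                     # ~ 1/(kappa rho0) = 5e9 s
  errs <- vapply(c(200, 400), function(nsteps) {
    dt <- horizon / nsteps
    n <- n_init
    for (s in seq_len(nsteps)) n <- reaction_step(n, S_o, S_g, S_l, dt, p, g)
    rho_end <- sum(outer(g$wy, g$wy) * n[3, , ])
    abs(rho_end - 1 / (1 + p$kappa * 1 * horizon))
  }, 0)
  expect_lt(errs[1], 1e-12)
  expect_lt(errs[2], 1e-12)
})

test_that("explicit substrate step preserves the relaxed steady state and decays correctly", {
  g <- make_grids(p, 40, 5)
  ab <- abiotic_quasi_steady(rep(0, g$nx), p, g)
  dt <- 0.9 * g$dx^2 / (2 * max(p$beta_o, p$beta_g, p$beta_l))
  stepd <- abiotic_step(ab$S_o, ab$S_g, ab$S_l, rep(0, g$nx), dt, p, g)
  expect_lt(max(abs(stepd$S_o - ab$S_o) / ab$S_o), 1e-8)
  expect_lt(max(abs(stepd$S_l - ab$S_l) / pmax(ab$S_l, 1e-300)), 1e-8)

  # with diffusion switched off, interior decay matches e^(-lambda dt) to 2nd order
  p0 <- p; p0$beta_o <- p0$beta_g <- p0$beta_l <- 0
  S <- rep(1e-5, g$nx)
  one <- abiotic_step(S, S, S, rep(0, g$nx), 50, p0, g)
  i <- 5
  expect_equal(one$S_l[i] / S[i], 1 / (1 + 50 * p$lambda_l))
  expect_lt(abs(one$S_l[i] / S[i] - exp(-50 * p$lambda_l)),
            (50 * p$lambda_l)^2)

  # lactate production raises the field wherever glycolytic cells sit
  # (relative to the identical step without cells)
  rho <- c(rep(0, 20), rep(1e3, 20))
  hyp <- list(S_o = rep(p$O_m / 2, g$nx), S_g = rep(1e-5, g$nx),
              S_l = rep(1e-8, g$nx))
  with_cells <- abiotic_step(hyp$S_o, hyp$S_g, hyp$S_l, rho, dt, p, g)
  no_cells <- abiotic_step(hyp$S_o, hyp$S_g, hyp$S_l, rep(0, g$nx), dt, p, g)
  expect_true(all(with_cells$S_l[25:39] > no_cells$S_l[25:39]))
  expect_equal(with_cells$S_l[2:15], no_cells$S_l[2:15])
})

test_that("quasi-stationary solve agrees with long explicit co-integration", {
  g <- make_grids(p, 20, 5)
  rho <- 1800 * exp(-g$x^2 / 2e-4)
  qs <- abiotic_quasi_steady(rho, p, g)
  # co-integrate from a different (linear) start until relaxed
  f <- list(S_o = seq(p$S_bar_o, p$S_under_o, length.out = g$nx),
            S_g = seq(p$S_bar_g, p$S_under_g, length.out = g$nx),
            S_l = rep(p$S_under_l, g$nx))
  dt <- 0.9 * g$dx^2 / (2 * max(p$beta_o, p$beta_g, p$beta_l))
  for (s in seq_len(ceiling(4000 / dt)))
    f <- abiotic_step(f$S_o, f$S_g, f$S_l, rho, dt, p, g)
  expect_lt(max(abs(f$S_o - qs$S_o) / max(qs$S_o)), 1e-4)
  expect_lt(max(abs(f$S_g - qs$S_g) / max(qs$S_g)), 1e-4)
  expect_lt(max(abs(f$S_l - qs$S_l) / max(qs$S_l)), 1e-4)
  expect_true(all(qs$S_o >= 0 & qs$S_g >= 0 & qs$S_l >= 0))

  # cell-free lactate matches the mixed Dirichlet/zero-flux closed form
  # (on a finer grid: the lactate decay length ~60 um needs resolving)
  gf <- make_grids(p, 200, 5)
  qs0 <- abiotic_quasi_steady(rep(0, gf$nx), p, gf)
  el <- analytic_neumann_profile(p$beta_l, p$lambda_l, gf$L, p$S_under_l, gf$x)
  expect_lt(max(abs(qs0$S_l - el) / el), 1e-3)
})

test_that("splitting run terminates, keeps positivity, and records increasing times", {
  g <- make_grids(p, 50, 9)
  opts <- solver_options(max_steps = 60, record_every = 10, snapshot_every = 30)
  traj <- run_simulation(p, g, opts)
  expect_s3_class(traj, "eet_trajectory")
  expect_true(all(diff(traj$summary$t) > 0))
  expect_true(all(traj$final$n >= 0))
  expect_true(all(traj$final$S_o >= 0))
  expect_true(traj$termination %in% c("equilibrium", "T_max", "max_steps"))
  expect_identical(traj$snapshots[[length(traj$snapshots)]]$t, traj$final$t)
  # identical configuration reruns bit-identically (deterministic model)
  traj2 <- run_simulation(p, g, opts)
  expect_identical(traj$summary, traj2$summary)
  expect_identical(traj$final$n, traj2$final$n)
})

test_that("first_crossing_time interpolates linearly and handles absent crossings", {
  t <- c(0, 10, 20, 30)
  expect_equal(first_crossing_time(t, c(0, 0.25, 0.75, 1)), 15)
  expect_true(is.na(first_crossing_time(t, c(0, 0.1, 0.2, 0.3))))
  expect_equal(first_crossing_time(t, c(0.6, 0.7, 0.8, 0.9)), 0)
})
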