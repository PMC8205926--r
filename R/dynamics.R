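#' Solver options
#'
#' @param dt Macro time step in seconds, or `NA` (automatic: the largest
#'   step allowed by the explicit stability bounds of the cell diffusion
#'   operators and the positivity bound of the implicit-explicit reaction
#'   update, times `stability_safety`).
#' @param abiotic_mode `"quasi-stationary"` (default) refreshes the
#'   substrate fields each macro step with their steady state at the
#'   current cell density, exploiting the ~1e5-fold timescale separation
#'   between substrate relaxation (seconds-minutes) and cell dynamics
#'   (weeks); `"co-integrate"` sub-cycles the substrate PDEs explicitly at
#'   their own stable step inside each macro step.
#' @param stability_safety Fraction of each stability bound actually used,
#'   in (0, 1].
#' @param equilibrium_tol Termination threshold on the relative state
#'   change per unit time (1/s): the run stops when
#'   `max |delta| / (dt * (1 + |value|))` over all state arrays falls below
#'   it.
#' @param max_steps Hard cap on macro steps.
#' @param record_every Record trajectory summaries every this many steps.
#' @param snapshot_every Store full state snapshots every this many steps
#'   (`NA`: none; the initial and final states are always kept).
#' @param seed Unused placeholder; the model is deterministic.
#' @return An object of class `"eet_solver_options"`.
#' @export
solver_options <- function(dt = NA_real_,
                           abiotic_mode = c("quasi-stationary", "co-integrate"),
                           stability_safety = 0.9,
                           equilibrium_tol = 1e-12,
                           max_steps = 100000L,
                           record_every = 1L,
                           snapshot_every = NA_integer_,
                           seed = NA_integer_) {
  abiotic_mode <- match.arg(abiotic_mode)
  stopifnot(is.na(dt) || dt > 0,
            stability_safety > 0, stability_safety <= 1,
            equilibrium_tol > 0, max_steps >= 1)
  structure(list(dt = dt, abiotic_mode = abiotic_mode,
                 stability_safety = stability_safety,
                 equilibrium_tol = equilibrium_tol,
                 max_steps = as.integer(max_steps),
                 record_every = as.integer(record_every),
                 snapshot_every = snapshot_every,
                 seed = seed),
            class = "eet_solver_options")
}

# Shift-based mirrored-ghost Laplacians (equivalent to padding with
# apply_cell_bcs, without allocating the ghost array).
.lap_x <- function(n, dx) {
  nx <- dim(n)[1]
  (n[c(2, seq_len(nx - 1)), , , drop = FALSE] - 2 * n +
     n[c(seq_len(nx - 1) + 1, nx - 1), , , drop = FALSE]) / dx^2
}
.lap_y <- function(n, dy) {
  ny <- dim(n)[2]
  jm <- c(2, seq_len(ny - 1)); jp <- c(seq_len(ny - 1) + 1, ny - 1)
  (n[, jm, , drop = FALSE] - 2 * n + n[, jp, , drop = FALSE] +
     n[, , jm, drop = FALSE] - 2 * n + n[, , jp, drop = FALSE]) / dy^2
}

.check_dt <- function(dt, bound, what) {
  if (dt > bound)
    stop(sprintf("unstable time step for %s: dt = %g exceeds admissible %g s",
                 what, dt, bound), call. = FALSE)
}

#' Explicit diffusion step in space
#'
#' Three-point Laplacian in x with zero-flux mirrored ghosts, applied
#' independently at each trait node. Refuses steps beyond the explicit
#' stability bound `safety * dx^2 / (2 beta_n)`.
#'
#' @param n Cell-density array.
#' @param dt Time step, s.
#' @param beta_n Cell motility, cm^2/s.
#' @param grids Grids.
#' @param safety Fraction of the stability bound allowed.
#' @return Updated array.
#' @export
diffusion_step_x <- function(n, dt, beta_n, grids, safety = 1) {
  if (beta_n == 0 || dt == 0) return(n)
  .check_dt(dt, safety * grids$dx^2 / (2 * beta_n), "x-diffusion")
  n + dt * beta_n * .lap_x(n, grids$dx)
}

#' Explicit diffusion step in trait space
#'
#' Five-point Laplacian over (y1, y2) with zero-flux edges, applied
#' independently at each spatial node; stability bound
#' `safety * dy^2 / (4 theta)`.
#'
#' @param n Cell-density array.
#' @param dt Time step, s.
#' @param theta Rate of spontaneous phenotypic change, 1/s.
#' @param grids Grids.
#' @param safety Fraction of the stability bound allowed.
#' @return Updated array.
#' @export
diffusion_step_y <- function(n, dt, theta, grids, safety = 1) {
  if (theta == 0 || dt == 0) return(n)
  .check_dt(dt, safety * grids$dy^2 / (4 * theta), "trait diffusion")
  n + dt * theta * .lap_y(n, grids$dy)
}

# Fitness landscape evaluated on the whole (x, y1, y2) grid, with rho
# frozen from the current n. Returns list(R = array, rho = vector).
.fitness_on_grid <- function(n, S_o, S_g, S_l, params, grids) {
  nm <- .flatten_traits(n, grids)
  rho <- as.vector(nm %*% .wy2(grids))
  base <- oxphos_rate(S_o, params) + glycolysis_rate(S_o, S_g, params) -
    crowding_death(rho, params)                                   # nx
  pen1 <- params$eta_l * outer(fittest_acidity_level(S_l, params), grids$y, function(p, y) (y - p)^2)  # nx x ny (j)
  pen2 <- params$eta_o * outer(fittest_hypoxia_level(S_o, params), grids$y, function(p, y) (y - p)^2)  # nx x ny (k)
  R <- array(base, dim = c(grids$nx, grids$ny, grids$ny))
  R <- R - as.vector(pen1)                         # recycles over k
  R <- R - as.vector(pen2[, rep(seq_len(grids$ny), each = grids$ny)])
  list(R = R, rho = rho)
}

#' Implicit-explicit reaction step
#'
#' Pointwise update `n' = n / (1 - dt * R)` with the fitness `R` evaluated
#' at the current substrate fields and with the cell density `rho` frozen
#' at the start of the step, so `R` is constant in `n` and the implicit
#' solve reduces to a scalar division. The step is refused (reporting the
#' admissible step) if `dt * R >= 1` anywhere, which also guarantees
#' positivity.
#'
#' @param n Cell-density array.
#' @param S_o,S_g,S_l Substrate fields over x.
#' @param dt Time step, s.
#' @param params Parameter set.
#' @param grids Grids.
#' @return Updated array.
#' @export
reaction_step <- function(n, S_o, S_g, S_l, dt, params, grids) {
  fg <- .fitness_on_grid(n, S_o, S_g, S_l, params, grids)
  mx <- max(fg$R)
  if (dt * mx >= 1)
    stop(sprintf("reaction step refused: dt * max(R) = %g >= 1; admissible dt < %g s",
                 dt * mx, 1 / mx), call. = FALSE)
  n / (1 - dt * fg$R)
}

#' Explicit substrate step (co-integration mode)
#'
#' One explicit step of the three substrate reaction-diffusion equations
#' at frozen cell density: three-point diffusion and consumption/production
#' sources explicit, natural decay implicit (division by `1 + dt*lambda`).
#' Dirichlet values are re-pinned after the step; the far-field lactate
#' node keeps its zero-flux mirror. Negative values (which the stability
#' control should prevent) are clamped to zero with a warning.
#'
#' @param S_o,S_g,S_l Substrate fields over x.
#' @param rho Cell-density vector over x.
#' @param dt Time step; must satisfy `safety * dx^2 / (2 max beta)`.
#' @param params Parameter set.
#' @param grids Grids.
#' @param safety Fraction of the stability bound allowed.
#' @return List of updated fields.
#' @export
abiotic_step <- function(S_o, S_g, S_l, rho, dt, params, grids, safety = 1) {
  bmax <- max(params$beta_o, params$beta_g, params$beta_l)
  .check_dt(dt, safety * grids$dx^2 / (2 * bmax), "substrate diffusion")
  nx <- grids$nx
  lap <- function(S, neumann_right = FALSE) {
    Sm <- S[c(2, seq_len(nx - 1))]
    Sp <- S[c(seq_len(nx - 1) + 1, nx - 1)]
    out <- (Sm - 2 * S + Sp) / grids$dx^2
    if (!neumann_right) out[nx] <- 0   # Dirichlet node, value re-pinned below
    out[1] <- 0
    out
  }
  p_g <- glycolysis_rate(S_o, S_g, params)
  step1 <- function(S, beta, lambda, src, neumann_right = FALSE) {
    (S + dt * (beta * lap(S, neumann_right) + src)) / (1 + dt * lambda)
  }
  S_o2 <- step1(S_o, params$beta_o, params$lambda_o,
                -params$zeta_o * oxphos_rate(S_o, params) * rho)
  S_g2 <- step1(S_g, params$beta_g, params$lambda_g,
                -params$zeta_g * p_g * rho)
  S_l2 <- step1(S_l, params$beta_l, params$lambda_l,
                 params$zeta_l * p_g * rho, neumann_right = TRUE)
  out <- apply_abiotic_bcs(S_o2, S_g2, S_l2, params)
  if (min(out$S_o, out$S_g, out$S_l) < 0) {
    warning("substrate field went negative; clamped to 0")
    out <- lapply(out, pmax, 0)
  }
  out
}

#' Quasi-stationary substrate fields
#'
#' Steady states of the three substrate equations at frozen cell density:
#' oxygen and glucose by the damped fixed-point/tridiagonal machinery of
#' [relax_abiotic_profiles()], lactate by a single linear solve with its
#' mixed Dirichlet (vessel) / zero-flux (far field) conditions. This is
#' the default coupling mode, justified by the ~1e5-fold separation
#' between substrate and cell timescales.
#'
#' @param rho Non-negative cell-density vector over x.
#' @param params Parameter set.
#' @param grids Grids.
#' @param warm Optional list of fields used as the iteration starting
#'   point (speeds up repeated refreshes during a run).
#' @param tol,max_iter Fixed-point controls.
#' @return List with fields `S_o`, `S_g`, `S_l`.
#' @export
abiotic_quasi_steady <- function(rho, params, grids, warm = NULL,
                                 tol = 1e-10, max_iter = 200) {
  stopifnot(length(rho) == grids$nx, all(rho >= 0))
  A_o <- .steady_operator(params$beta_o, params$lambda_o, grids, "dirichlet")
  S_o <- .relax_field(
    A_o, function(S) params$zeta_o * oxphos_rate(pmax(S, 0), params) * rho,
    S0 = if (is.null(warm)) seq(params$S_bar_o, params$S_under_o, length.out = grids$nx) else warm$S_o,
    bc0 = params$S_bar_o, bcL = params$S_under_o,
    tol = tol, max_iter = max_iter)
  S_o <- pmax(S_o, 0)

  A_g <- .steady_operator(params$beta_g, params$lambda_g, grids, "dirichlet")
  S_g <- .relax_field(
    A_g, function(S) params$zeta_g * glycolysis_rate(S_o, pmax(S, 0), params) * rho,
    S0 = if (is.null(warm)) seq(params$S_bar_g, params$S_under_g, length.out = grids$nx) else warm$S_g,
    bc0 = params$S_bar_g, bcL = params$S_under_g,
    tol = tol, max_iter = max_iter)
  S_g <- pmax(S_g, 0)

  A_l <- .steady_operator(params$beta_l, params$lambda_l, grids, "neumann")
  S_l <- .steady_solve(A_l, -params$zeta_l * glycolysis_rate(S_o, S_g, params) * rho,
                       bc0 = params$S_under_l)
  list(S_o = S_o, S_g = S_g, S_l = pmax(S_l, 0))
}

# Trajectory summary row at one instant.
.summarise_state <- function(state, params, grids, rho_floor = 1e-12) {
  mom <- compute_moments(state, grids, rho_floor)
  phio <- fittest_hypoxia_level(state$S_o, params)
  phil <- fittest_acidity_level(state$S_l, params)
  def <- !is.na(mom$mu1)
  ox <- classify_regions(state$S_o, grids$x, params$O_m, params$O_M)
  la <- classify_regions(state$S_l, grids$x, params$L_m, params$L_M)
  data.frame(
    t = state$t,
    mass = sum(grids$wx * mom$rho),
    nu1 = mom$nu1, nu2 = mom$nu2,
    x_O_M = unname(ox["x_high"]), x_O_m = unname(ox["x_low"]),
    x_L_m = unname(la["x_low"]), x_L_M = unname(la["x_high"]),
    sup_mu2_err = if (any(def)) max(abs(mom$mu2[def] - phio[def])) else NA_real_,
    sup_mu1_err = if (any(def)) max(abs(mom$mu1[def] - phil[def])) else NA_real_
  )
}

#' Run the coupled simulation
#'
#' Integrates the cell balance equation coupled to the substrate fields
#' with Strang-style operator splitting per macro step — half x-diffusion,
#' half trait-diffusion, implicit-explicit reaction, half trait-diffusion,
#' half x-diffusion — after refreshing the substrates (quasi-stationary
#' solve, or explicit sub-cycling at their own stable step). Terminates
#' when the relative state change per unit time drops below
#' `equilibrium_tol`, or at `T_max` / `max_steps`.
#'
#' @param params Parameter set from [default_parameters()].
#' @param grids Grids from [make_grids()].
#' @param opts Options from [solver_options()].
#' @param ic Optional initial condition: list with `n`, `S_o`, `S_g`,
#'   `S_l`. Default: the Gaussian cell bump of [initial_cell_density()]
#'   with substrates relaxed at its density profile.
#' @return An object of class `"eet_trajectory"`: `summary` (data frame of
#'   recorded diagnostics), `final` (final `"eet_state"`), `snapshots`
#'   (list of states, always including initial and final), `termination`
#'   (`"equilibrium"`, `"T_max"` or `"max_steps"`), `residual`, `dt`, and
#'   the resolved configuration.
#' @export
run_simulation <- function(params, grids, opts = solver_options(), ic = NULL) {
  viol <- validate_parameters(params)
  if (length(viol) > 0)
    stop(sprintf("invalid parameters: %s", paste(viol, collapse = "; ")), call. = FALSE)

  if (is.null(ic)) {
    n <- initial_cell_density(grids)
    nm <- .flatten_traits(n, grids)
    rho0 <- as.vector(nm %*% .wy2(grids))
    ab <- relax_abiotic_profiles(params, grids, rho0)
    ic <- list(n = n, S_o = ab$S_o, S_g = ab$S_g, S_l = ab$S_l)
  }
  n <- ic$n; S_o <- ic$S_o; S_g <- ic$S_g; S_l <- ic$S_l

  safety <- opts$stability_safety
  dt <- opts$dt
  if (is.na(dt)) {
    bounds <- c(
      if (params$beta_n > 0) grids$dx^2 / (2 * params$beta_n) else Inf,
      if (params$theta > 0) grids$dy^2 / (4 * params$theta) else Inf,
      1 / (params$gamma_o + params$gamma_g)   # reaction positivity
    )
    dt <- safety * min(bounds)
  }
  sub_m <- 1L
  if (opts$abiotic_mode == "co-integrate") {
    bmax <- max(params$beta_o, params$beta_g, params$beta_l)
    sub_m <- max(1L, ceiling(dt / (safety * grids$dx^2 / (2 * bmax))))
  }

  state <- make_state(0, n, S_o, S_g, S_l, grids)
  summaries <- list(.summarise_state(state, params, grids))
  snapshots <- list(state)
  termination <- "max_steps"
  residual <- NA_real_
  t <- 0

  for (step in seq_len(opts$max_steps)) {
    n_prev <- n; So_prev <- S_o; Sg_prev <- S_g; Sl_prev <- S_l

    nm <- .flatten_traits(n, grids)
    rho <- as.vector(nm %*% .wy2(grids))
    if (opts$abiotic_mode == "quasi-stationary") {
      ab <- abiotic_quasi_steady(rho, params, grids,
                                 warm = list(S_o = S_o, S_g = S_g, S_l = S_l))
    } else {
      ab <- list(S_o = S_o, S_g = S_g, S_l = S_l)
      dts <- dt / sub_m
      for (s in seq_len(sub_m))
        ab <- abiotic_step(ab$S_o, ab$S_g, ab$S_l, rho, dts, params, grids, safety = 1)
    }
    S_o <- ab$S_o; S_g <- ab$S_g; S_l <- ab$S_l

    n <- diffusion_step_x(n, dt / 2, params$beta_n, grids)
    n <- diffusion_step_y(n, dt / 2, params$theta, grids)
    n <- reaction_step(n, S_o, S_g, S_l, dt, params, grids)
    n <- diffusion_step_y(n, dt / 2, params$theta, grids)
    n <- diffusion_step_x(n, dt / 2, params$beta_n, grids)
    t <- t + dt

    state <- make_state(t, n, S_o, S_g, S_l, grids)
    if (step %% opts$record_every == 0)
      summaries[[length(summaries) + 1L]] <- .summarise_state(state, params, grids)
    if (!is.na(opts$snapshot_every) && step %% opts$snapshot_every == 0)
      snapshots[[length(snapshots) + 1L]] <- state

    rel <- function(a, b) max(abs(a - b) / (1 + abs(a)))
    residual <- max(rel(n, n_prev), rel(S_o, So_prev),
                    rel(S_g, Sg_prev), rel(S_l, Sl_prev)) / dt
    if (residual < opts$equilibrium_tol) { termination <- "equilibrium"; break }
    if (t >= params$T_max) { termination <- "T_max"; break }
  }
  if (snapshots[[length(snapshots)]]$t != state$t)
    snapshots[[length(snapshots) + 1L]] <- state
  if (summaries[[length(summaries)]]$t != state$t)
    summaries[[length(summaries) + 1L]] <- .summarise_state(state, params, grids)

  structure(list(
    summary = do.call(rbind, summaries),
    final = state,
    snapshots = snapshots,
    termination = termination,
    residual = residual,
    dt = dt,
    abiotic_substeps = sub_m,
    params = params, grids = grids, options = opts
  ), class = "eet_trajectory")
}

#' First time a trajectory summary crosses a level
#'
#' Linear interpolation between the first bracketing pair of recorded
#' times; `NA` when the level is never crossed from below.
#'
#' @param times,values Recorded times and values.
#' @param level Threshold (default 0.5).
#' @return Scalar time in seconds, or `NA`.
#' @export
first_crossing_time <- function(times, values, level = 0.5) {
  ok <- !is.na(values)
  times <- times[ok]; values <- values[ok]
  if (length(values) == 0) return(NA_real_)
  above <- values >= level
  if (above[1]) return(times[1])
  i <- which(!above[-length(above)] & above[-1])
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  times[i] + (times[i + 1] - times[i]) *
    (level - values[i]) / (values[i + 1] - values[i])
}

#' @export
print.eet_trajectory <- function(x, ...) {
  cat(sprintf("Simulation trajectory: %d recorded instants, t in [0, %g] s\n",
              nrow(x$summary), x$final$t))
  cat(sprintf("  termination: %s (residual %.3e 1/s), dt = %g s\n",
              x$termination, x$residual, x$dt))
  cat(sprintf("  final mass %.6g, nu1 = %.4f, nu2 = %.4f\n",
              x$summary$mass[nrow(x$summary)],
              x$summary$nu1[nrow(x$summary)],
              x$summary$nu2[nrow(x$summary)]))
  invisible(x)
}
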