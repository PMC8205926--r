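#' Experiment presets
#'
#' A preset bundles a parameter set, grid resolution and solver options
#' into a named, validated, reproducible experiment.
#'
#' @param name Preset name.
#' @param params Parameter set.
#' @param nx,ny Grid resolution.
#' @param opts Solver options.
#' @return An object of class `"eet_preset"`.
#' @export
make_preset <- function(name, params = default_parameters(),
                        nx = 200, ny = 41, opts = solver_options()) {
  viol <- validate_parameters(params)
  if (length(viol) > 0)
    stop(sprintf("preset '%s' does not validate: %s", name,
                 paste(viol, collapse = "; ")), call. = FALSE)
  structure(list(name = name, params = params, nx = nx, ny = ny, opts = opts),
            class = "eet_preset")
}

#' Baseline invasion/adaptation experiment
#'
#' The calibrated defaults: Gaussian cell bump at the vessel wall,
#' substrates relaxed to their steady profiles at the initial density,
#' quasi-stationary substrate coupling, run to numerical equilibrium.
#' Outputs are the density/trait-moment tables, tissue-wide phenotypic
#' distribution and habitat crossing positions.
#'
#' @param nx,ny Grid resolution (defaults 200 and 41).
#' @param opts Solver options.
#' @return An `"eet_preset"`.
#' @export
preset_baseline <- function(nx = 200, ny = 41, opts = solver_options()) {
  make_preset("baseline", default_parameters(), nx, ny, opts)
}

#' Selection-gradient ratio sweep
#'
#' One preset per requested ratio `eta_o / eta_l`, anchoring `eta_l` at its
#' calibrated value and setting `eta_o = ratio * eta_l`. Each run records
#' the evolutionary-pathway curve `phi(t) = (nu1(t), nu2(t))` and the first
#' times at which each tissue-wide trait mean crosses 0.5.
#'
#' @param ratios Positive ratios; default log-spaced
#'   `c(0.01, 0.1, 1, 10, 100)` covering the acidity-first, simultaneous
#'   and hypoxia-first regimes.
#' @param nx,ny Grid resolution.
#' @param opts Solver options.
#' @return List of `"eet_preset"` objects.
#' @export
preset_eta_sweep <- function(ratios = c(0.01, 0.1, 1, 10, 100),
                             nx = 200, ny = 41, opts = solver_options()) {
  if (length(ratios) == 0) stop("empty ratio list", call. = FALSE)
  stopifnot(all(ratios > 0))
  lapply(ratios, function(r) {
    p <- default_parameters()
    p$eta_o <- r * p$eta_l
    pre <- make_preset(sprintf("eta_sweep_ratio_%g", r), p, nx, ny, opts)
    pre$ratio <- r
    pre
  })
}

#' Generic one-parameter sensitivity harness
#'
#' One preset per multiplier applied to a named parameter; running each
#' and re-evaluating the final-state invariant suite probes the structural
#' stability of the equilibrium.
#'
#' @param parameter Name of a model parameter.
#' @param multipliers Positive factors.
#' @param nx,ny Grid resolution.
#' @param opts Solver options.
#' @return List of `"eet_preset"` objects.
#' @export
preset_sensitivity <- function(parameter, multipliers,
                               nx = 200, ny = 41, opts = solver_options()) {
  valid <- names(default_parameters())
  if (!parameter %in% valid)
    stop(sprintf("unknown parameter '%s'; valid names: %s",
                 parameter, paste(valid, collapse = ", ")), call. = FALSE)
  stopifnot(length(multipliers) >= 1, all(multipliers > 0))
  lapply(multipliers, function(m) {
    p <- default_parameters()
    p[[parameter]] <- m * p[[parameter]]
    pre <- make_preset(sprintf("sensitivity_%s_x%g", parameter, m), p, nx, ny, opts)
    pre$parameter <- parameter
    pre$multiplier <- m
    pre
  })
}

#' Final-state invariant suite
#'
#' Evaluates the qualitative equilibrium structure of a finished run:
#' oxygen profile nonincreasing and lactate profile nondecreasing with
#' distance from the vessel; cell-density plateau nonincreasing; local
#' mean traits tracking the fittest levels (`sup |mu2 - phi_o|` and
#' `sup |mu1 - phi_l|` over nodes with density above the floor); and the
#' local phenotypic distribution unimodal with its mode at the grid node
#' nearest the fittest state `(phi_l, phi_o)`.
#'
#' @param traj Trajectory from [run_simulation()].
#' @param rho_floor Density floor for defined trait moments.
#' @param mono_tol Relative tolerance for the monotonicity checks.
#' @return Named list of logical verdicts plus the measured sup errors.
#' @export
final_state_invariants <- function(traj, rho_floor = 1e-12, mono_tol = 1e-8) {
  st <- traj$final; params <- traj$params; grids <- traj$grids
  mom <- compute_moments(st, grids, rho_floor)
  phio <- fittest_hypoxia_level(st$S_o, params)
  phil <- fittest_acidity_level(st$S_l, params)
  def <- !is.na(mom$mu1)

  noninc <- function(v) all(diff(v) <= mono_tol * max(abs(v)))
  nondec <- function(v) all(diff(v) >= -mono_tol * max(abs(v)))

  sup2 <- if (any(def)) max(abs(mom$mu2[def] - phio[def])) else NA_real_
  sup1 <- if (any(def)) max(abs(mom$mu1[def] - phil[def])) else NA_real_

  mode_ok <- TRUE; unimodal_ok <- TRUE
  for (i in which(def)) {
    sl <- st$n[i, , ]
    am <- arrayInd(which.max(sl), dim(sl))
    j_fit <- which.min(abs(grids$y - phil[i]))
    k_fit <- which.min(abs(grids$y - phio[i]))
    if (am[1] != j_fit || am[2] != k_fit) mode_ok <- FALSE
    # no second interior local maximum away from the mode
    ny <- grids$ny
    locmax <- 0L
    for (j in seq_len(ny)) for (k in seq_len(ny)) {
      nb <- c(if (j > 1) sl[j - 1, k], if (j < ny) sl[j + 1, k],
              if (k > 1) sl[j, k - 1], if (k < ny) sl[j, k + 1])
      if (all(sl[j, k] >= nb) && any(sl[j, k] > nb)) locmax <- locmax + 1L
    }
    if (locmax > 1L) unimodal_ok <- FALSE
  }

  list(
    S_o_nonincreasing = noninc(st$S_o),
    S_l_nondecreasing = nondec(st$S_l),
    rho_nonincreasing = noninc(mom$rho),
    sup_mu2_err = sup2, sup_mu1_err = sup1,
    trait_tracking = is.finite(sup2) && is.finite(sup1) &&
      sup2 <= 0.05 && sup1 <= 0.05,
    mode_at_fittest = mode_ok,
    unimodal = unimodal_ok
  )
}

#' Run an experiment preset
#'
#' Executes a preset and gathers its standard outputs: the trajectory, the
#' final moments and crossing positions, the invariant-suite verdicts and
#' (for sweep presets) the 0.5-crossing times of the tissue-wide trait
#' means. When `outdir` is given, writes `moments.csv`, `trajectory.csv`
#' and a plain-text `manifest.txt` with the resolved configuration and
#' termination reason.
#'
#' @param preset From [preset_baseline()] and friends.
#' @param outdir Optional output directory (created if needed).
#' @param ic Optional initial condition passed to [run_simulation()] (e.g.
#'   externally measured substrate profiles).
#' @return List with `trajectory`, `moments`, `crossings`, `invariants`,
#'   `crossing_times`, `manifest`.
#' @export
run_preset <- function(preset, outdir = NULL, ic = NULL) {
  grids <- make_grids(preset$params, preset$nx, preset$ny)
  traj <- run_simulation(preset$params, grids, preset$opts, ic = ic)
  mom <- compute_moments(traj$final, grids)
  ox <- classify_regions(traj$final$S_o, grids$x, preset$params$O_m, preset$params$O_M)
  la <- classify_regions(traj$final$S_l, grids$x, preset$params$L_m, preset$params$L_M)
  crossings <- c(x_O_M = unname(ox["x_high"]), x_O_m = unname(ox["x_low"]),
                 x_L_m = unname(la["x_low"]), x_L_M = unname(la["x_high"]))
  inv <- final_state_invariants(traj)
  ct <- c(t_cross_nu1 = first_crossing_time(traj$summary$t, traj$summary$nu1),
          t_cross_nu2 = first_crossing_time(traj$summary$t, traj$summary$nu2))

  manifest <- c(
    sprintf("preset = %s", preset$name),
    sprintf("nx = %d", grids$nx), sprintf("ny = %d", grids$ny),
    serialise_config(preset$params),
    sprintf("dt = %.17g", traj$dt),
    sprintf("abiotic_mode = %s", traj$options$abiotic_mode),
    sprintf("equilibrium_tol = %.17g", traj$options$equilibrium_tol),
    sprintf("termination = %s", traj$termination),
    sprintf("final_time = %.17g", traj$final$t)
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(moments_table(mom, grids),
                     file.path(outdir, "moments.csv"), row.names = FALSE)
    utils::write.csv(traj$summary,
                     file.path(outdir, "trajectory.csv"), row.names = FALSE)
    # tissue-wide phenotypic distribution f(y1, y2) as a dense matrix
    # (rows: y1 nodes, columns: y2 nodes)
    utils::write.table(mom$f, file.path(outdir, "phenotype_distribution.csv"),
                       sep = ",", row.names = grids$y, col.names = grids$y)
    writeLines(manifest, file.path(outdir, "manifest.txt"))
  }
  list(trajectory = traj, moments = mom, crossings = crossings,
       invariants = inv, crossing_times = ct, manifest = manifest)
}

#' Run a sweep of presets
#'
#' Runs each preset independently (no shared mutable state) and returns a
#' tidy table with one row per preset: the identifying fields, the final
#' tissue-wide trait means and the 0.5-crossing times.
#'
#' @param presets List of presets (e.g. from [preset_eta_sweep()]).
#' @param outdir Optional directory; each run's outputs go to a
#'   subdirectory named after the preset, plus a combined `sweep.csv`.
#' @return A `data.frame`.
#' @export
run_sweep <- function(presets, outdir = NULL) {
  rows <- lapply(presets, function(pre) {
    sub <- if (is.null(outdir)) NULL else file.path(outdir, pre$name)
    res <- run_preset(pre, sub)
    s <- res$trajectory$summary
    data.frame(
      name = pre$name,
      ratio = if (is.null(pre$ratio)) NA_real_ else pre$ratio,
      t_cross_nu1 = unname(res$crossing_times["t_cross_nu1"]),
      t_cross_nu2 = unname(res$crossing_times["t_cross_nu2"]),
      nu1_final = s$nu1[nrow(s)], nu2_final = s$nu2[nrow(s)],
      termination = res$trajectory$termination
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(outdir, "sweep.csv"), row.names = FALSE)
  }
  out
}
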