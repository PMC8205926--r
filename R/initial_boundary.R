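#' Initial-condition specification
#'
#' The initial cell population is a separable Gaussian bump: cells are
#' concentrated against the vessel wall (spatial width^2 `x_width_sq`, in
#' cm^2, i.e. a ~100 um spread) with both resistance genes near their
#' minimal expression (trait width^2 `y_width_sq`).
#'
#' @param amplitude Peak density scale (cells per unit volume per unit
#'   trait area); default 200.
#' @param x_width_sq Gaussian denominator in x, cm^2; default 2e-4.
#' @param y_width_sq Gaussian denominator in trait space; default 0.4.
#' @return An object of class `"eet_ic_spec"`.
#' @export
ic_spec <- function(amplitude = 200, x_width_sq = 2e-4, y_width_sq = 0.4) {
  stopifnot(amplitude >= 0, x_width_sq > 0, y_width_sq > 0)
  structure(list(amplitude = amplitude, x_width_sq = x_width_sq,
                 y_width_sq = y_width_sq),
            class = "eet_ic_spec")
}

#' Initial cell density
#'
#' Evaluates
#' \deqn{n^0(x, y) = A \exp(-x^2/w_x - (y_1^2 + y_2^2)/w_y)}
#' nodewise on the grid (x in cm).
#'
#' @param grids Grids from [make_grids()].
#' @param spec From [ic_spec()].
#' @return Array `nx x ny x ny`.
#' @export
initial_cell_density <- function(grids, spec = ic_spec()) {
  gx <- exp(-grids$x^2 / spec$x_width_sq)
  gy <- exp(-grids$y^2 / spec$y_width_sq)
  spec$amplitude * outer(gx, outer(gy, gy))
}

# Sparse operator for a steady substrate equation
#   beta S'' - lambda S = rhs
# on the vertex-centred grid, Dirichlet at x = 0 and either Dirichlet or
# zero-flux (mirrored ghost) at x = L. Returns the assembled Matrix.
.steady_operator <- function(beta, lambda, grids, right_bc = c("dirichlet", "neumann")) {
  right_bc <- match.arg(right_bc)
  nx <- grids$nx
  h2 <- grids$dx^2
  main <- rep(-2 * beta / h2 - lambda, nx)
  lower <- rep(beta / h2, nx - 1)
  upper <- rep(beta / h2, nx - 1)
  # Dirichlet row at the vessel
  main[1] <- 1; upper[1] <- 0
  if (right_bc == "dirichlet") {
    main[nx] <- 1; lower[nx - 1] <- 0
  } else {
    lower[nx - 1] <- 2 * beta / h2   # ghost mirror: S_{nx+1} = S_{nx-1}
  }
  Matrix::bandSparse(nx, nx, k = c(-1, 0, 1),
                     diagonals = list(lower, main, upper))
}

.steady_solve <- function(A, rhs, bc0, bcL = NULL) {
  rhs[1] <- bc0
  if (!is.null(bcL)) rhs[length(rhs)] <- bcL
  out <- as.vector(Matrix::solve(A, rhs))
  out[1] <- bc0                       # pin Dirichlet rows exactly (no LU round-off)
  if (!is.null(bcL)) out[length(out)] <- bcL
  out
}

# Damped fixed-point iteration on the nonlinear consumption/production term
# around the linear tridiagonal solve. `src_fun(S)` returns the full RHS
# (interior rows); boundary rows are overwritten by the solve.
.relax_field <- function(A, src_fun, S0, bc0, bcL = NULL, tol = 1e-10,
                         max_iter = 200, damping = 1) {
  S <- S0
  for (it in seq_len(max_iter)) {
    S_new <- .steady_solve(A, src_fun(S), bc0, bcL)
    S_next <- (1 - damping) * S + damping * S_new
    rel <- max(abs(S_next - S)) / max(max(abs(S_next)), .Machine$double.xmin)
    S <- S_next
    if (rel < tol) return(S)
  }
  stop(sprintf("abiotic relaxation did not converge: relative update %.3e after %d iterations",
               rel, max_iter), call. = FALSE)
}

#' Relax the substrate fields to their steady profiles
#'
#' Computes the steady states of the oxygen and glucose reaction-diffusion
#' equations with the cell density frozen at `rho_ref`, under the vessel /
#' far-field Dirichlet conditions, by a damped fixed-point iteration on the
#' Michaelis-Menten consumption terms around a tridiagonal linear solve
#' (relative update < `tol`). Lactate starts uniform at its vessel-side
#' value `S_under_l`. These model-consistent profiles serve as initial
#' data; the long-run equilibrium does not depend on this choice.
#'
#' @param params Parameter set.
#' @param grids Grids.
#' @param rho_ref Non-negative cell-density vector over x used for the
#'   consumption terms (0 gives the cell-free closed-form profiles).
#' @param tol Relative-update convergence threshold.
#' @param max_iter Iteration cap (non-convergence is an error reporting the
#'   last residual).
#' @return List with fields `S_o`, `S_g`, `S_l`.
#' @export
relax_abiotic_profiles <- function(params, grids, rho_ref,
                                   tol = 1e-10, max_iter = 200) {
  stopifnot(length(rho_ref) == grids$nx, all(rho_ref >= 0))
  A_o <- .steady_operator(params$beta_o, params$lambda_o, grids, "dirichlet")
  S_o <- .relax_field(
    A_o,
    function(S) params$zeta_o * oxphos_rate(pmax(S, 0), params) * rho_ref,
    S0 = seq(params$S_bar_o, params$S_under_o, length.out = grids$nx),
    bc0 = params$S_bar_o, bcL = params$S_under_o,
    tol = tol, max_iter = max_iter)

  A_g <- .steady_operator(params$beta_g, params$lambda_g, grids, "dirichlet")
  S_g <- .relax_field(
    A_g,
    function(S) params$zeta_g * glycolysis_rate(S_o, pmax(S, 0), params) * rho_ref,
    S0 = seq(params$S_bar_g, params$S_under_g, length.out = grids$nx),
    bc0 = params$S_bar_g, bcL = params$S_under_g,
    tol = tol, max_iter = max_iter)

  list(S_o = pmax(S_o, 0), S_g = pmax(S_g, 0),
       S_l = rep(params$S_under_l, grids$nx))
}

#' Mirror ghost layers enforcing zero-flux cell boundaries
#'
#' Pads the cell-density array with one ghost layer on every face (two in
#' x, four edges in trait space), each mirroring the first interior
#' neighbour so the discrete normal flux of the symmetric diffusion
#' stencils vanishes on the boundary; combined with trapezoidal weights the
#' update telescopes and conserves mass exactly.
#'
#' @param n Array `nx x ny x ny`.
#' @return Array `(nx+2) x (ny+2) x (ny+2)`.
#' @export
apply_cell_bcs <- function(n) {
  d <- dim(n)
  out <- array(0, d + 2L)
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- n
  out[1, , ] <- out[3, , ];           out[d[1] + 2, , ] <- out[d[1], , ]
  out[, 1, ] <- out[, 3, ];           out[, d[2] + 2, ] <- out[, d[2], ]
  out[, , 1] <- out[, , 3];           out[, , d[3] + 2] <- out[, , d[3]]
  out
}

#' Apply substrate boundary conditions
#'
#' Pins the Dirichlet values — oxygen and glucose at both ends (vessel and
#' far field), lactate at the vessel — and leaves the far-field lactate
#' node free (its zero-flux condition is realised inside the diffusion and
#' steady solves via a mirrored ghost node).
#'
#' @param S_o,S_g,S_l Substrate fields over x.
#' @param params Parameter set.
#' @return List of updated fields.
#' @export
apply_abiotic_bcs <- function(S_o, S_g, S_l, params) {
  nx <- length(S_o)
  S_o[1] <- params$S_bar_o;  S_o[nx] <- params$S_under_o
  S_g[1] <- params$S_bar_g;  S_g[nx] <- params$S_under_g
  S_l[1] <- params$S_under_l
  list(S_o = S_o, S_g = S_g, S_l = S_l)
}
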