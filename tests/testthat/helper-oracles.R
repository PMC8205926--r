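# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed forms, base-R quadrature, and a
# plain-loop method-of-lines right-hand side for deSolve.

# Closed-form steady profile of beta*S'' = lambda*S with Dirichlet values
# at both ends.
analytic_dirichlet_profile <- function(beta, lambda, L, S0, SL, x) {
  m <- sqrt(lambda / beta)
  (SL * sinh(m * x) + S0 * sinh(m * (L - x))) / sinh(m * L)
}

# Closed form with Dirichlet at x = 0 and zero flux at x = L.
analytic_neumann_profile <- function(beta, lambda, L, S0, x) {
  m <- sqrt(lambda / beta)
  S0 * cosh(m * (L - x)) / cosh(m * L)
}

# Mean of one trait coordinate under the initial Gaussian profile,
# by adaptive 1-D quadrature.
initial_trait_mean_oracle <- function(width_sq = 0.4) {
  num <- stats::integrate(function(y) y * exp(-y^2 / width_sq), 0, 1,
                          rel.tol = 1e-12)$value
  den <- stats::integrate(function(y) exp(-y^2 / width_sq), 0, 1,
                          rel.tol = 1e-12)$value
  num / den
}

# Plain-loop right-hand side of the fully discretised coupled system
# (same stencils as the solver, written independently from the model
# equations), for use with deSolve as a high-accuracy reference.
mol_rhs_factory <- function(p, g) {
  nx <- g$nx; ny <- g$ny; dx <- g$dx; dy <- g$dy
  wy2 <- outer(g$wy, g$wy)
  function(t, state, parms) {
    n <- array(state[1:(nx * ny * ny)], c(nx, ny, ny))
    So <- state[nx * ny * ny + 1:nx]
    Sg <- state[nx * ny * ny + nx + 1:nx]
    Sl <- state[nx * ny * ny + 2 * nx + 1:nx]
    w <- pmin(pmax((So - p$O_m) / (p$O_M - p$O_m), 0), 1)
    phio <- 1 - w
    phil <- pmin(pmax((Sl - p$L_m) / (p$L_M - p$L_m), 0), 1)
    po <- p$gamma_o * So / (p$alpha_o + So) * w
    pg <- p$gamma_g * Sg / (p$alpha_g + Sg) * (1 - w)
    rho <- vapply(1:nx, function(i) sum(wy2 * n[i, , ]), 0)
    dn <- array(0, c(nx, ny, ny))
    for (i in 1:nx) for (j in 1:ny) for (k in 1:ny) {
      im <- if (i == 1) 2 else i - 1; ip <- if (i == nx) nx - 1 else i + 1
      jm <- if (j == 1) 2 else j - 1; jp <- if (j == ny) ny - 1 else j + 1
      km <- if (k == 1) 2 else k - 1; kp <- if (k == ny) ny - 1 else k + 1
      lapx <- (n[im, j, k] - 2 * n[i, j, k] + n[ip, j, k]) / dx^2
      lapy <- (n[i, jm, k] - 2 * n[i, j, k] + n[i, jp, k] +
                 n[i, j, km] - 2 * n[i, j, k] + n[i, j, kp]) / dy^2
      R <- po[i] + pg[i] - p$eta_o * (g$y[k] - phio[i])^2 -
        p$eta_l * (g$y[j] - phil[i])^2 - p$kappa * rho[i]
      dn[i, j, k] <- p$beta_n * lapx + p$theta * lapy + R * n[i, j, k]
    }
    dSo <- dSg <- dSl <- numeric(nx)
    for (i in 2:(nx - 1)) {
      dSo[i] <- p$beta_o * (So[i - 1] - 2 * So[i] + So[i + 1]) / dx^2 -
        p$lambda_o * So[i] - p$zeta_o * po[i] * rho[i]
      dSg[i] <- p$beta_g * (Sg[i - 1] - 2 * Sg[i] + Sg[i + 1]) / dx^2 -
        p$lambda_g * Sg[i] - p$zeta_g * pg[i] * rho[i]
      dSl[i] <- p$beta_l * (Sl[i - 1] - 2 * Sl[i] + Sl[i + 1]) / dx^2 -
        p$lambda_l * Sl[i] + p$zeta_l * pg[i] * rho[i]
    }
    dSl[nx] <- p$beta_l * (2 * Sl[nx - 1] - 2 * Sl[nx]) / dx^2 -
      p$lambda_l * Sl[nx] + p$zeta_l * pg[nx] * rho[nx]
    list(c(as.vector(dn), dSo, dSg, dSl))
  }
}
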