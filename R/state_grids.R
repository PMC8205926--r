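#' Vertex-centred computational grids
#'
#' Builds a uniform vertex-centred grid on the tissue strip
#' \[0, `L_domain`\] (including both endpoints; `x = 0` is the vessel wall)
#' and a tensor trait grid on \[0,1\]^2 with `ny` nodes per axis. Cell
#' density arrays are laid out as `n[i, j, k]` for
#' `(x[i], y1[j], y2[k])`.
#'
#' @param params Parameter set (only `L_domain` is used).
#' @param nx,ny Number of nodes in space and per trait axis (each >= 5).
#' @return An object of class `"eet_grids"` with fields `x`, `y`, `dx`,
#'   `dy`, `nx`, `ny`, `L`, and trapezoidal quadrature weights `wx`, `wy`.
#' @export
make_grids <- function(params, nx = 200, ny = 41) {
  stopifnot(nx >= 5, ny >= 5)
  L <- params$L_domain
  x <- seq(0, L, length.out = nx)
  y <- seq(0, 1, length.out = ny)
  dx <- L / (nx - 1)
  dy <- 1 / (ny - 1)
  g <- list(
    x = x, y = y, dx = dx, dy = dy, nx = as.integer(nx), ny = as.integer(ny),
    L = L,
    wx = dx * c(0.5, rep(1, nx - 2), 0.5),
    wy = dy * c(0.5, rep(1, ny - 2), 0.5)
  )
  class(g) <- "eet_grids"
  g
}

#' Assemble a system state
#'
#' Bundles the cell density array and the three substrate fields at one
#' instant, checking shapes, finiteness and non-negativity.
#'
#' @param t Time, s.
#' @param n Array `nx x ny x ny` of cell densities over (x, y1, y2).
#' @param S_o,S_g,S_l Substrate fields over the spatial nodes, g/cm^3.
#' @param grids Grids from [make_grids()].
#' @return An object of class `"eet_state"`.
#' @export
make_state <- function(t, n, S_o, S_g, S_l, grids) {
  if (!identical(dim(n), c(grids$nx, grids$ny, grids$ny)))
    stop("shape mismatch: n must be nx x ny x ny")
  for (nm in c("S_o", "S_g", "S_l")) {
    f <- get(nm)
    if (length(f) != grids$nx) stop(sprintf("shape mismatch: %s must have length nx", nm))
  }
  vals <- c(n, S_o, S_g, S_l)
  if (!all(is.finite(vals))) stop("state contains non-finite values")
  if (min(vals) < 0) stop("state contains negative values")
  structure(list(t = t, n = n, S_o = S_o, S_g = S_g, S_l = S_l),
            class = "eet_state")
}

# 2-D trapezoid weights over the trait square, as a flat vector aligned
# with the (j, k) layout of n[i, , ] after dim-dropping.
.wy2 <- function(grids) as.vector(outer(grids$wy, grids$wy))

# Flatten n (nx x ny x ny) to nx x ny^2 for vectorised quadrature.
.flatten_traits <- function(n, grids) {
  dim(n) <- c(grids$nx, grids$ny * grids$ny)
  n
}

#' Integral diagnostics: densities, trait moments and tissue summaries
#'
#' Computes, by trapezoidal quadrature:
#' * `rho(x)` — cell density, the integral of `n` over the trait square;
#' * `mu1(x)`, `mu2(x)` — local mean expression of the acidity- and
#'   hypoxia-resistance genes, `NA` where `rho <= rho_floor`;
#' * `f(y1, y2)` — the tissue-wide phenotypic distribution, the plain
#'   (unweighted) spatial average of `n`;
#' * `nu1`, `nu2` — tissue-wide mean trait levels, the spatial averages of
#'   `mu1`, `mu2`; nodes where the moments are undefined are excluded and
#'   the quadrature renormalised over the defined nodes.
#'
#' @param state State from [make_state()].
#' @param grids Grids from [make_grids()].
#' @param rho_floor Density below which trait means are marked undefined
#'   (guards the division by `rho`); default 1e-12 cells/cm^3.
#' @return An object of class `"eet_moments"` with fields `rho`, `mu1`,
#'   `mu2`, `f`, `nu1`, `nu2`.
#' @export
compute_moments <- function(state, grids, rho_floor = 1e-12) {
  nm <- .flatten_traits(state$n, grids)
  w2 <- .wy2(grids)
  y1_flat <- rep(grids$y, times = grids$ny)   # y1 varies along j (rows of n[i,,])
  y2_flat <- rep(grids$y, each = grids$ny)

  rho <- as.vector(nm %*% w2)
  m1 <- as.vector(nm %*% (w2 * y1_flat))
  m2 <- as.vector(nm %*% (w2 * y2_flat))
  defined <- rho > rho_floor
  mu1 <- ifelse(defined, m1 / rho, NA_real_)
  mu2 <- ifelse(defined, m2 / rho, NA_real_)

  f_flat <- as.vector(crossprod(nm, grids$wx)) / grids$L
  f <- matrix(f_flat, grids$ny, grids$ny)

  nu <- function(mu) {
    if (!any(defined)) return(NA_real_)
    sum(grids$wx[defined] * mu[defined]) / sum(grids$wx[defined])
  }
  structure(list(rho = rho, mu1 = mu1, mu2 = mu2, f = f,
                 nu1 = nu(mu1), nu2 = nu(mu2)),
            class = "eet_moments")
}

#' Total cell mass
#'
#' \eqn{\int_0^L \rho\, dx} by trapezoid, in cells per unit cross-section.
#' Used by the conservation checks of the pure-diffusion dynamics.
#'
#' @inheritParams compute_moments
#' @return Scalar.
#' @export
total_mass <- function(state, grids) {
  nm <- .flatten_traits(state$n, grids)
  rho <- as.vector(nm %*% .wy2(grids))
  sum(grids$wx * rho)
}

#' Locate habitat boundaries by threshold crossings
#'
#' Scans a spatial field from the vessel wall (`x = 0`) outward and returns
#' the position at which it first crosses each of two thresholds, located
#' by linear interpolation between the first bracketing node pair. For
#' oxygen with thresholds `(O_m, O_M)` this partitions the strip into
#' normoxic / moderately oxygenated / hypoxic habitats; for lactate with
#' `(L_m, L_M)`, into mildly / moderately / highly acidic ones. `NA` marks
#' an absent crossing.
#'
#' @param field Numeric vector over the spatial nodes.
#' @param x Spatial node coordinates.
#' @param low,high The two threshold values (`low < high`).
#' @return Named numeric vector `c(x_low = ..., x_high = ...)`.
#' @export
classify_regions <- function(field, x, low, high) {
  stopifnot(length(field) == length(x), all(is.finite(field)))
  cross <- function(thr) {
    d <- field - thr
    hit <- which(d[-length(d)] * d[-1] <= 0 & (d[-length(d)] != 0 | d[-1] != 0))
    exact <- which(d == 0)
    if (length(exact) > 0 && (length(hit) == 0 || exact[1] <= hit[1]))
      return(x[exact[1]])
    if (length(hit) == 0) return(NA_real_)
    i <- hit[1]
    x[i] + (x[i + 1] - x[i]) * d[i] / (d[i] - d[i + 1])
  }
  c(x_low = cross(low), x_high = cross(high))
}

#' Export moments as a tidy columnar table
#'
#' One row per spatial node with columns `x`, `rho`, `mu1`, `mu2`.
#'
#' @param moments From [compute_moments()].
#' @param grids Grids.
#' @return A `data.frame`.
#' @export
moments_table <- function(moments, grids) {
  data.frame(x = grids$x, rho = moments$rho,
             mu1 = moments$mu1, mu2 = moments$mu2)
}
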