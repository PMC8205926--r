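#' Phenotypic fitness landscape
#'
#' Pure, vectorisable functions implementing the fitness landscape
#' \deqn{R(S_o, S_g, S_l, \rho, y) = P(S_o, S_g, y_2) - D(S_l, y_1) - d(\rho),}
#' where the net proliferation rate combines oxidative phosphorylation and
#' glycolysis gated by the oxygen weight \eqn{w(S_o)}, selection penalties
#' are quadratic around the environment-dependent fittest traits
#' \eqn{\varphi_o(S_o)} (hypoxia resistance, trait \eqn{y_2}) and
#' \eqn{\varphi_l(S_l)} (acidity resistance, trait \eqn{y_1}), and crowding
#' death is linear in the local cell density \eqn{\rho}.
#'
#' All functions apply elementwise and recycle arguments like base
#' arithmetic, so whole-grid arrays can be passed directly.
#'
#' @param S_o,S_g,S_l Non-negative substrate concentrations, g/cm^3.
#' @param rho Non-negative local cell density, cells/cm^3.
#' @param y1,y2 Trait values in \[0, 1\]: expression of the
#'   acidity-resistance (`y1`) and hypoxia-resistance (`y2`) genes.
#' @param params Parameter set from [default_parameters()].
#' @return Rates in 1/s (dimensionless in \[0,1\] for `oxygen_weight`,
#'   `fittest_hypoxia_level`, `fittest_acidity_level`).
#' @name fitness_landscape
NULL

#' @describeIn fitness_landscape Oxygen weight \eqn{w(S_o)}: 1 in normoxia
#'   (`S_o >= O_M`), 0 in hypoxia (`S_o <= O_m`), linear in between.
#'   Gates the metabolic switch between oxidative phosphorylation and
#'   glycolysis.
#' @export
oxygen_weight <- function(S_o, params) {
  pmin(pmax((S_o - params$O_m) / (params$O_M - params$O_m), 0), 1)
}

#' @describeIn fitness_landscape Fittest hypoxia-resistance level
#'   \eqn{\varphi_o(S_o) = 1 - w(S_o)}: 0 in normoxia, 1 in hypoxia.
#' @export
fittest_hypoxia_level <- function(S_o, params) {
  1 - oxygen_weight(S_o, params)
}

#' @describeIn fitness_landscape Fittest acidity-resistance level
#'   \eqn{\varphi_l(S_l)}: 0 below `L_m`, 1 above `L_M`, linear in between.
#' @export
fittest_acidity_level <- function(S_l, params) {
  pmin(pmax((S_l - params$L_m) / (params$L_M - params$L_m), 0), 1)
}

#' @describeIn fitness_landscape Proliferation rate via oxidative
#'   phosphorylation, Michaelis-Menten in oxygen and gated by `w`:
#'   \eqn{p_o = \gamma_o S_o w(S_o) / (\alpha_o + S_o)}.
#' @export
oxphos_rate <- function(S_o, params) {
  params$gamma_o * S_o / (params$alpha_o + S_o) * oxygen_weight(S_o, params)
}

#' @describeIn fitness_landscape Proliferation rate via glycolysis,
#'   Michaelis-Menten in glucose and gated by `1 - w`:
#'   \eqn{p_g = \gamma_g S_g (1 - w(S_o)) / (\alpha_g + S_g)}.
#' @export
glycolysis_rate <- function(S_o, S_g, params) {
  params$gamma_g * S_g / (params$alpha_g + S_g) *
    (1 - oxygen_weight(S_o, params))
}

#' @describeIn fitness_landscape Net proliferation rate
#'   \eqn{P = p_o + p_g - \eta_o (y_2 - \varphi_o)^2}; maximised over
#'   \eqn{y_2 \in [0,1]} exactly at \eqn{y_2 = \varphi_o(S_o)}.
#' @export
net_proliferation <- function(S_o, S_g, y2, params) {
  oxphos_rate(S_o, params) + glycolysis_rate(S_o, S_g, params) -
    params$eta_o * (y2 - fittest_hypoxia_level(S_o, params))^2
}

#' @describeIn fitness_landscape Death rate from lactate-driven selection,
#'   \eqn{D = \eta_l (y_1 - \varphi_l)^2}; zero at the fittest acidity
#'   trait, at most `eta_l`.
#' @export
acid_death <- function(S_l, y1, params) {
  params$eta_l * (y1 - fittest_acidity_level(S_l, params))^2
}

#' @describeIn fitness_landscape Crowding death rate
#'   \eqn{d(\rho) = \kappa \rho}.
#' @export
crowding_death <- function(rho, params) {
  params$kappa * rho
}

#' @describeIn fitness_landscape The full landscape
#'   \eqn{R = P - D - d}; for positive selection gradients it is uniquely
#'   maximised over \eqn{[0,1]^2} at
#'   \eqn{(y_1, y_2) = (\varphi_l(S_l), \varphi_o(S_o))}.
#' @export
fitness <- function(S_o, S_g, S_l, rho, y1, y2, params) {
  net_proliferation(S_o, S_g, y2, params) -
    acid_death(S_l, y1, params) -
    crowding_death(rho, params)
}
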