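#' Phytoplankton limitation factors
#'
#' Computes the dimensionless growth-limitation factors for one
#' phytoplankton taxon at one instant: temperature
#' `f_T = min(1, q10^((T - t_ref)/10))`, light
#' `f_I = I/(I + k_light) * daylength/24`, and Monod nutrient factors for
#' DIN (`NO3 + NH4`), PO4 and (silicifiers only) silicate. The effective
#' nutrient factor is the Liebig minimum, and the realized growth rate is
#' `mu = mu_max * f_T * f_I * min(f_N, f_P[, f_Si])`.
#'
#' @param params a [phyto_params()] object.
#' @param env list with `temp` (deg C), `par` (PAR forcing units),
#'   `daylength` (h).
#' @param nutrients list with `no3`, `nh4`, `po4`, `si` (umol L-1).
#' @return list of factors `f_T`, `f_I`, `f_N`, `f_P`, `f_Si`, the Liebig
#'   minimum `f_nut`, and the realized growth rate `mu` (d-1).
#' @export
limitation_factors_phyto <- function(params, env, nutrients) {
  stopifnot(nutrients$no3 >= 0, nutrients$nh4 >= 0, nutrients$po4 >= 0)
  din <- nutrients$no3 + nutrients$nh4
  mono <- function(s, k) if (s > 0) s / (s + k) else 0
  f_T <- min(1, params$q10^((env$temp - params$t_ref) / 10))
  f_I <- mono(env$par, params$k_light) * env$daylength / 24
  f_N <- mono(din, params$k_din)
  f_P <- mono(nutrients$po4, params$k_po4)
  f_Si <- if (params$silicifier) mono(nutrients$si %||% 0, params$k_si) else 1
  f_nut <- if (params$silicifier) min(f_N, f_P, f_Si) else min(f_N, f_P)
  list(f_T = f_T, f_I = f_I, f_N = f_N, f_P = f_P, f_Si = f_Si,
       f_nut = f_nut, mu = params$mu_max * f_T * f_I * f_nut)
}

#' Phytoplankton process rates
#'
#' Carbon process rates for one phytoplankton taxon at biomass `B`:
#' photosynthesis `P = mu * B`, exudation `E = ke*B + fe*P`, respiration
#' `R = kr*B + fr*P`, and death `kd*B` split into a DOM share (`f_dom`,
#' distributed over `dom_alloc`) and a POM share.
#'
#' @param params a [phyto_params()] object.
#' @param B biomass (umol C L-1), `>= 0`.
#' @param factors output of [limitation_factors_phyto()] (only `mu` is used).
#' @return list of rates (umol C L-1 d-1): `photosynthesis`, `exudation`,
#'   `respiration`, `death_dom` (total over DOM species), `death_pom`.
#' @export
phyto_rates <- function(params, B, factors) {
  stopifnot(B >= 0)
  P <- factors$mu * B
  death <- (params$kd + (params$kd_quad %||% 0) * B) * B
  list(photosynthesis = P,
       exudation = params$ke * B + params$fe * P,
       respiration = params$kr * B + params$fr * P,
       death_dom = params$f_dom * death,
       death_pom = (1 - params$f_dom) * death)
}

#' Heterotrophic prokaryote process rates
#'
#' DOM uptake and derived rates for one heterotroph taxon. Uptake of DOM
#' species j is `v_max * f_T * B_active * w_j * D_j/(D_j + K_j)` with equal
#' weights over the usable species; growth is `yield` times total uptake and
#' the remainder is respired. Death follows the phytoplankton convention.
#'
#' @param params a [het_params()] object.
#' @param B_active active biomass (umol C L-1).
#' @param dom numeric vector of DOM species concentrations (umol C L-1).
#' @param temp temperature (deg C).
#' @return list with `uptake` (vector over DOM species), `uptake_total`,
#'   `growth`, `respiration`, `death_dom`, `death_pom`, `f_T`, and the
#'   saturation factor `f_S = sum(w_j * monod_j)`.
#' @export
het_rates <- function(params, B_active, dom, temp) {
  stopifnot(B_active >= 0, all(dom >= 0))
  f_T <- min(1, params$q10^((temp - params$t_ref) / 10))
  usable <- !is.na(params$affinity)
  w <- ifelse(usable, 1 / sum(usable), 0)
  mono <- ifelse(usable & dom > 0, dom / (dom + params$affinity), 0)
  uptake <- params$v_max * f_T * B_active * w * mono
  uptake[!usable] <- 0
  U <- sum(uptake)
  death <- (params$kd + (params$kd_quad %||% 0) * B_active) * B_active
  list(uptake = uptake, uptake_total = U, growth = params$yield * U,
       respiration = (1 - params$yield) * U,
       death_dom = params$f_dom * death,
       death_pom = (1 - params$f_dom) * death,
       f_T = f_T, f_S = sum(w * mono))
}

#' Net nutrient remineralization by heterotrophic consumption
#'
#' Nitrogen (or phosphorus) balance of DOM consumption: consumed DOM carries
#' nutrient at quota `q_dom`, biomass built at quota `q_bio`; the difference
#' `U * q_dom - G * q_bio` is released to (positive) or drawn from
#' (negative) the inorganic pool.
#'
#' @param U total uptake (umol C L-1 d-1), `U >= G`.
#' @param G growth (umol C L-1 d-1).
#' @param q_dom,q_bio nutrient:carbon quotas (mol:mol).
#' @return net inorganic nutrient flux (umol L-1 d-1; positive = release).
#' @export
remineralization <- function(U, G, q_dom, q_bio) {
  stopifnot(U >= G, G >= 0)
  U * q_dom - G * q_bio
}

#' POM dissolution flux
#'
#' Total dissolution is `k_dis * pom`, distributed over DOM species by the
#' allocation vector; producer attribution in the source ledger is carried
#' over unchanged by the simulator.
#'
#' @param pom POM carbon (umol C L-1).
#' @param k_dis dissolution rate (d-1).
#' @param dom_alloc allocation fractions over DOM species (normalized).
#' @return numeric vector of fluxes into each DOM species (umol C L-1 d-1).
#' @export
pom_dissolution <- function(pom, k_dis, dom_alloc) {
  stopifnot(pom >= 0, k_dis >= 0)
  alloc <- dom_alloc / sum(dom_alloc)
  k_dis * pom * alloc
}

#' Dormancy transfer (single Euler step)
#'
#' When net growth is negative, active biomass moves to the dormant pool at
#' rate `dorm_in`; when positive, dormant biomass reactivates at `dorm_out`.
#' The transfer itself conserves total biomass.
#'
#' @param active,dormant pool sizes (umol C L-1).
#' @param mu_net net specific growth rate (d-1).
#' @param params a [het_params()] object.
#' @param dt time step (days).
#' @return list with updated `active` and `dormant` pools.
#' @export
dormancy_update <- function(active, dormant, mu_net, params, dt) {
  stopifnot(active >= 0, dormant >= 0, dt > 0)
  tr <- 0
  if (mu_net < 0) tr <- min(params$dorm_in * active * dt, active)
  if (mu_net > 0) tr <- -min(params$dorm_out * dormant * dt, dormant)
  list(active = active - tr, dormant = dormant + tr)
}
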