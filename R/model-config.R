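#' Phytoplankton taxon parameters
#'
#' Physiological parameter set for one phytoplankton taxon. Growth follows a
#' maximum rate modulated by temperature (Q10), light (Monod in PAR times the
#' photoperiod fraction) and a Liebig minimum over Monod nutrient factors
#' (DIN, PO4 and, for silicifiers, silicate). DOM release has a basal
#' exudation rate `ke` plus a fraction `fe` of photosynthesis; respiration is
#' analogous (`kr`, `fr`). Death is a single lumped process at rate `kd`
#' whose flux is split between DOM (`f_dom`, e.g. viral lysis) and POM
#' (grazing, sinking aggregates).
#'
#' @param id taxon identifier (character scalar).
#' @param mu_max maximum specific growth rate (d-1).
#' @param k_light PAR half-saturation (same units as the PAR forcing).
#' @param k_din,k_po4,k_si Monod half-saturations (umol L-1); `k_si` is used
#'   only when `silicifier` is `TRUE`.
#' @param silicifier does this taxon require silicate (diatom-like)?
#' @param q10,t_ref temperature response: the rate factor is
#'   `min(1, q10^((T - t_ref)/10))`.
#' @param ke basal exudation rate (d-1); `fe` exuded fraction of
#'   photosynthesis (0-1).
#' @param fe,fr,f_dom dimensionless fractions in `[0, 1]`.
#' @param kr basal respiration rate (d-1); `fr` respired fraction of
#'   photosynthesis.
#' @param kd death rate (d-1); `f_dom` the fraction of the death flux routed
#'   directly to DOM (remainder to POM).
#' @param dom_alloc numeric vector of allocation fractions over DOM species
#'   for exudation and death-derived DOM (normalized to sum to 1); `NULL`
#'   means uniform.
#' @param synechococcus marks the taxon as a flow-cytometry-counted
#'   picocyanobacterium rather than an 18S-observed eukaryote.
#' @return an object of class `phyto_params`.
#' @export
phyto_params <- function(id, mu_max = 1.2, k_light = 20, k_din = 1,
                         k_po4 = 0.06, k_si = 1, silicifier = FALSE,
                         q10 = 2, t_ref = 12, ke = 0.02, fe = 0.08,
                         kr = 0.03, fr = 0.1, kd = 0.1, kd_quad = 0,
                         f_dom = 0.5, dom_alloc = NULL,
                         synechococcus = FALSE) {
  p <- list(id = as.character(id), mu_max = mu_max, k_light = k_light,
            k_din = k_din, k_po4 = k_po4, k_si = k_si,
            silicifier = isTRUE(silicifier), q10 = q10, t_ref = t_ref,
            ke = ke, fe = fe, kr = kr, fr = fr, kd = kd, kd_quad = kd_quad,
            f_dom = f_dom, dom_alloc = dom_alloc,
            synechococcus = isTRUE(synechococcus))
  class(p) <- "phyto_params"
  p
}

#' Heterotrophic prokaryote taxon parameters
#'
#' Parameter set for one heterotrophic prokaryote taxon. Growth is by DOM
#' uptake only (no exudation): uptake of DOM species j is
#' `v_max * fT * B_active * w_j * D_j/(D_j + K_j)` with equal weights `w_j`
#' over the usable species (those with a finite affinity). A fraction
#' `yield` of total uptake becomes biomass, the rest is respired. Death and
#' the DOM/POM split follow the phytoplankton convention. A dormant
#' sub-population (entered at rate `dorm_in` when net growth is negative,
#' left at `dorm_out` when positive) takes up nothing and dies at
#' `kd * dorm_death_mult`, preventing extinction and supporting coexistence.
#'
#' @param id taxon identifier.
#' @param v_max maximum specific uptake rate (d-1).
#' @param affinity numeric vector over DOM species of half-saturations
#'   (umol C L-1); `NA` marks a species the taxon cannot use.
#' @param yield growth efficiency in (0, 1].
#' @param q10,t_ref temperature response as for [phyto_params()].
#' @param kd linear death rate (d-1); `f_dom` death-DOM fraction.
#' @param kd_quad density-dependent death coefficient (L umol-C-1 d-1)
#'   applied to the active pool, as for [phyto_params()].
#' @param f_dom fraction of the death flux routed to DOM.
#' @param dom_alloc allocation of death-derived DOM over DOM species
#'   (`NULL` = uniform).
#' @param dorm_in,dorm_out dormancy transition rates (d-1).
#' @param dorm_death_mult death-rate multiplier for dormant cells.
#' @return an object of class `het_params`.
#' @export
het_params <- function(id, v_max = 4, affinity, yield = 0.3, q10 = 3,
                       t_ref = 17, kd = 0.25, kd_quad = 0, f_dom = 0.533,
                       dom_alloc = NULL, dorm_in = 0.3, dorm_out = 0.5,
                       dorm_death_mult = 0.02) {
  p <- list(id = as.character(id), v_max = v_max, affinity = affinity,
            yield = yield, q10 = q10, t_ref = t_ref, kd = kd,
            kd_quad = kd_quad, f_dom = f_dom, dom_alloc = dom_alloc,
            dorm_in = dorm_in, dorm_out = dorm_out,
            dorm_death_mult = dorm_death_mult)
  class(p) <- "het_params"
  p
}

#' Assemble a full ecosystem model configuration
#'
#' @param phyto list of [phyto_params()] objects.
#' @param het list of [het_params()] objects.
#' @param n_dom number of hypothetical DOM species.
#' @param dom_qn,dom_qp N:C and P:C quotas of each DOM species (mol:mol,
#'   recycled length `n_dom`); must not exceed the biomass quotas so that
#'   organic-organic transfers only release inorganic nutrients.
#' @param pom list with `k_dis` (dissolution rate, d-1), `k_sink` (sinking
#'   export rate, d-1; the only way carbon and nutrients leave the modeled
#'   volume besides respiration) and `dom_alloc` (allocation of dissolved
#'   POM over DOM species, `NULL` = uniform).
#' @param stoich biomass stoichiometry: `qn` (N:C), `qp` (P:C), `qsi`
#'   (Si:C, silicifiers only), mol:mol. Defaults are Redfield-type.
#' @param dt Euler time step (days).
#' @param output_every output cadence (days).
#' @return an object of class `flux_config`.
#' @export
model_config <- function(phyto, het, n_dom,
                         dom_qn = rep(0.8 * 16 / 106, n_dom),
                         dom_qp = rep(0.8 * 1 / 106, n_dom),
                         pom = list(k_dis = 0.08, k_sink = 0.05, dom_alloc = NULL),
                         stoich = list(qn = 16 / 106, qp = 1 / 106,
                                       qsi = 15 / 106),
                         dt = 0.05, output_every = 1) {
  cfg <- list(phyto = phyto, het = het, n_dom = as.integer(n_dom),
              dom_qn = rep_len(dom_qn, n_dom), dom_qp = rep_len(dom_qp, n_dom),
              pom = pom, stoich = stoich, dt = dt,
              output_every = output_every)
  class(cfg) <- "flux_config"
  validate_config(cfg)
  cfg
}

norm_alloc <- function(alloc, n, what) {
  if (is.null(alloc)) return(rep(1 / n, n))
  if (length(alloc) != n)
    stop(what, ": dom_alloc must have length ", n)
  if (any(alloc < 0) || sum(alloc) <= 0)
    stop(what, ": dom_alloc must be non-negative with positive sum")
  alloc / sum(alloc)
}

#' Validate a model configuration
#'
#' Checks the invariants of a [model_config()]: non-negative rates,
#' fractions in `[0, 1]`, DOM allocations that normalize to one, non-empty
#' affinity maps, and DOM nutrient quotas not exceeding biomass quotas.
#'
#' @param cfg a `flux_config`.
#' @return `cfg`, invisibly, after normalizing allocations.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "flux_config"), length(cfg$phyto) >= 1,
            cfg$n_dom >= 1, cfg$dt > 0)
  frac_ok <- function(x) is.numeric(x) && x >= 0 && x <= 1
  for (p in cfg$phyto) {
    rates <- c(p$mu_max, p$k_light, p$k_din, p$k_po4, p$k_si, p$ke, p$kr,
               p$kd, p$kd_quad %||% 0, p$q10)
    if (any(rates < 0)) stop("phyto ", p$id, ": negative rate or constant")
    if (!frac_ok(p$fe) || !frac_ok(p$fr) || !frac_ok(p$f_dom))
      stop("phyto ", p$id, ": fe, fr, f_dom must lie in [0, 1]")
  }
  for (h in cfg$het) {
    if (any(c(h$v_max, h$kd, h$kd_quad %||% 0, h$q10, h$dorm_in,
              h$dorm_out) < 0))
      stop("het ", h$id, ": negative rate")
    if (!frac_ok(h$f_dom)) stop("het ", h$id, ": f_dom must lie in [0, 1]")
    if (!(h$yield > 0 && h$yield <= 1))
      stop("het ", h$id, ": yield must lie in (0, 1]")
    aff <- h$affinity
    if (length(aff) != cfg$n_dom)
      stop("het ", h$id, ": affinity must have length n_dom")
    if (all(is.na(aff))) stop("het ", h$id, ": affinity map is empty")
    if (any(aff[!is.na(aff)] <= 0))
      stop("het ", h$id, ": affinities must be positive or NA")
  }
  if (any(cfg$dom_qn > cfg$stoich$qn + 1e-12) ||
      any(cfg$dom_qp > cfg$stoich$qp + 1e-12))
    stop("DOM nutrient quotas must not exceed biomass quotas")
  invisible(cfg)
}

#' Initial model state
#'
#' @param phyto_c,het_active_c,het_dormant_c named numeric vectors of carbon
#'   concentrations (umol C L-1) matching the taxa of the configuration.
#' @param dom_c DOM species carbon (umol C L-1, length `n_dom`).
#' @param pom_c POM carbon (umol C L-1, scalar).
#' @param no3,nh4,po4,si inorganic nutrients (umol L-1).
#' @return an object of class `model_state`.
#' @export
model_state <- function(phyto_c, het_active_c, het_dormant_c, dom_c,
                        pom_c = 0, no3 = 0, nh4 = 0, po4 = 0, si = 0) {
  st <- list(phyto_c = phyto_c, het_active_c = het_active_c,
             het_dormant_c = het_dormant_c, dom_c = dom_c, pom_c = pom_c,
             no3 = no3, nh4 = nh4, po4 = po4, si = si, exported_c = 0)
  if (any(unlist(st) < 0)) stop("model state entries must be >= 0")
  class(st) <- "model_state"
  st
}

phyto_ids <- function(cfg) vapply(cfg$phyto, `[[`, "", "id")
het_ids <- function(cfg) vapply(cfg$het, `[[`, "", "id")

# Flatten a config into the matrices the C++ core expects.
config_matrices <- function(cfg) {
  P <- length(cfg$phyto); H <- length(cfg$het); D <- cfg$n_dom
  pp <- t(vapply(cfg$phyto, function(p) c(
    p$mu_max, p$k_light, p$k_din, p$k_po4, p$k_si, as.numeric(p$silicifier),
    p$q10, p$t_ref, p$ke, p$fe, p$kr, p$fr, p$kd, p$f_dom, p$kd_quad),
    numeric(15)))
  pa <- t(vapply(cfg$phyto, function(p)
    norm_alloc(p$dom_alloc, D, p$id), numeric(D)))
  hp <- t(vapply(cfg$het, function(h) c(
    h$v_max, h$yield, h$q10, h$t_ref, h$kd, h$f_dom, h$dorm_in, h$dorm_out,
    h$dorm_death_mult, h$kd_quad), numeric(10)))
  hk <- t(vapply(cfg$het, function(h) {
    a <- h$affinity
    a[is.na(a)] <- -1
    a
  }, numeric(D)))
  ha <- t(vapply(cfg$het, function(h)
    norm_alloc(h$dom_alloc, D, h$id), numeric(D)))
  dim(pp) <- c(P, 15); dim(pa) <- c(P, D)
  dim(hp) <- c(H, 10); dim(hk) <- c(H, D); dim(ha) <- c(H, D)
  list(phyto_par = pp, phyto_alloc = pa, het_par = hp, het_K = hk,
       het_alloc = ha,
       pom_par = c(cfg$pom$k_dis, cfg$pom$k_sink %||% 0),
       pom_alloc = norm_alloc(cfg$pom$dom_alloc, D, "pom"),
       dom_qn = cfg$dom_qn, dom_qp = cfg$dom_qp,
       stoich = c(cfg$stoich$qn, cfg$stoich$qp, cfg$stoich$qsi))
}

state_vector <- function(state, cfg) {
  P <- length(cfg$phyto); H <- length(cfg$het); D <- cfg$n_dom
  stopifnot(length(state$phyto_c) == P, length(state$het_active_c) == H,
            length(state$dom_c) == D)
  c(state$phyto_c, state$het_active_c, state$het_dormant_c, state$dom_c,
    state$pom_c, state$no3, state$nh4, state$po4, state$si,
    state$exported_c %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Get or set a single parameter in a configuration
#'
#' Parameters are addressed by a path `"<kind>/<taxon id>/<name>"`, e.g.
#' `"phyto/diatom1/mu_max"` or `"het/SAR11x/v_max"`; `"pom//k_dis"`
#' addresses the global POM dissolution rate.
#'
#' @param cfg a `flux_config`.
#' @param path parameter path string.
#' @param value replacement value (for `config_set`).
#' @return `config_get` the numeric value; `config_set` the updated config.
#' @export
config_get <- function(cfg, path) {
  p <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (p[1] == "pom") return(cfg$pom[[p[3]]])
  grp <- cfg[[p[1]]]
  ids <- vapply(grp, `[[`, "", "id")
  grp[[match(p[2], ids)]][[p[3]]]
}

#' @rdname config_get
#' @export
config_set <- function(cfg, path, value) {
  p <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (p[1] == "pom") {
    cfg$pom[[p[3]]] <- value
    return(cfg)
  }
  grp <- cfg[[p[1]]]
  ids <- vapply(grp, `[[`, "", "id")
  i <- match(p[2], ids)
  if (is.na(i)) stop("unknown taxon in parameter path: ", path)
  cfg[[p[1]]][[i]][[p[3]]] <- value
  cfg
}
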