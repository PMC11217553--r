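# Shared fixtures: tiny configurations and a memoized default ground truth.

tiny_config <- function(mu_max = 0.8, ke = 0.02, fe = 0.1, kr = 0.02,
                        fr = 0.1, kd = 0.05, v_max = 2, yield = 0.3,
                        het_kd = 0.1, k_sink = 0, dt = 0.05, n_dom = 2,
                        phyto_f_dom = 0.5, het_f_dom = 0.5) {
  model_config(
    phyto = list(phyto_params("p1", mu_max = mu_max, k_light = 10,
                              k_din = 0.5, k_po4 = 0.02, ke = ke, fe = fe,
                              kr = kr, fr = fr, kd = kd,
                              f_dom = phyto_f_dom)),
    het = list(het_params("h1", v_max = v_max, yield = yield,
                          affinity = c(1, rep(NA, n_dom - 1)),
                          kd = het_kd, f_dom = het_f_dom, q10 = 2,
                          t_ref = 15)),
    n_dom = n_dom,
    pom = list(k_dis = 0.05, k_sink = k_sink, dom_alloc = NULL),
    dt = dt)
}

tiny_state <- function(cfg, phyto = 1, het = 0.5, dormant = 0, dom = 2,
                       pom = 1, no3 = 10, nh4 = 2, po4 = 1, si = 5) {
  model_state(phyto_c = stats::setNames(rep(phyto, length(cfg$phyto)),
                                        vapply(cfg$phyto, `[[`, "", "id")),
              het_active_c = stats::setNames(rep(het, length(cfg$het)),
                                             vapply(cfg$het, `[[`, "", "id")),
              het_dormant_c = stats::setNames(rep(dormant, length(cfg$het)),
                                              vapply(cfg$het, `[[`, "", "id")),
              dom_c = rep(dom, cfg$n_dom), pom_c = pom, no3 = no3,
              nh4 = nh4, po4 = po4, si = si)
}

const_forcing <- function(t1, temp = 15, par = 1e6, daylength = 24, ...) {
  data.frame(time = c(0, t1), temp = temp, par = par,
             daylength = daylength, ...)
}

# Default-scenario ground truth, computed once per test session.
.truth_cache <- new.env(parent = emptyenv())
default_truth <- function() {
  if (is.null(.truth_cache$truth))
    .truth_cache$truth <- suppressWarnings(
      generate_ground_truth(synthetic_scenario(seed = 1)))
  .truth_cache$truth
}
default_pairwise <- function() {
  if (is.null(.truth_cache$pw))
    .truth_cache$pw <- pairwise_fluxes(default_truth()$trajectory)
  .truth_cache$pw
}

# Restrict carbon observations to one calendar year.
cobs_year <- function(cobs, year) {
  keep <- as.integer(format(as.Date(cobs$dates), "%Y")) == year
  out <- cobs
  out$dates <- cobs$dates[keep]
  for (nm in c("total_phyto_c", "euk_phyto_c", "syn_c", "total_het_c",
               "temperature", "par", "daylength"))
    out[[nm]] <- cobs[[nm]][keep]
  out$phyto_otu_c <- cobs$phyto_otu_c[, keep, drop = FALSE]
  out$het_asv_c <- cobs$het_asv_c[, keep, drop = FALSE]
  out$nutrients <- lapply(cobs$nutrients, `[`, keep)
  out
}

exp_growth_error <- function(dt) {
  # nutrient-replete, saturating light, constant forcing: net rate is
  # r = mu*(1 - fe - fr) - (ke + kr + kd)
  cfg <- tiny_config(mu_max = 0.35, ke = 0.01, fe = 0.05, kr = 0.01,
                     fr = 0.05, kd = 0.02, dt = dt)
  st <- tiny_state(cfg, phyto = 0.1, het = 0, dom = 0, pom = 0,
                   no3 = 5e4, nh4 = 5e4, po4 = 1e4)
  tr <- simulate_ecosystem(cfg, st, const_forcing(20, temp = 15, par = 1e9,
                                                  daylength = 24),
                           t0 = 0, t1 = 20, dt = dt)
  mu <- 0.35 # f_T = f_I = f_nut ~ 1
  r <- mu * (1 - 0.05 - 0.05) - (0.01 + 0.01 + 0.02)
  expected <- 0.1 * exp(r * tr$time)
  max(abs(tr$phyto_c[, 1] - expected) / expected)
}
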