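#' Simulate the ecosystem model
#'
#' Integrates the mass-balance plankton ecosystem with a fixed-step explicit
#' Euler scheme. Outflows from every pool are capped per step by
#' proportional scaling so no pool can go negative, which makes the flux
#' bookkeeping exactly conservative: per step,
#' `delta(total organic C + exported C) = photosynthesis * dt` to round-off.
#' A source ledger tracks, for every DOM species and for the POM pool, how
#' much of the standing mass each producing taxon contributed; consumption
#' removes ledger mass proportionally to the current source fractions, so
#' the producer attribution of every uptake flux is known at all times.
#'
#' @param config a [model_config()].
#' @param state a [model_state()] at `t0`.
#' @param forcing data frame with columns `time` (days), `temp`, `par`,
#'   `daylength`, and optional loading-rate columns `load_no3`, `load_nh4`,
#'   `load_po4`, `load_si` (umol L-1 d-1, piecewise constant). Temperature,
#'   PAR and daylength are interpolated linearly between rows.
#' @param t0,t1 start and end time (days); `t1 > t0`.
#' @param dt Euler step (days); defaults to the configuration's.
#' @param output_every output cadence (days); defaults to the
#'   configuration's.
#' @param origin calendar date corresponding to `time = 0` (used by the
#'   bloom and reporting functions); default `"2015-01-01"`.
#' @param ledger optional initial source ledger (list with `dom_src`
#'   `n_dom x (P+H+1)` matrix and `pom_src` vector); by default all initial
#'   DOM/POM mass is attributed to a `"background"` producer.
#' @return an object of class `flux_trajectory`: daily (by default) state
#'   matrices, per-process flux matrices (umol C L-1 d-1), the per-consumer
#'   per-DOM-species uptake array, ledger source fractions, recorded
#'   limitation factors, and conservation diagnostics in `$balance`.
#' @export
simulate_ecosystem <- function(config, state, forcing, t0 = 0, t1,
                               dt = config$dt,
                               output_every = config$output_every,
                               origin = as.Date("2015-01-01"),
                               ledger = NULL) {
  validate_config(config)
  stopifnot(t1 > t0, dt > 0)
  need <- c("time", "temp", "par", "daylength")
  if (!all(need %in% names(forcing)))
    stop("forcing must contain columns: ", paste(need, collapse = ", "))
  if (min(forcing$time) > t0 || max(forcing$time) < t1)
    stop("forcing does not cover the simulation interval [",
         t0, ", ", t1, "]")
  for (cc in c("load_no3", "load_nh4", "load_po4", "load_si"))
    if (is.null(forcing[[cc]])) forcing[[cc]] <- 0
  fm <- as.matrix(forcing[order(forcing$time),
                          c("time", "temp", "par", "daylength", "load_no3",
                            "load_nh4", "load_po4", "load_si")])
  if (anyNA(fm)) stop("forcing contains missing values")

  mats <- config_matrices(config)
  P <- length(config$phyto); H <- length(config$het); D <- config$n_dom
  nprod <- P + H + 1
  if (is.null(ledger)) {
    dom_src <- matrix(0, D, nprod)
    dom_src[, nprod] <- state$dom_c
    pom_src <- c(rep(0, P + H), state$pom_c)
  } else {
    dom_src <- ledger$dom_src
    pom_src <- ledger$pom_src
  }

  out_steps <- max(1L, as.integer(round(output_every / dt)))
  res <- sim_core(state_vector(state, config),
                  mats$phyto_par, mats$phyto_alloc, mats$het_par,
                  mats$het_K, mats$het_alloc, mats$pom_par, mats$pom_alloc,
                  mats$dom_qn, mats$dom_qp, mats$stoich,
                  dom_src, pom_src, fm, t0, t1, dt, out_steps)

  pid <- phyto_ids(config); hid <- het_ids(config)
  prod_ids <- c(pid, hid, "background")
  colnames(res$phyto_c) <- pid
  colnames(res$het_active_c) <- colnames(res$het_dormant_c) <- hid
  colnames(res$dom_c) <- paste0("dom", seq_len(D))
  for (nm in c("photosynthesis", "exudation", "respiration_phyto",
               "death_dom_phyto", "death_pom_phyto"))
    colnames(res[[nm]]) <- pid
  for (nm in c("uptake_total", "growth_het", "respiration_het",
               "death_dom_het", "death_pom_het"))
    colnames(res[[nm]]) <- hid
  dimnames(res$uptake) <- list(NULL, hid, paste0("dom", seq_len(D)))
  dimnames(res$dom_src_frac) <- list(NULL, paste0("dom", seq_len(D)),
                                     prod_ids)
  colnames(res$pom_src_frac) <- prod_ids
  dimnames(res$lim_phyto) <- list(NULL, pid,
                                  c("f_T", "f_I", "f_N", "f_P", "f_Si"))
  dimnames(res$lim_het) <- list(NULL, hid, c("f_T", "f_S"))
  colnames(res$forcing) <- c("temp", "par", "daylength", "spare")

  res$config <- config
  res$origin <- as.Date(origin)
  res$producer_ids <- prod_ids
  res$producer_class <- c(rep("phytoplankton", P), rep("heterotroph", H),
                          "background")
  class(res) <- "flux_trajectory"
  res
}

#' @export
print.flux_trajectory <- function(x, ...) {
  cat("<flux_trajectory>\n")
  cat("  taxa:", ncol(x$phyto_c), "phytoplankton,",
      ncol(x$het_active_c), "heterotrophs,", ncol(x$dom_c),
      "DOM species\n")
  cat(sprintf("  time: %.1f to %.1f d (%d outputs), origin %s\n",
              min(x$time), max(x$time), length(x$time),
              format(x$origin)))
  b <- x$balance
  cat(sprintf(
    "  max relative imbalance: C %.2e, N %.2e, P %.2e, ledger %.2e\n",
    b["carbon"], b["nitrogen"], b["phosphorus"], b["ledger"]))
  invisible(x)
}

#' Trajectory state as a tidy data frame
#'
#' @param x a `flux_trajectory`.
#' @param ... unused.
#' @return data frame with columns `time`, `date`, `compartment_id`,
#'   `value` (umol C or nutrient L-1).
#' @export
as.data.frame.flux_trajectory <- function(x, ...) {
  wide <- cbind(x$phyto_c, x$het_active_c + x$het_dormant_c, x$dom_c,
                pom = x$pom_c, no3 = x$no3, nh4 = x$nh4, po4 = x$po4,
                si = x$si)
  data.frame(time = rep(x$time, ncol(wide)),
             date = rep(x$origin + x$time, ncol(wide)),
             compartment_id = rep(colnames(wide), each = nrow(wide)),
             value = as.vector(wide), row.names = NULL)
}

#' Single Euler step of the ecosystem model
#'
#' Convenience wrapper advancing the model by one `dt` and returning the
#' updated state plus the flux rates applied during the step. Used for
#' step-level testing; [simulate_ecosystem()] is the production entry point.
#'
#' @inheritParams simulate_ecosystem
#' @param forcing_at list with `temp`, `par`, `daylength` and optional
#'   `load_*` rates, treated as constant over the step.
#' @param dt step length (days).
#' @return list with `state` (a [model_state()]), `ledger`, and `fluxes`
#'   (the rates recorded at the start of the step).
#' @export
step_ecosystem <- function(config, state, forcing_at, dt = config$dt,
                           ledger = NULL) {
  fdf <- data.frame(time = c(0, dt), temp = forcing_at$temp,
                    par = forcing_at$par, daylength = forcing_at$daylength,
                    load_no3 = forcing_at$load_no3 %||% 0,
                    load_nh4 = forcing_at$load_nh4 %||% 0,
                    load_po4 = forcing_at$load_po4 %||% 0,
                    load_si = forcing_at$load_si %||% 0)
  tr <- simulate_ecosystem(config, state, fdf, t0 = 0, t1 = dt, dt = dt,
                           output_every = dt, ledger = ledger)
  P <- length(config$phyto); H <- length(config$het); D <- config$n_dom
  fs <- tr$final_state
  i <- 0
  take <- function(n) {
    v <- fs[i + seq_len(n)]
    i <<- i + n
    v
  }
  phy <- take(P); ha <- take(H); hd <- take(H); dm <- take(D)
  rest <- take(6)
  st <- model_state(stats::setNames(phy, phyto_ids(config)),
                    stats::setNames(ha, het_ids(config)),
                    stats::setNames(hd, het_ids(config)), dm,
                    pom_c = rest[1], no3 = rest[2], nh4 = rest[3],
                    po4 = rest[4], si = rest[5])
  st$exported_c <- rest[6]
  list(state = st,
       ledger = list(dom_src = tr$final_dom_src,
                     pom_src = tr$final_pom_src),
       fluxes = list(photosynthesis = tr$photosynthesis[1, ],
                     exudation = tr$exudation[1, ],
                     respiration_phyto = tr$respiration_phyto[1, ],
                     death_dom_phyto = tr$death_dom_phyto[1, ],
                     death_pom_phyto = tr$death_pom_phyto[1, ],
                     uptake = tr$uptake[1, , , drop = TRUE],
                     growth_het = tr$growth_het[1, ],
                     respiration_het = tr$respiration_het[1, ],
                     death_dom_het = tr$death_dom_het[1, ],
                     death_pom_het = tr$death_pom_het[1, ],
                     dissolution = tr$dissolution[1]),
       balance = tr$balance)
}
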