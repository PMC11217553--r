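#' Model-data objective score
#'
#' Sum over observation series of weighted squared log10 residuals:
#' `score = sum_series w * sum_dates (log10(model + eps) -
#' log10(obs + eps))^2` with `eps = 1e-4` umol C L-1. Missing observations
#' are skipped. Log residuals weight relative errors, which is appropriate
#' for concentrations spanning orders of magnitude; the small epsilon keeps
#' zero concentrations finite. By default each compositional series has
#' weight 1 and each total-pool series (total phytoplankton, total
#' heterotroph carbon) gets weight equal to its member-taxon count, so
#' totals and composition carry comparable weight.
#'
#' @param traj a `flux_trajectory` covering the observation dates.
#' @param cobs a `carbon_observations`.
#' @param weights optional named numeric vector of per-series weights
#'   (names: taxon ids, `"synechococcus"`, `"total_phyto"`, `"total_het"`).
#' @param eps log offset (umol C L-1).
#' @return non-negative scalar score.
#' @export
objective_score <- function(traj, cobs, weights = NULL, eps = 1e-4) {
  series <- model_series_at(traj, cobs$dates)
  if (nrow(series$phyto) == 0) stop("trajectory and observations share no dates")
  syn_flag <- vapply(traj$config$phyto, `[[`, TRUE, "synechococcus")
  pid <- phyto_ids(traj$config); hid <- het_ids(traj$config)
  default_w <- c(stats::setNames(rep(1, length(pid)), pid),
                 stats::setNames(rep(1, length(hid)), hid),
                 total_phyto = length(pid), total_het = length(hid))
  w <- default_w
  if (!is.null(weights)) w[names(weights)] <- weights

  sq <- function(model, obs) {
    keep <- !is.na(obs)
    sum((log10(model[keep] + eps) - log10(obs[keep] + eps))^2)
  }
  score <- 0
  for (id in rownames(cobs$phyto_otu_c)) {
    if (!id %in% pid) next
    score <- score + w[id] * sq(series$phyto[, id], cobs$phyto_otu_c[id, ])
  }
  if (any(syn_flag) && !is.null(cobs$syn_c)) {
    syn_model <- rowSums(series$phyto[, syn_flag, drop = FALSE])
    score <- score + w[pid[syn_flag][1]] * sq(syn_model, cobs$syn_c)
  }
  for (id in rownames(cobs$het_asv_c)) {
    if (!id %in% hid) next
    score <- score + w[id] * sq(series$het[, id], cobs$het_asv_c[id, ])
  }
  score <- score +
    w["total_phyto"] * sq(rowSums(series$phyto), cobs$total_phyto_c) +
    w["total_het"] * sq(rowSums(series$het), cobs$total_het_c)
  unname(score)
}

# Model series sampled at observation dates (nearest output <= 0.5 d).
model_series_at <- function(traj, dates) {
  t_obs <- as.numeric(as.Date(dates) - traj$origin)
  idx <- match(TRUE, FALSE) # placeholder
  idx <- vapply(t_obs, function(t) {
    k <- which.min(abs(traj$time - t))
    if (abs(traj$time[k] - t) > 0.51) NA_integer_ else k
  }, 1L)
  keep <- !is.na(idx)
  list(phyto = traj$phyto_c[idx[keep], , drop = FALSE],
       het = traj$het_active_c[idx[keep], , drop = FALSE] +
         traj$het_dormant_c[idx[keep], , drop = FALSE],
       dates = dates[keep])
}

#' Propose a random parameter perturbation
#'
#' Picks 1-3 of the free parameters at random and multiplies each by
#' lognormal noise `exp(N(0, sigma))`, clipping to the bounds. With
#' `sigma = 0` the configuration is returned unchanged. Deterministic
#' given the R random seed.
#'
#' @param cfg a `flux_config`.
#' @param free character vector of parameter paths (see [config_get()]).
#' @param bounds named list of `c(lower, upper)` per parameter name (the
#'   last path component), as from [default_parameter_bounds()].
#' @param sigma lognormal sigma of the multiplicative move.
#' @param max_moves upper bound on the number of parameters moved at once.
#' @return the perturbed configuration.
#' @export
propose_perturbation <- function(cfg, free, bounds, sigma = 0.25,
                                 max_moves = 3) {
  k <- sample.int(min(max_moves, length(free)), 1)
  picks <- sample(free, k)
  for (path in picks) {
    nm <- utils::tail(strsplit(path, "/", fixed = TRUE)[[1]], 1)
    val <- config_get(cfg, path) * exp(rnorm(1, 0, sigma))
    b <- bounds[[nm]]
    if (!is.null(b)) val <- min(max(val, b[1]), b[2])
    cfg <- config_set(cfg, path, val)
  }
  cfg
}

#' Literature-scale parameter bounds
#'
#' Reads the shipped YAML of realistic per-parameter ranges (by parameter
#' class, units as in [phyto_params()] / [het_params()]).
#'
#' @param path YAML file; defaults to the file shipped with the package.
#' @return named list of `c(lower, upper)`.
#' @export
default_parameter_bounds <- function(path = system.file(
  "extdata", "parameter_bounds.yaml", package = "carbonflux")) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(b) c(b$lower, b$upper))
}

#' Calibrate the model to one year of carbon observations
#'
#' Greedy stochastic hill climb: simulate, score with [objective_score()],
#' propose a bounded multiplicative perturbation of a random subset of the
#' free parameters, and accept iff the score decreases. Reproducible given
#' `seed`. A simulated-annealing acceptance (`temperature > 0` with
#' geometric cooling) is available but off by default.
#'
#' @param cfg starting configuration (within bounds).
#' @param cobs a `carbon_observations` restricted to the year.
#' @param forcing forcing data frame covering the year.
#' @param free parameter paths to optimize.
#' @param bounds bounds list, see [default_parameter_bounds()].
#' @param iterations number of proposals (`>= 0`).
#' @param seed RNG seed.
#' @param sigma proposal sigma.
#' @param year calendar year (defaults to the first observation's year).
#' @param init_state initial [model_state()]; by default built from the
#'   observations at the year's first sample via [state_from_observations()].
#' @param origin date of forcing time 0.
#' @param temperature initial annealing temperature (0 = greedy).
#' @param dt integration step override.
#' @return a `fit_result`: `best_config`, `objective_value`,
#'   `acceptance_trace` (iteration, objective; non-increasing), `year`,
#'   `rng_seed`, `n_failed` (proposals whose simulation failed).
#' @export
calibrate_year <- function(cfg, cobs, forcing, free,
                           bounds = default_parameter_bounds(),
                           iterations = 500, seed = 1, sigma = 0.25,
                           year = NULL, init_state = NULL,
                           origin = NULL, temperature = 0, dt = NULL) {
  stopifnot(iterations >= 0)
  dates <- as.Date(cobs$dates)
  year <- year %||% as.integer(format(min(dates), "%Y"))
  origin <- origin %||% as.Date(paste0(year, "-01-01"))
  init_state <- init_state %||% state_from_observations(cfg, cobs)
  if (!is.null(dt)) cfg$dt <- dt

  run <- function(config) {
    traj <- simulate_ecosystem(config, init_state, forcing, t0 = 0,
                               t1 = max(forcing$time), origin = origin)
    objective_score(traj, cobs)
  }
  set.seed(seed)
  best <- cfg
  best_score <- run(cfg)
  trace <- data.frame(iteration = 0L, objective = best_score)
  n_failed <- 0L
  temp <- temperature
  for (it in seq_len(iterations)) {
    prop <- propose_perturbation(best, free, bounds, sigma = sigma)
    sc <- tryCatch(run(prop), error = function(e) {
      n_failed <<- n_failed + 1L
      NA_real_
    })
    accept <- !is.na(sc) &&
      (sc < best_score ||
         (temp > 0 && runif(1) < exp(-(sc - best_score) / temp)))
    if (accept && sc < best_score) {
      best <- prop
      best_score <- sc
      trace <- rbind(trace, data.frame(iteration = it, objective = sc))
    } else if (accept) {
      best <- prop # annealing walk; trace records best-so-far only
    }
    temp <- temp * 0.999
  }
  structure(list(best_config = best, objective_value = best_score,
                 acceptance_trace = trace, year = year, rng_seed = seed,
                 n_failed = n_failed),
            class = "fit_result")
}

#' Initial model state from observations
#'
#' Builds the year-start state from the observed carbon at the first
#' sample: phytoplankton taxa at their observed OTU carbon, heterotrophs at
#' observed ASV carbon split 80/20 between active and dormant pools,
#' nutrients at observed concentrations, and configurable seed values for
#' the unobserved DOM and POM pools.
#'
#' @param cfg a `flux_config`.
#' @param cobs a `carbon_observations`.
#' @param dom_c0,pom_c0 initial DOM (per species) and POM carbon.
#' @param active_frac active fraction of observed heterotroph carbon.
#' @return a [model_state()].
#' @export
state_from_observations <- function(cfg, cobs, dom_c0 = 0.5, pom_c0 = 1,
                                    active_frac = 0.8) {
  first_of <- function(x) {
    i <- which(!is.na(x))[1]
    if (is.na(i)) 0 else x[i]
  }
  pid <- phyto_ids(cfg); hid <- het_ids(cfg)
  syn_flag <- vapply(cfg$phyto, `[[`, TRUE, "synechococcus")
  phy <- stats::setNames(numeric(length(pid)), pid)
  for (id in pid) {
    phy[id] <- if (syn_flag[match(id, pid)]) first_of(cobs$syn_c)
    else if (id %in% rownames(cobs$phyto_otu_c))
      first_of(cobs$phyto_otu_c[id, ]) else 0.05
  }
  het <- stats::setNames(numeric(length(hid)), hid)
  for (id in hid)
    het[id] <- if (id %in% rownames(cobs$het_asv_c))
      first_of(cobs$het_asv_c[id, ]) else 0.05
  model_state(phyto_c = pmax(phy, 1e-3),
              het_active_c = pmax(active_frac * het, 1e-3),
              het_dormant_c = pmax((1 - active_frac) * het, 1e-3),
              dom_c = rep_len(dom_c0, cfg$n_dom), pom_c = pom_c0,
              no3 = first_of(cobs$nutrients$no3no2),
              nh4 = first_of(cobs$nutrients$nh4),
              po4 = first_of(cobs$nutrients$po4),
              si = first_of(cobs$nutrients$si))
}

#' Replace lumped taxa with their member taxa
#'
#' Gradual delumping: each lumped taxon listed in `members` is replaced by
#' its member taxa, which inherit the parent's parameters with optional
#' multiplicative lognormal jitter; the parent's initial carbon is split by
#' the members' observed fractions at the first date (equal split with a
#' warning when unavailable), so the children's initial carbon sums to the
#' parent's.
#'
#' @param cfg a `flux_config`.
#' @param state a [model_state()] matching `cfg`.
#' @param members named list: parent taxon id -> character vector of member
#'   ids. Parents may be phytoplankton or heterotroph taxa.
#' @param member_obs optional matrix (rows = member ids, columns = dates)
#'   of observed member series used for the split.
#' @param jitter_sigma lognormal sigma of the parameter jitter (0 = exact
#'   inheritance).
#' @param seed RNG seed for the jitter.
#' @return list with the expanded `config` and `state`.
#' @export
delump_taxa <- function(cfg, state, members, member_obs = NULL,
                        jitter_sigma = 0.1, seed = 1) {
  set.seed(seed)
  jitter_params <- function(p, id) {
    q <- p
    q$id <- id
    if (jitter_sigma > 0)
      for (nm in c("mu_max", "ke", "fe", "kd", "v_max", "yield"))
        if (!is.null(q[[nm]]))
          q[[nm]] <- q[[nm]] * exp(rnorm(1, 0, jitter_sigma))
    if (!is.null(q$fe)) q$fe <- min(q$fe, 1)
    if (!is.null(q$yield)) q$yield <- min(q$yield, 1)
    q
  }
  for (parent in names(members)) {
    kids <- members[[parent]]
    split_group <- function(group, conc, state_field) {
      ids <- vapply(group, `[[`, "", "id")
      i <- match(parent, ids)
      if (is.na(i)) return(NULL)
      fr <- NULL
      if (!is.null(member_obs) && all(kids %in% rownames(member_obs))) {
        v <- member_obs[kids, 1]
        if (all(!is.na(v)) && sum(v) > 0) fr <- v / sum(v)
      }
      if (is.null(fr)) {
        warning("member fractions unavailable for ", parent,
                "; splitting equally")
        fr <- rep(1 / length(kids), length(kids))
      }
      new_group <- c(group[-i], lapply(seq_along(kids), function(k)
        jitter_params(group[[i]], kids[k])))
      parent_c <- state[[state_field]][parent]
      new_c <- c(state[[state_field]][setdiff(ids, parent)],
                 stats::setNames(parent_c * fr, kids))
      list(group = new_group, conc = new_c)
    }
    sp <- split_group(cfg$phyto, state$phyto_c, "phyto_c")
    if (!is.null(sp)) {
      cfg$phyto <- sp$group
      state$phyto_c <- sp$conc
    } else {
      sh <- split_group(cfg$het, state$het_active_c, "het_active_c")
      if (is.null(sh)) stop("unknown lumped taxon: ", parent)
      dorm <- state$het_dormant_c[parent]
      ids <- vapply(cfg$het, `[[`, "", "id")
      frac <- sh$conc[members[[parent]]] /
        max(sum(sh$conc[members[[parent]]]), 1e-12)
      cfg$het <- sh$group
      state$het_active_c <- sh$conc
      state$het_dormant_c <- c(
        state$het_dormant_c[setdiff(ids, parent)],
        stats::setNames(dorm * frac, members[[parent]]))
    }
  }
  validate_config(cfg)
  list(config = cfg, state = state)
}
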