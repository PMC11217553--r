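#' Producer-attributed pairwise carbon fluxes
#'
#' For every output time, each consumer's uptake of DOM species j is
#' attributed to the taxa that produced the standing mass of j, in
#' proportion to the ledger source fractions at that time. Summing the
#' attributed fluxes over producers recovers the consumer's total DOM
#' uptake exactly.
#'
#' @param traj a `flux_trajectory`.
#' @return a `pairwise_flux_table` data frame: `time`, `date`,
#'   `producer_id`, `producer_class` (`"phytoplankton"`, `"heterotroph"` or
#'   `"background"` for initial unattributed stocks), `consumer_id`, `flux`
#'   (umol C L-1 d-1).
#' @export
pairwise_fluxes <- function(traj) {
  nt <- length(traj$time)
  H <- ncol(traj$het_active_c); D <- ncol(traj$dom_c)
  np <- length(traj$producer_ids)
  out <- vector("list", nt)
  for (k in seq_len(nt)) {
    U <- matrix(traj$uptake[k, , ], H, D)         # consumers x dom
    Fk <- matrix(traj$dom_src_frac[k, , ], D, np) # dom x producers
    A <- U %*% Fk                                 # consumers x producers
    out[[k]] <- A
  }
  A <- do.call(rbind, out)
  cons <- colnames(traj$het_active_c)
  df <- data.frame(
    time = rep(traj$time, each = H)[rep(seq_len(nt * H), np)],
    producer_id = rep(traj$producer_ids, each = nt * H),
    producer_class = rep(traj$producer_class, each = nt * H),
    consumer_id = rep(rep(cons, nt), np),
    flux = as.vector(A))
  df$date <- traj$origin + df$time
  class(df) <- c("pairwise_flux_table", "data.frame")
  df
}

bloom_windows_def <- list(
  phyto_spring = list(months = 2:5, series = "chl"),
  bacteria_summer = list(months = 6:8, series = "het"),
  phyto_summer = list(months = 7:8, series = "chl"))

#' Detect a bloom window in a concentration series
#'
#' The peak is the maximum concentration inside the type's search window
#' (spring phytoplankton: Feb-May on chlorophyll; summer phytoplankton:
#' Jul-Aug on chlorophyll; summer bacteria: Jun-Aug on total heterotroph
#' concentration). The bloom start is the latest local minimum within the
#' default duration before the peak (start assignment is not strict;
#' `start_override` replaces it). The bloom ends `duration` days after the
#' start unless the concentration falls below the starting concentration
#' earlier, in which case it ends on the first such day after the peak.
#'
#' @param dates vector of dates.
#' @param values concentrations at `dates`.
#' @param bloom_type one of `"phyto_spring"`, `"phyto_summer"`,
#'   `"bacteria_summer"`.
#' @param year calendar year to search.
#' @param duration default bloom duration in days (28 unless overridden,
#'   e.g. 34 or 42 for persistent blooms).
#' @param start_override optional manual start date.
#' @return a one-row data frame (`bloom_type`, `year`, `start`, `peak`,
#'   `end`, `duration`), or `NULL` with a message when the search window
#'   holds no data.
#' @export
detect_blooms <- function(dates, values, bloom_type, year, duration = 28,
                          start_override = NULL) {
  def <- bloom_windows_def[[match.arg(bloom_type,
                                      names(bloom_windows_def))]]
  keep <- !is.na(values)
  dates <- dates[keep]; values <- values[keep]
  o <- order(dates)
  dates <- dates[o]; values <- values[o]
  mo <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  win <- yr == year & mo %in% def$months
  if (!any(win)) {
    message("no data in the ", bloom_type, " search window for ", year,
            "; no bloom assigned")
    return(NULL)
  }
  peak_i <- which(win)[which.max(values[win])]
  peak <- dates[peak_i]

  if (!is.null(start_override)) {
    start <- as.Date(start_override)
    start_i <- max(which(dates <= start))
  } else {
    lead <- which(dates >= peak - duration & dates <= peak)
    locmin <- lead[vapply(lead, function(i) {
      lo <- if (i > 1) values[i - 1] else Inf
      hi <- if (i < length(values)) values[i + 1] else Inf
      values[i] <= lo && values[i] <= hi &&
        (values[i] < lo || values[i] < hi) # strict: flat runs do not count
    }, TRUE)]
    locmin <- locmin[locmin < peak_i]
    if (length(locmin)) {
      start_i <- max(locmin)
    } else {
      start_i <- min(lead)
      warning("no local minimum before the ", bloom_type, " peak in ", year,
              "; bloom start set to the search lead-in")
    }
    start <- dates[start_i]
  }
  start_val <- values[start_i]
  after_peak <- which(dates > peak & dates <= start + duration)
  below <- after_peak[values[after_peak] < start_val]
  end <- if (length(below)) dates[min(below)] else start + duration
  data.frame(bloom_type = bloom_type, year = year, start = start,
             peak = peak, end = end,
             duration = as.numeric(end - start))
}

#' Detect all bloom windows of a trajectory
#'
#' Runs [detect_blooms()] for each bloom type and simulated year on the
#' trajectory's chlorophyll-equivalent (total phytoplankton carbon times
#' 12.011/40) and total heterotroph series.
#'
#' @param traj a `flux_trajectory`.
#' @param duration_overrides optional named vector
#'   `c("<type>:<year>" = days)`.
#' @param start_overrides optional named vector of manual start dates with
#'   the same key format.
#' @return data frame of bloom windows (possibly with fewer rows than
#'   `3 * years` when a window holds no bloom).
#' @export
detect_all_blooms <- function(traj, duration_overrides = NULL,
                              start_overrides = NULL) {
  dates <- traj$origin + traj$time
  chl <- rowSums(traj$phyto_c) * 12.011 / 40
  het <- rowSums(traj$het_active_c + traj$het_dormant_c)
  years <- sort(unique(as.integer(format(dates, "%Y"))))
  rows <- list()
  for (y in years) {
    in_year <- format(dates, "%Y") == as.character(y)
    if (sum(in_year) < 30) next # partial year stub (e.g. trailing day)
    for (ty in names(bloom_windows_def)) {
      key <- paste0(ty, ":", y)
      dur <- if (!is.null(duration_overrides) &&
                 key %in% names(duration_overrides))
        duration_overrides[[key]] else 28
      so <- if (!is.null(start_overrides) &&
                key %in% names(start_overrides))
        start_overrides[[key]] else NULL
      vals <- if (bloom_windows_def[[ty]]$series == "chl") chl else het
      b <- detect_blooms(dates, vals, ty, y, duration = dur,
                         start_override = so)
      if (!is.null(b)) rows[[key]] <- b
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Bloom-averaged and weekly pairwise fluxes
#'
#' Averages the producer-class fluxes over a bloom window and over weekly
#' bins anchored at the bloom start. The length-weighted mean of the weekly
#' bin means equals the bloom mean.
#'
#' @param pairwise a `pairwise_flux_table`.
#' @param window one row of a bloom table (needs `start` and `end`).
#' @param origin the trajectory origin date (used to map dates to times);
#'   inferred from the table's `date`/`time` columns.
#' @return list with `bloom_mean` (named vector: `phyto_to_het`,
#'   `het_to_het`, `background_to_het`) and `weekly` (data frame with
#'   `bin_start_day`, `phyto_to_het`, `het_to_het`).
#' @export
aggregate_bloom_fluxes <- function(pairwise, window, origin = NULL) {
  sel <- pairwise$date >= window$start & pairwise$date <= window$end
  if (!any(sel)) stop("bloom window is outside the trajectory span")
  pw <- pairwise[sel, ]
  class_flux <- function(df) {
    per_t <- tapply(df$flux, list(df$date, df$producer_class), sum)
    per_t[is.na(per_t)] <- 0
    cm <- colMeans(per_t)
    c(phyto_to_het = unname(cm["phytoplankton"]),
      het_to_het = unname(cm["heterotroph"]),
      background_to_het = unname(if ("background" %in% names(cm))
        cm["background"] else 0))
  }
  bloom_mean <- class_flux(pw)
  day <- as.numeric(pw$date - window$start)
  bin <- pmin(floor(day / 7), floor((window$duration - 1e-9) / 7))
  weekly <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    cf <- class_flux(pw[bin == b, ])
    data.frame(bin_start_day = b * 7, phyto_to_het = cf["phyto_to_het"],
               het_to_het = cf["het_to_het"],
               n_days = length(unique(pw$date[bin == b])),
               row.names = NULL)
  }))
  list(bloom_mean = bloom_mean, weekly = weekly)
}

#' Share of heterotroph-derived DOC in heterotroph consumption
#'
#' The internal-recycling share: heterotroph-to-heterotroph flux divided by
#' the summed phytoplankton-to-heterotroph and heterotroph-to-heterotroph
#' fluxes over a window (unattributed background stocks excluded).
#'
#' @param pairwise a `pairwise_flux_table`.
#' @param window bloom window row (or `NULL` for the whole table).
#' @return the share in `[0, 1]`.
#' @export
hp_flux_share <- function(pairwise, window = NULL) {
  pw <- if (is.null(window)) pairwise else
    pairwise[pairwise$date >= window$start & pairwise$date <= window$end, ]
  tot <- tapply(pw$flux, pw$producer_class, sum)
  hh <- if ("heterotroph" %in% names(tot)) tot[["heterotroph"]] else 0
  ph <- if ("phytoplankton" %in% names(tot)) tot[["phytoplankton"]] else 0
  if (hh + ph <= 0) return(NA_real_)
  hh / (hh + ph)
}

#' Primary and heterotrophic production metrics
#'
#' Gross primary production (GPP) is summed photosynthesis; net primary
#' production subtracts phytoplankton respiration; gross heterotrophic
#' production is summed growth (`yield x uptake`); net heterotrophic
#' production subtracts heterotroph death. Volumetric rates
#' (umol C L-1 d-1) are converted to areal rates with
#' `1 umol L-1 d-1 = 1 mmol m-3 d-1` times the integration depth.
#'
#' @param traj a `flux_trajectory`.
#' @param depth_m integration depth for areal rates (m).
#' @param window optional bloom window row restricting the averaging
#'   period.
#' @return data frame with one row per metric: `metric`,
#'   `volumetric_umol_l_d`, `areal_mmol_m2_d`.
#' @export
production_metrics <- function(traj, depth_m = 50, window = NULL) {
  stopifnot(depth_m > 0)
  dates <- traj$origin + traj$time
  sel <- if (is.null(window)) rep(TRUE, length(dates)) else
    dates >= window$start & dates <= window$end
  m <- function(x) mean(rowSums(x[sel, , drop = FALSE]))
  gpp <- m(traj$photosynthesis)
  npp <- gpp - m(traj$respiration_phyto)
  ghp <- m(traj$growth_het)
  nhp <- ghp - (m(traj$death_dom_het) + m(traj$death_pom_het))
  vol <- c(gpp = gpp, npp = npp, gross_het_prod = ghp, net_het_prod = nhp)
  data.frame(metric = names(vol), volumetric_umol_l_d = unname(vol),
             areal_mmol_m2_d = unname(vol) * depth_m)
}

#' DOC-concentration-normalized heterotrophy rate
#'
#' `rate = uptake / (het_c * doc)` with all three quantities in mutually
#' consistent carbon units (e.g. mol C: consumed mol C d-1, heterotroph
#' mol C L-1, DOC mol C L-1, giving L mol-1 d-1).
#'
#' @param uptake DOC consumption rate.
#' @param het_c heterotroph carbon concentration (> 0).
#' @param doc DOC concentration (> 0); for model output this is the sum of
#'   the DOM species pools (no recalcitrant background).
#' @return the normalized rate; `NaN` with a warning on a zero denominator.
#' @export
normalized_heterotrophy <- function(uptake, het_c, doc) {
  bad <- het_c <= 0 | doc <= 0
  if (any(bad)) {
    warning("zero denominator in normalized heterotrophy rate; ",
            "flagged as NaN")
    het_c[bad] <- NA
  }
  uptake / (het_c * doc)
}

#' Normalized heterotrophy series of a trajectory
#'
#' @param traj a `flux_trajectory`.
#' @return data frame with `time`, `date` and `rate`
#'   (L (mol C)-1 d-1, computed on mol-based concentrations).
#' @export
normalized_heterotrophy_series <- function(traj) {
  uptake <- rowSums(traj$uptake_total) * 1e-6   # mol C L-1 d-1
  het <- rowSums(traj$het_active_c + traj$het_dormant_c) * 1e-6
  doc <- rowSums(traj$dom_c) * 1e-6
  data.frame(time = traj$time, date = traj$origin + traj$time,
             rate = normalized_heterotrophy(uptake, het, doc))
}

#' DOM/POM release ratio of heterotroph death fluxes
#'
#' Ratio of death-derived DOM release to death-derived POM release over a
#' window. A ratio above 1 indicates lysis-dominated mortality (viral
#' lysis releases mostly dissolved matter, protist grazing mostly
#' particulate).
#'
#' @param traj a `flux_trajectory`.
#' @param taxa heterotroph ids to include (default all).
#' @param window optional bloom window row.
#' @return list with `ratio` and logical `lysis_dominated`; ratio is `NaN`
#'   with a warning when no POM is released.
#' @export
dom_pom_release_ratio <- function(traj, taxa = NULL, window = NULL) {
  dates <- traj$origin + traj$time
  sel <- if (is.null(window)) rep(TRUE, length(dates)) else
    dates >= window$start & dates <= window$end
  taxa <- taxa %||% colnames(traj$death_dom_het)
  dd <- sum(traj$death_dom_het[sel, taxa, drop = FALSE])
  dp <- sum(traj$death_pom_het[sel, taxa, drop = FALSE])
  if (dp <= 0) {
    warning("no POM release in window; ratio undefined")
    return(list(ratio = NaN, lysis_dominated = NA))
  }
  list(ratio = dd / dp, lysis_dominated = dd / dp > 1)
}

#' Limitation-factor time series
#'
#' Extracts (or recomputes from the stored states and forcing) the
#' per-taxon limitation factors along the trajectory: temperature, light,
#' DIN and PO4 (and silicate for silicifiers) for phytoplankton;
#' temperature and the substrate saturation factor for heterotrophs. The
#' minimum factor per taxon and date is flagged as most limiting.
#'
#' @param traj a `flux_trajectory`.
#' @param taxa taxa to include; default the `top_k` phytoplankton and
#'   heterotrophs by mean carbon.
#' @param top_k how many taxa of each class to keep when `taxa` is `NULL`.
#' @param recompute recompute factors from states and forcing with the R
#'   rate functions instead of reading the simulator's records (both must
#'   agree; used for verification).
#' @return data frame: `time`, `date`, `taxon_id`, `class`, `factor`,
#'   `value`, `most_limiting`.
#' @export
limitation_timeseries <- function(traj, taxa = NULL, top_k = 3,
                                  recompute = FALSE) {
  cfg <- traj$config
  pid <- colnames(traj$phyto_c); hid <- colnames(traj$het_active_c)
  if (is.null(taxa)) {
    top <- function(m, ids) ids[order(-colMeans(m))][seq_len(min(top_k,
                                                                 ncol(m)))]
    taxa <- c(top(traj$phyto_c, pid),
              top(traj$het_active_c + traj$het_dormant_c, hid))
  }
  nt <- length(traj$time)
  rows <- list()
  for (tx in taxa) {
    if (tx %in% pid) {
      i <- match(tx, pid)
      pars <- cfg$phyto[[i]]
      if (recompute) {
        vals <- t(vapply(seq_len(nt), function(k) {
          f <- limitation_factors_phyto(
            pars,
            list(temp = traj$forcing[k, "temp"],
                 par = traj$forcing[k, "par"],
                 daylength = traj$forcing[k, "daylength"]),
            list(no3 = traj$no3[k], nh4 = traj$nh4[k], po4 = traj$po4[k],
                 si = traj$si[k]))
          c(f$f_T, f$f_I, f$f_N, f$f_P, f$f_Si)
        }, numeric(5)))
      } else {
        vals <- traj$lim_phyto[, i, , drop = TRUE]
      }
      fac <- c("f_T", "f_I", "f_N", "f_P", "f_Si")
      keep <- if (pars$silicifier) 1:5 else 1:4
      df <- data.frame(time = rep(traj$time, length(keep)),
                       taxon_id = tx, class = "phytoplankton",
                       factor = rep(fac[keep], each = nt),
                       value = as.vector(vals[, keep]))
    } else {
      i <- match(tx, hid)
      if (recompute) {
        vals <- t(vapply(seq_len(nt), function(k) {
          r <- het_rates(cfg$het[[i]], traj$het_active_c[k, i],
                         traj$dom_c[k, ], traj$forcing[k, "temp"])
          c(r$f_T, r$f_S)
        }, numeric(2)))
      } else {
        vals <- traj$lim_het[, i, , drop = TRUE]
      }
      df <- data.frame(time = rep(traj$time, 2), taxon_id = tx,
                       class = "heterotroph",
                       factor = rep(c("f_T", "f_S"), each = nt),
                       value = as.vector(vals))
    }
    mins <- tapply(df$value, df$time, min)
    df$most_limiting <- df$value <= mins[as.character(df$time)] + 1e-12
    rows[[tx]] <- df
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$date <- traj$origin + out$time
  out
}

#' Flux-network snapshot for one day
#'
#' Edge list of the carbon flux network at the output time closest to
#' `date`: phytoplankton to DOM (exudation + death) and POM (death), POM
#' dissolution to DOM, DOM uptake by heterotrophs, and heterotroph death
#' back to DOM/POM. Node sizes follow the network-figure convention:
#' outflow for phytoplankton, inflow for heterotrophs, mean of inflow and
#' outflow (throughflow) for DOM and POM.
#'
#' @param traj a `flux_trajectory`.
#' @param date target calendar date.
#' @return list with `edges` (`from`, `to`, `process`, `flux`) and `nodes`
#'   (`id`, `class`, `size`).
#' @export
network_snapshot <- function(traj, date) {
  k <- which.min(abs(as.numeric(traj$origin + traj$time - as.Date(date))))
  pid <- colnames(traj$phyto_c); hid <- colnames(traj$het_active_c)
  D <- ncol(traj$dom_c)
  mats <- config_matrices(traj$config)
  edges <- list()
  add <- function(from, to, process, flux)
    edges[[length(edges) + 1]] <<- data.frame(from = from, to = to,
                                              process = process, flux = flux)
  for (i in seq_along(pid)) {
    rel <- (traj$exudation[k, i] + traj$death_dom_phyto[k, i]) *
      mats$phyto_alloc[i, ]
    add(pid[i], paste0("dom", 1:D), "release", rel)
    add(pid[i], "pom", "death_pom", traj$death_pom_phyto[k, i])
  }
  add("pom", paste0("dom", 1:D), "dissolution",
      traj$dissolution[k] * mats$pom_alloc)
  for (h in seq_along(hid)) {
    add(paste0("dom", 1:D), hid[h], "uptake", traj$uptake[k, h, ])
    add(hid[h], paste0("dom", 1:D), "death_dom",
        traj$death_dom_het[k, h] * mats$het_alloc[h, ])
    add(hid[h], "pom", "death_pom", traj$death_pom_het[k, h])
  }
  edges <- do.call(rbind, edges)
  edges <- edges[edges$flux > 0, ]
  nodes <- data.frame(id = c(pid, hid, paste0("dom", 1:D), "pom"),
                      class = c(rep("phytoplankton", length(pid)),
                                rep("heterotroph", length(hid)),
                                rep("dom", D), "pom"))
  outfl <- tapply(edges$flux, edges$from, sum)
  infl <- tapply(edges$flux, edges$to, sum)
  gv <- function(tab, id) if (id %in% names(tab)) tab[[id]] else 0
  nodes$size <- vapply(seq_len(nrow(nodes)), function(r) {
    id <- nodes$id[r]
    switch(nodes$class[r],
           phytoplankton = gv(outfl, id),
           heterotroph = gv(infl, id),
           (gv(outfl, id) + gv(infl, id)) / 2)
  }, 0)
  list(edges = edges, nodes = nodes, time = traj$time[k],
       date = traj$origin + traj$time[k])
}
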