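#' Define a synthetic observation scenario
#'
#' Bundles everything needed to generate forcing, a ground-truth model run
#' and noisy weekly observations with the statistical structure of a
#' temperate coastal time series: seasonal temperature/PAR/daylength
#' forcing, winter nutrient loadings, a true model configuration, and the
#' observation noise model (lognormal noise on bulk measurements,
#' Dirichlet-multinomial read sampling).
#'
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @param years number of simulated years.
#' @param n_phyto,n_het,n_dom taxa counts (phytoplankton incl. one
#'   Synechococcus-like taxon, heterotroph ASVs, DOM species). The shipped
#'   true configuration is defined for the default 5/8/6; other counts
#'   require a custom `config`.
#' @param temp_mean,temp_amp annual temperature mean/amplitude (deg C);
#'   `temp_peak_day` the day-of-year of the maximum.
#' @param par_mean,par_amp,par_peak_day PAR seasonal curve (mol photons
#'   m-2 d-1 scale).
#' @param daylength_min,daylength_max photoperiod range (h).
#' @param chl_sigma,nutrient_sigma,count_sigma lognormal noise sigmas.
#' @param read_depth_18s,read_depth_16s reads per sample.
#' @param dm_overdispersion Dirichlet concentration parameter (larger =
#'   closer to multinomial around the true fractions).
#' @param config the true [model_config()]; defaults to
#'   [default_true_config()].
#' @param origin calendar date of day 0.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 42L, years = 2L, n_phyto = 5L,
                               n_het = 8L, n_dom = 6L,
                               temp_mean = 13, temp_amp = 4,
                               temp_peak_day = 235,
                               par_mean = 26, par_amp = 21,
                               par_peak_day = 172,
                               daylength_min = 8, daylength_max = 16.5,
                               chl_sigma = 0.15, nutrient_sigma = 0.10,
                               count_sigma = 0.15,
                               read_depth_18s = 20000L,
                               read_depth_16s = 20000L,
                               dm_overdispersion = 200,
                               config = default_true_config(n_dom),
                               origin = as.Date("2015-01-01")) {
  stopifnot(years >= 1, n_phyto >= 1, n_het >= 1, n_dom >= 1)
  sc <- as.list(environment())
  class(sc) <- "synthetic_scenario"
  sc
}

#' The shipped ground-truth model configuration
#'
#' A desk-scale parameterization of the ecosystem model (5 phytoplankton
#' taxa including a Synechococcus-like picocyanobacterium, 8 heterotroph
#' ASVs, 6 DOM species) chosen to reproduce the qualitative temperate
#' coastal regime: a spring phytoplankton bloom when light returns and
#' winter nutrients are still high, a heterotroph bloom in early summer
#' once temperature releases the heterotrophs onto the accumulated DOM,
#' and a late-summer phytoplankton bloom fed by remineralized nitrogen.
#' Cold-adapted spring taxa and warm-adapted summer taxa coexist through
#' distinct temperature optima and nutrient affinities; heterotroph guilds
#' differ in which DOM species they can use (phytoplankton-derived vs
#' heterotroph-derived), which is what makes internal recycling grow during
#' bacterial blooms.
#'
#' @param n_dom number of DOM species (the shipped parameterization expects
#'   the default 6).
#' @return a [model_config()].
#' @export
default_true_config <- function(n_dom = 6L) {
  D <- n_dom
  alloc <- function(w) {
    a <- rep_len(w, D)
    a / sum(a)
  }
  # DOM species 1-2: fresh phytoplankton exudate; 3: phytoplankton lysate;
  # 4-5: heterotroph lysate; 6: dissolved POM background.
  phyto <- list(
    phyto_params("diatom_spring", mu_max = 1.9, k_light = 16, k_din = 1.2,
                 k_po4 = 0.06, k_si = 0.8, silicifier = TRUE, q10 = 1.9,
                 t_ref = 11, ke = 0.02, fe = 0.10, kr = 0.04, fr = 0.12,
                 kd = 0.06, kd_quad = 0.02, f_dom = 0.45,
                 dom_alloc = alloc(c(4, 3, 2, 0, 0, 1))),
    phyto_params("pico_prasinophyte", mu_max = 1.25, k_light = 8,
                 k_din = 0.45, k_po4 = 0.04, q10 = 2.2, t_ref = 13,
                 ke = 0.02, fe = 0.09, kr = 0.03, fr = 0.1, kd = 0.06, kd_quad = 0.02,
                 f_dom = 0.5, dom_alloc = alloc(c(4, 3, 2, 0, 0, 1))),
    phyto_params("summer_flagellate", mu_max = 1.25, k_light = 22,
                 k_din = 0.25, k_po4 = 0.03, q10 = 2.8, t_ref = 18,
                 ke = 0.02, fe = 0.08, kr = 0.03, fr = 0.1, kd = 0.06, kd_quad = 0.02,
                 f_dom = 0.5, dom_alloc = alloc(c(3, 3, 3, 0, 0, 1))),
    phyto_params("dinoflagellate", mu_max = 1.0, k_light = 26, k_din = 0.5,
                 k_po4 = 0.05, q10 = 2.2, t_ref = 15, ke = 0.02, fe = 0.08,
                 kr = 0.03, fr = 0.1, kd = 0.06, kd_quad = 0.02, f_dom = 0.5,
                 dom_alloc = alloc(c(3, 3, 3, 0, 0, 1))),
    phyto_params("synechococcus", mu_max = 1.15, k_light = 10, k_din = 0.2,
                 k_po4 = 0.02, q10 = 2.8, t_ref = 18, ke = 0.02, fe = 0.07,
                 kr = 0.03, fr = 0.1, kd = 0.06, kd_quad = 0.02, f_dom = 0.55,
                 dom_alloc = alloc(c(3, 3, 2, 0, 0, 2)),
                 synechococcus = TRUE))
  aff <- function(...) {
    a <- rep(NA_real_, D); v <- list(...)
    for (nm in names(v)) a[as.integer(nm)] <- v[[nm]]
    a
  }
  het_alloc <- alloc(c(0, 0, 0, 3, 2, 1))
  het <- list(
    het_params("PLAx", v_max = 3.4, affinity = aff(`1` = 0.8, `2` = 1.5),
               yield = 0.32, q10 = 2.8, t_ref = 15, kd = 0.12, kd_quad = 0.30,
               f_dom = 0.53, dom_alloc = het_alloc),
    het_params("TENx", v_max = 4.6, affinity = aff(`2` = 1.0, `3` = 1.4, `6` = 2.0),
               yield = 0.30, q10 = 3.5, t_ref = 20, kd = 0.24, kd_quad = 0.15,
               f_dom = 0.54, dom_alloc = het_alloc),
    het_params("SAR11x", v_max = 3.0, affinity = aff(`1` = 1.2, `2` = 0.9, `6` = 1.5),
               yield = 0.30, q10 = 3.0, t_ref = 18, kd = 0.16, kd_quad = 0.15,
               f_dom = 0.53, dom_alloc = het_alloc),
    het_params("ROSx", v_max = 4.0, affinity = aff(`3` = 1.0, `6` = 1.8),
               yield = 0.31, q10 = 3.5, t_ref = 20, kd = 0.28, kd_quad = 0.15,
               f_dom = 0.53, dom_alloc = het_alloc),
    het_params("FLAVx", v_max = 4.4, affinity = aff(`4` = 0.9, `5` = 1.1, `6` = 1.6),
               yield = 0.30, q10 = 3.8, t_ref = 22, kd = 0.26, kd_quad = 0.15,
               f_dom = 0.54, dom_alloc = het_alloc),
    het_params("GAMx", v_max = 4.6, affinity = aff(`4` = 1.0, `5` = 0.9),
               yield = 0.28, q10 = 4.0, t_ref = 22.5, kd = 0.30, kd_quad = 0.15,
               f_dom = 0.55, dom_alloc = het_alloc),
    het_params("ALTx", v_max = 3.6, affinity = aff(`1` = 1.5, `4` = 1.2, `6` = 1.2),
               yield = 0.30, q10 = 3.4, t_ref = 19.5, kd = 0.26, kd_quad = 0.15,
               f_dom = 0.52, dom_alloc = het_alloc),
    het_params("ARCx", v_max = 2.6, affinity = aff(`2` = 1.4, `5` = 1.2, `6` = 1.0),
               yield = 0.29, q10 = 3.0, t_ref = 18, kd = 0.20, kd_quad = 0.15,
               f_dom = 0.52, dom_alloc = het_alloc))
  model_config(phyto, het, n_dom = D,
               pom = list(k_dis = 0.08, k_sink = 0.06,
                          dom_alloc = alloc(c(0.5, 0.5, 1, 0.5, 0.5, 3))))
}

#' Default initial state for the synthetic scenario
#'
#' Winter (January 1) conditions: low biomass, replete nutrients.
#'
#' @param config the true configuration.
#' @return a [model_state()].
#' @export
default_initial_state <- function(config) {
  P <- length(config$phyto); H <- length(config$het)
  model_state(
    phyto_c = stats::setNames(rep(0.15, P), phyto_ids(config)),
    het_active_c = stats::setNames(rep(0.18, H), het_ids(config)),
    het_dormant_c = stats::setNames(rep(0.06, H), het_ids(config)),
    dom_c = rep(0.5, config$n_dom), pom_c = 1.0,
    no3 = 4.5, nh4 = 0.5, po4 = 0.5, si = 4.5)
}

#' Generate deterministic seasonal forcing
#'
#' Daily temperature, PAR and daylength follow smooth annual sinusoids;
#' winter nutrient loadings (late autumn through winter) emulate mixing
#' that restocks NO3, PO4 and silicate.
#'
#' @param scenario a [synthetic_scenario()].
#' @return data frame accepted by [simulate_ecosystem()] with one row per
#'   day (`365 * years + 1` rows).
#' @export
generate_forcing <- function(scenario) {
  days <- 0:(365 * scenario$years)
  doy <- days %% 365
  ann <- function(peak) cospi(2 * (doy - peak) / 365)
  temp <- scenario$temp_mean + scenario$temp_amp * ann(scenario$temp_peak_day)
  par <- pmax(0.5, scenario$par_mean + scenario$par_amp *
                ann(scenario$par_peak_day))
  dl_mid <- (scenario$daylength_min + scenario$daylength_max) / 2
  dl_amp <- (scenario$daylength_max - scenario$daylength_min) / 2
  daylength <- dl_mid + dl_amp * ann(172)
  winter <- doy >= 300 | doy <= 50
  data.frame(time = days, temp = temp, par = par, daylength = daylength,
             load_no3 = ifelse(winter, 0.06, 0),
             load_nh4 = 0,
             load_po4 = ifelse(winter, 0.0045, 0),
             load_si = ifelse(winter, 0.05, 0))
}

#' Run the ground-truth simulation for a scenario
#'
#' Simulates the true configuration under the scenario forcing, detects the
#' true bloom windows on the simulated chlorophyll-equivalent and total
#' heterotroph series, and attributes the true pairwise fluxes.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `trajectory` (a `flux_trajectory`), `pairwise`
#'   (producer-attributed flux table), `blooms` (data frame of detected
#'   bloom windows), `forcing`, `config` and the `scenario` itself. Warns
#'   if a year does not produce all three bloom types.
#' @export
generate_ground_truth <- function(scenario) {
  forcing <- generate_forcing(scenario)
  state <- default_initial_state(scenario$config)
  traj <- simulate_ecosystem(scenario$config, state, forcing, t0 = 0,
                             t1 = 365 * scenario$years,
                             origin = scenario$origin)
  pw <- pairwise_fluxes(traj)
  blooms <- detect_all_blooms(traj)
  want <- 3 * scenario$years
  if (nrow(blooms) < want)
    warning("scenario produced ", nrow(blooms), " bloom windows; ",
            want, " expected")
  list(trajectory = traj, pairwise = pw, blooms = blooms, forcing = forcing,
       config = scenario$config, scenario = scenario)
}

# Dirichlet-multinomial read sampling around true fractions.
rdirmult <- function(fractions, depth, conc) {
  pos <- fractions > 0
  alpha <- fractions[pos] * conc
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha
  p <- g / sum(g)
  reads <- numeric(length(fractions))
  reads[pos] <- as.vector(rmultinom(1, depth, p))
  reads
}

#' Sample weekly observations from a ground-truth trajectory
#'
#' Subsamples the daily trajectory every 7th day and applies the
#' observation model: chlorophyll is eukaryote phytoplankton carbon times
#' 12.011/40 with lognormal noise; 18S reads are Dirichlet-multinomial
#' draws around the true eukaryote carbon fractions (each taxon split over
#' two ASVs, plus heterotrophic and unassigned 18S ASVs that the ingest
#' filters must remove); 16S reads likewise around heterotroph carbon
#' fractions plus chloroplast and ammonia-oxidizer contaminant ASVs;
#' Synechococcus and total heterotroph cell counts are carbon divided by
#' the respective per-cell quota with lognormal noise; nutrients get
#' lognormal noise.
#'
#' @param truth output of [generate_ground_truth()].
#' @param scenario the scenario (defaults to the one stored in `truth`).
#' @return an `observation_set` (as from [read_observations()]).
#' @export
sample_observations <- function(truth, scenario = truth$scenario) {
  set.seed(scenario$seed)
  traj <- truth$trajectory
  cfg <- traj$config
  idx <- which(traj$time %% 7 == 3 & traj$time <= 365 * scenario$years)
  dates <- scenario$origin + traj$time[idx]
  n <- length(idx)

  syn_flag <- vapply(cfg$phyto, `[[`, TRUE, "synechococcus")
  euk <- traj$phyto_c[idx, !syn_flag, drop = FALSE]
  syn_c <- rowSums(traj$phyto_c[idx, syn_flag, drop = FALSE])
  het_tot <- rowSums(traj$het_active_c[idx, , drop = FALSE] +
                     traj$het_dormant_c[idx, , drop = FALSE])
  het_m <- traj$het_active_c[idx, , drop = FALSE] +
    traj$het_dormant_c[idx, , drop = FALSE]

  lnoise <- function(x, sigma)
    x * rlnorm(length(x), -sigma^2 / 2, sigma)

  chl <- lnoise(rowSums(euk) * 12.011 / 40, scenario$chl_sigma)
  syn_counts <- round(lnoise(syn_c / (1.4e-14 * 1e6), scenario$count_sigma))
  het_counts <- round(lnoise(het_tot / (2.0e-15 * 1e6),
                             scenario$count_sigma))

  # 18S: two ASVs per eukaryote taxon (70/30), one heterotrophic and one
  # unassigned contaminant at a few percent of reads.
  euk_ids <- colnames(euk)
  asv_ids18 <- c(paste0(rep(euk_ids, each = 2), c("_a", "_b")),
                 "asv18_het01", "asv18_unk01")
  reads18 <- matrix(0L, length(asv_ids18), n,
                    dimnames = list(asv_ids18, as.character(dates)))
  for (k in seq_len(n)) {
    fr <- euk[k, ] / max(sum(euk[k, ]), 1e-12)
    fr_asv <- c(rbind(fr * 0.7, fr * 0.3)) * 0.95
    fr_all <- c(fr_asv, 0.03, 0.02)
    reads18[, k] <- rdirmult(fr_all, scenario$read_depth_18s,
                             scenario$dm_overdispersion)
  }
  tax18 <- data.frame(
    asv_id = asv_ids18,
    lineage = c(paste0("Eukaryota;Phytoplankton;", rep(euk_ids, each = 2)),
                "Eukaryota;Ciliophora;Strombidium", "unassigned"),
    trophy = c(rep("phototrophic", 2 * length(euk_ids)), "heterotrophic",
               "unassigned"))

  # 16S: one ASV per heterotroph taxon plus contaminants.
  het_ids_v <- colnames(het_m)
  asv_ids16 <- c(het_ids_v, "asv16_chloro", "asv16_aoa")
  reads16 <- matrix(0L, length(asv_ids16), n,
                    dimnames = list(asv_ids16, as.character(dates)))
  for (k in seq_len(n)) {
    fr <- het_m[k, ] / max(sum(het_m[k, ]), 1e-12)
    fr_all <- c(fr * 0.95, 0.03, 0.02)
    reads16[, k] <- rdirmult(fr_all, scenario$read_depth_16s,
                             scenario$dm_overdispersion)
  }
  tax16 <- data.frame(
    asv_id = asv_ids16,
    lineage = c(paste0("Bacteria;Heterotroph;", het_ids_v),
                "Bacteria;Cyanobacteria;Chloroplast",
                "Archaea;Thaumarchaeota;Nitrosopumilus"),
    trophy = c(rep("heterotrophic", length(het_ids_v)), "phototrophic",
               "chemoautotrophic"))

  nut <- function(x) lnoise(x, scenario$nutrient_sigma)
  obs <- list(dates = dates,
              chlorophyll = chl, syn_counts = syn_counts,
              het_counts = het_counts,
              nutrients = list(no3no2 = nut(traj$no3[idx]),
                               nh4 = nut(traj$nh4[idx]),
                               po4 = nut(traj$po4[idx]),
                               si = nut(traj$si[idx])),
              temperature = traj$forcing[idx, "temp"],
              par = traj$forcing[idx, "par"],
              daylength = traj$forcing[idx, "daylength"],
              poc = lnoise(traj$pom_c[idx] + rowSums(traj$phyto_c[idx, ,
                           drop = FALSE]), scenario$count_sigma),
              asv18s = reads18, asv16s = reads16,
              tax18s = tax18, tax16s = tax16)
  class(obs) <- "observation_set"
  validate_observations(obs)
  obs
}

#' Write an observation set to CSV/TSV files
#'
#' Writes the file dialect read by [read_observations()] with the
#' [default_schema()].
#'
#' @param obs an `observation_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_observation_csvs <- function(obs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- as.character(obs$dates)
  w <- function(df, fn) write.csv(df, file.path(dir, fn), row.names = FALSE)
  w(data.frame(date = d, chl_mg_m3 = obs$chlorophyll), "chlorophyll.csv")
  w(data.frame(date = d, no3no2 = obs$nutrients$no3no2,
               nh4 = obs$nutrients$nh4, po4 = obs$nutrients$po4,
               si = obs$nutrients$si), "nutrients.csv")
  w(data.frame(date = d, temp_c = obs$temperature, par = obs$par,
               daylength_h = obs$daylength), "physics.csv")
  w(data.frame(date = d, cells_per_l = obs$syn_counts), "syn_counts.csv")
  w(data.frame(date = d, cells_per_l = obs$het_counts), "het_counts.csv")
  asv_wide <- function(m) {
    df <- data.frame(asv_id = rownames(m), check.names = FALSE)
    cbind(df, as.data.frame(m, check.names = FALSE))
  }
  w(asv_wide(obs$asv18s), "asv18s.csv")
  w(asv_wide(obs$asv16s), "asv16s.csv")
  write.table(obs$tax18s, file.path(dir, "tax18s.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(obs$tax16s, file.path(dir, "tax16s.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
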