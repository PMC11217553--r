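test_that("uptake is attributed to producers in ledger proportion", {
  # one phytoplankton feeding dom1, one heterotroph consuming it: after a
  # spin-up the consumer's intake must be attributed to the producer and to
  # the initial background stock in ledger proportion
  cfg <- tiny_config(mu_max = 0.5, ke = 0.1, fe = 0.1, kd = 0.05,
                     v_max = 1, yield = 0.3)
  st <- tiny_state(cfg, phyto = 1, het = 0.3, dom = 1, pom = 0)
  tr <- simulate_ecosystem(cfg, st, const_forcing(20, temp = 15, par = 30,
                                                  daylength = 12),
                           t0 = 0, t1 = 20)
  pw <- pairwise_fluxes(tr)
  # conservation: summed attributed flux equals total uptake at every time
  tot <- tapply(pw$flux, pw$time, sum)
  expect_equal(as.numeric(tot), as.numeric(rowSums(tr$uptake_total)),
               tolerance = 1e-9)
  # early on, background dominates; once exudation has fed the pool the
  # phytoplankton share must grow
  sh <- function(k, cls) {
    at <- pw[pw$time == tr$time[k], ]
    sum(at$flux[at$producer_class == cls]) / sum(at$flux)
  }
  expect_gt(sh(21, "phytoplankton"), sh(2, "phytoplankton"))
})

test_that("a 50/50 sourced pool splits uptake equally between producers", {
  cfg <- tiny_config(mu_max = 0, ke = 0, fe = 0, kr = 0, fr = 0, kd = 0,
                     v_max = 2, yield = 0.5, het_kd = 0)
  st <- tiny_state(cfg, phyto = 1, het = 0.5, dom = 1, pom = 0)
  # initial ledger: dom1 mass half from the phytoplankton, half background
  nprod <- 3 # p1, h1, background
  dom_src <- matrix(0, cfg$n_dom, nprod)
  dom_src[1, 1] <- 0.5
  dom_src[1, 3] <- 0.5
  tr <- simulate_ecosystem(cfg, st, const_forcing(1), t0 = 0, t1 = 0.05,
                           dt = 0.05, output_every = 0.05,
                           ledger = list(dom_src = dom_src,
                                         pom_src = c(0, 0, 0)))
  pw <- pairwise_fluxes(tr)
  at0 <- pw[pw$time == 0 & pw$flux > 0, ]
  expect_equal(sum(at0$flux[at0$producer_id == "p1"]),
               sum(at0$flux[at0$producer_id == "background"]))
  expect_equal(sum(at0$flux), unname(tr$uptake_total[1, 1]),
               tolerance = 1e-12)
})

mk_series <- function(vals, start = "2015-01-01") {
  list(dates = as.Date(start) + seq_along(vals) - 1, values = vals)
}

test_that("bloom windows honor the 28-day rule and the early-end rule", {
  # dip on Feb 25, peak on Mar 15, concentration stays high: the start is
  # the local minimum and the duration is capped at 28 d
  v <- c(rep(2, 55), 1, seq(1.2, 5, length.out = 18), rep(5, 120))
  s <- mk_series(v)
  b <- detect_blooms(s$dates, s$values, "phyto_spring", 2015)
  expect_equal(b$start, as.Date("2015-02-25"))
  expect_equal(b$duration, 28)
  expect_equal(b$end - b$start, as.difftime(28, units = "days"))
  expect_true(b$start <= b$peak && b$peak <= b$end)
  # concentration falls below the start value on day 17 after the start
  v2 <- c(rep(2, 59), 1.8, seq(2, 6, length.out = 8), seq(6, 0.5,
          length.out = 12), rep(0.5, 100))
  s2 <- mk_series(v2)
  b2 <- detect_blooms(s2$dates, s2$values, "phyto_spring", 2015)
  expect_lt(b2$duration, 28)
  below <- s2$values[s2$dates > b2$peak & s2$dates <= b2$end]
  expect_lt(min(below), s2$values[s2$dates == b2$start])
  # flat series: no local minimum, start falls back with a warning
  s3 <- mk_series(rep(1, 200))
  expect_warning(b3 <- detect_blooms(s3$dates, s3$values, "phyto_spring",
                                     2015), "local minimum")
  expect_equal(b3$duration, 28)
  # no data in the window: NULL with a message
  expect_message(
    none <- detect_blooms(as.Date("2015-10-01") + 0:30, rnorm(31, 10),
                          "phyto_spring", 2015),
    "no bloom")
  expect_null(none)
  # manual duration override (persistent bloom years)
  b4 <- detect_blooms(s$dates, s$values, "phyto_spring", 2015,
                      duration = 42)
  expect_equal(b4$duration, 42)
})

test_that("bloom-window search ranges match the seasonal definitions", {
  truth <- default_truth()
  bl <- truth$blooms
  mo <- function(ty) as.integer(format(bl$peak[bl$bloom_type == ty], "%m"))
  expect_true(all(mo("phyto_spring") %in% 2:5))
  expect_true(all(mo("phyto_summer") %in% 7:8))
  expect_true(all(mo("bacteria_summer") %in% 6:8))
  expect_true(all(bl$start <= bl$peak & bl$peak <= bl$end))
  expect_true(all(bl$duration <= 28))
})

test_that("bloom aggregation averages fluxes and partitions into weeks", {
  dates <- as.Date("2015-06-01") + 0:28
  ramp <- data.frame(time = 0:28, producer_id = "p",
                     producer_class = "phytoplankton", consumer_id = "h",
                     flux = seq(0, 0.28, length.out = 29), date = dates)
  const <- ramp
  const$flux <- 0.2
  const$producer_class <- "heterotroph"
  w <- data.frame(start = dates[1], end = dates[29], duration = 28)
  ag <- aggregate_bloom_fluxes(rbind(ramp, const), w)
  expect_equal(ag$bloom_mean[["phyto_to_het"]], 0.14)
  expect_equal(ag$bloom_mean[["het_to_het"]], 0.2)
  # length-weighted weekly means recover the bloom mean
  wk <- ag$weekly
  expect_equal(sum(wk$phyto_to_het * wk$n_days) / sum(wk$n_days),
               ag$bloom_mean[["phyto_to_het"]], tolerance = 1e-12)
  expect_error(aggregate_bloom_fluxes(ramp,
               data.frame(start = as.Date("2030-01-01"),
                          end = as.Date("2030-02-01"), duration = 28)),
               "outside")
})

test_that("production metrics convert volumetric to areal rates", {
  truth <- default_truth()
  pm <- production_metrics(truth$trajectory, depth_m = 50)
  expect_equal(pm$areal_mmol_m2_d, pm$volumetric_umol_l_d * 50)
  gpp <- pm$volumetric_umol_l_d[pm$metric == "gpp"]
  npp <- pm$volumetric_umol_l_d[pm$metric == "npp"]
  expect_lte(npp, gpp)
  expect_gt(gpp, 0)
  # zero biomass gives zero production
  cfg <- tiny_config()
  st <- tiny_state(cfg, phyto = 0, het = 0, dormant = 0, dom = 0, pom = 0)
  tr0 <- simulate_ecosystem(cfg, st, const_forcing(5), t0 = 0, t1 = 5)
  expect_true(all(production_metrics(tr0)$volumetric_umol_l_d == 0))
})

test_that("normalized heterotrophy rates scale as uptake/(biomass * DOC)", {
  expect_equal(normalized_heterotrophy(0.1, 0.5, 10), 0.02)
  expect_equal(normalized_heterotrophy(0, 0.5, 10), 0)
  expect_equal(normalized_heterotrophy(0.1, 0.5, 20),
               normalized_heterotrophy(0.1, 0.5, 10) / 2)
  expect_warning(nan <- normalized_heterotrophy(0.1, 0, 10), "denominator")
  expect_true(is.na(nan))
  truth <- default_truth()
  nh <- normalized_heterotrophy_series(truth$trajectory)
  expect_true(all(nh$rate >= 0, na.rm = TRUE))
})

test_that("the DOM/POM release ratio reflects the death partitioning", {
  mk <- function(f_dom) {
    cfg <- tiny_config(het_kd = 0.2, het_f_dom = f_dom)
    st <- tiny_state(cfg, phyto = 0, het = 1, dom = 5, pom = 0)
    simulate_ecosystem(cfg, st, const_forcing(5), t0 = 0, t1 = 5)
  }
  r5 <- dom_pom_release_ratio(mk(0.5))
  expect_equal(r5$ratio, 1, tolerance = 1e-9)
  r3 <- dom_pom_release_ratio(mk(0.3))
  expect_equal(r3$ratio, 3 / 7, tolerance = 1e-9)
  expect_false(r3$lysis_dominated)
  expect_true(dom_pom_release_ratio(mk(0.7))$lysis_dominated)
  expect_warning(bad <- dom_pom_release_ratio(mk(1)), "undefined")
  expect_true(is.nan(bad$ratio))
})

test_that("limitation factors recomputed from states match the recording", {
  truth <- default_truth()
  rec <- limitation_timeseries(truth$trajectory, top_k = 2)
  rec2 <- limitation_timeseries(truth$trajectory, top_k = 2,
                                recompute = TRUE)
  expect_equal(rec$value, rec2$value, tolerance = 1e-10)
  expect_setequal(unique(rec$class), c("phytoplankton", "heterotroph"))
  # exactly one most-limiting factor chain per taxon and date
  one <- rec[rec$taxon_id == rec$taxon_id[1], ]
  hits <- tapply(one$most_limiting, one$time, any)
  expect_true(all(hits))
})

test_that("limitation factors saturate under replete constant conditions", {
  cfg <- tiny_config()
  st <- tiny_state(cfg, no3 = 1e6, nh4 = 1e6, po4 = 1e6, si = 1e6,
                   dom = 1e6)
  tr <- simulate_ecosystem(cfg, st, const_forcing(1, temp = 15, par = 1e9,
                                                  daylength = 24),
                           t0 = 0, t1 = 1)
  lim <- limitation_timeseries(tr, taxa = c("p1", "h1"))
  expect_true(all(lim$value[lim$factor != "f_S"] > 0.99))
})

test_that("network snapshots balance node sizes against edge fluxes", {
  truth <- default_truth()
  snap <- network_snapshot(truth$trajectory,
                           truth$blooms$peak[truth$blooms$bloom_type ==
                                               "bacteria_summer"][1])
  expect_true(all(snap$edges$flux > 0))
  hetn <- snap$nodes[snap$nodes$class == "heterotroph", ]
  k <- which.max(hetn$size)
  expect_equal(hetn$size[k],
               sum(snap$edges$flux[snap$edges$to == hetn$id[k]]))
})
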