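test_that("seasonal forcing is smooth, bounded and deterministic", {
  sc <- synthetic_scenario(seed = 2, years = 1)
  f <- generate_forcing(sc)
  expect_equal(nrow(f), 366) # days 0..365 inclusive
  expect_true(all(f$daylength >= 8 & f$daylength <= 16.5))
  expect_true(all(f$par > 0))
  expect_equal(f, generate_forcing(synthetic_scenario(seed = 9, years = 1)))
  flat <- generate_forcing(synthetic_scenario(seed = 2, years = 1,
                                              temp_amp = 0))
  expect_equal(length(unique(flat$temp)), 1)
  # temperature peaks near the configured day of year
  expect_equal(f$time[which.max(f$temp[1:365])] , sc$temp_peak_day,
               tolerance = 1)
})

test_that("the ground-truth run shows the three-bloom seasonal regime", {
  truth <- default_truth()
  for (y in c(2015, 2016)) {
    bl <- truth$blooms[truth$blooms$year == y, ]
    expect_setequal(bl$bloom_type,
                    c("phyto_spring", "bacteria_summer", "phyto_summer"))
  }
  pw <- default_pairwise()
  sh <- function(ty, y) hp_flux_share(pw, truth$blooms[
    truth$blooms$bloom_type == ty & truth$blooms$year == y, ])
  # internal recycling matters in the bacteria bloom, not in spring
  expect_gt(sh("bacteria_summer", 2015), sh("phyto_spring", 2015))
  expect_gt(sh("bacteria_summer", 2016), sh("phyto_spring", 2016))
})

test_that("weekly sampling yields 52 valid observation dates per year", {
  truth <- default_truth()
  obs <- sample_observations(truth, synthetic_scenario(seed = 6, years = 1))
  expect_equal(length(obs$dates), 52)
  expect_s3_class(validate_observations(obs), "observation_set")
  expect_true(all(obs$asv18s == round(obs$asv18s)))
  expect_true(all(obs$asv16s >= 0))
  expect_equal(unname(colSums(obs$asv16s)),
               rep(20000, 52)) # configured read depth
  # same seed, byte-identical outputs
  obs2 <- sample_observations(truth, synthetic_scenario(seed = 6,
                                                        years = 1))
  expect_identical(obs, obs2)
})

test_that("the noiseless limit recovers true fractions and carbon", {
  truth <- default_truth()
  sc <- synthetic_scenario(seed = 8, chl_sigma = 0, nutrient_sigma = 0,
                           count_sigma = 0, dm_overdispersion = 1e9,
                           read_depth_18s = 2e6L, read_depth_16s = 2e6L)
  obs <- sample_observations(truth, sc)
  traj <- truth$trajectory
  idx <- which(traj$time %% 7 == 3 & traj$time <= 730)
  syn <- vapply(sc$config$phyto, `[[`, TRUE, "synechococcus")
  true_euk <- rowSums(traj$phyto_c[idx, !syn, drop = FALSE])
  # chlorophyll round trip equals true eukaryote carbon at sigma 0
  expect_equal(chl_to_carbon(obs$chlorophyll), true_euk, tolerance = 1e-9)
  # read fractions approach true carbon fractions at high depth
  cobs <- carbonize_observations(obs)
  ids <- rownames(cobs$phyto_otu_c)
  rel <- abs(t(cobs$phyto_otu_c[ids, ]) - traj$phyto_c[idx, ids]) /
    (true_euk + 1e-6)
  expect_lt(max(rel), 0.02)
})

test_that("ingest round-trip error shrinks with read depth", {
  truth <- default_truth()
  rmse_at <- function(depth) {
    sc <- synthetic_scenario(seed = 9, chl_sigma = 0, count_sigma = 0,
                             nutrient_sigma = 0,
                             read_depth_16s = as.integer(depth),
                             dm_overdispersion = 1e9)
    cobs <- carbonize_observations(sample_observations(truth, sc))
    traj <- truth$trajectory
    idx <- which(traj$time %% 7 == 3 & traj$time <= 730)
    het_true <- t(traj$het_active_c[idx, ] + traj$het_dormant_c[idx, ])
    sqrt(mean((cobs$het_asv_c - het_true)^2))
  }
  expect_lt(rmse_at(2e5), rmse_at(500))
})

test_that("sampled observations ingest into a consistent carbon set", {
  truth <- default_truth()
  obs <- sample_observations(truth, synthetic_scenario(seed = 10))
  cobs <- carbonize_observations(obs)
  expect_equal(rownames(cobs$phyto_otu_c),
               sort(c("diatom_spring", "pico_prasinophyte",
                      "summer_flagellate", "dinoflagellate")))
  expect_setequal(rownames(cobs$het_asv_c),
                  c("PLAx", "TENx", "SAR11x", "ROSx", "FLAVx", "GAMx",
                    "ALTx", "ARCx"))
})
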