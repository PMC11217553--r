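# A small simulated world reused across calibration tests.
calib_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- synthetic_scenario(seed = 11, years = 1)
      truth <- suppressWarnings(generate_ground_truth(sc))
      obs <- sample_observations(truth, sc)
      cache <<- list(sc = sc, truth = truth,
                     cobs = carbonize_observations(obs),
                     forcing = truth$forcing[truth$forcing$time <= 365, ])
    }
    cache
  }
})

test_that("the objective is zero at a perfect fit and grows with residuals", {
  w <- calib_world()
  traj <- w$truth$trajectory
  # fabricate observations equal to the model at weekly dates
  idx <- which(traj$time %% 7 == 3)
  syn <- vapply(w$sc$config$phyto, `[[`, TRUE, "synechococcus")
  perfect <- list(
    dates = w$sc$origin + traj$time[idx],
    phyto_otu_c = t(traj$phyto_c[idx, !syn, drop = FALSE]),
    syn_c = rowSums(traj$phyto_c[idx, syn, drop = FALSE]),
    het_asv_c = t(traj$het_active_c[idx, ] + traj$het_dormant_c[idx, ]),
    total_phyto_c = rowSums(traj$phyto_c[idx, ]),
    total_het_c = rowSums(traj$het_active_c[idx, ] +
                            traj$het_dormant_c[idx, ]),
    nutrients = list())
  expect_equal(objective_score(traj, perfect), 0)
  # a single 10x residual in one series contributes ~1 per unit weight
  bump <- perfect
  bump$het_asv_c["SAR11x", 5] <- 10 * bump$het_asv_c["SAR11x", 5]
  sc <- objective_score(traj, bump,
                        weights = c(total_het = 0, total_phyto = 0))
  expect_equal(sc, 1, tolerance = 0.05)
  # growing the residual strictly grows the score
  worse <- perfect
  worse$het_asv_c["SAR11x", 5] <- 100 * worse$het_asv_c["SAR11x", 5]
  sc2 <- objective_score(traj, worse,
                         weights = c(total_het = 0, total_phyto = 0))
  expect_gt(sc2, sc)
  # missing observations are skipped, not scored
  holes <- perfect
  holes$total_phyto_c[3:10] <- NA
  expect_equal(objective_score(traj, holes), 0)
})

test_that("perturbation proposals respect sigma, bounds and the seed", {
  w <- calib_world()
  bounds <- default_parameter_bounds()
  free <- c("phyto/diatom_spring/mu_max", "het/TENx/v_max",
            "het/TENx/yield")
  set.seed(1)
  same <- propose_perturbation(w$sc$config, free, bounds, sigma = 0)
  expect_equal(same, w$sc$config)
  set.seed(7)
  a <- propose_perturbation(w$sc$config, free, bounds, sigma = 0.5)
  set.seed(7)
  b <- propose_perturbation(w$sc$config, free, bounds, sigma = 0.5)
  expect_identical(a, b)
  # heavy perturbations stay inside bounds
  cfg <- w$sc$config
  set.seed(42)
  for (i in 1:50) {
    cfg <- propose_perturbation(cfg, free, bounds, sigma = 1.5)
    for (p in free) {
      nm <- utils::tail(strsplit(p, "/")[[1]], 1)
      v <- config_get(cfg, p)
      expect_gte(v, bounds[[nm]][1])
      expect_lte(v, bounds[[nm]][2])
    }
  }
})

test_that("hill climbing is greedy, reproducible and monotone", {
  w <- calib_world()
  free <- c("phyto/diatom_spring/mu_max", "het/TENx/v_max")
  f0 <- calibrate_year(w$sc$config, w$cobs, w$forcing, free = free,
                       iterations = 0, seed = 5, origin = w$sc$origin)
  expect_equal(f0$best_config, w$sc$config)
  expect_equal(nrow(f0$acceptance_trace), 1)
  fit <- calibrate_year(w$sc$config, w$cobs, w$forcing, free = free,
                        iterations = 40, seed = 5, origin = w$sc$origin)
  expect_true(all(diff(fit$acceptance_trace$objective) <= 0))
  expect_lte(fit$objective_value, f0$objective_value)
  again <- calibrate_year(w$sc$config, w$cobs, w$forcing, free = free,
                          iterations = 40, seed = 5, origin = w$sc$origin)
  expect_identical(fit$acceptance_trace, again$acceptance_trace)
  expect_equal(fit$objective_value, again$objective_value)
})

test_that("delumping splits parents by observed member fractions", {
  cfg <- tiny_config()
  st <- tiny_state(cfg, phyto = 2)
  members <- list(p1 = c("p1a", "p1b"))
  obs <- matrix(c(0.75, 0.25), 2, 1, dimnames = list(c("p1a", "p1b"), NULL))
  out <- delump_taxa(cfg, st, members, member_obs = obs, jitter_sigma = 0)
  expect_equal(length(out$config$phyto), 2)
  expect_equal(unname(out$state$phyto_c[c("p1a", "p1b")]), c(1.5, 0.5))
  expect_equal(sum(out$state$phyto_c), 2)
  # parameters inherited exactly at zero jitter
  expect_equal(out$config$phyto[[1]]$mu_max, cfg$phyto[[1]]$mu_max)
  # single member, zero jitter: identical model under a new name
  one <- delump_taxa(cfg, st, list(p1 = "p1x"),
                     member_obs = matrix(1, 1, 1,
                                         dimnames = list("p1x", NULL)),
                     jitter_sigma = 0)
  expect_equal(one$config$phyto[[1]]$kd, cfg$phyto[[1]]$kd)
  expect_equal(unname(one$state$phyto_c["p1x"]), 2)
  # missing fractions fall back to an equal split with a warning
  expect_warning(
    eq <- delump_taxa(cfg, st, members, member_obs = NULL,
                      jitter_sigma = 0),
    "equally")
  expect_equal(unname(eq$state$phyto_c[c("p1a", "p1b")]), c(1, 1))
  # taxon count bookkeeping for heterotroph parents
  h <- delump_taxa(cfg, st, list(h1 = c("h1a", "h1b", "h1c")),
                   member_obs = matrix(c(2, 1, 1), 3, 1,
                                       dimnames = list(c("h1a", "h1b",
                                                         "h1c"), NULL)),
                   jitter_sigma = 0)
  expect_equal(length(h$config$het), 3)
  expect_equal(sum(h$state$het_active_c), sum(st$het_active_c))
})

test_that("the year-start state is built from first observations", {
  w <- calib_world()
  st <- state_from_observations(w$sc$config, w$cobs)
  first_ok <- which(!is.na(w$cobs$phyto_otu_c["diatom_spring", ]))[1]
  expect_equal(unname(st$phyto_c["diatom_spring"]),
               unname(w$cobs$phyto_otu_c["diatom_spring", first_ok]))
  expect_equal(unname(st$het_active_c["PLAx"] + st$het_dormant_c["PLAx"]),
               unname(w$cobs$het_asv_c["PLAx", 1]), tolerance = 1e-9)
  expect_equal(st$no3, w$cobs$nutrients$no3no2[1])
})
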