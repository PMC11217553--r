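test_that("chlorophyll conversion preserves the 40 g/g carbon ratio", {
  # carbon mass back from umol C L-1 (= mmol m-3): x umol * 12.011 ug/umol
  chl <- c(0.3, 1, 2.5)
  carbon_ug_l <- chl_to_carbon(chl) * 12.011
  expect_equal(carbon_ug_l / chl, rep(40, 3))
  expect_equal(chl_to_carbon(0), 0)
  expect_equal(chl_to_carbon(1), 3.3303, tolerance = 1e-4)
  expect_error(chl_to_carbon(-1), "chlorophyll")
})

test_that("cell count conversion applies the per-cell quota", {
  expect_equal(cells_to_carbon(1), 1.4e-8)
  expect_equal(cells_to_carbon(0), 0)
  expect_equal(cells_to_carbon(1e7), 0.14)
  expect_equal(cells_to_carbon(1e9, mol_c_per_cell = 2e-15), 2)
  expect_error(cells_to_carbon(-5), "counts")
})

test_that("carbon conversions are linear and homogeneous", {
  for (a in c(0, 0.5, 3, 17)) {
    expect_equal(chl_to_carbon(a * 1.7), a * chl_to_carbon(1.7))
    expect_equal(cells_to_carbon(a * 1e6), a * cells_to_carbon(1e6))
  }
})

make_table <- function(totals) {
  m <- matrix(totals / 2, length(totals), 2,
              dimnames = list(names(totals), c("2015-01-01", "2015-01-08")))
  m
}

test_that("abundance prefilter keeps the top n with deterministic ties", {
  tab <- make_table(c(a = 5, b = 5, c = 1))
  expect_identical(rownames(prefilter_top_n(tab, 2)), c("a", "b"))
  big <- make_table(stats::setNames(1200:1, paste0("asv", sprintf("%04d", 1:1200))))
  expect_equal(nrow(prefilter_top_n(big, 1000)), 1000)
  expect_identical(prefilter_top_n(tab, 10000), tab)
  # idempotence
  once <- prefilter_top_n(big, 1000)
  expect_identical(prefilter_top_n(once, 1000), once)
  empty <- big[integer(0), , drop = FALSE]
  expect_equal(nrow(prefilter_top_n(empty, 5)), 0)
})

tax18 <- data.frame(
  asv_id = c("a1", "a2", "a3", "a4"),
  lineage = c("Euk;Chlorophyta;Micromonas", "Euk;Chlorophyta;Micromonas",
              "Euk;Ciliophora;Strombidium", "Euk;Dinophyceae;Tripos"),
  trophy = c("phototrophic", "phototrophic", "heterotrophic",
             "phototrophic"))

test_that("18S classification drops heterotrophs and lumps by finest name", {
  tab <- make_table(c(a1 = 10, a2 = 6, a3 = 4, a4 = 2))
  otu <- classify_and_lump_18s(tab, tax18)
  expect_identical(rownames(otu), c("Micromonas", "Tripos"))
  expect_equal(unname(rowSums(otu)["Micromonas"]), 16)
  # single phototrophic ASV passes through unchanged
  one <- classify_and_lump_18s(tab["a4", , drop = FALSE], tax18)
  expect_equal(unname(one["Tripos", ]), unname(tab["a4", ]))
  # all heterotrophic: empty table with a warning
  expect_warning(
    empty <- classify_and_lump_18s(tab["a3", , drop = FALSE], tax18),
    "empty")
  expect_equal(nrow(empty), 0)
  # unknown ASV treated as unassigned, with a message
  expect_message(
    out <- classify_and_lump_18s(make_table(c(a1 = 4, zz = 3)), tax18),
    "unassigned")
  expect_identical(rownames(out), "Micromonas")
})

test_that("16S filter removes chloroplast/unassigned/cyano/AOA lineages", {
  tax16 <- data.frame(
    asv_id = paste0("b", 1:5),
    lineage = c("Bacteria;Alphaproteobacteria;SAR11",
                "Bacteria;Cyanobacteria;Chloroplast",
                "Bacteria;Bacteroidetes;Flavo",
                "unassigned",
                "Archaea;Thaumarchaeota;Nitrosopumilus"))
  tab <- make_table(stats::setNames(5:1, paste0("b", 1:5)))
  kept <- filter_16s(tab, tax16)
  expect_identical(rownames(kept), c("b1", "b3"))
  ok <- tab[c("b1", "b3"), ]
  expect_identical(filter_16s(ok, tax16), ok)
  expect_warning(
    none <- filter_16s(tab[c("b2", "b4"), ], tax16), "excluded")
  expect_equal(nrow(none), 0)
})

test_that("read fractions scale pool carbon and conserve the total", {
  fr <- matrix(c(0.25, 0.5, 0.5, 0.5), 2,
               dimnames = list(c("x", "y"), NULL))
  pool <- c(4, 2)
  out <- reads_to_carbon(fr, pool)
  expect_equal(out["x", 1], 1.0, ignore_attr = TRUE)
  expect_equal(colSums(reads_to_carbon(matrix(c(0.5, 0.5), 2), 2)), 2)
  expect_equal(reads_to_carbon(matrix(0, 1), 5)[1], 0, ignore_attr = TRUE)
  expect_error(reads_to_carbon(matrix(c(0.7, 0.6), 2), 1), "more than 1")
})

test_that("nutrient loadings are the non-negative increments", {
  d <- as.Date("2015-01-01") + c(0, 7, 14, 21)
  out <- derive_nutrient_loadings(d, c(5, 7, 5, 5))
  expect_equal(out$loading, c(2, 0, 0))
  expect_equal(out$rate[1], 2 / 7)
  expect_equal(derive_nutrient_loadings(d, rep(3, 4))$loading, rep(0, 3))
  expect_equal(nrow(derive_nutrient_loadings(d[1], 5)), 0)
})

test_that("observation files round-trip through the CSV dialect", {
  truth <- default_truth()
  sc <- synthetic_scenario(seed = 3)
  obs <- sample_observations(truth, sc)
  dir <- withr::local_tempdir()
  write_observation_csvs(obs, dir)
  back <- read_observations(dir)
  expect_equal(back$dates, obs$dates)
  expect_equal(back$chlorophyll, obs$chlorophyll, tolerance = 1e-8)
  expect_equal(back$asv18s, obs$asv18s, ignore_attr = TRUE)
  expect_equal(back$nutrients$po4, obs$nutrients$po4, tolerance = 1e-8)
})

test_that("date union keeps extra dates with missing values, never zeros", {
  truth <- default_truth()
  obs <- sample_observations(truth, synthetic_scenario(seed = 3))
  dir <- withr::local_tempdir()
  write_observation_csvs(obs, dir)
  nut <- read.csv(file.path(dir, "nutrients.csv"))
  nut <- rbind(nut, data.frame(date = "2019-06-05", no3no2 = 1, nh4 = 0.1,
                               po4 = 0.05, si = 0.5))
  write.csv(nut, file.path(dir, "nutrients.csv"), row.names = FALSE)
  back <- read_observations(dir)
  extra <- as.Date("2019-06-05")
  expect_true(extra %in% back$dates)
  k <- match(extra, back$dates)
  expect_equal(back$nutrients$no3no2[k], 1)
  expect_true(is.na(back$chlorophyll[k]))
  expect_true(all(is.na(back$asv18s[, as.character(extra)])))
})

test_that("invalid observation values are rejected", {
  truth <- default_truth()
  obs <- sample_observations(truth, synthetic_scenario(seed = 3))
  dir <- withr::local_tempdir()
  write_observation_csvs(obs, dir)
  chl <- read.csv(file.path(dir, "chlorophyll.csv"))
  chl$chl_mg_m3[2] <- -1
  write.csv(chl, file.path(dir, "chlorophyll.csv"), row.names = FALSE)
  expect_error(read_observations(dir), "chlorophyll")
  # unparseable date
  write.csv(data.frame(date = "06/05/2015", chl_mg_m3 = 1),
            file.path(dir, "chlorophyll.csv"), row.names = FALSE)
  expect_error(read_observations(dir), "ISO-8601")
})

test_that("ingested OTU carbon sums to chlorophyll-derived phytoplankton carbon", {
  truth <- default_truth()
  obs <- sample_observations(truth, synthetic_scenario(seed = 4))
  cobs <- carbonize_observations(obs)
  ok <- !is.na(cobs$euk_phyto_c)
  expect_equal(colSums(cobs$phyto_otu_c)[ok], cobs$euk_phyto_c[ok],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(cobs$het_asv_c >= 0, na.rm = TRUE))
  ok16 <- !is.na(cobs$total_het_c)
  expect_equal(colSums(cobs$het_asv_c)[ok16], cobs$total_het_c[ok16],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("an all-zero observation set yields all-zero carbon without error", {
  truth <- default_truth()
  obs <- sample_observations(truth, synthetic_scenario(seed = 5))
  obs$chlorophyll[] <- 0
  obs$syn_counts[] <- 0
  obs$het_counts[] <- 0
  obs$asv18s[] <- 0
  obs$asv16s[] <- 0
  for (nm in names(obs$nutrients)) obs$nutrients[[nm]][] <- 0
  cobs <- carbonize_observations(obs)
  expect_true(all(unlist(cobs[c("total_phyto_c", "phyto_otu_c", "syn_c",
                                "het_asv_c", "total_het_c")]) == 0))
})
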