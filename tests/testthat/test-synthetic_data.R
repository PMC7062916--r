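test_that("study generation is deterministic under a fixed seed", {
  a <- generate_study(small_config(seed = 9L))
  b <- generate_study(small_config(seed = 9L))
  expect_identical(a$stems, b$stems)
  expect_identical(a$wd_samples, b$wd_samples)
  expect_identical(a$soils, b$soils)
  expect_identical(a$climate, b$climate)
  c2 <- generate_study(small_config(seed = 10L))
  expect_false(identical(a$stems, c2$stems))
})

test_that("every generated table round-trips through its reader", {
  dir <- tempfile()
  st <- generate_study(small_config(seed = 2L), dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("census.csv", "wd_samples.csv", "soils.csv", "climate.csv",
           "plots.csv", "ground_truth.json")))))
  census <- read_census(file.path(dir, "census.csv"))
  expect_equal(nrow(census$stems), nrow(st$stems))
  plots <- read_plots(file.path(dir, "plots.csv"))
  expect_equal(plots$plot_id, st$plots$plot_id)
  soils <- read_soils(file.path(dir, "soils.csv"))
  expect_equal(soils$c_gkg, st$soils$c_gkg, tolerance = 1e-9)
  samples <- read_wd_samples(file.path(dir, "wd_samples.csv"))
  expect_equal(nrow(samples), nrow(st$wd_samples))
  clim <- read_climate(file.path(dir, "climate.csv"))
  expect_equal(nrow(clim), nrow(st$plots))
  # writing the same seed twice is byte-identical
  dir2 <- tempfile()
  generate_study(small_config(seed = 2L), dir = dir2)
  for (f in c("census.csv", "soils.csv", "climate.csv")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("generated censuses respect the design invariants", {
  st <- generate_study(small_config(seed = 13L))
  expect_true(all(st$stems$dbh_cm >= 2.5))
  woody <- st$stems$growth_form %in% c("tree", "palm")
  expect_true(all(!is.na(st$stems$height_m[woody])))
  expect_true(all(st$stems$height_m[woody] > 0))
  expect_true(all(st$stems$growth_form %in%
                    c("tree", "palm", "liana", "tree_fern")))
  # some multi-stemmed individuals exist and aggregate correctly
  census <- validate_stems(st$stems)
  expect_gt(max(census$individuals$n_stems), 1L)
  expect_true(all(census$individuals$dbh_cm + 1e-9 >=
                    tapply(st$stems$dbh_cm,
                           paste(st$stems$plot_id, st$stems$individual_id,
                                 sep = "\r"), max)[
                      paste(census$individuals$plot_id,
                            census$individuals$individual_id,
                            sep = "\r")]))
})

test_that("planted trend coefficients match the configured toggles", {
  cfg <- study_config(seed = 1L)
  st <- generate_study(cfg)
  co <- st$ground_truth$coefficients
  a_co <- co$gradient_A
  expect_equal(-a_co[["b"]] / (2 * a_co[["c"]]), cfg$agc_peak_m)
  expect_equal(1 / (a_co[["a"]] + a_co[["b"]] * cfg$agc_peak_m +
                      a_co[["c"]] * cfg$agc_peak_m^2), cfg$agc_peak_mu)
  b_co <- co$gradient_B
  expect_equal(b_co[["b"]], 0)
  expect_equal(b_co[["c"]], 0)
  # total invariance: expected totals constant over plots within a site
  ex <- st$ground_truth$expected
  for (s in cfg$sites) {
    tot <- ex$total_mu[ex$site == s]
    expect_lt(diff(range(tot)), 1e-9)
  }
})

test_that("invalid configurations are rejected before generation", {
  cfg <- study_config()
  cfg$liana_fraction <- 1.2
  expect_error(validate_config(cfg), "rates")
  cfg <- study_config()
  cfg$belt_bands$mid <- c(900, 2100)
  expect_error(validate_config(cfg), "overlap")
  cfg <- study_config()
  cfg$agc_trend[["gradient_A"]] <- "cubic"
  expect_error(validate_config(cfg), "unimodal")
  cfg <- study_config()
  cfg$plot_area_ha <- 0
  expect_error(generate_study(cfg), "positive")
})

test_that("routing toggles remove lianas and tree ferns when zeroed", {
  cfg <- small_config(seed = 21L)
  cfg$liana_fraction <- 0
  cfg$tree_fern_fraction <- 0
  st <- generate_study(cfg)
  expect_true(all(st$stems$growth_form %in% c("tree", "palm")))
  est <- estimate_stocks(st$stems, st$wd_samples, st$soils, st$plots)
  bio <- individual_biomass(est$individuals)
  expect_true(all(bio$equation_used[bio$agb_kg > 0] == "chave3"))
})
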