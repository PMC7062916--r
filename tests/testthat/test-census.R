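test_that("combined_dbh implements the root-sum-of-squares rule", {
  expect_equal(combined_dbh(10), 10)
  expect_equal(combined_dbh(c(3, 4)), 5)
  expect_equal(combined_dbh(c(2.5, 2.5, 2.5)), 4.33012701892219,
               tolerance = 1e-12)
  expect_error(combined_dbh(numeric(0)), "at least one")
  expect_error(combined_dbh(c(3, -1)), "positive")
})

test_that("combined_dbh is permutation-invariant, monotone and additive", {
  set.seed(11)
  for (k in 1:25) {
    x <- runif(sample(1:6, 1), 2.5, 60)
    y <- runif(sample(1:4, 1), 2.5, 60)
    expect_equal(combined_dbh(x[sample.int(length(x))]), combined_dbh(x))
    expect_equal(combined_dbh(c(x, y))^2,
                 combined_dbh(x)^2 + combined_dbh(y)^2)
    x_up <- x
    x_up[1] <- x_up[1] + 1
    expect_gt(combined_dbh(x_up), combined_dbh(x))
  }
})

test_that("individual height is the tallest stem's height", {
  expect_equal(individual_height(12), 12)
  expect_equal(individual_height(c(5, 9, 7.5)), 9)
  expect_equal(individual_height(c(6, 6, 6)), 6)
  expect_true(is.na(individual_height(c(NA_real_, NA_real_))))
  expect_equal(individual_height(c(NA, 4)), 4)
  expect_error(individual_height(numeric(0)), "at least one")
})

test_that("read_census assembles individuals from shared individual ids", {
  path <- write_tiny_census()
  res <- read_census(path)
  expect_equal(nrow(res$stems), 3)
  expect_equal(nrow(res$individuals), 2)
  i1 <- res$individuals[res$individuals$individual_id == "i1", ]
  expect_equal(i1$dbh_cm, sqrt(10^2 + 5^2))
  expect_equal(i1$height_m, 12)
  expect_equal(i1$n_stems, 2L)
  # effective DBH never below the largest stem
  expect_true(all(res$individuals$dbh_cm >=
                    tapply(res$stems$dbh_cm, res$stems$individual_id, max)[
                      res$individuals$individual_id] - 1e-12))
})

test_that("census validation names offending rows and columns", {
  stems <- tiny_census()
  stems$dbh_cm[2] <- 1.0
  path <- write_tiny_census(stems)
  expect_error(read_census(path), "2.5 cm census threshold.*row\\(s\\) 2")
  expect_warning(res <- read_census(path, on_small_dbh = "drop"),
                 "dropping 1 stem")
  expect_equal(nrow(res$stems), 2)

  stems <- tiny_census()
  stems$growth_form <- NULL
  path <- write_tiny_census(stems)
  expect_error(read_census(path), "lacks mandatory column")

  stems <- tiny_census()
  stems$growth_form[1] <- "shrub"
  expect_error(validate_stems(stems), "unknown growth_form")
})

test_that("a generated census round-trips through the reader", {
  st <- generate_study(small_config())
  path <- tempfile(fileext = ".csv")
  write_census(st$stems, path)
  back <- read_census(path)
  expect_equal(back$stems$dbh_cm, st$stems$dbh_cm)
  expect_equal(back$stems$individual_id, st$stems$individual_id)
  expect_equal(back$stems$species, st$stems$species)
  # all census stems respect the inclusion threshold
  expect_true(all(back$stems$dbh_cm >= 2.5))
})

test_that("plot metadata is validated against belt altitude bands", {
  plots <- data.frame(plot_id = c("a", "b"), site = "gradient_A",
                      belt = c("low", "high"), altitude_m = c(900, 2800),
                      area_ha = 0.1)
  path <- tempfile(fileext = ".csv")
  write.csv(plots, path, row.names = FALSE)
  expect_silent(read_plots(path))
  plots$altitude_m[2] <- 1500
  write.csv(plots, path, row.names = FALSE)
  expect_error(read_plots(path), "outside its 'high' band")
})
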