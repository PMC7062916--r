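test_that("precipitation seasonality is SD as percent of mean", {
  expect_equal(precipitation_seasonality(rep(85, 12)), 0)
  # alternating series: mean 100, population SD 20
  alt <- rep(c(120, 80), 6)
  expect_equal(precipitation_seasonality(alt), 20)
  expect_equal(precipitation_seasonality(alt, sd_type = "sample"),
               100 * sd(alt) / 100)
  # scale invariance
  set.seed(41)
  for (k in 1:15) {
    x <- runif(12, 10, 300)
    expect_equal(precipitation_seasonality(3.7 * x),
                 precipitation_seasonality(x))
  }
  expect_error(precipitation_seasonality(rep(0, 12)), "zero mean")
  expect_error(precipitation_seasonality(1:11), "12 non-negative")
})

test_that("the extreme-month range is four seasonality units", {
  expect_equal(expected_extreme_range(50), 200)
  expect_equal(expected_extreme_range(10), 40)
  expect_equal(expected_extreme_range(0), 0)
  # linearity and the exact-quantile variant
  expect_equal(expected_extreme_range(c(5, 25)), c(20, 100))
  expect_equal(expected_extreme_range(50, z = 1.96), 196)
  expect_error(expected_extreme_range(-1), "non-negative")
})

test_that("the correlation screen partitions represented and retained", {
  set.seed(43)
  n <- 200
  t1 <- rnorm(n)
  tab <- data.frame(t1 = t1, dup = t1, corr = t1 + rnorm(n, 0, 0.1),
                    noise = rnorm(n), const = 1)
  res <- correlation_screen(tab, "t1")
  expect_equal(res$status[res$variable == "t1"], "reference")
  expect_equal(res$status[res$variable == "dup"], "represented")
  expect_equal(res$status[res$variable == "corr"], "represented")
  expect_equal(res$status[res$variable == "noise"], "retained")
  expect_equal(res$status[res$variable == "const"], "undefined")
  # strict threshold 1.0: only exact duplicates would exceed it, none do
  res1 <- correlation_screen(tab[, 1:4], "t1", threshold = 1.0)
  expect_true(all(res1$status[res1$variable != "t1"] == "retained"))
  expect_error(correlation_screen(tab, "absent"), "no column")
})

test_that("generated monthly series hit the seasonality target exactly", {
  set.seed(44)
  expect_equal(generate_monthly_precip(1200, 0), rep(100, 12))
  for (ps in c(10, 27, 50, 65)) {
    x <- generate_monthly_precip(1200, ps)
    expect_true(all(x >= 0))
    expect_equal(mean(x), 100, tolerance = 1e-9)
    expect_equal(precipitation_seasonality(x), ps, tolerance = 1e-9)
  }
  expect_error(generate_monthly_precip(1200, 340), "feasibility bound")
  expect_error(generate_monthly_precip(1200, 200), "infeasible")
  expect_error(generate_monthly_precip(-5, 10), "positive")
})

test_that("climate reader accepts monthly columns or precomputed PS", {
  st <- generate_study(small_config())
  path <- tempfile(fileext = ".csv")
  write.csv(st$climate, path, row.names = FALSE)
  clim <- read_climate(path)
  expect_true(all(c("precip_seasonality_pct", "annual_precip_mm") %in%
                    names(clim)))
  # planted per-plot seasonality recovered through the full file round trip
  m <- merge(clim, st$ground_truth$ps_planted)
  expect_equal(m$precip_seasonality_pct, m$ps, tolerance = 1e-6)

  pre <- clim[, c("plot_id", "annual_mean_temp_c",
                  "precip_seasonality_pct")]
  write.csv(pre, path, row.names = FALSE)
  clim2 <- read_climate(path)
  expect_equal(clim2$precip_seasonality_pct, clim$precip_seasonality_pct)
  write.csv(pre[, 1:2], path, row.names = FALSE)
  expect_error(read_climate(path), "either precip_seasonality_pct")
})
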