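test_that("degenerate error models reproduce the point estimate exactly", {
  ind <- tiny_individuals()
  ind$wd_sd[1] <- 0
  soc <- data.frame(plot_id = "p1", soc_mgha = 10)
  pc <- assemble_plot_carbon(ind, tiny_plots(), soc)
  res <- propagate_plot(ind, area_ha = 0.1, soc = 10,
                        model = error_model(0, 0, n_iter = 25))
  expect_equal(res$agc$mean, pc$agc)
  expect_equal(res$agc$sd, 0)
  expect_equal(res$bgc$mean, pc$bgc)
  expect_equal(res$total$mean, pc$total)
  expect_equal(res$agc$q025, res$agc$q975)
})

test_that("draws are reproducible under a fixed seed", {
  ind <- tiny_individuals()
  pc <- assemble_plot_carbon(ind, tiny_plots(),
                             data.frame(plot_id = "p1", soc_mgha = 5))
  m <- error_model(n_iter = 200, seed = 99L)
  a <- propagate_uncertainty(pc, ind, model = m)
  b <- propagate_uncertainty(pc, ind, model = m)
  expect_identical(a, b)
  # different seeds agree within Monte-Carlo error (3 standard errors)
  c2 <- propagate_uncertainty(pc, ind, model = error_model(n_iter = 2000,
                                                           seed = 100L))
  d2 <- propagate_uncertainty(pc, ind, model = error_model(n_iter = 2000,
                                                           seed = 101L))
  mc_se <- c2$agc_mc_sd[1] / sqrt(2000)
  expect_lt(abs(c2$agc_mc_mean[1] - d2$agc_mc_mean[1]), 3 * sqrt(2) * mc_se)
})

test_that("perturbed draws match their nominal error distribution", {
  set.seed(77)
  m <- error_model()
  one <- draw_individual(15, 10, 0.6, 0.05, m)
  expect_true(one$h > 0 && one$dbh > 0 && one$wd > 0)
  draws <- replicate(20000, draw_individual(15, 10, 0.6, 0.05, m)$dbh)
  expect_equal(mean(draws), 10, tolerance = 0.01)
  expect_equal(sd(draws), 0.5, tolerance = 0.02)
  expect_error(draw_individual(15, 10, 0.6, 0.05, model = list()),
               "error_model")
  expect_error(error_model(rel_sd_h = -0.1), "non-negative")
  expect_error(error_model(n_iter = 0), ">= 1")
})

test_that("wood-density-only error matches the delta-method slope", {
  # single tree, only WD perturbed: cv(AGC) ~ 0.976 * cv(WD)
  ind <- tiny_individuals()[1, ]
  ind$wd_sd <- 0.05 * ind$wd_mean
  set.seed(55)
  res <- propagate_plot(ind, area_ha = 0.1, soc = 0,
                        model = error_model(rel_sd_h = 0, rel_sd_dbh = 0,
                                            n_iter = 20000))
  cv <- res$agc$sd / res$agc$mean
  expect_equal(cv, 0.976 * 0.05, tolerance = 0.1 * 0.976 * 0.05)
})

test_that("spread grows with the height error and is order-independent", {
  ind <- tiny_individuals()[1, ]
  ind$wd_sd <- 0
  sds <- vapply(c(0, 0.05, 0.10), function(r) {
    set.seed(66)
    propagate_plot(ind, 0.1, 0,
                   error_model(rel_sd_h = r, rel_sd_dbh = 0,
                               n_iter = 4000))$agc$sd
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
  expect_equal(sds[1], 0)

  # two plots: summaries do not depend on processing order
  st <- generate_study(small_config())
  est <- estimate_stocks(st$stems, st$wd_samples, st$soils, st$plots)
  pc <- est$plot_carbon[1:2, ]
  m <- error_model(n_iter = 100, seed = 12L)
  fwd <- propagate_uncertainty(pc, est$individuals, model = m)
  # per-plot substreams are keyed to the plot id, so reordering rows
  # permutes, but never changes, the summaries
  rev2 <- propagate_uncertainty(pc[2:1, ], est$individuals, model = m)
  expect_equal(fwd$agc_mc_mean, rev2$agc_mc_mean[2:1])
  expect_equal(fwd$bgc_mc_sd, rev2$bgc_mc_sd[2:1])
})
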