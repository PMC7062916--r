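simulate_gamma <- function(n, beta, shape = 8, seed = 1,
                           link = "inverse") {
  set.seed(seed)
  x1 <- runif(n)
  x2 <- runif(n)
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2
  mu <- if (link == "inverse") 1 / eta else exp(eta)
  data.frame(y = rgamma(n, shape = shape, rate = shape / mu),
             x1 = x1, x2 = x2)
}

test_that("intercept-only Gamma fits return the sample mean", {
  set.seed(61)
  y <- rgamma(40, shape = 4, rate = 4 / 50)
  d <- data.frame(y = y)
  for (link in c("inverse", "log")) {
    fit <- fit_gamma_glm(y ~ 1, d, link = link)
    expect_equal(unname(fitted(fit$fit)[1]), mean(y), tolerance = 1e-7)
    expect_equal(fit$d_squared, 0)
  }
  expect_error(fit_gamma_glm(y ~ 1, data.frame(y = c(1, 0, 2))),
               "strictly positive")
})

test_that("known Gamma-GLM coefficients are recovered within 3 SE", {
  beta <- c(0.05, 0.02, -0.03)
  d <- simulate_gamma(2000, beta, seed = 62)
  fit <- fit_gamma_glm(y ~ x1 + x2, d)
  z <- (fit$coefficients$estimate - beta) / fit$coefficients$std_error
  expect_true(all(abs(z) < 3))
  # permutation invariance of the fit
  fit2 <- fit_gamma_glm(y ~ x1 + x2, d[sample(nrow(d)), ])
  expect_equal(fit$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("sequential deviance agrees with the analysis-of-deviance oracle", {
  d <- simulate_gamma(300, c(0.05, 0.015, -0.02), seed = 63)
  tab <- sequential_deviance_table("y", c("x1", "x2"), d)
  fit <- glm(y ~ x1 + x2, family = Gamma("inverse"), data = d)
  oracle <- anova(fit, test = "Chisq")
  expect_equal(tab$deviance, oracle$Deviance[2:3], tolerance = 1e-9)
  expect_equal(tab$p_value, oracle$`Pr(>Chi)`[2:3], tolerance = 1e-4)
  expect_equal(attr(tab, "null_deviance"), fit$null.deviance)
  # estimates and SEs come from the full model
  disp <- sum(residuals(fit, "pearson")^2) / df.residual(fit)
  sm <- summary(fit, dispersion = disp)
  expect_equal(tab$estimate, unname(sm$coefficients[2:3, 1]))
  expect_equal(tab$std_error, unname(sm$coefficients[2:3, 2]))
})

test_that("deviance-table rows satisfy the D-squared identity", {
  d <- simulate_gamma(120, c(0.04, 0.02, 0.01), seed = 64)
  tab <- sequential_deviance_table("y", c("x1", "x2"), d)
  null_dev <- attr(tab, "null_deviance")
  expect_equal(tab$d_squared * null_dev, tab$deviance, tolerance = 1e-12)
  expect_true(sum(tab$deviance) <= null_dev + 1e-8)
  # sequential decomposition: per-term D2 sums to the full-model D2
  full <- fit_gamma_glm(y ~ x1 + x2, d)
  expect_equal(sum(tab$d_squared), full$d_squared, tolerance = 1e-12)
})

test_that("explained deviance is the normalised deviance reduction", {
  expect_equal(explained_deviance(10, 6), 0.4)
  expect_equal(explained_deviance(10, 10), 0)
  expect_equal(explained_deviance(10, 0), 1)
  expect_error(explained_deviance(0, 0), "undefined")
  expect_error(explained_deviance(5, 6), "residual")
})

test_that("a duplicated term adds no deviance and is flagged", {
  d <- simulate_gamma(80, c(0.05, 0.02, 0), seed = 65)
  d$x1b <- d$x1
  expect_warning(tab <- sequential_deviance_table("y", c("x1", "x1b"), d),
                 "no degrees of freedom")
  expect_equal(tab$deviance[2], 0, tolerance = 1e-10)
  expect_equal(tab$df[2], 0L)
  expect_true(is.na(tab$p_value[2]))
})

test_that("the quadratic extremum sits at -b/(2c) on the link scale", {
  peak <- quadratic_peak(-7.757e-5, 2.481e-8)
  expect_equal(as.numeric(peak), 1563.28093510681, tolerance = 1e-9)
  expect_equal(attr(peak, "type"), "maximum")
  expect_equal(as.numeric(quadratic_peak(0, 1e-8)), 0)
  expect_equal(as.numeric(quadratic_peak(7.757e-5, -2.481e-8)),
               as.numeric(peak))
  expect_equal(attr(quadratic_peak(-1, 2, link = "log"), "type"), "minimum")
  expect_error(quadratic_peak(1, 0), "no extremum")
})

test_that("altitude and climate model wrappers cover all compartments", {
  st <- generate_study(study_config(seed = 17L, plots_per_belt = 5L,
                                    stems_per_plot = 120))
  est <- estimate_stocks(st$stems, st$wd_samples, st$soils, st$plots)
  clim <- read_climate_table_for_test(st$climate)
  alt <- altitude_models(est$plot_carbon)
  expect_equal(nrow(alt), 2 * 4 * 2)  # sites x responses x terms
  expect_true(all(alt$p_value >= 0 & alt$p_value <= 1))
  expect_true(all(alt$df == 1L))
  cli <- climate_models(est$plot_carbon, clim)
  expect_equal(nrow(cli), 4 * 3)
  expect_true(all(cli$term %in% c("t_c", "ps_pct", "t_c:ps_pct")))
  # missing climate rows are an error, not silent dropping
  expect_error(climate_models(est$plot_carbon, clim[-1, ]),
               "missing for some plots")
})
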