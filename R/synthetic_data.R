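#' Default configuration of a synthetic two-gradient study
#'
#' Describes a synthetic study with the reference design: two sites
#' (gradients), three altitudinal belts per site (low 800-1100 m, mid
#' 1900-2100 m, high 2700-2900 m), ten 0.1-ha plots per belt, around 320
#' individuals per plot above the 2.5 cm DBH census threshold, belt-dependent
#' diameter, height and wood-density distributions, planted wood-density
#' missingness, soil cores with belt-trending bulk density and carbon
#' concentration, and monthly precipitation with controlled seasonality.
#'
#' Plot-level expected aboveground carbon follows an inverse-link polynomial
#' in altitude: site A is unimodal with a peak near 1563 m (the
#' quadratic-trend signature), site B flat. Total carbon is altitude
#' invariant by default, so expected soil carbon is the complement of the
#' biomass compartments. Plot stocks are drawn from a Gamma distribution
#' around these expectations with shape `gamma_shape`.
#'
#' @param seed integer seed driving every random stage.
#' @param plots_per_belt plots per site x belt (default 10).
#' @param stems_per_plot target mean number of individuals per plot
#'   (default 320).
#' @param n_iter unused here; kept by the pipeline configuration.
#' @param gamma_shape Gamma shape of plot-level stock noise (default 8,
#'   i.e. a residual CV of about 0.35).
#' @param agc_trend named character: per-site aboveground trend,
#'   `"unimodal"` or `"flat"`.
#' @param total_invariant named logical: per-site altitude invariance of the
#'   expected total stock.
#' @return A `study_config` list; see the generated object for all tunable
#'   fields (belt bands, allometry parameters, soil and climate trends,
#'   missingness rates).
#' @export
study_config <- function(seed = 1L,
                         plots_per_belt = 10L,
                         stems_per_plot = 320,
                         n_iter = 1000L,
                         gamma_shape = 8,
                         agc_trend = c(gradient_A = "unimodal",
                                       gradient_B = "flat"),
                         total_invariant = c(gradient_A = TRUE,
                                             gradient_B = TRUE)) {
  belts <- c("low", "mid", "high")
  cfg <- list(
    seed = as.integer(seed),
    sites = c("gradient_A", "gradient_B"),
    belts = belts,
    belt_bands = list(low = c(800, 1100), mid = c(1900, 2100),
                      high = c(2700, 2900)),
    plots_per_belt = as.integer(plots_per_belt),
    plot_area_ha = 0.1,
    stems_per_plot = stems_per_plot,
    n_iter = as.integer(n_iter),
    gamma_shape = gamma_shape,
    # composition
    liana_fraction = 0.04,
    tree_fern_fraction = 0.02,
    multi_stem_fraction = 0.10,
    # planted wood-density missingness (fractions of all individuals)
    missing_family_rate = c(gradient_A = 0.062, gradient_B = 0.085),
    missing_drop_rate = c(gradient_A = 0.006, gradient_B = 0.013),
    # aboveground trend on the inverse-link scale
    agc_trend = agc_trend,
    agc_peak_m = 1563.2,
    agc_peak_mu = 95,
    agc_curvature = 2.481e-8,
    agc_flat_mu = 86,
    total_invariant = total_invariant,
    total_mu = c(gradient_A = 245, gradient_B = 212),
    # fallback soil trend when total_invariant is FALSE
    soc_trend = c(gradient_A = "increasing", gradient_B = "saturating"),
    soc_low_mu = c(gradient_A = 80, gradient_B = 45),
    soc_high_mu = c(gradient_A = 170, gradient_B = 58),
    # height allometry H = a * D^b * lognormal(sd = sigma_h)
    height_a = list(gradient_A = c(low = 3.0, mid = 3.2, high = 2.0),
                    gradient_B = c(low = 3.0, mid = 3.0, high = 2.8)),
    height_b = 0.5,
    sigma_h = 0.2,
    # wood density: species lognormal around belt meanlog
    wd_meanlog = list(
      gradient_A = log(c(low = 0.58, mid = 0.60, high = 0.62)),
      gradient_B = log(c(low = 0.62, mid = 0.58, high = 0.54))),
    wd_sdlog_species = 0.15,
    wd_sdlog_within = c(gradient_A = 0.235, gradient_B = 0.275),
    species_per_belt = 60L,
    liana_dbh_rate = 0.5,
    dbh_max_cm = 120,
    # soils (linear belt trends over altitude, site-specific)
    bd_gcm3 = list(gradient_A = c(low = 0.90, mid = 0.65, high = 0.45),
                   gradient_B = c(low = 0.80, mid = 0.55, high = 0.35)),
    fe_range = c(0.75, 0.95),
    ph = list(gradient_A = c(low = 5.0, mid = 4.0, high = 3.0),
              gradient_B = c(low = 6.0, mid = 5.2, high = 4.2)),
    cn = list(gradient_A = c(low = 16, mid = 20, high = 24),
              gradient_B = c(low = 12, mid = 15, high = 18)),
    core_volume_cm3 = 98.17,
    # climate
    temp_sea_level_c = c(gradient_A = 25.67, gradient_B = 30.27),
    lapse_c_per_m = c(gradient_A = 4.81e-3, gradient_B = 6.70e-3),
    ps_pct = list(gradient_A = c(low = 32, mid = 27, high = 30),
                  gradient_B = c(low = 33, mid = 42, high = 50)),
    ps_jitter = 1.5,
    annual_precip_mm = list(
      gradient_A = c(low = 980, mid = 1300, high = 1600),
      gradient_B = c(low = 1800, mid = 1050, high = 2000))
  )
  class(cfg) <- "study_config"
  validate_config(cfg)
  cfg
}

#' Validate a study configuration
#'
#' @param config a `study_config` list.
#' @return The config, invisibly; errors on inconsistency.
#' @export
validate_config <- function(config) {
  rates <- c(config$liana_fraction, config$tree_fern_fraction,
             config$multi_stem_fraction, config$missing_family_rate,
             config$missing_drop_rate)
  if (any(rates < 0) || any(rates > 1)) {
    stop("validate_config(): all rates must lie in [0, 1]", call. = FALSE)
  }
  if (config$liana_fraction + config$tree_fern_fraction >= 1) {
    stop("validate_config(): liana + tree-fern fractions must be < 1",
         call. = FALSE)
  }
  bands <- config$belt_bands
  if (bands$low[2] >= bands$mid[1] || bands$mid[2] >= bands$high[1]) {
    stop("validate_config(): belt altitude bands must not overlap",
         call. = FALSE)
  }
  if (config$plots_per_belt < 1 || config$stems_per_plot <= 0 ||
      config$plot_area_ha <= 0 || config$gamma_shape <= 0) {
    stop("validate_config(): sizes and shapes must be positive",
         call. = FALSE)
  }
  for (s in config$sites) {
    if (!config$agc_trend[[s]] %in% c("unimodal", "flat")) {
      stop("validate_config(): agc_trend must be 'unimodal' or 'flat'",
           call. = FALSE)
    }
  }
  invisible(config)
}

# ---- moment machinery for calibration ------------------------------------

# E[D^q] under a truncated exponential on [dmin, dmax] with rate r.
dbh_moment <- function(q, rate, dmin = 2.5, dmax = 120) {
  z <- 1 - exp(-rate * (dmax - dmin))
  f <- function(d) d^q * rate * exp(-rate * (d - dmin)) / z
  stats::integrate(f, dmin, dmax, rel.tol = 1e-9)$value
}

# E[AGB^m] per woody individual given belt parameters and a DBH rate
# (m = 1 for the mean, 2 for the second moment used by the overshoot
# correction).
woody_agb_moment <- function(rate, h_a, h_b, sigma_h, wd_meanlog, wd_sdlog,
                             dmax = 120, m = 1) {
  p <- 0.976 * m
  e_wd <- exp(p * wd_meanlog + p^2 * wd_sdlog^2 / 2)
  e_eps <- exp(-p * sigma_h^2 / 2 + p^2 * sigma_h^2 / 2)
  e_d <- dbh_moment((2 + h_b) * p, rate, dmax = dmax)
  0.0673^m * e_wd * e_eps * h_a^p * e_d
}

woody_bgb_moment <- function(rate, dmax = 120) {
  0.285 * dbh_moment(1.993, rate, dmax = dmax)
}

liana_agb_moment <- function(rate, dmax = 120, m = 1) {
  exp(-1.484 * m) * dbh_moment(2.657 * m, rate, dmax = dmax)
}

# Calibrate the belt DBH rate so the mean AGB per individual matches the
# target implied by the planted belt-mean AGC and the individuals-per-plot
# design value.
calibrate_dbh_rate <- function(target_agb_kg, h_a, h_b, sigma_h, wd_meanlog,
                               wd_sdlog, p_woody, p_liana, liana_rate,
                               drop_rate, dmax = 120) {
  f <- function(rate) {
    e_mix <- (p_woody - drop_rate) *
      woody_agb_moment(rate, h_a, h_b, sigma_h, wd_meanlog, wd_sdlog,
                       dmax = dmax) +
      p_liana * liana_agb_moment(liana_rate, dmax = dmax)
    e_mix - target_agb_kg
  }
  stats::uniroot(f, c(0.02, 3), tol = 1e-10)$root
}

# ---- planted expectations ------------------------------------------------

#' Planted GLM effects: expected stocks per plot
#'
#' Computes, for each plot, the expected aboveground, belowground, soil and
#' total carbon stocks implied by the configured trend toggles, together
#' with the inverse-link polynomial coefficients that generate them. The
#' belowground expectation is tied to the aboveground one through the
#' belt-level ratio of expected root to shoot biomass per individual (a
#' consequence of generating both compartments from the same stems); with
#' `total_invariant`, the soil expectation is the complement
#' `total - AGC - BGC`.
#'
#' @param config a [study_config()].
#' @param plots plot table with `plot_id`, `site`, `belt`, `altitude_m`.
#' @return List: `expected` (per-plot data frame with `agc_mu`, `bgc_mu`,
#'   `soc_mu`, `total_mu`), `coefficients` (per-site inverse-link `a`, `b`,
#'   `c` for AGC), `dbh_rate` and `bgb_agb_ratio` (site x belt matrices).
#' @export
plant_glm_effects <- function(config, plots) {
  sites <- config$sites
  belts <- config$belts
  coefs <- list()
  agc_mu_fun <- list()
  for (s in sites) {
    if (config$agc_trend[[s]] == "unimodal") {
      cc <- config$agc_curvature
      b <- -2 * cc * config$agc_peak_m
      a <- 1 / config$agc_peak_mu + cc * config$agc_peak_m^2
    } else {
      a <- 1 / config$agc_flat_mu
      b <- 0
      cc <- 0
    }
    coefs[[s]] <- c(a = a, b = b, c = cc)
    agc_mu_fun[[s]] <- local({
      a0 <- a; b0 <- b; c0 <- cc
      function(alt) 1 / (a0 + b0 * alt + c0 * alt^2)
    })
  }

  # belt-level DBH rate calibration and root:shoot ratio
  dbh_rate <- matrix(NA_real_, length(sites), length(belts),
                     dimnames = list(sites, belts))
  ratio <- dbh_rate
  p_fern <- config$tree_fern_fraction
  p_liana <- config$liana_fraction
  p_woody <- 1 - p_liana - p_fern
  for (s in sites) {
    for (b in belts) {
      in_belt <- plots$site == s & plots$belt == b
      mu_belt <- mean(agc_mu_fun[[s]](plots$altitude_m[in_belt]))
      target <- mu_belt * 2 * 1000 * config$plot_area_ha /
        config$stems_per_plot
      dr <- config$missing_drop_rate[[s]]
      r <- calibrate_dbh_rate(
        target, config$height_a[[s]][[b]], config$height_b, config$sigma_h,
        config$wd_meanlog[[s]][[b]], config$wd_sdlog_species,
        p_woody, p_liana, config$liana_dbh_rate, dr,
        dmax = config$dbh_max_cm)
      dbh_rate[s, b] <- r
      e_agb_mix <- (p_woody - dr) *
        woody_agb_moment(r, config$height_a[[s]][[b]], config$height_b,
                         config$sigma_h, config$wd_meanlog[[s]][[b]],
                         config$wd_sdlog_species, dmax = config$dbh_max_cm) +
        p_liana * liana_agb_moment(config$liana_dbh_rate,
                                   dmax = config$dbh_max_cm)
      ratio[s, b] <- (p_woody - dr) *
        woody_bgb_moment(r, dmax = config$dbh_max_cm) / e_agb_mix
    }
  }

  expected <- plots[, c("plot_id", "site", "belt", "altitude_m")]
  expected$agc_mu <- NA_real_
  for (s in sites) {
    i <- expected$site == s
    expected$agc_mu[i] <- agc_mu_fun[[s]](expected$altitude_m[i])
  }
  expected$bgc_mu <- expected$agc_mu *
    ratio[cbind(expected$site, expected$belt)]
  expected$soc_mu <- NA_real_
  for (s in sites) {
    i <- expected$site == s
    if (isTRUE(config$total_invariant[[s]])) {
      expected$soc_mu[i] <- config$total_mu[[s]] - expected$agc_mu[i] -
        expected$bgc_mu[i]
    } else if (config$soc_trend[[s]] == "increasing") {
      band <- range(unlist(config$belt_bands))
      w <- (expected$altitude_m[i] - band[1]) / diff(band)
      expected$soc_mu[i] <- config$soc_low_mu[[s]] +
        w * (config$soc_high_mu[[s]] - config$soc_low_mu[[s]])
    } else { # saturating
      half <- 600
      alt0 <- expected$altitude_m[i] - min(unlist(config$belt_bands))
      expected$soc_mu[i] <- config$soc_low_mu[[s]] +
        (config$soc_high_mu[[s]] - config$soc_low_mu[[s]]) *
        alt0 / (alt0 + half)
    }
  }
  if (any(expected$soc_mu <= 0)) {
    stop("plant_glm_effects(): configuration implies non-positive expected ",
         "soil carbon; lower the biomass expectations or raise total_mu",
         call. = FALSE)
  }
  expected$total_mu <- expected$agc_mu + expected$bgc_mu + expected$soc_mu
  list(expected = expected, coefficients = coefs, dbh_rate = dbh_rate,
       bgb_agb_ratio = ratio)
}

# ---- monthly precipitation ----------------------------------------------

#' Construct a monthly precipitation series with exact moments
#'
#' Builds 12 monthly values with exactly the requested mean (annual total /
#' 12) and population SD (seasonality x mean / 100), by phase-randomised
#' sinusoid plus noise, affinely standardised to the exact first two
#' moments. Seasonality targets above the non-negativity limit of this
#' construction (about 70% for a pure sinusoid) raise an error; the
#' theoretical feasibility bound for any 12-point series is sqrt(11) x 100%.
#'
#' @param annual_mean_mm annual precipitation total (mm), positive.
#' @param target_ps_percent target seasonality (%), non-negative.
#' @return 12 non-negative monthly values (mm); consumes random numbers from
#'   the current RNG stream.
#' @export
generate_monthly_precip <- function(annual_mean_mm, target_ps_percent) {
  if (!is.finite(annual_mean_mm) || annual_mean_mm <= 0) {
    stop("generate_monthly_precip(): annual mean must be positive",
         call. = FALSE)
  }
  if (!is.finite(target_ps_percent) || target_ps_percent < 0) {
    stop("generate_monthly_precip(): seasonality must be non-negative",
         call. = FALSE)
  }
  if (target_ps_percent > 100 * sqrt(11)) {
    stop("generate_monthly_precip(): seasonality above the 12-point ",
         "feasibility bound (", round(100 * sqrt(11), 1), "%)",
         call. = FALSE)
  }
  m <- annual_mean_mm / 12
  s <- target_ps_percent / 100 * m
  if (s == 0) return(rep(m, 12))
  standardise <- function(z) {
    z <- z - mean(z)
    sd_pop <- sqrt(sum(z^2) / 12)
    m + s * z / sd_pop
  }
  for (attempt in seq_len(50L)) {
    phase <- stats::runif(1, 0, 2 * pi)
    z <- cos(2 * pi * (0:11) / 12 + phase) +
      stats::rnorm(12, 0, 0.3)
    x <- standardise(z)
    if (all(x >= 0)) return(x)
  }
  x <- standardise(cos(2 * pi * (0:11) / 12))
  if (all(x >= 0)) return(x)
  stop("generate_monthly_precip(): seasonality ", target_ps_percent,
       "% is infeasible for a non-negative sinusoidal series (limit ~",
       round(100 / sqrt(2), 1), "%)", call. = FALSE)
}

# ---- study generation ----------------------------------------------------

# Inverse-CDF sampler for the truncated exponential DBH distribution.
draw_dbh <- function(n, rate, dmin = 2.5, dmax = 120) {
  u <- stats::runif(n)
  dmin - log(1 - u * (1 - exp(-rate * (dmax - dmin)))) / rate
}

# Build the per-site species pools and the branch-sample table.
build_species_pool <- function(config, site) {
  tag <- sub("gradient_", "", site)
  belts <- config$belts
  n_sp <- config$species_per_belt
  n_fam <- 22L
  fams <- sprintf("fam_%s_%02d", tag, seq_len(n_fam))
  pool <- list()
  samples <- list()
  sigma_w <- config$wd_sdlog_within[[site]]
  for (b in belts) {
    sp <- sprintf("sp_%s_%s_%03d", tag, b, seq_len(n_sp))
    fam <- sample(fams, n_sp, replace = TRUE)
    mu <- exp(stats::rnorm(n_sp, config$wd_meanlog[[site]][[b]],
                           config$wd_sdlog_species))
    n_k <- sample(1:4, n_sp, replace = TRUE,
                  prob = c(0.5, 0.25, 0.15, 0.10))
    rows <- lapply(seq_len(n_sp), function(k) {
      wd <- mu[k] * exp(stats::rnorm(n_k[k], 0, sigma_w) - sigma_w^2 / 2)
      d <- stats::runif(n_k[k], 1.5, 3)
      l <- stats::runif(n_k[k], 8, 12)
      data.frame(species = sp[k], family = fam[k], diameter_cm = d,
                 length_cm = l,
                 dry_mass_g = wd * pi * (d / 2)^2 * l,
                 stringsAsFactors = FALSE)
    })
    pool[[b]] <- data.frame(species = sp, family = fam, wd_true = mu,
                            weight = 0.93^seq_len(n_sp),
                            stringsAsFactors = FALSE)
    samples[[b]] <- do.call(rbind, rows)
  }
  # lianas: site-wide measured species
  liana_sp <- sprintf("liana_%s_%d", tag, 1:6)
  liana_fam <- sample(fams, 6, replace = TRUE)
  liana_rows <- lapply(1:6, function(k) {
    wd <- 0.5 * exp(stats::rnorm(2, 0, sigma_w) - sigma_w^2 / 2)
    d <- stats::runif(2, 1.5, 3)
    l <- stats::runif(2, 8, 12)
    data.frame(species = liana_sp[k], family = liana_fam[k],
               diameter_cm = d, length_cm = l,
               dry_mass_g = wd * pi * (d / 2)^2 * l,
               stringsAsFactors = FALSE)
  })
  list(pool = pool,
       lianas = data.frame(species = liana_sp, family = liana_fam,
                           stringsAsFactors = FALSE),
       ferns = data.frame(species = sprintf("fern_%s_%d", tag, 1:2),
                          family = sprintf("fam_%s_ferns", tag),
                          stringsAsFactors = FALSE),
       unmeasured_families = fams,
       samples = do.call(rbind, c(samples, liana_rows)))
}

# Split an individual's effective DBH into stem DBHs preserving the
# root-sum-of-squares, and stem heights below the individual height.
split_stems <- function(dbh, height, n_stems) {
  w <- stats::runif(n_stems, 0.6, 1.4)
  w <- w / sum(w)
  d <- dbh * sqrt(w)
  if (any(d < 2.5)) return(NULL)
  h <- if (is.na(height)) rep(NA_real_, n_stems) else
    c(height, height * stats::runif(n_stems - 1L, 0.6, 0.95))
  list(dbh = d, height = h)
}

#' Generate a complete synthetic study
#'
#' Generates the four input tables of a study (stem census, branch
#' wood-density samples, per-plot soils, per-plot climate), plus plot
#' metadata and the ground truth that produced them. Every generated table
#' round-trips through the corresponding reader, and the planted
#' wood-density missingness counts are recovered exactly by
#' [wd_imputation_report()].
#'
#' Plot-level stocks are planted first (Gamma draws around the configured
#' trend expectations); the stem list of each plot is then drawn with a
#' Poisson number of individuals whose mean is the planted aboveground
#' biomass target over the expected biomass per individual, making the
#' realised stocks unbiased for the planted means. Soil measurements are
#' back-computed so the fixed-depth SOC formula reproduces the planted soil
#' stock exactly.
#'
#' @param config a [study_config()].
#' @param dir optional output directory; when given, writes `census.csv`,
#'   `wd_samples.csv`, `soils.csv`, `climate.csv`, `plots.csv` and
#'   `ground_truth.json` into it.
#' @return List: `stems`, `wd_samples`, `soils`, `climate`, `plots` (data
#'   frames) and `ground_truth` (planted coefficients, per-plot expected and
#'   target stocks, belt means, missingness counts, seed).
#' @export
generate_study <- function(config = study_config(), dir = NULL) {
  validate_config(config)
  set.seed(config$seed)
  stage_seeds <- sample.int(1e8, 6)

  # plots and altitudes
  set.seed(stage_seeds[1])
  plots <- do.call(rbind, lapply(config$sites, function(s) {
    do.call(rbind, lapply(config$belts, function(b) {
      band <- config$belt_bands[[b]]
      alt <- sort(stats::runif(config$plots_per_belt, band[1], band[2]))
      data.frame(
        plot_id = sprintf("%s_%s_%02d", sub("gradient_", "", s), b,
                          seq_len(config$plots_per_belt)),
        site = s, belt = b, altitude_m = round(alt, 1),
        area_ha = config$plot_area_ha,
        lat = NA_real_, lon = NA_real_, stringsAsFactors = FALSE)
    }))
  }))
  rownames(plots) <- NULL

  planted <- plant_glm_effects(config, plots)
  expected <- planted$expected

  # plot-level Gamma targets
  set.seed(stage_seeds[2])
  k <- config$gamma_shape
  targets <- expected
  targets$agc_target <- stats::rgamma(nrow(targets), shape = k,
                                      rate = k / targets$agc_mu)
  targets$soc_target <- stats::rgamma(nrow(targets), shape = k,
                                      rate = k / targets$soc_mu)

  # species pools and branch samples
  set.seed(stage_seeds[3])
  pools <- lapply(stats::setNames(config$sites, config$sites),
                  function(s) build_species_pool(config, s))
  wd_samples <- do.call(rbind, lapply(config$sites, function(s) {
    cbind(site = s, pools[[s]]$samples, stringsAsFactors = FALSE)
  }))
  rownames(wd_samples) <- NULL

  # census: biomass-bearing stems are drawn iid and kept while they still
  # fit under the plot's planted aboveground-biomass target (greedy fill),
  # so the realised plot stock reproduces the planted Gamma draw to within
  # the smallest stem; tree ferns (no biomass) are appended by proportion
  set.seed(stage_seeds[4])
  p_liana <- config$liana_fraction
  p_fern <- config$tree_fern_fraction
  p_woody <- 1 - p_liana - p_fern
  # species-level wood density the estimation stage will assign (mean of
  # the generated branch samples)
  wd_lookup <- lapply(pools, function(po) {
    tapply(suppressWarnings(branch_density(po$samples$dry_mass_g,
                                           po$samples$diameter_cm,
                                           po$samples$length_cm)),
           po$samples$species, mean)
  })
  q_woody <- p_woody / (p_woody + p_liana)
  draw_batch <- function(n, s, b, rate) {
    form <- sample(c("tree", "liana"), n, replace = TRUE,
                   prob = c(q_woody, 1 - q_woody))
    # a small share of the woody individuals are palms (same allometry)
    form[form == "tree" & stats::runif(n) < 0.03] <- "palm"
    woody <- form %in% c("tree", "palm")
    dbh <- numeric(n)
    height <- rep(NA_real_, n)
    species <- character(n)
    family <- character(n)
    agb <- numeric(n)
    pool <- pools[[s]]$pool[[b]]
    if (any(woody)) {
      nw <- sum(woody)
      dbh[woody] <- draw_dbh(nw, rate, dmax = config$dbh_max_cm)
      height[woody] <- config$height_a[[s]][[b]] *
        dbh[woody]^config$height_b *
        exp(stats::rnorm(nw, 0, config$sigma_h) - config$sigma_h^2 / 2)
      idx <- sample.int(nrow(pool), nw, replace = TRUE, prob = pool$weight)
      species[woody] <- pool$species[idx]
      family[woody] <- pool$family[idx]
      agb[woody] <- 0.0673 * (wd_lookup[[s]][species[woody]] *
                                dbh[woody]^2 * height[woody])^0.976
    }
    liana <- form == "liana"
    if (any(liana)) {
      nl <- sum(liana)
      dbh[liana] <- draw_dbh(nl, config$liana_dbh_rate,
                             dmax = config$dbh_max_cm)
      li <- sample.int(nrow(pools[[s]]$lianas), nl, replace = TRUE)
      species[liana] <- pools[[s]]$lianas$species[li]
      family[liana] <- pools[[s]]$lianas$family[li]
      agb[liana] <- exp(-1.484 + 2.657 * log(dbh[liana]))
    }
    data.frame(growth_form = form, species = species, family = family,
               dbh_cm = dbh, height_m = height, agb_kg = agb,
               stringsAsFactors = FALSE)
  }
  ind_site_count <- stats::setNames(integer(length(config$sites)),
                                    config$sites)
  ind_rows <- vector("list", nrow(plots))
  for (i in seq_len(nrow(plots))) {
    s <- plots$site[i]
    b <- plots$belt[i]
    rate <- planted$dbh_rate[s, b]
    dr <- config$missing_drop_rate[[s]]
    e_w1 <- woody_agb_moment(rate, config$height_a[[s]][[b]],
                             config$height_b, config$sigma_h,
                             config$wd_meanlog[[s]][[b]],
                             config$wd_sdlog_species,
                             dmax = config$dbh_max_cm)
    e_l1 <- liana_agb_moment(config$liana_dbh_rate, dmax = config$dbh_max_cm)
    e_bio <- q_woody * e_w1 + (1 - q_woody) * e_l1
    dr_bio <- dr / (p_woody + p_liana)  # drop rate among biomass stems
    t_kg <- targets$agc_target[i] * 2 * 1000 * config$plot_area_ha
    fill_kg <- t_kg / (1 - dr_bio * e_w1 / e_bio)
    pool_df <- draw_batch(ceiling(fill_kg / e_bio * 1.25) + 40, s, b, rate)
    while (sum(pool_df$agb_kg) < fill_kg * 1.02 + 100) {
      pool_df <- rbind(pool_df, draw_batch(60L, s, b, rate))
    }
    # greedy fill: keep each stem while it still fits under the target
    csum <- 0
    keep <- logical(nrow(pool_df))
    agb <- pool_df$agb_kg
    for (j in seq_along(agb)) {
      if (csum + agb[j] <= fill_kg) {
        keep[j] <- TRUE
        csum <- csum + agb[j]
      }
    }
    batch <- pool_df[keep, , drop = FALSE]
    # zero-biomass tree ferns by proportion
    n_bio <- nrow(batch)
    n_fern <- round(p_fern / (1 - p_fern) * n_bio)
    if (n_fern > 0L) {
      nf <- n_fern
      fi <- sample.int(nrow(pools[[s]]$ferns), nf, replace = TRUE)
      ferns <- data.frame(
        growth_form = "tree_fern",
        species = pools[[s]]$ferns$species[fi],
        family = pools[[s]]$ferns$family[fi],
        dbh_cm = draw_dbh(nf, 0.4, dmax = 40),
        height_m = stats::runif(nf, 2, 8),
        agb_kg = 0, stringsAsFactors = FALSE)
      batch <- rbind(batch, ferns)
      # interleave ferns deterministically across the census order
      batch <- batch[order(stats::runif(nrow(batch))), , drop = FALSE]
    }
    batch$agb_kg <- NULL
    n_ind <- nrow(batch)
    ind_rows[[i]] <- cbind(
      data.frame(plot_id = plots$plot_id[i], site = s,
                 individual_id = sprintf("%s_i%04d", plots$plot_id[i],
                                         seq_len(n_ind)),
                 stringsAsFactors = FALSE),
      batch)
    ind_site_count[s] <- ind_site_count[s] + n_ind
  }
  individuals <- do.call(rbind, ind_rows)

  # plant missingness exactly: reassign species of randomly chosen woody
  # individuals per site
  missing_planted <- list()
  for (s in config$sites) {
    n_tot <- as.integer(ind_site_count[[s]])
    n_fam <- as.integer(round(config$missing_family_rate[[s]] * n_tot))
    n_drop <- as.integer(round(config$missing_drop_rate[[s]] * n_tot))
    woody_idx <- which(individuals$site == s &
                         individuals$growth_form %in% c("tree", "palm"))
    pick <- sample(woody_idx, n_fam + n_drop)
    fam_pick <- pick[seq_len(n_fam)]
    drop_pick <- pick[n_fam + seq_len(n_drop)]
    # unmeasured species within measured families -> family imputation
    fams <- unique(individuals$family[woody_idx])
    individuals$species[fam_pick] <- sprintf(
      "unm_%s_%04d", sub("gradient_", "", s), seq_len(n_fam))
    individuals$family[fam_pick] <- sample(fams, n_fam, replace = TRUE)
    # unresolved taxa -> removed from analyses
    individuals$species[drop_pick] <- ""
    individuals$family[drop_pick] <- ""
    missing_planted[[s]] <- list(n_individuals = n_tot,
                                 n_family = n_fam, n_dropped = n_drop)
  }

  # split some individuals into multiple stems (preserving the
  # root-sum-of-squares effective DBH) and write the long census
  n_all <- nrow(individuals)
  can_split <- individuals$growth_form %in% c("tree", "palm") &
    individuals$dbh_cm >= 4.5 &
    stats::runif(n_all) < config$multi_stem_fraction
  n_stems_draw <- ifelse(can_split,
                         ifelse(stats::runif(n_all) < 0.8, 2L, 3L), 1L)
  # per-stem weights: runif(0.6, 1.4) normalised within the individual;
  # a split whose smallest stem would fall below the census threshold is
  # kept single-stemmed
  idx0 <- rep(seq_len(n_all), n_stems_draw)
  w <- stats::runif(length(idx0), 0.6, 1.4)
  wsum <- tapply(w, idx0, sum)[as.character(idx0)]
  d0 <- individuals$dbh_cm[idx0] * sqrt(w / wsum)
  bad_ind <- unique(idx0[d0 < 2.5])
  keep_rows <- !(idx0 %in% bad_ind) | !duplicated(idx0)
  idx <- idx0[keep_rows]
  d_stem <- d0[keep_rows]
  demoted <- idx %in% bad_ind
  d_stem[demoted] <- individuals$dbh_cm[idx[demoted]]
  stem_rank <- stats::ave(idx, idx, FUN = seq_along)
  h_stem <- individuals$height_m[idx]
  secondary <- stem_rank > 1L
  h_stem[secondary] <- h_stem[secondary] *
    stats::runif(sum(secondary), 0.6, 0.95)
  stems <- data.frame(
    plot_id = individuals$plot_id[idx],
    individual_id = individuals$individual_id[idx],
    stem_id = sprintf("%s_s%d", individuals$individual_id[idx], stem_rank),
    dbh_cm = round(d_stem, 3),
    height_m = round(h_stem, 2),
    growth_form = individuals$growth_form[idx],
    species = individuals$species[idx],
    family = individuals$family[idx],
    stringsAsFactors = FALSE)
  rownames(stems) <- NULL

  # soils: back-computed so the SOC formula returns the planted target
  set.seed(stage_seeds[5])
  band_all <- range(unlist(config$belt_bands))
  soil_rows <- lapply(seq_len(nrow(plots)), function(i) {
    s <- plots$site[i]
    b <- plots$belt[i]
    alt <- plots$altitude_m[i]
    w <- (alt - band_all[1]) / diff(band_all)
    interp <- function(v) {
      stats::approx(x = c(0, 0.5, 1),
                    y = v[c("low", "mid", "high")], xout = w, rule = 2)$y
    }
    bd <- interp(config$bd_gcm3[[s]]) * exp(stats::rnorm(1, 0, 0.05))
    fe <- stats::runif(1, config$fe_range[1], config$fe_range[2])
    vols <- config$core_volume_cm3 * stats::runif(3, 0.98, 1.02)
    mt <- bd * sum(vols)
    shares <- stats::runif(3, 0.8, 1.2)
    masses <- mt * shares / sum(shares)
    coarse <- (1 - fe) * mt
    residue <- coarse * stats::runif(1, 0.15, 0.30)
    c_gkg <- targets$soc_target[i] * 10 / (bd * 15 * fe)
    cn <- interp(config$cn[[s]]) * exp(stats::rnorm(1, 0, 0.05))
    data.frame(
      plot_id = plots$plot_id[i], c_gkg = c_gkg, n_gkg = c_gkg / cn,
      ph = round(interp(config$ph[[s]]) + stats::rnorm(1, 0, 0.15), 2),
      layer_thickness_cm = 15,
      core_dry_mass1_g = masses[1], core_dry_mass2_g = masses[2],
      core_dry_mass3_g = masses[3],
      core_volume1_cm3 = vols[1], core_volume2_cm3 = vols[2],
      core_volume3_cm3 = vols[3],
      coarse_fraction_mass_g = coarse, coarse_residue_mass_g = residue,
      sand = 0.55, silt = 0.30, clay = 0.15,
      stringsAsFactors = FALSE)
  })
  soils <- do.call(rbind, soil_rows)

  # climate: temperature lapse and exact-moment monthly precipitation
  set.seed(stage_seeds[6])
  clim_rows <- lapply(seq_len(nrow(plots)), function(i) {
    s <- plots$site[i]
    b <- plots$belt[i]
    alt <- plots$altitude_m[i]
    t_c <- config$temp_sea_level_c[[s]] - config$lapse_c_per_m[[s]] * alt +
      stats::rnorm(1, 0, 0.15)
    ps <- config$ps_pct[[s]][[b]] + stats::rnorm(1, 0, config$ps_jitter)
    annual <- config$annual_precip_mm[[s]][[b]] * exp(stats::rnorm(1, 0, 0.05))
    mm <- generate_monthly_precip(annual, ps)
    out <- data.frame(plot_id = plots$plot_id[i],
                      annual_mean_temp_c = round(t_c, 2),
                      stringsAsFactors = FALSE)
    out[sprintf("m%02d", 1:12)] <- as.list(mm)
    out$ps_planted <- ps
    out
  })
  climate <- do.call(rbind, clim_rows)
  ps_planted <- climate$ps_planted
  climate$ps_planted <- NULL

  belt_means <- do.call(rbind, lapply(config$sites, function(s) {
    do.call(rbind, lapply(config$belts, function(b) {
      i <- expected$site == s & expected$belt == b
      data.frame(site = s, belt = b,
                 agc = mean(expected$agc_mu[i]),
                 bgc = mean(expected$bgc_mu[i]),
                 soc = mean(expected$soc_mu[i]),
                 total = mean(expected$total_mu[i]),
                 stringsAsFactors = FALSE)
    }))
  }))

  ground_truth <- list(
    seed = config$seed,
    coefficients = planted$coefficients,
    bgb_agb_ratio = planted$bgb_agb_ratio,
    dbh_rate = planted$dbh_rate,
    expected = expected,
    targets = targets[, c("plot_id", "agc_target", "soc_target")],
    belt_means = belt_means,
    missingness = missing_planted,
    ps_planted = data.frame(plot_id = plots$plot_id, ps = ps_planted,
                            stringsAsFactors = FALSE)
  )

  out <- list(stems = stems, wd_samples = wd_samples, soils = soils,
              climate = climate, plots = plots,
              ground_truth = ground_truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_census(stems, file.path(dir, "census.csv"))
    utils::write.csv(wd_samples, file.path(dir, "wd_samples.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(soils, file.path(dir, "soils.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(climate, file.path(dir, "climate.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(plots, file.path(dir, "plots.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      ground_truth[c("seed", "coefficients", "belt_means", "missingness")],
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
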