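#' Belt-level summaries of plot carbon stocks
#'
#' Mean and sample SD (n-1) of each compartment per site x belt.
#'
#' @param plot_carbon output of [assemble_plot_carbon()] (optionally with
#'   uncertainty columns).
#' @return Data frame: `site`, `belt`, `compartment`, `mean`, `sd`,
#'   `n_plots`; `sd` is `NA` for single-plot belts.
#' @export
belt_summary <- function(plot_carbon) {
  comps <- c("agc", "bgc", "soc", "total")
  out <- list()
  for (s in unique(plot_carbon$site)) {
    for (b in unique(plot_carbon$belt[plot_carbon$site == s])) {
      d <- plot_carbon[plot_carbon$site == s & plot_carbon$belt == b, ]
      for (comp in comps) {
        v <- d[[comp]]
        out[[length(out) + 1L]] <- data.frame(
          site = s, belt = b, compartment = toupper(comp),
          mean = mean(v),
          sd = if (nrow(d) > 1L) stats::sd(v) else NA_real_,
          n_plots = nrow(d), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percent decline between two means
#'
#' 100 * (1 - comparison / reference): the decline of the comparison belt
#' relative to the reference belt (the belt with the largest mean, in the
#' reporting convention).
#'
#' @param reference_mean reference mean, positive.
#' @param comparison_mean comparison mean.
#' @return Percent decline (negative when the comparison is larger).
#'   Vectorised.
#' @export
percent_change <- function(reference_mean, comparison_mean) {
  if (any(!is.finite(reference_mean)) || any(reference_mean <= 0)) {
    stop("percent_change(): reference mean must be positive", call. = FALSE)
  }
  100 * (1 - comparison_mean / reference_mean)
}

#' Percent declines relative to the largest belt per compartment
#'
#' For each site and compartment, reports every belt's decline relative to
#' the belt with the largest mean (the reference belt is always printed).
#'
#' @param belts output of [belt_summary()].
#' @return Data frame: `site`, `compartment`, `reference_belt`, `belt`,
#'   `decline_pct`.
#' @export
percent_decline_table <- function(belts) {
  out <- list()
  for (s in unique(belts$site)) {
    for (comp in unique(belts$compartment)) {
      d <- belts[belts$site == s & belts$compartment == comp, ]
      ref <- d$belt[which.max(d$mean)]
      ref_mean <- max(d$mean)
      others <- d[d$belt != ref, , drop = FALSE]
      if (nrow(others) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        site = s, compartment = comp, reference_belt = ref,
        belt = others$belt,
        decline_pct = percent_change(ref_mean, others$mean),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate plot carbon stocks from study tables
#'
#' Runs the estimation stages over in-memory study tables: census validation
#' and multi-stem aggregation, per-site wood-density tables and the
#' imputation ladder, soil stock derivation, plot-stock assembly, and
#' (optionally) Monte-Carlo error propagation.
#'
#' @param stems stem census table (long format).
#' @param wd_samples branch wood-density samples with a `site` column (or a
#'   single-site table).
#' @param soils per-plot soil measurements (see [read_soils()] schema).
#' @param plots plot metadata.
#' @param error_model an [error_model()], or `NULL` to skip the Monte-Carlo
#'   stage.
#' @param liana_bgb include lianas in belowground biomass.
#' @return List: `plot_carbon` (with uncertainty columns when propagated),
#'   `individuals` (with wood-density assignments), `wd_report` (per-site
#'   imputation report), `soil` (derived soil table), `sd_mean_ratios`
#'   (per-site ratios used).
#' @export
estimate_stocks <- function(stems, wd_samples, soils, plots,
                            error_model = NULL, liana_bgb = FALSE) {
  census <- validate_stems(stems)
  individuals <- census$individuals
  individuals$site <- plots$site[match(individuals$plot_id, plots$plot_id)]
  if (anyNA(individuals$site)) {
    stop("estimate_stocks(): census plot(s) missing from the plot table: ",
         paste(utils::head(unique(
           individuals$plot_id[is.na(individuals$site)]), 5L),
           collapse = ", "), call. = FALSE)
  }
  if (is.null(wd_samples$site)) wd_samples$site <- individuals$site[1]

  assigned <- list()
  reports <- list()
  ratios <- c()
  for (s in unique(individuals$site)) {
    samples_s <- wd_samples[wd_samples$site == s, , drop = FALSE]
    sp_tab <- species_wd_table(samples_s)
    fam_tab <- family_wd_table(sp_tab)
    ratio <- sd_mean_ratio(sp_tab)
    ind_s <- assign_wood_density(
      individuals[individuals$site == s, , drop = FALSE],
      sp_tab, fam_tab, ratio)
    assigned[[s]] <- ind_s
    rep_s <- wd_imputation_report(ind_s)
    rep_s$site <- s
    reports[[s]] <- rep_s
    ratios[s] <- ratio
  }
  individuals <- do.call(rbind, assigned)
  rownames(individuals) <- NULL

  soil <- soil_derive(soils)
  plot_carbon <- assemble_plot_carbon(individuals, plots,
                                      soc = soil[, c("plot_id", "soc_mgha")],
                                      liana_bgb = liana_bgb)
  if (!is.null(error_model)) {
    plot_carbon <- propagate_uncertainty(plot_carbon, individuals,
                                         model = error_model,
                                         liana_bgb = liana_bgb)
  }
  list(plot_carbon = plot_carbon, individuals = individuals,
       wd_report = do.call(rbind, reports), soil = soil,
       sd_mean_ratios = ratios)
}

#' Run the full synthetic-study pipeline
#'
#' Simulate, estimate, analyse and report in one call: generates a synthetic
#' study from the configuration, estimates plot stocks (with Monte-Carlo
#' uncertainty), summarises belts and percent declines, fits the altitudinal
#' and climate trend models, and (optionally) writes every table plus a run
#' log to `out_dir`.
#'
#' @param config a [study_config()]; its seed drives all stages.
#' @param out_dir optional output directory for CSV outputs and the run log.
#' @param n_iter Monte-Carlo iterations (default from `config`); `0` skips
#'   propagation.
#' @param link link function for the trend models.
#' @return List: `study` (generated tables and ground truth), `estimates`
#'   (see [estimate_stocks()]), `belts`, `declines`, `altitude_trends`,
#'   `climate_trends`.
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL,
                         n_iter = config$n_iter, link = "inverse") {
  study <- generate_study(config, dir = out_dir)
  em <- if (n_iter > 0) {
    error_model(n_iter = n_iter, seed = config$seed + 1L)
  } else {
    NULL
  }
  estimates <- estimate_stocks(study$stems, study$wd_samples, study$soils,
                               study$plots, error_model = em)
  climate <- read_climate_table(study$climate)
  belts <- belt_summary(estimates$plot_carbon)
  declines <- percent_decline_table(belts)
  altitude_trends <- altitude_models(estimates$plot_carbon, link = link)
  climate_trends <- climate_models(estimates$plot_carbon, climate,
                                   link = link)
  out <- list(study = study, estimates = estimates, belts = belts,
              declines = declines, altitude_trends = altitude_trends,
              climate_trends = climate_trends)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wr <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
    wr(estimates$plot_carbon, "plot_stocks.csv")
    wr(belts, "belt_summary.csv")
    wr(declines, "percent_declines.csv")
    wr(altitude_trends, "altitude_deviance_tables.csv")
    wr(climate_trends, "climate_deviance_tables.csv")
    wr(estimates$wd_report, "wd_imputation_report.csv")
    log_lines <- c(
      paste0("seed: ", config$seed),
      paste0("n_iter: ", n_iter),
      paste0("link: ", link),
      paste0("n_plots: ", nrow(estimates$plot_carbon)),
      paste0("n_individuals: ", nrow(estimates$individuals)),
      paste0("n_tree_fern_excluded: ",
             attr(estimates$plot_carbon, "n_tree_fern")),
      paste0("n_dropped_no_wd: ",
             attr(estimates$plot_carbon, "n_dropped")),
      paste0("sd_mean_ratios: ",
             paste(names(estimates$sd_mean_ratios),
                   round(estimates$sd_mean_ratios, 4),
                   sep = "=", collapse = ", ")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  out
}

# In-memory version of read_climate(): monthly columns to seasonality.
read_climate_table <- function(x, sd_type = "population") {
  months <- sprintf("m%02d", 1:12)
  if (all(months %in% names(x))) {
    mm <- as.matrix(x[, months])
    x$precip_seasonality_pct <- apply(mm, 1, precipitation_seasonality,
                                      sd_type = sd_type)
    x$annual_precip_mm <- rowSums(mm)
  }
  x[, c("plot_id", "annual_mean_temp_c", "precip_seasonality_pct",
        "annual_precip_mm")]
}
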