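#' Measurement-error model for Monte-Carlo propagation
#'
#' Height and diameter errors are normal with SD equal to a fraction of the
#' estimated value (default 5%, reflecting that larger trees carry larger
#' absolute errors); wood-density error is normal with the taxon's own mean
#' and SD. Draws that come out non-positive are redrawn.
#'
#' @param rel_sd_h relative SD of height error (default 0.05).
#' @param rel_sd_dbh relative SD of diameter error (default 0.05).
#' @param n_iter number of Monte-Carlo iterations (default 1000).
#' @param seed optional integer seed applied at the start of propagation.
#' @return An object of class `error_model`.
#' @export
error_model <- function(rel_sd_h = 0.05, rel_sd_dbh = 0.05, n_iter = 1000,
                        seed = NULL) {
  if (!is.finite(rel_sd_h) || rel_sd_h < 0 ||
      !is.finite(rel_sd_dbh) || rel_sd_dbh < 0) {
    stop("error_model(): relative SDs must be non-negative", call. = FALSE)
  }
  if (!is.finite(n_iter) || n_iter < 1) {
    stop("error_model(): n_iter must be >= 1", call. = FALSE)
  }
  structure(list(rel_sd_h = rel_sd_h, rel_sd_dbh = rel_sd_dbh,
                 n_iter = as.integer(n_iter), seed = seed),
            class = "error_model")
}

# Normal draws truncated to (0, Inf) by redraw; after max_attempts rounds any
# remaining non-positive draw is clamped to 1e-6 with a warning. Redrawing
# (rather than folding) avoids biasing small trees.
draw_positive_normal <- function(n, mean, sd, max_attempts = 100L) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  attempts <- 0L
  while (length(bad) > 0L && attempts < max_attempts) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x <= 0)
    attempts <- attempts + 1L
  }
  if (length(bad) > 0L) {
    warning("draw_positive_normal(): clamping ", length(bad),
            " draw(s) to 1e-6 after ", max_attempts, " redraw rounds",
            call. = FALSE)
    x[bad] <- 1e-6
  }
  x
}

#' Draw perturbed measurements for one individual
#'
#' One joint draw of (height, DBH, wood density) under an error model:
#' h* ~ N(h, rel_sd_h * h), dbh* ~ N(dbh, rel_sd_dbh * dbh),
#' wd* ~ N(wd_mean, wd_sd), each truncated to positive values by redraw.
#'
#' @param h,dbh point estimates (m, cm), positive.
#' @param wd_mean,wd_sd wood-density mean and SD (g cm^-3).
#' @param model an [error_model()].
#' @return Named list `h`, `dbh`, `wd`.
#' @export
draw_individual <- function(h, dbh, wd_mean, wd_sd, model = error_model()) {
  if (!inherits(model, "error_model")) {
    stop("draw_individual(): model must be an error_model", call. = FALSE)
  }
  list(h = draw_positive_normal(1L, h, model$rel_sd_h * h),
       dbh = draw_positive_normal(1L, dbh, model$rel_sd_dbh * dbh),
       wd = draw_positive_normal(1L, wd_mean, wd_sd))
}

# Summary statistics over Monte-Carlo iterations of one plot stock.
mc_summary <- function(draws) {
  n <- length(draws)
  list(mean = mean(draws),
       sd = if (n > 1L) stats::sd(draws) else NA_real_,
       q025 = unname(stats::quantile(draws, 0.025)),
       q975 = unname(stats::quantile(draws, 0.975)),
       n_iter = n)
}

#' Monte-Carlo propagation of measurement error into one plot's stocks
#'
#' For each iteration every individual's height, diameter and wood density
#' are redrawn jointly under the error model; plot aboveground and
#' belowground carbon are recomputed from the allometries and summarised over
#' iterations. Belowground carbon shares each iteration's diameter draws with
#' aboveground carbon (one measurement, two equations). Draws are independent
#' across individuals and iterations. The soil stock is not perturbed; total
#' carbon per iteration is AGC* + BGC* + SOC.
#'
#' @param individuals rows of one plot from [assign_wood_density()];
#'   tree-fern and dropped individuals are ignored.
#' @param area_ha plot area (ha).
#' @param soc soil organic carbon stock of the plot (Mg ha^-1); `NA` omits
#'   the total summary.
#' @param model an [error_model()]; zero SDs reproduce the point estimate
#'   exactly.
#' @param liana_bgb include lianas in belowground biomass.
#' @return Named list of summaries (`agc`, `bgc`, `total`), each with
#'   `mean`, `sd`, `q025`, `q975`, `n_iter` (Mg ha^-1).
#' @export
propagate_plot <- function(individuals, area_ha, soc = NA_real_,
                           model = error_model(), liana_bgb = FALSE) {
  if (!inherits(model, "error_model")) {
    stop("propagate_plot(): model must be an error_model", call. = FALSE)
  }
  dropped <- !is.na(individuals$wd_provenance) &
    individuals$wd_provenance == "dropped"
  keep <- individuals$growth_form != "tree_fern" & !dropped
  ind <- individuals[keep, , drop = FALSE]
  n_ind <- nrow(ind)
  n_iter <- model$n_iter

  if (n_ind == 0L) {
    zero <- mc_summary(rep(0, n_iter))
    tot <- mc_summary(rep(soc, n_iter))
    return(list(agc = zero, bgc = zero, total = tot))
  }

  woody <- ind$growth_form %in% c("tree", "palm")
  liana <- ind$growth_form == "liana"
  m <- n_ind * n_iter

  dbh <- matrix(draw_positive_normal(
    m, rep(ind$dbh_cm, n_iter), rep(model$rel_sd_dbh * ind$dbh_cm, n_iter)),
    nrow = n_ind)
  agb <- matrix(0, n_ind, n_iter)
  bgb <- matrix(0, n_ind, n_iter)
  if (any(woody)) {
    h0 <- ind$height_m[woody]
    wd0 <- ind$wd_mean[woody]
    wdsd <- ifelse(is.na(ind$wd_sd[woody]), 0, ind$wd_sd[woody])
    k <- sum(woody)
    h <- matrix(draw_positive_normal(
      k * n_iter, rep(h0, n_iter), rep(model$rel_sd_h * h0, n_iter)),
      nrow = k)
    wd <- matrix(draw_positive_normal(
      k * n_iter, rep(wd0, n_iter), rep(wdsd, n_iter)), nrow = k)
    agb[woody, ] <- 0.0673 * (wd * dbh[woody, , drop = FALSE]^2 * h)^0.976
    bgb[woody, ] <- 0.285 * dbh[woody, , drop = FALSE]^1.993
  }
  if (any(liana)) {
    dl <- dbh[liana, , drop = FALSE]
    agb[liana, ] <- exp(-1.484 + 2.657 * log(dl))
    if (liana_bgb) bgb[liana, ] <- 0.285 * dl^1.993
  }
  agc <- 0.5 * colSums(agb) / 1000 / area_ha
  bgc <- 0.5 * colSums(bgb) / 1000 / area_ha
  list(agc = mc_summary(agc),
       bgc = mc_summary(bgc),
       total = mc_summary(agc + bgc + soc))
}

#' Append Monte-Carlo uncertainty summaries to plot stocks
#'
#' Runs [propagate_plot()] for every plot and appends the summaries to the
#' plot-carbon table. With a seeded error model the whole propagation is
#' reproducible; plots are processed in table order but their summaries are
#' independent (each plot gets its own substream derived from the model
#' seed).
#'
#' @param plot_carbon output of [assemble_plot_carbon()].
#' @param individuals output of [assign_wood_density()].
#' @param model an [error_model()].
#' @param liana_bgb include lianas in belowground biomass.
#' @return `plot_carbon` with columns `agc_mc_mean`, `agc_mc_sd`, `agc_q025`,
#'   `agc_q975` (and the same for `bgc` and `total`) appended.
#' @export
propagate_uncertainty <- function(plot_carbon, individuals,
                                  model = error_model(),
                                  liana_bgb = FALSE) {
  base_seed <- if (is.null(model$seed)) {
    sample.int(.Machine$integer.max, 1L)
  } else {
    as.integer(model$seed)
  }
  for (comp in c("agc", "bgc", "total")) {
    for (stat in c("mc_mean", "mc_sd", "q025", "q975")) {
      plot_carbon[[paste0(comp, "_", stat)]] <- NA_real_
    }
  }
  # substreams keyed to the plot id, so summaries do not depend on row order
  stream <- match(plot_carbon$plot_id,
                  sort(unique(as.character(plot_carbon$plot_id))))
  for (i in seq_len(nrow(plot_carbon))) {
    pid <- plot_carbon$plot_id[i]
    set.seed((base_seed + stream[i]) %% .Machine$integer.max)
    res <- propagate_plot(
      individuals[individuals$plot_id == pid, , drop = FALSE],
      area_ha = plot_carbon$area_ha[i],
      soc = plot_carbon$soc[i],
      model = model, liana_bgb = liana_bgb)
    for (comp in c("agc", "bgc", "total")) {
      plot_carbon[[paste0(comp, "_mc_mean")]][i] <- res[[comp]]$mean
      plot_carbon[[paste0(comp, "_mc_sd")]][i] <- res[[comp]]$sd
      plot_carbon[[paste0(comp, "_q025")]][i] <- res[[comp]]$q025
      plot_carbon[[paste0(comp, "_q975")]][i] <- res[[comp]]$q975
    }
  }
  plot_carbon
}
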