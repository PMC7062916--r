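#' Aboveground biomass of a tree or palm
#'
#' Chave three-variable pantropical allometry:
#' AGB = 0.0673 * (WD * DBH^2 * H)^0.976, returning kg per individual with
#' wood density in g cm^-3, diameter at breast height in cm and height in m
#' (the unit conventions of the source allometry).
#'
#' @param wd wood density (g cm^-3), positive.
#' @param dbh diameter at breast height (cm), positive; multi-stem
#'   individuals use the effective DBH from [combined_dbh()].
#' @param h height (m), positive.
#' @return Aboveground biomass in kg. Vectorised.
#' @examples
#' tree_agb(0.6, 10, 15)
#' @export
tree_agb <- function(wd, dbh, h) {
  if (any(!is.finite(wd)) || any(wd <= 0) ||
      any(!is.finite(dbh)) || any(dbh <= 0) ||
      any(!is.finite(h)) || any(h <= 0)) {
    stop("tree_agb(): wd, dbh and h must all be positive", call. = FALSE)
  }
  0.0673 * (wd * dbh^2 * h)^0.976
}

#' Aboveground biomass of a liana
#'
#' Diameter-only liana allometry: AGB = exp(-1.484 + 2.657 * ln(DBH)), kg.
#'
#' @param dbh diameter at breast height (cm), positive.
#' @return Aboveground biomass in kg. Vectorised.
#' @export
liana_agb <- function(dbh) {
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("liana_agb(): dbh must be positive", call. = FALSE)
  }
  exp(-1.484 + 2.657 * log(dbh))
}

#' Belowground (coarse-root) biomass
#'
#' BGB = 0.285 * DBH^1.993, kg per individual from diameter alone.
#'
#' @param dbh diameter at breast height (cm), positive.
#' @return Belowground biomass in kg. Vectorised.
#' @export
tree_bgb <- function(dbh) {
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("tree_bgb(): dbh must be positive", call. = FALSE)
  }
  0.285 * dbh^1.993
}

#' Biomass to carbon
#'
#' Carbon is taken as 50% of biomass, applied identically to aboveground and
#' belowground pools.
#'
#' @param biomass non-negative biomass (kg or Mg ha^-1).
#' @return Carbon in the same units. Vectorised.
#' @export
biomass_to_carbon <- function(biomass) {
  if (any(!is.finite(biomass)) || any(biomass < 0)) {
    stop("biomass_to_carbon(): biomass must be non-negative", call. = FALSE)
  }
  0.5 * biomass
}

#' Per-area plot stock from per-individual masses
#'
#' Sums per-individual kg, converts to Mg and divides by plot area.
#'
#' @param kg numeric vector of per-individual masses (kg).
#' @param area_ha plot area (ha), positive.
#' @return Stock in Mg ha^-1.
#' @export
plot_stock <- function(kg, area_ha) {
  if (!is.finite(area_ha) || area_ha <= 0) {
    stop("plot_stock(): area_ha must be positive", call. = FALSE)
  }
  if (length(kg) == 0L) {
    warning("plot_stock(): no individuals; stock is 0", call. = FALSE)
    return(0)
  }
  (sum(kg) / 1000) / area_ha
}

#' Per-individual biomass from the growth-form-specific allometries
#'
#' Routes each individual to its equation: trees and palms through the Chave
#' three-variable model (requiring wood density and height), lianas through
#' the diameter-only liana model (aboveground only), tree ferns to no
#' equation. Individuals with provenance `dropped` contribute nothing.
#' Lianas are excluded from the root equation by default; set
#' `liana_bgb = TRUE` to include them.
#'
#' @param individuals output of [assign_wood_density()].
#' @param liana_bgb include lianas in belowground biomass (default `FALSE`).
#' @return Data frame: `individual_id`, `plot_id`, `growth_form`, `agb_kg`,
#'   `bgb_kg`, `equation_used` (chave3/liana/none).
#' @export
individual_biomass <- function(individuals, liana_bgb = FALSE) {
  n <- nrow(individuals)
  eq <- rep("none", n)
  agb <- numeric(n)
  bgb <- numeric(n)

  dropped <- !is.na(individuals$wd_provenance) &
    individuals$wd_provenance == "dropped"
  woody <- individuals$growth_form %in% c("tree", "palm") & !dropped
  liana <- individuals$growth_form == "liana"

  if (any(woody & is.na(individuals$wd_mean))) {
    bad <- individuals$individual_id[woody & is.na(individuals$wd_mean)]
    stop("individual_biomass(): tree/palm without wood density (should be ",
         "dropped upstream): ", paste(utils::head(bad, 10L), collapse = ", "),
         call. = FALSE)
  }
  agb[woody] <- tree_agb(individuals$wd_mean[woody],
                         individuals$dbh_cm[woody],
                         individuals$height_m[woody])
  bgb[woody] <- tree_bgb(individuals$dbh_cm[woody])
  eq[woody] <- "chave3"
  if (any(liana)) {
    agb[liana] <- liana_agb(individuals$dbh_cm[liana])
    if (liana_bgb) bgb[liana] <- tree_bgb(individuals$dbh_cm[liana])
    eq[liana] <- "liana"
  }
  data.frame(
    individual_id = individuals$individual_id,
    plot_id = individuals$plot_id,
    growth_form = individuals$growth_form,
    agb_kg = agb, bgb_kg = bgb, equation_used = eq,
    stringsAsFactors = FALSE
  )
}

#' Assemble per-plot carbon stocks
#'
#' Aggregates per-individual biomass to plot-level aboveground and
#' belowground carbon (50% of biomass, per area) and joins the soil organic
#' carbon stock. Tree ferns and dropped individuals are excluded; their
#' counts are reported as attributes `n_tree_fern` and `n_dropped`.
#'
#' @param individuals output of [assign_wood_density()].
#' @param plots plot metadata from [read_plots()].
#' @param soc data frame with `plot_id` and `soc_mgha` (e.g. from
#'   [soil_derive()]); plots without a soil record get `NA` SOC and total.
#' @param liana_bgb passed to [individual_biomass()].
#' @return Data frame, one row per plot: `plot_id`, `site`, `belt`,
#'   `altitude_m`, `area_ha`, `agc`, `bgc`, `soc`, `total` (Mg ha^-1),
#'   `n_individuals`.
#' @export
assemble_plot_carbon <- function(individuals, plots, soc = NULL,
                                 liana_bgb = FALSE) {
  bio <- individual_biomass(individuals, liana_bgb = liana_bgb)
  counted <- bio$equation_used != "none"
  out <- plots[, c("plot_id", "site", "belt", "altitude_m", "area_ha")]
  agb <- tapply(bio$agb_kg[counted], bio$plot_id[counted], sum)
  bgb <- tapply(bio$bgb_kg[counted], bio$plot_id[counted], sum)
  nind <- tapply(bio$plot_id[counted], bio$plot_id[counted], length)
  id <- as.character(out$plot_id)
  out$agc <- biomass_to_carbon(ifelse(is.na(agb[id]), 0, agb[id]) / 1000) /
    out$area_ha
  out$bgc <- biomass_to_carbon(ifelse(is.na(bgb[id]), 0, bgb[id]) / 1000) /
    out$area_ha
  out$n_individuals <- ifelse(is.na(nind[id]), 0L, as.integer(nind[id]))
  if (!is.null(soc)) {
    out$soc <- soc$soc_mgha[match(out$plot_id, soc$plot_id)]
  } else {
    out$soc <- NA_real_
  }
  out$total <- out$agc + out$bgc + out$soc
  attr(out, "n_tree_fern") <-
    sum(individuals$growth_form == "tree_fern")
  attr(out, "n_dropped") <-
    sum(!is.na(individuals$wd_provenance) &
          individuals$wd_provenance == "dropped")
  rownames(out) <- NULL
  out
}
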