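#' Soil bulk density from core samples
#'
#' BD = Mt / sum(Vi): the total oven-dry mass of the cores (105 degrees C)
#' over their total volume. The field protocol takes three cores per plot,
#' but any number is accepted.
#'
#' @param core_dry_masses_g per-core oven-dry masses (g).
#' @param core_volumes_cm3 per-core volumes (cm^3), same length.
#' @return Bulk density in g cm^-3.
#' @export
bulk_density <- function(core_dry_masses_g, core_volumes_cm3) {
  if (length(core_dry_masses_g) == 0L ||
      length(core_dry_masses_g) != length(core_volumes_cm3)) {
    stop("bulk_density(): need non-empty, equal-length mass and volume ",
         "vectors", call. = FALSE)
  }
  if (any(!is.finite(core_dry_masses_g)) || any(core_dry_masses_g <= 0) ||
      any(!is.finite(core_volumes_cm3)) || any(core_volumes_cm3 <= 0)) {
    stop("bulk_density(): masses and volumes must be positive", call. = FALSE)
  }
  sum(core_dry_masses_g) / sum(core_volumes_cm3)
}

#' Fine-earth mass fraction
#'
#' Fraction of the sample mass made of particles < 2 mm, i.e. excluding
#' gravel, stones and the coarse plant residue (which is part of the coarse
#' fraction).
#'
#' @param total_mass_g total oven-dry sample mass (g), positive.
#' @param coarse_fraction_mass_g mass of the > 2 mm fraction including plant
#'   residue (g), between 0 and `total_mass_g`.
#' @return Fraction in [0, 1]. Vectorised.
#' @export
fine_earth_fraction <- function(total_mass_g, coarse_fraction_mass_g) {
  if (any(!is.finite(total_mass_g)) || any(total_mass_g <= 0)) {
    stop("fine_earth_fraction(): total mass must be positive", call. = FALSE)
  }
  if (any(!is.finite(coarse_fraction_mass_g)) ||
      any(coarse_fraction_mass_g < 0) ||
      any(coarse_fraction_mass_g > total_mass_g)) {
    stop("fine_earth_fraction(): coarse fraction must lie in [0, total]",
         call. = FALSE)
  }
  (total_mass_g - coarse_fraction_mass_g) / total_mass_g
}

#' Soil organic carbon stock of a fixed-depth layer
#'
#' SOC = C * BD * LTH * FE / 10, in Mg ha^-1, with C the organic carbon
#' concentration (g kg^-1), BD the bulk density (g cm^-3), LTH the layer
#' thickness (cm) and FE the fine-earth mass fraction. This is the
#' fixed-depth convention; no equivalent-soil-mass correction is applied.
#'
#' @param c_gkg organic carbon concentration (g kg^-1), non-negative.
#' @param bd_gcm3 bulk density (g cm^-3), non-negative.
#' @param lth_cm layer thickness (cm), positive; the default sampling layer
#'   is 0-15 cm.
#' @param fe_fraction fine-earth fraction in [0, 1].
#' @return SOC stock in Mg ha^-1. Vectorised.
#' @export
soc_stock <- function(c_gkg, bd_gcm3, lth_cm = 15, fe_fraction = 1) {
  if (any(!is.finite(c_gkg)) || any(c_gkg < 0) ||
      any(!is.finite(bd_gcm3)) || any(bd_gcm3 < 0) ||
      any(!is.finite(fe_fraction)) || any(fe_fraction < 0) ||
      any(fe_fraction > 1)) {
    stop("soc_stock(): inputs must be non-negative (FE in [0, 1])",
         call. = FALSE)
  }
  if (any(!is.finite(lth_cm)) || any(lth_cm <= 0)) {
    stop("soc_stock(): layer thickness must be positive", call. = FALSE)
  }
  c_gkg * bd_gcm3 * lth_cm * fe_fraction / 10
}

#' Carbon-to-nitrogen ratio
#'
#' @param c_gkg organic carbon concentration (g kg^-1), non-negative.
#' @param n_gkg total nitrogen concentration (g kg^-1), positive.
#' @return C/N ratio. Vectorised.
#' @export
cn_ratio <- function(c_gkg, n_gkg) {
  if (any(!is.finite(n_gkg)) || any(n_gkg <= 0)) {
    stop("cn_ratio(): nitrogen must be positive", call. = FALSE)
  }
  if (any(!is.finite(c_gkg)) || any(c_gkg < 0)) {
    stop("cn_ratio(): carbon must be non-negative", call. = FALSE)
  }
  c_gkg / n_gkg
}

.soil_columns <- c("plot_id", "c_gkg", "n_gkg", "ph", "layer_thickness_cm",
                   "core_dry_mass1_g", "core_dry_mass2_g", "core_dry_mass3_g",
                   "core_volume1_cm3", "core_volume2_cm3", "core_volume3_cm3",
                   "coarse_fraction_mass_g", "coarse_residue_mass_g")

#' Read per-plot soil measurements
#'
#' @param path CSV with one row per plot: `plot_id`, `c_gkg`, `n_gkg`, `ph`,
#'   `layer_thickness_cm`, three `core_dry_mass*_g` and `core_volume*_cm3`
#'   columns, `coarse_fraction_mass_g`, `coarse_residue_mass_g`, and optional
#'   `sand`, `silt`, `clay` texture fractions.
#' @return Validated soil data frame.
#' @export
read_soils <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(.soil_columns, "coarse_residue_mass_g"),
                          names(x))
  if (length(missing_cols) > 0L) {
    stop("read_soils(): '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$plot_id)) {
    stop("read_soils(): duplicated plot_id in ", path, call. = FALSE)
  }
  if (!is.null(x$coarse_residue_mass_g) &&
      any(x$coarse_residue_mass_g > x$coarse_fraction_mass_g)) {
    stop("read_soils(): coarse plant residue exceeds the coarse fraction",
         call. = FALSE)
  }
  x
}

#' Derive bulk density, fine-earth fraction, SOC and C/N per plot
#'
#' The composite-sample mass used for the fine-earth fraction is the total
#' oven-dry core mass; the coarse fraction includes the plant residue, whose
#' percentage of the whole sample is also reported.
#'
#' @param soils data frame from [read_soils()].
#' @return Data frame: `plot_id`, `bulk_density_gcm3`, `fine_earth_fraction`,
#'   `soc_mgha`, `cn_ratio`, `residue_pct`.
#' @export
soil_derive <- function(soils) {
  masses <- as.matrix(soils[, c("core_dry_mass1_g", "core_dry_mass2_g",
                                "core_dry_mass3_g")])
  vols <- as.matrix(soils[, c("core_volume1_cm3", "core_volume2_cm3",
                              "core_volume3_cm3")])
  bd <- vapply(seq_len(nrow(soils)),
               function(i) bulk_density(masses[i, ], vols[i, ]),
               numeric(1))
  mt <- rowSums(masses)
  coarse <- soils$coarse_fraction_mass_g
  if (is.null(coarse) || all(is.na(coarse))) {
    warning("soil_derive(): no coarse-fraction masses; assuming fine-earth ",
            "fraction of 1 for all plots", call. = FALSE)
    fe <- rep(1, nrow(soils))
  } else {
    fe <- fine_earth_fraction(mt, coarse)
  }
  residue <- soils$coarse_residue_mass_g
  data.frame(
    plot_id = soils$plot_id,
    bulk_density_gcm3 = bd,
    fine_earth_fraction = fe,
    soc_mgha = soc_stock(soils$c_gkg, bd, soils$layer_thickness_cm, fe),
    cn_ratio = cn_ratio(soils$c_gkg, soils$n_gkg),
    residue_pct = if (is.null(residue)) NA_real_ else 100 * residue / mt,
    stringsAsFactors = FALSE
  )
}
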