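#' Volume of a branch cylinder
#'
#' Fresh branch sections are treated as cylinders; volume is
#' pi * (d/2)^2 * L.
#'
#' @param diameter_cm fresh diameter (cm), positive.
#' @param length_cm fresh length (cm), positive.
#' @return Volume in cm^3. Vectorised.
#' @export
cylinder_volume <- function(diameter_cm, length_cm) {
  if (any(!is.finite(diameter_cm)) || any(diameter_cm <= 0) ||
      any(!is.finite(length_cm)) || any(length_cm <= 0)) {
    stop("cylinder_volume(): diameter and length must be positive",
         call. = FALSE)
  }
  pi * (diameter_cm / 2)^2 * length_cm
}

#' Branch wood density
#'
#' Oven-dry mass divided by fresh cylinder volume, in g cm^-3. Values outside
#' (0.1, 1.5) g cm^-3 trigger a warning but are passed through, since field
#' samples can be extreme.
#'
#' @param dry_mass_g oven-dry mass (g), after drying at 80 degrees C.
#' @param diameter_cm,length_cm fresh cylinder dimensions (cm).
#' @return Wood density in g cm^-3. Vectorised.
#' @export
branch_density <- function(dry_mass_g, diameter_cm, length_cm) {
  if (any(!is.finite(dry_mass_g)) || any(dry_mass_g <= 0)) {
    stop("branch_density(): dry mass must be positive", call. = FALSE)
  }
  wd <- dry_mass_g / cylinder_volume(diameter_cm, length_cm)
  out <- which(wd < 0.1 | wd > 1.5)
  if (length(out) > 0L) {
    warning("branch_density(): ", length(out),
            " value(s) outside the plausible (0.1, 1.5) g cm^-3 range",
            call. = FALSE)
  }
  wd
}

#' Read branch wood-density samples
#'
#' @param path CSV with columns `species`, `family`, `diameter_cm`,
#'   `length_cm`, `dry_mass_g`.
#' @return Validated sample data frame with a computed `wd_gcm3` column.
#' @export
read_wd_samples <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "family", "diameter_cm", "length_cm", "dry_mass_g")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop("read_wd_samples(): '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$wd_gcm3 <- suppressWarnings(
    branch_density(x$dry_mass_g, x$diameter_cm, x$length_cm))
  x
}

#' Species-level wood-density table
#'
#' Mean and sample SD (n-1 denominator) of branch densities over all
#' conspecific samples. Species with a single sample get a missing SD and
#' provenance `species_single_sample`, to be filled by the site-level
#' SD/mean ratio during imputation.
#'
#' @param samples data frame with `species`, `family`, `wd_gcm3` (or the raw
#'   cylinder columns, from which densities are computed).
#' @return Data frame: `taxon`, `family`, `wd_mean`, `wd_sd`, `n_samples`,
#'   `provenance`.
#' @export
species_wd_table <- function(samples) {
  if (nrow(samples) == 0L) {
    return(data.frame(taxon = character(), family = character(),
                      wd_mean = numeric(), wd_sd = numeric(),
                      n_samples = integer(), provenance = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(samples$wd_gcm3)) {
    samples$wd_gcm3 <- suppressWarnings(
      branch_density(samples$dry_mass_g, samples$diameter_cm,
                     samples$length_cm))
  }
  sp <- split(samples, samples$species)
  out <- do.call(rbind, lapply(sp, function(s) {
    n <- nrow(s)
    data.frame(
      taxon = s$species[1], family = s$family[1],
      wd_mean = mean(s$wd_gcm3),
      wd_sd = if (n > 1L) stats::sd(s$wd_gcm3) else NA_real_,
      n_samples = n,
      provenance = if (n > 1L) "species_measured" else
        "species_single_sample",
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Family-level wood-density table
#'
#' Family means used as the second rung of the imputation ladder. By default
#' the family mean averages the species means (so heavily sampled species do
#' not dominate); `method = "samples"` averages the raw samples instead.
#'
#' @param species_table output of [species_wd_table()].
#' @param samples raw sample data frame; required for `method = "samples"`.
#' @param method `"species_means"` (default) or `"samples"`.
#' @return Data frame: `taxon` (family), `wd_mean`, `n_species`.
#' @export
family_wd_table <- function(species_table, samples = NULL,
                            method = c("species_means", "samples")) {
  method <- match.arg(method)
  if (method == "samples") {
    if (is.null(samples)) {
      stop("family_wd_table(): samples required for method = 'samples'",
           call. = FALSE)
    }
    if (is.null(samples$wd_gcm3)) {
      samples$wd_gcm3 <- suppressWarnings(
        branch_density(samples$dry_mass_g, samples$diameter_cm,
                       samples$length_cm))
    }
    fams <- split(samples$wd_gcm3, samples$family)
    nsp <- tapply(samples$species, samples$family,
                  function(x) length(unique(x)))
  } else {
    fams <- split(species_table$wd_mean, species_table$family)
    nsp <- tapply(species_table$taxon, species_table$family, length)
  }
  out <- data.frame(
    taxon = names(fams),
    wd_mean = vapply(fams, mean, numeric(1)),
    n_species = as.integer(nsp[names(fams)]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Site-level SD/mean ratio of wood density
#'
#' The average SD/mean ratio over species with a defined SD, used to impute
#' an SD for single-sample species and family-mean assignments. The reference
#' study-site defaults are 0.200 (gradient A) and 0.234 (gradient B); they
#' can be supplied directly wherever no multi-sample species exist.
#'
#' @param species_table output of [species_wd_table()].
#' @param over `"species"` (default: unweighted mean over species ratios) or
#'   `"samples"` (species ratios weighted by their sample counts).
#' @return Dimensionless ratio.
#' @export
sd_mean_ratio <- function(species_table, over = c("species", "samples")) {
  over <- match.arg(over)
  ok <- !is.na(species_table$wd_sd)
  if (!any(ok)) {
    stop("sd_mean_ratio(): no species with >1 sample; supply a default ",
         "ratio (e.g. 0.200 or 0.234) instead", call. = FALSE)
  }
  r <- species_table$wd_sd[ok] / species_table$wd_mean[ok]
  if (over == "species") mean(r)
  else stats::weighted.mean(r, species_table$n_samples[ok])
}

#' Assign wood density to individuals via the imputation ladder
#'
#' Deterministic ladder, applied independently per individual:
#' \enumerate{
#'   \item species-level record if the species was sampled; if its SD is
#'     missing (single sample), SD := mean x ratio;
#'   \item otherwise the family mean, with SD := mean x ratio and provenance
#'     `family_mean`;
#'   \item otherwise provenance `dropped`: the individual is excluded from
#'     all biomass computations downstream.
#' }
#' Lianas and tree ferns need no wood density: they are never dropped, and
#' their provenance is `not_required` when the ladder finds nothing.
#'
#' @param individuals individual table from [read_census()].
#' @param species_table output of [species_wd_table()].
#' @param family_table output of [family_wd_table()].
#' @param ratio site-level SD/mean ratio (see [sd_mean_ratio()]).
#' @return `individuals` with columns `wd_mean`, `wd_sd`, `wd_provenance`
#'   appended.
#' @export
assign_wood_density <- function(individuals, species_table, family_table,
                                ratio) {
  if (!is.finite(ratio) || ratio <= 0) {
    stop("assign_wood_density(): ratio must be positive", call. = FALSE)
  }
  isp <- match(individuals$species, species_table$taxon)
  ifa <- match(individuals$family, family_table$taxon)
  blank <- function(x) is.na(x) | x == "" | x == "unresolved"
  isp[blank(individuals$species)] <- NA_integer_
  ifa[blank(individuals$family)] <- NA_integer_

  wd_mean <- species_table$wd_mean[isp]
  wd_sd <- species_table$wd_sd[isp]
  prov <- ifelse(!is.na(isp), species_table$provenance[isp], NA_character_)
  wd_sd[!is.na(isp) & is.na(wd_sd)] <-
    wd_mean[!is.na(isp) & is.na(wd_sd)] * ratio

  use_family <- is.na(isp) & !is.na(ifa)
  wd_mean[use_family] <- family_table$wd_mean[ifa[use_family]]
  wd_sd[use_family] <- wd_mean[use_family] * ratio
  prov[use_family] <- "family_mean"

  none <- is.na(isp) & is.na(ifa)
  needs_wd <- individuals$growth_form %in% c("tree", "palm")
  prov[none & needs_wd] <- "dropped"
  prov[none & !needs_wd] <- "not_required"

  individuals$wd_mean <- wd_mean
  individuals$wd_sd <- wd_sd
  individuals$wd_provenance <- prov
  individuals
}

#' Summarise wood-density imputation outcomes
#'
#' Counts and fractions of individuals per provenance class, the reporting
#' side of the removal rule: family-imputed and dropped fractions are the
#' quantities quoted per site in inventory papers.
#'
#' @param individuals output of [assign_wood_density()].
#' @return Data frame: `provenance`, `n`, `fraction` (of all individuals).
#' @export
wd_imputation_report <- function(individuals) {
  n_total <- nrow(individuals)
  tab <- table(individuals$wd_provenance)
  data.frame(
    provenance = names(tab),
    n = as.integer(tab),
    fraction = as.numeric(tab) / n_total,
    stringsAsFactors = FALSE
  )
}
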