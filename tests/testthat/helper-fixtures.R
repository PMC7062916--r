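# Shared fixtures built in code.

# A small, fast study configuration for tests that do not fit GLMs.
small_config <- function(seed = 42L, plots_per_belt = 2L,
                         stems_per_plot = 60) {
  study_config(seed = seed, plots_per_belt = plots_per_belt,
               stems_per_plot = stems_per_plot)
}

# Three stems, two individuals, one plot.
tiny_census <- function() {
  data.frame(
    plot_id = "p1",
    individual_id = c("i1", "i1", "i2"),
    stem_id = c("s1", "s2", "s3"),
    dbh_cm = c(10, 5, 7),
    height_m = c(12, 9, 8),
    growth_form = "tree",
    species = c("spA", "spA", "spB"),
    family = "famA",
    stringsAsFactors = FALSE
  )
}

write_tiny_census <- function(stems = tiny_census()) {
  path <- tempfile(fileext = ".csv")
  write.csv(stems, path, row.names = FALSE, quote = FALSE)
  path
}

# One-plot individual table ready for biomass computation.
tiny_individuals <- function() {
  data.frame(
    plot_id = "p1",
    individual_id = c("t1", "l1"),
    growth_form = c("tree", "liana"),
    species = c("spA", "spL"),
    family = c("famA", "famL"),
    dbh_cm = c(10, 1),
    height_m = c(15, NA),
    n_stems = 1L,
    wd_mean = c(0.6, NA),
    wd_sd = c(0.05, NA),
    wd_provenance = c("species_measured", "not_required"),
    stringsAsFactors = FALSE
  )
}

read_climate_table_for_test <- function(x) {
  tmfcarbon:::read_climate_table(x)
}

tiny_plots <- function() {
  data.frame(plot_id = "p1", site = "gradient_A", belt = "low",
             altitude_m = 900, area_ha = 0.1, stringsAsFactors = FALSE)
}
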