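test_that("cylinder volume and branch density follow the cylinder model", {
  expect_equal(cylinder_volume(2, 1), pi)
  expect_equal(cylinder_volume(1, 10), 7.85398163397448, tolerance = 1e-12)
  expect_equal(cylinder_volume(4, 3), 4 * cylinder_volume(2, 3))
  expect_error(cylinder_volume(0, 1), "positive")

  expect_equal(branch_density(10, 2, 20 / pi), 0.5)
  expect_equal(branch_density(18.85, 2, 10), 18.85 / (pi * 10))
  expect_warning(out <- branch_density(60, 2, 20 / pi),
                 "outside the plausible")
  expect_equal(out, 3.0)
  # linear in mass, inverse in volume
  expect_equal(branch_density(20, 2, 5), 2 * branch_density(10, 2, 5))
  expect_equal(branch_density(10, 2, 10), branch_density(10, 2, 5) / 2)
})

test_that("species table computes conspecific means and sample SDs", {
  samples <- data.frame(
    species = c("a", "b", "a", "c"),
    family = c("F1", "F2", "F1", "F2"),
    wd_gcm3 = c(0.4, 0.7, 0.6, 0.55))
  tab <- species_wd_table(samples)
  a <- tab[tab$taxon == "a", ]
  expect_equal(a$wd_mean, 0.5)
  expect_equal(a$wd_sd, sd(c(0.4, 0.6)))
  expect_equal(a$wd_sd, 0.141421356237310, tolerance = 1e-12)
  expect_equal(a$provenance, "species_measured")
  cc <- tab[tab$taxon == "c", ]
  expect_equal(cc$wd_mean, 0.55)
  expect_true(is.na(cc$wd_sd))
  expect_equal(cc$provenance, "species_single_sample")
  expect_equal(nrow(tab), 3)
  expect_equal(nrow(species_wd_table(samples[0, ])), 0)
})

test_that("site SD/mean ratio averages species ratios", {
  tab <- data.frame(taxon = c("a", "b"), family = "F",
                    wd_mean = c(0.5, 0.8), wd_sd = c(0.1, 0.24),
                    n_samples = c(2L, 3L),
                    provenance = "species_measured")
  expect_equal(sd_mean_ratio(tab), 0.25)
  # weighted variant
  expect_equal(sd_mean_ratio(tab, over = "samples"),
               weighted.mean(c(0.2, 0.3), c(2, 3)))
  # fixed point: identical ratios
  tab$wd_sd <- tab$wd_mean * 0.2
  expect_equal(sd_mean_ratio(tab), 0.2)
  tab$wd_sd <- NA_real_
  expect_error(sd_mean_ratio(tab), "supply a default")
})

test_that("the imputation ladder walks species, family, dropped", {
  sp_tab <- data.frame(taxon = "spA", family = "famA", wd_mean = 0.5,
                       wd_sd = NA_real_, n_samples = 1L,
                       provenance = "species_single_sample")
  fam_tab <- data.frame(taxon = "famB", wd_mean = 0.62, n_species = 3L)
  ind <- data.frame(
    plot_id = "p", individual_id = c("a", "b", "c", "d"),
    growth_form = c("tree", "tree", "tree", "liana"),
    species = c("spA", "spX", "spY", "spZ"),
    family = c("famA", "famB", "", ""),
    dbh_cm = 10, height_m = 8, stringsAsFactors = FALSE)

  out <- assign_wood_density(ind, sp_tab, fam_tab, ratio = 0.200)
  # single-sample species: SD from the site ratio
  expect_equal(out$wd_mean[1], 0.5)
  expect_equal(out$wd_sd[1], 0.1)
  expect_equal(out$wd_provenance[1], "species_single_sample")
  # family rung with the other site's ratio
  out2 <- assign_wood_density(ind, sp_tab, fam_tab, ratio = 0.234)
  expect_equal(out2$wd_mean[2], 0.62)
  expect_equal(out2$wd_sd[2], 0.62 * 0.234, tolerance = 1e-12)
  expect_equal(out2$wd_provenance[2], "family_mean")
  # no species, no family: dropped for trees, not required for lianas
  expect_equal(out$wd_provenance[3], "dropped")
  expect_equal(out$wd_provenance[4], "not_required")
  expect_error(assign_wood_density(ind, sp_tab, fam_tab, ratio = -1),
               "positive")
})

test_that("imputation is deterministic, idempotent and order-independent", {
  st <- generate_study(small_config())
  est <- estimate_stocks(st$stems, st$wd_samples, st$soils, st$plots)
  ind <- est$individuals
  samples_a <- st$wd_samples[st$wd_samples$site == "gradient_A", ]
  sp_tab <- species_wd_table(samples_a)
  fam_tab <- family_wd_table(sp_tab)
  ratio <- sd_mean_ratio(sp_tab)
  sub <- ind[ind$site == "gradient_A",
             c("plot_id", "individual_id", "growth_form", "species",
               "family", "dbh_cm", "height_m")]
  once <- assign_wood_density(sub, sp_tab, fam_tab, ratio)
  twice <- assign_wood_density(once[, names(sub)], sp_tab, fam_tab, ratio)
  expect_equal(once$wd_mean, twice$wd_mean)
  perm <- sample(nrow(sub))
  shuffled <- assign_wood_density(sub[perm, ], sp_tab, fam_tab, ratio)
  expect_equal(shuffled$wd_mean, once$wd_mean[perm])
})

test_that("planted missingness rates are recovered exactly", {
  st <- generate_study(small_config(seed = 7L))
  est <- estimate_stocks(st$stems, st$wd_samples, st$soils, st$plots)
  rep <- est$wd_report
  for (s in c("gradient_A", "gradient_B")) {
    planted <- st$ground_truth$missingness[[s]]
    fam_n <- rep$n[rep$site == s & rep$provenance == "family_mean"]
    drop_n <- rep$n[rep$site == s & rep$provenance == "dropped"]
    expect_identical(fam_n, planted$n_family)
    expect_identical(drop_n, planted$n_dropped)
    expect_identical(sum(rep$n[rep$site == s]),
                     as.integer(planted$n_individuals))
  }
})

test_that("family means average species means by default", {
  samples <- data.frame(
    species = c("a", "a", "a", "b"),
    family = "F1",
    wd_gcm3 = c(0.4, 0.4, 0.4, 0.8))
  sp_tab <- species_wd_table(samples)
  fam <- family_wd_table(sp_tab)
  expect_equal(fam$wd_mean, 0.6)        # (0.4 + 0.8) / 2, not sample mean
  fam_s <- family_wd_table(sp_tab, samples, method = "samples")
  expect_equal(fam_s$wd_mean, 0.5)      # raw-sample mean
})
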