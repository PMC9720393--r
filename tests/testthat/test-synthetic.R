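test_that("simulated practices show the mode-typical covariate contrasts", {
  des <- survey_design(sites_per_mode = 5)
  pr <- simulate_practices(des, seed = 11)
  expect_equal(nrow(pr), 20)
  by_mode <- function(col) tapply(pr[[col]], pr$mode, mean)
  of <- by_mode("organic_fertilizer_1e3kg_ha")
  expect_gt(of[["RM"]], of[["RG"]])
  expect_gt(of[["RM"]], 1.8 * mean(of[c("RG", "RC", "RD")]))
  ir <- by_mode("irrigation_1e3m3_ha")
  expect_gt(min(ir[c("RC", "RD")]), max(ir[c("RG", "RM")]))
  hw <- by_mode("hand_weeding_h_ha")
  expect_lt(max(hw[c("RC", "RD")]), 0.65 * min(hw[c("RG", "RM")]))
  expect_true(all(pr$consecutive_years %in% 3:10))
  expect_true(all(pr$green_manure_1e3kg_ha[pr$mode != "RG"] == 0))
})

test_that("empty design yields an empty practice collection", {
  des <- survey_design(sites_per_mode = 0)
  pr <- simulate_practices(des, seed = 1)
  expect_equal(nrow(pr), 0)
  expect_true(all(c("site_id", "mode", "consecutive_years") %in% names(pr)))
})

test_that("identical seeds give byte-identical practices and surveys", {
  des <- survey_design()
  a <- simulate_seedbank(des, seed = 99)
  b <- simulate_seedbank(des, seed = 99)
  expect_identical(a$practices, b$practices)
  expect_identical(as.data.frame(a$survey), as.data.frame(b$survey))
  c2 <- simulate_seedbank(des, seed = 100)
  expect_false(identical(as.data.frame(a$survey), as.data.frame(c2$survey)))
})

test_that("generated counts are non-negative integers with full coverage", {
  des <- survey_design()
  sim <- simulate_seedbank(des, seed = 5)
  sv <- sim$survey
  expect_true(is.integer(sv$count))
  expect_true(all(sv$count >= 0))
  quad <- unique(sv[c("site", "field", "quadrat")])
  expect_equal(nrow(quad), 4 * 3 * 3 * 9)
  expect_true(all(sv$species %in% des$species_pool$species_id))
})

test_that("empirical mean density recovers the design density within 5%", {
  # >= 10^4 quadrats: 4 modes x 31 sites x 3 fields x 27 quadrats
  des <- survey_design(sites_per_mode = 31, quadrats_per_field = 27)
  sim <- simulate_seedbank(des, seed = 17)
  sv <- sim$survey
  n_quadrats <- nrow(unique(sv[c("site", "field", "quadrat")]))
  expect_gte(n_quadrats, 1e4)
  mean_density <- sum(sv$count) / n_quadrats /
    (survey_parts(sv) * survey_part_area(sv))
  expect_lt(abs(mean_density / des$mean_total_density - 1), 0.05)
})

test_that("count dispersion approaches Poisson as k grows", {
  # constant per-quadrat mean within a field: no site/field density noise
  des <- survey_design(sites_per_mode = 1, fields_per_site = 1,
                       quadrats_per_field = 3000,
                       overdispersion_k = 1e8,
                       density_site_sd = 0, density_field_sd = 0)
  pr <- simulate_practices(des, seed = 3)
  sim <- simulate_survey(des, pr, seed = 4)
  sv <- as.data.frame(sim$survey)
  # moment check per (site, species) over >= 10^4 draws in total
  one_site <- sv[sv$site == sv$site[1], ]
  wide <- xtabs(count ~ quadrat + species, data = one_site)
  mu <- colMeans(wide)
  v <- apply(wide, 2, stats::var)
  keep <- mu > 5
  expect_gt(sum(keep), 3)
  ratio <- v[keep] / mu[keep]
  expect_true(all(abs(ratio - 1) < 0.15))
  # and with strong overdispersion the same ratio is clearly above 1
  des2 <- survey_design(sites_per_mode = 1, fields_per_site = 1,
                        quadrats_per_field = 3000, overdispersion_k = 2,
                        density_site_sd = 0, density_field_sd = 0)
  sim2 <- simulate_survey(des2, simulate_practices(des2, seed = 3), seed = 4)
  sv2 <- as.data.frame(sim2$survey)
  one2 <- sv2[sv2$site == sv2$site[1], ]
  wide2 <- xtabs(count ~ quadrat + species, data = one2)
  mu2 <- colMeans(wide2)
  v2 <- apply(wide2, 2, stats::var)
  keep2 <- mu2 > 5
  expect_true(all(v2[keep2] / mu2[keep2] > 1.5))
})

test_that("symmetric design recovers equal guild IV shares", {
  pool <- data.frame(
    species_id = sprintf("sp%02d", 1:30),
    guild = rep(c("grass", "sedge", "broadleaf"), each = 10),
    stringsAsFactors = FALSE
  )
  profile <- matrix(1 / 3, 4, 3,
                    dimnames = list(c("RG", "RM", "RC", "RD"),
                                    c("grass", "sedge", "broadleaf")))
  des <- survey_design(sites_per_mode = 10, species_pool = pool,
                       mode_guild_profile = profile,
                       covariate_effect = matrix(0, 7, 3),
                       site_sd = 0.1)
  sim <- simulate_seedbank(des, seed = 23)
  tab <- phyto_table(sim$survey, by = "mode")
  comp <- guild_composition(tab, pool)
  shares <- tapply(comp$pct, comp$guild, mean)
  expect_true(all(abs(shares - 100 / 3) < 6))
})

test_that("default RD communities are grass-dominated", {
  sim <- simulate_seedbank(survey_design(sites_per_mode = 4), seed = 31)
  tab <- phyto_table(sim$survey, by = "mode")
  comp <- guild_composition(tab, jiangsu_occurrence())
  rd <- comp[comp$stratum == "RD", ]
  expect_equal(rd$guild[which.max(rd$pct)], "grass")
})

test_that("missing practice coverage and invalid designs are rejected", {
  des <- survey_design()
  expect_error(survey_design(overdispersion_k = 0), "overdispersion")
  expect_error(survey_design(geometric_ratio = 1), "geometric_ratio")
  expect_error(survey_design(mode_guild_profile = matrix(1, 2, 2)),
               "mode_guild_profile")
  pr <- simulate_practices(des, seed = 1)
  pr$crayfish_kg_ha[1] <- -5
  expect_error(simulate_survey(des, pr, seed = 1), "non-negative")
})
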