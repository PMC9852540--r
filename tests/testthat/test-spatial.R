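# a deterministic classified bundle with ranges, country raster, overrides
spatial_fixture <- function(n = 120, seed = 14) {
  cfg <- synth_config(n_species = n, seed = seed, grid = grid_spec(20, 20),
                      range_cells_mean = 25, n_countries = 5)
  tree <- sim_tree(cfg)
  rec <- build_threat_sets(classify_trends(sim_traits_and_trends(tree, cfg)))
  stack <- sim_ranges(rec, cfg)
  country <- sim_country_raster(cfg)
  overrides <- sim_overrides(rec, cfg, n_overrides = 6)
  list(rec = rec, stack = stack, country = country, overrides = overrides,
       cfg = cfg)
}

test_that("niche richness equals a brute-force per-cell recount", {
  fx <- spatial_fixture()
  for (ni in c("nocturnal", "diurnal")) {
    rr <- richness_raster(fx$stack, fx$rec, ni)
    members <- fx$rec$species_id[!is.na(fx$rec$diel_niche) &
                                   fx$rec$diel_niche == ni]
    for (cell in sample(400, 40)) {
      r <- (cell - 1) %/% 20 + 1; cc <- (cell - 1) %% 20 + 1
      expect_equal(rr[r, cc],
                   sum(fx$stack$presence[members, cell]))
    }
  }
  one <- fx$stack
  one$presence <- one$presence[1, , drop = FALSE]
  ni1 <- as.character(fx$rec$diel_niche[1])
  if (!is.na(ni1)) {
    r1 <- richness_raster(one, fx$rec, ni1)
    expect_equal(sum(r1), sum(one$presence))
  }
})

test_that("species missing from the trait table are an error", {
  fx <- spatial_fixture(30, 15)
  rownames(fx$stack$presence)[1] <- "ghost"
  expect_error(richness_raster(fx$stack, fx$rec, "nocturnal"), "ghost")
})

test_that("decline proportions equal the brute-force oracle in both mask modes, with overrides", {
  fx <- spatial_fixture()
  for (mm in c("richness", "decliners")) {
    got <- decline_proportion_raster(fx$stack, fx$rec, "nocturnal",
                                     "habitat_loss",
                                     overrides = fx$overrides,
                                     country_raster = fx$country,
                                     mask_mode = mm)
    want <- brute_decline_raster(fx$stack, fx$rec, "nocturnal",
                                 "habitat_loss", fx$overrides, fx$country,
                                 mask_mode = mm)
    expect_equal(got$numerator, want$numerator, label = mm)
    expect_equal(got$denominator, want$denominator, ignore_attr = TRUE)
    expect_equal(got$proportion, want$proportion, tolerance = 1e-12)
  }
  # and without overrides, for a second niche/threat pair
  got <- decline_proportion_raster(fx$stack, fx$rec, "diurnal", "harvesting")
  want <- brute_decline_raster(fx$stack, fx$rec, "diurnal", "harvesting")
  expect_equal(got$proportion, want$proportion, tolerance = 1e-12)
})

test_that("per-cell proportions are consistent fractions of the niche richness", {
  fx <- spatial_fixture(80, 16)
  ly <- decline_proportion_raster(fx$stack, fx$rec, "nocturnal",
                                  "habitat_loss")
  ok <- ly$mask_reason == "none"
  expect_true(all(ly$proportion[ok] >= 0 & ly$proportion[ok] <= 1))
  recon <- ly$proportion[ok] * ly$denominator[ok]
  expect_equal(recon, round(recon), tolerance = 1e-9)
  expect_true(all(ly$numerator <= ly$denominator))
  # masked exactly at the <= 5 boundary under the richness reading
  expect_true(all(ly$mask_reason[ly$denominator <= 5] != "none"))
  expect_true(all(ly$mask_reason[ly$denominator == 0] == "no_species"))
})

test_that("a country override removes the species from that country's numerator only", {
  g <- grid_spec(2, 2, cell_size_m = 1)
  rec <- make_records(7, niche = "nocturnal")
  rec$iucn_trend <- "decreasing"
  rec <- classify_trends(rec)
  rec$threat_habitat_loss <- 1L
  rec <- build_threat_sets(rec)
  P <- matrix(1L, 7, 4, dimnames = list(rec$species_id, NULL))
  stack <- range_stack(P, g)
  country <- matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE)
  ov <- data.frame(species_id = "sp1", country_code = 2L)
  ly <- decline_proportion_raster(stack, rec, "nocturnal", "habitat_loss",
                                  overrides = ov, country_raster = country,
                                  mask_mode = "richness", mask_threshold = 5)
  expect_equal(ly$numerator[1, ], c(7L, 7L))   # country 1 untouched
  expect_equal(ly$numerator[2, ], c(6L, 6L))   # override drops sp1
  expect_equal(ly$denominator[2, 1], 7L)       # denominator unchanged
  expect_equal(ly$proportion[2, 1], 6 / 7)
  ov2 <- data.frame(species_id = "nobody", country_code = 1L)
  expect_error(decline_proportion_raster(stack, rec, "nocturnal",
                                         "habitat_loss", overrides = ov2,
                                         country_raster = country),
               "unknown species")
  ov3 <- data.frame(species_id = "sp1", country_code = 9L)
  expect_error(decline_proportion_raster(stack, rec, "nocturnal",
                                         "habitat_loss", overrides = ov3,
                                         country_raster = country),
               "unknown country")
})

test_that("threat layers are not additive: multi-threat species are counted in each", {
  fx <- spatial_fixture(100, 17)
  threats <- c("habitat_loss", "harvesting", "conflict")
  nums <- lapply(threats, function(th)
    decline_proportion_raster(fx$stack, fx$rec, "nocturnal", th)$numerator)
  total <- Reduce(`+`, nums)
  any_threat <- decline_proportion_raster(fx$stack, fx$rec, "nocturnal",
                                          "habitat_loss")$denominator
  for (nm in nums) expect_true(all(total >= nm))
})

test_that("crepuscular layers are producible though absent from default reports", {
  fx <- spatial_fixture(60, 18)
  ly <- decline_proportion_raster(fx$stack, fx$rec, "crepuscular",
                                  "habitat_loss")
  expect_s3_class(ly, "decline_raster")
})

test_that("decline maps round-trip through disk with masked cells as nodata", {
  fx <- spatial_fixture(90, 19)
  ly <- decline_proportion_raster(fx$stack, fx$rec, "nocturnal",
                                  "habitat_loss")
  dir <- withr::local_tempdir()
  files <- write_decline_maps(list(ly), dir)
  m <- read_asc(file.path(dir, "nocturnal_habitat_loss.asc"))
  expect_equal(unclass(m), unclass(ly$proportion), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(is.na(m[ly$mask_reason != "none"])))
  mask <- read_asc(file.path(dir, "nocturnal_habitat_loss_mask.asc"))
  expect_equal(matrix(c("none", "low_richness", "no_species")[mask + 1],
                      nrow(mask)), unclass(ly$mask_reason),
               ignore_attr = TRUE)
  # stable across repeated writes
  dir2 <- withr::local_tempdir()
  write_decline_maps(list(ly), dir2)
  expect_identical(readLines(file.path(dir, "nocturnal_habitat_loss.asc")),
                   readLines(file.path(dir2, "nocturnal_habitat_loss.asc")))
})
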