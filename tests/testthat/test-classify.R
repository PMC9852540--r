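test_that("trend assignment follows the documented precedence", {
  cases <- list(
    # iucn_trend, category, literature -> class, provenance
    list("unknown", "EN", "unknown", "declining", "category_rule"),
    list("decreasing", "LC", "unknown", "declining", "iucn_trend"),
    list("unknown", "LC", "unknown", "unclassified", "none"),
    list("unknown", "DD", "declining", "declining", "literature"),
    list("stable", "CR", "unknown", "non_declining", "iucn_trend"),
    list("increasing", "VU", "declining", "non_declining", "iucn_trend"),
    list("unknown", "NT", "non_declining", "declining", "category_rule"),
    list("unknown", "DD", "non_declining", "non_declining", "literature"))
  for (cs in cases) {
    a <- assign_trend(cs[[1]], cs[[2]], cs[[3]])
    expect_equal(a$trend_class, cs[[4]],
                 label = paste(cs[[1]], cs[[2]], cs[[3]]))
    expect_equal(a$trend_provenance, cs[[5]])
  }
})

test_that("trend assignment is total, deterministic and order-invariant", {
  grid <- expand.grid(t = iucn_trend_levels(), c = iucn_categories(),
                      l = literature_trend_levels(),
                      stringsAsFactors = FALSE)
  a <- assign_trend(grid$t, grid$c, grid$l)
  expect_true(all(a$trend_class %in% c("declining", "non_declining",
                                       "unclassified")))
  expect_true(all(a$trend_provenance[a$trend_class != "unclassified"] !=
                    "none"))
  set.seed(1)
  perm <- sample(nrow(grid))
  b <- assign_trend(grid$t[perm], grid$c[perm], grid$l[perm])
  expect_identical(b, a[perm, ], ignore_attr = TRUE)
})

test_that("marine and fossorial species are excluded with counted reasons", {
  r <- make_records(50)
  r$is_marine[1:7] <- TRUE
  r$is_fossorial[7:11] <- TRUE  # one overlap with marine
  out <- filter_analysis_set(r)
  expect_equal(nrow(out), 39)
  expect_equal(attr(out, "exclusions"),
               c(marine = 7L, fossorial = 5L, either = 11L))
  expect_false(any(out$is_marine | out$is_fossorial))
})

test_that("category-trend concordance is the declining share of known-trend threatened species", {
  r <- make_records(12, category = "EN")
  r$iucn_trend <- c(rep("decreasing", 9), "stable", "unknown", "unknown")
  cc <- category_trend_concordance(r)
  expect_equal(as.numeric(cc), 0.9)
  expect_equal(attr(cc, "n"), 10L)
  r2 <- make_records(5, category = "LC")
  expect_warning(cc2 <- category_trend_concordance(r2), "undefined")
  expect_true(is.na(cc2))
})

test_that("threat sets distinguish empty from unknown and reject ambiguity", {
  r <- make_records(3)
  r$threat_habitat_loss[1] <- 1L
  r$threat_harvesting[1] <- 1L
  for (tc in paste0("threat_", threat_categories())) r[[tc]][2] <- NA_integer_
  r <- build_threat_sets(r)
  expect_true(all(r$threats_known == c(TRUE, FALSE, TRUE)))
  expect_equal(r$n_threats, c(2L, NA_integer_, 0L))
  expect_equal(threat_set(r[1, ]), c("habitat_loss", "harvesting"))
  expect_equal(count_threats(r[3, ]), 0L)
  expect_error(count_threats(r[2, ]), "unknown")
  r$threat_disease[2] <- 0L  # now mixed NA/0 for species 2
  expect_error(build_threat_sets(r), "mixed")
})

test_that("threat counts span the full ten-category contract", {
  r <- make_records(1)
  for (tc in paste0("threat_", threat_categories())) r[[tc]] <- 1L
  r <- build_threat_sets(r)
  expect_equal(count_threats(r[1, ]), 10L)
})

test_that("provenance classes partition every input table", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 60
    r <- make_records(n)
    r$iucn_trend <- sample(iucn_trend_levels(), n, TRUE)
    r$iucn_category <- sample(iucn_categories(), n, TRUE)
    r$literature_trend <- sample(literature_trend_levels(), n, TRUE)
    r <- classify_trends(r)
    s <- trend_provenance_summary(r)
    expect_equal(sum(s$counts), n)
    expect_equal(sum(s$unclassified_by_category),
                 unname(s$counts["unclassified"]))
  }
})

test_that("per-niche decline table matches a brute-force group-by recount", {
  set.seed(11)
  n <- 200
  r <- make_records(n)
  r$diel_niche <- factor(sample(diel_levels(), n, TRUE,
                                c(.5, .1, .2, .2)), levels = diel_levels())
  r$iucn_trend <- sample(iucn_trend_levels(), n, TRUE)
  r$iucn_category <- sample(iucn_categories(), n, TRUE)
  r <- classify_trends(r)
  tab <- niche_decline_table(r)
  for (i in seq_len(nrow(tab))) {
    ni <- tab$diel_niche[i]
    expect_equal(tab$n_total[i], sum(r$diel_niche == ni))
    expect_equal(tab$n_declining[i],
                 sum(r$diel_niche == ni & r$trend_class == "declining"))
  }
  # percent column always recomputable from its own counts
  expect_equal(tab$percent_declining,
               suppressWarnings(decline_percent(tab$n_declining, tab$n_total)))
  expect_equal(suppressWarnings(decline_percent(0, 10)), 0.0)
})

test_that("presentation rounding is half-up to one decimal", {
  expect_equal(round_half_up(39.85, 1), 39.9)  # round() would give 39.8
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(decline_percent(1402, 3498), 40.1)
})

test_that("megafauna niche fractions equal a brute-force filter-and-count", {
  set.seed(3)
  r <- make_records(80)
  r$diel_niche <- factor(sample(diel_levels(), 80, TRUE),
                         levels = diel_levels())
  r$body_mass_kg <- rlnorm(80, 1, 2)
  r$body_mass_kg[1:5] <- NA
  mf <- megafauna_niche_fraction(r, 45)
  heavy <- r[!is.na(r$body_mass_kg) & r$body_mass_kg > 45, ]
  expect_equal(attr(mf, "n_heavy"), nrow(heavy))
  expect_equal(attr(mf, "n_missing_mass"), 5L)
  for (i in seq_len(4))
    expect_equal(mf$n[i], sum(heavy$diel_niche == mf$diel_niche[i]))
  if (nrow(heavy)) expect_equal(sum(mf$fraction), 1)
  r$body_mass_kg <- 1
  expect_warning(mf2 <- megafauna_niche_fraction(r, 45), "threshold")
  expect_true(all(is.na(mf2$fraction)))
})

test_that("all-cathemeral heavyweights give fraction one", {
  r <- make_records(6, niche = "cathemeral")
  r$body_mass_kg <- 100
  mf <- megafauna_niche_fraction(r, 45)
  expect_equal(mf$fraction[mf$diel_niche == "cathemeral"], 1)
})
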