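test_that("tier boundaries are honoured exactly and tiers are monotone", {
  expect_equal(tier(c(0.92, 0.90, 0.80, 0.75, 0.60, 0.59, 0)),
               c("###", "###", "##", "##", "#", "", ""))
  fr <- seq(0, 1, by = 0.01)
  ranks <- match(tier(fr), c("", "#", "##", "###"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("hand-built fits aggregate with the documented estimators", {
  mk_fit_obj <- function(coefs, ps, r2 = 0.1) {
    list(coefficients = coefs, p_values = ps, pseudo_r2 = r2, alpha = 1,
         converged = TRUE, degenerate = FALSE, n_obs = 10,
         family = "binomial")
  }
  f1 <- mk_fit_obj(c(a = 1.0), c(a = 0.001))
  f2 <- mk_fit_obj(c(a = 2.0), c(a = 0.5))
  agg <- aggregate_fits(list(f1, f2))
  expect_equal(agg$summary$mean_coef, 1.5)
  expect_equal(agg$summary$sd_coef, sd(c(1, 2)))  # n-1 denominator
  expect_equal(agg$summary$frac_p_lt_001, 0.5)
  # order invariance
  agg2 <- aggregate_fits(list(f2, f1))
  expect_equal(agg2$summary, agg$summary)
  # non-converged fits are dropped with a warning and counted
  f3 <- mk_fit_obj(c(a = 50), c(a = 0.9)); f3$converged <- FALSE
  expect_warning(agg3 <- aggregate_fits(list(f1, f2, f3)), "did not converge")
  expect_equal(agg3$n_converged, 2)
  expect_equal(agg3$summary$mean_coef, 1.5)
})

test_that("an ensemble of identical trees gives sd zero and all-or-nothing significance", {
  b <- small_bundle(120, seed = 6, bl_jitter_sd = 0)
  rec <- classify_trends(b$records)
  rec$declining <- as.integer(rec$trend_class == "declining")
  rec <- rec[!is.na(rec$diel_niche), ]
  en <- fit_ensemble(declining ~ diel_niche, rec, b$trees,
                     family = "binomial", B = 3, seed = 1)
  expect_equal(en$summary$sd_coef, rep(0, nrow(en$summary)), tolerance = 1e-12)
  expect_true(all(en$summary$frac_p_lt_001 %in% c(0, 1)))
})

test_that("threat-model selection applies the >= 50 decliners rule", {
  r <- make_records(200)
  r$iucn_trend <- "decreasing"           # everyone declining
  r <- classify_trends(r)
  r$threat_habitat_loss <- c(rep(1L, 50), rep(0L, 150))  # boundary: kept
  r$threat_harvesting <- c(rep(1L, 49), rep(0L, 151))    # 49: excluded
  r$threat_conflict <- 1L
  r <- build_threat_sets(r)
  sel <- select_threat_models(r)
  expect_true("habitat_loss" %in% sel)
  expect_false("harvesting" %in% sel)
  expect_true("conflict" %in% sel)
  # brute-force count agreement
  counts <- attr(sel, "counts")
  dec <- r[r$trend_class == "declining" & r$threats_known, ]
  for (th in threat_categories())
    expect_equal(unname(counts[th]), sum(dec[[paste0("threat_", th)]] == 1L))
})

test_that("the full study yields one summary per model family and selected threat", {
  b <- small_bundle(200, seed = 9)
  rec <- filter_analysis_set(b$records)
  rec <- impute_niche(rec, b$tree)
  rec <- classify_trends(rec)
  rec <- build_threat_sets(rec)
  study <- suppressWarnings(run_study(rec, b$trees, B = 2, seed = 1,
                                      min_threat_n = 20L))
  sel <- select_threat_models(rec, 20L)
  expect_equal(length(study), 2 + length(sel))
  expect_s3_class(study$decline, "phylo_glm_ensemble")
  expect_s3_class(study$n_threats, "phylo_glm_ensemble")
  # imputed-niche species are excluded from the regression n
  expect_equal(study$decline$n_obs,
               sum(!rec$niche_imputed & !is.na(rec$diel_niche)))
})

test_that("a study with no decliners flags the threat models as empty", {
  b <- small_bundle(60, seed = 10)
  rec <- classify_trends(b$records)
  rec$iucn_trend <- "stable"
  rec$literature_trend <- "unknown"
  rec$iucn_category <- "LC"
  rec <- classify_trends(rec)
  rec <- build_threat_sets(rec)
  ws <- capture_warnings(study <- run_study(rec, b$trees, B = 2, seed = 1))
  expect_true(any(grepl("no declining species", ws)))
  expect_null(study$n_threats)
  expect_false(study$decline$reliable)  # constant response: flagged, not fit
})

test_that("study runs are bit-reproducible under a fixed seed", {
  b <- small_bundle(100, seed = 12)
  rec <- classify_trends(build_threat_sets(b$records))
  rec <- rec[!is.na(rec$diel_niche), ]
  rec$declining <- as.integer(rec$trend_class == "declining")
  e1 <- fit_ensemble(declining ~ diel_niche, rec, b$trees,
                     family = "binomial", B = 2, seed = 3)
  e2 <- fit_ensemble(declining ~ diel_niche, rec, b$trees,
                     family = "binomial", B = 2, seed = 3)
  expect_identical(e1$summary, e2$summary)
  expect_identical(e1$coef_matrix, e2$coef_matrix)
})

test_that("sensitivity variants subset and recode as documented", {
  b <- small_bundle(150, seed = 13)
  rec <- classify_trends(build_threat_sets(filter_analysis_set(b$records)))
  rec <- impute_niche(rec, b$tree)

  # threat_status_recode equals a brute-force recode of the category column
  v <- suppressWarnings(run_sensitivity(rec, b$trees, "threat_status_recode",
                                        B = 2, seed = 1, min_threat_n = 10L))
  brute <- ifelse(rec$iucn_category %in% c("VU", "EN", "CR"), 1L,
           ifelse(rec$iucn_category %in% c("LC", "NT"), 0L, 0L))
  rr <- rec[!rec$niche_imputed & !is.na(rec$diel_niche), ]
  brute_rr <- brute[match(rr$species_id, rec$species_id)]
  expect_equal(v$decline$n_obs, nrow(rr))
  expect_equal(sum(brute_rr),
               sum(rr$iucn_category %in% c("VU", "EN", "CR")))

  # excluding literature trends moves those species to unclassified; under
  # drop mode only iucn/category-rule species remain in the decline model
  v2 <- suppressWarnings(run_sensitivity(rec, b$trees,
                                         "exclude_literature_trends",
                                         B = 2, seed = 1,
                                         unclassified_mode = "drop",
                                         min_threat_n = 10L))
  expect_equal(v2$decline$n_obs,
               sum(rr$trend_provenance %in% c("iucn_trend", "category_rule")))

  # an empty subset is flagged, not fitted
  rec2 <- rec
  rec2$order <- "Rodentia"
  expect_warning(v3 <- run_sensitivity(rec2, b$trees, "primates_only",
                                       B = 2, seed = 1), "no species")
  expect_null(v3)
})
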