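#' Phylogenetically impute missing diel niches
#'
#' Fits an Mk model ([fit_mk()]) to the observed niches on the supplied
#' tree and fills each missing niche with its maximum-posterior state
#' ([impute_tips()]), flagging `niche_imputed`. Imputed species are
#' excluded from regressions downstream (to avoid circularity) but keep
#' their niche for descriptive summaries and maps.
#'
#' @param records species table (possibly with `NA` niches).
#' @param tree `phylo` covering the species.
#' @param model Mk flavour, `"ER"` or `"ARD"`.
#' @return records with `diel_niche` completed and `niche_imputed` set;
#'   attribute `"imputation"` holds the [impute_tips()] table.
#' @export
impute_niche <- function(records, tree, model = "ER") {
  miss <- is.na(records$diel_niche)
  if (!any(miss)) return(records)
  al <- .align_tree_data(tree, records)
  states <- setNames(as.character(al$data$diel_niche), al$data$species_id)
  fit <- fit_mk(al$tree, states, model = model, states = diel_levels())
  imp <- impute_tips(fit)
  idx <- match(imp$species_id, records$species_id)
  records$diel_niche[idx] <- factor(imp$state, levels = diel_levels())
  records$niche_imputed[idx] <- TRUE
  attr(records, "imputation") <- imp
  records
}

#' Run the full pipeline on a synthetic or supplied input bundle
#'
#' Stages: (1) simulate (or read) the input bundle; (2) classify — exclude
#' marine/fossorial species, impute missing niches, assign trends, build
#' threat sets; (3) fit the three model families across the tree ensemble;
#' (4) sensitivity variants; (5) map richness and per-threat proportional
#' declines. Every stage writes CSV/raster outputs plus a JSON manifest of
#' seeds and the full filter-count audit trail. Reruns with the same
#' config are byte-identical.
#'
#' @param config list with elements `synth` (a [synth_config()]; used when
#'   no `input_dir` is given), `B` (trees per model), `seed`
#'   (tree-sampling seed), `unclassified_mode`, `variants` (character
#'   vector of [run_sensitivity()] variants, possibly empty),
#'   `mask_mode`, `map_niches`, `map_threats`.
#' @param outdir output directory.
#' @return invisible list: `records`, `study`, `sensitivity`, `maps`,
#'   `manifest`, `outdir`.
#' @export
run_pipeline <- function(config = list(), outdir) {
  cfg <- modifyList(list(
    synth = synth_config(), B = NULL, seed = 1L,
    unclassified_mode = "code_zero",
    variants = character(),
    mask_mode = "richness",
    map_niches = c("nocturnal", "cathemeral", "diurnal"),
    map_threats = c("habitat_loss", "harvesting", "conflict"),
    min_threat_n = 50L), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: inputs ------------------------------------------------------
  bundle <- tryCatch(sim_bundle(cfg$synth, file.path(outdir, "inputs")),
                     error = function(e) stop("simulate stage: ",
                                              conditionMessage(e),
                                              call. = FALSE))
  records <- bundle$records
  trees <- bundle$trees
  n_input <- nrow(records)

  # stage 2: classify ----------------------------------------------------
  cls <- tryCatch({
    r <- filter_analysis_set(records)
    excl <- attr(r, "exclusions")
    r <- impute_niche(r, bundle$tree)
    r <- classify_trends(r)
    r <- build_threat_sets(r)
    list(records = r, exclusions = excl)
  }, error = function(e) stop("classify stage: ", conditionMessage(e),
                              call. = FALSE))
  rec <- cls$records
  write_species_table(rec, file.path(outdir, "classified.csv"))
  write.csv(niche_decline_table(rec),
            file.path(outdir, "decline_by_niche.csv"), row.names = FALSE)

  # stage 3: fit ----------------------------------------------------------
  study <- tryCatch(
    suppressWarnings(run_study(rec, trees, B = cfg$B, seed = cfg$seed,
                               unclassified_mode = cfg$unclassified_mode,
                               min_threat_n = cfg$min_threat_n)),
    error = function(e) stop("fit stage: ", conditionMessage(e),
                             call. = FALSE))
  fitrows <- do.call(rbind, lapply(study[!vapply(study, is.null, TRUE)],
                                   as.data.frame))
  write.csv(fitrows, file.path(outdir, "model_summaries.csv"),
            row.names = FALSE)

  # stage 4: sensitivity ---------------------------------------------------
  sens <- list()
  for (v in cfg$variants) {
    s <- tryCatch(
      suppressWarnings(run_sensitivity(rec, trees, v, B = cfg$B,
                                       seed = cfg$seed,
                                       unclassified_mode = cfg$unclassified_mode,
                                       min_threat_n = cfg$min_threat_n)),
      error = function(e) stop("sensitivity stage (", v, "): ",
                               conditionMessage(e), call. = FALSE))
    if (!is.null(s)) {
      rows <- do.call(rbind, lapply(s[!vapply(s, is.null, TRUE)],
                                    as.data.frame))
      write.csv(rows, file.path(outdir, paste0("sensitivity_", v, ".csv")),
                row.names = FALSE)
    }
    sens[[v]] <- s
  }

  # stage 5: map -----------------------------------------------------------
  maps <- tryCatch({
    stack <- bundle$stack
    stack$presence <- stack$presence[
      rownames(stack$presence) %in% rec$species_id, , drop = FALSE]
    layers <- list()
    for (ni in cfg$map_niches) for (th in cfg$map_threats) {
      layers[[paste(ni, th, sep = "_")]] <- decline_proportion_raster(
        stack, rec, ni, th,
        overrides = bundle$overrides, country_raster = bundle$country,
        mask_mode = cfg$mask_mode)
    }
    write_decline_maps(layers, file.path(outdir, "maps"))
    cellcsv <- do.call(rbind, lapply(layers, function(ly) {
      ok <- ly$mask_reason == "none"
      if (!any(ok)) return(NULL)
      data.frame(niche = ly$niche, threat = ly$threat,
                 cell = which(t(ok)) - 1L,
                 numerator = t(ly$numerator)[t(ok)],
                 denominator = t(ly$denominator)[t(ok)],
                 proportion = t(ly$proportion)[t(ok)])
    }))
    write.csv(cellcsv, file.path(outdir, "map_cells.csv"), row.names = FALSE)
    layers
  }, error = function(e) stop("map stage: ", conditionMessage(e),
                              call. = FALSE))

  # manifest ---------------------------------------------------------------
  prov <- trend_provenance_summary(rec)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dieldecline")),
    seed = cfg$seed, synth_seed = cfg$synth$seed,
    B = study$decline$B_used,
    counts = list(
      input = n_input,
      excluded_marine = unname(cls$exclusions["marine"]),
      excluded_fossorial = unname(cls$exclusions["fossorial"]),
      excluded_either = unname(cls$exclusions["either"]),
      retained = nrow(rec),
      niche_imputed = sum(rec$niche_imputed),
      regression_n = study$decline$n_obs,
      declining = sum(rec$trend_class == "declining"),
      unclassified = unname(prov$counts["unclassified"]),
      provenance = as.list(prov$counts)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  rep <- report_tables(rec, study, outdir)
  invisible(list(records = rec, study = study, sensitivity = sens,
                 maps = maps, manifest = manifest, report = rep,
                 outdir = outdir))
}

#' Summary tables in the shape of the headline figures
#'
#' Three tidy tables (written as CSV when `outdir` is given):
#' `decline_by_niche` — per-niche totals, decliners, percent and the
#' robustness tier of each modelled contrast; `threat_count_distribution`
#' — among decliners with known threats, the share facing 1, 2, 3 or 4+
#' threats per niche; `threat_by_niche` — per modelled threat, the percent
#' of each niche's decliners declining from it, with tiers.
#'
#' @param records classified species table.
#' @param study output of [run_study()].
#' @param outdir optional directory for the CSVs.
#' @return named list of data.frames.
#' @export
report_tables <- function(records, study, outdir = NULL) {
  ndt <- niche_decline_table(records)
  tiers <- study$decline$summary
  ndt$tier <- vapply(ndt$diel_niche, function(ni) {
    i <- grep(paste0(ni, "$"), tiers$term)
    if (length(i) == 1L) tiers$tier[i] else ""
  }, character(1))

  dec <- records[records$trend_class == "declining" &
                   records$threats_known %in% TRUE &
                   !is.na(records$diel_niche), , drop = FALSE]
  tcd <- do.call(rbind, lapply(diel_levels(), function(ni) {
    k <- dec$n_threats[dec$diel_niche == ni]
    bins <- c(`1` = sum(k == 1), `2` = sum(k == 2), `3` = sum(k == 3),
              `4+` = sum(k >= 4))
    data.frame(diel_niche = ni, n_declining = length(k),
               threats = names(bins), n = as.integer(bins),
               percent = suppressWarnings(
                 decline_percent(as.integer(bins), length(k))),
               stringsAsFactors = FALSE)
  }))

  tmods <- grep("^threat_", names(study), value = TRUE)
  tbn <- do.call(rbind, lapply(tmods, function(mn) {
    th <- sub("^threat_", "", mn)
    tc <- paste0("threat_", th)
    tiers <- study[[mn]]$summary
    do.call(rbind, lapply(diel_levels(), function(ni) {
      sel <- dec$diel_niche == ni
      i <- grep(paste0(ni, "$"), tiers$term)
      data.frame(threat = th, diel_niche = ni,
                 n_declining = sum(sel),
                 n_from_threat = sum(dec[[tc]][sel] == 1L),
                 percent = suppressWarnings(
                   decline_percent(sum(dec[[tc]][sel] == 1L), sum(sel))),
                 tier = if (length(i) == 1L) tiers$tier[i] else "",
                 stringsAsFactors = FALSE)
    }))
  }))

  out <- list(decline_by_niche = ndt, threat_count_distribution = tcd,
              threat_by_niche = tbn)
  if (!is.null(outdir)) {
    for (nm in names(out))
      write.csv(out[[nm]], file.path(outdir, paste0("report_", nm, ".csv")),
                row.names = FALSE)
  }
  out
}
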