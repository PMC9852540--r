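#' Configuration for the synthetic study generator
#'
#' Bundles every generative parameter for a complete study-shaped input
#' set: a birth-death phylogeny, diel niche evolved under a discrete
#' Markov (Mk-type) model whose stationary frequencies match the observed
#' niche mix of terrestrial mammals, decline status from a logistic model
#' with a latent phylogenetic (Brownian) effect, niche-dependent threat
#' rates, observation-layer missingness, and toy presence rasters. The
#' defaults emulate the real study's composition: niche base frequencies
#' from the published per-niche totals, a ~40% nocturnal decline rate with
#' a positive diurnal effect, ~3% missing niche, and primates concentrated
#' among diurnal species.
#'
#' @param n_species number of tips.
#' @param birth_rate,death_rate birth-death rates (birth > death).
#' @param mk_rate overall niche transition rate on a unit-depth tree.
#' @param niche_base_freqs length-4 simplex over [diel_levels()].
#' @param decline_logit named vector: `intercept` plus additive effects
#'   for crepuscular, cathemeral, diurnal (nocturnal is baseline).
#' @param phylo_signal marginal variance of the latent Brownian effect on
#'   the logit scale (0 = none).
#' @param threat_rates 10 x 4 matrix (threats x niches) of per-threat
#'   probabilities for *declining* species; non-decliners use
#'   `nondecliner_threat_scale` times these.
#' @param nondecliner_threat_scale multiplier for non-declining species.
#' @param missing_niche_frac,unknown_trend_frac,unknown_threat_frac
#'   observation-layer missingness fractions.
#' @param literature_known_frac fraction of rule-uncovered unknown-trend
#'   species whose trend a literature search recovers.
#' @param marine_frac,fossorial_frac fractions flagged for exclusion.
#' @param primate_frac_by_niche probability a species of each niche is a
#'   primate.
#' @param grid a [grid_spec()] for the toy rasters.
#' @param range_cells_mean mean range size in cells.
#' @param n_countries country regions on the toy country raster.
#' @param n_trees ensemble size; `bl_jitter_sd` log-normal branch jitter.
#' @param seed master seed; all stages derive from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_species = 800L, birth_rate = 1, death_rate = 0.3,
                         mk_rate = 6,
                         niche_base_freqs = c(nocturnal = 0.695,
                                              crepuscular = 0.0225,
                                              cathemeral = 0.1045,
                                              diurnal = 0.178),
                         decline_logit = c(intercept = -0.40,
                                           crepuscular = -0.01,
                                           cathemeral = 0.12,
                                           diurnal = 0.49),
                         phylo_signal = 0.5,
                         threat_rates = NULL,
                         nondecliner_threat_scale = 0.2,
                         missing_niche_frac = 0.03,
                         unknown_trend_frac = 0.42,
                         unknown_threat_frac = 0.013,
                         literature_known_frac = 0.75,
                         marine_frac = 0.025, fossorial_frac = 0.05,
                         primate_frac_by_niche = c(nocturnal = 0.033,
                                                   crepuscular = 0.02,
                                                   cathemeral = 0.04,
                                                   diurnal = 0.321),
                         grid = grid_spec(20, 20),
                         range_cells_mean = 12,
                         n_countries = 6L,
                         n_trees = 10L, bl_jitter_sd = 0.1,
                         seed = 1L) {
  niche_base_freqs <- niche_base_freqs / sum(niche_base_freqs)
  if (is.null(threat_rates)) {
    threat_rates <- rbind(
      habitat_loss  = c(0.91, 0.88, 0.88, 0.85),
      harvesting    = c(0.25, 0.25, 0.40, 0.52),
      conflict      = c(0.03, 0.03, 0.06, 0.07),
      climate_change = c(0.04, 0.04, 0.08, 0.04),
      non_native    = c(0.06, 0.05, 0.02, 0.02),
      pollution     = c(0.015, 0.015, 0.015, 0.015),
      hybridization = c(0.008, 0.008, 0.008, 0.008),
      prey_depletion = c(0.012, 0.012, 0.012, 0.012),
      disease       = c(0.015, 0.015, 0.015, 0.015),
      inbreeding    = c(0.006, 0.006, 0.006, 0.006))
    colnames(threat_rates) <- diel_levels()
  }
  stopifnot(birth_rate > death_rate, all(threat_rates >= 0 & threat_rates <= 1),
            abs(sum(niche_base_freqs) - 1) < 1e-9,
            all(c(missing_niche_frac, unknown_trend_frac,
                  unknown_threat_frac) >= 0),
            all(c(missing_niche_frac, unknown_trend_frac,
                  unknown_threat_frac) <= 1))
  structure(as.list(environment()), class = "synth_config")
}

# deterministic sub-seeds per stage, kept within 32-bit range
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% .Machine$integer.max
}

#' Simulate the study phylogeny
#'
#' Birth-death tree conditioned on the configured number of tips
#' (via `ape::rphylo`), rescaled to unit root-to-tip depth, tips labelled
#' `sp1..spN`.
#'
#' @param config a [synth_config()].
#' @return a rooted ultrametric `phylo`.
#' @export
sim_tree <- function(config) {
  tr <- with_seed(.stage_seed(config$seed, 1L),
                  ape::rphylo(config$n_species, config$birth_rate,
                              config$death_rate))
  tr$tip.label <- paste0("sp", seq_len(config$n_species))
  tr$edge.length <- tr$edge.length / max(diag(ape::vcv.phylo(tr)))
  tr
}

#' Simulate a posterior-style tree ensemble
#'
#' Copies of the base tree with independent log-normal branch-length
#' jitter (mean-preserving), standing in for a Bayesian posterior sample;
#' topology and tip set are preserved.
#'
#' @param tree base `phylo`.
#' @param config a [synth_config()].
#' @return `multiPhylo` of length `config$n_trees`.
#' @export
sim_ensemble <- function(tree, config) {
  sdl <- config$bl_jitter_sd
  trees <- with_seed(.stage_seed(config$seed, 2L), lapply(
    seq_len(config$n_trees), function(i) {
      tr <- tree
      if (sdl > 0)
        tr$edge.length <- tr$edge.length *
          rlnorm(length(tr$edge.length), -sdl^2 / 2, sdl)
      tr
    }))
  class(trees) <- "multiPhylo"
  trees
}

#' Simulate species traits, trends and threats
#'
#' Diel niche evolves along the tree under a discrete Markov model whose
#' stationary distribution equals the configured base frequencies
#' (rate matrix `Q_ij = mk_rate * pi_j`); a latent Brownian effect with
#' marginal variance `phylo_signal` is added to the decline logit; decline
#' is Bernoulli of `plogis(intercept + niche effect + latent)`. The
#' observation layer then emulates the classification inputs: Red List
#' trend known with probability `1 - unknown_trend_frac` (decreasing if
#' truly declining, else stable/increasing); Red List category drawn with
#' threatened categories concentrated on declining species (so the
#' category rule holds on average); a literature trend for part of the
#' species the rule does not cover; threat flags at niche-dependent rates
#' (all-NA for an `unknown_threat_frac` fraction); marine/fossorial flags;
#' body masses (heavier cathemeral species); and a `missing_niche_frac`
#' fraction of blanked niches. Ground truth is retained in `truth_*`
#' columns.
#'
#' @param tree `phylo` from [sim_tree()].
#' @param config a [synth_config()].
#' @return species table (one row per tip) ready for [classify_trends()],
#'   with truth columns `truth_niche`, `truth_decline`, `truth_latent`.
#' @export
sim_traits_and_trends <- function(tree, config) {
  n <- ape::Ntip(tree)
  pi <- config$niche_base_freqs
  with_seed(.stage_seed(config$seed, 3L), {
    Q <- config$mk_rate * matrix(pi, 4, 4, byrow = TRUE,
                                 dimnames = list(diel_levels(), diel_levels()))
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    root_state <- sample(diel_levels(), 1, prob = pi)
    x <- ape::rTraitDisc(tree, model = Q, states = diel_levels(),
                         root.value = match(root_state, diel_levels()))
    niche <- setNames(as.character(x), names(x))[tree$tip.label]

    C <- ape::vcv.phylo(tree)
    C <- C / max(diag(C))
    latent <- if (config$phylo_signal > 0) {
      L <- chol(C + diag(1e-10, n))
      sqrt(config$phylo_signal) * drop(crossprod(L, rnorm(n)))
    } else numeric(n)
    names(latent) <- rownames(C)
    latent <- latent[tree$tip.label]

    eff <- c(nocturnal = 0, config$decline_logit[c("crepuscular",
                                                   "cathemeral", "diurnal")])
    names(eff) <- diel_levels()
    p <- plogis(config$decline_logit[["intercept"]] + eff[niche] + latent)
    decl <- rbinom(n, 1, p) == 1L

    # observation layer ---------------------------------------------------
    trend_known <- runif(n) > config$unknown_trend_frac
    iucn_trend <- ifelse(!trend_known, "unknown",
                   ifelse(decl, "decreasing",
                          sample(c("stable", "increasing"), n, TRUE,
                                 c(0.8, 0.2))))
    cat_probs_decl <- c(LC = 0.22, NT = 0.15, VU = 0.20, EN = 0.20,
                        CR = 0.10, DD = 0.13, NE = 0)
    cat_probs_nond <- c(LC = 0.80, NT = 0.04, VU = 0.02, EN = 0.01,
                        CR = 0.00, DD = 0.13, NE = 0)
    iucn_category <- ifelse(decl,
      sample(iucn_categories(), n, TRUE, cat_probs_decl),
      sample(iucn_categories(), n, TRUE, cat_probs_nond))

    rule_covers <- iucn_trend == "unknown" &
      iucn_category %in% threatened_categories()
    lit_known <- iucn_trend == "unknown" & !rule_covers &
      runif(n) < config$literature_known_frac
    literature_trend <- ifelse(lit_known,
                               ifelse(decl, "declining", "non_declining"),
                               "unknown")

    rates <- config$threat_rates[, niche]  # 10 x n
    rates[, !decl] <- rates[, !decl] * config$nondecliner_threat_scale
    threats <- matrix(rbinom(length(rates), 1, as.vector(rates)),
                      nrow = nrow(rates))
    tm <- t(threats)
    colnames(tm) <- threat_cols()
    unknown_thr <- runif(n) < config$unknown_threat_frac
    tm[unknown_thr, ] <- NA_integer_

    niche_obs <- niche
    miss_niche <- runif(n) < config$missing_niche_frac
    niche_obs[miss_niche] <- NA_character_

    is_primate <- runif(n) < config$primate_frac_by_niche[niche]
    other_orders <- c("Rodentia", "Chiroptera", "Carnivora",
                      "Artiodactyla", "Eulipotyphla")
    order <- ifelse(is_primate, "Primates",
                    sample(other_orders, n, TRUE))
    mass_meanlog <- c(nocturnal = -0.5, crepuscular = -0.5,
                      cathemeral = 1.5, diurnal = 0.5)
    body_mass_kg <- rlnorm(n, mass_meanlog[niche], 2)

    marine <- runif(n) < config$marine_frac
    fossorial <- runif(n) < config$fossorial_frac

    df <- data.frame(
      species_id = tree$tip.label,
      binomial = paste("Genus", tree$tip.label),
      order = order,
      diel_niche = niche_obs,
      niche_imputed = FALSE,
      iucn_category = iucn_category,
      iucn_trend = iucn_trend,
      literature_trend = literature_trend,
      is_marine = marine,
      is_fossorial = fossorial,
      body_mass_kg = body_mass_kg,
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(tm))
    df$truth_niche <- niche
    df$truth_decline <- as.integer(decl)
    df$truth_latent <- unname(latent)
    validate_species_table(df)
  })
}

#' Simulate toy presence rasters
#'
#' Each species occupies a contiguous random blob of `1 + Poisson(mean-1)`
#' cells grown by 4-neighbour accretion from a random start cell.
#'
#' @param records species table (ids define the stack rows).
#' @param config a [synth_config()].
#' @return a [range_stack()].
#' @export
sim_ranges <- function(records, config) {
  g <- config$grid
  ncell <- g$nrows * g$ncols
  with_seed(.stage_seed(config$seed, 4L), {
    P <- matrix(0L, nrow(records), ncell,
                dimnames = list(records$species_id, NULL))
    for (i in seq_len(nrow(records))) {
      target <- min(1L + rpois(1, max(config$range_cells_mean - 1, 0)), ncell)
      cells <- sample.int(ncell, 1L)
      while (length(cells) < target) {
        frontier <- unique(unlist(lapply(cells, .cell_neighbours,
                                         nrows = g$nrows, ncols = g$ncols)))
        frontier <- setdiff(frontier, cells)
        if (!length(frontier)) break
        cells <- c(cells, frontier[sample.int(length(frontier), 1L)])
      }
      P[i, cells] <- 1L
    }
    range_stack(P, g)
  })
}

# 4-neighbourhood of a row-major cell index
.cell_neighbours <- function(cell, nrows, ncols) {
  r <- (cell - 1L) %/% ncols + 1L
  c <- (cell - 1L) %% ncols + 1L
  nb <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
  nb <- nb[nb[, 1L] >= 1L & nb[, 1L] <= nrows &
             nb[, 2L] >= 1L & nb[, 2L] <= ncols, , drop = FALSE]
  (nb[, 1L] - 1L) * ncols + nb[, 2L]
}

#' Simulate a toy country raster
#'
#' Nearest-seed (Voronoi) partition of the grid into `n_countries`
#' contiguous regions coded 1..n.
#'
#' @param config a [synth_config()].
#' @return integer matrix (nrows x ncols) of country codes.
#' @export
sim_country_raster <- function(config) {
  g <- config$grid
  with_seed(.stage_seed(config$seed, 5L), {
    seeds <- cbind(runif(config$n_countries, 1, g$nrows),
                   runif(config$n_countries, 1, g$ncols))
    m <- matrix(0L, g$nrows, g$ncols)
    for (r in seq_len(g$nrows)) for (c in seq_len(g$ncols)) {
      d2 <- (seeds[, 1] - r)^2 + (seeds[, 2] - c)^2
      m[r, c] <- which.min(d2)
    }
    m
  })
}

#' Simulate a country-override table
#'
#' Picks a few declining species and marks one country each where they
#' are known not to be declining.
#'
#' @param records classified species table.
#' @param config a [synth_config()].
#' @param n_overrides rows to generate.
#' @return data.frame (`species_id`, `country_code`).
#' @export
sim_overrides <- function(records, config, n_overrides = 5L) {
  decl <- records$species_id[records$trend_class %in% "declining"]
  with_seed(.stage_seed(config$seed, 6L), {
    if (!length(decl)) return(data.frame(species_id = character(),
                                         country_code = integer()))
    sp <- sample(decl, min(n_overrides, length(decl)))
    data.frame(species_id = sp,
               country_code = sample.int(config$n_countries, length(sp),
                                         replace = TRUE))
  })
}

#' Write a complete synthetic input bundle
#'
#' Generates tree ensemble, species table, presence rasters, country
#' raster and override table and writes them under `dir` (species CSV with
#' truth columns, Newick trees, `.asc` rasters, overrides CSV, config
#' JSON). Fully deterministic under `config$seed`.
#'
#' @param config a [synth_config()].
#' @param dir output directory.
#' @return invisible list of the generated objects and file paths.
#' @export
sim_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- sim_tree(config)
  trees <- sim_ensemble(tree, config)
  records <- sim_traits_and_trends(tree, config)
  stack <- sim_ranges(records, config)
  country <- sim_country_raster(config)
  # overrides reference the post-exclusion analysis set, as real override
  # tables reference the mapped species
  classified <- classify_trends(filter_analysis_set(records))
  overrides <- sim_overrides(classified, config)

  paths <- list(
    species = file.path(dir, "species.csv"),
    trees = file.path(dir, "trees.nwk"),
    country = file.path(dir, "country.asc"),
    overrides = file.path(dir, "overrides.csv"),
    ranges_dir = file.path(dir, "ranges"),
    config = file.path(dir, "config.json"))
  write_species_table(records, paths$species)
  ape::write.tree(trees, paths$trees)
  write_asc(country, paths$country, config$grid)
  write.csv(overrides, paths$overrides, row.names = FALSE)
  dir.create(paths$ranges_dir, showWarnings = FALSE)
  for (sp in rownames(stack$presence))
    write_asc(cells_to_matrix(stack$presence[sp, ], config$grid),
              file.path(paths$ranges_dir, paste0(sp, ".asc")), config$grid)
  cfg <- unclass(config)
  cfg$grid <- unclass(cfg$grid)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)
  invisible(list(tree = tree, trees = trees, records = records,
                 stack = stack, country = country, overrides = overrides,
                 paths = paths))
}
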