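#' Robustness tier from the fraction of significant repetitions
#'
#' Repeating a model over many candidate trees yields, per term, the
#' fraction of repetitions with p < 0.01. Tiers: `"###"` for >= 0.90,
#' `"##"` for \[0.75, 0.90), `"#"` for \[0.60, 0.75), `""` otherwise.
#'
#' @param frac_p_lt_001 numeric vector in \[0, 1\].
#' @return character vector of tier annotations.
#' @export
tier <- function(frac_p_lt_001) {
  stopifnot(all(frac_p_lt_001 >= 0 & frac_p_lt_001 <= 1, na.rm = TRUE))
  out <- character(length(frac_p_lt_001))
  out[frac_p_lt_001 >= 0.60] <- "#"
  out[frac_p_lt_001 >= 0.75] <- "##"
  out[frac_p_lt_001 >= 0.90] <- "###"
  out[is.na(frac_p_lt_001)] <- NA_character_
  out
}

#' Fit one model specification across a tree ensemble
#'
#' Repeats a [phylo_glm()] fit over `B` trees sampled without replacement
#' from the supplied ensemble and aggregates: per-term mean coefficient,
#' sample SD (n-1), fraction of repetitions with p < 0.01 (over converged
#' fits), robustness [tier()], and mean pseudo-R2. Non-converged fits are
#' dropped from the aggregation with a warning; fewer than `B/2` converged
#' fits flags the summary unreliable.
#'
#' @inheritParams phylo_glm
#' @param trees `multiPhylo` ensemble.
#' @param B trees to use (default `min(100, length(trees))`).
#' @param seed seed for tree sampling.
#' @param ... passed to [phylo_glm()].
#' @return object of class `phylo_glm_ensemble`: `summary` data.frame
#'   (term, mean_coef, sd_coef, frac_p_lt_001, tier), `mean_pseudo_r2`,
#'   `B_used`, `n_converged`, `reliable`, `coef_matrix`, `p_matrix`,
#'   `tree_indices`, `model_id`.
#' @export
fit_ensemble <- function(formula, data, trees, family = c("binomial", "poisson"),
                         B = NULL, seed = 1L, model_id = NULL, ...) {
  family <- match.arg(family)
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  B <- as.integer(B %||% min(100L, length(trees)))
  sel <- sample_trees(trees, B, seed)
  fits <- lapply(seq_len(B), function(b)
    phylo_glm(formula, data, sel[[b]], family = family,
              model_id = model_id, ...))
  aggregate_fits(fits, model_id = model_id %||% paste0("phylo_", family),
                 tree_indices = attr(sel, "indices"))
}

#' Aggregate a list of per-tree fits
#'
#' @param fits list of `phylo_glm` objects over identical designs.
#' @param model_id label.
#' @param tree_indices optional record of which ensemble trees were used.
#' @return a `phylo_glm_ensemble` (see [fit_ensemble()]).
#' @export
aggregate_fits <- function(fits, model_id = "model", tree_indices = NULL) {
  B <- length(fits)
  conv <- vapply(fits, function(f) isTRUE(f$converged) && !isTRUE(f$degenerate),
                 logical(1))
  if (!all(conv))
    warning(sum(!conv), " of ", B, " fits did not converge and were dropped")
  use <- fits[conv]
  if (!length(use)) {
    warning("no converged fits to aggregate: summary flagged empty")
    terms <- names(fits[[1L]]$coefficients)
    summ <- data.frame(term = terms, mean_coef = NA_real_,
                       sd_coef = NA_real_, frac_p_lt_001 = NA_real_,
                       tier = NA_character_, stringsAsFactors = FALSE)
    return(structure(list(summary = summ, mean_pseudo_r2 = NA_real_,
                          mean_alpha = NA_real_, B_used = B,
                          n_converged = 0L, reliable = FALSE,
                          n_obs = fits[[1L]]$n_obs, family = NA_character_,
                          coef_matrix = NULL, p_matrix = NULL,
                          tree_indices = tree_indices,
                          model_id = model_id),
                     class = "phylo_glm_ensemble"))
  }
  terms <- names(use[[1L]]$coefficients)
  cm <- matrix(unlist(lapply(use, function(f) f$coefficients[terms])),
               ncol = length(terms), byrow = TRUE,
               dimnames = list(NULL, terms))
  pm <- matrix(unlist(lapply(use, function(f) f$p_values[terms])),
               ncol = length(terms), byrow = TRUE,
               dimnames = list(NULL, terms))
  frac <- colMeans(pm < 0.01)
  summ <- data.frame(
    term = terms,
    mean_coef = colMeans(cm),
    sd_coef = if (nrow(cm) > 1L) apply(cm, 2L, sd) else rep(0, length(terms)),
    frac_p_lt_001 = frac,
    tier = tier(frac),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    summary = summ,
    mean_pseudo_r2 = mean(vapply(use, function(f) f$pseudo_r2, numeric(1))),
    mean_alpha = mean(vapply(use, function(f) f$alpha, numeric(1))),
    B_used = B, n_converged = sum(conv),
    reliable = sum(conv) >= B / 2,
    n_obs = use[[1L]]$n_obs,
    family = use[[1L]]$family %||% use[[1L]]$method,
    coef_matrix = cm, p_matrix = pm,
    tree_indices = tree_indices, model_id = model_id),
    class = "phylo_glm_ensemble")
}

#' @export
print.phylo_glm_ensemble <- function(x, ...) {
  cat("Ensemble model '", x$model_id, "': ", x$n_converged, "/", x$B_used,
      " converged fits, n = ", x$n_obs, "\n", sep = "")
  df <- x$summary
  df$mean_coef <- round(df$mean_coef, 3)
  df$sd_coef <- round(df$sd_coef, 3)
  print(df, row.names = FALSE)
  cat("mean pseudo-R2:", format(x$mean_pseudo_r2, digits = 3),
      if (!x$reliable) " [UNRELIABLE: <B/2 converged]" else "", "\n")
  invisible(x)
}

#' @export
summary.phylo_glm_ensemble <- function(object, ...) object$summary

#' @export
as.data.frame.phylo_glm_ensemble <- function(x, ...) {
  cbind(model_id = x$model_id, x$summary,
        mean_pseudo_r2 = x$mean_pseudo_r2, B = x$B_used,
        n_converged = x$n_converged, n = x$n_obs)
}

#' Threats prevalent enough to model
#'
#' Among declining species with known threats, retains threat categories
#' affecting at least `min_n` species (default 50; rarer threats are too
#' sparse for stable per-threat models).
#'
#' @param records species table (trends and threat sets built).
#' @param min_n minimum number of declining species per threat.
#' @return character vector of retained threat categories, with attribute
#'   `"counts"` (all ten counts).
#' @export
select_threat_models <- function(records, min_n = 50L) {
  dec <- records[records$trend_class == "declining" &
                   records$threats_known %in% TRUE, , drop = FALSE]
  counts <- vapply(threat_cols(), function(tc) sum(dec[[tc]] == 1L), integer(1))
  names(counts) <- threat_categories()
  structure(threat_categories()[counts >= min_n], counts = counts)
}

# build the 0/1 decline response under an unclassified-handling mode
.decline_response <- function(records, unclassified_mode = c("code_zero", "drop")) {
  unclassified_mode <- match.arg(unclassified_mode)
  if (unclassified_mode == "drop")
    records <- records[records$trend_class != "unclassified", , drop = FALSE]
  records$declining <- as.integer(records$trend_class == "declining")
  records
}

# analysis subset for regressions: niche known and not imputed
.regression_records <- function(records) {
  keep <- !is.na(records$diel_niche) & !(records$niche_imputed %in% TRUE)
  out <- records[keep, , drop = FALSE]
  out$diel_niche <- factor(out$diel_niche, levels = diel_levels())
  out
}

#' Run the full comparative study across a tree ensemble
#'
#' The three model families, each repeated over `B` sampled trees:
#' 1. decline (0/1) ~ diel niche, logistic MPLE, all analysis species
#'    (species with imputed niche excluded; unclassified trends coded 0 by
#'    default or dropped per `unclassified_mode`);
#' 2. number of threats ~ diel niche, Poisson GEE, declining species with
#'    known threats;
#' 3. declining-from-threat (0/1) ~ diel niche, logistic MPLE, declining
#'    species, one model per threat retained by [select_threat_models()].
#'
#' @param records species table with trends classified and threat sets
#'   built (see [classify_trends()], [build_threat_sets()]).
#' @param trees `multiPhylo` ensemble whose tips cover the species.
#' @param B trees per model.
#' @param seed tree-sampling seed (shared across models so every model
#'   sees the same trees).
#' @param unclassified_mode handling of unclassified-trend species in the
#'   decline model: `"code_zero"` (default) or `"drop"`.
#' @param min_threat_n threshold for [select_threat_models()].
#' @return named list of `phylo_glm_ensemble`: `decline`, `n_threats`
#'   (NULL if no eligible decliners), and `threat_<category>` entries.
#' @export
run_study <- function(records, trees, B = NULL, seed = 1L,
                      unclassified_mode = c("code_zero", "drop"),
                      min_threat_n = 50L) {
  unclassified_mode <- match.arg(unclassified_mode)
  rr <- .regression_records(records)
  out <- list()

  dmod <- .decline_response(rr, unclassified_mode)
  out$decline <- fit_ensemble(declining ~ diel_niche, dmod, trees,
                              family = "binomial", B = B, seed = seed,
                              model_id = "decline")

  dec <- rr[rr$trend_class == "declining" & rr$threats_known %in% TRUE, ,
            drop = FALSE]
  if (nrow(dec) == 0L) {
    warning("no declining species with known threats: threat models skipped")
    out$n_threats <- NULL
    return(out)
  }
  out$n_threats <- fit_ensemble(n_threats ~ diel_niche, dec, trees,
                                family = "poisson", B = B, seed = seed,
                                model_id = "n_threats")
  for (th in select_threat_models(rr, min_threat_n)) {
    dec$from_threat <- as.integer(dec[[paste0("threat_", th)]] == 1L)
    out[[paste0("threat_", th)]] <-
      fit_ensemble(from_threat ~ diel_niche, dec, trees,
                   family = "binomial", B = B, seed = seed,
                   model_id = paste0("threat_", th))
  }
  out
}

#' Sensitivity variants of the study
#'
#' Re-runs [run_study()] under one of the published robustness checks:
#' `primates_only` / `non_primates_only` (taxonomic split),
#' `exclude_literature_trends` (literature-derived trends reset to
#' unclassified and handled per `unclassified_mode`), or
#' `threat_status_recode` (decline re-derived from Red List category:
#' VU/EN/CR declining, LC/NT non-declining, DD/NE unclassified).
#'
#' @inheritParams run_study
#' @param variant one of the four variant names above.
#' @return as [run_study()]; `NULL` with a warning if the subset is empty.
#' @export
run_sensitivity <- function(records, trees, variant = c(
                              "primates_only", "non_primates_only",
                              "exclude_literature_trends",
                              "threat_status_recode"),
                            B = NULL, seed = 1L,
                            unclassified_mode = c("code_zero", "drop"),
                            min_threat_n = 50L) {
  variant <- match.arg(variant)
  r <- records
  if (variant == "primates_only") {
    r <- r[r$order == "Primates", , drop = FALSE]
  } else if (variant == "non_primates_only") {
    r <- r[r$order != "Primates", , drop = FALSE]
  } else if (variant == "exclude_literature_trends") {
    lit <- r$trend_provenance == "literature"
    r$trend_class[lit] <- "unclassified"
    r$trend_provenance[lit] <- "none"
  } else { # threat_status_recode
    r$trend_class <- ifelse(r$iucn_category %in% c("VU", "EN", "CR"),
                            "declining",
                     ifelse(r$iucn_category %in% c("LC", "NT"),
                            "non_declining", "unclassified"))
    r$trend_provenance <- ifelse(r$trend_class == "unclassified",
                                 "none", "category_rule")
  }
  if (nrow(r) == 0L) {
    warning("variant '", variant, "' selects no species")
    return(NULL)
  }
  run_study(r, trees, B = B, seed = seed,
            unclassified_mode = unclassified_mode,
            min_threat_n = min_threat_n)
}
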