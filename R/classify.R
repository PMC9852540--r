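#' Restrict to the terrestrial, non-fossorial analysis set
#'
#' Sea mammals and highly/fully fossorial species rely on different light
#' cues than above-surface terrestrial species and are excluded before any
#' diel-niche analysis.
#'
#' @param records species table (see [read_species_table()]).
#' @return the retained records, with attribute `"exclusions"` giving counts
#'   by reason (marine, fossorial, either).
#' @export
filter_analysis_set <- function(records) {
  marine <- records$is_marine %in% TRUE
  fossorial <- records$is_fossorial %in% TRUE
  drop <- marine | fossorial
  out <- records[!drop, , drop = FALSE]
  attr(out, "exclusions") <- c(marine = sum(marine), fossorial = sum(fossorial),
                               either = sum(drop))
  out
}

#' Assign population-trend class with provenance
#'
#' Deterministic precedence: (1) a known Red List trend wins (decreasing ->
#' declining; stable/increasing -> non_declining); (2) otherwise species in
#' a threatened category (NT, VU, EN, CR) are classed declining by the
#' category rule (justified by [category_trend_concordance()]); (3)
#' otherwise a literature-derived trend is used; (4) otherwise the species
#' stays unclassified.
#'
#' @param iucn_trend character vector in [iucn_trend_levels()].
#' @param iucn_category character vector in [iucn_categories()].
#' @param literature_trend character vector in [literature_trend_levels()].
#' @return data.frame with columns `trend_class` (declining, non_declining,
#'   unclassified) and `trend_provenance` (iucn_trend, category_rule,
#'   literature, none).
#' @export
assign_trend <- function(iucn_trend, iucn_category, literature_trend) {
  n <- length(iucn_trend)
  stopifnot(length(iucn_category) == n, length(literature_trend) == n)
  cls <- rep("unclassified", n)
  prov <- rep("none", n)

  known <- iucn_trend != "unknown"
  cls[known & iucn_trend == "decreasing"] <- "declining"
  cls[known & iucn_trend %in% c("stable", "increasing")] <- "non_declining"
  prov[known] <- "iucn_trend"

  rule <- !known & iucn_category %in% threatened_categories()
  cls[rule] <- "declining"
  prov[rule] <- "category_rule"

  lit <- !known & !rule & literature_trend != "unknown"
  cls[lit] <- literature_trend[lit]
  prov[lit] <- "literature"

  data.frame(trend_class = cls, trend_provenance = prov,
             stringsAsFactors = FALSE)
}

#' Apply trend assignment to a species table
#'
#' @param records species table.
#' @return records with `trend_class` and `trend_provenance` columns set.
#' @export
classify_trends <- function(records) {
  a <- assign_trend(records$iucn_trend, records$iucn_category,
                    records$literature_trend)
  records$trend_class <- a$trend_class
  records$trend_provenance <- a$trend_provenance
  records
}

#' Concordance between threatened status and known declining trend
#'
#' Among species in a threatened category (NT-CR) whose Red List trend is
#' known, the fraction whose trend is decreasing. A value near 1 is what
#' justifies assigning "declining" to threatened species with unclassified
#' trends.
#'
#' @param records species table.
#' @return fraction in \[0, 1\], or `NA` (with warning) if no species
#'   qualifies; attribute `"n"` carries the denominator.
#' @export
category_trend_concordance <- function(records) {
  sel <- records$iucn_category %in% threatened_categories() &
    records$iucn_trend != "unknown"
  n <- sum(sel)
  if (n == 0) {
    warning("no threatened species with known trend: concordance undefined")
    return(structure(NA_real_, n = 0L))
  }
  structure(sum(records$iucn_trend[sel] == "decreasing") / n, n = n)
}

#' Build per-species threat sets from 0/1/NA columns
#'
#' All-NA across the ten columns means the species' threats are unknown
#' (`threats_known = FALSE`); a mix of NA and 0/1 is rejected as an
#' ambiguous knowledge state.
#'
#' @param records species table with the ten `threat_*` columns.
#' @return records with logical `threats_known` and integer `n_threats`
#'   (NA where unknown) columns added.
#' @export
build_threat_sets <- function(records) {
  cols <- threat_cols()
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("missing threat column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(records[, cols])
  n_na <- rowSums(is.na(m))
  mixed <- n_na > 0 & n_na < length(cols)
  if (any(mixed))
    stop("mixed NA/non-NA threat columns for species: ",
         paste(records$species_id[mixed], collapse = ", "), call. = FALSE)
  records$threats_known <- n_na == 0
  records$n_threats <- ifelse(records$threats_known, rowSums(m), NA_integer_)
  records
}

#' Threat-set membership and count for one species
#'
#' @param record a single-row species table (threat sets built).
#' @return `threat_set()`: character vector of threat categories flagged 1;
#'   `count_threats()`: their number.
#' @export
threat_set <- function(record) {
  stopifnot(nrow(record) == 1L)
  if (!isTRUE(record$threats_known))
    stop("threats unknown for ", record$species_id,
         "; exclude such species upstream", call. = FALSE)
  cols <- threat_cols()
  threat_categories()[unlist(record[, cols]) == 1]
}

#' @rdname threat_set
#' @export
count_threats <- function(record) length(threat_set(record))

#' Partition of species by trend provenance
#'
#' @param records species table after [classify_trends()].
#' @return list with `counts` (iucn_trend, category_rule, literature,
#'   unclassified; summing to `nrow(records)`) and
#'   `unclassified_by_category` (table of IUCN categories among
#'   unclassified species).
#' @export
trend_provenance_summary <- function(records) {
  prov <- ifelse(records$trend_class == "unclassified", "unclassified",
                 records$trend_provenance)
  counts <- vapply(c("iucn_trend", "category_rule", "literature", "unclassified"),
                   function(p) sum(prov == p), integer(1))
  stopifnot(sum(counts) == nrow(records))
  uncl <- records$iucn_category[prov == "unclassified"]
  list(counts = counts,
       unclassified_by_category = table(factor(uncl, levels = iucn_categories())))
}

#' Per-niche decline table
#'
#' For each diel niche: total species (unclassified-trend species count in
#' the denominator), number declining, and the percent declining rounded
#' half-up to one decimal.
#'
#' @param records species table after [classify_trends()]; species with
#'   missing niche are dropped with a message.
#' @return data.frame with columns `diel_niche`, `n_total`, `n_declining`,
#'   `percent_declining`.
#' @export
niche_decline_table <- function(records) {
  if (anyNA(records$diel_niche)) {
    message(sum(is.na(records$diel_niche)), " species without diel niche dropped")
    records <- records[!is.na(records$diel_niche), , drop = FALSE]
  }
  niche <- factor(records$diel_niche, levels = diel_levels())
  n_total <- as.integer(table(niche))
  n_decl <- as.integer(table(niche[records$trend_class == "declining"]))
  pct <- suppressWarnings(decline_percent(n_decl, n_total))
  data.frame(diel_niche = diel_levels(), n_total = n_total,
             n_declining = n_decl, percent_declining = pct,
             stringsAsFactors = FALSE)
}

#' Diel-niche composition of heavy species
#'
#' Fraction of species above a body-mass threshold falling in each niche
#' (e.g. the prevalence of cathemerality among megafauna > 45 kg).
#'
#' @param records species table with `body_mass_kg`.
#' @param mass_threshold_kg threshold in kilograms (default 45).
#' @return data.frame `diel_niche`, `n`, `fraction`; attributes `"n_heavy"`
#'   and `"n_missing_mass"`. Fractions are `NA` if no species qualifies.
#' @export
megafauna_niche_fraction <- function(records, mass_threshold_kg = 45) {
  has_mass <- !is.na(records$body_mass_kg)
  heavy <- records[has_mass & records$body_mass_kg > mass_threshold_kg, , drop = FALSE]
  heavy <- heavy[!is.na(heavy$diel_niche), , drop = FALSE]
  n <- as.integer(table(factor(heavy$diel_niche, levels = diel_levels())))
  frac <- if (nrow(heavy)) n / nrow(heavy) else rep(NA_real_, 4L)
  if (!nrow(heavy)) warning("no species above mass threshold")
  structure(
    data.frame(diel_niche = diel_levels(), n = n, fraction = frac,
               stringsAsFactors = FALSE),
    n_heavy = nrow(heavy), n_missing_mass = sum(!has_mass))
}

#' Trend bookkeeping from aggregate counts
#'
#' Derives the audit-trail quantities of a trend-assignment run from its
#' aggregate counts alone: how many species remain unclassified after
#' download, the category rule and literature estimation, and the share of
#' declining species whose threats stay unknown.
#'
#' @param n_unclassified_lc,n_unclassified_dd species with unclassified
#'   downloaded trend in LC and DD.
#' @param n_literature species whose trend was estimated from literature.
#' @param n_threats_unknown,n_threats_recovered declining species with
#'   unknown threats before/after literature search.
#' @param n_decliners total declining species.
#' @return list with `n_unclassified_remaining` and
#'   `pct_threats_unclassified` (percent, rounded half-up to 1 decimal).
#' @export
trend_bookkeeping <- function(n_unclassified_lc, n_unclassified_dd,
                              n_literature, n_threats_unknown,
                              n_threats_recovered, n_decliners) {
  list(
    n_unclassified_remaining =
      n_unclassified_lc + n_unclassified_dd - n_literature,
    pct_threats_unclassified =
      round_half_up(100 * (n_threats_unknown - n_threats_recovered) / n_decliners, 1)
  )
}
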