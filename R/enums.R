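#' Controlled vocabularies
#'
#' The fixed factor levels used throughout: the four diel niches (with
#' nocturnal first, the regression base level), the ten anthropogenic
#' threat categories, IUCN Red List categories and population-trend codes.
#'
#' @return Character vector of levels, in their canonical order.
#' @examples
#' diel_levels()
#' threat_categories()
#' @export
diel_levels <- function() c("nocturnal", "crepuscular", "cathemeral", "diurnal")

#' @rdname diel_levels
#' @export
threat_categories <- function() {
  c("habitat_loss", "harvesting", "conflict", "climate_change",
    "non_native", "pollution", "hybridization", "prey_depletion",
    "disease", "inbreeding")
}

#' @rdname diel_levels
#' @export
iucn_categories <- function() c("LC", "NT", "VU", "EN", "CR", "DD", "NE")

#' @rdname diel_levels
#' @export
iucn_trend_levels <- function() c("decreasing", "stable", "increasing", "unknown")

#' @rdname diel_levels
#' @export
literature_trend_levels <- function() c("declining", "non_declining", "unknown")

# threatened categories eligible for the category->declining rule
threatened_categories <- function() c("NT", "VU", "EN", "CR")

threat_cols <- function() paste0("threat_", threat_categories())

.check_enum <- function(x, levels, what, allow_na = FALSE) {
  bad <- !(x %in% levels)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("invalid %s token '%s' (row %d); expected one of: %s",
                 what, as.character(x[i]), i, paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
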