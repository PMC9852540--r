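#' Per-cell species richness of a diel niche
#'
#' @param stack a [range_stack()].
#' @param records species table covering every stack species, with final
#'   niche assignments.
#' @param niche one of [diel_levels()].
#' @return integer matrix (nrows x ncols, north to south) of per-cell
#'   counts, attribute `"grid"`; cells with zero species are 0 (flagged
#'   `no_species` downstream).
#' @export
richness_raster <- function(stack, records, niche) {
  niche <- match.arg(niche, diel_levels())
  unknown <- setdiff(rownames(stack$presence), records$species_id)
  if (length(unknown))
    stop("stack species absent from records: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  members <- records$species_id[!is.na(records$diel_niche) &
                                  records$diel_niche == niche]
  members <- intersect(rownames(stack$presence), members)
  counts <- if (length(members))
    colSums(stack$presence[members, , drop = FALSE]) else
    numeric(ncol(stack$presence))
  structure(cells_to_matrix(as.integer(counts), stack$grid),
            grid = stack$grid, niche = niche)
}

#' Proportion of a niche's species declining from a threat, per cell
#'
#' For every grid cell: numerator = species of the niche present in the
#' cell, classed declining, flagged for the threat, and not overridden for
#' the cell's country; denominator = the niche's richness in the cell
#' (unclassified-trend species included — they are niche members). The
#' default assumption is that a declining species declines throughout its
#' range; the override table removes named species from the numerator in
#' countries where they are known not to be declining. Cells are masked
#' where the denominator is <= `mask_threshold` (`mask_mode = "richness"`,
#' default) or where the numerator is <= `mask_threshold`
#' (`mask_mode = "decliners"`).
#'
#' @inheritParams richness_raster
#' @param threat one of [threat_categories()].
#' @param overrides optional table from [read_override_table()].
#' @param country_raster optional integer matrix of country codes aligned
#'   to the grid (required if `overrides` given).
#' @param mask_mode which count the low-richness mask tests.
#' @param mask_threshold mask cutoff (default 5, i.e. "<= 5 excluded").
#' @return object of class `decline_raster`: `proportion` (matrix, NA
#'   where masked), `numerator`, `denominator`, `mask_reason` (matrix of
#'   `"none"`, `"low_richness"`, `"no_species"`), `grid`, `niche`,
#'   `threat`, `mask_mode`.
#' @export
decline_proportion_raster <- function(stack, records, niche, threat,
                                      overrides = NULL, country_raster = NULL,
                                      mask_mode = c("richness", "decliners"),
                                      mask_threshold = 5L) {
  mask_mode <- match.arg(mask_mode)
  niche <- match.arg(niche, diel_levels())
  threat <- match.arg(threat, threat_categories())
  grid <- stack$grid
  denom_m <- richness_raster(stack, records, niche)
  denom <- as.integer(t(denom_m))  # back to row-major cells

  tc <- paste0("threat_", threat)
  decl <- records$species_id[!is.na(records$diel_niche) &
                               records$diel_niche == niche &
                               records$trend_class == "declining" &
                               records$threats_known %in% TRUE &
                               records[[tc]] %in% 1L]
  decl <- intersect(rownames(stack$presence), decl)
  P <- stack$presence
  numer <- if (length(decl)) colSums(P[decl, , drop = FALSE]) else
    numeric(ncol(P))

  if (!is.null(overrides) && nrow(overrides)) {
    if (is.null(country_raster))
      stop("overrides require a country_raster", call. = FALSE)
    stopifnot(all(dim(country_raster) == c(grid$nrows, grid$ncols)))
    country_cells <- as.vector(t(country_raster))
    unknown_sp <- setdiff(overrides$species_id, records$species_id)
    if (length(unknown_sp))
      stop("override references unknown species: ",
           paste(unknown_sp, collapse = ", "), call. = FALSE)
    unknown_cc <- setdiff(overrides$country_code,
                          country_cells[!is.na(country_cells)])
    if (length(unknown_cc))
      stop("override references unknown country code: ",
           paste(unknown_cc, collapse = ", "), call. = FALSE)
    for (i in seq_len(nrow(overrides))) {
      sp <- overrides$species_id[i]
      if (!(sp %in% decl)) next
      cells <- which(country_cells %in% overrides$country_code[i])
      numer[cells] <- numer[cells] - P[sp, cells]
    }
  }
  stopifnot(all(numer >= 0), all(numer <= denom))

  masked <- if (mask_mode == "richness") denom <= mask_threshold
            else numer <= mask_threshold
  reason <- ifelse(denom == 0L, "no_species",
                   ifelse(masked, "low_richness", "none"))
  prop <- ifelse(reason == "none", numer / denom, NA_real_)
  structure(list(
    proportion = cells_to_matrix(prop, grid),
    numerator = cells_to_matrix(as.integer(numer), grid),
    denominator = denom_m,
    mask_reason = cells_to_matrix(reason, grid),
    grid = grid, niche = niche, threat = threat, mask_mode = mask_mode,
    mask_threshold = mask_threshold), class = "decline_raster")
}

#' @export
print.decline_raster <- function(x, ...) {
  ok <- x$mask_reason == "none"
  cat("decline_raster:", x$niche, "/", x$threat, "-", sum(ok),
      "unmasked cells; proportion range",
      if (any(ok)) paste(round(range(x$proportion[ok]), 3), collapse = "-")
      else "n/a", "\n")
  invisible(x)
}

#' @export
plot.decline_raster <- function(x, ...) {
  m <- x$proportion[nrow(x$proportion):1, , drop = FALSE]  # south-up for image()
  graphics::image(t(m), zlim = c(0, 1), useRaster = TRUE,
                  main = paste(x$niche, "declining from",
                               gsub("_", " ", x$threat)), axes = FALSE, ...)
  invisible(x)
}

#' Write decline layers to disk
#'
#' One text raster per layer (`<niche>_<threat>.asc`, nodata for masked
#' cells) plus a companion mask raster (`*_mask.asc`: 0 none, 1
#' low_richness, 2 no_species) and the CRS sidecars.
#'
#' @param layers list of `decline_raster` objects.
#' @param dir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
write_decline_maps <- function(layers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (ly in layers) {
    stopifnot(inherits(ly, "decline_raster"))
    stem <- file.path(dir, paste0(ly$niche, "_", ly$threat))
    write_asc(ly$proportion, paste0(stem, ".asc"), ly$grid)
    codes <- matrix(match(ly$mask_reason, c("none", "low_richness",
                                            "no_species")) - 1L,
                    nrow = ly$grid$nrows)
    write_asc(codes, paste0(stem, "_mask.asc"), ly$grid)
    files <- c(files, paste0(stem, ".asc"), paste0(stem, "_mask.asc"))
  }
  invisible(files)
}
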