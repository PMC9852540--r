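#' Read and write species trait tables
#'
#' The species table is a flat UTF-8 CSV with one row per species. Required
#' columns: `species_id`, `binomial`, `order`, `diel_niche` (empty = missing,
#' to be imputed), `iucn_category`, `iucn_trend`, `literature_trend`,
#' `is_marine`, `is_fossorial` (0/1), `body_mass_kg` (empty = unknown) and
#' one 0/1/NA column per threat category (`threat_habitat_loss`, ...,
#' `threat_inbreeding`); NA in *all* ten means threats unknown for that
#' species. Optional columns (`niche_imputed`, `trend_class`,
#' `trend_provenance`, ground-truth `truth_*` columns from the simulator)
#' are carried through untouched.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` of species records with validated enum columns;
#'   `diel_niche` is a factor with levels [diel_levels()] (NA = missing).
#' @seealso [assign_trend()], [build_threat_sets()]
#' @export
read_species_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_species_table(df)
}

#' @rdname read_species_table
#' @param records a species table as returned by [read_species_table()].
#' @export
write_species_table <- function(records, path) {
  out <- records
  out$diel_niche <- as.character(out$diel_niche)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_species_table
#' @param df a data.frame to validate in place.
#' @export
validate_species_table <- function(df) {
  required <- c("species_id", "binomial", "order", "diel_niche",
                "iucn_category", "iucn_trend", "literature_trend",
                "is_marine", "is_fossorial")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("species table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dup <- df$species_id[duplicated(df$species_id)]
  if (length(dup))
    stop("duplicate species_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  .check_enum(df$diel_niche, diel_levels(), "diel_niche", allow_na = TRUE)
  .check_enum(df$iucn_category, iucn_categories(), "iucn_category")
  .check_enum(df$iucn_trend, iucn_trend_levels(), "iucn_trend")
  .check_enum(df$literature_trend, literature_trend_levels(), "literature_trend")
  df$diel_niche <- factor(df$diel_niche, levels = diel_levels())
  df$is_marine <- as.logical(df$is_marine)
  df$is_fossorial <- as.logical(df$is_fossorial)
  if (!"body_mass_kg" %in% names(df)) df$body_mass_kg <- NA_real_
  if (any(!is.na(df$body_mass_kg) & df$body_mass_kg <= 0))
    stop("body_mass_kg must be positive where present", call. = FALSE)
  for (tc in intersect(threat_cols(), names(df))) {
    v <- df[[tc]]
    if (any(!is.na(v) & !(v %in% c(0L, 1L))))
      stop("threat column ", tc, " must be 0/1/NA", call. = FALSE)
  }
  if (!"niche_imputed" %in% names(df)) df$niche_imputed <- FALSE
  df$species_id <- normalize_label(df$species_id)
  df
}

#' Read a country-override table
#'
#' Rows of (species_id, country_code) marking countries where a species
#' that is declining at global level is known *not* to be declining; such
#' species are removed from the decline numerator in cells belonging to
#' that country.
#'
#' @param path CSV with columns `species_id`, `country_code`.
#' @return data.frame with unique (species_id, country_code) rows.
#' @export
read_override_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "country_code") %in% names(df)))
    stop("override table needs columns species_id, country_code", call. = FALSE)
  df$species_id <- normalize_label(df$species_id)
  key <- paste(df$species_id, df$country_code)
  if (anyDuplicated(key))
    stop("duplicate (species_id, country_code) pair in override table", call. = FALSE)
  df
}
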