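#' Equal-area grid specification
#'
#' Describes the analysis grid: an equal-area CRS identifier (default the
#' cylindrical equal-area EASE-Grid 2.0, EPSG:6933), a square cell size in
#' metres (default 96 500 m), and the extent. Cells are indexed row-major
#' from the grid's upper-left corner, so matrix row 1 is the northernmost
#' row — the same convention as the portable text rasters written by
#' [write_asc()].
#'
#' @param nrows,ncols grid dimensions.
#' @param cell_size_m cell edge length in metres.
#' @param xmin,ymin lower-left corner coordinates.
#' @param crs_id equal-area CRS identifier string.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(nrows, ncols, cell_size_m = 96500,
                      xmin = 0, ymin = 0, crs_id = "EPSG:6933") {
  stopifnot(nrows >= 1, ncols >= 1, cell_size_m > 0)
  nrows <- unname(nrows); ncols <- unname(ncols)
  cell_size_m <- unname(cell_size_m)
  xmin <- unname(xmin); ymin <- unname(ymin)
  structure(list(crs_id = crs_id, cell_size_m = cell_size_m,
                 xmin = xmin, ymin = ymin,
                 xmax = xmin + ncols * cell_size_m,
                 ymax = ymin + nrows * cell_size_m,
                 nrows = as.integer(nrows), ncols = as.integer(ncols)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("grid_spec:", x$nrows, "x", x$ncols, "cells of",
      x$cell_size_m, "m,", x$crs_id, "\n")
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    abs(a$cell_size_m - b$cell_size_m) < tol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol
}

#' Read and write text rasters (ESRI ASCII grid)
#'
#' Raster layers are exchanged as ESRI ASCII grids (`.asc`) — a plain-text
#' format understood by GDAL, QGIS and ArcGIS — with the equal-area CRS id
#' recorded in a JSON sidecar (`<file>.json`). Values are written at full
#' precision; `NA` maps to the declared nodata value.
#'
#' @param path file path.
#' @return `read_asc()`: a numeric matrix (rows = north to south) with
#'   attribute `"grid"` (a [grid_spec()]).
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- setNames(vapply(kv, function(x) as.numeric(x[2L]), numeric(1)),
                  tolower(vapply(kv, `[[`, "", 1L)))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  m <- as.matrix(read.table(path, skip = 6L))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(hdr["nrows"], hdr["ncols"])))
    stop("grid dimensions do not match header in ", path, call. = FALSE)
  m[m == hdr["nodata_value"]] <- NA
  crs <- "EPSG:6933"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    crs <- meta$crs_id %||% crs
  }
  attr(m, "grid") <- grid_spec(hdr["nrows"], hdr["ncols"], hdr["cellsize"],
                               hdr["xllcorner"], hdr["yllcorner"], crs)
  m
}

#' @rdname read_asc
#' @param m numeric matrix (rows north to south).
#' @param grid a [grid_spec()].
#' @param nodata value standing in for `NA`.
#' @export
write_asc <- function(m, path, grid, nodata = -9999) {
  stopifnot(inherits(grid, "grid_spec"),
            nrow(m) == grid$nrows, ncol(m) == grid$ncols)
  hdr <- c(paste("ncols", grid$ncols), paste("nrows", grid$nrows),
           paste("xllcorner", format(grid$xmin, scientific = FALSE)),
           paste("yllcorner", format(grid$ymin, scientific = FALSE)),
           paste("cellsize", format(grid$cell_size_m, scientific = FALSE)),
           paste("NODATA_value", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r) paste(format(r, digits = 12, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  jsonlite::write_json(list(crs_id = grid$crs_id,
                            cell_size_m = grid$cell_size_m),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a stack of per-species presence rasters
#'
#' One binary raster per species (values 0/1; nodata treated as absence).
#' All rasters must share the grid geometry. Species ids are taken from
#' file names (sans extension) unless `species_ids` is given.
#'
#' @param paths character vector of `.asc` files.
#' @param grid optional [grid_spec()] the rasters must match.
#' @param species_ids optional ids, parallel to `paths`.
#' @return object of class `range_stack`: `grid` and `presence`, a species
#'   x cell 0/1 integer matrix (cells in row-major order from the grid's
#'   upper-left corner).
#' @export
read_range_stack <- function(paths, grid = NULL, species_ids = NULL) {
  ids <- species_ids %||% sub("\\.[^.]+$", "", basename(paths))
  ids <- normalize_label(ids)
  rows <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    m <- read_asc(paths[i])
    g <- attr(m, "grid")
    if (is.null(grid)) grid <- g
    else if (!grids_equal(grid, g))
      stop("raster geometry mismatch: ", paths[i], call. = FALSE)
    m[is.na(m)] <- 0
    if (!all(m %in% c(0, 1)))
      stop("non-binary presence value in ", paths[i], call. = FALSE)
    rows[[i]] <- as.integer(t(m))  # row-major flatten
  }
  presence <- do.call(rbind, rows)
  rownames(presence) <- ids
  range_stack(presence, grid)
}

#' @rdname read_range_stack
#' @param presence species x cell 0/1 matrix with species ids as rownames.
#' @export
range_stack <- function(presence, grid) {
  stopifnot(inherits(grid, "grid_spec"),
            ncol(presence) == grid$nrows * grid$ncols,
            !is.null(rownames(presence)))
  if (!all(presence %in% c(0L, 1L)))
    stop("presence matrix must be strictly binary", call. = FALSE)
  structure(list(grid = grid, presence = presence), class = "range_stack")
}

#' @export
print.range_stack <- function(x, ...) {
  cat("range_stack:", nrow(x$presence), "species on a", x$grid$nrows, "x",
      x$grid$ncols, "grid; mean range",
      round(mean(rowSums(x$presence)), 1), "cells\n")
  invisible(x)
}

# cell vector (row-major) -> display matrix
cells_to_matrix <- function(v, grid) {
  matrix(v, nrow = grid$nrows, ncol = grid$ncols, byrow = TRUE)
}
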