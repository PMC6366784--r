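# Gridded habitat-suitability surfaces: construction, ESRI ASCII grid I/O,
# point lookup with a nearest-valid-cell fallback, and cross-species
# standardization.

#' Construct a habitat-suitability surface
#'
#' A regular lon/lat grid of habitat-suitability values in \[0, 1\] for one
#' species, with `NA` marking no-data (e.g. land) cells. Row 1 of `grid` is
#' the northernmost row, matching the ESRI ASCII grid layout.
#'
#' @param species_id identifier.
#' @param grid numeric matrix of suitability values in \[0, 1\] (`NA` =
#'   no data); rows run north to south, columns west to east.
#' @param xll,yll longitude/latitude of the lower-left corner of the grid.
#' @param cellsize cell size in decimal degrees.
#' @return object of class `suitability_surface`.
#' @export
suitability_surface <- function(species_id, grid, xll, yll, cellsize) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  vals <- grid[!is.na(grid)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  if (cellsize <= 0) stop("cellsize must be positive", call. = FALSE)
  structure(list(species_id = as.character(species_id), grid = grid,
                 xll = as.numeric(xll), yll = as.numeric(yll),
                 cellsize = as.numeric(cellsize)),
            class = "suitability_surface")
}

#' @export
print.suitability_surface <- function(x, ...) {
  vals <- x$grid[!is.na(x$grid)]
  cat(sprintf("Suitability surface: %s\n", x$species_id))
  cat(sprintf("  %d x %d cells of %g deg, origin (%g, %g)\n",
              nrow(x$grid), ncol(x$grid), x$cellsize, x$xll, x$yll))
  cat(sprintf("  %d valid cells, range [%g, %g]\n", length(vals),
              if (length(vals)) min(vals) else NA,
              if (length(vals)) max(vals) else NA))
  invisible(x)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `nodata_value`) followed by rows of cell values,
#' northernmost row first.
#'
#' @param path file path.
#' @param species_id identifier to attach; defaults to the file name without
#'   extension.
#' @return a `suitability_surface`.
#' @export
read_ascii_grid <- function(path, species_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII grid header in ", path, call. = FALSE)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  grid <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (is.null(species_id))
    species_id <- sub("\\.[^.]*$", "", basename(path))
  suitability_surface(species_id, grid, hdr$xllcorner, hdr$yllcorner,
                      hdr$cellsize)
}

#' Write a suitability surface as an ESRI ASCII grid
#' @param surface a `suitability_surface`.
#' @param path output path.
#' @param nodata value written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(surface, path, nodata = -9999) {
  g <- surface$grid
  g[is.na(g)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(g)), sprintf("nrows %d", nrow(g)),
           sprintf("xllcorner %.10g", surface$xll),
           sprintf("yllcorner %.10g", surface$yll),
           sprintf("cellsize %.10g", surface$cellsize),
           sprintf("nodata_value %g", nodata))
  body <- apply(g, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Cell-center coordinates of every cell, as a data.frame (row, col, lon, lat).
cell_centers <- function(surface) {
  nr <- nrow(surface$grid); nc <- ncol(surface$grid)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  data.frame(row = row, col = col,
             lon = surface$xll + (col - 0.5) * surface$cellsize,
             lat = surface$yll + (nr - row + 0.5) * surface$cellsize)
}

#' Habitat suitability at a point
#'
#' Returns the value of the grid cell containing the point. Ports sit on
#' coastlines where model grids are frequently masked, so if that cell is
#' no-data (or the point falls just outside the grid extent) the nearest
#' valid cell center within `radius_km` is used instead.
#'
#' @param surface a `suitability_surface`.
#' @param lon,lat point coordinates in decimal degrees.
#' @param radius_km search radius for the nearest-valid-cell fallback
#'   (default 50 km).
#' @param label optional name (e.g. the port id) used in error messages.
#' @return suitability value in \[0, 1\] (or above 1 only if the surface has
#'   not been standardized and was built that way).
#' @export
suitability_at <- function(surface, lon, lat, radius_km = 50, label = NULL) {
  nr <- nrow(surface$grid); nc <- ncol(surface$grid)
  col <- floor((lon - surface$xll) / surface$cellsize) + 1L
  row <- nr - floor((lat - surface$yll) / surface$cellsize)
  inside <- col >= 1 && col <= nc && row >= 1 && row <= nr
  if (inside && !is.na(surface$grid[row, col]))
    return(surface$grid[row, col])
  cc <- cell_centers(surface)
  valid <- cc[!is.na(surface$grid[cbind(cc$row, cc$col)]), , drop = FALSE]
  who <- if (is.null(label)) sprintf("(%g, %g)", lon, lat) else label
  if (nrow(valid) == 0L)
    stop("coverage error: no valid suitability cell for ", who, call. = FALSE)
  d <- geosphere::distHaversine(c(lon, lat), cbind(valid$lon, valid$lat)) / 1000
  j <- which.min(d)
  if (d[j] > radius_km)
    stop(sprintf("coverage error: no valid suitability cell within %g km of %s",
                 radius_km, who), call. = FALSE)
  surface$grid[valid$row[j], valid$col[j]]
}

#' Standardize suitability surfaces across species
#'
#' Divides every surface by the single maximum suitability value found across
#' all species' valid cells, so the highest modelled suitability in the study
#' region maps to exactly 1 and species remain mutually comparable. The study
#' region is operationally the union of the supplied grids.
#'
#' @param surfaces list of `suitability_surface` objects (one per species).
#' @return list of surfaces with a `global_max` attribute recording the
#'   divisor.
#' @export
standardize_suitability <- function(surfaces) {
  if (length(surfaces) == 0L) stop("no surfaces supplied", call. = FALSE)
  gmax <- max(vapply(surfaces, function(s) {
    v <- s$grid[!is.na(s$grid)]
    if (length(v)) max(v) else -Inf
  }, numeric(1)))
  if (!is.finite(gmax) || gmax <= 0)
    stop("degenerate input: global maximum suitability is zero or undefined",
         call. = FALSE)
  out <- lapply(surfaces, function(s) { s$grid <- s$grid / gmax; s })
  attr(out, "global_max") <- gmax
  out
}
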