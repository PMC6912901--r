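#' Create a regular raster grid
#'
#' A light container for a single-layer raster on a regular grid in Cartesian
#' meters. The value matrix is stored with row 1 as the *bottom* row of the
#' landscape, so `values[i, j]` is the cell in row `i` from the bottom and
#' column `j` from the left. Cell centers are at
#' `origin + (index - 0.5) * cell_size` in each direction.
#'
#' @param values Numeric matrix of cell values (`NA` allowed for missing).
#' @param cell_size Cell edge length in meters (default 25, i.e. 0.0625 ha
#'   cells).
#' @param origin Numeric length-2 vector, `(x, y)` of the lower-left corner of
#'   the raster in meters.
#'
#' @return An object of class `sdm_grid` with elements `values`, `cell_size`,
#'   `origin`.
#' @export
#' @examples
#' g <- sdm_grid(matrix(1:12, 3, 4))
#' dim(g$values)
#' cell_area_ha(g)
sdm_grid <- function(values, cell_size = 25, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1 || ncol(values) < 1)
    stop("grid must have at least one row and one column")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2 || any(!is.finite(origin)))
    stop("`origin` must be a finite (x, y) pair")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "sdm_grid"
  )
}

#' @export
print.sdm_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<sdm_grid> %d x %d cells, cell size %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  r <- range(v, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g], %d missing\n",
              r[1], r[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.sdm_grid <- function(x) dim(x$values)

#' Cell area in hectares
#'
#' @param grid An [sdm_grid()].
#' @return Cell area in ha (a 25 m cell is 0.0625 ha).
#' @export
cell_area_ha <- function(grid) {
  stopifnot(inherits(grid, "sdm_grid"))
  grid$cell_size^2 / 1e4
}

#' Landscape extent of a grid
#'
#' @param grid An [sdm_grid()].
#' @return Named numeric vector `c(xmin, xmax, ymin, ymax)` in meters.
#' @export
grid_extent <- function(grid) {
  stopifnot(inherits(grid, "sdm_grid"))
  d <- dim(grid$values)
  c(xmin = grid$origin[1], xmax = grid$origin[1] + d[2] * grid$cell_size,
    ymin = grid$origin[2], ymax = grid$origin[2] + d[1] * grid$cell_size)
}

#' Coordinates of all cell centers
#'
#' @param grid An [sdm_grid()].
#' @return A two-column matrix `(x, y)` of cell-center coordinates, in
#'   column-major cell order (matching `as.vector(grid$values)`).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "sdm_grid"))
  d <- dim(grid$values)
  cs <- grid$cell_size
  x <- grid$origin[1] + (seq_len(d[2]) - 0.5) * cs
  y <- grid$origin[2] + (seq_len(d[1]) - 0.5) * cs
  cbind(x = rep(x, each = d[1]), y = rep.int(y, d[2]))
}

#' Map point coordinates to cell indices
#'
#' Points on the exact upper/right boundary are assigned to the last cell so
#' that the closed extent is fully covered.
#'
#' @param grid An [sdm_grid()].
#' @param xy Two-column matrix of point coordinates in meters.
#' @return Integer matrix with columns `row`, `col` (`NA` outside the extent).
#' @export
cell_index <- function(grid, xy) {
  stopifnot(inherits(grid, "sdm_grid"))
  xy <- as_xy_matrix(xy)
  d <- dim(grid$values)
  cs <- grid$cell_size
  col <- ceiling((xy[, 1] - grid$origin[1]) / cs)
  row <- ceiling((xy[, 2] - grid$origin[2]) / cs)
  # points exactly on the lower/left edge fall in the first cell
  col[xy[, 1] == grid$origin[1]] <- 1L
  row[xy[, 2] == grid$origin[2]] <- 1L
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract grid values at point locations
#'
#' @param grid An [sdm_grid()].
#' @param xy Two-column matrix of coordinates.
#' @return Numeric vector of the values of the cells containing each point
#'   (`NA` outside the extent).
#' @export
extract_values <- function(grid, xy) {
  idx <- cell_index(grid, xy)
  out <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx[, 1])
  out[ok] <- grid$values[idx[ok, , drop = FALSE]]
  out
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

as_xy_matrix <- function(xy) {
  if (is.data.frame(xy)) xy <- as.matrix(xy[, c("x", "y")])
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  storage.mode(xy) <- "double"
  if (ncol(xy) < 2) stop("coordinates must have two columns (x, y)")
  xy[, 1:2, drop = FALSE]
}

#' Build a covariate stack from aligned grids
#'
#' @param grids Named list of [sdm_grid()] objects sharing geometry.
#' @param standardized Logical flag; set by [standardize_stack()].
#' @param constants Optional per-layer list of `c(mean, sd)` normalization
#'   constants.
#' @return An object of class `covariate_stack`.
#' @export
covariate_stack <- function(grids, standardized = FALSE, constants = NULL) {
  if (!is.list(grids) || length(grids) < 1)
    stop("`grids` must be a non-empty list of sdm_grid objects")
  if (is.null(names(grids)) || any(names(grids) == ""))
    stop("all layers must be named")
  if (anyDuplicated(names(grids)))
    stop("layer names must be unique")
  for (g in grids) stopifnot(inherits(g, "sdm_grid"))
  ref <- grids[[1]]
  for (k in seq_along(grids)) {
    if (!same_geometry(ref, grids[[k]]))
      stop(sprintf("layer '%s' does not share the geometry of layer '%s'",
                   names(grids)[k], names(grids)[1]))
  }
  structure(
    list(grids = grids, standardized = isTRUE(standardized),
         constants = constants),
    class = "covariate_stack"
  )
}

#' @export
print.covariate_stack <- function(x, ...) {
  d <- dim(x$grids[[1]]$values)
  cat(sprintf("<covariate_stack> %d layer(s) [%s], %d x %d cells%s\n",
              length(x$grids), paste(names(x$grids), collapse = ", "),
              d[1], d[2],
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' @export
names.covariate_stack <- function(x) names(x$grids)

#' Covariate values of every cell as a matrix
#'
#' @param stack A [covariate_stack()].
#' @return Numeric matrix with one column per layer and one row per cell, in
#'   column-major cell order.
#' @export
stack_as_matrix <- function(stack) {
  stopifnot(inherits(stack, "covariate_stack"))
  vapply(stack$grids, function(g) as.vector(g$values),
         numeric(length(stack$grids[[1]]$values)))
}

#' Standardize a covariate stack to zero mean and unit variance
#'
#' Centers and scales every layer over its non-missing cells and records the
#' normalization constants so the same transformation can be replayed on
#' prediction rasters. Applying it to an already standardized stack is a
#' no-op up to numerical precision.
#'
#' @param stack A [covariate_stack()].
#' @return A standardized `covariate_stack` with `constants` filled in.
#' @export
standardize_stack <- function(stack) {
  stopifnot(inherits(stack, "covariate_stack"))
  constants <- vector("list", length(stack$grids))
  names(constants) <- names(stack$grids)
  out <- stack$grids
  for (nm in names(out)) {
    v <- out[[nm]]$values
    mu <- mean(v, na.rm = TRUE)
    sdv <- stats::sd(as.vector(v), na.rm = TRUE)
    if (!is.finite(sdv) || sdv <= 0)
      stop(sprintf("layer '%s' is constant (zero sd): cannot standardize", nm))
    out[[nm]]$values <- (v - mu) / sdv
    constants[[nm]] <- c(mean = mu, sd = sdv)
  }
  covariate_stack(out, standardized = TRUE, constants = constants)
}

# ---- raster I/O (ESRI ASCII grid) -------------------------------------------

#' Write a grid as an ESRI ASCII raster
#'
#' @param grid An [sdm_grid()].
#' @param path Output file path.
#' @param nodata Value used to encode missing cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "sdm_grid"))
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  # file rows run top-to-bottom; internal storage is bottom-up
  for (i in rev(seq_len(nrow(v))))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 15),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path Path to an ESRI ASCII grid file.
#' @return An [sdm_grid()].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7)
    stop(sprintf("'%s': too short for an ESRI ASCII grid", path))
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop(sprintf("'%s' line %d: malformed header line '%s'",
                   path, i, lines[i]))
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr)))
    stop(sprintf("'%s': header missing %s", path,
                 paste(setdiff(req, names(hdr)), collapse = ", ")))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop(sprintf("'%s': expected %d data rows, found %d (at line %d)",
                 path, nr, length(body), i))
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != nc || anyNA(row) && !("nodata_value" %in% names(hdr)))
      if (length(row) != nc)
        stop(sprintf("'%s': data row %d has %d values, expected %d",
                     path, r, length(row), nc))
    vals[nr - r + 1, ] <- row  # invert back to bottom-up storage
  }
  if ("nodata_value" %in% names(hdr))
    vals[vals == hdr$nodata_value] <- NA_real_
  sdm_grid(vals, cell_size = hdr$cellsize,
           origin = c(hdr$xllcorner, hdr$yllcorner))
}

#' Read several aligned rasters into a covariate stack
#'
#' @param paths Named character vector of ESRI ASCII grid files; names become
#'   layer names.
#' @return A [covariate_stack()]; layers with mismatched geometry are
#'   rejected.
#' @export
read_covariate_stack <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("`paths` must be a named vector (names become layer names)")
  covariate_stack(lapply(paths, read_esri_ascii))
}
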