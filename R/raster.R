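#' Lightweight geographic raster
#'
#' A minimal in-memory raster: a numeric matrix of cell values plus a WGS84
#' (EPSG:4326) bounding box, north-up. Row 1 is the northernmost row; cell
#' values are addressed by matrix (row, col) or by linear cell id
#' (column-major, as in R matrices). This is the single grid container used
#' throughout the package; heavyweight raster stacks are represented as
#' named lists of co-registered \code{grid_raster} objects.
#'
#' @param values numeric matrix (rows = latitude bands, row 1 = north).
#' @param xmin,xmax,ymin,ymax extent in decimal degrees.
#' @return object of class \code{grid_raster}.
#' @export
grid_raster <- function(values, xmin = -10, xmax = 30, ymin = 35, ymax = 70) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid_raster needs at least one row and one column")
  if (xmax <= xmin || ymax <= ymin) stop("degenerate extent")
  structure(
    list(values = values, xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster %d x %d, extent [%g, %g] x [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$xmin, x$xmax, x$ymin, x$ymax))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%g, %g], %d NA\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Cell resolution in degrees (x, y)
#' @param r a \code{grid_raster}
#' @return numeric length 2: c(xres, yres)
#' @export
rst_res <- function(r) {
  c((r$xmax - r$xmin) / ncol(r$values), (r$ymax - r$ymin) / nrow(r$values))
}

#' Longitudes of column centers / latitudes of row centers
#' @param r a \code{grid_raster}
#' @return list with \code{lon} (by column) and \code{lat} (by row, north first)
#' @export
rst_axes <- function(r) {
  res <- rst_res(r)
  list(
    lon = r$xmin + (seq_len(ncol(r$values)) - 0.5) * res[1],
    lat = r$ymax - (seq_len(nrow(r$values)) - 0.5) * res[2]
  )
}

#' Coordinates of every cell center
#' @param r a \code{grid_raster}
#' @return data.frame with \code{lon}, \code{lat} in column-major cell order
#' @export
rst_coords <- function(r) {
  ax <- rst_axes(r)
  data.frame(
    lon = rep(ax$lon, each = nrow(r$values)),
    lat = rep(ax$lat, times = ncol(r$values))
  )
}

#' Linear cell ids for point coordinates
#'
#' Points outside the extent get NA. Cell ids are column-major matrix
#' indices into \code{r$values}.
#' @param r a \code{grid_raster}
#' @param lon,lat coordinate vectors
#' @return integer vector of cell ids (NA outside extent)
#' @export
rst_cell <- function(r, lon, lat) {
  res <- rst_res(r)
  col <- floor((lon - r$xmin) / res[1]) + 1
  row <- floor((r$ymax - lat) / res[2]) + 1
  # points exactly on the max edge belong to the last cell
  col[lon == r$xmax] <- ncol(r$values)
  row[lat == r$ymin] <- nrow(r$values)
  bad <- is.na(lon) | is.na(lat) |
    col < 1 | col > ncol(r$values) | row < 1 | row > nrow(r$values)
  out <- (col - 1L) * nrow(r$values) + row
  out[bad] <- NA_integer_
  as.integer(out)
}

#' Extract cell values at point coordinates
#' @inheritParams rst_cell
#' @return numeric vector (NA outside extent)
#' @export
rst_extract <- function(r, lon, lat) {
  idx <- rst_cell(r, lon, lat)
  out <- rep(NA_real_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- r$values[idx[ok]]
  out
}

#' Build a raster on the same grid from a vector of cell values
#' @param r template \code{grid_raster}
#' @param v numeric vector, length = number of cells (column-major)
#' @return \code{grid_raster}
#' @export
rst_like <- function(r, v) {
  stopifnot(length(v) == length(r$values))
  grid_raster(matrix(v, nrow = nrow(r$values)), r$xmin, r$xmax, r$ymin, r$ymax)
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$xmax - b$xmax) < tol &&
    abs(a$ymin - b$ymin) < tol && abs(a$ymax - b$ymax) < tol
}

#' Validate and wrap a named list of co-registered rasters
#' @param layers named list of \code{grid_raster} objects on one grid
#' @return the list, classed \code{raster_stack}
#' @export
raster_stack <- function(layers) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named")
  if (length(layers) > 1L) {
    ok <- vapply(layers[-1], same_grid, logical(1), b = layers[[1]])
    if (!all(ok))
      stop("layers not co-registered: ", paste(names(layers)[-1][!ok], collapse = ", "))
  }
  structure(layers, class = "raster_stack")
}

#' Cell-by-layer value matrix of a stack
#' @param stack a \code{raster_stack} (or plain named list of rasters)
#' @return numeric matrix, rows = cells (column-major order), cols = layers
#' @export
stack_values <- function(stack) {
  m <- vapply(stack, function(l) as.vector(l$values),
              numeric(length(stack[[1]]$values)))
  colnames(m) <- names(stack)
  m
}

#' Sample stack layer values at points
#' @param stack a \code{raster_stack}
#' @param lon,lat coordinates
#' @return data.frame, one column per layer
#' @export
stack_extract <- function(stack, lon, lat) {
  out <- lapply(stack, rst_extract, lon = lon, lat = lat)
  as.data.frame(out)
}

#' Write a raster as an ESRI ASCII grid (plain text)
#'
#' The portable plain-text raster interchange format used for all on-disk
#' grids (square cells are not required by this writer; xres is recorded as
#' cellsize and yres implied by nrows).
#' @param r a \code{grid_raster}
#' @param path output file path (.asc)
#' @param nodata value used for NA cells
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  res <- rst_res(r)
  hdr <- c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", res[1]),
    sprintf("NODATA_value %g", nodata)
  )
  v <- r$values
  v[is.na(v)] <- nodata
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by \code{write_ascii_grid}
#' @param path file path
#' @return \code{grid_raster}
#' @export
read_ascii_grid <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(trimws(ln[1:6]), "\\s+")
  hdr <- stats::setNames(
    as.numeric(vapply(kv, `[`, "", 2)),
    tolower(vapply(kv, `[`, "", 1))
  )
  vals <- do.call(rbind, lapply(ln[-(1:6)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  vals[vals == hdr[["nodata_value"]]] <- NA
  cs <- hdr[["cellsize"]]
  grid_raster(vals,
              xmin = hdr[["xllcorner"]],
              xmax = hdr[["xllcorner"]] + cs * hdr[["ncols"]],
              ymin = hdr[["yllcorner"]],
              ymax = hdr[["yllcorner"]] + cs * hdr[["nrows"]])
}
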