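#' Lightweight georeferenced grid layer
#'
#' A minimal container for a regular, axis-aligned raster in a projected
#' coordinate system (units: km). Values are stored as a matrix whose rows run
#' south to north and whose columns run west to east, so `values[i, j]` is the
#' cell whose centre is at `(xmin + (j - 0.5) * cell, ymin + (i - 0.5) * cell)`.
#'
#' @param values numeric (or integer) matrix of cell values.
#' @param cell cell edge length in km.
#' @param xmin,ymin coordinates of the grid's south-west corner in km.
#' @return An object of class `grid_layer`.
#' @export
grid_layer <- function(values, cell, xmin = 0, ymin = 0) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell) || length(cell) != 1L || cell <= 0)
    stop("`cell` must be a single positive number")
  structure(
    list(values = values, cell = cell, xmin = xmin, ymin = ymin),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf(
    "<grid_layer> %d x %d cells of %g km (extent x: [%g, %g], y: [%g, %g])\n",
    nrow(x$values), ncol(x$values), x$cell,
    x$xmin, x$xmin + ncol(x$values) * x$cell,
    x$ymin, x$ymin + nrow(x$values) * x$cell
  ))
  invisible(x)
}

#' @export
dim.grid_layer <- function(x) dim(x$values)

#' Cell-centre coordinates of a grid layer
#'
#' @param grid a [grid_layer()].
#' @return A data frame with one row per cell (column-major order, matching
#'   `as.vector(grid$values)`) and columns `x`, `y`, `row`, `col`.
#' @export
grid_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  rows <- rep.int(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  data.frame(
    x = grid$xmin + (cols - 0.5) * grid$cell,
    y = grid$ymin + (rows - 0.5) * grid$cell,
    row = rows, col = cols
  )
}

#' Locate points on a grid
#'
#' Maps projected coordinates to (row, col) indices of the cell containing
#' each point. Points on a cell boundary belong to the cell above/right of it,
#' except on the outer edge where they are pulled back inside.
#'
#' @param grid a [grid_layer()].
#' @param x,y numeric vectors of point coordinates in km.
#' @return A data frame with columns `row`, `col` and logical `inside`.
#' @export
grid_locate <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((x - grid$xmin) / grid$cell) + 1L
  row <- floor((y - grid$ymin) / grid$cell) + 1L
  inside <- x >= grid$xmin & x <= grid$xmin + nc * grid$cell &
    y >= grid$ymin & y <= grid$ymin + nr * grid$cell
  col <- pmin.int(pmax.int(col, 1L), nc)
  row <- pmin.int(pmax.int(row, 1L), nr)
  data.frame(row = row, col = col, inside = inside)
}

#' Read and write ESRI ASCII grid files
#'
#' Plain-text raster exchange format (`.asc`): a six-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by rows of
#' values from north to south.
#'
#' @param grid a [grid_layer()].
#' @param path file path.
#' @param digits significant digits written (values are formatted, not
#'   rounded in memory).
#' @return `read_ascii_grid` returns a [grid_layer()]; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(grid, path, digits = 10) {
  v <- grid$values
  v[is.na(v)] <- -9999
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$cell),
    "NODATA_value -9999"
  )
  # rows are written north-first per the format; storage is south-first
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  nr <- as.integer(val[["nrows"]]); nc <- as.integer(val[["ncols"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  v <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  v <- v[rev(seq_len(nr)), , drop = FALSE]
  v[v == val[["nodata_value"]]] <- NA_real_
  grid_layer(v, cell = val[["cellsize"]],
             xmin = val[["xllcorner"]], ymin = val[["yllcorner"]])
}

# shared check that two layers sit on the same grid
same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell - b$cell) < tol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "layers") {
  if (!same_grid(a, b))
    stop(sprintf("alignment error: %s are not on the same grid", what))
  invisible(TRUE)
}
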