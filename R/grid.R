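#' Planar analysis grid
#'
#' A regular raster lattice in a single planar coordinate system, the shared
#' discretization for all layers, occurrence records and suitability maps.
#' Rows count upward from the grid origin (row 1 is the bottom row), columns
#' rightward; a point with coordinates (x, y) falls in the half-open cell
#' `[origin + (k-1)*cell, origin + k*cell)`.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param cell_size_m Cell edge length in meters (> 0).
#' @param origin Numeric length-2, the (x, y) of the grid's lower-left corner
#'   in projected meters.
#' @param region Optional character matrix (`n_rows` x `n_cols`) of region
#'   labels; `NA` marks cells outside any region (e.g., sea).
#' @return An object of class `sdm_grid`.
#' @export
sdm_grid <- function(n_rows, n_cols, cell_size_m = 1000, origin = c(0, 0),
                     region = NULL) {
  if (cell_size_m <= 0) stopf("cell_size_m must be positive")
  if (n_rows < 1 || n_cols < 1) stopf("grid dimensions must be >= 1")
  if (is.null(region)) {
    region <- matrix(NA_character_, n_rows, n_cols)
  }
  if (!all(dim(region) == c(n_rows, n_cols))) {
    stopf("region mask must be %d x %d", n_rows, n_cols)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_m = as.numeric(cell_size_m),
         origin = as.numeric(origin), region = region),
    class = "sdm_grid"
  )
}

#' @export
print.sdm_grid <- function(x, ...) {
  regs <- sort(unique(as.vector(x$region)))
  cat(sprintf("<sdm_grid> %d x %d cells of %g m; regions: %s\n",
              x$n_rows, x$n_cols, x$cell_size_m,
              if (length(regs)) paste(regs, collapse = ", ") else "none"))
  invisible(x)
}

#' Map point coordinates to grid cells
#'
#' Half-open binning: `col = floor((x - origin_x)/cell) + 1`, likewise for
#' rows, so a point on a shared cell edge belongs to the higher-indexed cell.
#' Points outside the grid get `NA` row/col.
#'
#' @param grid An [sdm_grid].
#' @param x,y Coordinate vectors in projected meters.
#' @return A data.frame with integer columns `row`, `col`.
#' @export
cell_from_xy <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size_m) + 1
  row <- floor((y - grid$origin[2]) / grid$cell_size_m) + 1
  bad <- !is.finite(row) | !is.finite(col) |
    row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates
#'
#' @param grid An [sdm_grid].
#' @param row,col Integer cell indices (1-based).
#' @return A data.frame with columns `x`, `y` (cell centers, meters).
#' @export
xy_from_cell <- function(grid, row, col) {
  data.frame(
    x = grid$origin[1] + (col - 0.5) * grid$cell_size_m,
    y = grid$origin[2] + (row - 0.5) * grid$cell_size_m
  )
}

# Linear cell id (row-major within a column-major matrix is irrelevant here;
# we use R's native column-major linear index throughout).
cell_id <- function(grid, row, col) (col - 1L) * grid$n_rows + row

#' Environmental raster stack
#'
#' Named, NA-aware layers over a shared [sdm_grid]. Each layer carries a
#' provenance tag; the (at most one) layer tagged `"effort"` is exempt from
#' standardization and collinearity pruning throughout the pipeline.
#'
#' @param grid An [sdm_grid].
#' @param layers Named list of numeric matrices (`n_rows` x `n_cols`).
#' @param tags Character vector of per-layer provenance tags, recycled if
#'   length 1; one of `"climatic"`, `"topographic"`, `"anthropogenic"`,
#'   `"vegetation"`, `"effort"`.
#' @return An object of class `sdm_stack`.
#' @export
sdm_stack <- function(grid, layers, tags = "climatic") {
  if (is.null(names(layers)) || anyDuplicated(names(layers))) {
    stopf("layers must be uniquely named")
  }
  tags <- rep_len(tags, length(layers))
  names(tags) <- names(layers)
  ok <- c("climatic", "topographic", "anthropogenic", "vegetation", "effort")
  if (!all(tags %in% ok)) stopf("unknown layer tag")
  if (sum(tags == "effort") > 1) stopf("at most one effort layer")
  for (nm in names(layers)) {
    if (!all(dim(layers[[nm]]) == c(grid$n_rows, grid$n_cols))) {
      stopf("layer '%s' does not match the grid", nm)
    }
  }
  structure(list(grid = grid, layers = layers, tags = tags),
            class = "sdm_stack")
}

#' @export
print.sdm_stack <- function(x, ...) {
  cat(sprintf("<sdm_stack> %d layers on a %d x %d grid\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols))
  for (nm in names(x$layers)) cat(sprintf("  %s [%s]\n", nm, x$tags[[nm]]))
  invisible(x)
}

#' Layer names of a stack
#' @param stack An [sdm_stack].
#' @param effort Include the effort layer? Default `TRUE`.
#' @return Character vector.
#' @export
stack_layer_names <- function(stack, effort = TRUE) {
  nms <- names(stack$layers)
  if (!effort) nms <- nms[stack$tags[nms] != "effort"]
  nms
}

effort_layer_name <- function(stack) {
  nm <- names(stack$tags)[stack$tags == "effort"]
  if (length(nm)) nm else NULL
}

#' Logical matrix of cells where every layer is non-NA
#' @param stack An [sdm_stack].
#' @return Logical matrix the size of the grid.
#' @export
complete_cells <- function(stack) {
  ok <- matrix(TRUE, stack$grid$n_rows, stack$grid$n_cols)
  for (lay in stack$layers) ok <- ok & !is.na(lay)
  ok
}

#' Extract per-cell predictor values
#'
#' @param stack An [sdm_stack].
#' @param cells Data.frame with `row`, `col`.
#' @return Data.frame, one column per layer, rows aligned with `cells`.
#' @export
extract_cells <- function(stack, cells) {
  idx <- cbind(cells$row, cells$col)
  out <- lapply(stack$layers, function(m) m[idx])
  as.data.frame(out, optional = TRUE)
}

#' Write a layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by standard GIS tools.
#' Values are written top row first, `NA` as the declared nodata value.
#'
#' @param values Numeric matrix on the stack's grid.
#' @param grid An [sdm_grid].
#' @param path Output file path.
#' @param nodata Nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.6f", grid$origin[1]),
    sprintf("yllcorner %.6f", grid$origin[2]),
    sprintf("cellsize %.6f", grid$cell_size_m),
    sprintf("NODATA_value %g", nodata)
  ), con)
  v <- values
  v[is.na(v)] <- nodata
  for (r in grid$n_rows:1) {
    writeLines(paste(formatC(v[r, ], format = "g", digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' @param path File path.
#' @return List with elements `values` (matrix, `NA` for nodata) and `grid`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  val <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
  names(val) <- tolower(vapply(kv, `[`, character(1), 1))
  body <- utils::read.table(path, skip = 6)
  m <- as.matrix(body)
  dimnames(m) <- NULL
  m <- m[nrow(m):1, , drop = FALSE]
  m[m == val[["nodata_value"]]] <- NA
  grid <- sdm_grid(val[["nrows"]], val[["ncols"]], val[["cellsize"]],
                   origin = c(val[["xllcorner"]], val[["yllcorner"]]))
  list(values = m, grid = grid)
}
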