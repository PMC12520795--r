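# Projection of the selected ensemble to suitability maps (with effort
# standardization), aggregation of independent survey data, and habitat-
# overlap scoring at focal-species occurrences.

#' Project an ensemble to a suitability map
#'
#' In `"standardized"` effort mode, every terrestrial effort cell is set to
#' the training-layer mean of non-zero effort values before prediction, so
#' the map reflects environmental suitability with observer bias held
#' constant. `"observed"` mode uses the effort layer as-is. `NA` cells
#' propagate.
#'
#' @param ensemble An `sdm_ensemble` (or a single `sdm_fit`).
#' @param stack Pruned [sdm_stack] standardized with the training constants,
#'   including the effort layer.
#' @param effort_mode `"standardized"` (default) or `"observed"`.
#' @param effort_constant Override for the standardized effort value;
#'   defaults to the stack's recorded mean non-zero training effort.
#' @return An object of class `suitability_map`: list with `values`
#'   (matrix in `[0, 1]`), `grid`, `effort_mode`, `effort_constant`,
#'   `ensemble_id`.
#' @export
project_map <- function(ensemble, stack,
                        effort_mode = c("standardized", "observed"),
                        effort_constant = NULL) {
  effort_mode <- match.arg(effort_mode)
  eff_nm <- effort_layer_name(stack)
  if (is.null(eff_nm)) stopf("stack has no effort layer")
  used_constant <- NA_real_
  if (effort_mode == "standardized") {
    used_constant <- effort_constant %||% attr(stack, "effort_mean_nonzero")
    if (is.null(used_constant) || !is.finite(used_constant)) {
      stopf("no effort constant recorded on the stack; pass effort_constant")
    }
    eff <- stack$layers[[eff_nm]]
    eff[!is.na(eff)] <- used_constant
    stack$layers[[eff_nm]] <- eff
  }
  values <- if (inherits(ensemble, "sdm_ensemble")) {
    predict_ensemble(ensemble, stack)
  } else {
    predict_sdm(ensemble, stack)
  }
  structure(
    list(values = values, grid = stack$grid, effort_mode = effort_mode,
         effort_constant = used_constant,
         ensemble_id = if (inherits(ensemble, "sdm_ensemble")) ensemble$id
                       else ensemble$algorithm),
    class = "suitability_map"
  )
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> %s, effort %s; mean %.3f over %d cells\n",
              x$ensemble_id, x$effort_mode,
              mean(x$values, na.rm = TRUE), sum(!is.na(x$values))))
  invisible(x)
}

#' Aggregate independent survey points to the grid
#'
#' At most one point is retained per occupied cell, with precedence to
#' presences: a cell is labeled presence if any point in it is a presence.
#'
#' @param points Data.frame with `x`, `y` (meters) and binary `label`
#'   (1 = presence).
#' @param grid An [sdm_grid].
#' @return Data.frame `row`, `col`, `label`, one row per occupied cell.
#' @export
aggregate_independent <- function(points, grid) {
  rc <- cell_from_xy(grid, points$x, points$y)
  ok <- !is.na(rc$row)
  if (!all(ok)) points <- points[ok, , drop = FALSE]
  rc <- rc[ok, , drop = FALSE]
  id <- cell_id(grid, rc$row, rc$col)
  lab <- tapply(as.integer(points$label), id, max)
  ids <- as.integer(names(lab))
  data.frame(
    row = ((ids - 1L) %% grid$n_rows) + 1L,
    col = ((ids - 1L) %/% grid$n_rows) + 1L,
    label = as.integer(lab)
  )
}

#' Habitat-overlap summary at focal-species occurrences
#'
#' Occurrences are thinned to one per raster cell; the suitability map is
#' read at those cells and summarized as mean and standard error
#' (`sd / sqrt(n_cells)`). Occurrences in `NA` map cells are dropped with a
#' logged count.
#'
#' @param map A `suitability_map`.
#' @param occurrences Data.frame with `longitude`, `latitude` (meters).
#' @param species Optional species label for the summary.
#' @return Data.frame `species`, `n_cells`, `mean_suitability`, `se`,
#'   `n_dropped_na`.
#' @export
overlap_summary <- function(map, occurrences, species = "focal") {
  grid <- map$grid
  rc <- cell_from_xy(grid, occurrences$longitude, occurrences$latitude)
  ok <- !is.na(rc$row)
  rc <- rc[ok, , drop = FALSE]
  dup <- duplicated(cell_id(grid, rc$row, rc$col))
  rc <- rc[!dup, , drop = FALSE]
  vals <- map$values[cbind(rc$row, rc$col)]
  n_na <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stopf("all occurrences fall in NA map cells")
  data.frame(
    species = species,
    n_cells = length(vals),
    mean_suitability = mean(vals),
    se = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0,
    n_dropped_na = n_na,
    stringsAsFactors = FALSE
  )
}
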