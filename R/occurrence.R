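# Occurrence preparation: validity screen, region-specific coordinate-
# uncertainty filtering, and per-cell thinning. Pipeline order is fixed:
# clean -> CU filter -> thin.

#' Remove invalid and non-terrestrial occurrence records
#'
#' Drops records with non-finite coordinates, records outside the grid, and
#' records falling in cells where every predictor layer is `NA` (the
#' non-terrestrial screen). Survivor order is preserved.
#'
#' @param records Occurrence data.frame (see [sample_occurrences()]).
#' @param grid An [sdm_grid].
#' @param stack An [sdm_stack] aligned to `grid`.
#' @return The surviving records, with a `"dropped"` attribute holding a
#'   named count per removal reason.
#' @export
basic_clean <- function(records, grid, stack) {
  if (nrow(records) == 0) return(records)
  finite <- is.finite(records$longitude) & is.finite(records$latitude)
  rc <- cell_from_xy(grid, records$longitude, records$latitude)
  inside <- finite & !is.na(rc$row)
  land <- rep(FALSE, nrow(records))
  if (any(inside)) {
    any_layer <- matrix(FALSE, grid$n_rows, grid$n_cols)
    for (lay in stack$layers) any_layer <- any_layer | !is.na(lay)
    land[inside] <- any_layer[cbind(rc$row[inside], rc$col[inside])]
  }
  keep <- inside & land
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped") <- c(
    invalid_or_outside = sum(!inside),
    non_terrestrial = sum(inside & !land)
  )
  out
}

#' Filter records by region-specific coordinate-uncertainty thresholds
#'
#' A record is retained iff its CU is less than or equal to the threshold
#' configured for its region (strictly greater is excluded). Records with a
#' missing CU are excluded by default, since the thresholds are defined on
#' CU; set `keep_missing_cu = TRUE` to retain them.
#'
#' @param records Occurrence data.frame.
#' @param max_cu_m Named numeric vector of per-region thresholds in meters,
#'   e.g. `c(A = 1000, B = 15000)`.
#' @param keep_missing_cu Retain records whose CU is `NA`? Default `FALSE`.
#' @return Surviving records with a `"dropped"` attribute
#'   (`over_threshold`, `missing_cu` counts).
#' @export
filter_uncertainty <- function(records, max_cu_m, keep_missing_cu = FALSE) {
  if (any(max_cu_m <= 0)) stopf("CU thresholds must be positive")
  missing_thr <- setdiff(unique(records$region), names(max_cu_m))
  if (length(missing_thr)) {
    stopf("no CU threshold configured for region: %s",
          paste(missing_thr, collapse = ", "))
  }
  cu <- records$coordinate_uncertainty_m
  thr <- max_cu_m[records$region]
  keep <- ifelse(is.na(cu), keep_missing_cu, cu <= thr)
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped") <- c(
    over_threshold = sum(!is.na(cu) & cu > thr),
    missing_cu = if (keep_missing_cu) 0L else sum(is.na(cu))
  )
  out
}

#' Thin occurrence records to one presence per grid cell
#'
#' The retained representative of each occupied cell is the first record in
#' input order (deterministic, independent of possibly-missing dates).
#'
#' @param records Cleaned occurrence data.frame.
#' @param grid An [sdm_grid].
#' @return An object of class `presence_cells`: data.frame with columns
#'   `row`, `col`, `region`, plus the grid as an attribute.
#' @export
thin_to_cells <- function(records, grid) {
  rc <- cell_from_xy(grid, records$longitude, records$latitude)
  if (nrow(records) && anyNA(rc$row)) stopf("records outside grid; run basic_clean first")
  id <- cell_id(grid, rc$row, rc$col)
  first <- !duplicated(id)
  out <- data.frame(
    row = rc$row[first], col = rc$col[first],
    region = if (nrow(records)) records$region[first] else character(0),
    stringsAsFactors = FALSE
  )
  attr(out, "grid") <- grid
  class(out) <- c("presence_cells", "data.frame")
  out
}
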