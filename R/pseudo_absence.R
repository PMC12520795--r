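# Pseudo-absence generation at 1:1 with presences per region, under two
# exclusion modes: presence-cell exclusion (precise records) and positional-
# uncertainty buffer exclusion (imprecise records).

valid_region_cells <- function(grid, stack, region) {
  ok <- complete_cells(stack) & !is.na(grid$region) & grid$region == region
  which(ok)
}

#' Eligible background cells under presence-cell exclusion
#'
#' Every cell of the region with complete predictors is eligible except the
#' cells that contain a presence; neighbors of presence cells remain viable.
#'
#' @param presences A `presence_cells` object (see [thin_to_cells()]).
#' @param grid An [sdm_grid].
#' @param stack An [sdm_stack] (defines predictor completeness).
#' @param region Region label.
#' @return Integer vector of eligible linear cell ids (see notes: R
#'   column-major index into grid matrices).
#' @export
eligible_cells_cellexcl <- function(presences, grid, stack, region) {
  valid <- valid_region_cells(grid, stack, region)
  pres <- presences[presences$region == region, , drop = FALSE]
  excl <- cell_id(grid, pres$row, pres$col)
  out <- setdiff(valid, excl)
  if (!length(out)) stopf("no eligible pseudo-absence cells in region '%s'", region)
  out
}

# Distance from a point to an axis-aligned rectangle: clamp the point into
# the rectangle and measure to the clamped position. Exact; no polygon
# discretization.
point_rect_dist <- function(px, py, xlo, xhi, ylo, yhi) {
  dx <- pmax(pmax(xlo - px, 0), px - xhi)
  dy <- pmax(pmax(ylo - py, 0), py - yhi)
  sqrt(dx * dx + dy * dy)
}

#' Eligible background cells under uncertainty-buffer exclusion
#'
#' A cell is excluded iff its rectangle intersects any disc of radius CU
#' centered on a record's coordinates (nearest-point distance <= CU). Used
#' where positional uncertainty spans multiple cells.
#'
#' @param records Occurrence data.frame with finite
#'   `coordinate_uncertainty_m`.
#' @param grid An [sdm_grid].
#' @param stack An [sdm_stack].
#' @param region Region label.
#' @return Integer vector of eligible linear cell ids.
#' @export
eligible_cells_bufferexcl <- function(records, grid, stack, region) {
  cu <- records$coordinate_uncertainty_m
  if (anyNA(cu) || any(!is.finite(cu)) || any(cu < 0)) {
    stopf("buffer exclusion requires finite non-negative CU on every record")
  }
  cs <- grid$cell_size_m
  excluded <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (i in seq_len(nrow(records))) {
    px <- records$longitude[i]; py <- records$latitude[i]; r <- cu[i]
    # candidate window: cells whose rectangle could be within r of the point,
    # padded one cell so exact-boundary contacts are kept for the distance test
    c_lo <- max(1L, floor((px - r - grid$origin[1]) / cs))
    c_hi <- min(grid$n_cols, floor((px + r - grid$origin[1]) / cs) + 2L)
    r_lo <- max(1L, floor((py - r - grid$origin[2]) / cs))
    r_hi <- min(grid$n_rows, floor((py + r - grid$origin[2]) / cs) + 2L)
    if (c_lo > c_hi || r_lo > r_hi) next
    cols <- c_lo:c_hi
    rows <- r_lo:r_hi
    g <- expand.grid(row = rows, col = cols)
    d <- point_rect_dist(px, py,
                         grid$origin[1] + (g$col - 1) * cs,
                         grid$origin[1] + g$col * cs,
                         grid$origin[2] + (g$row - 1) * cs,
                         grid$origin[2] + g$row * cs)
    hit <- d <= r
    excluded[cbind(g$row[hit], g$col[hit])] <- TRUE
  }
  valid <- valid_region_cells(grid, stack, region)
  out <- setdiff(valid, which(excluded))
  if (!length(out)) stopf("no eligible pseudo-absence cells in region '%s'", region)
  out
}

#' Draw replicated pseudo-absence sets
#'
#' Set `k` is drawn under seed `base_seed + k`, uniformly without replacement
#' within the set from each region's eligible pool; sets are mutually
#' independent (a cell may recur across sets). Counts are 1:1 with presences
#' per region by construction of `n_per_region`.
#'
#' @param eligible Named list (by region) of eligible linear cell ids.
#' @param n_per_region Named integer vector of draws per region.
#' @param n_sets Number of sets, default 10.
#' @param base_seed Integer; set `k` uses `base_seed + k`.
#' @param grid An [sdm_grid], for cell coordinates.
#' @return List of `n_sets` data.frames (`set_id`, `seed`, `row`, `col`,
#'   `region`, `x`, `y`).
#' @export
draw_pa_sets <- function(eligible, n_per_region, n_sets = 10, base_seed = 0,
                         grid = NULL) {
  regions <- names(n_per_region)
  for (reg in regions) {
    if (n_per_region[[reg]] > length(eligible[[reg]])) {
      stopf("region '%s': %d pseudo-absences requested from %d eligible cells",
            reg, n_per_region[[reg]], length(eligible[[reg]]))
    }
  }
  lapply(seq_len(n_sets), function(k) {
    seed_k <- base_seed + k
    with_seed(seed_k, {
      parts <- lapply(regions, function(reg) {
        ids <- eligible[[reg]]
        take <- ids[sample.int(length(ids), n_per_region[[reg]])]
        row <- ((take - 1L) %% grid$n_rows) + 1L
        col <- ((take - 1L) %/% grid$n_rows) + 1L
        ctr <- xy_from_cell(grid, row, col)
        data.frame(set_id = k, seed = seed_k, row = row, col = col,
                   region = reg, x = ctr$x, y = ctr$y,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, parts)
    })
  })
}
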