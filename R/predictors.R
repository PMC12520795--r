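# Effort surface, collinearity pruning, standardization.

#' Build the community-science sampling-effort layer
#'
#' Each cell is scored by its observation count `n`: 0 for unsampled cells,
#' 0.33 for a single observation, and `ln(n)` for `n >= 2`. The 0.33 value
#' keeps single-observation cells distinct from unsampled ones (ln 1 would
#' collapse both to 0) while staying below `ln 2`. The effort layer is never
#' centered or scaled.
#'
#' @param points Data.frame with coordinates `x`, `y` (projected meters) of
#'   raw observation points; points outside the grid are ignored.
#' @param grid An [sdm_grid].
#' @return An object of class `effort_layer`: list with `values` (matrix),
#'   `grid`, `mean_nonzero` (mean of the positive cell values, the constant
#'   used for standardized-effort projection), and `n_points`.
#' @export
build_effort <- function(points, grid) {
  rc <- cell_from_xy(grid, points$x, points$y)
  ok <- !is.na(rc$row)
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  if (any(ok)) {
    tab <- table(cell_id(grid, rc$row[ok], rc$col[ok]))
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  values <- matrix(0, grid$n_rows, grid$n_cols)
  values[counts == 1L] <- 0.33
  many <- counts >= 2L
  values[many] <- log(counts[many])
  structure(
    list(values = values, grid = grid,
         mean_nonzero = mean(values[values > 0]),
         n_points = sum(ok)),
    class = "effort_layer"
  )
}

#' @export
print.effort_layer <- function(x, ...) {
  cat(sprintf("<effort_layer> %d points; %d sampled cells; mean non-zero %.3f\n",
              x$n_points, sum(x$values > 0), x$mean_nonzero))
  invisible(x)
}

#' Add an effort layer to a stack
#' @param stack An [sdm_stack].
#' @param effort An `effort_layer` from [build_effort()].
#' @param name Layer name, default `"effort"`.
#' @return The stack with the effort layer appended (tagged `"effort"`).
#'   Effort is `NA` outside terrestrial cells, matching the other layers.
#' @export
add_effort_layer <- function(stack, effort, name = "effort") {
  v <- effort$values
  v[is.na(stack$grid$region)] <- NA_real_
  layers <- c(stack$layers, stats::setNames(list(v), name))
  out <- sdm_stack(stack$grid, layers, tags = c(stack$tags, "effort"))
  attr(out, "effort_mean_nonzero") <- effort$mean_nonzero
  attr(out, "standardization") <- attr(stack, "standardization")
  out
}

#' Prune collinear layers at a |r| threshold
#'
#' Pairwise Pearson correlations are computed over cells where all compared
#' layers are non-NA. While any pair of kept layers exceeds the threshold in
#' absolute value, the layer with the largest mean absolute correlation
#' against all other kept layers is dropped (ties broken alphabetically).
#' The effort layer is exempt.
#'
#' @param stack An [sdm_stack].
#' @param threshold Absolute-correlation cutoff, default 0.7.
#' @return List with `stack` (pruned) and `report`: a list with `kept`
#'   (character) and `dropped` (data.frame `layer`, `max_abs_r`, `partner`).
#' @export
prune_collinear <- function(stack, threshold = 0.7) {
  env_nms <- stack_layer_names(stack, effort = FALSE)
  if (length(env_nms) < 2) stopf("need at least two non-effort layers")
  vals <- sapply(env_nms, function(nm) as.vector(stack$layers[[nm]]))
  ok <- stats::complete.cases(vals)
  vals <- vals[ok, , drop = FALSE]
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("zero-variance layer: %s", paste(env_nms[sds == 0], collapse = ", "))
  }
  cm <- stats::cor(vals)
  kept <- sort(env_nms)
  dropped <- data.frame(layer = character(0), max_abs_r = numeric(0),
                        partner = character(0), stringsAsFactors = FALSE)
  repeat {
    sub <- abs(cm[kept, kept, drop = FALSE])
    diag(sub) <- 0
    if (max(sub) <= threshold) break
    viol <- rownames(sub)[apply(sub > threshold, 1, any)]
    mean_r <- rowMeans(sub)[viol]
    # largest mean |r| first; alphabetical order of `kept` breaks ties
    victim <- viol[which.max(mean_r)]
    partner <- colnames(sub)[which.max(sub[victim, ])]
    dropped <- rbind(dropped, data.frame(
      layer = victim, max_abs_r = max(sub[victim, ]), partner = partner,
      stringsAsFactors = FALSE
    ))
    kept <- setdiff(kept, victim)
  }
  keep_nms <- names(stack$layers)[names(stack$layers) %in%
                                    c(kept, effort_layer_name(stack))]
  out <- sdm_stack(stack$grid, stack$layers[keep_nms], tags = stack$tags[keep_nms])
  attr(out, "effort_mean_nonzero") <- attr(stack, "effort_mean_nonzero")
  attr(out, "standardization") <- attr(stack, "standardization")
  list(stack = out, report = list(kept = kept, dropped = dropped,
                                  threshold = threshold))
}

#' Center and scale non-effort layers
#'
#' Each non-effort layer is transformed to mean 0, sd 1 over its non-NA
#' cells (pooled across regions). The effort layer passes through untouched.
#' The centering/scaling constants are recorded in the
#' `"standardization"` attribute so projection onto new extents can reuse
#' them via [apply_standardization()].
#'
#' @param stack An [sdm_stack].
#' @return The standardized stack.
#' @export
standardize_stack <- function(stack) {
  env_nms <- stack_layer_names(stack, effort = FALSE)
  consts <- data.frame(layer = env_nms, center = NA_real_, scale = NA_real_,
                       stringsAsFactors = FALSE)
  layers <- stack$layers
  for (i in seq_along(env_nms)) {
    nm <- env_nms[i]
    v <- layers[[nm]]
    mu <- mean(v, na.rm = TRUE)
    sg <- stats::sd(as.vector(v), na.rm = TRUE)
    if (!is.finite(sg) || sg == 0) stopf("zero-variance layer: %s", nm)
    layers[[nm]] <- (v - mu) / sg
    consts$center[i] <- mu
    consts$scale[i] <- sg
  }
  out <- sdm_stack(stack$grid, layers, tags = stack$tags)
  attr(out, "standardization") <- consts
  attr(out, "effort_mean_nonzero") <- attr(stack, "effort_mean_nonzero")
  out
}

#' Apply frozen standardization constants to a (projection) stack
#'
#' @param stack An [sdm_stack] on the raw scale.
#' @param constants The `"standardization"` attribute of a stack returned by
#'   [standardize_stack()].
#' @return The stack standardized with the supplied constants.
#' @export
apply_standardization <- function(stack, constants) {
  layers <- stack$layers
  for (i in seq_len(nrow(constants))) {
    nm <- constants$layer[i]
    if (!nm %in% names(layers)) stopf("layer '%s' absent from stack", nm)
    layers[[nm]] <- (layers[[nm]] - constants$center[i]) / constants$scale[i]
  }
  out <- sdm_stack(stack$grid, layers, tags = stack$tags)
  attr(out, "standardization") <- constants
  attr(out, "effort_mean_nonzero") <- attr(stack, "effort_mean_nonzero")
  out
}
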