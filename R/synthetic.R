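# Synthetic landscapes with the statistical structure the analysis assumes:
# spatially autocorrelated predictors (optionally with controlled collinearity),
# a logistic suitability truth, and occurrence sampling proportional to
# suitability x observation effort with region-dependent coordinate
# uncertainty. Everything is seed-stable.

# Gaussian-kernel smoothing of a matrix, separable, edge-normalized so border
# cells are averages over the kernel mass that falls inside the grid.
smooth_field <- function(m, radius) {
  if (radius <= 0) stopf("smoothness must be positive")
  half <- max(1L, ceiling(3 * radius))
  k <- stats::dnorm(seq(-half, half), sd = radius)
  k <- k / sum(k)
  pass <- function(mat) {
    num <- matrix(0, nrow(mat), ncol(mat))
    den <- matrix(0, nrow(mat), ncol(mat))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(nrow(mat)) + off
      ok <- src >= 1L & src <= nrow(mat)
      num[ok, ] <- num[ok, ] + k[j] * mat[src[ok], ]
      den[ok, ] <- den[ok, ] + k[j]
    }
    num / den
  }
  t(pass(t(pass(m))))
}

#' Simulate spatially autocorrelated predictor layers
#'
#' Layers are kernel-smoothed Gaussian white-noise fields. Controlled
#' collinearity between a pair of layers is induced by mixing their noise
#' fields before smoothing (`L2 = r L1 + sqrt(1 - r^2) e`), which preserves
#' the target Pearson correlation under the shared smoothing operator. Cells
#' outside every region of the grid's mask are set to `NA` (non-terrestrial).
#'
#' @param grid An [sdm_grid].
#' @param n_layers Number of layers (>= 2); named `env01`, `env02`, ...
#' @param smoothness Gaussian kernel radius in cells (> 0).
#' @param target_corr Optional data.frame with columns `layer1`, `layer2`,
#'   `r` requesting a realized pairwise Pearson correlation.
#' @param seed Integer seed; identical seed gives bit-identical output.
#' @param tags Provenance tags passed to [sdm_stack()].
#' @return An [sdm_stack] of `n_layers` layers.
#' @export
simulate_predictors <- function(grid, n_layers, smoothness = 3,
                                target_corr = NULL, seed = 1,
                                tags = "climatic") {
  if (n_layers < 2) stopf("n_layers must be >= 2")
  if (smoothness <= 0) stopf("smoothness must be positive")
  nms <- sprintf("env%02d", seq_len(n_layers))
  if (!is.null(target_corr)) {
    if (any(abs(target_corr$r) >= 1)) stopf("target correlations must lie in (-1, 1)")
    if (!all(c(target_corr$layer1, target_corr$layer2) %in% nms)) {
      stopf("target_corr names a layer outside env01..env%02d", n_layers)
    }
  }
  with_seed(seed, {
    noise <- lapply(seq_len(n_layers), function(i) {
      matrix(stats::rnorm(grid$n_rows * grid$n_cols), grid$n_rows, grid$n_cols)
    })
    names(noise) <- nms
    if (!is.null(target_corr)) {
      for (i in seq_len(nrow(target_corr))) {
        a <- target_corr$layer1[i]; b <- target_corr$layer2[i]
        r <- target_corr$r[i]
        noise[[b]] <- r * noise[[a]] + sqrt(1 - r^2) * noise[[b]]
      }
    }
    layers <- lapply(noise, smooth_field, radius = smoothness)
    mask <- is.na(grid$region)
    layers <- lapply(layers, function(m) { m[mask] <- NA_real_; m })
    sdm_stack(grid, layers, tags = tags)
  })
}

#' Define a logistic suitability truth over a stack
#'
#' Per-cell suitability is `plogis(intercept + sum(coef * z(layer)))` where
#' `z()` standardizes each referenced layer over its non-NA cells; cells with
#' any referenced layer `NA` are `NA`.
#'
#' @param stack An [sdm_stack].
#' @param coefficients Named numeric vector of layer coefficients.
#' @param intercept Intercept on the logit scale.
#' @return An object of class `sdm_truth` with elements `suitability`
#'   (matrix in `[0, 1]`), `coefficients`, `intercept`, `grid`.
#' @export
define_truth <- function(stack, coefficients, intercept = 0) {
  unknown <- setdiff(names(coefficients), names(stack$layers))
  if (length(unknown)) stopf("unknown layer name: %s", paste(unknown, collapse = ", "))
  lin <- matrix(intercept, stack$grid$n_rows, stack$grid$n_cols)
  for (nm in names(coefficients)) {
    v <- stack$layers[[nm]]
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(as.vector(v), na.rm = TRUE)
    lin <- lin + coefficients[[nm]] * z
  }
  structure(
    list(suitability = stats::plogis(lin), coefficients = coefficients,
         intercept = intercept, grid = stack$grid),
    class = "sdm_truth"
  )
}

# --- coordinate-uncertainty models -----------------------------------------

#' Coordinate-uncertainty distribution specs
#'
#' `cu_constant()` returns a degenerate distribution; `cu_lognormal()` a
#' truncated log-normal (meters); `cu_mixture_uniform()` a mixture of uniform
#' components. `cu_native_default()` is the heavy-tailed native-range preset:
#' 50% Uniform(4 m, 1 km), 50% Uniform(1 km, 15 km), mirroring a record pool
#' in which only about half the records are GPS-precision.
#' `cu_invasive_default()` is a log-normal with median 31 m truncated at
#' 1 km, emulating modern community-science precision.
#'
#' @param value,meanlog,sdlog,lower,upper,ranges,probs Distribution
#'   parameters; `ranges` is a list of `c(min, max)` pairs in meters.
#' @return A cu-model spec consumed by [sample_occurrences()].
#' @export
cu_constant <- function(value) list(kind = "constant", value = value)

#' @rdname cu_constant
#' @export
cu_lognormal <- function(meanlog, sdlog, lower = 1, upper = Inf) {
  list(kind = "lognormal", meanlog = meanlog, sdlog = sdlog,
       lower = lower, upper = upper)
}

#' @rdname cu_constant
#' @export
cu_mixture_uniform <- function(ranges, probs) {
  stopifnot(length(ranges) == length(probs), abs(sum(probs) - 1) < 1e-9)
  list(kind = "mixture_uniform", ranges = ranges, probs = probs)
}

#' @rdname cu_constant
#' @export
cu_native_default <- function() {
  cu_mixture_uniform(list(c(4, 1000), c(1000, 15000)), c(0.5, 0.5))
}

#' @rdname cu_constant
#' @export
cu_invasive_default <- function() cu_lognormal(log(31), 1.2, lower = 1, upper = 1000)

draw_cu <- function(cu_model, n) {
  switch(cu_model$kind,
    constant = rep(cu_model$value, n),
    lognormal = {
      x <- stats::rlnorm(n, cu_model$meanlog, cu_model$sdlog)
      pmin(pmax(x, cu_model$lower), cu_model$upper)
    },
    mixture_uniform = {
      comp <- sample.int(length(cu_model$ranges), n, replace = TRUE,
                         prob = cu_model$probs)
      lo <- vapply(cu_model$ranges, `[`, numeric(1), 1)[comp]
      hi <- vapply(cu_model$ranges, `[`, numeric(1), 2)[comp]
      stats::runif(n, lo, hi)
    },
    stopf("unknown cu model kind '%s'", cu_model$kind)
  )
}

#' Sample effort-biased occurrence records
#'
#' Detection emulation: within one region, cells are drawn (with replacement)
#' with probability proportional to `suitability x effort`; zero-effort cells
#' can never produce a record. Coordinates are the cell center plus uniform
#' within-cell jitter; each record carries a coordinate uncertainty drawn
#' from `cu_model`.
#'
#' @param truth An `sdm_truth` from [define_truth()].
#' @param effort Numeric matrix of non-negative effort values on the grid.
#' @param n_target Number of records to draw.
#' @param region Region label restricting the sample.
#' @param cu_model A spec from [cu_constant()] and friends.
#' @param seed Integer seed.
#' @param basis_probs Named probabilities over
#'   `c("human_observation", "preserved_specimen", "other")`.
#' @param date_range Character length-2, bounds for random event dates.
#' @return A data.frame of occurrence records with columns `longitude`,
#'   `latitude`, `coordinate_uncertainty_m`, `event_date`, `basis_of_record`,
#'   `region`.
#' @export
sample_occurrences <- function(truth, effort, n_target, region, cu_model,
                               seed = 1,
                               basis_probs = c(human_observation = 1,
                                               preserved_specimen = 0,
                                               other = 0),
                               date_range = c("2000-01-01", "2024-12-01")) {
  grid <- truth$grid
  if (any(effort < 0, na.rm = TRUE)) stopf("effort must be non-negative")
  in_region <- !is.na(grid$region) & grid$region == region
  if (!any(in_region)) stopf("region '%s' has no cells", region)
  w <- truth$suitability * effort
  w[!in_region | is.na(w)] <- 0
  if (sum(w) == 0) stopf("all sampling weights are zero in region '%s'", region)
  with_seed(seed, {
    pick <- sample.int(length(w), n_target, replace = TRUE, prob = as.vector(w))
    rc <- arrayInd(pick, dim(w))
    ctr <- xy_from_cell(grid, rc[, 1], rc[, 2])
    jit <- grid$cell_size_m * (cbind(stats::runif(n_target), stats::runif(n_target)) - 0.5)
    dates <- as.Date(date_range[1]) +
      floor(stats::runif(n_target) *
              as.numeric(as.Date(date_range[2]) - as.Date(date_range[1]) + 1))
    basis <- sample(names(basis_probs), n_target, replace = TRUE, prob = basis_probs)
    data.frame(
      longitude = ctr$x + jit[, 1],
      latitude = ctr$y + jit[, 2],
      coordinate_uncertainty_m = draw_cu(cu_model, n_target),
      event_date = dates,
      basis_of_record = basis,
      region = region,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a complete two-region synthetic study system
#'
#' Bundles the study conditions the pipeline targets: an invasive region `A`
#' and a much smaller-sample native region `B` separated by a non-terrestrial
#' strip; spatially autocorrelated predictors including one pair with
#' `|r| = 0.9`; a logistic suitability truth; a smooth observation-effort
#' intensity from which community-science observation points are drawn; and
#' effort-biased occurrence records with small coordinate uncertainty in `A`
#' and a heavy-tailed (up to 15 km) distribution in `B`.
#'
#' @param n_rows,n_cols Grid dimensions (a vertical sea strip splits columns
#'   into region `A` left, region `B` right).
#' @param cell_size_m Cell edge (meters).
#' @param n_layers Number of environmental layers.
#' @param smoothness Kernel radius in cells for all random fields.
#' @param coefficients Named truth coefficients (defaults use the first two
#'   layers with effects 2 and -1).
#' @param intercept Truth intercept (logit scale).
#' @param n_occ_A,n_occ_B Raw occurrence records to draw per region.
#' @param n_effort_points Community-science observation points used to build
#'   the effort layer.
#' @param seed Integer seed for every stochastic component.
#' @return A list with `grid`, `stack` (environmental layers), `truth`,
#'   `effort` (an `effort_layer`), `effort_points`, and `occurrences`.
#' @export
synth_landscape <- function(n_rows = 100, n_cols = 180, cell_size_m = 1000,
                            n_layers = 11, smoothness = 4,
                            coefficients = NULL, intercept = -0.5,
                            n_occ_A = 1100, n_occ_B = 75,
                            n_effort_points = 60000, seed = 1) {
  sea <- floor(n_cols * 0.45):ceiling(n_cols * 0.55)
  region <- matrix("A", n_rows, n_cols)
  region[, sea] <- NA_character_
  region[, seq(max(sea) + 1, n_cols)] <- "B"
  grid <- sdm_grid(n_rows, n_cols, cell_size_m, region = region)

  stack <- simulate_predictors(
    grid, n_layers = n_layers, smoothness = smoothness,
    target_corr = if (n_layers >= 3)
      data.frame(layer1 = "env01", layer2 = "env03", r = 0.9),
    seed = stage_seed(seed, "landscape")
  )
  if (is.null(coefficients)) {
    coefficients <- c(env01 = 2, env02 = -1)
  }
  truth <- define_truth(stack, coefficients, intercept)

  # Observation activity: its own smooth intensity field, mildly tied to
  # suitability so popular places are also sampled places.
  eff_seed <- stage_seed(seed, "effort")
  intensity <- with_seed(eff_seed, {
    f <- smooth_field(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                      radius = smoothness)
    exp(f / stats::sd(f) + 0.5 * (truth$suitability - 0.5))
  })
  intensity[is.na(grid$region)] <- 0
  eff_pts <- with_seed(eff_seed + 1L, {
    pick <- sample.int(length(intensity), n_effort_points, replace = TRUE,
                       prob = as.vector(intensity))
    rc <- arrayInd(pick, dim(intensity))
    ctr <- xy_from_cell(grid, rc[, 1], rc[, 2])
    data.frame(
      x = ctr$x + cell_size_m * (stats::runif(n_effort_points) - 0.5),
      y = ctr$y + cell_size_m * (stats::runif(n_effort_points) - 0.5)
    )
  })
  effort <- build_effort(eff_pts, grid)

  occ_seed <- stage_seed(seed, "occurrences")
  occ_A <- sample_occurrences(
    truth, effort$values, n_occ_A, "A", cu_invasive_default(),
    seed = occ_seed,
    basis_probs = c(human_observation = 0.92, preserved_specimen = 0.08, other = 0)
  )
  occ_B <- sample_occurrences(
    truth, effort$values, n_occ_B, "B", cu_native_default(),
    seed = occ_seed + 1L,
    basis_probs = c(human_observation = 0.35, preserved_specimen = 0.65, other = 0),
    date_range = c("1950-01-01", "2024-12-01")
  )
  list(grid = grid, stack = stack, truth = truth, effort = effort,
       effort_points = eff_pts, occurrences = rbind(occ_A, occ_B))
}

#' Write occurrence records to CSV
#' @param records Occurrence data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read occurrence records from CSV
#' @param path Input path.
#' @return Occurrence data.frame.
#' @export
read_occurrences <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$event_date <- as.Date(out$event_date)
  out
}
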