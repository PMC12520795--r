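# Shared fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# A small two-region grid with a sea strip; all-land stack of k layers.
tiny_grid <- function(n_rows = 12, n_cols = 20, cell = 100) {
  region <- matrix("A", n_rows, n_cols)
  region[, 9:12] <- NA_character_
  region[, 13:n_cols] <- "B"
  sdm_grid(n_rows, n_cols, cell, region = region)
}

tiny_stack <- function(grid = tiny_grid(), n_layers = 3, seed = 42) {
  simulate_predictors(grid, n_layers = n_layers, smoothness = 1.5, seed = seed)
}

# Full small landscape shared by engine/pipeline tests.
fixture_land <- function() {
  memo("land", function() {
    synth_landscape(n_rows = 60, n_cols = 100, n_layers = 6,
                    n_occ_A = 500, n_occ_B = 80, n_effort_points = 8000,
                    seed = 7)
  })
}

fixture_prepared <- function() {
  memo("prepared", function() {
    land <- fixture_land()
    occ <- basic_clean(land$occurrences, land$grid, land$stack)
    occ <- filter_uncertainty(occ, c(A = 1000, B = 15000))
    pres <- thin_to_cells(occ, land$grid)
    pruned <- prune_collinear(land$stack)
    stack <- add_effort_layer(standardize_stack(pruned$stack), land$effort)
    elig <- list(
      A = eligible_cells_cellexcl(pres, land$grid, stack, "A"),
      B = eligible_cells_bufferexcl(occ[occ$region == "B", ], land$grid, stack, "B")
    )
    n_per <- c(A = sum(pres$region == "A"), B = sum(pres$region == "B"))
    pa <- draw_pa_sets(elig, n_per, n_sets = 2, base_seed = 100, grid = land$grid)
    frame <- assemble_frame(pres, pa[[1]], stack)
    list(land = land, occ = occ, presences = pres, stack = stack,
         eligible = elig, pa_sets = pa, frame = frame)
  })
}

# A linearly separable toy model frame on two predictors.
toy_frame <- function(n = 60, seed = 3) {
  with_seed(seed, {
    cls <- rep(c(1L, 0L), each = n / 2)
    x1 <- ifelse(cls == 1, stats::rnorm(n, 3), stats::rnorm(n, -3))
    x2 <- stats::rnorm(n)
    data.frame(row = seq_len(n), col = 1L, region = rep(c("A", "B"), n / 2),
               class = cls, x1 = x1, x2 = x2)
  })
}

# Brute-force max-TSS oracle: scan every distinct score (plus 0 and 1) as a
# threshold with the >= rule.
oracle_max_tss <- function(obs, scores) {
  cand <- unique(c(0, sort(unique(scores)), 1))
  best <- -Inf
  for (t in cand) {
    pos <- scores >= t
    tss <- sum(pos & obs == 1) / sum(obs == 1) +
      sum(!pos & obs == 0) / sum(obs == 0) - 1
    if (tss > best) best <- tss
  }
  best
}

# Beta outcomes with logit-linear means, a run random intercept, and
# region x predictor dispersion; region_shift moves predictor p1 in region B
# on the logit scale. Used for GLMM calibration and recovery checks.
simulate_importance_data <- function(n_runs, region_shift = 0, seed = 1,
                                     predictors = c("p1", "p2", "p3")) {
  with_seed(seed, {
    d <- expand.grid(run = sprintf("run%02d", seq_len(n_runs)),
                     region = c("A", "B"), predictor = predictors,
                     stringsAsFactors = FALSE)
    base <- stats::setNames(seq(-1, 0.2, length.out = length(predictors)),
                            predictors)
    u <- stats::setNames(rnorm(n_runs, 0, 0.25),
                         sprintf("run%02d", seq_len(n_runs)))
    eta <- base[d$predictor] + u[d$run] +
      ifelse(d$predictor == "p1" & d$region == "B", region_shift, 0)
    mu <- plogis(eta)
    phi <- exp(4 + 0.4 * (d$region == "B") - 0.3 * (d$predictor == "p2"))
    d$scaled <- rbeta(nrow(d), mu * phi, (1 - mu) * phi)
    d
  })
}

# Exhaustive disc-rectangle exclusion oracle: loops over every cell of the
# grid with no candidate-window shortcut.
oracle_buffer_excluded <- function(records, grid) {
  excluded <- matrix(FALSE, grid$n_rows, grid$n_cols)
  cs <- grid$cell_size_m
  for (r in seq_len(grid$n_rows)) {
    for (cc in seq_len(grid$n_cols)) {
      xlo <- grid$origin[1] + (cc - 1) * cs; xhi <- xlo + cs
      ylo <- grid$origin[2] + (r - 1) * cs; yhi <- ylo + cs
      for (i in seq_len(nrow(records))) {
        px <- records$longitude[i]; py <- records$latitude[i]
        dx <- max(xlo - px, 0, px - xhi)
        dy <- max(ylo - py, 0, py - yhi)
        if (sqrt(dx^2 + dy^2) <= records$coordinate_uncertainty_m[i]) {
          excluded[r, cc] <- TRUE
          break
        }
      }
    }
  }
  excluded
}
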