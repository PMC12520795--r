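# A linear scoring "algorithm" whose effort dependence can be switched off,
# used to ablate the effort channel.
register_linear <- function() {
  register_algorithm(
    "LIN",
    fit = function(x, y, hyper, seed) hyper$weights,
    predict = function(object, x) {
      w <- object[names(object) %in% names(x)]
      plogis(as.matrix(x[names(w)]) %*% w)[, 1]
    },
    defaults = list(weights = c())
  )
}

test_that("standardized-effort projection holds effort constant at the training mean", {
  prep <- fixture_prepared()
  register_linear()
  w_eff <- c(env02 = 1.5, effort = 2)
  fit <- fit_sdm("LIN", prep$frame, list(weights = w_eff), seed = 1)
  mu <- attr(prep$stack, "effort_mean_nonzero")
  expect_equal(mu, prep$land$effort$mean_nonzero)
  map_std <- project_map(fit, prep$stack, "standardized")
  expect_equal(map_std$effort_constant, mu)
  # manual recomputation: effort replaced by its mean non-zero value
  ok <- complete_cells(prep$stack)
  manual <- plogis(1.5 * prep$stack$layers$env02 + 2 * mu)
  expect_equal(map_std$values[ok], manual[ok], tolerance = 1e-12)
  expect_true(all(is.na(map_std$values[!ok])))

  # perturbing observed effort does not move the standardized map
  stack2 <- prep$stack
  eff <- stack2$layers$effort
  eff[!is.na(eff)] <- eff[!is.na(eff)] + 5
  stack2$layers$effort <- eff
  attr(stack2, "effort_mean_nonzero") <- mu
  map_std2 <- project_map(fit, stack2, "standardized")
  expect_equal(map_std2$values, map_std$values, tolerance = 1e-12)

  # ablation: with a zero effort coefficient, observed and standardized agree
  fit0 <- fit_sdm("LIN", prep$frame, list(weights = c(env02 = 1.5, effort = 0)),
                  seed = 1)
  expect_equal(project_map(fit0, prep$stack, "observed")$values,
               project_map(fit0, prep$stack, "standardized")$values,
               tolerance = 1e-12)
  # but they differ when effort matters
  expect_false(isTRUE(all.equal(project_map(fit, prep$stack, "observed")$values,
                                map_std$values)))
})

test_that("independent survey points aggregate to one per cell with presence precedence", {
  g <- sdm_grid(6, 6, 100)
  pts <- data.frame(
    x = c(150, 160, 170, 350, 550, 555),  # cells: 3x in (.,2), 1 in (.,4), 2 in (.,6)
    y = c(150, 155, 160, 150, 150, 152),
    label = c(1, 0, 0, 0, 1, 1)
  )
  agg <- aggregate_independent(pts, g)
  expect_equal(nrow(agg), 3)
  expect_equal(agg$label[order(agg$col)], c(1, 0, 1))
  # all-distinct cells: identity; count never grows
  pts2 <- data.frame(x = c(150, 350, 550), y = 150, label = c(1, 0, 1))
  expect_equal(nrow(aggregate_independent(pts2, g)), 3)
  expect_lte(nrow(agg), nrow(pts))
})

test_that("overlap summaries thin to cells and report mean and SE of suitability", {
  g <- sdm_grid(6, 6, 100)
  vals <- matrix(seq(0, 1, length.out = 36), 6, 6)
  vals[1, 1] <- NA
  map <- structure(list(values = vals, grid = g, effort_mode = "standardized",
                        effort_constant = 1, ensemble_id = "toy"),
                   class = "suitability_map")
  # all occurrences in one cell: mean = that cell, SE = 0
  one <- data.frame(longitude = c(310, 320, 330), latitude = c(310, 320, 330))
  s1 <- overlap_summary(map, one, species = "snail")
  expect_equal(s1$n_cells, 1)
  expect_equal(s1$mean_suitability, vals[4, 4])
  expect_equal(s1$se, 0)
  # two cells at 0.4 and 0.6 give mean 0.5, SE 0.1
  map2 <- map
  map2$values[2, 2] <- 0.4
  map2$values[3, 3] <- 0.6
  two <- data.frame(longitude = c(150, 250), latitude = c(150, 250))
  s2 <- overlap_summary(map2, two)
  expect_equal(s2$mean_suitability, 0.5)
  expect_equal(s2$se, 0.1)
  # duplicated raw points thin to unique cells; NA cells drop with a count
  with_seed(61, {
    raw <- data.frame(longitude = rep(c(150, 250, 350, 50), c(20, 20, 15, 5)),
                      latitude = rep(c(150, 250, 350, 50), c(20, 20, 15, 5)))
  })
  s3 <- overlap_summary(map2, raw)
  expect_equal(s3$n_cells, 3)
  expect_equal(s3$n_dropped_na, 1)  # (1,1) is the NA cell
  expect_equal(s3$mean_suitability, mean(c(0.4, 0.6, vals[4, 4])))
  expect_error(overlap_summary(map, data.frame(longitude = 50, latitude = 50)),
               "NA map cells")
})
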