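test_that("predictor simulation is deterministic and respects layer count", {
  g <- tiny_grid()
  s1 <- simulate_predictors(g, n_layers = 11, smoothness = 2, seed = 1)
  s2 <- simulate_predictors(g, n_layers = 11, smoothness = 2, seed = 1)
  expect_identical(s1$layers, s2$layers)
  expect_length(s1$layers, 11)
  expect_named(s1$layers, sprintf("env%02d", 1:11))
  s3 <- simulate_predictors(g, n_layers = 11, smoothness = 2, seed = 2)
  expect_false(identical(s1$layers, s3$layers))
  # sea-strip cells are NA, land cells are not
  expect_true(all(is.na(s1$layers$env01[, 9:12])))
  expect_false(anyNA(s1$layers$env01[, 1:8]))
  expect_error(simulate_predictors(g, 3, smoothness = 0), "positive")
  expect_error(simulate_predictors(g, 3, smoothness = 2,
                                   target_corr = data.frame(layer1 = "env01",
                                                            layer2 = "env02",
                                                            r = 1)),
               "\\(-1, 1\\)")
})

test_that("requested high correlation between layers is realized", {
  g <- sdm_grid(100, 100, 1000, region = matrix("A", 100, 100))
  hits <- 0L
  for (seed in 1:20) {
    s <- simulate_predictors(g, n_layers = 4, smoothness = 3,
                             target_corr = data.frame(layer1 = "env01",
                                                      layer2 = "env02",
                                                      r = 0.9),
                             seed = seed)
    r <- cor(as.vector(s$layers$env01), as.vector(s$layers$env02))
    if (abs(r - 0.9) <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("truth suitability matches the inverse-logit formula cell by cell", {
  g <- tiny_grid()
  s <- tiny_stack(g)
  flat <- define_truth(s, c(env01 = 0, env02 = 0), intercept = 0)
  land <- !is.na(g$region)
  expect_true(all(abs(flat$suitability[land] - 0.5) < 1e-12))
  expect_true(all(is.na(flat$suitability[!land])))

  hot <- define_truth(s, c(env01 = 0), intercept = 50)
  expect_true(all(hot$suitability[land] > 1 - 1e-9))

  tr <- define_truth(s, c(env01 = 2, env02 = -1), intercept = 0.3)
  z <- function(m) (m - mean(m, na.rm = TRUE)) / sd(as.vector(m), na.rm = TRUE)
  manual <- plogis(0.3 + 2 * z(s$layers$env01) - z(s$layers$env02))
  expect_equal(tr$suitability, manual, tolerance = 1e-12)

  expect_error(define_truth(s, c(nope = 1)), "unknown layer")
})

test_that("occurrence sampling follows suitability x effort and honors zero effort", {
  g <- sdm_grid(10, 10, 100, region = matrix("A", 10, 10))
  s <- simulate_predictors(g, 2, smoothness = 1, seed = 5)
  tr <- define_truth(s, c(env01 = 1))
  # degenerate effort: only one live cell
  eff <- matrix(0, 10, 10); eff[4, 7] <- 2
  occ <- sample_occurrences(tr, eff, 50, "A", cu_constant(31), seed = 9)
  rc <- cell_from_xy(g, occ$longitude, occ$latitude)
  expect_true(all(rc$row == 4 & rc$col == 7))
  expect_true(all(occ$coordinate_uncertainty_m == 31))

  # all-zero weights error
  expect_error(sample_occurrences(tr, matrix(0, 10, 10), 5, "A",
                                  cu_constant(1), seed = 1),
               "zero")

  # chi-square goodness of fit of cell counts against the weight vector
  eff2 <- matrix(1, 10, 10)
  occ2 <- sample_occurrences(tr, eff2, 10000, "A", cu_constant(10), seed = 11)
  rc2 <- cell_from_xy(g, occ2$longitude, occ2$latitude)
  counts <- table(factor(cell_id(g, rc2$row, rc2$col), levels = 1:100))
  w <- as.vector(tr$suitability) / sum(tr$suitability)
  gof <- suppressWarnings(chisq.test(as.vector(counts), p = w))
  expect_gt(gof$p.value, 0.01)

  # determinism
  occ3 <- sample_occurrences(tr, eff2, 100, "A", cu_native_default(), seed = 4)
  occ4 <- sample_occurrences(tr, eff2, 100, "A", cu_native_default(), seed = 4)
  expect_identical(occ3, occ4)
})

test_that("native CU preset is heavy-tailed up to 15 km, invasive preset stays under 1 km", {
  cu_b <- with_seed(2, draw_cu(cu_native_default(), 5000))
  expect_true(all(cu_b >= 4 & cu_b <= 15000))
  expect_equal(mean(cu_b <= 1000), 0.5, tolerance = 0.05)
  cu_a <- with_seed(2, draw_cu(cu_invasive_default(), 5000))
  expect_true(all(cu_a >= 1 & cu_a <= 1000))
  expect_equal(median(cu_a), 31, tolerance = 5)
})
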