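test_that("cell exclusion removes presence cells but keeps their neighbors", {
  g <- sdm_grid(10, 10, 100, region = matrix("A", 10, 10))
  st <- simulate_predictors(g, 2, smoothness = 1, seed = 2)
  pres <- data.frame(row = 5L, col = 5L, region = "A")
  elig <- eligible_cells_cellexcl(pres, g, st, "A")
  expect_false(cell_id(g, 5L, 5L) %in% elig)
  expect_true(cell_id(g, 5L, 6L) %in% elig)
  expect_length(elig, 99)
  # empty presence set: everything valid is eligible
  expect_length(eligible_cells_cellexcl(pres[0, ], g, st, "A"), 100)
  # presences blanket the region: error
  all_pres <- expand.grid(row = 1:10, col = 1:10)
  all_pres$region <- "A"
  expect_error(eligible_cells_cellexcl(all_pres, g, st, "A"), "no eligible")
})

test_that("buffer exclusion matches geometry: zero radius, 1.5-cell radius, total cover", {
  g <- sdm_grid(9, 9, 100, region = matrix("A", 9, 9))
  st <- simulate_predictors(g, 2, smoothness = 1, seed = 2)
  rec <- function(x, y, cu) data.frame(longitude = x, latitude = y,
                                       coordinate_uncertainty_m = cu,
                                       region = "A")
  # CU = 0 at a cell interior point: only the containing cell is excluded
  e0 <- eligible_cells_bufferexcl(rec(433, 433, 0), g, st, "A")
  expect_length(setdiff(seq_len(81), e0), 1)
  expect_false(cell_id(g, 5L, 5L) %in% e0)
  # CU = 1.5 cells at a cell center: full 3x3 plus edge-adjacent cells of the
  # 5x5 ring whose nearest point is within 150 m; corners of the 5x5 ring
  # (nearest point sqrt(50^2+50^2) + cell = ~158 m away) stay eligible
  ctr <- xy_from_cell(g, 5, 5)
  e1 <- eligible_cells_bufferexcl(rec(ctr$x, ctr$y, 150), g, st, "A")
  excluded <- setdiff(seq_len(81), e1)
  manual <- oracle_buffer_excluded(
    data.frame(longitude = ctr$x, latitude = ctr$y,
               coordinate_uncertainty_m = 150), g)
  expect_setequal(excluded, which(manual))
  expect_length(excluded, 13)  # 3x3 plus the 4 edge-center cells
  # radius beyond the grid diagonal: nothing eligible
  expect_error(eligible_cells_bufferexcl(rec(ctr$x, ctr$y, 5000), g, st, "A"),
               "no eligible")
  # CU must be present and finite
  expect_error(eligible_cells_bufferexcl(rec(433, 433, NA), g, st, "A"),
               "finite")
})

test_that("PA draws hit 1:1 totals, avoid excluded cells, and reproduce under a seed", {
  prep <- fixture_prepared()
  n_per <- c(A = sum(prep$presences$region == "A"),
             B = sum(prep$presences$region == "B"))
  sets <- draw_pa_sets(prep$eligible, n_per, n_sets = 10, base_seed = 77,
                       grid = prep$land$grid)
  expect_length(sets, 10)
  for (s in sets) {
    expect_equal(sum(s$region == "A"), n_per[["A"]])
    expect_equal(sum(s$region == "B"), n_per[["B"]])
    ids <- cell_id(prep$land$grid, s$row, s$col)
    expect_false(any(duplicated(paste(ids, s$region))))
    # no PA cell may be an excluded cell
    expect_true(all(ids[s$region == "A"] %in% prep$eligible$A))
    expect_true(all(ids[s$region == "B"] %in% prep$eligible$B))
  }
  sets2 <- draw_pa_sets(prep$eligible, n_per, n_sets = 10, base_seed = 77,
                        grid = prep$land$grid)
  expect_identical(sets, sets2)
  expect_false(identical(sets[[1]]$row, sets[[2]]$row))
  expect_error(draw_pa_sets(list(A = 1:5), c(A = 10), 2, 1, prep$land$grid),
               "requested")
})

test_that("single-point draws are uniform over the eligible pool", {
  g <- sdm_grid(4, 5, 100, region = matrix("A", 4, 5))
  st <- simulate_predictors(g, 2, smoothness = 1, seed = 3)
  elig <- list(A = eligible_cells_cellexcl(
    data.frame(row = integer(0), col = integer(0), region = character(0)),
    g, st, "A"))
  k <- length(elig$A)
  draws <- draw_pa_sets(elig, c(A = 1L), n_sets = 2000, base_seed = 5, grid = g)
  picks <- vapply(draws, function(d) cell_id(g, d$row, d$col), numeric(1))
  freq <- table(factor(picks, levels = elig$A)) / 2000
  sd_bin <- sqrt((1 / k) * (1 - 1 / k) / 2000)
  expect_true(all(abs(freq - 1 / k) <= 5 * sd_bin))
})
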