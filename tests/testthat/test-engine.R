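test_that("model frames have one row per presence and PA cell with full predictors", {
  prep <- fixture_prepared()
  fr <- prep$frame
  expect_equal(nrow(fr), 2 * nrow(prep$presences))
  for (reg in c("A", "B")) {
    expect_equal(sum(fr$region == reg & fr$class == 1),
                 sum(fr$region == reg & fr$class == 0))
  }
  expect_false(anyNA(fr))
  expect_setequal(frame_predictors(fr), names(prep$stack$layers))
  # frames from different PA sets differ only in class-0 rows
  fr2 <- assemble_frame(prep$presences, prep$pa_sets[[2]], prep$stack)
  expect_identical(fr[fr$class == 1, ], fr2[fr2$class == 1, ])
  expect_false(identical(fr[fr$class == 0, ], fr2[fr2$class == 0, ]))
})

test_that("stratified splits honor the 70/30 fraction within every stratum", {
  prep <- fixture_prepared()
  fr <- prep$frame
  plans <- split_train_valid(fr, train_frac = 0.7, rep_seeds = c(11, 12, 13))
  expect_length(plans, 3)
  for (p in plans) {
    expect_setequal(c(p$train, p$valid), seq_len(nrow(fr)))
    expect_length(intersect(p$train, p$valid), 0)
    for (reg in c("A", "B")) {
      for (cl in 0:1) {
        idx <- which(fr$region == reg & fr$class == cl)
        got <- length(intersect(p$train, idx))
        expect_lte(abs(got - 0.7 * length(idx)), 1)
      }
    }
  }
  plans2 <- split_train_valid(fr, train_frac = 0.7, rep_seeds = c(11, 12, 13))
  expect_identical(plans, plans2)
  # a 100-row single-stratum frame splits exactly 70/30
  fr100 <- data.frame(row = 1:100, col = 1, region = "A",
                      class = rep(1:0, 50), x = rnorm(100))
  p100 <- split_train_valid(fr100, rep_seeds = 1)[[1]]
  expect_equal(length(p100$train), 70)
})

test_that("registered algorithms separate a separable frame and reproduce under a seed", {
  fr <- toy_frame()
  for (alg in c("RF", "CTA", "ANN", "GBM")) {
    hyper <- if (alg == "GBM") list(nrounds = 50, eta = 0.3) else list()
    fit <- fit_sdm(alg, fr, hyperparams = hyper, seed = 5)
    sc <- predict_sdm(fit, fr)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_equal(optimal_tss(fr$class, sc)$tss, 1,
                 info = alg, tolerance = 1e-12)
    fit2 <- fit_sdm(alg, fr, hyperparams = hyper, seed = 5)
    expect_equal(predict_sdm(fit2, fr), sc, tolerance = 1e-12, info = alg)
  }
  expect_error(fit_sdm("NOPE", fr), "unknown algorithm")
  fr1 <- fr; fr1$class <- 1L
  expect_error(fit_sdm("RF", fr1), "both classes")
})

test_that("held-out skill vanishes when class labels are shuffled", {
  prep <- fixture_prepared()
  fr <- prep$frame[prep$frame$region == "A", ]
  tss <- vapply(1:10, function(s) {
    with_seed(1000 + s, fr$class <- sample(fr$class))
    plan <- split_train_valid(fr, rep_seeds = s)[[1]]
    fit <- fit_sdm("RF", fr[plan$train, ], list(ntree = 200), seed = s)
    optimal_tss(fr$class[plan$valid], predict_sdm(fit, fr[plan$valid, ]))$tss
  }, numeric(1))
  expect_lt(mean(abs(tss)), 0.2)
})

test_that("frame and stack prediction agree and NA cells propagate", {
  prep <- fixture_prepared()
  fit <- fit_sdm("RF", prep$frame, list(ntree = 100), seed = 9)
  map <- predict_sdm(fit, prep$stack)
  # NA exactly off the land mask
  expect_identical(is.na(map), !complete_cells(prep$stack))
  # scores at frame cells equal frame-path scores
  sc_frame <- predict_sdm(fit, prep$frame)
  sc_map <- map[cbind(prep$frame$row, prep$frame$col)]
  expect_equal(sc_map, sc_frame, tolerance = 1e-12)
  expect_error(predict_sdm(fit, prep$frame[, 1:5]), "missing predictor")
})

test_that("strong synthetic signal yields high held-out skill for RF", {
  prep <- fixture_prepared()
  plans <- split_train_valid(prep$frame, rep_seeds = 301:303)
  tss <- vapply(plans, function(p) {
    fit <- fit_sdm("RF", prep$frame[p$train, ], list(ntree = 300),
                   seed = p$seed)
    sc <- predict_sdm(fit, prep$frame[p$valid, ])
    optimal_tss(prep$frame$class[p$valid], sc)$tss
  }, numeric(1))
  expect_gte(median(tss), 0.6)
})
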