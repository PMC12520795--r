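# A deterministic pass-through "model" for importance arithmetic: its
# prediction is exactly one predictor column, clamped to [0, 1].
register_ident <- function(column) {
  register_algorithm(
    "IDENT",
    fit = function(x, y, hyper, seed) hyper$column,
    predict = function(object, x) pmin(pmax(x[[object]], 0), 1),
    defaults = list(column = column)
  )
}

test_that("permutation importance is 0 for unused and ~1 for identity predictors", {
  register_ident("a")
  with_seed(51, {
    fr <- data.frame(row = 1:10000, col = 1, region = "A",
                     class = rep(0:1, 5000),
                     a = runif(10000), b = runif(10000))
  })
  fit <- fit_sdm("IDENT", fr, seed = 1)
  # shuffling an unused column leaves predictions identical: importance 0
  expect_identical(as.numeric(permutation_importance(fit, fr, "b", seed = 2)), 0)
  # shuffling the identity column decorrelates predictions: importance ~ 1
  imp_a <- permutation_importance(fit, fr, "a", seed = 2)
  expect_lt(abs(as.numeric(imp_a) - 1), 0.02)
  # determinism under the seed
  expect_identical(as.numeric(permutation_importance(fit, fr, "a", seed = 2)),
                   as.numeric(imp_a))
  # a constant predictor column cannot matter
  fr$const <- 0.7
  expect_identical(as.numeric(permutation_importance(fit, fr, "const", seed = 3)), 0)
  # constant reference predictions are flagged with importance 0
  fitb <- fit_sdm("IDENT", fr, hyperparams = list(column = "const"), seed = 1)
  impc <- permutation_importance(fitb, fr, "a", seed = 1)
  expect_identical(as.numeric(impc), 0)
  expect_true(attr(impc, "flagged"))
})

test_that("scaled importances sum to one within run x region, zeros flagged", {
  tbl <- data.frame(
    run = rep(c("r1", "r2"), each = 3),
    region = "A",
    predictor = rep(c("p1", "p2", "p3"), 2),
    raw = c(2, 1, 1, 0, 0, 0)
  )
  out <- scale_importances(tbl)
  expect_equal(out$scaled[1:3], c(0.5, 0.25, 0.25))
  expect_false(any(out$flagged[1:3]))
  expect_equal(out$scaled[4:6], c(0, 0, 0))
  expect_true(all(out$flagged[4:6]))
  # normalized input passes through unchanged
  tbl2 <- tbl[1:3, ]; tbl2$raw <- c(0.5, 0.25, 0.25)
  expect_equal(scale_importances(tbl2)$scaled, tbl2$raw)
  tbl3 <- tbl; tbl3$raw[1] <- -1
  expect_error(scale_importances(tbl3), "non-negative")
  # property: random tables always renormalize to 1 per group
  with_seed(52, {
    big <- expand.grid(run = paste0("r", 1:6), region = c("A", "B"),
                       predictor = paste0("p", 1:5),
                       stringsAsFactors = FALSE)
    big$raw <- rexp(nrow(big))
  })
  sums <- tapply(scale_importances(big)$scaled,
                 interaction(big$run, big$region), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("beta GLMM recovers known coefficients against an independent optimizer", {
  d <- simulate_importance_data(n_runs = 3, seed = 99)  # < 5 runs: no RE
  fit <- fit_beta_glmm(d)
  expect_false(fit$random_intercept)
  expect_true(fit$converged)
  # independent oracle: direct ML fit of the same beta likelihood
  y <- fit$data$y
  Xm <- model.matrix(~ region * predictor, fit$data)
  nll <- function(par) {
    k <- ncol(Xm)
    mu <- plogis(Xm %*% par[1:k])
    phi <- exp(Xm %*% par[(k + 1):(2 * k)])
    -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  opt <- stats::nlminb(rep(0, 2 * ncol(Xm)), nll,
                       control = list(iter.max = 2000, eval.max = 4000))
  expect_equal(unname(glmmTMB::fixef(fit$model)$cond),
               opt$par[1:ncol(Xm)], tolerance = 1e-3)
  expect_equal(unname(glmmTMB::fixef(fit$model)$disp),
               opt$par[(ncol(Xm) + 1):(2 * ncol(Xm))], tolerance = 1e-3)
})

test_that("all-0.5 outcomes give a near-zero logit intercept", {
  d <- expand.grid(run = sprintf("r%d", 1:6), region = c("A", "B"),
                   predictor = c("p1", "p2"), stringsAsFactors = FALSE)
  d$scaled <- 0.5
  fit <- suppressWarnings(fit_beta_glmm(d))
  expect_lt(abs(glmmTMB::fixef(fit$model)$cond[["(Intercept)"]]), 0.05)
})

test_that("region contrasts carry the fixed sign convention and flip under relabeling", {
  d <- simulate_importance_data(n_runs = 30, region_shift = 1, seed = 7)
  fit <- fit_beta_glmm(d)
  expect_true(fit$converged)
  ctr <- region_contrasts(fit, invasive = "A")
  expect_setequal(ctr$predictor, c("p1", "p2", "p3"))
  # p1 is more important in B (native): positive estimate near +1
  p1 <- ctr[ctr$predictor == "p1", ]
  expect_gt(p1$estimate, 0)
  expect_lt(abs(p1$estimate - 1), 2.5 * p1$se + 0.2)
  expect_equal(ctr$z, ctr$estimate / ctr$se)
  # relabel the regions: estimates flip sign, |z| unchanged
  d2 <- d; d2$region <- ifelse(d$region == "A", "B", "A")
  ctr2 <- region_contrasts(fit_beta_glmm(d2), invasive = "B")
  m <- match(ctr$predictor, ctr2$predictor)
  expect_equal(ctr2$estimate[m], ctr$estimate, tolerance = 1e-4)
  expect_equal(abs(ctr2$z[m]), abs(ctr$z), tolerance = 1e-3)
  # declaring the other region invasive reverses the convention
  ctr3 <- region_contrasts(fit, invasive = "B")
  expect_equal(ctr3$estimate, -ctr$estimate, tolerance = 1e-9)
})
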