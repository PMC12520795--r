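# Permutation variable importance and the beta-regression mixed model that
# contrasts scaled importances between regions.

#' Permutation importance of one predictor
#'
#' The predictor column is shuffled `n_shuffles` times; after each shuffle
#' the model is re-predicted and the Pearson correlation with the reference
#' predictions computed. Raw importance is the mean of `1 - correlation`
#' (range `[0, 2]`). A shuffle producing constant predictions contributes a
#' correlation of 1 (importance 0); if the reference predictions themselves
#' are constant the importance is 0 and the result is flagged.
#'
#' @param fit An `sdm_fit` (or `sdm_ensemble`).
#' @param rows Data.frame of predictor rows (>= 3 rows).
#' @param predictor Column name to shuffle.
#' @param n_shuffles Number of shuffles, default 9.
#' @param seed Integer seed.
#' @return Raw importance (numeric scalar); attribute `"flagged"` is TRUE
#'   when reference predictions were constant.
#' @export
permutation_importance <- function(fit, rows, predictor, n_shuffles = 9,
                                   seed = 1) {
  if (nrow(rows) < 3) stopf("need at least 3 rows")
  if (!predictor %in% names(rows)) stopf("predictor '%s' absent", predictor)
  pred_fun <- if (inherits(fit, "sdm_ensemble")) predict_ensemble else predict_sdm
  ref <- pred_fun(fit, rows)
  if (stats::sd(ref) == 0) {
    return(structure(0, flagged = TRUE))
  }
  with_seed(seed, {
    cors <- vapply(seq_len(n_shuffles), function(s) {
      shuffled <- rows
      shuffled[[predictor]] <- sample(shuffled[[predictor]])
      p <- pred_fun(fit, shuffled)
      if (stats::sd(p) == 0) 1 else stats::cor(ref, p)
    }, numeric(1))
    structure(mean(1 - cors), flagged = FALSE)
  })
}

#' Build a per-run, per-region raw importance table
#'
#' Computes [permutation_importance()] for every fitted run, region and
#' predictor, on the supplied evaluation rows (typically the validation
#' partition of the first pseudo-absence set).
#'
#' @param fits Named list of `sdm_fit` objects (names become run ids).
#' @param rows Model-frame rows with `region` plus predictor columns.
#' @param predictors Predictor names; default all frame predictors.
#' @param n_shuffles,seed Passed to [permutation_importance()].
#' @return Data.frame `run`, `region`, `predictor`, `raw`.
#' @export
importance_table <- function(fits, rows, predictors = NULL, n_shuffles = 9,
                             seed = 1) {
  if (is.null(predictors)) predictors <- frame_predictors(rows)
  regions <- sort(unique(rows$region))
  grid <- expand.grid(run = names(fits), region = regions,
                      predictor = predictors, stringsAsFactors = FALSE)
  grid$raw <- mapply(function(run, region, predictor) {
    sub <- rows[rows$region == region, , drop = FALSE]
    permutation_importance(fits[[run]], sub, predictor,
                           n_shuffles = n_shuffles,
                           seed = seed + fit_seed(0, predictor, 1, 1) %% 10000)
  }, grid$run, grid$region, grid$predictor)
  grid
}

#' Scale raw importances to sum to one within run x region
#'
#' All-zero groups pass through as zeros and are flagged in the `flagged`
#' column rather than producing `NaN`.
#'
#' @param raw_table Data.frame with `run`, `region`, `predictor`, `raw`
#'   (all `raw >= 0`).
#' @return The table with columns `scaled` and `flagged` added.
#' @export
scale_importances <- function(raw_table) {
  if (any(raw_table$raw < 0)) stopf("raw importances must be non-negative")
  key <- interaction(raw_table$run, raw_table$region, drop = TRUE)
  totals <- as.vector(tapply(raw_table$raw, key, sum)[key])
  zero <- totals == 0
  raw_table$scaled <- ifelse(zero, 0, raw_table$raw / totals)
  raw_table$flagged <- as.vector(zero)
  raw_table
}

#' Fit the beta-regression mixed model over scaled importances
#'
#' Outcome: scaled importance in `[0, 1]`, squeezed off the boundary by
#' `y' = (y (n - 1) + 0.5) / n`. Mean model (logit link):
#' `region * predictor` fixed effects plus a run-level random intercept;
#' dispersion model (log link): `region * predictor`. With fewer than
#' `min_runs` runs the random intercept is dropped (its variance is not
#' identifiable) and the fit is flagged accordingly.
#'
#' @param imp_table Output of [scale_importances()] (needs `run`, `region`,
#'   `predictor`, `scaled`).
#' @param min_runs Minimum runs for the random intercept, default 5.
#' @return An object of class `sdm_betareg`: list with `model` (glmmTMB
#'   fit), `converged`, `random_intercept`, `data`.
#' @export
fit_beta_glmm <- function(imp_table, min_runs = 5) {
  y <- imp_table$scaled
  if (any(y < 0 | y > 1)) stopf("outcomes must lie in [0, 1]")
  n <- length(y)
  d <- data.frame(
    y = (y * (n - 1) + 0.5) / n,
    region = factor(imp_table$region),
    predictor = factor(imp_table$predictor),
    run = factor(imp_table$run)
  )
  use_re <- nlevels(d$run) >= min_runs
  form <- if (use_re) y ~ region * predictor + (1 | run) else y ~ region * predictor
  fit <- glmmTMB::glmmTMB(
    form, dispformula = ~ region * predictor,
    family = glmmTMB::beta_family(), data = d
  )
  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  structure(list(model = fit, converged = conv, random_intercept = use_re,
                 data = d),
            class = "sdm_betareg")
}

#' @export
print.sdm_betareg <- function(x, ...) {
  cat(sprintf("<sdm_betareg> %d obs, %d predictors, %s random intercept; converged: %s\n",
              nrow(x$data), nlevels(x$data$predictor),
              if (x$random_intercept) "with" else "no", x$converged))
  invisible(x)
}

#' Region contrasts of estimated marginal importance
#'
#' Per predictor, the difference of estimated marginal means between the
#' two regions on the logit-link scale, with delta-method standard errors.
#' The sign convention is `native - invasive`: negative estimates mean the
#' predictor is more influential in the invasive region.
#'
#' @param fit An `sdm_betareg` from [fit_beta_glmm()].
#' @param invasive Label of the invasive region, default `"A"`.
#' @param adjust P-value adjustment: `"none"` (default, raw p-values) or
#'   `"holm"`.
#' @return Data.frame `predictor`, `estimate`, `se`, `z`, `p`.
#' @export
region_contrasts <- function(fit, invasive = "A", adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (!fit$converged) stopf("cannot form contrasts from a non-converged fit")
  regions <- levels(fit$data$region)
  if (length(regions) != 2) stopf("contrasts need exactly two regions")
  if (!invasive %in% regions) stopf("unknown invasive region '%s'", invasive)
  emm <- emmeans::emmeans(fit$model, ~ region | predictor)
  ctr <- summary(emmeans::contrast(emm, method = "pairwise"), adjust = "none")
  # pairwise is first level minus second; flip where needed so the reported
  # estimate is native minus invasive
  sign <- if (regions[1] == invasive) 1 else -1
  est <- -sign * ctr$estimate  # native - invasive
  z <- est / ctr$SE
  p <- 2 * stats::pnorm(-abs(z))
  if (adjust == "holm") p <- stats::p.adjust(p, method = "holm")
  data.frame(predictor = as.character(ctr$predictor), estimate = est,
             se = ctr$SE, z = z, p = p, stringsAsFactors = FALSE)
}
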