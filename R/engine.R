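# Model frames, repeated stratified splits, the algorithm registry, fitting
# and prediction. All stochastic fits take an explicit seed.

#' Assemble a presence/pseudo-absence model frame
#'
#' One row per presence cell (class 1) and per pseudo-absence cell (class 0);
#' the predictor vector is every layer of the (pruned, standardized) stack,
#' including effort.
#'
#' @param presences A `presence_cells` object.
#' @param pa_set One pseudo-absence set from [draw_pa_sets()].
#' @param stack Pruned, standardized [sdm_stack] with an effort layer.
#' @return Data.frame with columns `row`, `col`, `region`, `class` and one
#'   column per layer.
#' @export
assemble_frame <- function(presences, pa_set, stack) {
  cells <- rbind(
    data.frame(row = presences$row, col = presences$col,
               region = presences$region, class = 1L),
    data.frame(row = pa_set$row, col = pa_set$col,
               region = pa_set$region, class = 0L)
  )
  preds <- extract_cells(stack, cells)
  if (anyNA(preds)) stopf("model frame has NA predictors; check cell validity")
  cbind(cells, preds)
}

frame_predictors <- function(frame) {
  setdiff(names(frame), c("row", "col", "region", "class"))
}

#' Repeated stratified 70/30 train/validation splits
#'
#' Splits are stratified by region x class, so training fractions hold
#' within every stratum to +/- 1 row; each repetition uses its own seed.
#'
#' @param frame A model frame from [assemble_frame()].
#' @param train_frac Training fraction, default 0.7.
#' @param rep_seeds Integer vector, one seed per repetition.
#' @return List of plans: each a list with `rep_id`, `seed`, `train`,
#'   `valid` (integer row indices into `frame`).
#' @export
split_train_valid <- function(frame, train_frac = 0.7, rep_seeds) {
  strata <- interaction(frame$region, frame$class, drop = TRUE)
  if (any(table(strata) < 2)) stopf("every region x class stratum needs >= 2 rows")
  lapply(seq_along(rep_seeds), function(r) {
    with_seed(rep_seeds[r], {
      train <- integer(0)
      for (s in levels(strata)) {
        idx <- which(strata == s)
        n_tr <- max(1L, min(length(idx) - 1L, round(length(idx) * train_frac)))
        train <- c(train, idx[sample.int(length(idx), n_tr)])
      }
      train <- sort(train)
      list(rep_id = r, seed = rep_seeds[r], train = train,
           valid = setdiff(seq_len(nrow(frame)), train))
    })
  })
}

# --- algorithm registry -----------------------------------------------------

.sdm_registry <- new.env(parent = emptyenv())

#' Register a modeling algorithm
#'
#' An algorithm is a pair of functions behind a common contract:
#' `fit(x, y, hyper, seed)` returns an opaque fitted object and
#' `predict(object, x)` returns scores in `[0, 1]` for a predictor
#' data.frame `x`. Registration replaces any existing entry of the same id.
#'
#' @param id Algorithm id (e.g. `"RF"`).
#' @param fit,predict Functions as described above.
#' @param defaults Named list of default hyperparameters.
#' @return `id`, invisibly.
#' @export
register_algorithm <- function(id, fit, predict, defaults = list()) {
  assign(id, list(fit = fit, predict = predict, defaults = defaults),
         envir = .sdm_registry)
  invisible(id)
}

#' List registered algorithm ids
#' @return Character vector.
#' @export
list_algorithms <- function() sort(ls(.sdm_registry))

register_builtin_algorithms <- function() {
  register_algorithm(
    "RF",
    fit = function(x, y, hyper, seed) {
      with_seed(seed, randomForest::randomForest(
        x = x, y = factor(y, levels = c(0, 1)),
        ntree = hyper$ntree, mtry = max(1L, floor(sqrt(ncol(x))))
      ))
    },
    predict = function(object, x) {
      unname(stats::predict(object, newdata = x, type = "prob")[, "1"])
    },
    defaults = list(ntree = 500)
  )
  register_algorithm(
    "CTA",
    fit = function(x, y, hyper, seed) {
      d <- cbind(.class = factor(y, levels = c(0, 1)), x)
      with_seed(seed, {
        tree <- rpart::rpart(.class ~ ., data = d, method = "class",
                             control = rpart::rpart.control(
                               cp = hyper$cp, xval = hyper$xval))
        # cost-complexity pruning at the cp minimizing internal CV error
        cptab <- tree$cptable
        rpart::prune(tree, cp = cptab[which.min(cptab[, "xerror"]), "CP"])
      })
    },
    predict = function(object, x) {
      unname(stats::predict(object, newdata = x, type = "prob")[, "1"])
    },
    defaults = list(cp = 0.001, xval = 10)
  )
  register_algorithm(
    "ANN",
    fit = function(x, y, hyper, seed) {
      with_seed(seed, nnet::nnet(
        x = as.matrix(x), y = y, size = hyper$size, decay = hyper$decay,
        maxit = hyper$maxit, entropy = TRUE, trace = FALSE
      ))
    },
    predict = function(object, x) {
      as.vector(stats::predict(object, newdata = as.matrix(x)))
    },
    defaults = list(size = 8, decay = 0.01, maxit = 500)
  )
  # Classic gradient boosting machine settings (shallow trees, slow
  # learning rate, many stages) on the xgboost engine.
  xgb_fit <- function(x, y, hyper, seed) {
    params <- list(objective = "binary:logistic", max_depth = hyper$max_depth,
                   eta = hyper$eta, nthread = 1, seed = seed)
    xgboost::xgb.train(
      params = params,
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
      nrounds = hyper$nrounds, verbose = 0
    )
  }
  xgb_predict <- function(object, x) {
    as.vector(stats::predict(object, newdata = xgboost::xgb.DMatrix(as.matrix(x))))
  }
  register_algorithm("GBM", fit = xgb_fit, predict = xgb_predict,
                     defaults = list(nrounds = 1000, max_depth = 3, eta = 0.01))
  register_algorithm("XGBOOST", fit = xgb_fit, predict = xgb_predict,
                     defaults = list(nrounds = 100, max_depth = 6, eta = 0.3))
  # Penalized logistic approximation to maximum entropy on background-
  # contrasted data; fidelity to the original software is a non-goal.
  register_algorithm(
    "MAXENT",
    fit = function(x, y, hyper, seed) {
      if (!requireNamespace("glmnet", quietly = TRUE)) {
        stopf("algorithm 'MAXENT' needs the glmnet package")
      }
      with_seed(seed, {
        foldid <- sample(rep_len(seq_len(hyper$nfolds), length(y)))
        glmnet::cv.glmnet(as.matrix(x), y, family = "binomial",
                          alpha = hyper$alpha, foldid = foldid)
      })
    },
    predict = function(object, x) {
      as.vector(stats::predict(object, newx = as.matrix(x),
                               s = "lambda.min", type = "response"))
    },
    defaults = list(alpha = 1, nfolds = 5)
  )
}

#' Fit one registered algorithm on training rows
#'
#' @param algorithm_id Registered id (see [list_algorithms()]).
#' @param train Training rows of a model frame (both classes present).
#' @param hyperparams Named list overriding the algorithm's defaults.
#' @param seed Integer seed for any stochastic element of the fit.
#' @return An object of class `sdm_fit`.
#' @export
fit_sdm <- function(algorithm_id, train, hyperparams = list(), seed = 1) {
  if (!exists(algorithm_id, envir = .sdm_registry)) {
    stopf("unknown algorithm '%s'", algorithm_id)
  }
  if (length(unique(train$class)) < 2) {
    stopf("training data must contain both classes")
  }
  alg <- get(algorithm_id, envir = .sdm_registry)
  hyper <- utils::modifyList(alg$defaults, hyperparams)
  preds <- frame_predictors(train)
  obj <- alg$fit(train[preds], train$class, hyper, seed)
  structure(
    list(algorithm = algorithm_id, predictors = preds, object = obj,
         hyper = hyper, seed = seed),
    class = "sdm_fit"
  )
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> %s on %d predictors (seed %d)\n",
              x$algorithm, length(x$predictors), x$seed))
  invisible(x)
}

#' Predict suitability scores from a fitted model
#'
#' For a data.frame, returns one score per row; for an [sdm_stack], returns
#' a matrix of per-cell scores with `NA` wherever any predictor is `NA`.
#' Scores are clamped into `[0, 1]`.
#'
#' @param fit An `sdm_fit`.
#' @param newdata Data.frame of predictors (or a model frame) or an
#'   [sdm_stack].
#' @return Numeric vector or matrix of scores.
#' @export
predict_sdm <- function(fit, newdata) {
  alg <- get(fit$algorithm, envir = .sdm_registry)
  if (inherits(newdata, "sdm_stack")) {
    missing <- setdiff(fit$predictors, names(newdata$layers))
    if (length(missing)) stopf("stack lacks predictor: %s", paste(missing, collapse = ", "))
    ok <- complete_cells(newdata)
    idx <- which(ok)
    out <- matrix(NA_real_, newdata$grid$n_rows, newdata$grid$n_cols)
    if (length(idx)) {
      x <- as.data.frame(lapply(newdata$layers[fit$predictors], function(m) m[idx]),
                         optional = TRUE)
      out[idx] <- pmin(pmax(alg$predict(fit$object, x), 0), 1)
    }
    return(out)
  }
  missing <- setdiff(fit$predictors, names(newdata))
  if (length(missing)) stopf("missing predictor column: %s", paste(missing, collapse = ", "))
  pmin(pmax(alg$predict(fit$object, newdata[fit$predictors]), 0), 1)
}

# Deterministic per-fit seed from (algorithm, pa_set, rep) and a base seed.
fit_seed <- function(base_seed, algorithm, pa_set, rep) {
  h <- sum(utf8ToInt(algorithm) * seq_along(utf8ToInt(algorithm)))
  as.integer((as.numeric(base_seed) * 131 + h * 1009 +
                pa_set * 97 + rep * 13) %% 2147483647)
}
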