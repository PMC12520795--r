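# Ensemble schemes over member predictions: unweighted mean (EMmean),
# committee averaging of binary votes at each member's optimal threshold
# (EMca), and TSS-weighted mean (EMwmean).

#' Combine member scores with an ensemble scheme
#'
#' `scores` holds one column per member, aligned on rows (observations or
#' cells). EMmean is the row mean; EMca the row mean of `1{score >=
#' member threshold}`; EMwmean the weighted row mean with weights
#' proportional to member TSS after flooring negatives to zero.
#'
#' @param scores Numeric matrix, rows = observations, columns = members.
#' @param scheme One of `"EMmean"`, `"EMca"`, `"EMwmean"`.
#' @param tss Member TSS values (EMwmean).
#' @param thresholds Member TSS-optimal thresholds (EMca).
#' @return Numeric vector of ensemble scores in `[0, 1]`.
#' @export
combine_scores <- function(scores, scheme = c("EMmean", "EMca", "EMwmean"),
                           tss = NULL, thresholds = NULL) {
  scheme <- match.arg(scheme)
  scores <- as.matrix(scores)
  if (ncol(scores) < 1) stopf("ensemble needs at least one member")
  switch(scheme,
    EMmean = rowMeans(scores),
    EMca = {
      if (is.null(thresholds) || length(thresholds) != ncol(scores)) {
        stopf("EMca needs one threshold per member")
      }
      votes <- sweep(scores, 2, thresholds, `>=`)
      rowMeans(votes)
    },
    EMwmean = {
      if (is.null(tss) || length(tss) != ncol(scores)) {
        stopf("EMwmean needs one TSS value per member")
      }
      w <- pmax(tss, 0)
      if (sum(w) == 0) stopf("EMwmean degenerate: all member weights are zero")
      as.vector(scores %*% (w / sum(w)))
    }
  )
}

#' Lazily-evaluated ensemble over fitted members
#'
#' Wraps fitted models plus a scheme into a single score function usable on
#' frames and stacks; member predictions are computed on demand, so the
#' output is identical to eager computation by construction.
#'
#' @param fits List of `sdm_fit` members.
#' @param scheme Ensemble scheme (see [combine_scores()]).
#' @param tss,thresholds Member statistics as required by the scheme.
#' @param id Ensemble id for reporting.
#' @return An object of class `sdm_ensemble`.
#' @export
make_ensemble <- function(fits, scheme = "EMmean", tss = NULL,
                          thresholds = NULL, id = scheme) {
  if (!length(fits)) stopf("ensemble needs at least one member")
  structure(list(fits = fits, scheme = scheme, tss = tss,
                 thresholds = thresholds, id = id),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> %s: %s over %d members\n",
              x$id, x$scheme, length(x$fits)))
  invisible(x)
}

#' Predict from an ensemble
#'
#' @param ensemble An `sdm_ensemble`.
#' @param newdata Predictor data.frame or [sdm_stack].
#' @return Scores as in [predict_sdm()] (vector for frames, matrix for
#'   stacks).
#' @export
predict_ensemble <- function(ensemble, newdata) {
  member_scores <- lapply(ensemble$fits, predict_sdm, newdata = newdata)
  if (inherits(newdata, "sdm_stack")) {
    flat <- sapply(member_scores, as.vector)
    ok <- stats::complete.cases(flat)
    out <- rep(NA_real_, nrow(flat))
    if (any(ok)) {
      out[ok] <- combine_scores(flat[ok, , drop = FALSE], ensemble$scheme,
                                tss = ensemble$tss,
                                thresholds = ensemble$thresholds)
    }
    matrix(out, newdata$grid$n_rows, newdata$grid$n_cols)
  } else {
    combine_scores(do.call(cbind, member_scores), ensemble$scheme,
                   tss = ensemble$tss, thresholds = ensemble$thresholds)
  }
}
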