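# Discrimination metrics: max-TSS with its optimal threshold, the continuous
# Boyce index, confusion summaries, and final-model selection. Metrics are
# always reported per region; pooled values are additional, never a
# replacement.

#' Maximize the True Skill Statistic over thresholds
#'
#' Candidate thresholds are the midpoints of consecutive sorted unique
#' scores plus 0 and 1; a score is classified positive iff it is `>=` the
#' threshold. Ties in maximal TSS are broken toward the larger threshold.
#'
#' @param obs Binary labels (0/1).
#' @param scores Finite numeric scores.
#' @return List with `tss`, `threshold`, `sensitivity`, `specificity`.
#' @export
optimal_tss <- function(obs, scores) {
  obs <- as.integer(obs)
  if (length(unique(obs)) < 2) stopf("both classes must be present")
  if (any(!is.finite(scores))) stopf("scores must be finite")
  u <- sort(unique(scores))
  cand <- unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1))
  n_pos <- sum(obs == 1L)
  n_neg <- sum(obs == 0L)
  ord <- order(scores)
  s_sorted <- scores[ord]
  pos_sorted <- obs[ord] == 1L
  # positives / negatives with score >= t, for all candidates at once
  tail_pos <- rev(cumsum(rev(pos_sorted)))
  tail_neg <- rev(cumsum(rev(!pos_sorted)))
  first_ge <- length(s_sorted) - findInterval(cand, s_sorted,
                                              left.open = TRUE)
  tp <- ifelse(first_ge == 0, 0, tail_pos[length(s_sorted) - first_ge + 1])
  fp <- ifelse(first_ge == 0, 0, tail_neg[length(s_sorted) - first_ge + 1])
  sens <- tp / n_pos
  spec <- (n_neg - fp) / n_neg
  tss <- sens + spec - 1
  hit <- which(tss == max(tss))
  best <- hit[which.max(cand[hit])]  # ties toward the larger threshold
  list(tss = tss[best], threshold = cand[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Continuous Boyce index
#'
#' Over `n_windows` overlapping windows of width `window_width` (as a
#' fraction of the combined score range), the predicted-to-expected ratio
#' `P/E` is the fraction of presence scores in the window divided by the
#' fraction of background scores in it. Windows with zero background mass
#' are skipped; the index is the Spearman rank correlation between `P/E`
#' and the window midpoint (tied ranks averaged).
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @param window_width Window width as a fraction of the score range,
#'   default 0.1.
#' @param n_windows Number of windows, default 101.
#' @return Boyce index in `[-1, 1]`.
#' @export
boyce_index <- function(presence_scores, background_scores,
                        window_width = 0.1, n_windows = 101) {
  all_scores <- c(presence_scores, background_scores)
  lo <- min(all_scores)
  hi <- max(all_scores)
  if (hi <= lo) stopf("degenerate score range")
  w <- window_width * (hi - lo)
  mids <- seq(lo + w / 2, hi - w / 2, length.out = n_windows)
  pe <- vapply(mids, function(m) {
    p <- mean(presence_scores >= m - w / 2 & presence_scores <= m + w / 2)
    e <- mean(background_scores >= m - w / 2 & background_scores <= m + w / 2)
    if (e == 0) NA_real_ else p / e
  }, numeric(1))
  ok <- !is.na(pe)
  if (sum(ok) < 2) stopf("fewer than 2 windows with background mass")
  if (stats::sd(pe[ok]) == 0) return(0)  # flat P/E: no association
  stats::cor(pe[ok], mids[ok], method = "spearman")
}

#' Confusion-matrix summary at a threshold
#'
#' Positive classification iff `score >= threshold`. Cohen's kappa is
#' `(po - pe) / (1 - pe)`, defined as 0 when chance agreement `pe` is 1.
#'
#' @param obs Binary labels (0/1).
#' @param scores Numeric scores.
#' @param threshold Classification threshold.
#' @return List with `accuracy`, `sensitivity`, `specificity`, `kappa`,
#'   `balanced_accuracy`, `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_summary <- function(obs, scores, threshold) {
  obs <- as.integer(obs)
  if (length(unique(obs)) < 2) stopf("both classes must be present")
  pos <- scores >= threshold
  tp <- sum(pos & obs == 1L); fn <- sum(!pos & obs == 1L)
  fp <- sum(pos & obs == 0L); tn <- sum(!pos & obs == 0L)
  n <- tp + fn + fp + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(
    accuracy = po,
    sensitivity = sens,
    specificity = spec,
    kappa = if (pe >= 1) 0 else (po - pe) / (1 - pe),
    balanced_accuracy = (sens + spec) / 2,
    tp = tp, fn = fn, fp = fp, tn = tn
  )
}

#' Region-stratified evaluation of a score vector
#'
#' @param frame_rows Rows of a model frame (needs `region` and `class`).
#' @param scores Scores aligned with `frame_rows`.
#' @param regions Regions to evaluate, default those present.
#' @param ... Passed to [boyce_index()].
#' @return Data.frame with one row per region (plus `"pooled"`): `tss`,
#'   `threshold`, `sensitivity`, `specificity`, `boyce`, `n_presence`,
#'   `n_background`.
#' @export
evaluate_regional <- function(frame_rows, scores,
                              regions = sort(unique(frame_rows$region)), ...) {
  one <- function(sel, label) {
    o <- frame_rows$class[sel]
    s <- scores[sel]
    ot <- optimal_tss(o, s)
    bi <- tryCatch(boyce_index(s[o == 1], s[o == 0], ...),
                   error = function(e) NA_real_)
    data.frame(region = label, tss = ot$tss, threshold = ot$threshold,
               sensitivity = ot$sensitivity, specificity = ot$specificity,
               boyce = bi, n_presence = sum(o == 1), n_background = sum(o == 0),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(regions, function(reg) {
    one(frame_rows$region == reg, reg)
  }))
  rbind(out, one(rep(TRUE, nrow(frame_rows)), "pooled"))
}

#' Select the final ensemble by joint mean of TSS and Boyce index
#'
#' The selection score of a candidate is the unweighted mean of its two
#' per-region TSS values and two per-region Boyce values. Ties break toward
#' the higher mean TSS, then lexicographic id.
#'
#' @param eval_table Data.frame with columns `id`, `region`, `tss`, `boyce`,
#'   two regions per candidate.
#' @return The winning `id` (with the scored table as attribute
#'   `"scores"`).
#' @export
select_best <- function(eval_table) {
  ids <- unique(eval_table$id)
  scores <- do.call(rbind, lapply(ids, function(i) {
    sub <- eval_table[eval_table$id == i & eval_table$region != "pooled", ]
    if (anyNA(c(sub$tss, sub$boyce)) || nrow(sub) < 2) {
      stopf("candidate '%s' lacks metrics for both regions", i)
    }
    data.frame(id = i, joint = mean(c(sub$tss, sub$boyce)),
               mean_tss = mean(sub$tss), stringsAsFactors = FALSE)
  }))
  ord <- order(-scores$joint, -scores$mean_tss, scores$id)
  best <- scores$id[ord[1]]
  attr(best, "scores") <- scores[ord, ]
  best
}
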