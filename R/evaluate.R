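overlaps_within <- function(a_start, a_end, b_start, b_end, tol) {
  a_start < b_end + tol & b_start < a_end + tol
}

#' Score the caller against simulation ground truth
#'
#' A true insertion counts as recovered when some filter-passing candidate's
#' insertion interval overlaps its truth interval within `match_tolerance`
#' bases.  Sensitivity is the recovered fraction of true insertions;
#' specificity is the fraction of bare-element controls yielding no passing
#' candidate.  For the ROC, every truth locus (true or control) is assigned
#' the best total score among all emitted candidates overlapping it (loci
#' with no candidate score `-Inf`), and the score threshold is swept over
#' all observed values; the AUC is computed by the trapezoidal rule, which
#' equals the Mann-Whitney rank statistic.
#'
#' @param candidates a `retro_candidates` data frame from
#'   [detect_candidates()].
#' @param truths truth table from [plant_insertions()] /
#'   [simulate_retro()].
#' @param match_tolerance matching slack in bases (default 20).
#' @return a list of class `retro_eval` with counts (`tp`, `fn`, `fp`),
#'   `sensitivity`, `specificity`, `roc` (data.frame `threshold`, `fpr`,
#'   `tpr`), `auc`, `scores` (per-locus best scores and labels) and
#'   `match_tolerance`.
#' @export
evaluate_candidates <- function(candidates, truths, match_tolerance = 20L) {
  if (nrow(truths) == 0L || !any(!truths$isControl))
    stop("no positive instances: the truth table contains no true insertions")
  tol <- as.integer(match_tolerance)
  pass <- candidates[candidates$passedFilters, , drop = FALSE]

  hit_by <- function(cand, tr) {
    cand$chrom == tr$chrom &
      overlaps_within(cand$start, cand$end, tr$postStart, tr$postEnd, tol)
  }
  matched_pass <- vapply(seq_len(nrow(truths)), function(i)
    any(hit_by(pass, truths[i, ])), TRUE)
  best_score <- vapply(seq_len(nrow(truths)), function(i) {
    m <- hit_by(candidates, truths[i, ])
    if (any(m)) max(candidates$totalScore[m]) else -Inf
  }, 0)

  is_true <- !truths$isControl
  tp <- sum(matched_pass & is_true)
  fn <- sum(!matched_pass & is_true)
  fp_controls <- sum(matched_pass & !is_true)
  # passing candidates not matching any true insertion
  if (nrow(pass)) {
    cand_matched <- rep(FALSE, nrow(pass))
    for (i in which(is_true)) cand_matched <- cand_matched | hit_by(pass, truths[i, ])
    fp <- sum(!cand_matched)
  } else fp <- 0L

  sensitivity <- tp / sum(is_true)
  specificity <- if (any(!is_true))
    1 - fp_controls / sum(!is_true) else NA_real_

  scores_true <- best_score[is_true]
  scores_ctrl <- best_score[!is_true]
  roc <- roc_points(scores_true, scores_ctrl)
  auc <- if (length(scores_ctrl)) auc_trapezoid(roc$fpr, roc$tpr) else NA_real_

  structure(list(tp = tp, fn = fn, fp = fp,
                 sensitivity = sensitivity, specificity = specificity,
                 roc = roc, auc = auc,
                 scores = data.frame(id = truths$id,
                                     isControl = truths$isControl,
                                     score = best_score,
                                     recovered = matched_pass,
                                     stringsAsFactors = FALSE),
                 match_tolerance = tol,
                 n_true = sum(is_true), n_control = sum(!is_true)),
            class = "retro_eval")
}

#' ROC curve points from class-wise score vectors
#'
#' Sweeps the decision threshold over all observed scores (`-Inf` allowed
#' for undetected loci) and returns `(FPR, TPR)` pairs, anchored at (0, 0)
#' and ending at (1, 1); both coordinates are monotone non-decreasing.
#'
#' @param scores_true scores of the positive class.
#' @param scores_ctrl scores of the negative class.
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores_true, scores_ctrl) {
  thr <- sort(unique(c(scores_true, scores_ctrl, -Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores_true >= t), 0)
  fpr <- if (length(scores_ctrl))
    vapply(thr, function(t) mean(scores_ctrl >= t), 0) else rep(0, length(thr))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under an ROC curve
#'
#' @param fpr,tpr coordinates in sweep order (monotone non-decreasing).
#' @return the area, in \[0, 1\].
#' @export
auc_trapezoid <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' @export
print.retro_eval <- function(x, ...) {
  cat("<retro_eval> ", x$n_true, " true / ", x$n_control, " control loci",
      " (tolerance ", x$match_tolerance, " nt)\n", sep = "")
  cat(sprintf("  sensitivity %.3f   specificity %s   AUC %s\n",
              x$sensitivity,
              ifelse(is.na(x$specificity), "NA", sprintf("%.3f", x$specificity)),
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param x a `retro_eval` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.retro_eval <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.4f", x$auc))
  invisible(x)
}

#' Write evaluation metrics to disk
#'
#' Emits `<prefix>.metrics.tsv` (sensitivity, specificity, AUC, counts) and
#' `<prefix>.roc.tsv` (the ROC points).
#'
#' @param eval a `retro_eval` object.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_eval <- function(eval, prefix) {
  metrics <- data.frame(metric = c("sensitivity", "specificity", "auc",
                                   "tp", "fn", "fp", "n_true", "n_control",
                                   "match_tolerance"),
                        value = c(eval$sensitivity, eval$specificity,
                                  eval$auc, eval$tp, eval$fn, eval$fp,
                                  eval$n_true, eval$n_control,
                                  eval$match_tolerance))
  mp <- paste0(prefix, ".metrics.tsv")
  rp <- paste0(prefix, ".roc.tsv")
  write.table(metrics, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(eval$roc, rp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(metrics = mp, roc = rp))
}
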