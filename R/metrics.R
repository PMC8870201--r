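.round1 <- function(x) floor(x * 10 + 0.5) / 10  # half-up to 1 decimal

#' Confusion table at a fixed cutoff
#'
#' `score >= cutoff` is called positive (ties at the cutoff are positive).
#'
#' @param scores predicted probabilities.
#' @param labels binary outcome.
#' @param cutoff probability cutoff in `(0, 1)`.
#' @return An object of class `confusion_table`: list with `TP`, `FP`,
#'   `TN`, `FN` and `cutoff`.
#' @export
confusion_at <- function(scores, labels, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  labels <- as.integer(as.logical(labels))
  pos <- scores >= cutoff
  structure(list(TP = sum(pos & labels == 1L),
                 FP = sum(pos & labels == 0L),
                 TN = sum(!pos & labels == 0L),
                 FN = sum(!pos & labels == 1L),
                 cutoff = cutoff),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> cutoff %.3f: TP %d, FP %d, TN %d, FN %d\n",
              x$cutoff, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Sensitivity, specificity, balanced accuracy and Youden index
#'
#' `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Bacc = (Se+Sp)/2`,
#' `YI = Se + Sp - 1`. Percentages are rounded half-up to one decimal in
#' the `*_pct` fields. Also reports the below/above-cutoff group sizes and
#' their within-group false shares, mirroring the reference report layout.
#'
#' @param ct a [confusion_at()] result (or a list with TP/FP/TN/FN).
#' @return An object of class `metric_set`.
#' @export
classification_metrics <- function(ct) {
  n1 <- ct$TP + ct$FN; n0 <- ct$TN + ct$FP
  if (n1 == 0L || n0 == 0L) stop("each class needs >= 1 member")
  se <- ct$TP / n1; sp <- ct$TN / n0
  n <- n1 + n0
  below <- ct$TN + ct$FN; above <- ct$TP + ct$FP
  structure(list(
    sensitivity = se, specificity = sp,
    bacc = (se + sp) / 2, youden = se + sp - 1,
    se_pct = .round1(100 * se), sp_pct = .round1(100 * sp),
    bacc_pct = .round1(100 * (se + sp) / 2),
    n = n, below_n = below, above_n = above,
    fn_share_below = if (below > 0) ct$FN / below else NA_real_,
    fp_share_above = if (above > 0) ct$FP / above else NA_real_),
    class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> Se %.1f%%, Sp %.1f%%, Bacc %.1f%% (YI %.3f)\n",
              x$se_pct, x$sp_pct, x$bacc_pct, x$youden))
  invisible(x)
}

#' ROC AUC with a Mann-Whitney null-hypothesis p-value
#'
#' AUC via the midrank Mann-Whitney identity; two-sided p-value from the
#' tie-corrected normal approximation of the Mann-Whitney test of
#' AUC = 0.5.
#'
#' @param scores predicted probabilities.
#' @param labels binary outcome, both classes present.
#' @return list with `auc` (unfolded, in `[0, 1]`) and `p_value`.
#' @export
roc_auc_test <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  n <- n1 + n0
  r <- rank(scores, ties.method = "average")
  U <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n0)
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  varU <- n1 * n0 / 12 * (n + 1 - tie_term)
  if (varU <= 0) return(list(auc = auc, p_value = 1))
  z <- (U - n1 * n0 / 2) / sqrt(varU)
  list(auc = auc, p_value = 2 * pnorm(-abs(z)))
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model at each threshold probability
#' `p_t`: `NB(p_t) = TP/N - FP/N * p_t/(1-p_t)`, with the treat-all and
#' treat-none reference strategies.
#'
#' @param scores predicted probabilities.
#' @param labels binary outcome.
#' @param thresholds grid of threshold probabilities in `(0, 1)`.
#' @return data.frame with columns `threshold`, `nb_model`, `nb_all`,
#'   `nb_none`.
#' @export
decision_curve <- function(scores, labels, thresholds = seq(0.01, 0.5, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  labels <- as.integer(as.logical(labels))
  n <- length(labels)
  prev <- mean(labels)
  rows <- lapply(thresholds, function(pt) {
    w <- pt / (1 - pt)
    pos <- scores >= pt
    data.frame(threshold = pt,
               nb_model = sum(pos & labels == 1L) / n -
                          sum(pos & labels == 0L) / n * w,
               nb_all = prev - (1 - prev) * w,
               nb_none = 0)
  })
  do.call(rbind, rows)
}

#' Evaluate a fitted model on a cohort at its locked cutoff
#'
#' @param model a [pcr_model()].
#' @param features cohort feature table.
#' @param labels binary pCR outcome.
#' @return list with `scores`, `confusion`, `metrics`, `auc`, `p_value`.
#' @export
evaluate_model <- function(model, features, labels) {
  sc <- predict(model, features, type = "prob")
  ct <- confusion_at(sc, labels, model$cutoff)
  rt <- roc_auc_test(sc, labels)
  list(scores = sc, confusion = ct, metrics = classification_metrics(ct),
       auc = rt$auc, p_value = rt$p_value)
}

#' Render a performance report row
#'
#' One row of the model-performance report: AUC, p, cutoff in percent,
#' Se/Sp/Bacc percentages, and the below/above-cutoff breakdown with TN/FN
#' and FP/TP counts and within-group shares.
#'
#' @param model a [pcr_model()].
#' @param eval an [evaluate_model()] result.
#' @return one-row data.frame.
#' @export
report_row <- function(model, eval) {
  ct <- eval$confusion; m <- eval$metrics
  pct <- function(a, b) if (b > 0) .round1(100 * a / b) else NA_real_
  data.frame(
    Model = model$kind,
    AUC = round(eval$auc, 2),
    p = signif(eval$p_value, 2),
    Cutoff_pct = .round1(model$cutoff_pct),
    Se_pct = m$se_pct, Sp_pct = m$sp_pct, Bacc_pct = m$bacc_pct,
    Below_n = m$below_n, Below_share_pct = pct(m$below_n, m$n),
    TN_n = ct$TN, TN_share_pct = pct(ct$TN, m$below_n),
    FN_n = ct$FN, FN_share_pct = pct(ct$FN, m$below_n),
    Above_n = m$above_n, Above_share_pct = pct(m$above_n, m$n),
    FP_n = ct$FP, FP_share_pct = pct(ct$FP, m$above_n),
    TP_n = ct$TP, TP_share_pct = pct(ct$TP, m$above_n),
    stringsAsFactors = FALSE)
}

#' Plot decision curves
#'
#' Base-graphics net-benefit plot for one or more models plus the
#' treat-all/treat-none references.
#'
#' @param curves named list of [decision_curve()] data.frames.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly `NULL`.
#' @export
plot_decision_curves <- function(curves, ...) {
  stopifnot(length(curves) > 0)
  thr <- curves[[1]]$threshold
  mat <- cbind(sapply(curves, function(d) d$nb_model),
               all = curves[[1]]$nb_all, none = curves[[1]]$nb_none)
  graphics::matplot(thr, mat, type = "l", lty = c(rep(1, length(curves)), 2, 3),
                    xlab = "Threshold probability", ylab = "Net benefit", ...)
  graphics::legend("topright", legend = colnames(mat), lty = c(rep(1, length(curves)), 2, 3),
                   col = seq_len(ncol(mat)), cex = 0.8)
  invisible(NULL)
}
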