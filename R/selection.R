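#' Orientation-folded AUC of one feature for a binary outcome
#'
#' Mann-Whitney AUC with midrank tie handling, folded to
#' `max(AUC, 1 - AUC)` so a feature predictive in either direction scores
#' above 0.5.
#'
#' @param values numeric feature values, one per patient.
#' @param labels binary outcome (0/1 or logical), both classes present.
#' @return AUC in `[0.5, 1]`.
#' @export
feature_auc <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(values, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(auc, 1 - auc)
}

#' Two-step univariate feature selection
#'
#' Training-set-only selection: (1) keep features whose orientation-folded
#' AUC for the outcome is at least `auc_min`; (2) walk the survivors in
#' descending AUC (ties broken lexicographically by name) and retain a
#' feature only if its absolute rank correlation with every already-retained
#' feature is at most `rho_max` — when two features are highly correlated
#' only the one with the higher AUC is kept.
#'
#' @param features patients x features data.frame (training rows only).
#' @param labels binary outcome.
#' @param auc_min univariate AUC threshold (inclusive), default 0.60.
#' @param rho_max de-correlation threshold, default 0.7 (drop when
#'   `|rho| > rho_max`).
#' @param method correlation statistic, `"spearman"` (default) or
#'   `"pearson"`.
#' @return An object of class `selection_result`: data.frame with columns
#'   `feature`, `auc`, `retained`, `reason`
#'   (`retained` / `low_auc` / `correlated_with:<name>`), plus attributes
#'   `auc_min`, `rho_max`, `retained` (character vector).
#' @export
select_features <- function(features, labels, auc_min = 0.60, rho_max = 0.7,
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  X <- as.data.frame(features)
  if (ncol(X) == 0L || nrow(X) == 0L) stop("empty feature table")
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  aucs <- vapply(X, feature_auc, numeric(1), labels = labels)
  res <- data.frame(feature = names(aucs), auc = unname(aucs),
                    retained = FALSE, reason = "low_auc",
                    stringsAsFactors = FALSE)
  cand <- res$feature[res$auc >= auc_min]
  ord <- cand[order(-res$auc[match(cand, res$feature)], cand)]
  # standardized (rank-transformed for Spearman) columns so pairwise
  # correlations reduce to cross-products
  Zc <- vapply(ord, function(f) {
    v <- X[[f]]
    if (method == "spearman") v <- rank(v, ties.method = "average")
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s  # constant: no redundancy
  }, numeric(nrow(X)))
  kept <- character(0)
  for (f in ord) {
    if (length(kept)) {
      rho <- abs(crossprod(Zc[, kept, drop = FALSE], Zc[, f])) / (nrow(X) - 1)
      if (any(rho > rho_max)) {
        res$reason[res$feature == f] <-
          paste0("correlated_with:", kept[which.max(rho)])
        next
      }
    }
    kept <- c(kept, f)
    res$retained[res$feature == f] <- TRUE
    res$reason[res$feature == f] <- "retained"
  }
  structure(res, auc_min = auc_min, rho_max = rho_max, retained = kept,
            class = c("selection_result", "data.frame"))
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d/%d features retained (AUC >= %.2f, |rho| <= %.2f)\n",
              sum(x$retained), nrow(x), attr(x, "auc_min"), attr(x, "rho_max")))
  kept <- x[x$retained, ]
  kept <- kept[order(-kept$auc), ]
  for (i in seq_len(nrow(kept)))
    cat(sprintf("  %-50s AUC %.3f\n", kept$feature[i], kept$auc[i]))
  invisible(x)
}
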