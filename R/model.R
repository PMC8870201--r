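#' Youden-index optimal cutoff
#'
#' Scans every midpoint between consecutive sorted unique scores and returns
#' the cutoff maximizing `YI = Se + Sp - 1` under the decision rule
#' `score >= cutoff` is positive. Ties are broken towards the higher cutoff
#' (fewer predicted positives, hence higher specificity). With a single
#' unique score the cutoff is that score and YI = 0.
#'
#' @param scores predicted probabilities (or any scores).
#' @param labels binary outcome, both classes present.
#' @return An object of class `youden_result`: list with `cutoff`, `youden`
#'   (YI at the cutoff), `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  su <- sort(unique(scores))
  half <- (max(su) - min(su) + 1) / 2
  # midpoints plus the two boundary thresholds (everyone / no one positive),
  # so the maximized YI is never below 0
  cands <- c(if (length(su) > 1L) (su[-1] + su[-length(su)]) / 2,
             min(su) - half, max(su) + half)
  best <- list(cutoff = -Inf, youden = -Inf, sensitivity = NA, specificity = NA)
  for (cc in cands) {
    pos <- scores >= cc
    se <- sum(pos & labels == 1L) / n1
    sp <- sum(!pos & labels == 0L) / n0
    yi <- se + sp - 1
    if (yi > best$youden + 1e-12 ||
        (abs(yi - best$youden) <= 1e-12 && cc > best$cutoff)) {
      best <- list(cutoff = cc, youden = yi, sensitivity = se, specificity = sp)
    }
  }
  structure(best, class = "youden_result")
}

#' @export
print.youden_result <- function(x, ...) {
  cat(sprintf("<youden_result> cutoff %.4f (%.1f%%), YI %.3f (Se %.3f, Sp %.3f)\n",
              x$cutoff, 100 * x$cutoff, x$youden, x$sensitivity, x$specificity))
  invisible(x)
}

.fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0] <- 1
  list(center = mu, scale = sdv)
}

.apply_scaler <- function(X, scaler) {
  scale(as.matrix(X), center = scaler$center, scale = scaler$scale)
}

.fit_net <- function(X, y, hidden, decay, maxit) {
  nnet::nnet(x = as.matrix(X), y = y, size = hidden, decay = decay,
             maxit = maxit, entropy = TRUE, trace = FALSE, MaxNWts = 25000L)
}

#' Bootstrap out-of-bag validation of the SMOTE + MLP workflow
#'
#' For each replicate, patients are resampled with replacement, the
#' resample is SMOTE-balanced and a network fitted on it, and out-of-bag
#' patients are scored. Replicates whose resample lacks two members of each
#' class, or whose out-of-bag set is single-class, are redrawn. Reports the
#' mean and 2.5/97.5 percentiles of the out-of-bag AUC.
#'
#' @param features standardized training feature table.
#' @param labels binary outcome.
#' @param n_boot number of replicates (the reference workflow uses 1000).
#' @param hidden,decay,maxit network hyperparameters.
#' @param smote_k SMOTE neighbour count.
#' @return list with `mean_auc`, `ci` (2.5/97.5 percentiles), `n_boot`,
#'   `aucs`.
#' @export
bootstrap_validate <- function(features, labels, n_boot = 1000L,
                               hidden = 3L, decay = 1e-3, maxit = 200L,
                               smote_k = 5L) {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  X <- as.data.frame(features)
  labels <- as.integer(as.logical(labels))
  n <- nrow(X)
  aucs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    for (try in 1:50) {
      take <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), take)
      yb <- labels[take]
      if (min(sum(yb == 1L), sum(yb == 0L)) >= 2L &&
          length(unique(labels[oob])) == 2L) break
      if (try == 50L) stop("could not draw a usable bootstrap resample")
    }
    bal <- smote_balance(X[take, , drop = FALSE], yb, k = smote_k)
    fit <- .fit_net(bal$features, bal$labels, hidden, decay, maxit)
    sc <- as.numeric(predict(fit, as.matrix(X[oob, , drop = FALSE])))
    aucs[b] <- roc_auc_test(sc, labels[oob])$auc  # oriented, not folded
  }
  list(mean_auc = mean(aucs),
       ci = quantile(aucs, c(0.025, 0.975), names = FALSE),
       n_boot = n_boot, aucs = aucs)
}

#' Fit a pCR prediction model
#'
#' The modelling core of the workflow: the (already selected) training
#' features are standardized, the minority class is SMOTE-balanced to 1:1,
#' a single-hidden-layer neural network with logistic output is fitted, the
#' operating cutoff is locked by maximizing the Youden index on the
#' training-set scores, and (optionally) a bootstrap out-of-bag validation
#' summary is computed. The locked cutoff is reused unchanged on any test
#' cohort via [predict.pcr_model()] and [evaluate_model()].
#'
#' @param features training feature table (rows = patients, columns =
#'   selected features).
#' @param labels binary pCR outcome (1 = pCR).
#' @param kind model label, one of `"Clinical"`, `"Radiomic"`,
#'   `"Combined"`, `"ComBat_Radiomic"`, `"ComBat_Combined"` (free-form
#'   allowed).
#' @param hidden hidden-layer width; default `max(2, ceiling((p + 1) / 2))`.
#' @param decay,maxit weight decay and iteration cap for the network.
#' @param smote_k SMOTE neighbour count (default 5).
#' @param n_boot bootstrap replicates for internal validation; 0 skips the
#'   bootstrap.
#' @param seed optional RNG seed making the whole fit deterministic.
#' @return An object of class `pcr_model` with `print`, `summary`,
#'   `predict` and `coef` methods. The cutoff is stored as a probability
#'   (`cutoff`) and in percent (`cutoff_pct`).
#' @export
pcr_model <- function(features, labels, kind = "Radiomic", hidden = NULL,
                      decay = 1e-3, maxit = 200L, smote_k = 5L,
                      n_boot = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.data.frame(features)
  labels <- as.integer(as.logical(labels))
  if (min(table(labels)) < 2L) stop("need >= 2 patients per class")
  if (!all(vapply(X, function(c) all(is.finite(c)), TRUE)))
    stop("non-finite feature values")
  p <- ncol(X)
  if (is.null(hidden)) hidden <- max(2L, ceiling((p + 1) / 2))
  scaler <- .fit_scaler(as.matrix(X))
  Z <- as.data.frame(.apply_scaler(X, scaler))
  boot <- if (n_boot > 0L)
    bootstrap_validate(Z, labels, n_boot = n_boot, hidden = hidden,
                       decay = decay, maxit = maxit, smote_k = smote_k)
  else NULL
  bal <- smote_balance(Z, labels, k = smote_k)
  net <- .fit_net(bal$features, bal$labels, hidden, decay, maxit)
  train_scores <- as.numeric(predict(net, as.matrix(Z)))
  yd <- youden_cutoff(train_scores, labels)
  structure(list(kind = kind, features = colnames(X), scaler = scaler,
                 net = net, hidden = hidden, decay = decay,
                 smote_k = smote_k,
                 cutoff = yd$cutoff, cutoff_pct = 100 * yd$cutoff,
                 youden = yd, train_scores = train_scores,
                 train_labels = labels, bootstrap = boot,
                 n_train = nrow(X)),
            class = "pcr_model")
}

#' Predict pCR probabilities or classes
#'
#' @param object a [pcr_model()].
#' @param newdata feature table containing the model's feature columns.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 calls at the
#'   locked cutoff (`prob >= cutoff` is positive).
#' @param ... unused.
#' @return numeric vector of probabilities or integer classes.
#' @export
predict.pcr_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.data.frame(newdata)[, object$features, drop = FALSE]
  Z <- .apply_scaler(X, object$scaler)
  pr <- as.numeric(predict(object$net, as.matrix(Z)))
  if (type == "prob") pr else as.integer(pr >= object$cutoff)
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("<pcr_model %s> %d features, hidden width %d, cutoff %.1f%%\n",
              x$kind, length(x$features), x$hidden, x$cutoff_pct))
  invisible(x)
}

#' @export
summary.pcr_model <- function(object, ...) {
  tr_auc <- feature_auc(object$train_scores, object$train_labels)
  cat(sprintf("pCR prediction model: %s\n", object$kind))
  cat(sprintf("  features (%d): %s\n", length(object$features),
              paste(object$features, collapse = ", ")))
  cat(sprintf("  hidden units: %d, weight decay: %g\n",
              object$hidden, object$decay))
  cat(sprintf("  locked Youden cutoff: %.1f%% (YI %.3f)\n",
              object$cutoff_pct, object$youden$youden))
  cat(sprintf("  training AUC: %.3f (n = %d, %d pCR)\n", tr_auc,
              object$n_train, sum(object$train_labels)))
  if (!is.null(object$bootstrap))
    cat(sprintf("  bootstrap OOB AUC: %.3f [%.3f, %.3f] (n_boot = %d)\n",
                object$bootstrap$mean_auc, object$bootstrap$ci[1],
                object$bootstrap$ci[2], object$bootstrap$n_boot))
  invisible(object)
}

#' @export
coef.pcr_model <- function(object, ...) object$net$wts

#' Serialize a fitted model to JSON
#'
#' @param model a [pcr_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(kind = model$kind, features = model$features,
              scaler = model$scaler, hidden = model$hidden,
              decay = model$decay, weights = model$net$wts,
              n_nodes = model$net$n, cutoff = model$cutoff,
              cutoff_pct = model$cutoff_pct)
  if (!is.null(model$bootstrap))
    obj$bootstrap <- model$bootstrap[c("mean_auc", "ci", "n_boot")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
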