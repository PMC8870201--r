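#' SMOTE: synthetic minority oversampling
#'
#' Each synthetic sample is `x + u (x_nn - x)` with `u ~ Uniform(0,1)`,
#' where `x` is a minority-class row and `x_nn` one of its `k` nearest
#' minority neighbours (Euclidean distance on per-feature standardized
#' values). Source rows are cycled deterministically; neighbour and `u`
#' draws come from the current RNG state, so results are reproducible under
#' `set.seed()`.
#'
#' @param minority data.frame/matrix of minority-class rows (> k rows).
#' @param n_needed number of synthetic rows to generate.
#' @param k number of nearest neighbours (default 5).
#' @return data.frame of `n_needed` synthetic rows, same columns.
#' @export
smote <- function(minority, n_needed, k = 5L) {
  X <- as.matrix(minority)
  m <- nrow(X)
  if (m <= k) stop("minority count (", m, ") must exceed k (", k, ")")
  if (n_needed <= 0L) return(as.data.frame(X[0, , drop = FALSE]))
  sds <- apply(X, 2L, sd)
  sds[sds == 0] <- 1
  Z <- sweep(X, 2L, sds, "/")
  D <- as.matrix(dist(Z))
  diag(D) <- Inf
  nn <- matrix(0L, m, k)
  for (i in seq_len(m)) nn[i, ] <- order(D[i, ])[seq_len(k)]
  src <- rep_len(seq_len(m), n_needed)
  pick <- nn[cbind(src, sample.int(k, n_needed, replace = TRUE))]
  u <- runif(n_needed)
  out <- X[src, , drop = FALSE] + u * (X[pick, , drop = FALSE] - X[src, , drop = FALSE])
  as.data.frame(out)
}

#' Balance a training set to class parity with SMOTE
#'
#' Oversamples the minority class up to the majority count (1:1 ratio).
#' `k` is clamped to `minority - 1` when the minority class is very small
#' (e.g. inside bootstrap resamples).
#'
#' @param features training feature table.
#' @param labels binary outcome.
#' @param k nearest-neighbour count, default 5.
#' @return list with balanced `features` and `labels` (original rows first).
#' @export
smote_balance <- function(features, labels, k = 5L) {
  labels <- as.integer(as.logical(labels))
  X <- as.data.frame(features)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  minority_class <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  if (n_min == n_maj || n_min < 2L)
    return(list(features = X, labels = labels))
  k_use <- min(k, n_min - 1L)
  synth <- smote(X[labels == minority_class, , drop = FALSE],
                 n_needed = n_maj - n_min, k = k_use)
  out <- rbind(X, synth)
  rownames(out) <- NULL
  list(features = out,
       labels = c(labels, rep.int(minority_class, nrow(synth))))
}
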