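#' Build the four texture matrices from a discretized ROI
#'
#' All matrices use the merging strategy: a single matrix accounting for all
#' 13 unique 3D directions at a distance of 1 voxel (GLCM and GLRLM), and
#' 26-connectivity for GLSZM zones and NGTDM neighbourhoods. Only in-mask
#' voxels contribute; out-of-mask neighbours are ignored (and break runs).
#'
#' @param levels 3D integer array of gray levels in `1..n_bins`, with 0
#'   marking out-of-mask voxels.
#' @param n_bins number of gray levels Nb.
#' @return An object of class `texture_matrix_set`: list with `glcm`
#'   (Nb x Nb symmetric counts), `glrlm` (Nb x max-run-length counts),
#'   `glszm` (Nb x max-zone-size counts), `ngtdm` (Nb x 2: per-level count
#'   n_i and summed absolute difference s_i), plus `n_voxels`,
#'   `n_directions` (13) and `n_bins`.
#' @export
build_texture_matrices <- function(levels, n_bins) {
  levels <- as.array(levels)
  stopifnot(length(dim(levels)) == 3L)
  lv <- as.integer(levels)
  if (anyNA(lv) || any(lv < 0L) || any(lv > n_bins))
    stop("levels must be integers in 0..n_bins (0 = outside mask)")
  nvox <- sum(lv > 0L)
  if (nvox == 0L) stop("empty mask: no in-mask levels")
  dm <- dim(levels)
  structure(list(
    glcm = cpp_glcm(lv, dm, n_bins),
    glrlm = cpp_glrlm(lv, dm, n_bins),
    glszm = cpp_glszm(lv, dm, n_bins),
    ngtdm = cpp_ngtdm(lv, dm, n_bins),
    n_voxels = nvox, n_directions = 13L, n_bins = as.integer(n_bins)),
    class = "texture_matrix_set")
}

.entropy2 <- function(p) { p <- p[p > 0]; if (!length(p)) 0 else -sum(p * log2(p)) }

.glcm_features <- function(M, nb) {
  tot <- sum(M)
  nm <- c("joint_maximum", "joint_average", "joint_variance", "joint_entropy",
          "difference_average", "difference_variance", "difference_entropy",
          "sum_average", "sum_variance", "sum_entropy",
          "angular_second_moment", "contrast", "dissimilarity",
          "inverse_difference", "inverse_difference_norm",
          "inverse_difference_moment", "inverse_difference_moment_norm",
          "inverse_variance", "correlation", "autocorrelation",
          "cluster_tendency", "cluster_shade", "cluster_prominence",
          "information_correlation_1", "information_correlation_2")
  if (tot == 0) return(setNames(numeric(25), nm))  # single-voxel ROI: no pairs
  p <- M / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p)                       # symmetric: px == py
  mu <- sum(seq_len(nb) * px)
  sig2 <- sum((seq_len(nb) - mu)^2 * px)
  pd <- numeric(nb)                      # difference distribution, k = 0..nb-1
  pd[sort(unique(as.vector(abs(i - j)))) + 1L] <-
    rowsum(as.vector(p), as.vector(abs(i - j)))
  da <- sum((0:(nb - 1)) * pd)
  ps <- numeric(2 * nb - 1)              # sum distribution, k = 2..2nb
  ps[sort(unique(as.vector(i + j))) - 1L] <-
    rowsum(as.vector(p), as.vector(i + j))
  sa <- sum((2:(2 * nb)) * ps)
  hxy <- .entropy2(p)
  hx <- .entropy2(px)
  pxy <- outer(px, px)
  nzp <- p > 0
  hxy1 <- -sum(p[nzp & pxy > 0] * log2(pxy[nzp & pxy > 0]))
  hxy2 <- .entropy2(pxy)
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  setNames(c(
    max(p),
    sum(i * p),
    sum((i - mu)^2 * p),
    hxy,
    da,
    sum(((0:(nb - 1)) - da)^2 * pd),
    .entropy2(pd),
    sa,
    sum(((2:(2 * nb)) - sa)^2 * ps),
    .entropy2(ps),
    sum(p^2),
    sum((i - j)^2 * p),
    sum(abs(i - j) * p),
    sum(p / (1 + abs(i - j))),
    sum(p / (1 + abs(i - j) / nb)),
    sum(p / (1 + (i - j)^2)),
    sum(p / (1 + (i - j)^2 / nb^2)),
    sum(p[i != j] / (i - j)[i != j]^2),
    corr,
    sum(i * j * p),
    sum((i + j - 2 * mu)^2 * p),
    sum((i + j - 2 * mu)^3 * p),
    sum((i + j - 2 * mu)^4 * p),
    ic1, ic2), nm)
}

.glrlm_features <- function(M, nvox, ndir) {
  ns <- sum(M)
  i <- row(M); l <- col(M)
  p <- M / ns
  ri <- rowSums(M); rl <- colSums(M)
  mu_i <- sum(row(p) * p); mu_l <- sum(col(p) * p)
  c(SRE = sum(p / l^2),
    LRE = sum(p * l^2),
    LGLRE = sum(p / i^2),
    HGLRE = sum(p * i^2),
    SRLGLE = sum(p / (i^2 * l^2)),
    SRHGLE = sum(p * i^2 / l^2),
    LRLGLE = sum(p * l^2 / i^2),
    LRHGLE = sum(p * i^2 * l^2),
    GLNU = sum(ri^2) / ns,
    GLNU_norm = sum(ri^2) / ns^2,
    RLNU = sum(rl^2) / ns,
    RLNU_norm = sum(rl^2) / ns^2,
    run_percentage = ns / (ndir * nvox),
    GL_variance = sum(p * (i - mu_i)^2),
    run_length_variance = sum(p * (l - mu_l)^2),
    run_entropy = .entropy2(p))
}

.glszm_features <- function(M, nvox) {
  nz <- sum(M)
  i <- row(M); s <- col(M)
  p <- M / nz
  gi <- rowSums(M); zs <- colSums(M)
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  c(SZE = sum(p / s^2),
    LZE = sum(p * s^2),
    LGLZE = sum(p / i^2),
    HGLZE = sum(p * i^2),
    SZLGLE = sum(p / (i^2 * s^2)),
    SZHGLE = sum(p * i^2 / s^2),
    LZLGLE = sum(p * s^2 / i^2),
    LZHGLE = sum(p * i^2 * s^2),
    GLNU = sum(gi^2) / nz,
    GLNU_norm = sum(gi^2) / nz^2,
    ZSNU = sum(zs^2) / nz,
    ZSNU_norm = sum(zs^2) / nz^2,
    zone_percentage = nz / nvox,
    GL_variance = sum(p * (i - mu_i)^2),
    zone_size_variance = sum(p * (s - mu_s)^2),
    zone_entropy = .entropy2(p))
}

.ngtdm_features <- function(M) {
  n_i <- M[, 1]; s_i <- M[, 2]
  nvc <- sum(n_i)
  nm <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  if (nvc == 0) return(setNames(numeric(5), nm))  # no voxel has a neighbour
  p <- n_i / nvc
  lev <- seq_along(p)
  act <- p > 0
  ngp <- sum(act)
  denom_coarse <- sum(p * s_i)
  coarse <- if (denom_coarse > 0) 1 / denom_coarse else 1e6
  if (ngp > 1) {
    li <- lev[act]; pi_ <- p[act]; si <- s_i[act]
    dmat <- outer(li, li, "-")
    contrast <- sum(outer(pi_, pi_) * dmat^2) / (ngp * (ngp - 1)) * sum(si) / nvc
    busy_den <- sum(abs(outer(li * pi_, li * pi_, "-")))
    busy <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0
    compl <- sum(abs(dmat) * (outer(pi_ * si, rep(1, ngp)) +
                              outer(rep(1, ngp), pi_ * si)) /
                 (outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_))) / nvc
    strength_num <- sum((outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_)) * dmat^2)
    strength <- if (sum(si) > 0) strength_num / sum(si) else 0
  } else { contrast <- 0; busy <- 0; compl <- 0; strength <- 0 }
  setNames(c(coarse, contrast, busy, compl, strength), nm)
}

#' Texture features from a matrix set
#'
#' Computes the 62-feature texture catalog: 25 co-occurrence (GLCM), 16
#' run-length (GLRLM), 16 size-zone (GLSZM) and 5 neighbourhood gray-tone
#' difference (NGTDM) features, each from the merged-direction matrices.
#' Degenerate single-voxel ROIs yield 0 for pair-based features and
#' emphasis-type features computed from the single available run/zone.
#'
#' @param tm a `texture_matrix_set` from [build_texture_matrices()].
#' @return named numeric vector of 62 finite values, names prefixed with the
#'   matrix family (`GLCM_`, `GLRLM_`, `GLSZM_`, `NGTDM_`).
#' @export
texture_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix_set"))
  glcm <- .glcm_features(tm$glcm, tm$n_bins)
  glrlm <- .glrlm_features(tm$glrlm, tm$n_voxels, tm$n_directions)
  glszm <- .glszm_features(tm$glszm, tm$n_voxels)
  ngtdm <- .ngtdm_features(tm$ngtdm)
  out <- c(setNames(glcm, paste0("GLCM_", names(glcm))),
           setNames(glrlm, paste0("GLRLM_", names(glrlm))),
           setNames(glszm, paste0("GLSZM_", names(glszm))),
           setNames(ngtdm, paste0("NGTDM_", names(ngtdm))))
  if (!all(is.finite(out))) stop("non-finite texture feature")
  out
}
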