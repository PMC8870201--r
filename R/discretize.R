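#' Discretization specification
#'
#' Fixed-bin-number (FBN) intensity discretization. Two schemes are
#' supported: `"linear"` equal-width binning of the raw intensity range, and
#' `"equalization"` — midrank-based histogram equalization of the ROI
#' intensities followed by the same linear FBN binning of the equalized
#' (rank) values. Equalization is deterministic and rank-preserving.
#'
#' @param scheme `"linear"` or `"equalization"`.
#' @param n_bins number of gray levels Nb (>= 2); the workflow uses 32 and 64.
#' @return An object of class `discretization_spec`.
#' @export
discretization_spec <- function(scheme = c("linear", "equalization"),
                                n_bins = 64L) {
  scheme <- match.arg(scheme)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be an integer >= 2")
  structure(list(scheme = scheme, n_bins = n_bins),
            class = "discretization_spec")
}

#' The four discretization variants used for texture features
#'
#' Linear and equalization schemes crossed with Nb = 32 and 64.
#'
#' @return named list of four [discretization_spec()] objects.
#' @export
default_discretizations <- function() {
  out <- list()
  for (scheme in c("linear", "equalization")) for (nb in c(32L, 64L)) {
    tag <- paste0(substr(scheme, 1, 3), nb)
    out[[tag]] <- discretization_spec(scheme, nb)
  }
  out
}

.linear_bin <- function(x, nb) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep.int(1L, length(x)))
  lev <- floor(nb * (x - rng[1]) / (rng[2] - rng[1])) + 1L
  as.integer(pmin(lev, nb))
}

#' Discretize ROI intensities to integer gray levels
#'
#' Linear: `level = min(Nb, floor(Nb (x - xmin)/(xmax - xmin)) + 1)`.
#' Equalization: intensities are replaced by their midranks, then linearly
#' binned. Constant input maps every voxel to level 1 under either scheme.
#'
#' @param x numeric vector of ROI intensities (non-empty, finite).
#' @param spec a [discretization_spec()].
#' @return integer vector of levels in `1..Nb`.
#' @export
discretize <- function(x, spec = discretization_spec("linear", 64L)) {
  if (length(x) == 0L) stop("cannot discretize an empty intensity list")
  if (!all(is.finite(x))) stop("intensities must be finite")
  stopifnot(inherits(spec, "discretization_spec"))
  if (spec$scheme == "equalization") x <- rank(x, ties.method = "average")
  .linear_bin(x, spec$n_bins)
}
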