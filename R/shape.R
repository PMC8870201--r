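.boundary_voxels <- function(mask) {
  dm <- dim(mask)
  pad <- array(0L, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask
  inner <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
  nbr <- pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] +
         pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] +
         pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] +
         pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] +
         pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] +
         pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  which(inner == 1L & nbr < 6L)
}

# mesh area and volume: marching tetrahedra at the 0.5 isolevel of the
# binary grid smoothed with a sigma = 0.7 voxel Gaussian (takes the
# staircase out of the voxelized surface); tiny masks whose smoothed field
# falls entirely below the isolevel fall back to the raw binary mesh
.mesh_props <- function(mask, spacing) {
  bb <- .bbox(mask, pad = 0L)
  mask <- mask[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
  dm <- dim(mask)
  pad <- array(0, dm + 8L)  # padding > smoothing kernel radius keeps the mesh closed
  pad[5:(dm[1] + 4), 5:(dm[2] + 4), 5:(dm[3] + 4)] <- mask
  mp <- cpp_mesh_props(.smooth3d(pad, 0.7), dim(pad), spacing)
  if (mp[1] <= 0) mp <- cpp_mesh_props(pad, dim(pad), spacing)
  mp
}

#' 3D morphological shape features
#'
#' The 15-feature shape catalog: voxel-counting volume, mesh surface area
#' (marching tetrahedra over the binary grid), surface-to-volume ratio,
#' compactness 1 and 2, spherical disproportion, sphericity, asphericity,
#' centre-of-mass shift (distance in mm between the unweighted and the
#' intensity-weighted centroid; 0 when no image is supplied), maximum 3D
#' diameter (largest distance between boundary voxel centres), and the PCA
#' axis set: major/minor/least axis lengths, elongation and flatness.
#' Axis lengths are \eqn{4\sqrt{\lambda}} of the coordinate covariance
#' eigenvalues; elongation \eqn{= \sqrt{\lambda_2/\lambda_1}}, flatness
#' \eqn{= \sqrt{\lambda_3/\lambda_1}} (1 for degenerate single-voxel ROIs).
#'
#' @param mask an [roi_mask()] with >= 1 foreground voxel.
#' @param volume optional paired [image_volume()] for the centre-of-mass
#'   shift.
#' @return named numeric vector of 15 features (volumes in mm^3, areas in
#'   mm^2, lengths in mm; ratios dimensionless).
#' @export
shape_features <- function(mask, volume = NULL) {
  m <- mask$voxels
  n <- sum(m)
  if (n == 0L) stop("empty mask")
  sp <- mask$spacing
  # all shape features are translation-invariant: work in the ROI bounding box
  bb <- .bbox(m, pad = 0L)
  m <- m[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
  vox <- if (!is.null(volume)) {
    validate_pair(volume, mask)
    volume$voxels[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                  drop = FALSE]
  } else NULL
  vol <- n * prod(sp)
  mp <- .mesh_props(m, sp)
  area <- mp[1]; mvol <- mp[2]
  r_equiv <- (3 * mvol / (4 * pi))^(1 / 3)
  sphericity <- (36 * pi * mvol^2)^(1 / 3) / area

  idx <- arrayInd(which(m == 1L), dim(m))
  pts <- sweep(idx - 1L, 2L, sp, "*")
  com_geom <- colMeans(pts)
  com_shift <- 0
  if (!is.null(vox)) {
    w <- as.numeric(vox[m == 1L])
    if (min(w) < 0) w <- w - min(w)  # weights must be non-negative
    com_w <- if (sum(w) > 0) colSums(pts * w) / sum(w) else com_geom
    com_shift <- sqrt(sum((com_geom - com_w)^2))
  }

  bnd <- .boundary_voxels(m)
  bpts <- sweep(arrayInd(bnd, dim(m)) - 1L, 2L, sp, "*")
  max_diam <- if (nrow(bpts) > 1L) cpp_max_pairwise_dist(bpts) else 0

  if (n > 1L) {
    ev <- sort(eigen(cov(pts), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  if (ev[1] > 0) {
    elong <- sqrt(ev[2] / ev[1]); flat <- sqrt(ev[3] / ev[1])
  } else { elong <- 1; flat <- 1 }

  c(volume_voxel = vol,
    surface_area = area,
    surface_to_volume_ratio = area / mvol,
    compactness1 = mvol / (sqrt(pi) * area^1.5),
    compactness2 = 36 * pi * mvol^2 / area^3,
    spherical_disproportion = area / (4 * pi * r_equiv^2),
    sphericity = sphericity,
    asphericity = (area^3 / (36 * pi * mvol^2))^(1 / 3) - 1,
    com_shift = com_shift,
    max_3d_diameter = max_diam,
    major_axis_length = 4 * sqrt(ev[1]),
    minor_axis_length = 4 * sqrt(ev[2]),
    least_axis_length = 4 * sqrt(ev[3]),
    elongation = elong,
    flatness = flat)
}
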