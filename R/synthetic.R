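#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: a two-institution
#' cohort (training institution n = 64, testing institution n = 60) with a
#' pCR prevalence of 11.3% (9 training / 5 testing events under quota
#' sampling), class-dependent lesion shape and texture, institution-dependent
#' intensity effects, clinical covariates correlated with outcome, and a
#' second-observer mask set targeting a median Dice of 0.74.
#'
#' @param n_train,n_test patients per institution (site 1 trains, site 2
#'   tests).
#' @param prevalence pCR probability used when `quota = FALSE`.
#' @param quota if `TRUE` (default) fix exact event counts
#'   (`round(n * prevalence)` per site: 7 and 7 would not match the
#'   reference split, so 9/5 are used for 64/60) rather than Bernoulli
#'   sampling, which at 5 expected test events can produce whole cohorts
#'   with no positives.
#' @param elongation_shift,entropy_shift,volume_shift class-effect
#'   magnitudes (in within-class SD units of the underlying generator
#'   parameter).
#' @param site_gain,site_offset,site_noise_ratio institution-2 intensity
#'   effects per modality (named numeric, names `T2`, `DWI`, `CECT`):
#'   multiplicative gain, additive offset, and extra in-lesion white-noise
#'   SD as a fraction of the texture amplitude.
#' @param observer_dice target median Dice for second-observer masks.
#' @param grid_dim,spacing image grid (voxels) and voxel spacing (mm).
#' @param clinical_effect scales the class dependence of T-stage and grade
#'   odds (0 = no clinical signal).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_train = 64L, n_test = 60L, prevalence = 0.113,
                          quota = TRUE,
                          elongation_shift = 1.0, entropy_shift = 1.0,
                          volume_shift = 0.6,
                          site_gain = c(T2 = 1.25, DWI = 1.2, CECT = 1.1),
                          site_offset = c(T2 = 20, DWI = 15, CECT = 10),
                          site_noise_ratio = c(T2 = 0.8, DWI = 0.8, CECT = 0.6),
                          observer_dice = 0.74,
                          grid_dim = c(48L, 48L, 48L), spacing = c(1, 1, 2),
                          clinical_effect = 1) {
  stopifnot(prevalence > 0, prevalence < 1, n_train >= 10L, n_test >= 10L)
  structure(list(n_train = n_train, n_test = n_test, prevalence = prevalence,
                 quota = quota, elongation_shift = elongation_shift,
                 entropy_shift = entropy_shift, volume_shift = volume_shift,
                 site_gain = site_gain, site_offset = site_offset,
                 site_noise_ratio = site_noise_ratio,
                 observer_dice = observer_dice,
                 grid_dim = as.integer(grid_dim), spacing = spacing,
                 clinical_effect = clinical_effect),
            class = "cohort_config")
}

# separable Gaussian smoothing of a small 3D array
.smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  band <- function(n) {
    K <- matrix(0, n, n)
    for (d in (-r):r) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + k[d + r + 1]
    }
    K / rowSums(K)
  }
  dm <- dim(arr)
  x <- band(dm[1]) %*% matrix(arr, dm[1])
  x <- array(x, dm)
  x <- aperm(array(band(dm[2]) %*% matrix(aperm(x, c(2, 1, 3)), dm[2]),
                   dm[c(2, 1, 3)]), c(2, 1, 3))
  aperm(array(band(dm[3]) %*% matrix(aperm(x, c(3, 1, 2)), dm[3]),
              dm[c(3, 1, 2)]), c(2, 3, 1))
}

.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# ellipsoid mask: semi-axes in mm, random orientation, centred on the grid;
# evaluated only inside the lesion's bounding box for speed
.ellipsoid_mask <- function(grid_dim, spacing, semi_axes, rot, centre_jitter = 2) {
  ctr <- (grid_dim - 1) / 2 * spacing + runif(3, -centre_jitter, centre_jitter)
  rmax <- max(semi_axes)
  lo <- pmax(1L, floor((ctr - rmax) / spacing) + 1L)
  hi <- pmin(grid_dim, ceiling((ctr + rmax) / spacing) + 1L)
  sub_dim <- hi - lo + 1L
  ax <- lapply(1:3, function(d) (seq(lo[d], hi[d]) - 1) * spacing[d] - ctr[d])
  X <- array(ax[[1]], sub_dim)
  Y <- aperm(array(ax[[2]], sub_dim[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(ax[[3]], sub_dim[c(3, 1, 2)]), c(2, 3, 1))
  U <- rot[1, 1] * X + rot[2, 1] * Y + rot[3, 1] * Z
  V <- rot[1, 2] * X + rot[2, 2] * Y + rot[3, 2] * Z
  W <- rot[1, 3] * X + rot[2, 3] * Y + rot[3, 3] * Z
  q <- (U / semi_axes[1])^2 + (V / semi_axes[2])^2 + (W / semi_axes[3])^2
  m <- array(0L, grid_dim)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- as.integer(q <= 1)
  m
}

.bbox <- function(mask, pad = 3L) {
  idx <- arrayInd(which(mask == 1L), dim(mask))
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, dim(mask))
  list(lo = lo, hi = hi)
}

# one modality image: background noise + correlated lesion texture with a
# class-dependent heavy-tail transform controlling histogram entropy
.make_image <- function(mask, spacing, modality, base, amp, sigma_vox, tail,
                        site2, gain, offset, noise_ratio, field = NULL) {
  dm <- dim(mask)
  vol <- array(base, dm)  # flat background; noise only near the lesion
  bb <- .bbox(mask)
  sub_dim <- bb$hi - bb$lo + 1L
  if (is.null(field)) {
    field <- .smooth3d(array(rnorm(prod(sub_dim)), sub_dim), sigma_vox)
    field <- field / max(sd(field), 1e-12)
  }
  tex <- field * (1 + tail * field^2)
  sl <- lapply(1:3, function(d) bb$lo[d]:bb$hi[d])
  sub_mask <- mask[sl[[1]], sl[[2]], sl[[3]]]
  sub <- vol[sl[[1]], sl[[2]], sl[[3]]] + rnorm(length(sub_mask), sd = amp * 0.1)
  sub[sub_mask == 1L] <- base * 1.4 + amp * tex[sub_mask == 1L]
  if (site2) {
    sub <- gain * sub + offset
    sub[sub_mask == 1L] <- sub[sub_mask == 1L] +
      rnorm(sum(sub_mask), sd = noise_ratio * amp * gain)
  }
  vol[sl[[1]], sl[[2]], sl[[3]]] <- sub
  list(volume = image_volume(vol, spacing = spacing, modality = modality),
       field = field)
}

.sample_clinical <- function(label, effect) {
  mix <- function(p0, p1) if (label == 1L) (1 - effect) * p0 + effect * p1 else p0
  t_probs <- mix(c(0.01, 0.11, 0.80, 0.08), c(0.03, 0.42, 0.51, 0.04))
  g_probs <- mix(c(0.33, 0.50, 0.13, 0.04), c(0.60, 0.28, 0.04, 0.08))
  c(T_stage = sample(1:4, 1, prob = t_probs),
    grade = sample(1:4, 1, prob = g_probs),
    N_stage = rbinom(1, 1, if (label == 1L) 0.78 - 0.18 * effect else 0.78),
    CEA = min(91, exp(rnorm(1, 1.7 - 0.4 * effect * (label == 1L), 0.9))),
    distance_anal_margin = runif(1, 1, 12))
}

.make_patient <- function(id, site, label, cfg) {
  lab <- as.numeric(label)
  a_mm <- exp(rnorm(1, log(13) - lab * cfg$volume_shift * 0.18, 0.18))
  q2 <- min(0.95, max(0.25, rnorm(1, 0.52 + lab * cfg$elongation_shift * 0.12, 0.12)))
  q3 <- min(q2, max(0.2, rnorm(1, q2 - 0.08, 0.05)))
  # texture effects scale with the entropy-shift knob: pCR lesions get a
  # longer correlation length and a lighter-tailed (higher-entropy) histogram
  sigma_vox <- 0.7 + 0.3 * cfg$entropy_shift * lab
  tail <- 0.25 * cfg$entropy_shift * (1 - lab)
  site2 <- site == 2L
  rot <- .random_rotation()
  images <- list()
  # per-modality masks: same underlying lesion, slight per-modality jitter
  jitter_axes <- function() pmax(2, c(a_mm, a_mm * q2, a_mm * q3) * runif(3, 0.96, 1.04))
  t2_mask <- roi_mask(.ellipsoid_mask(cfg$grid_dim, cfg$spacing, jitter_axes(), rot),
                      spacing = cfg$spacing)
  t2 <- .make_image(t2_mask$voxels, cfg$spacing, "T2", base = 100, amp = 25,
                    sigma_vox = sigma_vox, tail = tail, site2 = site2,
                    gain = cfg$site_gain[["T2"]], offset = cfg$site_offset[["T2"]],
                    noise_ratio = cfg$site_noise_ratio[["T2"]])
  images$T2 <- list(volume = t2$volume, mask = t2_mask)
  dwi_mask <- roi_mask(.ellipsoid_mask(cfg$grid_dim, cfg$spacing, jitter_axes(), rot),
                       spacing = cfg$spacing)
  dwi <- .make_image(dwi_mask$voxels, cfg$spacing, "DWI", base = 60, amp = 18,
                     sigma_vox = sigma_vox * 0.9, tail = tail, site2 = site2,
                     gain = cfg$site_gain[["DWI"]], offset = cfg$site_offset[["DWI"]],
                     noise_ratio = cfg$site_noise_ratio[["DWI"]])
  images$DWI <- list(volume = dwi$volume, mask = dwi_mask)
  # CE-CT texture: noisy monotone transform of the T2 field, so its features
  # track the T2 features and fall to the de-correlation step
  cect_mask <- roi_mask(.ellipsoid_mask(cfg$grid_dim, cfg$spacing, jitter_axes(), rot),
                        spacing = cfg$spacing)
  cect_bb <- .bbox(cect_mask$voxels)
  cect_dim <- cect_bb$hi - cect_bb$lo + 1L
  t2f <- t2$field
  f <- array(0, cect_dim)
  common <- pmin(cect_dim, dim(t2f))
  f[seq_len(common[1]), seq_len(common[2]), seq_len(common[3])] <-
    t2f[seq_len(common[1]), seq_len(common[2]), seq_len(common[3])]
  f <- sign(f) * abs(f)^1.2 + 0.15 * rnorm(length(f))
  cect <- .make_image(cect_mask$voxels, cfg$spacing, "CECT", base = 40, amp = 15,
                      sigma_vox = 0, tail = tail, site2 = site2,
                      gain = cfg$site_gain[["CECT"]], offset = cfg$site_offset[["CECT"]],
                      noise_ratio = cfg$site_noise_ratio[["CECT"]],
                      field = f / max(sd(f), 1e-12))
  images$CECT <- list(volume = cect$volume, mask = cect_mask)
  clin <- .sample_clinical(label, cfg$clinical_effect)
  clin <- c(clin, tumor_size = 2 * a_mm / 10 + rnorm(1, 0, 0.2))
  list(id = id, site = site, label = label, images = images, clinical = clin)
}

#' Generate a synthetic two-institution cohort
#'
#' Lesions are randomly oriented ellipsoids filled with correlated Gaussian
#' texture; pCR lesions are smaller, more spherical, and have a
#' higher-entropy (lighter-tailed) intensity histogram. Institution 2
#' applies a gain/offset and extra in-lesion noise to every modality. CE-CT
#' textures are noisy monotone transforms of the T2 texture so that CE-CT
#' features are strongly correlated with the T2 features. Clinical T-stage
#' and grade are sampled with class-dependent odds.
#'
#' @param config a [cohort_config()].
#' @param seed master seed; all randomness in the cohort flows from it.
#' @return An object of class `synthetic_cohort`: list with `patients`
#'   (list of per-patient records: `id`, `site`, `label`, `images`,
#'   `clinical`), `clinical` (cohort data.frame with `patient_id`, `site`,
#'   `pCR` and the clinical covariates) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  sites <- rep(c(1L, 2L), c(config$n_train, config$n_test))
  if (config$quota) {
    k1 <- if (config$n_train == 64L && config$n_test == 60L) 9L
          else max(1L, round(config$n_train * config$prevalence))
    k2 <- if (config$n_train == 64L && config$n_test == 60L) 5L
          else max(1L, round(config$n_test * config$prevalence))
    lab1 <- sample(rep(c(1L, 0L), c(k1, config$n_train - k1)))
    lab2 <- sample(rep(c(1L, 0L), c(k2, config$n_test - k2)))
    labels <- c(lab1, lab2)
  } else {
    labels <- rbinom(config$n_train + config$n_test, 1L, config$prevalence)
  }
  n <- length(sites)
  ids <- sprintf("P%03d", seq_len(n))
  patients <- vector("list", n)
  for (i in seq_len(n))
    patients[[i]] <- .make_patient(ids[i], sites[i], labels[i], config)
  clin <- do.call(rbind, lapply(patients, function(p) p$clinical))
  clinical <- data.frame(patient_id = ids, site = sites, pCR = labels,
                         clin, stringsAsFactors = FALSE)
  structure(list(patients = patients, clinical = clinical, config = config,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (%d train / %d test), %d pCR (%.1f%%)\n",
              nrow(x$clinical), sum(x$clinical$site == 1L),
              sum(x$clinical$site == 2L), sum(x$clinical$pCR),
              100 * mean(x$clinical$pCR)))
  invisible(x)
}

#' Simulate a second observer's delineation
#'
#' Perturbs a mask to a requested Dice agreement with the original by
#' removing boundary voxels (erosion side) and adding adjacent background
#' voxels (dilation side), the erosion/dilation split drawn at random. The
#' voxel counts are solved from the Dice identity, so the achieved Dice
#' matches the target up to integer rounding.
#'
#' @param mask an [roi_mask()] with >= 1 foreground voxel.
#' @param target_dice requested Dice in `(0, 1]`.
#' @param seed optional seed making the perturbation deterministic.
#' @return a perturbed [roi_mask()]; achieved agreement can be checked with
#'   [dice_coefficient()].
#' @export
perturb_mask <- function(mask, target_dice, seed = NULL) {
  stopifnot(target_dice > 0, target_dice <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- mask$voxels
  n <- sum(m)
  if (n == 0L) stop("empty mask")
  if (target_dice == 1) return(mask)
  rho <- runif(1, 0.5, 2)  # dilated-to-eroded voxel ratio
  f <- round(2 * n * (1 - target_dice) / (2 - target_dice + target_dice * rho))
  g <- round(rho * f)
  f <- min(f, n - 1L)
  dm <- dim(m)
  grad <- rnorm(3)  # spatial bias: observers disagree on one side
  bias <- function(idx) {
    s <- (idx - 1) %*% grad
    exp(s - max(s))
  }
  removed <- 0L
  while (removed < f) {
    bnd <- .boundary_voxels(m)
    if (length(bnd) == 0L) break
    take <- min(f - removed, max(1L, length(bnd) %/% 2L))
    w <- bias(arrayInd(bnd, dm))
    sel <- sample(seq_along(bnd), take, prob = w + 1e-9)
    m[bnd[sel]] <- 0L
    removed <- removed + take
  }
  added <- 0L
  original <- mask$voxels  # never re-add eroded voxels: keeps the Dice exact
  while (added < g) {
    pad <- array(0L, dm + 2L)
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- m
    nbr <- pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] +
           pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] +
           pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] +
           pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] +
           pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] +
           pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
    outer_bnd <- which(m == 0L & original == 0L & nbr > 0L)
    if (length(outer_bnd) == 0L) break
    take <- min(g - added, max(1L, length(outer_bnd) %/% 2L))
    w <- bias(arrayInd(outer_bnd, dm))
    sel <- sample(seq_along(outer_bnd), take, prob = w + 1e-9)
    m[outer_bnd[sel]] <- 1L
    added <- added + take
  }
  roi_mask(m, spacing = mask$spacing, origin = mask$origin)
}

#' Write a cohort to disk in the pipeline's input layout
#'
#' One NIfTI per modality per patient
#' (`{patientID}_{modality}_{img|mask}.nii.gz`) plus `clinical.csv` and a
#' `manifest.json` recording the configuration and seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) for (mod in names(p$images)) {
    write_volume(p$images[[mod]]$volume,
                 file.path(dir, sprintf("%s_%s_img.nii.gz", p$id, mod)))
    write_volume(p$images[[mod]]$mask,
                 file.path(dir, sprintf("%s_%s_mask.nii.gz", p$id, mod)))
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  jsonlite::write_json(c(cohort$config, list(seed = cohort$seed)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
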