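#' Extract the per-image radiomic feature set
#'
#' Computes the 88-feature base catalog (15 shape + 11 intensity + 62
#' texture) for one volume/mask pair. Texture features are computed once per
#' discretization variant (default: linear and equalization schemes at
#' Nb = 32 and 64), intensity-histogram features once (linear, Nb = 64) and
#' shape features once, giving 15 + 11 + 62 x 4 = 274 named values.
#'
#' @param volume an [image_volume()].
#' @param mask the paired [roi_mask()].
#' @param specs named list of [discretization_spec()] variants for texture
#'   features; names become feature-name tags.
#' @return named numeric vector of length `15 + 11 + 62 * length(specs)`,
#'   names of the form `<family>_<feature>[_<tag>]`.
#' @export
extract_image <- function(volume, mask, specs = default_discretizations()) {
  validate_pair(volume, mask)
  roi <- roi_intensities(volume, mask)
  shp <- shape_features(mask, volume)
  names(shp) <- paste0("shape_", names(shp))
  ih <- intensity_features(roi$values)
  names(ih) <- paste0("intensity_", names(ih))
  bb <- .bbox(mask$voxels, pad = 0L)  # texture matrices only need the ROI box
  sub <- mask$voxels[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                     drop = FALSE]
  tex <- unlist(lapply(names(specs), function(tag) {
    spec <- specs[[tag]]
    lev <- array(0L, dim(sub))
    lev[sub == 1L] <- discretize(roi$values, spec)
    f <- texture_features(build_texture_matrices(lev, spec$n_bins))
    setNames(f, paste0(names(f), "_", tag))
  }))
  c(shp, ih, tex)
}

#' Extract the full multimodal feature vector for one patient
#'
#' Concatenates [extract_image()] output across the available modalities,
#' prefixing names with the modality, e.g. `T2__GLRLM_HGLRE_lin32`. With the
#' three modalities (T2, DWI, CE-CT) this yields 822 features per patient.
#'
#' @param images named list (names in `T2`, `DWI`, `CECT`) of
#'   `list(volume =, mask =)` pairs; at least one modality.
#' @param specs texture discretization variants, as in [extract_image()].
#' @return named numeric vector, 274 entries per modality.
#' @export
extract_patient <- function(images, specs = default_discretizations()) {
  if (length(images) == 0L) stop("at least one modality is required")
  if (is.null(names(images)) || !all(names(images) %in% MODALITIES))
    stop("images must be a named list with names among ",
         paste(MODALITIES, collapse = ", "))
  out <- unlist(lapply(names(images), function(mod) {
    f <- extract_image(images[[mod]]$volume, images[[mod]]$mask, specs)
    setNames(f, paste0(mod, "__", names(f)))
  }))
  if (anyDuplicated(names(out))) stop("duplicate feature names")
  out
}

#' Feature catalog metadata
#'
#' Parses generated feature names into provenance fields.
#'
#' @param feature_names character vector of names produced by
#'   [extract_patient()].
#' @return data.frame with columns `feature`, `modality`, `family`
#'   (shape/intensity/GLCM/GLRLM/GLSZM/NGTDM), `scheme` and `n_bins`
#'   (`"none"`/`NA` for shape and non-texture features).
#' @export
feature_catalog <- function(feature_names) {
  parts <- strsplit(feature_names, "__", fixed = TRUE)
  modality <- vapply(parts, `[`, "", 1L)
  rest <- vapply(parts, `[`, "", 2L)
  family <- sub("_.*$", "", rest)
  tag <- ifelse(grepl("_(lin|equ)(32|64)$", rest),
                sub("^.*_((lin|equ)(32|64))$", "\\1", rest), "none")
  n_bins <- rep(NA_integer_, length(tag))
  n_bins[tag != "none"] <- as.integer(sub("^(lin|equ)", "", tag[tag != "none"]))
  data.frame(feature = feature_names, modality = modality, family = family,
             scheme = ifelse(tag == "none", "none",
                             ifelse(grepl("^lin", tag), "linear", "equalization")),
             n_bins = n_bins, stringsAsFactors = FALSE)
}

#' Extract features for a whole cohort
#'
#' @param patients list of synthetic or loaded patients, each with `id` and
#'   `images` as accepted by [extract_patient()].
#' @param specs texture discretization variants.
#' @param verbose print progress every 25 patients.
#' @return data.frame: one row per patient, `patient_id` column plus one
#'   column per feature.
#' @export
extract_cohort <- function(patients, specs = default_discretizations(),
                           verbose = FALSE) {
  rows <- lapply(seq_along(patients), function(i) {
    if (verbose && i %% 25L == 0L) message("  extracted ", i, " patients")
    extract_patient(patients[[i]]$images, specs)
  })
  nm <- names(rows[[1]])
  stopifnot(all(vapply(rows, function(r) identical(names(r), nm), TRUE)))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(patient_id = vapply(patients, function(p) p$id, ""), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
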