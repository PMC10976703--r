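#' Reference-region specification
#'
#' The SUVr reference is the pons, either as the mean over the whole
#' pons label (`"label"`, the default for phantoms) or as the mean over
#' a mid-pons box: a cube of edge `box_edge_mm` centered at the pons
#' centroid and clipped to the pons mask (`"box"`, mirroring a 16 x 16 mm
#' mid-pons reference box; the slab thickness is completed symmetrically
#' to a cube).
#'
#' @param mode `"label"` or `"box"`.
#' @param box_edge_mm Edge length of the reference cube in mm
#'   (default 16).
#' @return A `reference_spec` list.
#' @export
reference_spec <- function(mode = c("label", "box"), box_edge_mm = 16) {
  mode <- match.arg(mode)
  stopifnot(box_edge_mm > 0)
  structure(list(mode = mode, box_edge_mm = box_edge_mm),
            class = "reference_spec")
}

#' Mean activity of the pons reference region
#'
#' @param volume A `pet_volume` of raw activity.
#' @param atlas The co-registered `label_atlas` (same grid and voxel
#'   size).
#' @param spec A [reference_spec()].
#' @return Positive scalar: mean voxel intensity over the reference
#'   voxels.
#' @export
extract_reference_mean <- function(volume, atlas, spec = reference_spec()) {
  stopifnot(inherits(volume, "pet_volume"), inherits(atlas, "label_atlas"),
            inherits(spec, "reference_spec"))
  check_geometry(volume, atlas)
  if (!"PONS" %in% names(atlas$label_map)) {
    stop("atlas has no PONS label; a pons reference region is required")
  }
  pons_mask <- atlas$labels == atlas$label_map[["PONS"]]
  if (!any(pons_mask)) stop("PONS region is empty in this atlas")
  if (spec$mode == "box") {
    idx <- which(pons_mask, arr.ind = TRUE)
    centroid <- colMeans(idx)
    half <- spec$box_edge_mm / 2
    in_box <- rep(TRUE, nrow(idx))
    for (ax in 1:3) {
      in_box <- in_box &
        abs(idx[, ax] - centroid[ax]) * volume$voxel_size_mm[ax] <= half
    }
    if (!any(in_box)) {
      stop("mid-pons reference box contains no pons voxels; ",
           "increase box_edge_mm or the pons extent")
    }
    ref <- mean(volume$intensities[idx[in_box, , drop = FALSE]])
  } else {
    ref <- mean(volume$intensities[pons_mask])
  }
  if (!is.finite(ref) || ref <= 0) {
    stop("reference mean is non-positive; cannot normalize to SUVr")
  }
  ref
}

#' Voxelwise SUVr volume
#'
#' Divides every voxel by the reference mean; the pons-label mean of the
#' result is 1 when the reference was the pons-label mean of the same
#' volume. SUVr is invariant to global rescaling of the raw activity.
#'
#' @param volume A `pet_volume` of raw activity.
#' @param reference_mean Positive scalar from
#'   [extract_reference_mean()].
#' @return A `pet_volume` holding SUVr values.
#' @export
compute_suvr_volume <- function(volume, reference_mean) {
  stopifnot(inherits(volume, "pet_volume"))
  if (!is.finite(reference_mean) || reference_mean <= 0) {
    stop("reference_mean must be a positive finite scalar")
  }
  pet_volume(volume$intensities / reference_mean, volume$voxel_size_mm)
}

#' Per-VOI mean SUVr
#'
#' Arithmetic mean of the SUVr voxels inside each of the seven named
#' VOIs; boundary voxels belong to the label stored in the atlas (no
#' partial-volume weighting).
#'
#' @param suvr_volume A `pet_volume` of SUVr values.
#' @param atlas The co-registered `label_atlas`.
#' @param subject_id Optional subject identifier carried into the
#'   output.
#' @param vois VOIs to aggregate (default the seven standard regions).
#' @return Tibble `subject_id`, `voi`, `mean_suvr`, `voxel_count`, one
#'   row per VOI.
#' @export
aggregate_vois <- function(suvr_volume, atlas, subject_id = NA_character_,
                           vois = voi_names()) {
  stopifnot(inherits(suvr_volume, "pet_volume"),
            inherits(atlas, "label_atlas"))
  check_geometry(suvr_volume, atlas)
  missing_voi <- setdiff(vois, names(atlas$label_map))
  if (length(missing_voi) > 0) {
    stop("atlas does not define VOI(s): ",
         paste(missing_voi, collapse = ", "))
  }
  rows <- lapply(vois, function(v) {
    mask <- atlas$labels == atlas$label_map[[v]]
    n <- sum(mask)
    if (n == 0) stop("VOI ", v, " has no voxels in this atlas")
    tibble::tibble(subject_id = subject_id, voi = v,
                   mean_suvr = mean(suvr_volume$intensities[mask]),
                   voxel_count = n)
  })
  dplyr::bind_rows(rows)
}

#' Full image-space SUVr measurement for one subject
#'
#' Convenience wrapper: reference extraction, SUVr normalization and VOI
#' aggregation in one call.
#'
#' @inheritParams extract_reference_mean
#' @inheritParams aggregate_vois
#' @return As [aggregate_vois()].
#' @export
measure_subject_suvr <- function(volume, atlas, subject_id = NA_character_,
                                 spec = reference_spec()) {
  ref <- extract_reference_mean(volume, atlas, spec)
  aggregate_vois(compute_suvr_volume(volume, ref), atlas, subject_id)
}
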