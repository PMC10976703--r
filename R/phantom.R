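#' Label atlas and PET volume containers
#'
#' Lightweight containers pairing a 3D grid with its voxel size and a
#' RAS+ diagonal affine. `label_atlas()` wraps an integer label grid with
#' a label-name map; `pet_volume()` wraps a non-negative activity (or
#' SUVr) grid. A volume and an atlas may only be combined when their grid
#' shapes and voxel sizes match; voxel indices are 1-based in R, world
#' coordinates are RAS+ with the first voxel at the origin.
#'
#' @param labels 3D integer array of region labels.
#' @param voxel_size_mm Numeric length-3, positive voxel edge lengths.
#' @param label_map Named integer vector mapping region name -> label.
#' @return An object of class `label_atlas` / `pet_volume`.
#' @export
label_atlas <- function(labels, voxel_size_mm, label_map) {
  stopifnot(length(dim(labels)) == 3, length(voxel_size_mm) == 3,
            all(voxel_size_mm > 0), !is.null(names(label_map)))
  structure(
    list(labels = labels,
         voxel_size_mm = as.numeric(voxel_size_mm),
         affine = diag(c(as.numeric(voxel_size_mm), 1)),
         label_map = label_map),
    class = "label_atlas"
  )
}

#' @rdname label_atlas
#' @param intensities 3D numeric array of non-negative voxel values.
#' @export
pet_volume <- function(intensities, voxel_size_mm) {
  stopifnot(length(dim(intensities)) == 3, length(voxel_size_mm) == 3,
            all(voxel_size_mm > 0))
  if (any(intensities < 0)) stop("PET intensities must be non-negative")
  structure(
    list(intensities = intensities,
         voxel_size_mm = as.numeric(voxel_size_mm),
         affine = diag(c(as.numeric(voxel_size_mm), 1))),
    class = "pet_volume"
  )
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("<label_atlas> ", paste(dim(x$labels), collapse = "x"),
      " voxels @ ", paste(x$voxel_size_mm, collapse = "x"), " mm\n", sep = "")
  counts <- atlas_region_sizes(x)
  for (nm in names(counts)) cat(sprintf("  %-13s %6d voxels\n", nm, counts[[nm]]))
  invisible(x)
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("<pet_volume> ", paste(dim(x$intensities), collapse = "x"),
      " voxels @ ", paste(x$voxel_size_mm, collapse = "x"),
      " mm, range [", signif(min(x$intensities), 4), ", ",
      signif(max(x$intensities), 4), "]\n", sep = "")
  invisible(x)
}

#' Region voxel counts of an atlas
#'
#' @param atlas A `label_atlas`.
#' @return Named integer vector of voxel counts per mapped region.
#' @export
atlas_region_sizes <- function(atlas) {
  stopifnot(inherits(atlas, "label_atlas"))
  vapply(atlas$label_map,
         function(l) sum(atlas$labels == l), integer(1))
}

check_geometry <- function(volume, atlas) {
  if (!identical(dim(volume$intensities), dim(atlas$labels)) ||
      !isTRUE(all.equal(volume$voxel_size_mm, atlas$voxel_size_mm))) {
    stop("volume and atlas geometry mismatch: grids and voxel sizes ",
         "must be identical")
  }
  invisible(TRUE)
}

#' Generate a deterministic block-layout brain phantom atlas
#'
#' Partitions the grid into a 3 x 3 x 2 lattice of cells and places one
#' rectangular region per assigned cell: the seven cortical VOIs plus a
#' pons block centered low and medial (so a mid-pons reference box fits),
#' everything else being background (label 0). The layout is a pure
#' function of the grid shape and voxel size, so identical inputs give
#' identical atlases.
#'
#' @param grid_shape Integer length-3 grid dimensions (default 64^3).
#' @param voxel_size_mm Voxel size in mm (default 2 mm isotropic).
#' @param fill_fraction Fraction of each lattice cell occupied by its
#'   region block (default 0.7).
#' @param min_pons_extent_mm Minimum in-plane pons extent; the pons block
#'   is enlarged to at least this so the reference box fits (default 18).
#' @return A `label_atlas` with regions FRONTAL, PARIETAL, MTL,
#'   LAT_TEMPORAL, PCC, PRECUNEUS, OCCIPITAL, PONS (labels 1-8) and
#'   BACKGROUND (0).
#' @export
generate_atlas_phantom <- function(grid_shape = c(64L, 64L, 64L),
                                   voxel_size_mm = c(2, 2, 2),
                                   fill_fraction = 0.7,
                                   min_pons_extent_mm = 18) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            fill_fraction > 0, fill_fraction <= 1)
  grid_shape <- as.integer(grid_shape)
  # cell assignment: (x-cell, y-cell, z-slab); y = posterior->anterior,
  # z = inferior->superior
  placement <- list(
    FRONTAL      = c(2, 3, 2),
    PARIETAL     = c(1, 2, 2),
    PRECUNEUS    = c(3, 2, 2),
    OCCIPITAL    = c(2, 1, 2),
    PCC          = c(2, 2, 2),
    MTL          = c(1, 3, 1),
    LAT_TEMPORAL = c(3, 3, 1),
    PONS         = c(2, 2, 1)
  )
  label_map <- c(FRONTAL = 1L, PARIETAL = 2L, MTL = 3L, LAT_TEMPORAL = 4L,
                 PCC = 5L, PRECUNEUS = 6L, OCCIPITAL = 7L, PONS = 8L,
                 BACKGROUND = 0L)
  ncell <- c(3L, 3L, 2L)
  cell_bounds <- lapply(1:3, function(ax) {
    cuts <- round(seq(0, grid_shape[ax], length.out = ncell[ax] + 1))
    cbind(lo = cuts[-length(cuts)] + 1, hi = cuts[-1])
  })
  labels <- array(0L, dim = grid_shape)
  for (region in names(placement)) {
    cell <- placement[[region]]
    rng <- lapply(1:3, function(ax) {
      b <- cell_bounds[[ax]][cell[ax], ]
      extent <- b["hi"] - b["lo"] + 1
      want <- max(1L, round(fill_fraction * extent))
      if (region == "PONS" && ax <= 2) {
        want <- max(want, ceiling(min_pons_extent_mm / voxel_size_mm[ax]))
      }
      if (want > extent) {
        stop("grid too small to place region ", region,
             ": need ", want, " voxels along axis ", ax,
             " but the lattice cell has only ", extent)
      }
      lo <- b["lo"] + floor((extent - want) / 2)
      lo:(lo + want - 1)
    })
    labels[rng[[1]], rng[[2]], rng[[3]]] <- label_map[[region]]
  }
  atlas <- label_atlas(labels, voxel_size_mm, label_map)
  sizes <- atlas_region_sizes(atlas)
  named <- setdiff(names(label_map), "BACKGROUND")
  if (any(sizes[named] == 0)) {
    stop("grid too small: region(s) ",
         paste(named[sizes[named] == 0], collapse = ", "), " are empty")
  }
  atlas
}

#' Render a synthetic PET activity volume for one subject
#'
#' Inverts the SUVr definition: each VOI is filled with
#' `suvr[voi] * pons_activity`, the pons with `pons_activity`, and the
#' background with `background_fraction * pons_activity`, then optional
#' multiplicative Gaussian voxel noise is applied. Running the rendered
#' volume through the SUVr pipeline therefore recovers the input values
#' (exactly at zero noise).
#'
#' @param subject_voi_suvr Named numeric: target SUVr per VOI; must cover
#'   every VOI named in the atlas (other than PONS/BACKGROUND).
#' @param atlas A `label_atlas`.
#' @param pons_activity Mean activity of the pons reference (default
#'   1000, arbitrary units).
#' @param noise_sd_fraction SD of the multiplicative voxel noise as a
#'   fraction of the local mean (>= 0; default 0).
#' @param seed Optional integer seed for the noise draw.
#' @param background_fraction Background activity as a fraction of the
#'   pons (default 0.25).
#' @return A `pet_volume` on the atlas geometry.
#' @export
render_pet_volume <- function(subject_voi_suvr, atlas,
                              pons_activity = 1000,
                              noise_sd_fraction = 0,
                              seed = NULL,
                              background_fraction = 0.25) {
  stopifnot(inherits(atlas, "label_atlas"), pons_activity > 0)
  if (noise_sd_fraction < 0) stop("noise_sd_fraction must be >= 0")
  vois <- setdiff(names(atlas$label_map), c("PONS", "BACKGROUND"))
  missing_voi <- setdiff(vois, names(subject_voi_suvr))
  if (length(missing_voi) > 0) {
    stop("missing SUVr value for VOI(s): ",
         paste(missing_voi, collapse = ", "))
  }
  act <- array(background_fraction * pons_activity, dim = dim(atlas$labels))
  for (v in vois) {
    act[atlas$labels == atlas$label_map[[v]]] <-
      subject_voi_suvr[[v]] * pons_activity
  }
  act[atlas$labels == atlas$label_map[["PONS"]]] <- pons_activity
  if (noise_sd_fraction > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    act <- act * (1 + rnorm(length(act), 0, noise_sd_fraction))
    act <- pmax(act, 0)
  }
  pet_volume(act, atlas$voxel_size_mm)
}

#' Read and write volumes and atlases as NIfTI-1
#'
#' Volumes are written as gzipped NIfTI-1 with the voxel size in the
#' header; an atlas additionally writes its label map to a JSON sidecar
#' (`<path>.labels.json`).
#'
#' @param volume A `pet_volume`; `atlas` a `label_atlas`.
#' @param path Output `.nii.gz` path.
#' @return The input, invisibly (writers); the reconstructed object
#'   (readers).
#' @export
write_pet_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- volume$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(volume)
}

#' @rdname write_pet_volume
#' @export
read_pet_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pet_volume(array(as.numeric(img), dim = dim(img)), RNifti::pixdim(img)[1:3])
}

#' @rdname write_pet_volume
#' @export
write_label_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "label_atlas"))
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- atlas$voxel_size_mm
  RNifti::writeNifti(img, path)
  jsonlite::write_json(as.list(atlas$label_map),
                       paste0(path, ".labels.json"), auto_unbox = TRUE)
  invisible(atlas)
}

#' @rdname write_pet_volume
#' @export
read_label_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  side <- paste0(path, ".labels.json")
  if (!file.exists(side)) stop("label map sidecar not found: ", side)
  lm <- unlist(jsonlite::read_json(side))
  storage.mode(lm) <- "integer"
  labels <- array(as.integer(img), dim = dim(img))
  label_atlas(labels, RNifti::pixdim(img)[1:3], lm)
}
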