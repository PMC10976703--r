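#' Build a VOI-level normative database from control measurements
#'
#' Per VOI: sample mean and sample SD (n - 1 denominator) of the control
#' subjects' mean SUVr, with the SD clamped below by `sd_floor` so
#' degenerate inputs never produce a zero divisor.
#'
#' @param control_measurements Tibble with columns `subject_id`, `voi`,
#'   `mean_suvr` (e.g. from [aggregate_vois()] or [cohort_suvr_long()]).
#' @param sd_floor Positive lower bound on the per-VOI SD (default
#'   1e-6).
#' @return A tibble of class `normative_db` with columns `voi`, `mu_db`,
#'   `sigma_db`, `n_controls`.
#' @export
build_normative_db <- function(control_measurements, sd_floor = 1e-6) {
  stopifnot(sd_floor > 0)
  need <- c("subject_id", "voi", "mean_suvr")
  if (!all(need %in% names(control_measurements))) {
    stop("control_measurements must have columns ",
         paste(need, collapse = ", "))
  }
  db <- control_measurements |>
    dplyr::group_by(.data$voi) |>
    dplyr::summarise(
      mu_db = mean(.data$mean_suvr),
      sigma_db = pmax(sd(.data$mean_suvr), sd_floor),
      n_controls = dplyr::n(),
      .groups = "drop"
    )
  if (any(db$n_controls < 2)) {
    stop("normative database requires at least 2 control subjects per ",
         "VOI; got n = ", min(db$n_controls),
         " — supply more controls (group_sizes['CN'] >= 2)")
  }
  structure(db, class = c("normative_db", class(db)),
            sd_floor = sd_floor)
}

#' Z-transform VOI measurements against a normative database
#'
#' Default orientation `"subject_minus_db"` gives
#' `z = (subject - mu_db) / sigma_db`, so hypometabolism (low uptake)
#' yields negative z and the `z < -2` rule flags it. Orientation
#' `"db_minus_subject"` returns the negation, matching the convention in
#' which the database mean is the minuend.
#'
#' @param measurements Tibble `subject_id`, `voi`, `mean_suvr`.
#' @param db A `normative_db` covering every VOI present.
#' @param orientation `"subject_minus_db"` (default) or
#'   `"db_minus_subject"`.
#' @return Tibble `subject_id`, `voi`, `z` (plus any extra columns of
#'   `measurements`, e.g. `group`).
#' @export
z_transform <- function(measurements, db,
                        orientation = c("subject_minus_db",
                                        "db_minus_subject")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(db, "normative_db"))
  missing_voi <- setdiff(unique(measurements$voi), db$voi)
  if (length(missing_voi) > 0) {
    stop("VOI(s) absent from normative database: ",
         paste(missing_voi, collapse = ", "))
  }
  out <- dplyr::left_join(measurements, db[, c("voi", "mu_db", "sigma_db")],
                          by = "voi")
  z <- (out$mean_suvr - out$mu_db) / out$sigma_db
  out$z <- if (orientation == "subject_minus_db") z else -z
  out$mu_db <- NULL
  out$sigma_db <- NULL
  out$mean_suvr <- NULL
  out
}

#' Build a voxelwise normative database
#'
#' Voxel-by-voxel mean and SD over a list of control SUVr volumes on a
#' common geometry, with the SD floored.
#'
#' @param suvr_volumes List of `pet_volume` SUVr volumes with identical
#'   geometry.
#' @param sd_floor Positive lower bound on the voxel SD (default 1e-6).
#' @return A list of class `voxel_normative_db`: `mu`, `sigma` (3D
#'   arrays), `n_controls`, `voxel_size_mm`.
#' @export
build_voxel_db <- function(suvr_volumes, sd_floor = 1e-6) {
  stopifnot(length(suvr_volumes) >= 2, sd_floor > 0)
  dims <- dim(suvr_volumes[[1]]$intensities)
  vox <- suvr_volumes[[1]]$voxel_size_mm
  mats <- vapply(suvr_volumes, function(v) {
    stopifnot(inherits(v, "pet_volume"))
    if (!identical(dim(v$intensities), dims) ||
        !isTRUE(all.equal(v$voxel_size_mm, vox))) {
      stop("all control volumes must share one geometry")
    }
    as.numeric(v$intensities)
  }, numeric(prod(dims)))
  mu <- rowMeans(mats)
  sigma <- pmax(apply(mats, 1, sd), sd_floor)
  structure(list(mu = array(mu, dims), sigma = array(sigma, dims),
                 n_controls = length(suvr_volumes), voxel_size_mm = vox),
            class = "voxel_normative_db")
}

#' Voxelwise Z map (and optional hypometabolism mask)
#'
#' @param suvr_volume A `pet_volume` of SUVr values on the database
#'   geometry.
#' @param voxel_db A `voxel_normative_db`.
#' @param orientation As in [z_transform()].
#' @param threshold Optional scalar; when given, a logical mask of
#'   voxels with `z < threshold` is returned alongside the map (the
#'   display convention for individual hypometabolism maps).
#' @return List with `z` (3D array), `voxel_size_mm`, and `mask`
#'   (logical 3D array or `NULL`).
#' @export
z_volume <- function(suvr_volume, voxel_db,
                     orientation = c("subject_minus_db",
                                     "db_minus_subject"),
                     threshold = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(suvr_volume, "pet_volume"),
            inherits(voxel_db, "voxel_normative_db"))
  if (!identical(dim(suvr_volume$intensities), dim(voxel_db$mu)) ||
      !isTRUE(all.equal(suvr_volume$voxel_size_mm,
                        voxel_db$voxel_size_mm))) {
    stop("SUVr volume and voxel database geometry mismatch")
  }
  z <- (suvr_volume$intensities - voxel_db$mu) / voxel_db$sigma
  if (orientation == "db_minus_subject") z <- -z
  mask <- if (!is.null(threshold)) z < threshold else NULL
  list(z = z, voxel_size_mm = suvr_volume$voxel_size_mm, mask = mask)
}

#' Serialize a VOI-level normative database to JSON
#'
#' @param db A `normative_db`.
#' @param path JSON file path.
#' @return `db` invisibly / the reconstructed `normative_db`.
#' @export
write_normative_db <- function(db, path) {
  stopifnot(inherits(db, "normative_db"))
  jsonlite::write_json(
    list(sd_floor = attr(db, "sd_floor"),
         entries = as.data.frame(db)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(db)
}

#' @rdname write_normative_db
#' @export
read_normative_db <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  db <- tibble::as_tibble(obj$entries)
  db$n_controls <- as.integer(db$n_controls)
  structure(db, class = c("normative_db", class(db)),
            sd_floor = obj$sd_floor)
}
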