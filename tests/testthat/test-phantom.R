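test_that("atlas phantom places all nine regions deterministically", {
  at <- generate_atlas_phantom(c(64L, 64L, 64L), c(2, 2, 2))
  sizes <- atlas_region_sizes(at)
  expect_length(sizes, 9)
  expect_true(all(sizes[setdiff(names(sizes), "BACKGROUND")] > 0))
  # labels mutually exclusive by construction; region + background = grid
  expect_equal(sum(sizes), 64^3)
  # pons hosts the 16 mm in-plane reference box
  pons <- which(at$labels == at$label_map[["PONS"]], arr.ind = TRUE)
  extent_mm <- (apply(pons, 2, max) - apply(pons, 2, min) + 1) *
    at$voxel_size_mm
  expect_true(all(extent_mm[1:2] >= 16))

  at2 <- generate_atlas_phantom(c(64L, 64L, 64L), c(2, 2, 2))
  expect_identical(at$labels, at2$labels)

  expect_error(generate_atlas_phantom(c(8L, 8L, 8L), c(2, 2, 2)),
               "grid too small")
})

test_that("rendering inverts the SUVr definition", {
  at <- small_atlas()
  # all SUVr 1, no noise: labeled tissue uniform at pons activity
  v1 <- render_pet_volume(uniform_suvr(1), at, pons_activity = 800,
                          noise_sd_fraction = 0)
  lab <- at$labels > 0
  expect_true(all(v1$intensities[lab] == 800))
  expect_true(all(v1$intensities[!lab] == 0.25 * 800))

  # region means equal suvr * pons activity before noise
  truth <- mci_c_true_suvr()
  v2 <- render_pet_volume(truth, at, pons_activity = 1000,
                          noise_sd_fraction = 0)
  mtl <- v2$intensities[at$labels == at$label_map[["MTL"]]]
  expect_equal(mean(mtl), truth[["MTL"]] * 1000, tolerance = 1e-12)
  expect_equal(unique(mtl), 910, tolerance = 1e-9)

  expect_error(render_pet_volume(truth[-3], at), "missing SUVr")
  expect_error(render_pet_volume(truth, at, noise_sd_fraction = -1),
               ">= 0")
})

test_that("noisy rendering hits region targets within Monte-Carlo error", {
  at <- small_atlas()
  truth <- uniform_suvr(1.2)
  v <- render_pet_volume(truth, at, pons_activity = 1000,
                         noise_sd_fraction = 0.05, seed = 42)
  for (r in c("MTL", "PCC", "PONS")) {
    vox <- v$intensities[at$labels == at$label_map[[r]]]
    target <- if (r == "PONS") 1000 else 1200
    se <- 0.05 * target / sqrt(length(vox))
    expect_lt(abs(mean(vox) - target), 3 * se)
  }
  # fixed seed reproduces the noise field
  v2 <- render_pet_volume(truth, at, pons_activity = 1000,
                          noise_sd_fraction = 0.05, seed = 42)
  expect_identical(v$intensities, v2$intensities)
})

test_that("round trip: rendered phantom recovers input SUVr end-to-end", {
  at <- small_atlas()
  truth <- mci_c_true_suvr()
  v0 <- render_pet_volume(truth, at, 1000, 0)
  m0 <- measure_subject_suvr(v0, at, "s1")
  expect_equal(setNames(m0$mean_suvr, m0$voi), truth, tolerance = 1e-12)

  v1 <- render_pet_volume(truth, at, 1000, 0.05, seed = 1)
  m1 <- measure_subject_suvr(v1, at, "s1")
  sizes <- atlas_region_sizes(at)
  se <- 0.05 * truth[m1$voi] *
    sqrt(1 / sizes[m1$voi] + 1 / sizes[["PONS"]])
  expect_true(all(abs(m1$mean_suvr - truth[m1$voi]) < 4 * se))
})

test_that("NIfTI round trip preserves volumes, atlases and label maps", {
  at <- generate_atlas_phantom(c(24L, 24L, 24L), c(3, 3, 3),
                               min_pons_extent_mm = 12)
  v <- render_pet_volume(uniform_suvr(1.1), at, 1000, 0.05, seed = 2)
  td <- withr::local_tempdir()
  pv <- file.path(td, "pet.nii.gz")
  pa <- file.path(td, "atlas.nii.gz")
  write_pet_volume(v, pv)
  write_label_atlas(at, pa)
  v2 <- read_pet_volume(pv)
  at2 <- read_label_atlas(pa)
  expect_equal(v2$intensities, v$intensities, tolerance = 1e-6)
  expect_equal(v2$voxel_size_mm, v$voxel_size_mm)
  expect_identical(at2$labels, at$labels)
  expect_equal(at2$label_map[names(at$label_map)], at$label_map)
})

test_that("geometry mismatches between volume and atlas are rejected", {
  at <- small_atlas()
  v <- pet_volume(array(1, dim = c(10, 10, 10)), c(2, 2, 2))
  expect_error(extract_reference_mean(v, at), "geometry mismatch")
  v2 <- pet_volume(array(1, dim = dim(at$labels)), c(1, 1, 1))
  expect_error(aggregate_vois(v2, at), "geometry mismatch")
  expect_error(pet_volume(array(-1, dim = c(2, 2, 2)), c(1, 1, 1)),
               "non-negative")
})
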