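test_that("radial placement families match their analytic laws", {
  # uniform over disk area: CDF(r) = r^2
  pos <- sample_radial_positions("uniform-disk", 1e5, seed = 42)
  r <- sqrt(rowSums(pos^2))
  expect_true(all(r <= 1))
  ks <- max(abs(sort(r)^2 - (seq_along(r) - 0.5) / length(r)))
  expect_lt(ks, 0.01)

  # peripheral shift moves the mean radius outward (common seed)
  r_unif <- sqrt(rowSums(sample_radial_positions("uniform-disk", 1e4, seed = 7)^2))
  r_shift <- sqrt(rowSums(sample_radial_positions(
    radial_density("peripheral-shifted", 2), 1e4, seed = 7)^2))
  expect_gt(mean(r_shift), mean(r_unif))

  expect_equal(nrow(sample_radial_positions("uniform-disk", 0, seed = 1)), 0L)
  expect_error(sample_radial_positions("banana-disk", 10, seed = 1), "family")
})

test_that("phantom rendering honors the noise-free intensity contract", {
  spec <- small_phantom_spec(seed = 3)
  ph <- make_phantom_cell(spec)
  truth_mask <- mask_from_voxels(ph$truth$voxel_union, dim(ph$stack))
  expect_true(all(ph$stack$data[truth_mask] == spec$signal_level))
  expect_true(all(ph$stack$data[!truth_mask] <= spec$background_level))
  # the nucleus is rendered darker than background
  expect_lt(min(ph$stack$data), spec$background_level)
})

test_that("phantom ground truth satisfies its geometric invariants", {
  spec <- small_phantom_spec(seed = 5)
  ph <- make_phantom_cell(spec)
  vox <- ph$truth$voxel_union
  ctr <- spec$nucleus_center
  vs <- spec$voxel_size
  dxy <- sqrt(((vox[, "y"] - ctr["y"]) * vs["y"])^2 +
                ((vox[, "x"] - ctr["x"]) * vs["x"])^2)
  d3 <- sqrt(dxy^2 + ((vox[, "z"] - ctr["z"]) * vs["z"])^2)
  expect_true(all(dxy <= spec$cell_radius))      # inside the cell cylinder
  expect_true(all(d3 > spec$nucleus_radius))     # outside the nucleus sphere
  expect_equal(max(ph$truth$norm_distances), 1)
  expect_equal(length(ph$truth$norm_distances), nrow(vox))

  # each rendered mitochondrion is one 26-connected piece, and distinct
  # mitochondria never touch
  for (mv in ph$truth$mito_voxels) {
    sub <- label_components_3d(mask_from_voxels(mv, dim(ph$stack)))
    expect_length(sub$components, 1L)
  }
  all_lab <- label_components_3d(truth_mask <- mask_from_voxels(vox, dim(ph$stack)))
  expect_length(all_lab$components, length(ph$truth$mito_voxels))
})

test_that("phantom generation is deterministic and handles the empty case", {
  spec <- small_phantom_spec(seed = 11)
  a <- make_phantom_cell(spec)
  b <- make_phantom_cell(spec)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$voxel_union, b$truth$voxel_union)

  empty <- make_phantom_cell(phantom_spec(stack_shape = c(5, 64, 64),
                                          cell_radius = 1.5, nucleus_radius = 0.3,
                                          n_mito = 0, seed = 1))
  expect_length(empty$truth$mito_voxels, 0L)
  expect_true(all(empty$stack$data <= 100))
})

test_that("noise models perturb intensities as advertised", {
  spec_g <- small_phantom_spec(seed = 2)
  spec_g$noise_model <- list(type = "gaussian", sd = 25)
  ph <- make_phantom_cell(spec_g)
  expect_true(all(ph$stack$data >= 0))
  bg <- ph$stack$data[ph$stack$data < 500]
  expect_gt(sd(bg), 5)

  spec_p <- small_phantom_spec(seed = 2)
  spec_p$noise_model <- list(type = "poisson")
  php <- make_phantom_cell(spec_p)
  sig <- php$stack$data[mask_from_voxels(php$truth$voxel_union, dim(php$stack))]
  expect_gt(sd(sig), 10)   # shot noise scales with intensity
  expect_true(all(php$stack$data == round(php$stack$data)))
})

test_that("phantom_spec validates degenerate geometry and intensities", {
  expect_error(phantom_spec(nucleus_radius = 9, cell_radius = 8), "degenerate")
  expect_error(phantom_spec(signal_level = 100, background_level = 100), "exceed")
  expect_error(phantom_spec(noise_model = "salt"), "unknown noise")
  expect_error(phantom_spec(n_mito = -1), "n_mito")
})

test_that("condition datasets are reproducible and annotated per cell", {
  spec <- small_phantom_spec(seed = 1)
  d1 <- make_condition_dataset(spec, n_cells = 3, seed = 50)
  d2 <- make_condition_dataset(spec, n_cells = 3, seed = 50)
  expect_identical(d1$annotations, d2$annotations)
  expect_identical(d1$cells[[2]]$stack$data, d2$cells[[2]]$stack$data)
  expect_equal(nrow(d1$annotations), 3L)
  expect_setequal(names(d1$annotations),
                  c("cell_id", "stack_path", "nucleus_z", "nucleus_y", "nucleus_x"))

  # on-disk variant: stacks + truth JSON + annotation CSV, stacks readable
  dir <- withr::local_tempdir()
  dd <- make_condition_dataset(spec, n_cells = 2, seed = 50, dir = dir)
  ann <- read.csv(file.path(dir, "annotations.csv"))
  expect_equal(nrow(ann), 2L)
  expect_true(all(file.exists(ann$stack_path)))
  back <- read_stack_tiff(ann$stack_path[1])
  expect_identical(back$data, round(dd$cells[[1]]$stack$data))
  expect_true(file.exists(file.path(dir, "cell_001_truth.json")))
})
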