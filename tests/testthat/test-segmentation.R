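test_that("preprocessing leaves constants unchanged and stays slice-wise", {
  const <- array(500, dim = c(3, 16, 16))
  out <- preprocess_stack(const, segmentation_config())
  expect_equal(out, const, tolerance = 1e-10)

  # a single bright voxel spreads only within its own slice
  spot <- array(0, dim = c(3, 31, 31))
  spot[2, 16, 16] <- 1000
  out <- preprocess_stack(spot, segmentation_config())
  expect_true(all(out[1, , ] == 0))
  expect_true(all(out[3, , ] == 0))
  expect_gt(sum(out[2, , ] > 0), 1)
})

test_that("Laplacian sharpening steepens edges beyond smoothing alone", {
  step <- array(0, dim = c(1, 32, 32))
  step[1, , 17:32] <- 1000
  smoothed <- preprocess_stack(step, segmentation_config(laplacian_weight = 0))
  sharpened <- preprocess_stack(step, segmentation_config(laplacian_weight = 1))
  grad <- function(a) max(abs(diff(t(a[1, , ])[, 16])))
  expect_gt(grad(sharpened), grad(smoothed))
})

test_that("binarization is strict and monotone in the threshold", {
  arr <- array(c(0, 749, 750, 751, 2000, 100), dim = c(1, 2, 3))
  mask <- binarize_stack(arr, 750)
  expect_identical(as.vector(mask), c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_true(all(binarize_stack(array(0, c(2, 4, 4)), 750) == FALSE))

  set.seed(1)
  noise <- array(runif(4 * 10 * 10, 0, 1000), dim = c(4, 10, 10))
  counts <- vapply(c(100, 300, 500, 700, 900),
                   function(th) sum(binarize_stack(noise, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("26-connectivity labeling matches the definition on corner cases", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- m[2, 2, 2] <- TRUE        # full-diagonal neighbors: one component
  expect_length(label_components_3d(m)$components, 1L)

  m2 <- array(FALSE, c(1, 1, 3))
  m2[1, 1, 1] <- m2[1, 1, 3] <- TRUE      # gap of one voxel: two components
  expect_length(label_components_3d(m2)$components, 2L)
})

test_that("labeling agrees with a brute-force flood fill on random masks", {
  set.seed(99)
  for (i in 1:30) {
    d <- c(sample(2:5, 1), sample(3:12, 1), sample(3:12, 1))
    mask <- array(runif(prod(d)) < runif(1, 0.2, 0.6), dim = d)
    cs <- label_components_3d(mask)
    expect_identical(component_set_signature(cs),
                     unname(partition_signature(oracle_flood_fill_26(mask))))
  }
})

test_that("size filtering uses exclusive bounds and is idempotent", {
  # components of sizes 125, 126, 99999 (approximated by runs), 1
  shape <- c(1, 1, 400)
  mk <- function(sizes) {
    comps <- list()
    pos <- 1L
    for (s in sizes) {
      comps[[length(comps) + 1L]] <-
        cbind(z = 1L, y = 1L, x = pos:(pos + s - 1L))
      pos <- pos + s + 1L
    }
    structure(list(components = comps, shape = c(1, 1, pos), config = NULL),
              class = "component_set")
  }
  cs <- mk(c(125, 126, 200, 1))
  kept <- filter_components(cs)
  expect_equal(component_sizes(kept), c(126, 200))
  expect_identical(filter_components(kept), kept)   # idempotent

  big <- mk(c(50, 60))
  expect_length(filter_components(big)$components, 0L)
  expect_error(filter_components(cs, 100, 100), "min_size_excl")
})

test_that("component stats report the mean size and a missing mean when empty", {
  cs <- structure(list(components = list(cbind(z = 1, y = 1, x = 1:200),
                                         cbind(z = 1, y = 2, x = 1:400)),
                       shape = c(1, 5, 500), config = NULL),
                  class = "component_set")
  st <- component_stats(cs)
  expect_equal(st$n_components, 2L)
  expect_equal(st$mean_component_size, 300)

  empty <- structure(list(components = list(), shape = c(1, 1, 1), config = NULL),
                     class = "component_set")
  st0 <- component_stats(empty)
  expect_equal(st0$n_components, 0L)
  expect_true(is.na(st0$mean_component_size))
})

test_that("noise-free phantoms are recovered exactly without smoothing and in count with it", {
  spec <- small_phantom_spec(seed = 7)
  ph <- make_phantom_cell(spec)
  truth_mask <- mask_from_voxels(ph$truth$voxel_union, dim(ph$stack))

  cs_raw <- segment_stack(ph$stack, segmentation_config(smooth = FALSE))
  expect_identical(mask_from_components(cs_raw), truth_mask)
  expect_equal(length(cs_raw$components), length(ph$truth$mito_voxels))

  cs_smooth <- segment_stack(ph$stack, segmentation_config())
  expect_equal(length(cs_smooth$components), length(ph$truth$mito_voxels))
  seg_mask <- mask_from_components(cs_smooth)
  jaccard <- sum(seg_mask & truth_mask) / sum(seg_mask | truth_mask)
  expect_gt(jaccard, 0.75)
})

test_that("segmentation_config validates its invariants", {
  expect_error(segmentation_config(gaussian_sigma = 0), "gaussian_sigma")
  expect_error(segmentation_config(threshold = -1), "threshold")
  expect_error(segmentation_config(min_size_excl = 10, max_size_excl = 10),
               "min_size_excl")
})
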