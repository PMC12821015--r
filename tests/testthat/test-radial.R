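cs_single <- function(vox, shape = c(21, 64, 64)) {
  structure(list(components = list(vox), shape = shape, config = NULL),
            class = "component_set")
}

test_that("pixel distances apply anisotropic physical scaling", {
  ctr <- c(10, 30, 30)
  # 3-4-5 triangle in-plane: 5 pixels * 0.0542 um
  cs <- cs_single(cbind(z = 10, y = 33, x = 34))
  expect_equal(compute_pixel_distances(cs, ctr), 5 * 0.0542)
  # one z-step is 0.2 um
  cs_z <- cs_single(cbind(z = 11, y = 30, x = 30))
  expect_equal(compute_pixel_distances(cs_z, ctr), 0.2)
  # coincident voxel
  expect_equal(compute_pixel_distances(cs_single(cbind(z = 10, y = 30, x = 30)), ctr), 0)
  # voxel units ignore the physical calibration
  expect_equal(compute_pixel_distances(cs_z, ctr, units = "voxel"), 1)
  # center outside bounds: error unless overridden
  expect_error(compute_pixel_distances(cs_z, c(40, 30, 30)), "outside")
  expect_warning(compute_pixel_distances(cs_z, c(40, 30, 30), allow_outside = TRUE),
                 "outside")
})

test_that("normalization rescales to max 1 and is scale invariant", {
  nd <- normalize_distances(c(0.271, 0.542, 1.084))
  expect_equal(nd$values, c(0.25, 0.5, 1.0))
  expect_equal(normalize_distances(3.7)$values, 1.0)
  for (k in c(0.01, 1, 250)) {
    expect_equal(normalize_distances(k * c(1, 2, 5))$values,
                 normalize_distances(c(1, 2, 5))$values)
  }
  expect_error(normalize_distances(numeric(0)), "empty")
  expect_error(normalize_distances(c(0, 0)), "degenerate")
})

test_that("pooling concatenates pixel-weighted and validates input", {
  a <- normalize_distances(c(0.5, 1), "a")
  b <- normalize_distances(1, "b")
  expect_equal(sort(pool_condition(list(a, b))), c(0.5, 1, 1))
  expect_equal(length(pool_condition(list(a, b, a))),
               sum(lengths(list(a$values, b$values, a$values))))
  expect_error(pool_condition(list()), "no cells")
  expect_error(pool_condition(list(1:3)), "normalized_distances")
})

test_that("peripheral subset takes the top fraction with tie inclusion", {
  pooled <- seq(0.1, 1.0, by = 0.1)
  expect_equal(sort(peripheral_subset(pooled, 0.3)), c(0.8, 0.9, 1.0))
  expect_equal(sort(peripheral_subset(pooled, 1)), pooled)
  expect_error(peripheral_subset(numeric(0)), "empty")
  expect_error(peripheral_subset(pooled, 0), "fraction")
  # ties at the cutoff are all included
  expect_equal(peripheral_subset(c(1, 1, 1, 0.2), 0.25), c(1, 1, 1))
  # subset minimum is at least the 70th percentile
  set.seed(4)
  x <- runif(1000)
  expect_gte(min(peripheral_subset(x, 0.3)), quantile(x, 0.7) - 1e-12)
})

test_that("KS statistic and p-values match definition and enumeration", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)

  disj <- ks_two_sample(1:3, 4:6)
  expect_equal(disj$D, 1)
  expect_equal(disj$p_value, 0.1)   # 2 of the C(6,3)=20 assignments reach D=1
  expect_equal(oracle_ks_exact_p(1:3, 4:6), 0.1)

  # symmetry
  set.seed(8)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  f <- ks_two_sample(x, y); g <- ks_two_sample(y, x)
  expect_equal(f$D, g$D)
  expect_equal(f$p_value, g$p_value)

  # implementation vs exhaustive enumeration on small random samples
  for (i in 1:12) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    x <- round(runif(n), 2); y <- round(runif(m), 2)
    expect_equal(ks_two_sample(x, y)$p_value, oracle_ks_exact_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "nonempty")
})

test_that("asymptotic p-value matches the Kolmogorov series at large n", {
  set.seed(21)
  x <- runif(300); y <- runif(280)
  res <- ks_two_sample(x, y)
  expect_identical(res$method, "asymptotic")
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE)$p.value)
  expect_equal(res$p_value, ref, tolerance = 1e-6)
})

test_that("radial histograms are density normalized over [0, 1]", {
  h <- radial_histogram(rep(1, 50), n_bins = 10)
  expect_equal(h$density[10], 10)
  expect_equal(sum(h$density[1:9]), 0)
  binw <- diff(h$bin_edges)
  expect_equal(sum(h$density * binw), 1)

  set.seed(31)
  hu <- radial_histogram(runif(1e5), n_bins = 10)
  expect_true(all(abs(hu$density - 1) < 0.1))
  expect_equal(sum(hu$density * diff(hu$bin_edges)), 1)

  expect_error(radial_histogram(c(0.5, 1.2)), "outside")
  expect_error(radial_histogram(0.5, n_bins = 1), "n_bins")
})
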