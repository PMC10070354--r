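test_that("global signal is the masked per-volume mean", {
  b <- tiny_bold(grid = c(3, 3, 3), n_t = 4, seed = 1)
  mask <- array(FALSE, c(3, 3, 3))
  mask[1, 1, 1] <- TRUE; mask[2, 1, 1] <- TRUE
  b$data[1, 1, 1, ] <- c(1, 2, 1, 2)
  b$data[2, 1, 1, ] <- c(3, 4, 3, 4)
  expect_equal(extract_global_signal(b, mask), c(2, 3, 2, 3))
  mask1 <- array(FALSE, c(3, 3, 3)); mask1[3, 2, 1] <- TRUE
  expect_equal(extract_global_signal(b, mask1), b$data[3, 2, 1, ])
  expect_error(extract_global_signal(b, array(FALSE, c(3, 3, 3))), "empty")
})

test_that("global signal equals a brute-force voxel loop", {
  b <- tiny_bold(grid = c(6, 5, 4), n_t = 25, seed = 3)
  mask <- withr::with_seed(4, array(runif(120) < 0.8, c(6, 5, 4)))
  gs <- extract_global_signal(b, mask)
  brute <- numeric(25)
  for (tt in 1:25) {
    acc <- c()
    for (i in 1:6) for (j in 1:5) for (k in 1:4)
      if (mask[i, j, k]) acc <- c(acc, b$data[i, j, k, tt])
    brute[tt] <- mean(acc)
  }
  expect_lt(max(abs(gs - brute)), 1e-12)
})

test_that("sphere masks match exhaustive distance enumeration", {
  grid <- c(11, 11, 11)
  affine <- diag(c(3, 3, 3, 1)); affine[1:3, 4] <- c(-15, -15, -15)
  roi <- roi_spec("test", c(0, 0, 0), 8)
  m <- sphere_mask(roi, grid, affine)
  brute <- array(FALSE, grid)
  for (i in 1:11) for (j in 1:11) for (k in 1:11) {
    xyz <- affine %*% c(i - 1, j - 1, k - 1, 1)
    brute[i, j, k] <- sqrt(sum((xyz[1:3] - roi$center)^2)) <= 8
  }
  expect_identical(m, brute)
  # sub-voxel radius centred on a voxel centre selects exactly that voxel
  tiny <- sphere_mask(roi_spec("pt", c(0, 0, 0), 1), grid, affine)
  expect_equal(sum(tiny), 1)
  expect_true(tiny[6, 6, 6])
  expect_error(sphere_mask(roi_spec("out", c(500, 0, 0), 8), grid, affine),
               "empty")
})

test_that("the six self-system spheres are nonempty and disjoint on a 3 mm grid", {
  layers <- default_self_layers()
  geom <- simulation_grid(layers, 3)
  for (lay in layers) for (roi in lay$rois)
    expect_gt(sum(sphere_mask(roi, geom$grid_dim, geom$affine)), 0)
  expect_silent(assert_disjoint_layers(layers, geom$grid_dim, geom$affine))
  # an artificial overlap is rejected
  clash <- c(layers, list(layer_definition("dup", list(
    roi_spec("dup", c(34, 14, 12), 8)))))
  expect_error(assert_disjoint_layers(clash, geom$grid_dim, geom$affine),
               "overlap")
})

test_that("layer time series equal the brute-force masked mean", {
  b <- tiny_bold(grid = c(12, 12, 12), n_t = 20, voxel = 3,
                 origin = c(-18, -18, -18), seed = 5)
  one <- layer_definition("one", list(roi_spec("a", c(0, 0, 0), 4)))
  m <- sphere_mask(one$rois[[1]], c(12, 12, 12), b$affine)
  ts1 <- layer_timeseries(b, one)
  expect_equal(ts1, colMeans(voxel_matrix(b)[as.vector(m), ]))
  # two disjoint single-voxel ROIs average the two series
  two <- layer_definition("two", list(roi_spec("p", c(0, 0, 0), 1),
                                      roi_spec("q", c(9, 9, 9), 1)))
  ts2 <- layer_timeseries(b, two)
  v1 <- b$data[7, 7, 7, ]; v2 <- b$data[10, 10, 10, ]
  expect_lt(max(abs(ts2 - (v1 + v2) / 2)), 1e-12)
})

test_that("compute_gscorr matches the explicit sum formula and clips at 1", {
  # orthogonal case
  g <- compute_gscorr(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(g$rho, 0)
  expect_equal(g$z, 0)
  # identity case: clipped, finite
  x <- rnorm(50)
  gi <- compute_gscorr(x, x)
  expect_equal(gi$rho, 1)
  expect_equal(gi$z, atanh(1 - 1e-12))
  expect_true(is.finite(gi$z))
  # sum-formula oracle, term by term
  sum_formula <- function(x, y) {
    n <- length(x)
    num <- n * sum(x * y) - sum(x) * sum(y)
    den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
    rho <- num / den
    list(rho = rho, z = 0.5 * log((1 + rho) / (1 - rho)))
  }
  o <- sum_formula(c(1, 2, 3, 4), c(1, 2, 3, 5))
  g2 <- compute_gscorr(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(g2$rho, o$rho, tolerance = 1e-12)
  expect_equal(g2$z, o$z, tolerance = 1e-12)
  withr::with_seed(8, for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    expect_equal(compute_gscorr(a, b)$z, sum_formula(a, b)$z,
                 tolerance = 1e-10)
  })
  expect_error(compute_gscorr(rep(1, 10), rnorm(10)), "constant")
  expect_error(compute_gscorr(rnorm(9), rnorm(10)), "lengths differ")
})

test_that("GSCORR is invariant to positive affine rescaling of the series", {
  withr::with_seed(10, { x <- rnorm(40); gs <- rnorm(40) })
  base <- compute_gscorr(x, gs)
  up <- compute_gscorr(3.7 * x + 2, gs)
  down <- compute_gscorr(-3.7 * x + 2, gs)
  expect_equal(up$z, base$z, tolerance = 1e-12)
  expect_equal(down$z, -base$z, tolerance = 1e-12)
})

test_that("parcel GSCORR maps match brute-force computation over 360 labels", {
  b <- tiny_bold(grid = c(12, 10, 9), n_t = 30, seed = 6)
  labels <- withr::with_seed(7,
    array(sample(0:360, 12 * 10 * 9, replace = TRUE), c(12, 10, 9)))
  gs <- extract_global_signal(b)
  tab <- parcel_gscorr_map(b, labels, gs)
  present <- sort(unique(as.vector(labels[labels != 0])))
  expect_equal(tab$region, present)
  lab_vec <- as.vector(labels)
  m <- voxel_matrix(b)
  for (lb in sample(present, 25)) {
    ts <- colMeans(m[lab_vec == lb, , drop = FALSE])
    expect_equal(tab$z[tab$region == lb], compute_gscorr(ts, gs)$z,
                 tolerance = 1e-12)
  }
  # a single label covering everything reproduces the GS itself
  all1 <- array(1L, c(12, 10, 9))
  t1 <- parcel_gscorr_map(b, all1, gs)
  expect_equal(t1$z, atanh(1 - 1e-12))
  # absent expected label warns and is skipped
  expect_warning(parcel_gscorr_map(b, labels, gs, expected_labels = 9999),
                 "absent")
})

test_that("every parcel is exactly orthogonal to the regressed global signal", {
  b <- tiny_bold(grid = c(8, 8, 8), n_t = 50, seed = 9)
  gs <- extract_global_signal(b)
  clean <- global_signal_regression(b, gs)
  labels <- withr::with_seed(2,
    array(sample(1:40, 512, replace = TRUE), c(8, 8, 8)))
  tab <- parcel_gscorr_map(clean, labels, gs)
  expect_lt(max(abs(tab$z)), 1e-8)
})
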