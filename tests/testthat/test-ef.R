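test_that("EF from semi-axes follows the rod/plate sign conventions", {
  expect_identical(ef_from_axes(1, 1, 1), 0)
  expect_equal(ef_from_axes(5, 5, 50), 0.9)
  expect_equal(ef_from_axes(5, 50, 50), -0.9)
  # the q-class a = qb = q^2 c is exactly EF 0 for any scale
  for (q in c(0.1, 0.35, 0.8, 1)) for (cc in c(1, 7, 120))
    expect_equal(ef_from_axes(q^2 * cc, q * cc, cc), 0)
  expect_error(ef_from_axes(0, 1, 1), "positive")
  expect_error(ef_from_axes(2, 1, 3), "a <= b <= c")
  # all EF values live in [-1, 1]
  set.seed(4)
  ax <- t(apply(matrix(runif(300, 0.1, 50), ncol = 3), 1, sort))
  ef <- ef_from_axes(ax[, 1], ax[, 2], ax[, 3])
  expect_true(all(ef >= -1 & ef <= 1))
})

test_that("medial seeds collapse to the center of a ball, the axis of a rod", {
  sph <- make_sphere(20, dims = c(51, 51, 51))
  s1 <- medial_seeds(sph)
  expect_true(all(sqrt(rowSums(sweep(unclass(s1)[, 1:3, drop = FALSE], 2,
                                     c(25.5, 25.5, 25.5))^2)) <= 2))
  cyl <- make_cylinder(5, dims = c(33, 33, 100))
  s2 <- medial_seeds(cyl)
  perp <- sqrt((s2[, 1] - 16.5)^2 + (s2[, 2] - 16.5)^2)
  expect_true(all(perp <= 1.5))
  expect_error(medial_seeds(voxel_image(array(0L, c(5, 5, 5)))),
               "no foreground")
  # the cap subsamples deterministically under the seed
  s3 <- medial_seeds(cyl, max_seeds = 10, seed = 7)
  s4 <- medial_seeds(cyl, max_seeds = 10, seed = 7)
  expect_identical(s3, s4)
  expect_equal(nrow(s3), 10)
})

test_that("maximal ellipsoid fits recover sphere, rod and slab geometry", {
  set.seed(11)
  sph <- make_sphere(20, dims = c(51, 51, 51))
  f1 <- fit_max_ellipsoid(sph, c(25.5, 25.5, 25.5))
  expect_true(all(abs(f1$semi_axes - 20) <= 1))
  expect_lt(abs(f1$ef), 0.1)
  cyl <- make_cylinder(5, dims = c(32, 32, 100))
  f2 <- fit_max_ellipsoid(cyl, c(16, 16, 50))
  expect_gte(f2$ef, 0.5)
  expect_true(all(abs(f2$semi_axes[1:2] - 5) <= 1))
  plt <- make_plate(10, dims = c(100, 100, 32))
  f3 <- fit_max_ellipsoid(plt, c(50, 50, 16))
  expect_lte(f3$ef, -0.5)
  expect_true(abs(f3$semi_axes[1] - 5) <= 1)
  expect_error(fit_max_ellipsoid(sph, c(1.5, 1.5, 1.5)), "background")
})

test_that("fit optimization is volume-monotone and seed-deterministic", {
  cyl <- make_cylinder(5, dims = c(32, 32, 64))
  set.seed(3)
  f1 <- fit_max_ellipsoid(cyl, c(16, 16, 32))
  expect_false(is.unsorted(f1$volumes))
  set.seed(3)
  f2 <- fit_max_ellipsoid(cyl, c(16, 16, 32))
  expect_identical(f1$semi_axes, f2$semi_axes)
  expect_identical(f1$center, f2$center)
  # orthonormal proper rotation
  QtQ <- t(f1$orientation) %*% f1$orientation
  expect_equal(QtQ, diag(3), tolerance = 1e-9)
  expect_gt(det(f1$orientation), 0)
  expect_true(all(diff(f1$semi_axes) >= 0))
})

test_that("EF map assigns the largest containing ellipsoid and tracks coverage", {
  sph <- make_sphere(20, dims = c(51, 51, 51))
  set.seed(5)
  fit <- fit_max_ellipsoid(sph, c(25.5, 25.5, 25.5))
  m <- compute_ef_map(sph, list(fit))
  expect_lt(abs(m$mean_ef - fit$ef), 1e-12)
  expect_lt(abs(m$mean_ef), 0.1)
  expect_gt(m$coverage, 0.9)
  expect_true(all(m$map[!is.na(m$map)] >= -1 & m$map[!is.na(m$map)] <= 1))
  # nested fits: contained voxels take the larger (prolate) ellipsoid's EF
  f_small <- structure(list(center = c(25.5, 25.5, 25.5), semi_axes = c(3, 3, 3),
                            orientation = diag(3),
                            volume = 4 / 3 * pi * 27, ef = 0),
                       class = "ellipsoid_fit")
  f_big <- structure(list(center = c(25.5, 25.5, 25.5), semi_axes = c(4, 4, 12),
                          orientation = diag(3),
                          volume = 4 / 3 * pi * 4 * 4 * 12,
                          ef = ef_from_axes(4, 4, 12)),
                     class = "ellipsoid_fit")
  m2 <- compute_ef_map(sph, list(f_small, f_big))
  expect_equal(m2$map[26, 26, 26], f_big$ef)
  expect_error(compute_ef_map(sph, list()), "no ellipsoid fits")
})

test_that("mean EF separates rod lattices from plate lattices by sign", {
  rods <- make_lattice(4, 0, 16, c(48, 48, 48))
  plates <- make_lattice(0, 8, 24, c(48, 48, 48))
  ef_r <- compute_ef(rods, max_seeds = 40, seed = 9)
  ef_p <- compute_ef(plates, max_seeds = 40, seed = 9)
  expect_gt(ef_r$mean_ef, 0.3)
  expect_lt(ef_p$mean_ef, -0.3)
})

test_that("mean EF is stable under stack translation and 90-degree rotation", {
  # a multi-element phantom seeded over its whole medial axis, so the mean
  # pools many independent fits and only re-fitting noise remains
  ph <- make_lattice(4, 3, 16, c(48, 48, 48))
  base <- compute_ef(ph, max_seeds = 2000, seed = 21)
  rot <- voxel_image(aperm(ph$data, c(3, 1, 2)), ph$spacing)  # 90 deg
  rt <- compute_ef(rot, max_seeds = 2000, seed = 21)
  expect_lt(abs(base$mean_ef - rt$mean_ef), 0.05)
  shifted <- array(0L, c(54, 54, 54))
  shifted[4:51, 2:49, 5:52] <- ph$data
  st <- compute_ef(voxel_image(shifted), max_seeds = 2000, seed = 21)
  expect_lt(abs(base$mean_ef - st$mean_ef), 0.05)
})
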