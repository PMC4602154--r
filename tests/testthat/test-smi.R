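test_that("mesh dilation: rigid translation of planes, analytic sphere offset", {
  plt <- marching_cubes(make_plate(8, dims = c(64, 64, 32)),
                        resample_factor = 1, smoothing = 0, boundary = "open")
  d <- dilate_mesh(plt, 2)
  expect_equal(face_areas(d), face_areas(plt), tolerance = 1e-12)
  # sphere offset: area ratio ((R + r) / R)^2
  sph <- marching_cubes(make_sphere(20, dims = c(51, 51, 51)),
                        resample_factor = 1, smoothing = 0.5,
                        smooth_iterations = 10)
  r <- 2
  ratio <- mesh_area(dilate_mesh(sph, r)) / mesh_area(sph)
  R_eff <- sqrt(mesh_area(sph) / (4 * pi))  # radius of the smoothed mesh
  expect_lt(abs(ratio - ((R_eff + r) / R_eff)^2), 0.005)
  expect_error(dilate_mesh(sph, 0), "positive")
  expect_error(dilate_mesh(sph, -1), "positive")
})

test_that("triangle deltas: zero on identity, positive on spheres, exact total", {
  sph <- marching_cubes(make_sphere(15, dims = c(40, 40, 40)),
                        resample_factor = 1, smoothing = 0.5,
                        smooth_iterations = 10)
  td0 <- triangle_deltas(sph, sph)
  expect_true(all(td0$delta == 0))
  expect_true(all(td0$class == "flat"))
  d <- dilate_mesh(sph, 0.01)
  td <- triangle_deltas(sph, d)
  # residual voxelization ripple leaves a minority of shrinking faces on any
  # discrete sphere; convex growth must dominate by area and in total
  expect_gt(sum(td$area[td$delta > 0]) / sum(td$area), 0.7)
  expect_gt(sum(td$delta), 0)
  expect_equal(sum(td$delta), mesh_area(d) - mesh_area(sph))
  # an exactly convex polyhedron grows on every face
  cube <- unit_cube_mesh()
  tdc <- triangle_deltas(cube, dilate_mesh(cube, 0.01))
  expect_true(all(tdc$delta > 0))
  bad <- triangle_mesh(sph$vertices, sph$faces[-1, , drop = FALSE],
                       clean = FALSE)
  expect_error(triangle_deltas(sph, bad), "identical face list")
})

test_that("torus concave-area fraction matches the analytic tube integral", {
  # fraction of torus area with negative mean curvature:
  # cos(theta) < -R / (2 rho), weighted by the area element (R + rho cos)
  rho <- 1; R <- 1.5 * rho
  f_num <- integrate(function(th) ifelse(cos(th) < -R / (2 * rho),
                                         R + rho * cos(th), 0), 0, 2 * pi)
  f_den <- integrate(function(th) R + rho * cos(th), 0, 2 * pi)
  frac_analytic <- f_num$value / f_den$value
  tor <- torus_mesh(R, rho, nu = 240, nv = 160)
  td <- triangle_deltas(tor, dilate_mesh(tor, 1e-4))
  frac_mesh <- sum(td$area[td$delta < 0]) / sum(td$area)
  expect_lt(abs(frac_mesh - frac_analytic), 0.02)
})

test_that("SMI partition identity holds on every phantom family", {
  imgs <- list(
    sphere = make_sphere(12, dims = c(34, 34, 34)),
    lattice = make_lattice(4, 3, 16, c(48, 48, 48)),
    pseudo = make_pseudo_trabecular(c(40, 40, 40), 0.4, 10, seed = 3))
  for (nm in names(imgs)) {
    res <- compute_smi(imgs[[nm]], resample_factor = 1, smoothing = 0.5)
    expect_lt(abs(res$smi - (res$smi_plus + res$smi_minus)),
              1e-9 * max(1, abs(res$smi)))
    expect_gte(res$smi_plus, 0)
    expect_lte(res$smi_minus, 0)
    expect_gte(res$cf, 0); expect_lte(res$cf, 1)
    # CF = 0 exactly when no face shrinks
    expect_identical(res$cf == 0, res$smi_minus == 0)
  }
})

test_that("SMI hits the defining values on sphere, cylinder and plate", {
  expect_equal(smi_phantom(make_sphere(40, dims = c(100, 100, 100)))$smi, 4,
               tolerance = 0.15 / 4)
  expect_equal(smi_phantom(make_cylinder(10, dims = c(64, 64, 128)),
                           "open")$smi, 3, tolerance = 0.15 / 3)
  plate <- smi_phantom(make_plate(8, dims = c(128, 128, 64)), "open")
  expect_lt(abs(plate$smi), 0.01)
  expect_identical(plate$cf, 0)
  expect_identical(plate$smi_minus, 0)
})

test_that("SMI is r-robust and scale invariant", {
  sph <- make_sphere(20, dims = c(51, 51, 51))
  a <- smi_phantom(sph)
  b <- do.call(compute_smi, c(list(img = sph, r = 0.0025),
                              phantom_smi_params))
  expect_lt(abs(a$smi - b$smi), 0.01)
  cyl <- make_cylinder(8, dims = c(40, 40, 60))
  a2 <- do.call(compute_smi, c(list(img = cyl, boundary = "open"),
                               phantom_smi_params))
  b2 <- do.call(compute_smi, c(list(img = cyl, r = 0.0025,
                                    boundary = "open"), phantom_smi_params))
  expect_lt(abs(a2$smi - b2$smi), 0.01)
  # dimensionless under uniform spacing change (r = "auto" scales along)
  sph2 <- voxel_image(sph$data, spacing = 7.66)
  c2 <- smi_phantom(sph2)
  expect_equal(c2$smi, a$smi, tolerance = 1e-6)
  expect_equal(c2$cf, a$cf, tolerance = 1e-12)
})

test_that("sphere SMI error is largest at the coarsest radius", {
  errs <- vapply(c(10, 20, 40), function(R)
    abs(smi_phantom(make_sphere(R, dims = rep(2 * R + 20, 3)))$smi - 4),
    numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[1])
  expect_true(all(errs < 0.15))
})

test_that("lattice junctions drive CF up; removing plates drives it down", {
  lat <- smi_phantom(make_lattice(5, 4, 24, c(72, 72, 72)))
  expect_gt(lat$cf, 0.02)
  rods <- do.call(compute_smi,
                  c(list(img = make_lattice(5, 0, 24, c(72, 72, 72)),
                         boundary = "open"), phantom_smi_params))
  expect_lt(rods$cf, lat$cf / 2)
})

test_that("curvature classes: spheres all convex, plates all flat, saddles blue", {
  sph <- compute_smi(make_sphere(15, dims = c(40, 40, 40)),
                     resample_factor = 1, smoothing = 0.5,
                     smooth_iterations = 10, keep_deltas = TRUE)
  cc <- classify_and_color(sph$deltas, sph$r)
  expect_gt(sum(sph$deltas$area[cc$class == "convex"]) / sph$S, 0.7)
  expect_gt(sph$smi_plus, 3 * abs(sph$smi_minus))
  expect_true(all(cc$colors[cc$class == "convex", 1] == 255L))
  plt <- compute_smi(make_plate(8, dims = c(64, 64, 32)),
                     resample_factor = 1, smoothing = 0, boundary = "open",
                     keep_deltas = TRUE)
  ccp <- classify_and_color(plt$deltas, plt$r)
  expect_true(all(ccp$class == "flat"))
  expect_true(all(ccp$colors == 255L))
  # the classes agree with a direct sign re-check of each delta
  lat <- compute_smi(make_lattice(5, 4, 24, c(72, 72, 72)),
                     resample_factor = 1, smoothing = 0.5,
                     smooth_iterations = 10, keep_deltas = TRUE)
  ccl <- classify_and_color(lat$deltas, lat$r)
  eps <- 1e-6
  rel <- lat$deltas$delta / (lat$r * lat$deltas$area)
  expect_identical(as.character(ccl$class),
                   ifelse(rel > eps, "convex",
                          ifelse(rel < -eps, "concave", "flat")))
  expect_true(any(ccl$class == "concave"))
  # colored export round-trips bit-exactly
  path <- withr::local_tempfile(fileext = ".ply")
  export_colored_mesh(lat$mesh, ccl$colors, path)
  expect_identical(read_ply(path)$face_colors, ccl$colors)
})
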