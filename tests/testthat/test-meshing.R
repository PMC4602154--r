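test_that("mesh primitives: areas and volume on hand-built meshes", {
  cube <- unit_cube_mesh()
  expect_equal(mesh_area(cube), 6)
  expect_equal(mesh_volume(cube), 1)
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(1:3, 1))
  expect_equal(mesh_area(tri), 0.5)
  expect_false(is_closed_mesh(tri))
  expect_error(mesh_volume(tri), "not closed")
})

test_that("area and volume scale as s^2 and s^3 under uniform scaling", {
  m <- marching_cubes(make_sphere(12, dims = c(34, 34, 34)),
                      resample_factor = 1, smoothing = 0)
  s <- 2.7
  ms <- triangle_mesh(m$vertices * s, m$faces, clean = FALSE)
  expect_equal(mesh_area(ms), s^2 * mesh_area(m), tolerance = 1e-12)
  expect_equal(mesh_volume(ms), s^3 * mesh_volume(m), tolerance = 1e-12)
})

test_that("capped marching extraction is closed, Euler-correct, deterministic", {
  sph <- make_sphere(15, dims = c(40, 40, 40))
  m <- marching_cubes(sph, resample_factor = 1, smoothing = 0)
  expect_true(is_closed_mesh(m))
  nV <- nrow(m$vertices); nF <- nrow(m$faces); nE <- 3L * nF / 2L
  expect_equal(nV - nE + nF, 2)  # genus-0 closed surface
  m2 <- marching_cubes(sph, resample_factor = 1, smoothing = 0)
  expect_identical(m$vertices, m2$vertices)
  expect_identical(m$faces, m2$faces)
})

test_that("sphere mesh area and volume approach the analytic values", {
  m <- marching_cubes(make_sphere(40, dims = c(100, 100, 100)),
                      resample_factor = 1, smoothing = 0.5,
                      smooth_iterations = 10)
  expect_lt(abs(mesh_area(m) - 4 * pi * 40^2) / (4 * pi * 40^2), 0.03)
  expect_lt(abs(mesh_volume(m) - 4 / 3 * pi * 40^3) / (4 / 3 * pi * 40^3),
            0.03)
})

test_that("open-boundary plate mesh is two parallel planar sheets", {
  m <- marching_cubes(make_plate(8, dims = c(64, 64, 32)),
                      resample_factor = 1, smoothing = 0, boundary = "open")
  fn <- face_cross(m)
  fn <- fn / sqrt(rowSums(fn^2))
  expect_true(all(abs(abs(fn[, 3]) - 1) < 1e-9))
  zs <- sort(unique(round(m$vertices[, 3], 6)))
  expect_length(zs, 2)
  # dilation translates the sheets rigidly, so every area is unchanged
  d <- dilate_mesh(m, 0.5)
  expect_equal(face_areas(d), face_areas(m), tolerance = 1e-12)
})

test_that("marching_cubes rejects empty or out-of-range iso input", {
  expect_error(marching_cubes(voxel_image(array(0L, c(5, 5, 5)))), "outside")
  low <- voxel_image(array(c(0L, 100L), c(6, 6, 6)))
  expect_error(marching_cubes(low, iso = 128), "outside")
})

test_that("smoothing: identity at 0, fixed plane interior, convex shrinkage", {
  m <- marching_cubes(make_sphere(12, dims = c(34, 34, 34)),
                      resample_factor = 1, smoothing = 0)
  expect_identical(smooth_mesh(m, 0), m)
  sm <- smooth_mesh(m, 0.5, 3)
  expect_identical(sm$faces, m$faces)
  expect_lt(mesh_volume(sm), mesh_volume(m))
  # interior vertices of a planar sheet stay in the plane
  plt <- marching_cubes(make_plate(6, dims = c(32, 32, 24)),
                        resample_factor = 1, smoothing = 0, boundary = "open")
  spl <- smooth_mesh(plt, 0.5, 5)
  expect_equal(sort(unique(round(spl$vertices[, 3], 6))),
               sort(unique(round(plt$vertices[, 3], 6))))
  expect_error(smooth_mesh(m, 1.5), "\\[0, 1\\]")
})

test_that("vertex normals are unit, outward-radial on spheres, flip with winding", {
  sph <- marching_cubes(make_sphere(15, dims = c(40, 40, 40)),
                        resample_factor = 1, smoothing = 0.5,
                        smooth_iterations = 10)
  vn <- vertex_normals(sph)
  expect_equal(unname(sqrt(rowSums(vn^2))), rep(1, nrow(vn)), tolerance = 1e-9)
  ctr <- matrix(20, nrow(sph$vertices), 3)
  rad <- sph$vertices - ctr
  rad <- rad / sqrt(rowSums(rad^2))
  dots <- rowSums(vn * rad)
  expect_gt(mean(dots), 0.99)   # residual extraction ripple bounds the min
  expect_gt(min(dots), 0.9)
  # on a regular parametric surface the normals match the analytic field
  tor <- torus_mesh(3, 1, nu = 120, nv = 60)
  vt <- vertex_normals(tor)
  ring <- tor$vertices
  rho_dir <- ring
  ring_xy <- ring[, 1:2] / sqrt(rowSums(ring[, 1:2]^2)) * 3
  rho_dir[, 1:2] <- ring[, 1:2] - ring_xy
  rho_dir <- rho_dir / sqrt(rowSums(rho_dir^2))
  expect_gt(min(abs(rowSums(vt * rho_dir))), 0.99)
  flipped <- triangle_mesh(sph$vertices, sph$faces[, c(1, 3, 2)],
                           clean = FALSE)
  expect_equal(vertex_normals(flipped), -vn, tolerance = 1e-12)
  # axis-aligned sheet: all normals equal the sheet normal
  plt <- marching_cubes(make_plate(6, dims = c(32, 32, 24)),
                        resample_factor = 1, smoothing = 0, boundary = "open")
  vnp <- vertex_normals(plt)
  expect_true(all(abs(abs(vnp[, 3]) - 1) < 1e-9))
})

test_that("PLY round-trips meshes and per-face colors in both formats", {
  m <- marching_cubes(make_sphere(8, dims = c(24, 24, 24)),
                      resample_factor = 1, smoothing = 0)
  cols <- matrix(as.integer((seq_len(3 * nrow(m$faces)) * 37) %% 256),
                 nrow(m$faces), 3)
  for (fmt in c("ascii", "binary_le")) {
    path <- withr::local_tempfile(fileext = ".ply")
    write_ply(m, path, format = fmt, face_colors = cols)
    back <- read_ply(path)
    expect_identical(back$mesh$faces, m$faces)
    expect_identical(back$face_colors, cols)  # colors are bit-exact
    expect_equal(back$mesh$vertices, m$vertices, tolerance = 1e-6)
  }
  # ascii and binary variants load to identical data
  p1 <- withr::local_tempfile(fileext = ".ply")
  p2 <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, p1, "ascii", cols); write_ply(m, p2, "binary_le", cols)
  a <- read_ply(p1); b <- read_ply(p2)
  expect_identical(a$face_colors, b$face_colors)
  expect_equal(a$mesh$vertices, b$mesh$vertices, tolerance = 1e-6)
  expect_error(export_colored_mesh(triangle_mesh(matrix(0, 1, 3),
                                                 matrix(integer(), 0, 3)),
                                   cols, tempfile()), "no faces")
})
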