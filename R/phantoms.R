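# Analytic binary phantoms. A voxel is foreground iff its CENTER satisfies
# the analytic inclusion test, so every phantom can be checked exactly by
# brute-force lattice enumeration. All phantoms use spacing = 1 (voxel units).

voxel_centers_1d <- function(n) seq_len(n) - 0.5  # 0-based index i -> i + 0.5

#' Solid sphere phantom
#'
#' A binary ball centered at the image-center point. Spheres are the SMI = 4
#' reference geometry.
#'
#' @param radius sphere radius, voxels; may be sub-voxel.
#' @param dims integer vector of length 3 (stack dims, voxels).
#' @param spacing voxel spacing to attach (default 1).
#' @return a binary [voxel_image].
#' @export
make_sphere <- function(radius, dims = rep(ceiling(2 * radius) + 11, 3),
                        spacing = 1) {
  dims <- as.integer(dims)
  if (radius <= 0) stop("radius must be positive")
  if (radius + 2 > min(dims) / 2)
    stop("sphere of radius ", radius, " does not fit in dims with 2-voxel margin")
  cx <- dims / 2
  dx2 <- (voxel_centers_1d(dims[1]) - cx[1])^2
  dy2 <- (voxel_centers_1d(dims[2]) - cx[2])^2
  dz2 <- (voxel_centers_1d(dims[3]) - cx[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  out <- array(0L, dims)
  out[d2 <= radius^2] <- 255L
  voxel_image(out, spacing)
}

#' Solid cylinder phantom
#'
#' A circular rod spanning the full image extent along `axis`, centered in the
#' perpendicular plane. Cylindrical rods are the SMI = 3 reference geometry.
#'
#' @param radius rod radius, voxels.
#' @param dims stack dims (length 3).
#' @param axis rod axis: `"x"`, `"y"` or `"z"` (default).
#' @param spacing voxel spacing (default 1).
#' @return a binary [voxel_image].
#' @export
make_cylinder <- function(radius, dims, axis = "z", spacing = 1) {
  dims <- as.integer(dims)
  ax <- axis_index(axis)
  if (radius <= 0) stop("radius must be positive")
  perp <- setdiff(1:3, ax)
  if (radius + 2 > min(dims[perp]) / 2)
    stop("cylinder of radius ", radius, " does not fit in the cross-section")
  c1 <- dims[perp[1]] / 2; c2 <- dims[perp[2]] / 2
  d2 <- outer((voxel_centers_1d(dims[perp[1]]) - c1)^2,
              (voxel_centers_1d(dims[perp[2]]) - c2)^2, `+`)
  disc <- d2 <= radius^2
  out <- array(0L, dims)
  idx <- which(disc, arr.ind = TRUE)
  for (k in seq_len(dims[ax])) {
    coords <- matrix(0L, nrow(idx), 3)
    coords[, perp[1]] <- idx[, 1]; coords[, perp[2]] <- idx[, 2]
    coords[, ax] <- k
    out[coords] <- 255L
  }
  voxel_image(out, spacing)
}

#' Flat plate phantom
#'
#' A slab of the given thickness, centered along `normal_axis` and spanning
#' the full extent of the other two axes. Flat plates are the SMI = 0
#' reference geometry.
#'
#' @param thickness slab thickness, voxels (integer).
#' @param dims stack dims (length 3).
#' @param normal_axis axis normal to the plate (default `"z"`).
#' @param spacing voxel spacing (default 1).
#' @return a binary [voxel_image].
#' @export
make_plate <- function(thickness, dims, normal_axis = "z", spacing = 1) {
  dims <- as.integer(dims)
  ax <- axis_index(normal_axis)
  thickness <- as.integer(thickness)
  if (thickness < 1) stop("thickness must be a positive integer")
  if (thickness > dims[ax]) stop("thickness exceeds the stack extent")
  lo <- (dims[ax] - thickness) %/% 2 + 1L
  sel <- lo:(lo + thickness - 1L)
  out <- array(0L, dims)
  if (ax == 1) out[sel, , ] <- 255L
  else if (ax == 2) out[, sel, ] <- 255L
  else out[, , sel] <- 255L
  voxel_image(out, spacing)
}

#' Rod-plate lattice phantom
#'
#' A union of parallel rods (along z) on a square (x, y) grid and parallel
#' plates normal to z on a regular grid, forming rod-plate junctions with
#' concave saddle regions, in the spirit of test stacks of intersecting rods
#' and plates. `plate_thickness = 0` gives a rods-only lattice (no junctions);
#' `rod_radius = 0` gives plates only.
#'
#' @param rod_radius rod radius, voxels (0 to omit rods).
#' @param plate_thickness plate thickness, voxels (0 to omit plates).
#' @param cell_spacing grid period, voxels; must exceed `2 * rod_radius` and
#'   `plate_thickness`.
#' @param dims stack dims (length 3).
#' @param spacing voxel spacing (default 1).
#' @return a binary [voxel_image].
#' @export
make_lattice <- function(rod_radius, plate_thickness, cell_spacing, dims,
                         spacing = 1) {
  dims <- as.integer(dims)
  if (rod_radius < 0 || plate_thickness < 0) stop("negative element size")
  if (rod_radius == 0 && plate_thickness == 0)
    stop("at least one of rods or plates must be present")
  if (rod_radius > 0 && cell_spacing < 2 * rod_radius)
    stop("cell_spacing must be at least 2 * rod_radius")
  if (plate_thickness > 0 && cell_spacing < plate_thickness)
    stop("cell_spacing must be at least plate_thickness")
  fg <- array(FALSE, dims)
  grid_pos <- function(n) {  # cell centers along an axis
    p <- seq(cell_spacing / 2, n, by = cell_spacing)
    p[p <= n]
  }
  if (rod_radius > 0) {
    xs <- voxel_centers_1d(dims[1]); ys <- voxel_centers_1d(dims[2])
    in_disc <- matrix(FALSE, dims[1], dims[2])
    for (gx in grid_pos(dims[1]))
      for (gy in grid_pos(dims[2]))
        in_disc <- in_disc | (outer((xs - gx)^2, (ys - gy)^2, `+`) <= rod_radius^2)
    fg <- fg | array(in_disc, dims)
  }
  if (plate_thickness > 0) {
    zs <- voxel_centers_1d(dims[3])
    in_slab <- rep(FALSE, dims[3])
    for (gz in grid_pos(dims[3]))  # half-open band -> exactly `thickness` layers
      in_slab <- in_slab |
        (zs - gz > -plate_thickness / 2 & zs - gz <= plate_thickness / 2)
    fg <- fg | array(rep(in_slab, each = dims[1] * dims[2]), dims)
  }
  out <- array(0L, dims)
  out[fg] <- 255L
  voxel_image(out, spacing)
}

#' Pseudo-trabecular noise phantom
#'
#' A connected two-phase structure obtained by thresholding a smooth, seeded
#' random field (coarse Gaussian noise, trilinearly upsampled) at the quantile
#' giving the requested bone volume fraction. Stands in for real trabecular
#' stacks in the resorption simulation: it has abundant concave junctions and
#' tunable BV/TV.
#'
#' @param dims stack dims (length 3).
#' @param target_bvtv requested foreground fraction, in (0, 1).
#' @param correlation_length feature length scale, voxels (default 16;
#'   elements are a little thinner than this scale).
#' @param seed RNG seed making the phantom reproducible.
#' @param spacing voxel spacing (default 1).
#' @return a binary [voxel_image] whose BV/TV is within 0.01 of the target.
#' @export
make_pseudo_trabecular <- function(dims, target_bvtv, correlation_length = 16,
                                   seed = 1, spacing = 1) {
  dims <- as.integer(dims)
  if (target_bvtv <= 0 || target_bvtv >= 1)
    stop("target_bvtv must lie strictly between 0 and 1")
  if (correlation_length < 2) stop("correlation_length must be >= 2")
  cdims <- pmax(2L, as.integer(ceiling(dims / correlation_length)) + 2L)
  field <- with_seed(seed, array(rnorm(prod(cdims)), cdims))
  up <- trilinear_upsample(field, dims, correlation_length)
  thr <- quantile(up, 1 - target_bvtv, names = FALSE)
  out <- array(0L, dims)
  out[up > thr] <- 255L
  got <- mean(out == 255L)
  if (abs(got - target_bvtv) > 0.01)
    stop("degenerate dims: achieved BV/TV ", round(got, 3),
         " misses target by more than 0.01")
  voxel_image(out, spacing)
}

# coarse grid node j (1-based) sits at coordinate (j - 1) * h in voxel units
trilinear_upsample <- function(coarse, dims, h) {
  pos <- lapply(1:3, function(ax) {
    x <- (voxel_centers_1d(dims[ax])) / h
    j <- pmin(floor(x) + 1L, dim(coarse)[ax] - 1L)
    list(j = j, f = x - (j - 1L))
  })
  out <- array(0, dims)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - pos[[1]]$f else pos[[1]]$f
    wy <- if (dy == 0) 1 - pos[[2]]$f else pos[[2]]$f
    wz <- if (dz == 0) 1 - pos[[3]]$f else pos[[3]]$f
    w <- outer(outer(wx, wy), wz)
    out <- out + w * coarse[pos[[1]]$j + dx, pos[[2]]$j + dy, pos[[3]]$j + dz]
  }
  out
}
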