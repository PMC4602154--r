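# Ellipsoid factor: medial-axis seeding, maximal inscribed ellipsoid fitting
# by stochastic dilation/rotation/translation, per-voxel assignment of the
# largest containing ellipsoid.

#' Ellipsoid factor from semi-axes
#'
#' `EF = a/b - b/c` for semi-axes `a <= b <= c`. Prolate (javelin, rod-like)
#' ellipsoids approach +1, oblate (discus, plate-like) ellipsoids approach
#' -1, and the q-class with `a = qb = q^2 c` (including spheres) gives 0.
#'
#' @param a,b,c semi-axes with `0 < a <= b <= c`; vectorized.
#' @return EF values in `[-1, 1]`.
#' @examples
#' ef_from_axes(1, 1, 1)    #  0 (sphere)
#' ef_from_axes(5, 5, 50)   #  0.9 (rod)
#' ef_from_axes(5, 50, 50)  # -0.9 (plate)
#' @export
ef_from_axes <- function(a, b, c) {
  if (any(a <= 0)) stop("semi-axes must be positive")
  if (any(a > b | b > c)) stop("semi-axes must satisfy a <= b <= c")
  a / b - b / c
}

#' Squared Euclidean distance transform
#'
#' Exact squared distance (voxel units) from each foreground voxel center to
#' the nearest background voxel center. The stack border is treated as
#' background, matching the erosion border policy.
#'
#' @param img binary [voxel_image].
#' @return a 3-D numeric array of squared distances (0 on background).
#' @export
distance_transform_sq <- function(img) {
  img <- as_voxel_image(img)
  stopifnot_binary(img)
  d <- dim(img$data)
  fg <- array(FALSE, d + 2L)
  fg[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- img$data == 255
  out <- cpp_sqedt(fg)
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
}

#' Medial-axis seed points
#'
#' Ridge of the exact Euclidean distance transform: foreground voxels whose
#' distance value is a 26-neighborhood local maximum, followed by
#' maximal-ball containment suppression (a candidate is dropped when another
#' candidate's inscribed ball covers its own). This is the medial axis in the
#' maximal-inscribed-ball sense: the ball of a sphere collapses to its
#' center, a cylinder's ridge is its axis. If more than `max_seeds` survive,
#' a seeded random subsample is returned.
#'
#' @param img binary [voxel_image] with foreground.
#' @param max_seeds cap on the number of seeds (default 1000).
#' @param seed RNG seed for the subsample (default 1).
#' @return a matrix of seed points (voxel-center coordinates, voxel units,
#'   one row per seed) with the inscribed-ball radius as attribute
#'   `"radius"`.
#' @export
medial_seeds <- function(img, max_seeds = 1000L, seed = 1L) {
  img <- as_voxel_image(img)
  stopifnot_binary(img)
  if (!any(img$data == 255)) stop("image has no foreground")
  d2 <- distance_transform_sq(img)
  d <- dim(d2)
  pad <- array(-1, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- d2
  core <- function(dx, dy, dz)
    pad[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dz,
        drop = FALSE]
  is_max <- d2 > 0
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    is_max <- is_max & (d2 >= core(dx, dy, dz))
  }
  idx <- which(is_max, arr.ind = TRUE)
  r <- sqrt(d2[is_max])
  # canonical, axis-permutation-invariant candidate order (largest ball
  # first, ties broken by the elementary symmetric functions of the
  # coordinates) so that subsampling does not depend on stack orientation
  s1 <- rowSums(idx)
  s2 <- idx[, 1] * idx[, 2] + idx[, 2] * idx[, 3] + idx[, 1] * idx[, 3]
  s3 <- idx[, 1] * idx[, 2] * idx[, 3]
  can <- order(-r, s1, s2, s3)
  idx <- idx[can, , drop = FALSE]; r <- r[can]
  # plateau-heavy ridges (plates) can yield tens of thousands of candidates;
  # pre-thin with a seeded subsample before the quadratic suppression pass
  cap0 <- max(5000L, 4L * max_seeds)
  if (nrow(idx) > cap0) {
    pick <- sort(with_seed(seed, sample.int(nrow(idx), cap0)))
    idx <- idx[pick, , drop = FALSE]; r <- r[pick]
  }
  # containment suppression: drop x if some larger ball covers x's ball
  keep <- rep(TRUE, length(r))
  for (i in seq_along(r)) {
    if (!keep[i]) next
    if (i == length(r)) break
    later <- (i + 1):length(r)
    cand <- later[keep[later] & r[later] < r[i]]
    if (!length(cand)) next
    dist <- sqrt(rowSums((idx[cand, , drop = FALSE] -
                          matrix(idx[i, ], length(cand), 3, byrow = TRUE))^2))
    keep[cand[dist + r[cand] <= r[i] + 0.5]] <- FALSE
  }
  idx <- idx[keep, , drop = FALSE]; r <- r[keep]
  if (nrow(idx) > max_seeds) {
    pick <- with_seed(seed, sample.int(nrow(idx), max_seeds))
    idx <- idx[pick, , drop = FALSE]; r <- r[pick]
  }
  pts <- idx - 0.5  # 1-based index -> voxel-center coordinate
  colnames(pts) <- c("x", "y", "z")
  attr(pts, "radius") <- r
  pts
}

#' Fit a maximal inscribed ellipsoid at a seed point
#'
#' Starting from a small sphere at the seed, the ellipsoid is iteratively
#' dilated (one random semi-axis at a time), rotated and translated slightly;
#' a proposal is accepted when a fixed quasi-uniform field of surface sample
#' points stays inside the foreground, the seed stays inside the ellipsoid,
#' and the volume does not decrease. The climb stops after `max_rejects`
#' consecutive rejected proposals. Uses R's RNG, so results are reproducible
#' under [set.seed()].
#'
#' @param img binary [voxel_image].
#' @param seed_point numeric length-3 foreground point (voxel units).
#' @param start_radius starting sphere radius, voxels (default 1; halved
#'   automatically in very thin structures).
#' @param dilation_step semi-axis growth per accepted dilation, voxels
#'   (default 0.5).
#' @param max_rotation largest proposal rotation, radians (default 5 degrees).
#' @param max_translation largest per-axis proposal shift, voxels (0.5).
#' @param n_surface_points surface sample points for the containment check
#'   (default 100).
#' @param max_rejects consecutive rejections that end the climb (default 100).
#' @param refine_phases after the climb stalls, number of refinement phases
#'   that re-approach the boundary with a 4x finer dilation step (default 1).
#' @param max_iter hard cap on proposals (default 10000).
#' @return an object of class `ellipsoid_fit`: `center`, sorted `semi_axes`
#'   `(a <= b <= c)`, `orientation` (rotation matrix, columns = axes),
#'   `volume`, `ef`, and the accepted `volumes` trace.
#' @export
fit_max_ellipsoid <- function(img, seed_point, start_radius = 1,
                              dilation_step = 0.5,
                              max_rotation = 5 * pi / 180,
                              max_translation = 0.5,
                              n_surface_points = 100L, max_rejects = 100L,
                              refine_phases = 1L, max_iter = 10000L) {
  img <- as_voxel_image(img)
  stopifnot_binary(img)
  seed_point <- as.numeric(seed_point)
  vi <- floor(seed_point) + 1L
  d <- dim(img$data)
  if (any(vi < 1L) || any(vi > d) || img$data[vi[1], vi[2], vi[3]] != 255)
    stop("seed point lies in the background")
  fg <- img$data == 255
  raw <- cpp_fit_ellipsoid(fg, seed_point, start_radius, dilation_step,
                           max_rotation, max_translation,
                           as.integer(n_surface_points),
                           as.integer(max_rejects), as.integer(max_iter),
                           as.integer(refine_phases))
  ord <- order(raw$semi_axes)
  axes <- raw$semi_axes[ord]
  Q <- raw$orientation[, ord, drop = FALSE]
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]  # keep a proper rotation
  structure(list(center = raw$center, semi_axes = axes, orientation = Q,
                 volume = 4 / 3 * pi * prod(axes),
                 ef = ef_from_axes(axes[1], axes[2], axes[3]),
                 volumes = raw$volumes, iterations = raw$iterations),
            class = "ellipsoid_fit")
}

#' @export
print.ellipsoid_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipsoid_fit> a,b,c = %.2f, %.2f, %.2f  EF = %.3f  volume = %.1f\n",
    x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], x$ef, x$volume))
  invisible(x)
}

#' Per-voxel EF map from a set of ellipsoid fits
#'
#' Each foreground voxel takes the EF of the largest-volume fitted ellipsoid
#' that contains its center; voxels contained by no ellipsoid stay
#' unassigned (NA) and are reported through the coverage fraction.
#'
#' @param img binary [voxel_image].
#' @param fits list of [fit_max_ellipsoid()] results.
#' @return an object of class `ef_map`: `map` (3-D array, NA where
#'   unassigned or background), `mean_ef` over assigned voxels, `coverage`
#'   (assigned / foreground), `n_foreground`, `fits`.
#' @export
compute_ef_map <- function(img, fits) {
  img <- as_voxel_image(img)
  stopifnot_binary(img)
  if (!length(fits)) stop("no ellipsoid fits supplied")
  d <- dim(img$data)
  fg_idx <- which(img$data == 255, arr.ind = TRUE)
  pts <- fg_idx - 0.5
  ef_vals <- rep(NA_real_, nrow(pts))
  vols <- vapply(fits, `[[`, numeric(1), "volume")
  for (fi in order(vols, decreasing = TRUE)) {
    un <- which(is.na(ef_vals))
    if (!length(un)) break
    fit <- fits[[fi]]
    rel <- sweep(pts[un, , drop = FALSE], 2, fit$center)
    y <- rel %*% fit$orientation  # body-frame coordinates
    inside <- (y[, 1] / fit$semi_axes[1])^2 + (y[, 2] / fit$semi_axes[2])^2 +
      (y[, 3] / fit$semi_axes[3])^2 <= 1
    ef_vals[un[inside]] <- fit$ef
  }
  map <- array(NA_real_, d)
  map[fg_idx] <- ef_vals
  structure(list(map = map, mean_ef = mean(ef_vals, na.rm = TRUE),
                 coverage = mean(!is.na(ef_vals)),
                 n_foreground = nrow(pts), fits = fits),
            class = "ef_map")
}

#' @export
print.ef_map <- function(x, ...) {
  cat(sprintf("<ef_map> mean EF = %.3f over %.1f%% of %d foreground voxels (%d fits)\n",
              x$mean_ef, 100 * x$coverage, x$n_foreground, length(x$fits)))
  invisible(x)
}

#' End-to-end ellipsoid factor measurement
#'
#' Seeds ellipsoids on the medial axis, fits a maximal inscribed ellipsoid at
#' each seed, and assigns each foreground voxel the EF of the largest
#' containing ellipsoid.
#'
#' @param img binary [voxel_image] with foreground.
#' @param max_seeds cap on medial seeds (default 1000).
#' @param seed RNG seed for the whole run (subsampling + stochastic fits).
#' @param ... further arguments passed to [fit_max_ellipsoid()].
#' @return an [compute_ef_map()] result (class `ef_map`).
#' @export
compute_ef <- function(img, max_seeds = 1000L, seed = 42L, ...) {
  img <- as_voxel_image(img)
  seeds <- medial_seeds(img, max_seeds = max_seeds, seed = seed)
  # every fit runs on its own substream derived from the run seed and the
  # seed-point location relative to the foreground bounding box (symmetric
  # in the coordinates), so results do not depend on enumeration order and
  # are stable under axis permutations and whole-voxel translations
  fg_idx <- which(img$data == 255, arr.ind = TRUE)
  origin <- apply(fg_idx, 2, min) - 0.5
  fits <- lapply(seq_len(nrow(seeds)), function(i) {
    with_seed(seed_point_hash(seed, as.numeric(seeds[i, ]) - origin),
              fit_max_ellipsoid(img, seeds[i, ], ...))
  })
  compute_ef_map(img, fits)
}

seed_point_hash <- function(seed, p) {
  s <- sort(round(2 * as.numeric(p)))
  as.integer((as.numeric(seed) + s[1] * 73856 + s[2] * 19349 +
              s[3] * 83492) %% 2147483647)
}
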