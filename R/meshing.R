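#' Indexed triangle mesh
#'
#' Vertices are 3-D points in physical units (micrometres); faces are triples
#' of vertex indices with consistent outward winding. Construction drops
#' degenerate (zero-area) faces, merges duplicate vertices, and removes
#' unreferenced vertices.
#'
#' @param vertices numeric `n x 3` matrix.
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @param clean drop degenerate faces / merge duplicate vertices (default TRUE).
#' @return an object of class `triangle_mesh` with fields `vertices`, `faces`.
#' @export
triangle_mesh <- function(vertices, faces, clean = TRUE) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("`faces` must be an m x 3 matrix")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face index out of range")
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (clean && nrow(faces)) mesh <- clean_mesh(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

clean_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  # merge vertices that coincide within 1e-9 of the coordinate scale
  scale <- max(1, max(abs(v)))
  q <- round(v / (scale * 1e-9))
  ord <- do.call(order, list(q[, 1], q[, 2], q[, 3]))
  qs <- q[ord, , drop = FALSE]
  new_grp <- c(TRUE, rowSums(qs[-1, , drop = FALSE] !=
                             qs[-nrow(qs), , drop = FALSE]) > 0)
  grp <- cumsum(new_grp)             # group id per sorted row
  first_sorted <- ord[!duplicated(grp)]  # representative per group
  first <- integer(nrow(v)); first[ord] <- first_sorted[grp]
  if (any(first != seq_along(first))) {
    keep <- sort(unique(first))
    remap <- match(first, keep)
    v <- v[keep, , drop = FALSE]
    f[] <- remap[f]
  }
  a <- face_areas(list(vertices = v, faces = f))
  f <- f[a > max(a, 0) * 1e-12 & a > 0, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  if (length(used) < nrow(v)) {
    remap <- integer(nrow(v)); remap[used] <- seq_along(used)
    v <- v[used, , drop = FALSE]
    f[] <- remap[f]
  }
  structure(list(vertices = v, faces = f), class = "triangle_mesh")
}

face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

#' Per-face areas of a triangle mesh
#' @param mesh a [triangle_mesh].
#' @return numeric vector of triangle areas.
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area
#' @param mesh a [triangle_mesh].
#' @return the sum of all triangle areas.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron sum (divergence theorem). Errors if the mesh is not
#' closed (some edge not shared by exactly two opposed faces).
#'
#' @param mesh a closed [triangle_mesh] with outward winding.
#' @return enclosed volume (positive for outward-wound meshes).
#' @export
mesh_volume <- function(mesh) {
  if (!is_closed_mesh(mesh))
    stop("mesh is not closed: enclosed volume is undefined")
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Is every edge shared by exactly two opposed faces?
#' @param mesh a [triangle_mesh].
#' @return logical scalar.
#' @export
is_closed_mesh <- function(mesh) {
  f <- mesh$faces
  if (!nrow(f)) return(FALSE)
  n <- nrow(mesh$vertices)
  he <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  storage.mode(he) <- "double"  # keys up to n^2 exceed integer range
  fwd <- (he[, 1] - 1) * n + he[, 2]
  rev <- (he[, 2] - 1) * n + he[, 1]
  !anyDuplicated(fwd) && all(fwd %in% rev)
}

#' Area-weighted vertex normals
#'
#' Each vertex normal is the normalized, area-weighted mean of its incident
#' face normals (the cross-product accumulation). Errors if a vertex has no
#' incident face.
#'
#' @param mesh a [triangle_mesh] with consistent winding.
#' @return an `n x 3` matrix of unit vectors.
#' @export
vertex_normals <- function(mesh) {
  f <- mesh$faces
  if (!nrow(f)) stop("mesh has no faces")
  cr <- face_cross(mesh)  # length = 2 * area, direction = face normal
  acc <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    acc[, 1] <- acc[, 1] + unname(rowsum_into(cr[, 1], f[, k], nrow(acc)))
    acc[, 2] <- acc[, 2] + unname(rowsum_into(cr[, 2], f[, k], nrow(acc)))
    acc[, 3] <- acc[, 3] + unname(rowsum_into(cr[, 3], f[, k], nrow(acc)))
  }
  len <- sqrt(rowSums(acc^2))
  if (any(len == 0)) {
    deg <- sum(tabulate(as.vector(f), nrow(acc)) == 0)
    if (deg > 0) stop(deg, " vertices have no incident face")
    stop("zero vertex normal (conflicting winding around a vertex)")
  }
  acc / len
}

rowsum_into <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Laplacian mesh smoothing
#'
#' Each vertex moves `factor` of the way toward the centroid of its
#' edge-connected neighbors, repeated `iterations` times. Topology is
#' unchanged; convex meshes shrink slightly.
#'
#' @param mesh a [triangle_mesh].
#' @param factor relaxation factor in `[0, 1]` (default 0.5).
#' @param iterations number of passes (default 1).
#' @return the smoothed [triangle_mesh].
#' @export
smooth_mesh <- function(mesh, factor = 0.5, iterations = 1L) {
  if (factor < 0 || factor > 1) stop("factor must lie in [0, 1]")
  if (factor == 0 || iterations < 1) return(mesh)
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(v)
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  adj <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(n, n))
  adj@x[] <- 1  # collapse repeated edges to simple adjacency
  deg <- Matrix::rowSums(adj)
  deg[deg == 0] <- 1
  for (it in seq_len(iterations)) {
    centroid <- as.matrix(adj %*% v) / deg
    v <- v + factor * (centroid - v)
  }
  structure(list(vertices = v, faces = f), class = "triangle_mesh")
}

#' Extract a triangle surface mesh from a voxel image
#'
#' Iso-surface extraction at level `iso` after optional block resampling,
#' following the measurement protocol used for SMI on binary stacks
#' (threshold 128, voxel resampling 3, smoothing 0.5). Cells are triangulated
#' by a uniform tetrahedral decomposition of the marching-cubes grid with
#' linear vertex interpolation along cell edges, which yields a crack-free,
#' watertight surface; on binary 0/255 input, vertices fall at (near) edge
#' midpoints.
#'
#' With `boundary = "capped"` the image is padded with one background layer so
#' structures cut by the stack faces are closed by "cut edge" faces and the
#' mesh is a closed 2-manifold. With `boundary = "open"` all faces lying in
#' the stack boundary planes are removed, which makes edge effects vanish for
#' full-span analytic phantoms (plates, cylinders).
#'
#' @param img a [voxel_image] (or 3-D array) containing foreground.
#' @param iso iso-level (default 128).
#' @param resample_factor block-resampling factor applied first (default 3).
#' @param smoothing Laplacian smoothing factor in `[0, 1]` applied after
#'   extraction (default 0.5); `0` disables smoothing.
#' @param smooth_iterations smoothing passes (default 1).
#' @param boundary `"capped"` (default) or `"open"`.
#' @return a [triangle_mesh] in physical units (`spacing` taken from `img`).
#' @export
marching_cubes <- function(img, iso = 128, resample_factor = 3L,
                           smoothing = 0.5, smooth_iterations = 1L,
                           boundary = c("capped", "open")) {
  img <- as_voxel_image(img)
  boundary <- match.arg(boundary)
  rng <- range(img$data)
  if (iso <= rng[1] || iso > rng[2])
    stop("iso level ", iso, " is outside the image value range [",
         rng[1], ", ", rng[2], "]")
  rimg <- block_resample(img, resample_factor)
  if (!any(rimg$data >= iso))
    stop("no foreground at iso level ", iso, " after resampling")
  s <- rimg$spacing
  d <- dim(rimg$data)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- rimg$data
  raw <- cpp_mesh_extract(padded, iso)
  # padded lattice index p maps to physical (p - 0.5) * spacing
  verts <- (raw$vertices - 0.5) * s
  mesh <- triangle_mesh(verts, raw$faces)
  if (boundary == "open") {
    # strip everything within the boundary cell layer: the cut faces proper
    # plus the slanted bevel strips joining them to the interior surface
    lim <- d * s
    tol <- 0.51 * s
    v <- mesh$vertices; f <- mesh$faces
    drop <- rep(FALSE, nrow(f))
    for (ax in 1:3) for (plane in c(0, lim[ax])) {
      nearv <- abs(v[, ax] - plane) < tol
      drop <- drop | (nearv[f[, 1]] & nearv[f[, 2]] & nearv[f[, 3]])
    }
    mesh <- triangle_mesh(v, f[!drop, , drop = FALSE])
    if (!nrow(mesh$faces)) stop("open-boundary extraction removed all faces")
  }
  if (smoothing > 0)
    mesh <- smooth_mesh(mesh, smoothing, smooth_iterations)
  mesh
}
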