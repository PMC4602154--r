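#' 3-D voxel image
#'
#' The substrate of all measurements: a 3-D scalar grid (8-bit, 0--255, or
#' binary 0/255 after thresholding) with isotropic voxel spacing. Indices are
#' 0-based and voxel-centered: voxel `(i, j, k)` occupies the physical point
#' `(i + 0.5, j + 0.5, k + 0.5) * spacing`. Foreground is 255, background 0.
#'
#' @param data numeric or integer 3-D array of voxel values.
#' @param spacing isotropic voxel edge length (micrometres; default 1).
#' @return an object of class `voxel_image` with fields `data` and `spacing`.
#' @examples
#' img <- voxel_image(array(0L, c(4, 4, 4)))
#' dim(img$data)
#' @export
voxel_image <- function(data, spacing = 1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 1L)) stop("all three dims must be >= 1")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("`spacing` must be a single positive number")
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d x %d voxels, spacing %g\n",
              d[1], d[2], d[3], x$spacing))
  v <- range(x$data)
  cat(sprintf("  values in [%g, %g]%s\n", v[1], v[2],
              if (is_binary(x)) " (binary 0/255)" else ""))
  invisible(x)
}

as_voxel_image <- function(img, spacing = 1) {
  if (inherits(img, "voxel_image")) return(img)
  voxel_image(img, spacing)
}

is_binary <- function(img) {
  img <- as_voxel_image(img)
  all(img$data == 0 | img$data == 255)
}

stopifnot_binary <- function(img) {
  if (!is_binary(img))
    stop("image must be binary (values 0/255); run binarize() first")
  invisible(img)
}

#' Read a multi-page 8-bit TIFF stack
#'
#' Pages become z-slices; page rows map to y and page columns to x, so
#' `img$data[x, y, z]` indexes the stack. Values are preserved bit-exactly.
#'
#' @param path path to a multi-page TIFF (8-bit grayscale or binary).
#' @param spacing isotropic voxel spacing to attach (micrometres).
#' @return a [voxel_image].
#' @export
read_stack <- function(path, spacing = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits != 8L)
    stop("unsupported bit depth: ", bits, " (only 8-bit stacks are supported)")
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mixed page sizes in ", path)
  if (any(vapply(pages, function(p) length(dim(p)) > 2 && dim(p)[3] > 1,
                 logical(1))))
    stop("multi-channel TIFF pages are not supported")
  nz <- length(pages)
  ny <- dims[1, 1]; nx <- dims[2, 1]
  data <- array(0L, c(nx, ny, nz))
  for (k in seq_len(nz)) data[, , k] <- as.integer(t(pages[[k]]))
  voxel_image(data, spacing)
}

#' Write a voxel image as a multi-page 8-bit TIFF stack
#'
#' @param img a [voxel_image] (or 3-D array) with values in 0--255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(img, path) {
  img <- as_voxel_image(img)
  if (any(img$data < 0 | img$data > 255))
    stop("values must lie in [0, 255] for an 8-bit stack")
  pages <- lapply(seq_len(dim(img$data)[3]),
                  function(k) t(img$data[, , k]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' IsoData automatic threshold
#'
#' The classic iterative intermeans scheme: start from the mid-range value,
#' then repeatedly set `t <- (mean(values <= t) + mean(values > t)) / 2` until
#' the threshold stops moving. For integer-valued images the floor of the
#' converged value is returned, matching integer-histogram implementations.
#'
#' @param img a [voxel_image] or 3-D array with at least two distinct values.
#' @return the converged threshold (scalar).
#' @examples
#' img <- voxel_image(array(c(10, 200), c(2, 2, 2)))
#' isodata_threshold(img)  # 105
#' @export
isodata_threshold <- function(img) {
  img <- as_voxel_image(img)
  v <- as.numeric(img$data)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("constant image: no separable classes for IsoData")
  t <- mean(rng)
  for (i in seq_len(1000L)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(hi)) break  # threshold at or above max: lower side only
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 1e-8) { t <- t_new; break }
    t <- t_new
  }
  if (all(v == round(v))) floor(t) else t
}

#' Binarize an image at a threshold
#'
#' Voxels at or above the threshold become foreground (255), the rest
#' background (0). The comparison is inclusive, so the default cut of 128 is a
#' no-op on 0/255 binaries.
#'
#' @param img a [voxel_image] or 3-D array.
#' @param threshold scalar cut (default 128).
#' @return a binary [voxel_image].
#' @export
binarize <- function(img, threshold = 128) {
  img <- as_voxel_image(img)
  out <- array(0L, dim(img$data))
  out[img$data >= threshold] <- 255L
  voxel_image(out, img$spacing)
}

#' Block-average resampling
#'
#' Each output voxel is the arithmetic mean of a `factor^3` block of input
#' voxels (trailing partial blocks are averaged over the voxels available),
#' and the voxel spacing is multiplied by `factor`.
#'
#' @param img a [voxel_image] or 3-D array.
#' @param factor positive integer block edge length.
#' @return a resampled [voxel_image] (values no longer necessarily binary).
#' @export
block_resample <- function(img, factor) {
  img <- as_voxel_image(img)
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  a <- img$data
  for (ax in 1:3) {
    n <- dim(a)[1]
    g <- (seq_len(n) - 1L) %/% factor
    m <- matrix(as.numeric(a), nrow = n)
    sums <- rowsum(m, g, reorder = TRUE)
    cnts <- as.numeric(table(g))
    a <- array(sums / cnts, c(nrow(sums), dim(a)[2], dim(a)[3]))
    a <- aperm(a, c(2, 3, 1))
  }
  voxel_image(a, img$spacing * factor)
}

#' Rectangular crop of a volume of interest
#'
#' @param img a [voxel_image].
#' @param x,y,z integer index ranges (1-based, inclusive) to keep.
#' @return the cropped [voxel_image].
#' @export
crop_voi <- function(img, x = NULL, y = NULL, z = NULL) {
  img <- as_voxel_image(img)
  d <- dim(img$data)
  x <- x %||% seq_len(d[1]); y <- y %||% seq_len(d[2]); z <- z %||% seq_len(d[3])
  if (any(x < 1 | x > d[1]) || any(y < 1 | y > d[2]) || any(z < 1 | z > d[3]))
    stop("crop range outside image dims")
  voxel_image(img$data[x, y, z, drop = FALSE], img$spacing)
}
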