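# Minimal PLY surface-mesh I/O (ASCII and binary little-endian), sufficient
# for plain triangle meshes with optional per-face RGB colors. Vertex
# coordinates are stored as 32-bit floats (the format's convention); face
# colors round-trip bit-exactly.

#' Write a triangle mesh to a PLY file
#'
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @param format `"binary_le"` (little-endian, default) or `"ascii"`.
#' @param face_colors optional integer `m x 3` RGB matrix (0--255).
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, format = c("binary_le", "ascii"),
                      face_colors = NULL) {
  format <- match.arg(format)
  v <- mesh$vertices; f <- mesh$faces
  if (!is.null(face_colors)) {
    face_colors <- as.matrix(face_colors)
    if (nrow(face_colors) != nrow(f) || ncol(face_colors) != 3)
      stop("face_colors must be an m x 3 matrix matching the face count")
    if (any(face_colors < 0 | face_colors > 255))
      stop("face colors must lie in 0..255")
    storage.mode(face_colors) <- "integer"
  }
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (format == "ascii") "ascii" else "binary_little_endian"),
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           if (!is.null(face_colors))
             c("property uchar red", "property uchar green", "property uchar blue"),
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  put_lines <- function(x)
    writeChar(paste0(paste(x, collapse = "\n"), "\n"), con, eos = NULL)
  put_lines(hdr)
  if (format == "ascii") {
    put_lines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]))
    fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    if (!is.null(face_colors))
      fl <- paste(fl, face_colors[, 1], face_colors[, 2], face_colors[, 3])
    put_lines(fl)
  } else {
    writeBin(as.vector(t(v)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(f[i, ] - 1L, con, size = 4, endian = "little")
      if (!is.null(face_colors))
        writeBin(as.raw(face_colors[i, ]), con)
    }
  }
  invisible(path)
}

#' Read a PLY file written by [write_ply()]
#'
#' Supports ASCII and binary little-endian files with float vertex
#' coordinates, triangular faces, and optional per-face uchar RGB.
#'
#' @param path PLY file path.
#' @return a list with `mesh` (a [triangle_mesh]) and `face_colors` (integer
#'   matrix or NULL).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, 1)
    if (!length(line)) stop("premature end of PLY header")
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format ", "", grep("^format ", hdr, value = TRUE))
  ascii <- startsWith(fmt, "ascii")
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face ", hdr, value = TRUE)))
  has_col <- any(grepl("^property uchar red", hdr))
  if (ascii) {
    vl <- readLines(con, nv)
    v <- matrix(as.numeric(unlist(strsplit(vl, " "))), ncol = 3, byrow = TRUE)
    fl <- readLines(con, nf)
    toks <- strsplit(fl, " ")
    f <- t(vapply(toks, function(tk) as.integer(tk[2:4]), integer(3))) + 1L
    cols <- if (has_col)
      t(vapply(toks, function(tk) as.integer(tk[5:7]), integer(3)))
  } else {
    v <- matrix(readBin(con, "numeric", nv * 3, size = 4, endian = "little"),
                ncol = 3, byrow = TRUE)
    f <- matrix(0L, nf, 3)
    cols <- if (has_col) matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (cnt != 3L) stop("only triangular faces are supported")
      f[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
      if (has_col) cols[i, ] <- as.integer(readBin(con, "raw", 3))
    }
  }
  list(mesh = triangle_mesh(v, f, clean = FALSE),
       face_colors = if (has_col) cols else NULL)
}
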