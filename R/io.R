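# Standard-format I/O: NPY (depth/disparity/normal maps), PLY (meshes, point
# clouds, Gaussian clouds in the de-facto splat layout), TUM trajectories,
# intrinsics JSON, PNG images/masks.

# ---- NPY (v1.0) --------------------------------------------------------------

.npy_descr <- c(float32 = "<f4", float64 = "<f8", int32 = "<i4",
                uint8 = "|u1")

#' Write an array to NPY format
#'
#' NumPy `.npy` version 1.0, little-endian, Fortran (column-major) order --
#' matching R's native layout.
#'
#' @param x Numeric/integer/logical vector, matrix or array.
#' @param path Output file.
#' @param dtype One of `"float32"`, `"float64"`, `"int32"`, `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path, dtype = "float32") {
  descr <- .npy_descr[dtype]
  if (is.na(descr)) stop("write_npy: unsupported dtype")
  shp <- dim2(x)
  shape_str <- if (length(shp) == 1) sprintf("(%d,)", shp) else
    paste0("(", paste(shp, collapse = ", "), ")")
  header <- sprintf("{'descr': '%s', 'fortran_order': True, 'shape': %s, }",
                    descr, shape_str)
  pad <- 64 - ((10 + nchar(header) + 1) %% 64)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  v <- as.vector(x)
  if (dtype %in% c("float32", "float64")) {
    v[is.na(v)] <- NaN
    writeBin(as.numeric(v), con, size = ifelse(dtype == "float32", 4, 8),
             endian = "little")
  } else {
    writeBin(as.integer(v), con, size = ifelse(dtype == "uint8", 1, 4),
             endian = "little")
  }
  invisible(path)
}

#' Read an NPY file
#'
#' Supports v1.0/v2.0 headers, little-endian `<f4`, `<f8`, `<i4`, `|u1`,
#' `|b1` data, and both storage orders.
#'
#' @param path Input file.
#' @return Vector, matrix or array with the stored shape.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("read_npy: not an NPY file")
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2)
    readBin(con, "integer", 1, size = 4, endian = "little")
  else readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  n <- prod(shape)
  data <- switch(descr,
    "<f4" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "<f8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    "<i8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "|u1" = as.integer(readBin(con, "raw", n)),
    "|b1" = as.integer(readBin(con, "raw", n)) > 0,
    stop("read_npy: unsupported descr ", descr))
  if (length(shape) <= 1) return(data)
  if (fortran) array(data, dim = shape)
  else aperm(array(data, dim = rev(shape)), rev(seq_along(shape)))
}

# ---- PLY ---------------------------------------------------------------------

#' Write a PLY file
#'
#' Vertices with arbitrary float properties, optional triangle faces. ASCII
#' or binary little-endian.
#'
#' @param path Output file.
#' @param vertices Matrix of per-vertex properties; column names are the
#'   property names (default `x`, `y`, `z`, ...).
#' @param faces Optional Fx3 matrix of 1-based vertex indices.
#' @param binary Write `binary_little_endian` (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(path, vertices, faces = NULL, binary = TRUE) {
  vertices <- as.matrix(vertices)
  defaults <- c("x", "y", "z",
                paste0("p", seq_len(max(0, ncol(vertices) - 3))))[
                  seq_len(ncol(vertices))]
  if (is.null(colnames(vertices))) colnames(vertices) <- defaults
  blank <- !nzchar(colnames(vertices))
  colnames(vertices)[blank] <- defaults[blank]
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(vertices)),
           sprintf("property float %s", colnames(vertices)))
  if (!is.null(faces))
    hdr <- c(hdr, sprintf("element face %d", nrow(faces)),
             "property list uchar int vertex_indices")
  hdr <- c(hdr, "end_header")
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (binary) {
    writeBin(as.numeric(t(vertices)), con, size = 4, endian = "little")
    if (!is.null(faces)) {
      f0 <- t(matrix(as.integer(faces), ncol = 3)) - 1L
      for (i in seq_len(ncol(f0))) {
        writeBin(as.raw(3), con)
        writeBin(f0[, i], con, size = 4, endian = "little")
      }
    }
  } else {
    utils::write.table(vertices, con, row.names = FALSE, col.names = FALSE)
    if (!is.null(faces))
      utils::write.table(cbind(3L, matrix(as.integer(faces), ncol = 3) - 1L),
                         con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a PLY file
#'
#' Handles ASCII and binary little-endian files with float/double vertex
#' properties and (optionally) uchar-counted integer face lists.
#'
#' @param path Input file.
#' @return A list with `vertices` (matrix, property names as columns) and
#'   `faces` (Fx3 1-based matrix or `NULL`).
#' @export
read_ply <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  # locate end_header by raw byte search (the body may contain nul bytes)
  pat <- charToRaw("end_header")
  starts <- which(raw == pat[1])
  hd_start <- NA_integer_
  for (s in starts) {
    if (s + length(pat) - 1 <= length(raw) &&
        identical(raw[s:(s + length(pat) - 1)], pat)) { hd_start <- s; break }
  }
  if (is.na(hd_start)) stop("read_ply: malformed header")
  body_off <- hd_start + length(pat) - 1
  if (body_off < length(raw) && raw[body_off + 1] == charToRaw("\r"))
    body_off <- body_off + 1
  if (body_off < length(raw) && raw[body_off + 1] == charToRaw("\n"))
    body_off <- body_off + 1
  hdr <- strsplit(rawToChar(raw[seq_len(hd_start - 1)]), "\r?\n")[[1]]
  fmt <- sub("^format\\s+(\\S+).*", "\\1", grep("^format", hdr, value = TRUE))
  nvert <- 0; nface <- 0; props <- character(0); ptypes <- character(0)
  cur <- ""
  for (l in hdr) {
    w <- strsplit(trimws(l), "\\s+")[[1]]
    if (w[1] == "element") {
      cur <- w[2]
      if (cur == "vertex") nvert <- as.integer(w[3])
      if (cur == "face") nface <- as.integer(w[3])
    } else if (w[1] == "property" && cur == "vertex") {
      ptypes <- c(ptypes, w[2]); props <- c(props, w[length(w)])
    }
  }
  sz <- c(float = 4, float32 = 4, double = 8, float64 = 8, int = 4,
          int32 = 4, uint = 4, uint32 = 4, uchar = 1, uint8 = 1)
  if (fmt == "ascii") {
    txt <- rawToChar(raw[(body_off + 1):length(raw)])
    lines <- strsplit(txt, "\r?\n")[[1]]
    vl <- lines[seq_len(nvert)]
    V <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
                nvert, length(props), byrow = TRUE)
    colnames(V) <- props
    Fc <- NULL
    if (nface > 0) {
      fl <- lines[nvert + seq_len(nface)]
      Fm <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))),
                   nface, 4, byrow = TRUE)
      Fc <- Fm[, 2:4, drop = FALSE] + 1L
    }
    return(list(vertices = V, faces = Fc))
  }
  if (fmt != "binary_little_endian")
    stop("read_ply: unsupported format ", fmt)
  psz <- sz[ptypes]
  if (any(is.na(psz))) stop("read_ply: unsupported vertex property type")
  con <- rawConnection(raw[(body_off + 1):length(raw)])
  on.exit(close(con))
  if (length(unique(ptypes)) == 1 && ptypes[1] %in%
      c("float", "float32", "double", "float64")) {
    v <- readBin(con, "numeric", nvert * length(props), size = psz[1],
                 endian = "little")
    V <- matrix(v, nvert, length(props), byrow = TRUE)
  } else {
    V <- matrix(0, nvert, length(props))
    for (i in seq_len(nvert)) for (j in seq_along(props)) {
      V[i, j] <- if (ptypes[j] %in% c("float", "float32", "double", "float64"))
        readBin(con, "numeric", 1, size = psz[j], endian = "little")
      else if (psz[j] == 1) as.integer(readBin(con, "raw", 1))
      else readBin(con, "integer", 1, size = psz[j], endian = "little")
    }
  }
  colnames(V) <- props
  Fc <- NULL
  if (nface > 0) {
    Fc <- matrix(0L, nface, 3)
    for (i in seq_len(nface)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      ix <- readBin(con, "integer", cnt, size = 4, endian = "little")
      Fc[i, ] <- ix[1:3] + 1L
    }
  }
  list(vertices = V, faces = Fc)
}

# SH degree-0 basis constant (de-facto splat PLY stores colors as DC coeffs)
.SH_C0 <- 0.28209479177387814

#' Write a Gaussian cloud in the de-facto splat PLY layout
#'
#' Per-vertex properties `x, y, z, f_dc_0..2` (degree-0 spherical-harmonic
#' color coefficients), `opacity` (logit), `scale_0..2` (log), `rot_0..3`
#' (quaternion), so standard splat viewers can open the export.
#'
#' @param cloud A `gaussian_cloud`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gaussian_ply <- function(cloud, path) {
  fdc <- (cloud$colors - 0.5) / .SH_C0
  V <- cbind(cloud$positions, fdc, cloud$opacity_logits, cloud$log_scales,
             cloud$rotations)
  colnames(V) <- c("x", "y", "z", paste0("f_dc_", 0:2), "opacity",
                   paste0("scale_", 0:2), paste0("rot_", 0:3))
  write_ply(path, V, binary = TRUE)
}

#' Read a Gaussian cloud from a splat PLY file
#' @param path Input file.
#' @return A `gaussian_cloud`.
#' @export
read_gaussian_ply <- function(path) {
  p <- read_ply(path)
  V <- p$vertices
  need <- c("x", "y", "z", paste0("f_dc_", 0:2), "opacity",
            paste0("scale_", 0:2), paste0("rot_", 0:3))
  if (!all(need %in% colnames(V)))
    stop("read_gaussian_ply: missing splat properties")
  gaussian_cloud(V[, c("x", "y", "z"), drop = FALSE],
                 V[, paste0("scale_", 0:2), drop = FALSE],
                 V[, paste0("rot_", 0:3), drop = FALSE],
                 V[, "opacity"],
                 V[, paste0("f_dc_", 0:2), drop = FALSE] * .SH_C0 + 0.5)
}

# ---- TUM trajectories --------------------------------------------------------

#' Read a TUM-format trajectory
#'
#' One line per frame: `timestamp tx ty tz qx qy qz qw`, camera-to-world.
#' Converted to the package's world-to-camera convention on read. Lines whose
#' quaternion norm deviates from 1 by more than 1e-3 are rejected.
#'
#' @param path Input file.
#' @return A list with `poses` (list of [pose()]) and `timestamps`.
#' @export
read_tum_trajectory <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  M <- matrix(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))),
              length(lines), 8, byrow = TRUE)
  poses <- vector("list", nrow(M))
  for (i in seq_len(nrow(M))) {
    q <- M[i, 5:8]  # qx qy qz qw
    if (abs(sqrt(sum(q^2)) - 1) > 1e-3)
      stop(sprintf("read_tum_trajectory: non-unit quaternion on line %d", i))
    R_c2w <- quat_to_rotmat(c(q[4], q[1], q[2], q[3]))
    R <- t(R_c2w)
    poses[[i]] <- pose(R, -as.numeric(R %*% M[i, 2:4]))
  }
  list(poses = poses, timestamps = M[, 1])
}

#' Write a trajectory in TUM format
#' @param poses List of world-to-camera [pose()]s.
#' @param path Output file.
#' @param timestamps Numeric vector (default `0, 1, 2, ...`).
#' @return `path`, invisibly.
#' @export
write_tum_trajectory <- function(poses, path, timestamps = NULL) {
  if (is.null(timestamps)) timestamps <- seq_along(poses) - 1
  lines <- vapply(seq_along(poses), function(i) {
    inv <- pose_inverse(poses[[i]])
    q <- rotmat_to_quat(inv$R)  # (w, x, y, z)
    sprintf("%.6f %.9f %.9f %.9f %.9f %.9f %.9f %.9f", timestamps[i],
            inv$t[1], inv$t[2], inv$t[3], q[2], q[3], q[4], q[1])
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# ---- intrinsics JSON, PNG ----------------------------------------------------

#' Read camera intrinsics from JSON
#' @param path JSON file with fields `fx, fy, cx, cy, width, height`.
#' @return A [camera_intrinsics()].
#' @export
read_intrinsics_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("fx", "fy", "cx", "cy", "width", "height")
  miss <- setdiff(need, names(j))
  if (length(miss) > 0)
    stop("read_intrinsics_json: missing field(s) ",
         paste(miss, collapse = ", "), " in ", path)
  camera_intrinsics(j$fx, j$fy, j$cx, j$cy, j$width, j$height)
}

#' Write camera intrinsics to JSON
#' @param intrinsics A [camera_intrinsics()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_intrinsics_json <- function(intrinsics, path) {
  jsonlite::write_json(unclass(intrinsics), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write an image or mask as PNG
#' @param image H x W x 3 array or H x W matrix in `[0, 1]` (logical masks
#'   are written as 0/255).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_png_image <- function(image, path) {
  if (is.logical(image)) image <- image * 1
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a PNG image
#' @param path Input file.
#' @return H x W x 3 array (or H x W matrix for grayscale), values in
#'   `[0, 1]`.
#' @export
read_png_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3 && dim(x)[3] == 4) x <- x[, , 1:3]
  x
}
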