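#' Read and write HU volumes (NRRD or NIfTI)
#'
#' The native format is NRRD (`.nrrd`, raw little-endian encoding with the
#' voxel spacing in `space directions` and the world position of the first
#' voxel in `space origin`): values, spacing and origin round-trip exactly.
#' Paths ending in `.nii` / `.nii.gz` are handled through NIfTI instead
#' (note NIfTI stores spacing as 32-bit floats, so spacing round-trips only
#' to single precision there).
#'
#' @param path file path (`.nrrd`, `.nii` or `.nii.gz`)
#' @param volume a [VoxelVolume-class]
#' @return `readVolume`: a [VoxelVolume-class]; `writeVolume`: the path,
#'   invisibly.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(read_nrrd(path))
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  vals <- array(as.vector(img), dim = dim(img))
  if (length(dim(vals)) != 3L)
    stop("expected a 3D volume, got ", length(dim(vals)), "D")
  new("VoxelVolume", values = vals,
      spacing = as.numeric(RNifti::pixdim(img))[1:3],
      origin = as.numeric(xf[1:3, 4]))
}

#' @rdname readVolume
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "VoxelVolume"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(volume, path)
  } else {
    vals <- volume@values
    storage.mode(vals) <- "double"
    img <- RNifti::asNifti(vals)
    RNifti::pixdim(img) <- volume@spacing
    m <- diag(c(volume@spacing, 1))
    m[1:3, 4] <- volume@origin
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

# minimal NRRD codec: 3D, raw little-endian encoding, axis-aligned space
# directions (no installed package provides NRRD)
write_nrrd <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(volume@values)
  sp <- volume@spacing; og <- volume@origin
  hdr <- c(
    "NRRD0004",
    "# palatemap HU volume",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            sp[1], sp[2], sp[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)", og[1], og[2], og[3]),
    "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(as.double(volume@values)), con, size = 8L,
           endian = "little")
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("malformed NRRD header (no blank line): ", path)
    if (line == "") break
    hdr <- c(hdr, line)
  }
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file: ", path)
  field <- function(name) {
    ln <- grep(paste0("^", name, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^", name, ":"), "", ln[1]))
  }
  if (!identical(tolower(field("encoding")), "raw"))
    stop("only raw NRRD encoding is supported")
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  type <- tolower(field("type"))
  nums <- function(s) as.numeric(regmatches(s,
    gregexpr("[-+0-9.eE]+", s))[[1]])
  dirs <- nums(field("space directions"))
  sp <- c(dirs[1], dirs[5], dirs[9])
  og <- if (!is.null(field("space origin"))) nums(field("space origin"))
        else c(0, 0, 0)
  n <- prod(sizes)
  vals <- switch(type,
    double = readBin(con, "numeric", n = n, size = 8L, endian = "little"),
    float  = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    short  = readBin(con, "integer", n = n, size = 2L, endian = "little"),
    int    = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    stop("unsupported NRRD type: ", type))
  new("VoxelVolume", values = array(as.double(vals), sizes),
      spacing = sp, origin = og)
}

#' Read and write STL surface meshes
#'
#' `writeSTL` emits binary little-endian STL. `readSTL` auto-detects binary
#' vs ASCII. STL stores a triangle soup; on read, vertices closer than
#' `tol` are merged so shared edges are recovered.
#'
#' @param mesh a [TriMesh-class]
#' @param path file path
#' @param tol vertex merge tolerance in mm on read
#' @return `readSTL`: a [TriMesh-class]; `writeSTL`: the path, invisibly.
#' @export
writeSTL <- function(mesh, path) {
  stopifnot(is(mesh, "TriMesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("palatemap binary STL", width = 80, flag = "-"))
  writeBin(header[1:80], con)
  nf <- nrow(mesh@faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  if (nf) {
    N <- faceNormals(mesh)
    V <- mesh@vertices; F <- mesh@faces
    # 12 floats per facet: normal, v1, v2, v3
    block <- t(cbind(N, V[F[, 1], ], V[F[, 2], ], V[F[, 3], ]))
    dat <- writeBin(as.vector(block), raw(), size = 4L, endian = "little")
    dat <- matrix(dat, nrow = 48L)
    attr_bytes <- as.raw(c(0L, 0L))
    out <- rbind(dat, matrix(rep(attr_bytes, nf), nrow = 2L))
    writeBin(as.vector(out), con)
  }
  invisible(path)
}

#' @rdname writeSTL
#' @export
readSTL <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  head <- readBin(path, "raw", n = 512L)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    !any(head == as.raw(0L))
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  soup_to_mesh(tri, tol)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (nf == 0) return(matrix(numeric(), 0L, 3L))
  raw_all <- readBin(con, "raw", n = nf * 50L)
  dim(raw_all) <- c(50L, nf)
  vals <- readBin(as.vector(raw_all[1:48, ]), "numeric", n = 12L * nf,
                  size = 4L, endian = "little")
  m <- matrix(vals, nrow = 12L) # cols = facets; rows 4:12 are the vertices
  verts <- matrix(as.vector(m[4:12, ]), ncol = 3L, byrow = TRUE)
  verts
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) return(matrix(numeric(), 0L, 3L))
  parts <- strsplit(trimws(vl), "\\s+")
  verts <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (nrow(verts) %% 3L != 0L) stop("malformed ASCII STL: ", path)
  verts
}

# collapse a triangle soup (3 rows per facet) into an indexed mesh
soup_to_mesh <- function(verts, tol) {
  if (!nrow(verts)) return(triMesh(matrix(numeric(), 0L, 3L),
                                   matrix(integer(), 0L, 3L)))
  key <- apply(round(verts / tol), 1L, paste, collapse = ",")
  idx <- match(key, unique(key))
  first <- !duplicated(idx)
  V <- verts[first, , drop = FALSE]
  F <- matrix(idx, ncol = 3L, byrow = TRUE)
  triMesh(V, F)
}

#' Write a colored mesh as ASCII PLY
#'
#' Per-vertex RGB colors (if present) are written as uchar; used for the
#' color-coded distance maps.
#'
#' @param mesh a [TriMesh-class]
#' @param path file path
#' @return the path, invisibly
#' @export
writePLY <- function(mesh, path) {
  stopifnot(is(mesh, "TriMesh"))
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
  has_col <- nrow(mesh@vertexColors) == nv && nv > 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               if (has_col) c("property uchar red", "property uchar green",
                              "property uchar blue"),
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  if (nv) {
    if (has_col) {
      rgb8 <- round(pmin(pmax(mesh@vertexColors, 0), 1) * 255)
      writeLines(sprintf("%.6f %.6f %.6f %d %d %d",
                         mesh@vertices[, 1], mesh@vertices[, 2],
                         mesh@vertices[, 3],
                         rgb8[, 1], rgb8[, 2], rgb8[, 3]), con)
    } else {
      writeLines(sprintf("%.6f %.6f %.6f", mesh@vertices[, 1],
                         mesh@vertices[, 2], mesh@vertices[, 3]), con)
    }
  }
  if (nf)
    writeLines(sprintf("3 %d %d %d", mesh@faces[, 1] - 1L,
                       mesh@faces[, 2] - 1L, mesh@faces[, 3] - 1L), con)
  invisible(path)
}

#' Read and write landmark sets as JSON
#'
#' @param landmarks a [LandmarkSet-class]
#' @param path file path
#' @return `readLandmarks`: a [LandmarkSet-class]; `writeLandmarks`: the
#'   path, invisibly.
#' @export
writeLandmarks <- function(landmarks, path) {
  stopifnot(is(landmarks, "LandmarkSet"))
  obj <- list(
    points = landmarks@points,
    occlusal_points = landmarks@occlusalPoints,
    tooth_bands = lapply(landmarks@toothBands, function(tb)
      list(anchors = as.list(tb$anchors), bands = tb$bands))
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bands <- lapply(obj$tooth_bands, function(tb) {
    list(anchors = unlist(tb$anchors),
         bands = lapply(tb$bands, as.numeric))
  })
  new("LandmarkSet",
      points = lapply(obj$points, as.numeric),
      occlusalPoints = matrix(as.numeric(as.matrix(obj$occlusal_points)),
                              ncol = 3L),
      toothBands = bands)
}
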