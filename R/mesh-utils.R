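#' Construct a TriMesh
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param faces M x 3 matrix of 1-based vertex indices.
#' @param faceLabels optional character vector, one label per face.
#' @return a [TriMesh-class]
#' @export
triMesh <- function(vertices, faces, faceLabels = character()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  colnames(vertices) <- c("x", "y", "z")
  new("TriMesh", vertices = vertices, faces = faces,
      faceLabels = as.character(faceLabels))
}

#' Per-face unit normals, areas and centroids
#'
#' Normals follow the winding convention (counter-clockwise seen from
#' outside); areas in mm^2, centroids in mm.
#'
#' @param mesh a [TriMesh-class]
#' @return `faceNormals`: M x 3 matrix; `faceAreas`: numeric(M);
#'   `faceCentroids`: M x 3 matrix.
#' @export
faceNormals <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname faceNormals
#' @export
faceAreas <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(n^2)) / 2
}

#' @rdname faceNormals
#' @export
faceCentroids <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
     V[F[, 3], , drop = FALSE]) / 3
}

#' Per-vertex unit normals (area-weighted average of incident face normals)
#'
#' @param mesh a [TriMesh-class]
#' @return N x 3 matrix of unit normals
#' @export
vertexNormals <- function(mesh) {
  F <- mesh@faces
  n <- faceNormals(mesh) * faceAreas(mesh) # area weighting
  out <- matrix(0, nrow(mesh@vertices), 3L)
  for (c in 1:3) {
    for (ax in 1:3) {
      acc <- rowsum(n[, ax], F[, c], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      out[idx, ax] <- out[idx, ax] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(out^2))
  len[len == 0] <- 1
  out / len
}

#' Signed enclosed volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes against the coordinate origin; equals
#' the enclosed volume (mm^3) for a watertight mesh with outward normals.
#'
#' @param mesh a [TriMesh-class]
#' @return numeric volume in mm^3 (signed)
#' @export
meshVolume <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Keep a subset of faces, dropping unreferenced vertices
#'
#' @param mesh a [TriMesh-class]
#' @param keep logical or integer index over faces
#' @return a [TriMesh-class]; vertex scalars/colors are subset accordingly
#' @export
subsetFaces <- function(mesh, keep) {
  F <- mesh@faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(mesh@vertices))
  remap[used] <- seq_along(used)
  F2 <- matrix(remap[F], ncol = 3L)
  storage.mode(F2) <- "integer"
  out <- triMesh(mesh@vertices[used, , drop = FALSE], F2,
                 if (length(mesh@faceLabels)) mesh@faceLabels[keep] else character())
  if (length(mesh@vertexScalars)) out@vertexScalars <- mesh@vertexScalars[used]
  if (nrow(mesh@vertexColors))
    out@vertexColors <- mesh@vertexColors[used, , drop = FALSE]
  out
}

#' Remove zero-area faces
#'
#' @param mesh a [TriMesh-class]
#' @param tol area threshold in mm^2 below which a face is dropped
#' @return a cleaned [TriMesh-class]
#' @export
cleanMesh <- function(mesh, tol = 1e-10) {
  if (!nrow(mesh@faces)) return(mesh)
  subsetFaces(mesh, faceAreas(mesh) > tol)
}

#' Merge bone and teeth meshes, preserving coordinates and labels
#'
#' Concatenates two meshes in the same coordinate frame (no resampling, no
#' deformation): every input vertex coordinate appears unchanged in the
#' output and the face labels record the source block, so downstream
#' root-collision queries can address the dental component.
#'
#' @param bone a [TriMesh-class], labelled `"bone"` unless already labelled
#' @param teeth a [TriMesh-class], labelled `"teeth"` unless already labelled
#' @return merged [TriMesh-class]
#' @export
mergeMeshes <- function(bone, teeth) {
  lb <- if (length(bone@faceLabels)) bone@faceLabels else
    rep("bone", nrow(bone@faces))
  lt <- if (length(teeth@faceLabels)) teeth@faceLabels else
    rep("teeth", nrow(teeth@faces))
  if (nrow(teeth@vertices) == 0L) {
    out <- bone
    out@faceLabels <- lb
    return(out)
  }
  V <- rbind(bone@vertices, teeth@vertices)
  F <- rbind(bone@faces, teeth@faces + nrow(bone@vertices))
  triMesh(V, F, c(lb, lt))
}

#' Laplacian mesh smoothing
#'
#' Umbrella-operator smoothing: each vertex moves a fraction `lambda`
#' toward the mean of its edge neighbours, `iterations` times. Off by
#' default throughout the pipeline (extracted surfaces are used as-is);
#' exposed for users who want to trade geometric fidelity for visual
#' smoothness in exported maps.
#'
#' @param mesh a [TriMesh-class]
#' @param iterations number of smoothing sweeps
#' @param lambda per-sweep relaxation factor in (0, 1]
#' @return a smoothed [TriMesh-class]
#' @export
smoothMesh <- function(mesh, iterations = 5, lambda = 0.5) {
  if (iterations < 1) return(mesh)
  V <- mesh@vertices
  F <- mesh@faces
  edges <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  deg <- tabulate(edges[, 1], nbins = nrow(V))
  deg[deg == 0] <- 1
  for (it in seq_len(iterations)) {
    acc <- matrix(0, nrow(V), 3L)
    for (ax in 1:3) {
      s <- rowsum(V[edges[, 2], ax], edges[, 1], reorder = FALSE)
      acc[as.integer(rownames(s)), ax] <- s[, 1]
    }
    V <- V + lambda * (acc / deg - V)
  }
  out <- mesh
  out@vertices <- V
  out
}

# ray cast wrapper: origins/directions N x 3, returns list(hit, distance, face)
castRays <- function(mesh, origins, directions, maxRay = 40, minDist = 1e-9) {
  origins <- matrix(as.double(origins), ncol = 3L)
  directions <- matrix(as.double(directions), ncol = 3L)
  .cpp_ray_cast(mesh@vertices, mesh@faces, origins, directions,
                as.double(maxRay), as.double(minDist))
}
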