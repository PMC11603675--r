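#' Per-vertex oral-to-nasal thickness map
#'
#' For each vertex of the oral palatal patch, a ray is cast into the bone
#' and the Euclidean distance to its first intersection with the nasal
#' surface is recorded. The default direction rule is the per-vertex
#' anti-normal (opposite the oral-facing surface normal, i.e. into the
#' bone, "relative to the palatal surface"); `"frame_z"` instead shoots
#' straight up the anatomical Z axis. Rays that do not reach the nasal
#' surface within `max_ray_mm` (e.g. over a canal void) are marked invalid
#' and excluded from all summaries.
#'
#' @param oral_patch a [TriMesh-class] in the anatomical frame, normals
#'   oriented toward the oral cavity
#' @param nasal_surface a [TriMesh-class] in the same frame
#' @param direction_rule `"antinormal"` (default) or `"frame_z"`
#' @param max_ray_mm maximum ray length (default 40 mm)
#' @return a [DistanceMap-class]
#' @export
computeDistanceMap <- function(oral_patch, nasal_surface,
                               direction_rule = c("antinormal", "frame_z"),
                               max_ray_mm = 40) {
  stopifnot(is(oral_patch, "TriMesh"), is(nasal_surface, "TriMesh"))
  direction_rule <- match.arg(direction_rule)
  if (nrow(nasal_surface@faces) == 0L)
    stop("empty nasal surface")
  # the patch is oriented with outward normals toward the oral cavity
  # (extracted surfaces point toward low HU; constructed pairs are wound
  # accordingly), so the anti-normal points into the bone
  n <- vertexNormals(oral_patch)
  dirs <- if (direction_rule == "antinormal") -n
          else matrix(c(0, 0, 1), nrow(n), 3L, byrow = TRUE)
  hits <- castRays(nasal_surface, oral_patch@vertices, dirs,
                   maxRay = max_ray_mm)
  d <- hits$distance
  d[!hits$hit] <- NA_real_
  new("DistanceMap", distances = d, valid = hits$hit,
      directionRule = direction_rule, maxRay = max_ray_mm)
}

#' ROI-wise AA / MD / Vol summaries of a distance map
#'
#' Vertex weights follow the barycentric one-third rule: each vertex
#' carries one third of the area of its incident labelled triangles,
#' restricted to valid (hit) vertices. Then per ROI
#' `AA = sum(w)` (analysis area, mm^2),
#' `MD = sum(w d) / AA` (area-weighted mean thickness, mm) and
#' `Vol = sum(w d)` (integrated distance, mm^3), so the identity
#' `Vol = AA x MD` holds by construction. Vertices whose ray missed
#' contribute no area (they are excluded from AA, not zero-filled);
#' `coverage` reports the retained area fraction. A `total` row aggregates
#' the six ROIs.
#'
#' @param oral_patch the [TriMesh-class] the partition and map refer to
#' @param partition a [RoiPartition-class]
#' @param dmap a [DistanceMap-class]
#' @return data.frame with one row per ROI (`1r`, `1l`, ..., `total`) and
#'   columns `roi`, `AA`, `MD`, `Vol`, `n_valid_vertices`, `coverage`
#' @export
summarizeRoi <- function(oral_patch, partition, dmap) {
  stopifnot(is(oral_patch, "TriMesh"), is(partition, "RoiPartition"),
            is(dmap, "DistanceMap"))
  if (length(partition@labels) != nrow(oral_patch@faces))
    stop("partition does not match the mesh face count")
  if (length(dmap@distances) != nrow(oral_patch@vertices))
    stop("distance map does not match the mesh vertex count")
  areas <- faceAreas(oral_patch)
  F <- oral_patch@faces
  rois <- c("1r", "1l", "2r", "2l", "3r", "3l")
  out <- data.frame(roi = c(rois, "total"), AA = 0, MD = NA_real_, Vol = 0,
                    n_valid_vertices = 0L, coverage = NA_real_)
  d0 <- ifelse(dmap@valid, dmap@distances, 0)
  for (i in seq_along(rois)) {
    fsel <- which(partition@labels == rois[i])
    if (!length(fsel)) next
    w <- numeric(nrow(oral_patch@vertices))
    for (c in 1:3) {
      acc <- rowsum(areas[fsel] / 3, F[fsel, c], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      w[idx] <- w[idx] + acc[, 1]
    }
    w_valid <- w * dmap@valid
    AA <- sum(w_valid)
    Vol <- sum(w_valid * d0)
    out$AA[i] <- AA
    out$Vol[i] <- Vol
    out$MD[i] <- if (AA > 0) Vol / AA else NA_real_
    out$n_valid_vertices[i] <- sum(w > 0 & dmap@valid)
    out$coverage[i] <- if (sum(w) > 0) AA / sum(w) else NA_real_
    if (AA == 0)
      warning("ROI ", rois[i], " has no valid vertices")
  }
  k <- length(rois) + 1L
  out$AA[k] <- sum(out$AA[seq_along(rois)])
  out$Vol[k] <- sum(out$Vol[seq_along(rois)])
  out$MD[k] <- if (out$AA[k] > 0) out$Vol[k] / out$AA[k] else NA_real_
  out$n_valid_vertices[k] <- sum(out$n_valid_vertices[seq_along(rois)])
  cov <- out$coverage[seq_along(rois)]
  aa_tot_all <- sum(out$AA[seq_along(rois)] / cov, na.rm = TRUE)
  out$coverage[k] <- if (aa_tot_all > 0) out$AA[k] / aa_tot_all else NA_real_
  out
}

#' Export a color-coded thickness map as PLY (+ JSON sidecar)
#'
#' Distances are mapped through a monotone blue-to-red scale between
#' `limits[1]` and `limits[2]` (defaults to the observed range); invalid
#' vertices are grey. The scale bounds and color stops are recorded in a
#' sidecar JSON next to the PLY.
#'
#' @param oral_patch a [TriMesh-class]
#' @param dmap the matching [DistanceMap-class]
#' @param path output PLY path (`<path>.json` sidecar is written alongside)
#' @param limits numeric(2) scale bounds in mm, or `NULL` for data range
#' @param palette character vector of color stops, low to high
#' @return the PLY path, invisibly
#' @export
exportColorMap <- function(oral_patch, dmap, path, limits = NULL,
                           palette = c("#2166AC", "#67A9CF", "#F7F7F7",
                                       "#EF8A62", "#B2182B")) {
  stopifnot(is(oral_patch, "TriMesh"), is(dmap, "DistanceMap"))
  d <- dmap@distances
  if (is.null(limits)) {
    dv <- d[dmap@valid]
    limits <- if (length(dv)) range(dv) else c(0, 1)
  }
  span <- max(limits[2] - limits[1], 1e-12)
  u <- pmin(1, pmax(0, (d - limits[1]) / span))
  ramp <- grDevices::colorRamp(palette)
  cols <- matrix(0.5, length(d), 3L) # grey for invalid
  if (any(dmap@valid))
    cols[dmap@valid, ] <- ramp(u[dmap@valid]) / 255
  out <- oral_patch
  out@vertexColors <- cols
  out@vertexScalars <- ifelse(dmap@valid, d, NA_real_)
  writePLY(out, path)
  jsonlite::write_json(
    list(limits_mm = limits, palette = palette,
         direction_rule = dmap@directionRule, max_ray_mm = dmap@maxRay,
         n_vertices = length(d), n_valid = sum(dmap@valid)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
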