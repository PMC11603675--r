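unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("geometry error: zero-length vector")
  v / n
}

#' Build the anatomical coordinate frame from landmarks
#'
#' Axes follow the standard cephalometric convention: the Y axis runs
#' through the anterior and posterior nasal spine (positive anterior), the
#' Z axis is the component of the occlusal-plane normal orthogonal to Y
#' (positive superior, i.e. from the occlusal plane toward the palate), and
#' X = Y x Z (positive toward patient right, checked against the molar
#' fissure landmarks). The origin is the ANS-PNS midpoint, so the
#' midsagittal plane is x = 0.
#'
#' @param landmarks a [LandmarkSet-class]
#' @return an [AnatomicalFrame-class]
#' @export
buildFrame <- function(landmarks) {
  stopifnot(is(landmarks, "LandmarkSet"))
  validObject(landmarks)
  ans <- landmarks@points$ANS
  pns <- landmarks@points$PNS
  if (sqrt(sum((ans - pns)^2)) < 1e-9)
    stop("geometry error: ANS and PNS coincide")
  Yax <- unitv(ans - pns)

  occ <- landmarks@occlusalPoints
  ctr <- colMeans(occ)
  sv <- svd(sweep(occ, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("geometry error: occlusal points are collinear")
  n_occ <- sv$v[, 3]
  # superior = from the occlusal plane toward the nasal spines
  if (sum(n_occ * ((ans + pns) / 2 - ctr)) < 0) n_occ <- -n_occ
  Zax <- n_occ - sum(n_occ * Yax) * Yax
  if (sqrt(sum(Zax^2)) < 1e-9)
    stop("geometry error: occlusal normal parallel to the ANS-PNS axis")
  Zax <- unitv(Zax)
  Xax <- c(Yax[2] * Zax[3] - Yax[3] * Zax[2],
           Yax[3] * Zax[1] - Yax[1] * Zax[3],
           Yax[1] * Zax[2] - Yax[2] * Zax[1])
  Xax <- unitv(Xax)
  mr <- landmarks@points$molar_fissure_r
  ml <- landmarks@points$molar_fissure_l
  if (sum(Xax * (mr - ml)) < 0)
    warning("molar fissure landmarks disagree with the right-hand ",
            "convention; check landmark sides")
  new("AnatomicalFrame", origin = as.numeric((ans + pns) / 2),
      axes = rbind(X = Xax, Y = Yax, Z = Zax))
}

#' Transform a mesh or points into frame coordinates
#'
#' Rigid transform `p -> axes (p - origin)`: pairwise distances are
#' preserved and the frame axes map to the canonical basis.
#'
#' @param mesh a [TriMesh-class]
#' @param frame an [AnatomicalFrame-class]
#' @param points N x 3 matrix of world points
#' @param inverse map frame coordinates back to world coordinates
#' @return transformed [TriMesh-class] / point matrix
#' @export
transformToFrame <- function(mesh, frame, inverse = FALSE) {
  stopifnot(is(mesh, "TriMesh"), is(frame, "AnatomicalFrame"))
  out <- mesh
  out@vertices <- transformPoints(mesh@vertices, frame, inverse = inverse)
  colnames(out@vertices) <- c("x", "y", "z")
  out
}

#' @rdname transformToFrame
#' @export
transformPoints <- function(points, frame, inverse = FALSE) {
  points <- matrix(points, ncol = 3L)
  if (inverse)
    sweep(points %*% frame@axes, 2, frame@origin, "+")
  else
    sweep(points, 2, frame@origin) %*% t(frame@axes)
}

#' Transform a landmark set into frame coordinates
#'
#' @param landmarks a [LandmarkSet-class]
#' @param frame an [AnatomicalFrame-class]
#' @return a [LandmarkSet-class] with transformed points (tooth bands are
#'   already frame Y-levels and are left unchanged)
#' @export
transformLandmarks <- function(landmarks, frame) {
  out <- landmarks
  out@points <- lapply(landmarks@points, function(p)
    as.numeric(transformPoints(p, frame)))
  out@occlusalPoints <- transformPoints(landmarks@occlusalPoints, frame)
  out
}

#' Select the oral-facing (or nasal-facing) patch of a bone mesh
#'
#' The oral palatal surface consists of the faces whose outward normal
#' points toward the oral cavity (normal Z below `-z_thresh` in the
#' anatomical frame); the nasal floor faces point superiorly (normal Z
#' above `z_thresh`). With `occlusion = TRUE`, faces hidden behind another
#' candidate face along the viewing direction (straight down for the oral
#' patch, straight up for the nasal patch) are discarded, which removes
#' interior walls of carved structures (tooth sockets, canal).
#'
#' @param mesh a [TriMesh-class] in the anatomical frame
#' @param z_thresh normal Z-component threshold (default 0.2)
#' @param occlusion drop faces occluded along the view direction
#' @return a [TriMesh-class] sub-mesh
#' @export
selectOralPatch <- function(mesh, z_thresh = 0.2, occlusion = TRUE) {
  select_patch(mesh, z_thresh, direction = c(0, 0, -1), occlusion)
}

#' @rdname selectOralPatch
#' @export
selectNasalPatch <- function(mesh, z_thresh = 0.2, occlusion = TRUE) {
  select_patch(mesh, z_thresh, direction = c(0, 0, 1), occlusion)
}

select_patch <- function(mesh, z_thresh, direction, occlusion) {
  n <- faceNormals(mesh)
  keep <- if (direction[3] < 0) n[, 3] < -z_thresh else n[, 3] > z_thresh
  if (!any(keep)) stop("empty patch: no faces pass the normal criterion")
  patch <- subsetFaces(mesh, keep)
  if (occlusion && nrow(patch@faces) > 1L) {
    ctr <- faceCentroids(patch)
    dirs <- matrix(direction, nrow(ctr), 3L, byrow = TRUE)
    hit <- castRays(patch, ctr, dirs, maxRay = 1e3, minDist = 1e-6)
    patch <- subsetFaces(patch, !hit$hit)
  }
  patch
}

#' Partition the oral palatal patch into the six ROIs
#'
#' A face is labelled `<band><side>` (bands 1 = first premolar, 2 = second
#' premolar, 3 = first molar; sides r = x > 0, l = x < 0) when its centroid
#' lies within the paramedian strip (`min_paramedian <= |x| <=
#' paramedian_limit`) and its Y coordinate falls inside the corresponding
#' tooth band. Band intervals are closed below and open above
#' (anterior-closed); x = 0 exactly is assigned to the right. All other
#' faces are labelled `none`.
#'
#' @param oral_patch a [TriMesh-class] in the anatomical frame
#' @param landmarks a [LandmarkSet-class] providing the tooth bands
#' @param paramedian_limit_mm lateral ROI half-width (default 10 mm)
#' @param min_paramedian_mm inner exclusion half-width (default 0:
#'   midline strip included, split at x = 0)
#' @return a [RoiPartition-class]
#' @export
partitionRoi <- function(oral_patch, landmarks, paramedian_limit_mm = 10,
                         min_paramedian_mm = 0) {
  stopifnot(is(oral_patch, "TriMesh"), is(landmarks, "LandmarkSet"))
  ctr <- faceCentroids(oral_patch)
  lv <- c("1r", "1l", "2r", "2l", "3r", "3l", "none")
  lab <- rep("none", nrow(ctr))
  side <- ifelse(ctr[, 1] >= 0, "r", "l") # x = 0 assigned right
  in_strip <- abs(ctr[, 1]) <= paramedian_limit_mm &
    abs(ctr[, 1]) >= min_paramedian_mm
  band_names <- c("1" = "p1", "2" = "p2", "3" = "m1")
  for (s in c("r", "l")) {
    bands <- landmarks@toothBands[[s]]$bands
    for (k in names(band_names)) {
      b <- bands[[band_names[[k]]]]
      sel <- in_strip & side == s & ctr[, 2] >= b[1] & ctr[, 2] < b[2]
      lab[sel] <- paste0(k, s)
    }
  }
  if (all(lab == "none"))
    warning("empty ROI: no face fell inside the paramedian bands")
  new("RoiPartition", labels = factor(lab, levels = lv),
      paramedianLimit = paramedian_limit_mm,
      minParamedian = min_paramedian_mm)
}

#' Place the six paramedian probe points on the oral surface
#'
#' For each side, three insertion-site candidates are dropped onto the oral
#' surface at `x = +/- paramedian_offset_mm`: point 1 at the canine / first
#' premolar contact level, point 2 at the first-premolar mid level, point 3
#' at the first / second premolar contact level. Each point is found by
#' projecting straight down (-Z) onto the oral patch; its surface normal is
#' taken from the hit face, oriented toward the oral cavity.
#'
#' @param oral_patch a [TriMesh-class] in the anatomical frame
#' @param landmarks a [LandmarkSet-class] providing the anchors
#' @param paramedian_offset_mm lateral offset from the median suture
#'   (default 3 mm)
#' @return data.frame with columns `id`, `side`, `x`, `y`, `z`,
#'   `nx`, `ny`, `nz` (unit surface normal, oral-facing)
#' @export
placeProbePoints <- function(oral_patch, landmarks,
                             paramedian_offset_mm = 3) {
  stopifnot(is(oral_patch, "TriMesh"), is(landmarks, "LandmarkSet"))
  z_top <- max(oral_patch@vertices[, 3]) + 5
  anchor_names <- c("1" = "canine_p1", "2" = "p1_mid", "3" = "p1_p2")
  ids <- character(); sides <- character()
  orgs <- NULL
  for (s in c("r", "l")) {
    sgn <- if (s == "r") 1 else -1
    anchors <- landmarks@toothBands[[s]]$anchors
    for (k in names(anchor_names)) {
      ids <- c(ids, paste0(k, s)); sides <- c(sides, s)
      orgs <- rbind(orgs, c(sgn * paramedian_offset_mm,
                            anchors[[anchor_names[[k]]]], z_top))
    }
  }
  dirs <- matrix(c(0, 0, -1), nrow(orgs), 3L, byrow = TRUE)
  hits <- castRays(oral_patch, orgs, dirs, maxRay = 1e3)
  if (!all(hits$hit))
    stop("placement error: no oral surface under probe point(s) ",
         paste(ids[!hits$hit], collapse = ", "))
  pos <- orgs + dirs * hits$distance
  # surface normal: area-weighted average over faces near the hit point
  # (robust against the facet-level noise of extracted meshes)
  all_n <- faceNormals(oral_patch)
  all_a <- faceAreas(oral_patch)
  all_c <- faceCentroids(oral_patch)
  fn <- t(vapply(seq_len(nrow(pos)), function(i) {
    d2 <- (all_c[, 1] - pos[i, 1])^2 + (all_c[, 2] - pos[i, 2])^2 +
      (all_c[, 3] - pos[i, 3])^2
    near <- d2 < 1.5^2
    if (!any(near)) near <- hits$face[i]
    v <- colSums(all_n[near, , drop = FALSE] * all_a[near])
    v / sqrt(sum(v^2))
  }, numeric(3)))
  # orient toward the oral cavity (downward in the frame)
  flip <- fn[, 3] > 0
  fn[flip, ] <- -fn[flip, , drop = FALSE]
  data.frame(id = ids, side = sides,
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             nx = fn[, 1], ny = fn[, 2], nz = fn[, 3])
}
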