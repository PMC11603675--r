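#' Angled insertion direction at a probe point
#'
#' The 0-degree direction is the anti-normal (straight into the bone,
#' opposite the oral-facing surface normal). Positive tilts rotate that
#' direction about the frame X axis toward anterior (+Y), i.e. a purely
#' sagittal tilt of the simulated mini-implant axis.
#'
#' @param surface_normal oral-facing unit normal (numeric(3))
#' @param theta_deg tilt angle in degrees, in `[0, 45]`
#' @param zero_reference what "0 degrees" means: `"normal"` (local surface
#'   anti-normal, the default) or `"occlusal"` (perpendicular to the
#'   occlusal plane, i.e. the frame +Z axis)
#' @return unit direction vector (numeric(3))
#' @export
angledDirection <- function(surface_normal, theta_deg,
                            zero_reference = c("normal", "occlusal")) {
  zero_reference <- match.arg(zero_reference)
  if (theta_deg < 0 || theta_deg > 45)
    stop("theta_deg must be in [0, 45]")
  n2 <- sum(surface_normal^2)
  if (n2 < 1e-24) stop("geometry error: zero surface normal")
  d0 <- if (zero_reference == "occlusal") c(0, 0, 1)
        else -surface_normal / sqrt(n2)
  th <- theta_deg * pi / 180
  c(d0[1],
    cos(th) * d0[2] + sin(th) * d0[3],
    -sin(th) * d0[2] + cos(th) * d0[3])
}

#' Measure bone thickness at probe points under angulation
#'
#' For each probe point and tilt angle, a ray is cast along
#' [angledDirection()] and the distance to the first nasal-surface hit is
#' the bone thickness (the oral-to-nasal-floor definition; a miss within
#' `max_ray_mm` is flagged, not an error). Independently, intersection with
#' the teeth mesh at a depth shallower than the thickness is recorded as a
#' root conflict with its depth -- the thickness itself is never truncated
#' by a root hit.
#'
#' @param points probe-point data.frame from [placeProbePoints()] (or any
#'   subset of its rows)
#' @param angles_deg tilt angles in degrees (default `c(0, 10, 20, 30)`)
#' @param nasal_surface a [TriMesh-class]
#' @param teeth_mesh optional [TriMesh-class] of the dental component
#' @param max_ray_mm maximum ray length
#' @param zero_reference passed to [angledDirection()]
#' @return data.frame with one row per (point, angle): `point_id`, `side`,
#'   `angle_deg`, `thickness_mm` (`NA` on miss), `valid`, `root_hit`,
#'   `root_depth_mm`, direction components `dx`, `dy`, `dz`
#' @export
measurePointThickness <- function(points, angles_deg = c(0, 10, 20, 30),
                                  nasal_surface, teeth_mesh = NULL,
                                  max_ray_mm = 40,
                                  zero_reference = c("normal", "occlusal")) {
  stopifnot(is.data.frame(points), is(nasal_surface, "TriMesh"))
  zero_reference <- match.arg(zero_reference)
  rows <- expand.grid(pt = seq_len(nrow(points)), angle = angles_deg,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- rows[order(rows$pt, rows$angle), ]
  orgs <- as.matrix(points[rows$pt, c("x", "y", "z")])
  dirs <- t(mapply(function(i, a)
    angledDirection(as.numeric(points[i, c("nx", "ny", "nz")]), a,
                    zero_reference),
    rows$pt, rows$angle))
  nas <- castRays(nasal_surface, orgs, dirs, maxRay = max_ray_mm)
  thick <- ifelse(nas$hit, nas$distance, NA_real_)
  root_hit <- rep(FALSE, nrow(rows))
  root_depth <- rep(NA_real_, nrow(rows))
  if (!is.null(teeth_mesh) && nrow(teeth_mesh@faces) > 0L) {
    th <- castRays(teeth_mesh, orgs, dirs, maxRay = max_ray_mm)
    sel <- th$hit & (!nas$hit | th$distance < nas$distance)
    root_hit[sel] <- TRUE
    root_depth[sel] <- th$distance[sel]
  }
  data.frame(point_id = points$id[rows$pt], side = points$side[rows$pt],
             angle_deg = rows$angle, thickness_mm = thick,
             valid = nas$hit, root_hit = root_hit,
             root_depth_mm = root_depth,
             dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3])
}

#' Mini-implant dimensions
#'
#' Typical palatal mini-implants are 2-2.3 mm in diameter and 7-11 mm
#' long.
#'
#' @param diameter_mm implant diameter, in (0, 5]
#' @param length_mm implant length, in (0, 20]
#' @return a validated list
#' @export
implantSpec <- function(diameter_mm = 2.2, length_mm = 9) {
  if (!(diameter_mm > 0 && diameter_mm <= 5))
    stop("diameter_mm must be in (0, 5]")
  if (!(length_mm > 0 && length_mm <= 20))
    stop("length_mm must be in (0, 20]")
  structure(list(diameter_mm = diameter_mm, length_mm = length_mm),
            class = "ImplantSpec")
}

#' Check whether an implant corridor fits at a probe point
#'
#' Simulates a cylindrical implant of the given diameter and length along
#' the angled insertion direction: the axial ray plus `n_perimeter` rays
#' started on the cylinder perimeter. The corridor fits when the implant
#' length does not exceed the bone thickness on any ray (nasal-floor
#' perforation) and no tooth root is met within the implant length.
#'
#' @param point one row of [placeProbePoints()] output
#' @param theta_deg tilt angle in degrees
#' @param implant an [implantSpec()]
#' @param nasal_surface,teeth_mesh geometry in the anatomical frame
#' @param n_perimeter number of perimeter rays (default 8)
#' @param max_ray_mm maximum ray length
#' @return list with `fits` (logical), `limiting_structure` (`"none"`,
#'   `"nasal_floor"` or `"tooth_root"`), `min_thickness_mm`,
#'   `min_root_depth_mm`
#' @export
corridorFit <- function(point, theta_deg, implant, nasal_surface,
                        teeth_mesh = NULL, n_perimeter = 8,
                        max_ray_mm = 40) {
  stopifnot(inherits(implant, "ImplantSpec"))
  nrm <- as.numeric(point[1, c("nx", "ny", "nz")])
  d <- angledDirection(nrm, theta_deg)
  ctr <- as.numeric(point[1, c("x", "y", "z")])
  # orthonormal basis of the disc perpendicular to the insertion axis
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * d) * d; u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  ang <- seq(0, 2 * pi, length.out = n_perimeter + 1L)[-(n_perimeter + 1L)]
  r <- implant$diameter_mm / 2
  offs <- rbind(c(0, 0, 0), t(vapply(ang, function(a)
    r * (cos(a) * u + sin(a) * v), numeric(3))))
  orgs <- sweep(offs, 2, ctr, "+")
  dirs <- matrix(d, nrow(orgs), 3L, byrow = TRUE)
  nas <- castRays(nasal_surface, orgs, dirs, maxRay = max_ray_mm)
  min_thick <- if (any(nas$hit)) min(nas$distance[nas$hit], na.rm = TRUE)
               else Inf
  min_root <- Inf
  if (!is.null(teeth_mesh) && nrow(teeth_mesh@faces) > 0L) {
    th <- castRays(teeth_mesh, orgs, dirs, maxRay = max_ray_mm)
    if (any(th$hit)) min_root <- min(th$distance[th$hit], na.rm = TRUE)
  }
  L <- implant$length_mm
  root_block <- min_root <= L
  nasal_block <- min_thick < L
  limiting <- if (root_block && (min_root <= min_thick)) "tooth_root"
              else if (nasal_block) "nasal_floor"
              else if (root_block) "tooth_root"
              else "none"
  list(fits = !root_block && !nasal_block,
       limiting_structure = limiting,
       min_thickness_mm = min_thick,
       min_root_depth_mm = if (is.finite(min_root)) min_root else NA_real_)
}

#' Which ROIs have tooth roots within the insertion corridor?
#'
#' From the centroid of every labelled oral face, a ray is cast along the
#' 0-degree measurement direction (the face anti-normal); an ROI is flagged
#' when any of its rays meets the teeth mesh within `corridor_depth_mm` --
#' the discrete version of sweeping the ROI faces to depth and testing for
#' dental material (the "teeth" covariate of the cohort models).
#'
#' @param oral_patch a [TriMesh-class] in the anatomical frame
#' @param partition a [RoiPartition-class] over the patch
#' @param teeth_mesh a [TriMesh-class] (may be empty)
#' @param corridor_depth_mm sweep depth (default 8 mm, a typical implant
#'   length)
#' @return named logical over the six ROIs
#' @export
rootsInRegion <- function(oral_patch, partition, teeth_mesh,
                          corridor_depth_mm = 8) {
  rois <- c("1r", "1l", "2r", "2l", "3r", "3l")
  out <- setNames(rep(FALSE, 6L), rois)
  if (is.null(teeth_mesh) || nrow(teeth_mesh@faces) == 0L) return(out)
  lab <- partition@labels
  sel <- which(lab != "none")
  if (!length(sel)) return(out)
  ctr <- faceCentroids(oral_patch)[sel, , drop = FALSE]
  n <- faceNormals(oral_patch)[sel, , drop = FALSE]
  flip <- n[, 3] > 0
  n[flip, ] <- -n[flip, , drop = FALSE]
  hits <- castRays(teeth_mesh, ctr, -n, maxRay = corridor_depth_mm)
  hit_lab <- lab[sel][hits$hit]
  out[rois %in% hit_lab] <- TRUE
  out
}
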