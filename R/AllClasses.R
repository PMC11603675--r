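#' @useDynLib palatemap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif setNames
#' @import methods
NULL

#' VoxelVolume: an HU-valued 3D scalar grid
#'
#' Container for CBCT-like image data: a 3D array of Hounsfield-unit (HU)
#' values together with the physical voxel spacing and the world coordinate
#' of the first voxel centre, both in millimetres. Voxel `(i, j, k)` (1-based)
#' sits at `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @slot values 3D numeric array of HU values.
#' @slot spacing positive numeric(3), voxel edge lengths in mm.
#' @slot origin numeric(3), world position of voxel (1,1,1) in mm.
#' @export
setClass("VoxelVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L || any(dim(object@values) < 1L))
      msg <- c(msg, "values must be a non-empty 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values (mm)")
    if (length(msg)) msg else TRUE
  })

#' BinaryMask: a logical voxel grid with geometry
#'
#' Result of thresholding a [VoxelVolume-class]; shares its spacing and
#' origin. The `values` slot holds a logical array of the same shape.
#'
#' @export
setClass("BinaryMask", contains = "VoxelVolume",
  validity = function(object) {
    if (!is.logical(object@values)) "mask values must be logical" else TRUE
  })

#' TriMesh: a triangulated surface in mm coordinates
#'
#' @slot vertices N x 3 numeric matrix of vertex positions (mm).
#' @slot faces M x 3 integer matrix of 1-based vertex indices.
#' @slot faceLabels character of length 0 or M: component labels (e.g.
#'   `"bone"` / `"teeth"`) retained across [mergeMeshes()].
#' @slot vertexScalars numeric of length 0 or N (e.g. mapped distances).
#' @slot vertexColors matrix with 0 or N rows of RGB values in `[0, 1]`.
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", faces = "matrix",
                 faceLabels = "character", vertexScalars = "numeric",
                 vertexColors = "matrix"),
  prototype(faceLabels = character(), vertexScalars = numeric(),
            vertexColors = matrix(numeric(), 0L, 3L)),
  validity = function(object) {
    msg <- character()
    nv <- nrow(object@vertices); nf <- nrow(object@faces)
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be N x 3")
    if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be M x 3")
    if (nf > 0 && (min(object@faces) < 1L || max(object@faces) > nv))
      msg <- c(msg, "face indices out of range")
    if (length(object@faceLabels) && length(object@faceLabels) != nf)
      msg <- c(msg, "faceLabels must have one entry per face")
    if (length(object@vertexScalars) && length(object@vertexScalars) != nv)
      msg <- c(msg, "vertexScalars must have one entry per vertex")
    if (nrow(object@vertexColors) && nrow(object@vertexColors) != nv)
      msg <- c(msg, "vertexColors must have one row per vertex")
    if (length(msg)) msg else TRUE
  })

#' AnatomicalFrame: landmark-derived orthonormal coordinate frame
#'
#' Rows of `axes` are the unit X (patient right), Y (anterior) and Z
#' (superior) directions expressed in world coordinates; the frame is
#' right-handed. A world point `p` maps to frame coordinates
#' `axes %*% (p - origin)`.
#'
#' @slot origin numeric(3), world position of the frame origin (mm).
#' @slot axes 3 x 3 rotation matrix, rows = X, Y, Z unit vectors.
#' @export
setClass("AnatomicalFrame",
  representation(origin = "numeric", axes = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@origin) != 3L) msg <- c(msg, "origin must be numeric(3)")
    A <- object@axes
    if (!all(dim(A) == c(3L, 3L))) {
      msg <- c(msg, "axes must be 3 x 3")
    } else {
      if (max(abs(A %*% t(A) - diag(3))) > 1e-9)
        msg <- c(msg, "axes must be orthonormal (within 1e-9)")
      if (abs(det(A) - 1) > 1e-9)
        msg <- c(msg, "axes must be right-handed (det = +1)")
    }
    if (length(msg)) msg else TRUE
  })

#' LandmarkSet: named anatomical landmarks and tooth band levels
#'
#' Holds the midsagittal nasal spines (ANS anterior, PNS posterior), the
#' distal fissures of the first molars, at least three non-collinear points
#' on the occlusal plane, and per-side tooth levels along the
#' antero-posterior axis: the three probe-point anchors (canine/P1 contact,
#' P1 mid, P1/P2 contact) and the three ROI band intervals (P1, P2, M1).
#' Tooth levels are Y-values in the anatomical frame built from the same
#' landmarks, so they are invariant under rigid motion of the scan.
#'
#' @slot points named list of numeric(3) world points: `ANS`, `PNS`,
#'   `molar_fissure_r`, `molar_fissure_l`.
#' @slot occlusalPoints k x 3 matrix (k >= 3) of occlusal-plane points.
#' @slot toothBands per-side (`r`, `l`) list with `anchors` (named numeric:
#'   `canine_p1`, `p1_mid`, `p1_p2`) and `bands` (list of numeric(2)
#'   intervals: `p1`, `p2`, `m1`), all frame Y-values in mm.
#' @export
setClass("LandmarkSet",
  representation(points = "list", occlusalPoints = "matrix",
                 toothBands = "list"),
  validity = function(object) {
    msg <- character()
    need <- c("ANS", "PNS", "molar_fissure_r", "molar_fissure_l")
    if (!all(need %in% names(object@points)))
      msg <- c(msg, paste("points must include", paste(need, collapse = ", ")))
    else {
      if (any(!vapply(object@points[need], function(p)
        is.numeric(p) && length(p) == 3L && all(is.finite(p)), logical(1))))
        msg <- c(msg, "each landmark must be a finite numeric(3)")
      else if (sqrt(sum((object@points$ANS - object@points$PNS)^2)) < 1e-9)
        msg <- c(msg, "ANS and PNS must be distinct")
    }
    if (nrow(object@occlusalPoints) < 3L || ncol(object@occlusalPoints) != 3L)
      msg <- c(msg, "occlusalPoints must be a k x 3 matrix with k >= 3")
    for (s in c("r", "l")) {
      tb <- object@toothBands[[s]]
      if (is.null(tb)) { msg <- c(msg, paste0("toothBands$", s, " missing")); next }
      a <- tb$anchors
      if (!all(c("canine_p1", "p1_mid", "p1_p2") %in% names(a)))
        msg <- c(msg, "anchors must name canine_p1, p1_mid, p1_p2")
      else if (!(a[["canine_p1"]] > a[["p1_mid"]] && a[["p1_mid"]] > a[["p1_p2"]]))
        msg <- c(msg, "anchors must be strictly ordered anterior -> posterior")
      if (!all(c("p1", "p2", "m1") %in% names(tb$bands)))
        msg <- c(msg, "bands must name p1, p2, m1")
    }
    if (length(msg)) msg else TRUE
  })

#' RoiPartition: per-face ROI labels over the oral palatal patch
#'
#' @slot labels factor of length M over levels
#'   `1r, 1l, 2r, 2l, 3r, 3l, none`.
#' @slot paramedianLimit lateral half-width of the ROI strip (mm).
#' @slot minParamedian inner exclusion half-width around the median suture
#'   (mm, default 0 = midline included).
#' @export
setClass("RoiPartition",
  representation(labels = "factor", paramedianLimit = "numeric",
                 minParamedian = "numeric"),
  validity = function(object) {
    lv <- c("1r", "1l", "2r", "2l", "3r", "3l", "none")
    if (!all(levels(object@labels) == lv))
      return("labels must be a factor with levels 1r,1l,2r,2l,3r,3l,none")
    TRUE
  })

#' DistanceMap: per-vertex oral-to-nasal bone thickness
#'
#' @slot distances numeric(N), mm; `NA` where the ray missed.
#' @slot valid logical(N), hit indicator.
#' @slot directionRule ray rule used (`"antinormal"` or `"frame_z"`).
#' @slot maxRay maximum ray length in mm.
#' @export
setClass("DistanceMap",
  representation(distances = "numeric", valid = "logical",
                 directionRule = "character", maxRay = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@distances) != length(object@valid))
      msg <- c(msg, "distances and valid must have equal length")
    d <- object@distances[object@valid]
    if (length(d) && (any(!is.finite(d)) || any(d <= 0) ||
                      any(d > object@maxRay + 1e-9)))
      msg <- c(msg, "valid distances must lie in (0, maxRay]")
    if (any(is.finite(object@distances[!object@valid])))
      msg <- c(msg, "invalid vertices must carry no distance")
    if (length(msg)) msg else TRUE
  })

#' PhantomTruth: analytic ground truth attached to a synthetic phantom
#'
#' @slot thicknessField function mapping an N x 3 matrix of points on the
#'   oral surface to true bone thickness in mm (`NA` where undefined, e.g.
#'   over the nerve-canal void).
#' @slot landmarks the phantom's [LandmarkSet-class].
#' @slot rootsPresent named logical(2) (`r`, `l`): incisor roots intruding
#'   into the anterior corridor.
#' @slot canalPresent logical(1): nerve-canal void carved.
#' @slot huLevels named numeric of tissue HU values
#'   (`air`, `soft`, `bone`, `teeth`).
#' @export
setClass("PhantomTruth",
  representation(thicknessField = "function", landmarks = "LandmarkSet",
                 rootsPresent = "logical", canalPresent = "logical",
                 huLevels = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(c("air", "soft", "bone", "teeth") %in% names(object@huLevels)))
      msg <- c(msg, "huLevels must name air, soft, bone, teeth")
    if (length(msg)) msg else TRUE
  })

#' LmmFit: a fitted random-intercept linear mixed model
#'
#' @slot coefTable data.frame with columns `term`, `estimate`, `se`,
#'   `lower`, `upper`, `z`, `p` (Wald, 95% CI with 1.96).
#' @slot sigmaB random-intercept SD.
#' @slot sigmaE residual SD.
#' @slot lambda variance ratio sigmaB^2 / sigmaE^2 at the REML optimum.
#' @slot nGroups number of grouping units (patients).
#' @slot nObs number of observations.
#' @slot logREML restricted log-likelihood at the optimum (up to constant).
#' @slot converged logical.
#' @slot vcov covariance matrix of the fixed effects.
#' @export
setClass("LmmFit",
  representation(coefTable = "data.frame", sigmaB = "numeric",
                 sigmaE = "numeric", lambda = "numeric", nGroups = "integer",
                 nObs = "integer", logREML = "numeric", converged = "logical",
                 vcov = "matrix"),
  validity = function(object) {
    msg <- character()
    if (object@sigmaB < 0 || object@sigmaE < 0)
      msg <- c(msg, "variance components must be non-negative")
    ct <- object@coefTable
    if (nrow(ct)) {
      if (any(ct$lower > ct$estimate + 1e-12 | ct$upper < ct$estimate - 1e-12))
        msg <- c(msg, "each CI must contain its coefficient")
      if (any(ct$p <= 0 | ct$p > 1)) msg <- c(msg, "p-values must be in (0, 1]")
    }
    if (length(msg)) msg else TRUE
  })
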