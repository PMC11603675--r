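#' @rdname VoxelVolume-class
#' @export
setMethod("voxelValues", "VoxelVolume", function(x) x@values)

#' @rdname VoxelVolume-class
#' @export
setMethod("spacing", "VoxelVolume", function(x) x@spacing)

#' @rdname VoxelVolume-class
#' @export
setMethod("origin", "VoxelVolume", function(x) x@origin)

#' @rdname VoxelVolume-class
#' @export
setMethod("dim", "VoxelVolume", function(x) dim(x@values))

#' @rdname TriMesh-class
#' @export
setMethod("meshVertices", "TriMesh", function(x) x@vertices)

#' @rdname TriMesh-class
#' @export
setMethod("meshFaces", "TriMesh", function(x) x@faces)

#' @rdname TriMesh-class
#' @export
setMethod("faceLabels", "TriMesh", function(x) x@faceLabels)

#' @rdname AnatomicalFrame-class
#' @export
setMethod("frameAxes", "AnatomicalFrame", function(x) x@axes)

#' @rdname AnatomicalFrame-class
#' @export
setMethod("origin", "AnatomicalFrame", function(x) x@origin)

#' @rdname DistanceMap-class
#' @export
setMethod("distances", "DistanceMap", function(x) x@distances)

#' @rdname DistanceMap-class
#' @export
setMethod("validVertices", "DistanceMap", function(x) x@valid)

#' @rdname RoiPartition-class
#' @export
setMethod("roiLabels", "RoiPartition", function(x) x@labels)

#' @rdname LmmFit-class
#' @export
setMethod("coefTable", "LmmFit", function(x) x@coefTable)

#' @rdname PhantomTruth-class
#' @export
setMethod("thicknessField", "PhantomTruth", function(x) x@thicknessField)

#' @rdname PhantomTruth-class
#' @export
setMethod("phantomLandmarks", "PhantomTruth", function(x) x@landmarks)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d x %d voxels @ (%.3g, %.3g, %.3g) mm\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  if (is.logical(object@values)) {
    cat(sprintf("  %d foreground voxels (%.1f%%)\n", sum(object@values),
                100 * mean(object@values)))
  } else {
    cat(sprintf("  value range [%.4g, %.4g] HU\n",
                min(object@values), max(object@values)))
  }
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm\n",
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
  if (length(object@faceLabels))
    cat("  face labels:", paste(sprintf("%s (%d)",
        names(table(object@faceLabels)), table(object@faceLabels)),
        collapse = ", "), "\n")
  if (nrow(object@vertices)) {
    rng <- apply(object@vertices, 2, range)
    cat(sprintf("  extent x [%.2f, %.2f], y [%.2f, %.2f], z [%.2f, %.2f] mm\n",
                rng[1,1], rng[2,1], rng[1,2], rng[2,2], rng[1,3], rng[2,3]))
  }
})

setMethod("show", "AnatomicalFrame", function(object) {
  cat("AnatomicalFrame (rows = X right, Y anterior, Z superior):\n")
  cat(sprintf("  origin (%.3f, %.3f, %.3f) mm\n",
              object@origin[1], object@origin[2], object@origin[3]))
  print(round(object@axes, 6))
})

setMethod("show", "DistanceMap", function(object) {
  n <- length(object@distances)
  nv <- sum(object@valid)
  cat(sprintf("DistanceMap: %d vertices, %d valid (%.1f%%), rule '%s'\n",
              n, nv, if (n) 100 * nv / n else 0, object@directionRule))
  if (nv)
    cat(sprintf("  thickness range [%.3f, %.3f] mm, mean %.3f mm\n",
                min(object@distances[object@valid]),
                max(object@distances[object@valid]),
                mean(object@distances[object@valid])))
})

setMethod("show", "RoiPartition", function(object) {
  tb <- table(object@labels)
  cat(sprintf("RoiPartition (|x| <= %.1f mm): ", object@paramedianLimit))
  cat(paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
})

setMethod("show", "LmmFit", function(object) {
  cat(sprintf(
    "Random-intercept LMM (REML): %d obs, %d groups%s\n",
    object@nObs, object@nGroups,
    if (object@converged) "" else " [NOT converged]"))
  cat(sprintf("  sigma_b = %.4f, sigma_e = %.4f\n",
              object@sigmaB, object@sigmaE))
  ct <- object@coefTable
  ct$estimate <- round(ct$estimate, 4)
  ct$lower <- round(ct$lower, 4); ct$upper <- round(ct$upper, 4)
  ct$p <- signif(ct$p, 3)
  print(ct[, c("term", "estimate", "lower", "upper", "p")], row.names = FALSE)
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet:", paste(names(object@points), collapse = ", "), "\n")
  cat(sprintf("  %d occlusal points; tooth bands per side (frame Y, mm)\n",
              nrow(object@occlusalPoints)))
})

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth: analytic thickness field,",
      sprintf("roots r/l = %s/%s, canal = %s\n",
              object@rootsPresent[["r"]], object@rootsPresent[["l"]],
              object@canalPresent))
})
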