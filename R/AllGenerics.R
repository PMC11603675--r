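#' @rdname VoxelVolume-class
#' @param object,x a palatemap object
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname VoxelVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname VoxelVolume-class
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname TriMesh-class
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname TriMesh-class
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname TriMesh-class
#' @export
setGeneric("faceLabels", function(x) standardGeneric("faceLabels"))

#' @rdname AnatomicalFrame-class
#' @export
setGeneric("frameAxes", function(x) standardGeneric("frameAxes"))

#' @rdname DistanceMap-class
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname DistanceMap-class
#' @export
setGeneric("validVertices", function(x) standardGeneric("validVertices"))

#' @rdname RoiPartition-class
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname LmmFit-class
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname PhantomTruth-class
#' @export
setGeneric("thicknessField", function(x) standardGeneric("thicknessField"))

#' @rdname PhantomTruth-class
#' @export
setGeneric("phantomLandmarks", function(x) standardGeneric("phantomLandmarks"))
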