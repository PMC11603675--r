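#' Construct a VoxelVolume
#'
#' @param values 3D numeric array of HU values
#' @param spacing numeric(3) voxel spacing in mm (scalar recycled)
#' @param origin numeric(3) world position of voxel (1,1,1) in mm
#' @return a [VoxelVolume-class]
#' @export
voxelVolume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VoxelVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Threshold an HU volume into a binary mask
#'
#' Selects voxels with `lo_hu <= value <= hi_hu`. The working range for
#' maxillary hard-tissue segmentation is 50-2000 HU; the bone pass and the
#' separate teeth pass differ only in the lower bound (defaults 400 and
#' 1500 HU).
#'
#' @param volume a [VoxelVolume-class]
#' @param lo_hu,hi_hu inclusive HU bounds, `lo_hu < hi_hu`
#' @return a [BinaryMask-class]
#' @export
segmentThreshold <- function(volume, lo_hu, hi_hu) {
  stopifnot(is(volume, "VoxelVolume"))
  if (!(lo_hu < hi_hu))
    stop("inverted thresholds: lo_hu (", lo_hu, ") must be < hi_hu (", hi_hu, ")")
  m <- volume@values >= lo_hu & volume@values <= hi_hu
  new("BinaryMask", values = m, spacing = volume@spacing,
      origin = volume@origin)
}

#' Keep the largest connected component(s) of a mask
#'
#' Components are 26-connected. The largest component is always kept;
#' additional components are kept when they contain at least `min_voxels`
#' voxels. This is the automated stand-in for the manual clean-up step of
#' interactive segmentation protocols.
#'
#' @param mask a [BinaryMask-class]
#' @param min_voxels size threshold for secondary components (default 1000,
#'   calibrated for 0.3 mm voxels = 27 mm^3)
#' @return a filtered [BinaryMask-class]
#' @export
largestComponent <- function(mask, min_voxels = 1000) {
  stopifnot(is(mask, "BinaryMask"))
  if (!any(mask@values)) {
    warning("empty mask: no components to keep")
    return(mask)
  }
  lab <- .cpp_label_components(as.vector(mask@values), dim(mask@values))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  keep <- union(1L, keep) # labels sorted by size, 1 = largest
  vals <- array(lab %in% keep & lab > 0L, dim(mask@values))
  new("BinaryMask", values = vals, spacing = mask@spacing,
      origin = mask@origin)
}

#' Extract an iso-surface mesh from a volume or mask
#'
#' Marching-tetrahedra iso-surfacing on the continuous HU field (sub-voxel
#' linear interpolation, which avoids the staircase bias of meshing the
#' binary mask directly). Vertex coordinates are in mm
#' (`voxel index * spacing + origin`); triangle winding gives outward
#' normals (pointing toward the low-HU side). For a [BinaryMask-class] the
#' surface is placed halfway between foreground and background voxels.
#'
#' @param x a [VoxelVolume-class] or [BinaryMask-class]
#' @param iso_level iso value in HU (ignored for masks); typically the
#'   segmentation lower threshold
#' @return a [TriMesh-class]
#' @export
extractSurface <- function(x, iso_level = NULL) {
  stopifnot(is(x, "VoxelVolume"))
  if (is(x, "BinaryMask")) {
    vals <- array(as.double(x@values), dim(x@values))
    iso_level <- 0.5
  } else {
    vals <- x@values
    storage.mode(vals) <- "double"
    if (is.null(iso_level)) stop("iso_level is required for an HU volume")
  }
  if (all(vals < iso_level) || all(vals >= iso_level))
    stop("empty mesh: iso level ", iso_level,
         " does not intersect the volume")
  res <- .cpp_marching_tets(as.vector(vals), dim(vals),
                            x@spacing, x@origin, as.double(iso_level))
  cleanMesh(triMesh(res$vertices, res$faces))
}

#' Voxel-count volume of a mask
#'
#' Number of foreground voxels times the voxel volume; the independent
#' oracle for enclosed mesh volumes.
#'
#' @param mask a [BinaryMask-class]
#' @return volume in mm^3
#' @export
voxelVolumeOf <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  sum(mask@values) * prod(mask@spacing)
}

#' Segment bone and teeth surfaces from an HU volume
#'
#' The two-pass procedure: a bone pass at `[lo_hu, hi_hu]` and a separate
#' teeth pass at `[teeth_lo_hu, hi_hu]` (tooth enamel/dentin sit at higher
#' HU than trabecular bone), each followed by component filtering and
#' iso-surface extraction, then merged with per-face labels. Voxels in the
#' teeth pass are excluded from the bone pass so the two surfaces do not
#' duplicate.
#'
#' @param volume a [VoxelVolume-class]
#' @param lo_hu,hi_hu bone-pass thresholds (defaults 400, 2000 HU)
#' @param teeth_lo_hu teeth-pass lower threshold (default 1500 HU)
#' @param min_voxels component-size threshold, see [largestComponent()]
#' @param smooth_iterations optional Laplacian smoothing sweeps applied to
#'   both surfaces (default 0: extracted surfaces are used as-is)
#' @param hu_air HU value assigned to rejected voxels
#' @return list with `bone`, `teeth` and `merged` [TriMesh-class] objects
#'   plus the two masks
#' @export
segmentBoneTeeth <- function(volume, lo_hu = 400, hi_hu = 2000,
                             teeth_lo_hu = 1500, min_voxels = 1000,
                             smooth_iterations = 0,
                             hu_air = -1000) {
  teeth_mask <- segmentThreshold(volume, teeth_lo_hu, hi_hu)
  if (any(teeth_mask@values))
    teeth_mask <- largestComponent(teeth_mask,
                                   min_voxels = max(1, min_voxels / 4))
  bone_mask <- segmentThreshold(volume, lo_hu, hi_hu)
  bone_mask@values <- bone_mask@values & !teeth_mask@values
  bone_mask <- largestComponent(bone_mask, min_voxels = min_voxels)

  # mesh the continuous HU field so the surface keeps sub-voxel grey-value
  # interpolation; only voxels above threshold that were rejected (teeth,
  # discarded components) are knocked down to air -- sub-threshold voxels
  # keep their grey values, preserving the partial-volume gradient
  bone_field <- volume
  rejected <- (volume@values >= lo_hu & !bone_mask@values) |
    teeth_mask@values
  bone_field@values[rejected] <- hu_air
  bone <- extractSurface(bone_field, iso_level = lo_hu)

  teeth <- if (any(teeth_mask@values)) {
    teeth_field <- volume
    teeth_field@values[volume@values >= teeth_lo_hu &
                         !teeth_mask@values] <- hu_air
    extractSurface(teeth_field, iso_level = teeth_lo_hu)
  } else triMesh(matrix(numeric(), 0L, 3L), matrix(integer(), 0L, 3L))
  if (smooth_iterations > 0) {
    bone <- smoothMesh(bone, smooth_iterations)
    if (nrow(teeth@vertices)) teeth <- smoothMesh(teeth, smooth_iterations)
  }
  list(bone = bone, teeth = teeth,
       merged = mergeMeshes(bone, teeth),
       bone_mask = bone_mask, teeth_mask = teeth_mask)
}
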