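test_that("thresholding selects the inclusive HU window and validates bounds", {
  vals <- array(c(-1000, 40, 1200, 1800, 400, 2000, 2001, 399),
                c(2, 2, 2))
  vol <- voxelVolume(vals, 0.5)
  m <- segmentThreshold(vol, 400, 2000)
  expect_identical(as.vector(voxelValues(m)),
                   as.vector(vals >= 400 & vals <= 2000))
  m2 <- segmentThreshold(vol, 1500, 2000)
  expect_identical(sum(voxelValues(m2)), 2L) # 1800 and 2000
  expect_error(segmentThreshold(vol, 2000, 50), "inverted")

  # monotone: widening the window never removes voxels
  set.seed(1)
  rv <- voxelVolume(array(runif(4000, -1000, 2500), c(20, 20, 10)), 0.4)
  narrow <- voxelValues(segmentThreshold(rv, 400, 1500))
  wide <- voxelValues(segmentThreshold(rv, 300, 1800))
  expect_true(all(wide[narrow]))
  # idempotent by definition (pointwise predicate)
  expect_identical(voxelValues(segmentThreshold(rv, 400, 1500)), narrow)
})

test_that("component filtering keeps the largest plus large-enough blobs", {
  a <- array(FALSE, c(30, 12, 12))
  a[1:5, 1:5, 1:4] <- TRUE          # 100 voxels
  a[20:24, 1:4, 1:3] <- TRUE        # 60 voxels
  a[28:29, 10:11, 10:11] <- TRUE    # 8 voxels
  m <- new("BinaryMask", values = a, spacing = rep(0.5, 3),
           origin = c(0, 0, 0))
  kept <- voxelValues(largestComponent(m, min_voxels = 50))
  expect_true(all(kept[1:5, 1:5, 1:4]))
  expect_true(all(kept[20:24, 1:4, 1:3]))
  expect_false(any(kept[28:29, 10:11, 10:11]))
  kept2 <- voxelValues(largestComponent(m, min_voxels = 70))
  expect_identical(sum(kept2), 100L)
  # single blob unchanged
  b <- m; b@values[] <- FALSE; b@values[5:10, 5:10, 5:10] <- TRUE
  expect_identical(voxelValues(largestComponent(b, 50)), b@values)
  empty <- m; empty@values[] <- FALSE
  expect_warning(largestComponent(empty), "empty")
})

test_that("voxel-count volume is count times voxel volume", {
  a <- array(FALSE, c(20, 20, 20))
  a[1:10, 1:10, 1:10] <- TRUE
  m <- new("BinaryMask", values = a, spacing = rep(0.3, 3),
           origin = c(0, 0, 0))
  expect_equal(voxelVolumeOf(m), 1000 * 0.027)
  m@values[] <- FALSE
  expect_equal(voxelVolumeOf(m), 0)
  m@values[] <- TRUE
  m@spacing <- c(1, 1, 1)
  expect_equal(voxelVolumeOf(m), 8000)
})

test_that("iso-surface of a sphere matches the voxel-count volume within 2%", {
  vol <- sphere_volume()
  mask <- segmentThreshold(vol, 400, 2000)
  mesh <- extractSurface(vol, 400)
  mv <- meshVolume(mesh)
  vv <- voxelVolumeOf(mask)
  expect_lt(abs(mv - vv) / vv, 0.02)
  expect_lt(abs(mv - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
  # outward orientation gives positive signed volume
  expect_gt(mv, 0)
  # empty / non-intersecting iso level
  expect_error(extractSurface(vol, 5000), "empty mesh")
})

test_that("segmented slab surfaces sit at the slab planes", {
  px <- slab_seg()
  V <- meshVertices(px$oral)
  inner <- abs(V[, 1]) < 8 & abs(V[, 2]) < 3
  # oral plane at z ~ 0 (frame z is shifted by the landmark midpoint)
  z_oral <- V[inner, 3] - min(V[inner, 3])
  expect_lt(diff(range(V[inner, 3])), 0.2)
  dm <- computeDistanceMap(px$oral, px$nasal)
  d <- distances(dm)[inner]
  expect_true(all(abs(d - 5) < 2 * 0.3))
})

test_that("mesh merging preserves coordinates and labels", {
  mp <- slab_pair()
  bone <- mp$oral; teeth <- mp$nasal
  merged <- mergeMeshes(bone, teeth)
  nb <- nrow(meshVertices(bone))
  expect_identical(nrow(meshVertices(merged)),
                   nb + nrow(meshVertices(teeth)))
  expect_identical(meshVertices(merged)[seq_len(nb), ],
                   meshVertices(bone))
  expect_identical(meshVertices(merged)[-seq_len(nb), ],
                   meshVertices(teeth))
  expect_setequal(unique(faceLabels(merged)), c("bone", "teeth"))
  expect_identical(faceLabels(merged)[nrow(meshFaces(bone)) + 1L], "teeth")
  # empty teeth -> identity
  empty <- triMesh(matrix(numeric(), 0, 3), matrix(integer(), 0, 3))
  same <- mergeMeshes(bone, empty)
  expect_identical(meshVertices(same), meshVertices(bone))
  # merge order only permutes blocks, coordinates never change
  m2 <- mergeMeshes(teeth, bone)
  expect_equal(sort(meshVertices(m2)[, 1]), sort(meshVertices(merged)[, 1]))
})

test_that("volume IO round-trips exactly through NRRD", {
  td <- withr::local_tempdir()
  v <- voxelVolume(array(rnorm(10 * 12 * 8), c(10, 12, 8)),
                   c(0.3, 0.3, 0.6), c(-5, 2, 1.5))
  writeVolume(v, file.path(td, "v.nrrd"))
  v2 <- readVolume(file.path(td, "v.nrrd"))
  expect_identical(voxelValues(v2), voxelValues(v))
  expect_identical(spacing(v2), spacing(v))   # anisotropic, exact
  expect_identical(origin(v2), origin(v))
  expect_error(readVolume(file.path(td, "absent.nrrd")), "not found")
  # malformed header
  writeLines("not a volume", file.path(td, "bad.nrrd"))
  expect_error(readVolume(file.path(td, "bad.nrrd")), "NRRD")
})

test_that("STL IO round-trips binary and reads ASCII", {
  td <- withr::local_tempdir()
  mesh <- slab_pair()$oral
  writeSTL(mesh, file.path(td, "m.stl"))
  m2 <- readSTL(file.path(td, "m.stl"))
  expect_equal(nrow(meshVertices(m2)), nrow(meshVertices(mesh)))
  expect_equal(sum(faceAreas(m2)), sum(faceAreas(mesh)), tolerance = 1e-6)
  expect_equal(meshVolume(m2), meshVolume(mesh), tolerance = 1e-6)
  # a minimal ASCII STL: one triangle
  writeLines(c("solid t",
               " facet normal 0 0 1", "  outer loop",
               "   vertex 0 0 0", "   vertex 1 0 0", "   vertex 0 1 0",
               "  endloop", " endfacet", "endsolid t"),
             file.path(td, "a.stl"))
  ma <- readSTL(file.path(td, "a.stl"))
  expect_identical(nrow(meshFaces(ma)), 1L)
  expect_equal(unname(faceAreas(ma)), 0.5)
})
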