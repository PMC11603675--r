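make_test_landmarks <- function(R = diag(3), t = c(0, 0, 0)) {
  mv <- function(p) as.numeric(rigidly_move(rbind(p), R, t))
  new("LandmarkSet",
      points = list(ANS = mv(c(0, 50, 0)), PNS = mv(c(0, 0, 0)),
                    molar_fissure_r = mv(c(20, 20, -5)),
                    molar_fissure_l = mv(c(-20, 20, -5))),
      occlusalPoints = rigidly_move(
        rbind(c(-10, 10, -10), c(10, 10, -10), c(0, 40, -10)), R, t),
      toothBands = list(
        r = list(anchors = c(canine_p1 = 30, p1_mid = 27, p1_p2 = 24),
                 bands = list(p1 = c(24, 30), p2 = c(20, 24),
                              m1 = c(12, 18))),
        l = list(anchors = c(canine_p1 = 30, p1_mid = 27, p1_p2 = 24),
                 bands = list(p1 = c(24, 30), p2 = c(20, 24),
                              m1 = c(12, 18)))))
}

test_that("frame axes follow the anatomical convention in the aligned case", {
  fr <- buildFrame(make_test_landmarks())
  expect_equal(frameAxes(fr), rbind(X = c(1, 0, 0), Y = c(0, 1, 0),
                                    Z = c(0, 0, 1)), tolerance = 1e-12)
  expect_equal(origin(fr), c(0, 25, 0))
  expect_equal(det(frameAxes(fr)), 1, tolerance = 1e-12)
})

test_that("frame construction is orthonormal, scale-free and motion-equivariant", {
  set.seed(42)
  for (i in 1:10) {
    R <- random_rotation()
    t <- rnorm(3, 0, 30)
    lm <- make_test_landmarks(R, t)
    fr <- buildFrame(lm)
    A <- frameAxes(fr)
    expect_lt(max(abs(A %*% t(A) - diag(3))), 1e-9)
    expect_equal(det(A), 1, tolerance = 1e-9)
    # the recovered axes undo the applied rotation
    expect_lt(max(abs(A %*% R - diag(3))), 1e-8)
  }
  # scale-free: doubling all landmarks leaves the rotation unchanged
  lm1 <- make_test_landmarks()
  lm2 <- lm1
  lm2@points <- lapply(lm1@points, function(p) 2 * p)
  lm2@occlusalPoints <- 2 * lm1@occlusalPoints
  expect_equal(frameAxes(buildFrame(lm2)), frameAxes(buildFrame(lm1)),
               tolerance = 1e-12)
  # degenerate landmarks
  bad <- lm1
  bad@points$ANS <- bad@points$PNS
  expect_error(buildFrame(bad), "distinct|coincide")
})

test_that("transformToFrame is a rigid motion with exact round-trip", {
  set.seed(7)
  mesh <- slab_pair()$oral
  R <- random_rotation(); t <- c(12, -30, 5)
  moved <- mesh
  moved@vertices <- rigidly_move(meshVertices(mesh), R, t)
  fr <- new("AnatomicalFrame", origin = t, axes = t(R))
  back <- transformToFrame(moved, fr)
  expect_equal(meshVertices(back), meshVertices(mesh), tolerance = 1e-9,
               ignore_attr = TRUE)
  # pairwise distances preserved
  i <- sample(nrow(meshVertices(mesh)), 50)
  d0 <- dist(meshVertices(moved)[i, ])
  d1 <- dist(meshVertices(back)[i, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # identity frame
  id <- new("AnatomicalFrame", origin = c(0, 0, 0), axes = diag(3))
  expect_identical(meshVertices(transformToFrame(mesh, id)),
                   meshVertices(mesh))
  # inverse round trip
  p <- matrix(rnorm(30), 10)
  expect_equal(transformPoints(transformPoints(p, fr), fr, inverse = TRUE),
               p, tolerance = 1e-9)
})

test_that("ROI partition obeys band, strip and tie-break rules", {
  mp <- slab_pair()
  lm <- phantomLandmarks(mp$truth)
  fr <- buildFrame(lm)
  oral <- transformToFrame(mp$oral, fr)
  part <- partitionRoi(oral, lm)
  lab <- roiLabels(part)
  ctr <- faceCentroids(oral)
  # definition checks on every face
  b <- lm@toothBands$r$bands
  in1r <- ctr[, 1] >= 0 & ctr[, 1] <= 10 &
    ctr[, 2] >= b$p1[1] & ctr[, 2] < b$p1[2]
  expect_identical(lab == "1r", in1r)
  # symmetric phantom: equal left/right areas per band
  A <- faceAreas(oral)
  expect_equal(sum(A[lab == "1r"]), sum(A[lab == "1l"]), tolerance = 1e-9)
  expect_equal(sum(A[lab == "2r"]), sum(A[lab == "2l"]), tolerance = 1e-9)
  # beyond the paramedian limit -> none
  part5 <- partitionRoi(oral, lm, paramedian_limit_mm = 3)
  expect_true(all(abs(ctr[roiLabels(part5) != "none", 1]) <= 3))
  # labels invariant under consistent rigid motion (bands are frame-level)
  expect_identical(lab, roiLabels(partitionRoi(oral, lm)))
  # sum of ROI areas cannot exceed the patch area
  expect_lte(sum(A[lab != "none"]), sum(A) + 1e-9)
})

test_that("probe points sit on the oral surface at +/-3 mm paramedian", {
  px <- vault_roots()
  pts <- placeProbePoints(px$oral, phantomLandmarks(px$ph$truth))
  expect_setequal(pts$id, c("1r", "2r", "3r", "1l", "2l", "3l"))
  expect_equal(pts$x, c(3, 3, 3, -3, -3, -3), tolerance = 1e-9)
  # mirror symmetry of the two sides
  expect_equal(pts$y[match("1r", pts$id)], pts$y[match("1l", pts$id)])
  expect_equal(pts$z[match("1r", pts$id)], pts$z[match("1l", pts$id)],
               tolerance = 0.1)
  # on the oral surface: re-casting a vertical ray hits at ~0 distance
  hit <- palatemap:::castRays(px$oral,
                              cbind(pts$x, pts$y, pts$z + 1),
                              matrix(rep(c(0, 0, -1), each = 6), ncol = 3),
                              maxRay = 10)
  expect_true(all(abs(hit$distance - 1) < 0.05))
  # normals face the oral cavity
  expect_true(all(pts$nz < 0))
  # anchor outside the mesh -> placement error naming the point
  lm_bad <- phantomLandmarks(px$ph$truth)
  lm_bad@toothBands$r$anchors[["canine_p1"]] <- 500
  expect_error(placeProbePoints(px$oral, lm_bad), "1r")
})
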