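test_that("angled directions rotate the anti-normal sagittally", {
  expect_equal(angledDirection(c(0, 0, -1), 0), c(0, 0, 1))
  expect_equal(angledDirection(c(0, 0, -1), 30),
               c(0, 0.5, cos(30 * pi / 180)), tolerance = 1e-6)
  # 0 degrees is exactly antiparallel for any normal
  set.seed(3)
  for (i in 1:10) {
    nv <- rnorm(3); nv <- nv / sqrt(sum(nv^2))
    d <- angledDirection(nv, 0)
    expect_equal(sum(d * nv), -1, tolerance = 1e-12)
    # any tilt returns a unit vector at the requested angle from d0
    th <- runif(1, 0, 45)
    dt <- angledDirection(nv, th)
    expect_equal(sqrt(sum(dt^2)), 1, tolerance = 1e-12)
  }
  expect_error(angledDirection(c(0, 0, 0), 10), "zero")
  expect_error(angledDirection(c(0, 0, -1), 60), "theta")
})

test_that("plane-parallel thickness follows the 1/cos(theta) law", {
  mp <- slab_pair()
  lm <- phantomLandmarks(mp$truth)
  fr <- buildFrame(lm)
  oral <- transformToFrame(mp$oral, fr)
  nasal <- transformToFrame(mp$nasal, fr)
  pts <- placeProbePoints(oral, lm)
  pr <- measurePointThickness(pts, c(0, 10, 20, 30), nasal)
  expect_identical(nrow(pr), 24L)
  for (th in c(0, 10, 20, 30)) {
    expected <- 5 / cos(th * pi / 180)
    got <- pr$thickness_mm[pr$angle_deg == th]
    expect_lt(max(abs(got - expected)), 1e-6)
  }
  expect_equal(pr$thickness_mm[pr$point_id == "1r" & pr$angle_deg == 30],
               5.7735, tolerance = 1e-4)
  # 0-degree probe equals the distance map at the same location
  dm <- computeDistanceMap(oral, nasal)
  expect_lt(max(abs(pr$thickness_mm[pr$angle_deg == 0] -
                      distances(dm)[1])), 1e-6)
  expect_false(any(pr$root_hit))
})

test_that("vault roots intercept only the tilted point-1 rays", {
  px <- vault_roots()
  pts <- placeProbePoints(px$oral, phantomLandmarks(px$ph$truth))
  pr <- measurePointThickness(pts, c(0, 10, 20, 30), px$nasal, px$teeth)
  p1 <- pr[pr$point_id %in% c("1r", "1l"), ]
  expect_false(any(p1$root_hit[p1$angle_deg %in% c(0, 10)]))
  expect_true(all(p1$root_hit[p1$angle_deg %in% c(20, 30)]))
  expect_true(all(p1$root_depth_mm[p1$angle_deg == 30] <
                    p1$thickness_mm[p1$angle_deg == 30], na.rm = TRUE))
  # usable depth decreases toward 30 degrees at point 1 ...
  usable <- function(rows) pmin(rows$thickness_mm, rows$root_depth_mm,
                                na.rm = TRUE)
  u1 <- vapply(c(0, 20, 30), function(a)
    usable(p1[p1$angle_deg == a & p1$side == "r", ]), numeric(1))
  expect_true(all(diff(u1) < 0))
  # ... while thickness at points 2/3 increases with the angle
  for (pid in c("2r", "3r", "2l", "3l")) {
    th <- pr$thickness_mm[pr$point_id == pid][order(
      pr$angle_deg[pr$point_id == pid])]
    expect_true(all(diff(th) > 0))
  }
})

test_that("corridor fit reports the limiting structure", {
  imp <- implantSpec(diameter_mm = 2, length_mm = 7)
  # generous bone: 12 mm slab, no teeth -> fits
  thick <- makeMeshPair("slab", thickness = 12)
  lm <- phantomLandmarks(thick$truth)
  pts <- placeProbePoints(thick$oral, lm)
  fit <- corridorFit(pts[1, ], 0, implantSpec(2, 9), thick$nasal)
  expect_true(fit$fits)
  expect_identical(fit$limiting_structure, "none")
  expect_equal(fit$min_thickness_mm, 12, tolerance = 1e-9)
  # shallow bone: 6 mm slab, 7 mm implant -> nasal floor perforation
  shallow <- makeMeshPair("slab", thickness = 6)
  pts_s <- placeProbePoints(shallow$oral, phantomLandmarks(shallow$truth))
  fit_s <- corridorFit(pts_s[1, ], 0, imp, shallow$nasal)
  expect_false(fit_s$fits)
  expect_identical(fit_s$limiting_structure, "nasal_floor")
  # root plate at 4 mm depth inside 12 mm bone -> tooth root blocks
  root_plate <- triMesh(
    rbind(c(-8, -6, 4), c(8, -6, 4), c(8, 6, 4), c(-8, 6, 4)),
    rbind(c(1, 2, 3), c(1, 3, 4)))
  fit_r <- corridorFit(pts[1, ], 0, imp, thick$nasal, root_plate)
  expect_false(fit_r$fits)
  expect_identical(fit_r$limiting_structure, "tooth_root")
  expect_equal(fit_r$min_root_depth_mm, 4, tolerance = 1e-9)
  expect_error(implantSpec(diameter_mm = 7), "diameter")
  expect_error(implantSpec(length_mm = 30), "length")
})

test_that("root-in-ROI flags mirror the phantom construction", {
  px <- vault_roots()
  flags <- rootsInRegion(px$oral, px$part, px$teeth, corridor_depth_mm = 8)
  expect_true(flags[["1r"]])
  expect_true(flags[["1l"]])
  expect_false(flags[["3r"]])
  expect_false(flags[["3l"]])
  # no teeth -> false everywhere
  empty <- triMesh(matrix(numeric(), 0, 3), matrix(integer(), 0, 3))
  expect_false(any(rootsInRegion(px$oral, px$part, empty)))
  pp <- vault_plain()
  expect_false(any(rootsInRegion(pp$oral, pp$part, pp$teeth)))
})
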