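test_that("distance maps recover analytic separations on exact mesh pairs", {
  mp <- slab_pair()
  dm <- computeDistanceMap(mp$oral, mp$nasal)
  expect_true(all(validVertices(dm)))
  expect_lt(max(abs(distances(dm) - 5)), 1e-9)
  # monotonicity: thickening the slab by delta shifts every distance by delta
  mp6 <- makeMeshPair("slab", thickness = 6.5)
  dm6 <- computeDistanceMap(mp6$oral, mp6$nasal)
  expect_lt(max(abs(distances(dm6) - distances(dm) - 1.5)), 1e-9)

  sh <- shell_pair()
  dsh <- computeDistanceMap(sh$oral, sh$nasal)
  expect_lt(max(abs(distances(dsh) - 2)), 0.01)

  expect_error(computeDistanceMap(mp$oral,
    triMesh(matrix(numeric(), 0, 3), matrix(integer(), 0, 3))), "empty")
})

test_that("ROI summaries satisfy AA/MD/Vol identities and slab oracles", {
  mp <- slab_pair()
  lm <- phantomLandmarks(mp$truth)
  fr <- buildFrame(lm)
  oral <- transformToFrame(mp$oral, fr)
  # nasal stays in world frame: distances are frame-invariant here because
  # the slab frame is a pure translation
  dm <- computeDistanceMap(oral, transformToFrame(mp$nasal, fr))
  part <- partitionRoi(oral, lm)
  rs <- summarizeRoi(oral, part, dm)
  tot <- rs[rs$roi == "total", ]
  expect_equal(tot$AA, 200)           # 20 x 10 mm patch
  expect_equal(tot$MD, 5)
  expect_equal(tot$Vol, 1000)
  # Vol == AA * MD identically, per ROI
  per <- rs[rs$roi != "total", ]
  expect_lt(max(abs(per$Vol - per$AA * per$MD) / pmax(per$Vol, 1)), 1e-9)
  # conservation: ROI volumes sum to the union total
  expect_equal(sum(per$Vol), tot$Vol, tolerance = 1e-9)
})

test_that("gradient wedge mean distance equals the ramp midpoint", {
  mw <- wedge_pair()
  lm <- phantomLandmarks(mw$truth)
  fr <- buildFrame(lm)
  oral <- transformToFrame(mw$oral, fr)
  dm <- computeDistanceMap(oral, transformToFrame(mw$nasal, fr))
  part <- partitionRoi(oral, lm)
  rs <- summarizeRoi(oral, part, dm)
  tot <- rs[rs$roi == "total", ]
  expect_equal(tot$MD, 6.75, tolerance = 1e-9) # (10 + 3.5) / 2
  expect_equal(tot$Vol, tot$AA * 6.75, tolerance = 1e-9)
})

test_that("segmented vault thickness map matches the analytic truth", {
  px <- vault_plain()
  dm <- computeDistanceMap(px$oral, px$nasal)
  rs <- summarizeRoi(px$oral, px$part, dm)
  # per-band truth: area-weighted mean of the linear profile at band centre
  truth_md <- c(`1` = 8.18, `2` = 6.88, `3` = 5.06)
  for (band in c("1", "2", "3")) {
    for (s in c("r", "l")) {
      md <- rs$MD[rs$roi == paste0(band, s)]
      expect_lt(abs(md - truth_md[[band]]), 2 * 0.4)
    }
  }
  # left/right symmetry of the phantom
  expect_lt(abs(rs$AA[rs$roi == "1r"] - rs$AA[rs$roi == "1l"]) /
              rs$AA[rs$roi == "1l"], 0.05)
  # analytic band area: 6 mm x inner-arc strip half-width 10 mm
  expect_lt(abs(rs$AA[rs$roi == "1r"] - 6 * 15 * asin(10 / 15)) /
              (6 * 15 * asin(10 / 15)), 0.05)
})

test_that("canal void invalidates map vertices and reduces coverage", {
  pc <- vault_canal()
  pp <- vault_plain()
  dc <- computeDistanceMap(pc$oral, pc$nasal)
  dp <- computeDistanceMap(pp$oral, pp$nasal)
  rc <- summarizeRoi(pc$oral, pc$part, dc)
  rp <- summarizeRoi(pp$oral, pp$part, dp)
  # the canal pierces ROI 3r: area drops there relative to the intact vault
  expect_lt(rc$AA[rc$roi == "3r"], rp$AA[rp$roi == "3r"] - 1)
  # and only there: the mirrored ROI is unaffected
  expect_equal(rc$AA[rc$roi == "3l"], rp$AA[rp$roi == "3l"],
               tolerance = 0.02)
})

test_that("color map export writes PLY plus a faithful JSON sidecar", {
  td <- withr::local_tempdir()
  mp <- slab_pair()
  dm <- computeDistanceMap(mp$oral, mp$nasal)
  out <- file.path(td, "map.ply")
  exportColorMap(mp$oral, dm, out, limits = c(2, 8))
  expect_true(file.exists(out))
  side <- jsonlite::read_json(paste0(out, ".json"), simplifyVector = TRUE)
  expect_equal(side$limits_mm, c(2, 8))
  expect_equal(side$n_valid, sum(validVertices(dm)))
  ply <- readLines(out)
  expect_true(any(grepl("property uchar red", ply)))
  # constant map -> a single color for all vertices
  body <- ply[(which(ply == "end_header") + 1):(which(ply == "end_header") +
                                                  side$n_vertices)]
  cols <- unique(vapply(strsplit(body, " "),
                        function(p) paste(p[4:6], collapse = ","),
                        character(1)))
  expect_identical(length(cols), 1L)
})
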