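test_that("slab phantom is built to specification and rejects coarse grids", {
  ph <- makeSlabPhantom(thickness_mm = 5, spacing_mm = 0.3)
  expect_s4_class(ph$volume, "VoxelVolume")
  expect_equal(spacing(ph$volume), rep(0.3, 3))
  # truth field is the constant slab thickness
  p <- cbind(runif(10, -5, 5), runif(10, -3, 3), 0)
  expect_equal(thicknessField(ph$truth)(p), rep(5, 10))
  # tilted-ray plane-parallel oracle
  expect_equal(5 / cos(30 * pi / 180), 5.7735, tolerance = 1e-4)
  expect_error(makeSlabPhantom(thickness_mm = 5, spacing_mm = 2),
               "resolution")
})

test_that("vault phantom carries the anterior-posterior thickness gradient", {
  ph <- vault_plain()$ph
  tf <- thicknessField(ph$truth)
  z1 <- sqrt(15^2 - 0)
  ant <- tf(cbind(0, 39, z1))
  post <- tf(cbind(0, 16, z1))
  expect_equal(ant, 9.74, tolerance = 1e-6) # linear profile at y = 39
  expect_equal(post, 3.76, tolerance = 1e-6)
  expect_gt(ant, post)
  # band-level truth: ~10 anteriorly, ~3.5 posteriorly at the profile ends
  expect_equal(tf(cbind(0, 40, z1)), 10)
  expect_equal(tf(cbind(0, 15, z1)), 3.5)
  # undefined outside the shell
  expect_true(is.na(tf(cbind(0, 5, z1))))
  expect_error(makeVaultPhantom(thickness_anterior_mm = 2,
                                thickness_posterior_mm = 5),
               "thickness")
})

test_that("vault truth marks the nerve-canal footprint undefined", {
  ph <- makeVaultPhantom(canal_on = TRUE, spacing_mm = 0.5)
  tf <- thicknessField(ph$truth)
  inside <- tf(cbind(6.5, 21, sqrt(15^2 - 6.5^2)))
  outside <- tf(cbind(-6.5, 21, sqrt(15^2 - 6.5^2)))
  expect_true(is.na(inside))
  expect_false(is.na(outside))
})

test_that("mesh pairs have their analytic separation", {
  mp <- slab_pair()
  dm <- computeDistanceMap(mp$oral, mp$nasal)
  expect_true(all(validVertices(dm)))
  expect_equal(max(abs(distances(dm) - 5)), 0, tolerance = 1e-9)

  sh <- shell_pair()
  dsh <- computeDistanceMap(sh$oral, sh$nasal)
  expect_true(all(validVertices(dsh)))
  expect_lt(max(abs(distances(dsh) - 2)), 0.01)

  expect_error(makeMeshPair("dodecahedron"), "arg")
})

test_that("cohort simulation is seed-deterministic and noiseless in the limit", {
  cs <- cohortSpec(n_patients = 50, seed = 1)
  t1 <- sampleCohort(cs)
  t2 <- sampleCohort(cs)
  expect_identical(t1, t2)
  t3 <- sampleCohort(cohortSpec(n_patients = 50, seed = 2))
  expect_false(identical(t1$response, t3$response))

  # sigma_b = sigma_e = 0 -> responses are exactly X beta
  cs0 <- cohortSpec(n_patients = 20, sigma_b = 0, sigma_e = 0, seed = 7)
  t0 <- sampleCohort(cs0)
  X <- model.matrix(~ sex + age_group + teeth + side + roi, t0)
  beta <- setNames(numeric(ncol(X)), colnames(X))
  beta[names(cs0$fixed_effects)] <- cs0$fixed_effects
  expect_equal(t0$response, as.vector(X %*% beta), tolerance = 1e-12)

  # ages are consistent with their age group
  grp <- assignAgeGroup(t0$age_years)
  expect_identical(as.character(grp), as.character(t0$age_group))

  expect_error(cohortSpec(age_group_probs = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(cohortSpec(sigma_b = -1), "sigma")
})

test_that("cohort fixed effects are recovered by the mixed model", {
  # parameter recovery at n = 200, one seed (deeper sweep in acceptance)
  cs <- cohortSpec(n_patients = 200, seed = 11)
  ct <- coefTable(fitLmm(sampleCohort(cs),
                         response ~ sex + age_group + teeth + side + roi))
  i <- match("sexfemale", ct$term)
  expect_lt(abs(ct$estimate[i] - (-1.12)) / ct$se[i], 3)
})
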