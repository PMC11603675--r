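# Shared fixtures, built once per test run and cached. All geometry fixtures
# are generated in code; nothing is loaded from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, build(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# full segmentation -> frame -> patches -> partition pipeline on a phantom
phantom_pipeline <- function(ph) {
  seg <- segmentBoneTeeth(ph$volume)
  fr <- buildFrame(phantomLandmarks(ph$truth))
  bone <- transformToFrame(seg$bone, fr)
  teeth <- if (nrow(meshVertices(seg$teeth)))
    transformToFrame(seg$teeth, fr) else seg$teeth
  oral <- selectOralPatch(bone)
  nasal <- selectNasalPatch(bone)
  part <- partitionRoi(oral, phantomLandmarks(ph$truth))
  list(ph = ph, seg = seg, frame = fr, bone = bone, teeth = teeth,
       oral = oral, nasal = nasal, part = part)
}

vault_roots <- function() fixture("vault_roots", function() {
  phantom_pipeline(makeVaultPhantom(roots_on = TRUE, spacing_mm = 0.4))
})

vault_plain <- function() fixture("vault_plain", function() {
  phantom_pipeline(makeVaultPhantom(spacing_mm = 0.4))
})

vault_canal <- function() fixture("vault_canal", function() {
  phantom_pipeline(makeVaultPhantom(canal_on = TRUE, spacing_mm = 0.4))
})

slab_seg <- function() fixture("slab_seg", function() {
  # lateral extent large enough that 30-degree rays from the probe points
  # still exit through the top surface
  phantom_pipeline(makeSlabPhantom(thickness_mm = 5,
                                   lateral_extent_mm = c(20, 20),
                                   spacing_mm = 0.3))
})

slab_pair <- function() fixture("slab_pair", function() {
  makeMeshPair("slab", thickness = 5)
})

shell_pair <- function() fixture("shell_pair", function() {
  makeMeshPair("spherical_shell", inner_r = 10, thickness = 2)
})

wedge_pair <- function() fixture("wedge_pair", function() {
  makeMeshPair("gradient_wedge", t_from = 10, t_to = 3.5, length = 30)
})

# 10 mm sphere rendered as a binary HU volume at 0.3 mm spacing
sphere_volume <- function() fixture("sphere_volume", function() {
  sp <- 0.3; r <- 10
  xs <- seq(-12, 12, by = sp)
  n <- length(xs)
  vals <- array(-1000, c(n, n, n))
  X <- matrix(xs, n, n); Y <- matrix(xs, n, n, byrow = TRUE)
  for (k in seq_len(n))
    vals[, , k][X^2 + Y^2 + xs[k]^2 <= r^2] <- 1200
  voxelVolume(vals, sp, rep(xs[1], 3))
})

# random rotation matrix (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigidly_move <- function(points, R, t) sweep(points %*% t(R), 2, t, "+")
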