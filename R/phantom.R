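#' Default tissue HU levels for synthetic phantoms
#'
#' Air -1000, soft tissue 40, bone 1200, teeth 1800: bone and teeth both sit
#' inside the 50-2000 HU working range used for maxillary hard-tissue
#' thresholding, and are separable by a second, higher threshold (the teeth
#' pass).
#'
#' @return named numeric with entries `air`, `soft`, `bone`, `teeth`
#' @export
defaultHuLevels <- function() {
  c(air = -1000, soft = 40, bone = 1200, teeth = 1800)
}

# evaluate an expression with a private RNG stream; global RNG state is
# saved and restored, so all phantom randomness flows from explicit seeds
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# landmark assembly helper; tooth bands are Y-levels in the anatomical frame
make_landmarks <- function(ans, pns, molar_r, molar_l, occlusal, anchors,
                           bands) {
  per_side <- list(anchors = anchors, bands = bands)
  new("LandmarkSet",
      points = list(ANS = ans, PNS = pns,
                    molar_fissure_r = molar_r, molar_fissure_l = molar_l),
      occlusalPoints = occlusal,
      toothBands = list(r = per_side, l = per_side))
}

#' Flat-slab phantom with uniform analytic thickness
#'
#' A horizontal bone slab of uniform thickness between two parallel planes
#' (air everywhere else): the simplest analytic oracle for the whole
#' segmentation -> surface -> thickness pipeline. The oral surface is the
#' lower plane (z = 0), the nasal surface the upper plane (z = thickness),
#' so the 0-degree thickness is exactly `thickness_mm` and a ray tilted by
#' theta measures `thickness_mm / cos(theta)`.
#'
#' @param thickness_mm slab thickness (> 0)
#' @param lateral_extent_mm numeric(2): slab extent in x and y
#' @param spacing_mm isotropic voxel spacing; must be <= thickness_mm / 3 so
#'   the slab is resolved across its thin dimension
#' @param hu_levels tissue HU map, see [defaultHuLevels()]
#' @return list with `volume` ([VoxelVolume-class]) and `truth`
#'   ([PhantomTruth-class])
#' @export
makeSlabPhantom <- function(thickness_mm = 5, lateral_extent_mm = c(20, 10),
                            spacing_mm = 0.3, hu_levels = defaultHuLevels()) {
  if (thickness_mm <= 0) stop("thickness_mm must be > 0")
  if (spacing_mm <= 0) stop("spacing_mm must be > 0")
  if (spacing_mm > thickness_mm / 3)
    stop("resolution error: spacing ", spacing_mm,
         " mm too coarse to resolve a ", thickness_mm, " mm slab ",
         "(need spacing <= thickness / 3)")
  ex <- lateral_extent_mm[1] / 2
  ey <- lateral_extent_mm[2] / 2
  pad <- 2
  xs <- seq(-ex - pad, ex + pad, by = spacing_mm)
  ys <- seq(-ey - pad, ey + pad, by = spacing_mm)
  zs <- seq(-pad, thickness_mm + pad, by = spacing_mm)
  # signed penetration depth into the slab, rendered with a partial-volume
  # ramp (~1.5 voxels) so iso-surfacing reconstructs smooth planes
  h <- 1.5 * spacing_mm
  dx <- ex - abs(xs); dy <- ey - abs(ys)
  dz <- pmin(zs, thickness_mm - zs)
  d <- outer(outer(dx, dy, pmin), dz, pmin)
  w <- array(pmin(1, pmax(0, d / h + 0.5)), dim(d))
  vals <- hu_levels[["air"]] + (hu_levels[["bone"]] - hu_levels[["air"]]) * w
  vol <- voxelVolume(vals, spacing_mm, c(xs[1], ys[1], zs[1]))

  eyb <- lateral_extent_mm[2]
  lm <- make_landmarks(
    ans = c(0, 0.45 * eyb, thickness_mm + 2),
    pns = c(0, -0.45 * eyb, thickness_mm + 2),
    molar_r = c(ex, 0, -3), molar_l = c(-ex, 0, -3),
    occlusal = rbind(c(-ex / 2, -ey / 2, -3), c(ex / 2, -ey / 2, -3),
                     c(0, ey / 2, -3)),
    anchors = c(canine_p1 = 0.30 * eyb, p1_mid = 0.15 * eyb, p1_p2 = 0),
    bands = list(p1 = c(eyb / 6, eyb / 2 + 1),
                 p2 = c(-eyb / 6, eyb / 6),
                 m1 = c(-eyb / 2 - 1, -eyb / 6)))
  t_mm <- thickness_mm
  truth <- new("PhantomTruth",
               thicknessField = function(p) {
                 p <- matrix(p, ncol = 3L)
                 rep(t_mm, nrow(p))
               },
               landmarks = lm,
               rootsPresent = c(r = FALSE, l = FALSE),
               canalPresent = FALSE, huLevels = hu_levels)
  list(volume = vol, truth = truth)
}

# linear anterior -> posterior thickness profile of the vault wall
vault_thickness_profile <- function(y, t_ant, t_post, y_post = 15, y_ant = 40) {
  f <- pmin(1, pmax(0, (y - y_post) / (y_ant - y_post)))
  t_post + (t_ant - t_post) * f
}

#' Palatal-vault phantom: concentric arcs with an anterior -> posterior
#' thickness gradient
#'
#' The palatal vault is modelled as a partial cylindrical shell (axis along
#' the antero-posterior Y axis): the oral surface is the inner arc of
#' radius `inner_radius_mm`, the nasal floor the outer arc, and the wall
#' thickness interpolates linearly from `thickness_anterior_mm` at the
#' anterior end to `thickness_posterior_mm` posteriorly, reproducing the
#' anterior > posterior gradient of palatal bone supply. Because the two
#' arcs are concentric, the thickness along the inward oral-surface normal
#' is exactly the wall thickness at that Y level -- the analytic truth.
#'
#' With `roots_on`, high-HU incisor-root blocks are placed anterior of the
#' point-1 probe corridor (plus a deeper lateral tongue reaching into the
#' first-premolar ROI band), so that probe rays tilted 20-30 degrees
#' anteriorly from the point-1 positions intersect them while the 0-degree
#' rays do not. With `canal_on`, a vertical tubular void (nerve canal) is
#' carved through the right posterior shell; the truth thickness field is
#' `NA` on its footprint.
#'
#' @param inner_radius_mm inner (oral) arc radius
#' @param thickness_anterior_mm,thickness_posterior_mm wall thickness at the
#'   anterior / posterior end; anterior must be >= posterior > 0
#' @param roots_on logical(1) or named logical(2) (`r`, `l`)
#' @param canal_on logical(1)
#' @param spacing_mm isotropic voxel spacing
#' @param hu_levels tissue HU map
#' @return list with `volume` and `truth` as in [makeSlabPhantom()]
#' @export
makeVaultPhantom <- function(inner_radius_mm = 15,
                             thickness_anterior_mm = 10,
                             thickness_posterior_mm = 3.5,
                             roots_on = FALSE, canal_on = FALSE,
                             spacing_mm = 0.4,
                             hu_levels = defaultHuLevels()) {
  if (!(thickness_anterior_mm >= thickness_posterior_mm &&
        thickness_posterior_mm > 0))
    stop("need thickness_anterior_mm >= thickness_posterior_mm > 0")
  R <- inner_radius_mm
  if (R <= thickness_anterior_mm / 2)
    stop("geometry error: inner radius too small for the requested thickness")
  if (length(roots_on) == 1L) roots_on <- c(r = roots_on, l = roots_on)
  theta_max <- 60 * pi / 180
  t_ant <- thickness_anterior_mm
  t_post <- thickness_posterior_mm
  y_lo <- 10; y_hi <- 46

  xs <- seq(-23, 23, by = spacing_mm)
  ys <- seq(8, 48, by = spacing_mm)
  zs <- seq(6, R + t_ant + 2.5, by = spacing_mm)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  vals <- array(hu_levels[["soft"]], c(nx, ny, nz))

  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  TY <- vault_thickness_profile(Y, t_ant, t_post)
  # partial-volume ramp width: boundaries are rendered as linear HU ramps
  # so iso-surfacing reconstructs smooth, staircase-free surfaces
  h <- 1.5 * spacing_mm
  ramp <- function(d) pmin(1, pmax(0, d / h + 0.5))
  d_y <- pmin(Y - y_lo, y_hi - Y)
  d_canal_xy <- 1.2 - sqrt((X - 6.5)^2 + (Y - 21)^2)
  sides <- c(r = 1, l = -1)
  hu_soft <- hu_levels[["soft"]]; hu_air <- hu_levels[["air"]]
  hu_bone <- hu_levels[["bone"]]; hu_teeth <- hu_levels[["teeth"]]

  for (k in seq_len(nz)) {
    z <- zs[k]
    r <- sqrt(X^2 + z^2)
    theta <- atan2(abs(X), z)
    slice <- matrix(hu_soft, nx, ny)
    slice[r < R - 1 & theta <= 75 * pi / 180] <- hu_air
    # bone shell: concentric arcs, cut by the y range and the angular rim
    d_bone <- pmin(r - R, R + TY - r, d_y, (theta_max - theta) * r)
    wb <- ramp(d_bone)
    slice <- slice * (1 - wb) + hu_bone * wb
    for (s in names(sides)) {
      if (!roots_on[[s]]) next
      sx <- X * sides[[s]]
      frac <- (r - R) / TY
      # conical taper of the main root block toward its apex
      xmax_eff <- ifelse(frac > 0.7, 6.5 - 10 * (frac - 0.7), 6.5)
      d_main <- pmin(Y - 38, 44 - Y, sx - 0.8, xmax_eff - sx,
                     r - (R - 2.5), (R + TY - 1.2) - r,
                     (theta_max - theta) * r)
      d_tongue <- pmin(Y - 34, 38 - Y, sx - 5.5, 7.5 - sx,
                       r - (R + 1.5), (R + TY - 1.2) - r,
                       (theta_max - theta) * r)
      wt <- ramp(pmax(d_main, d_tongue))
      slice <- slice * (1 - wt) + hu_teeth * wt
    }
    if (canal_on) {
      wc <- ramp(pmin(d_canal_xy, r - (R - 0.5)))
      slice <- slice * (1 - wc) + hu_air * wc
    }
    vals[, , k] <- slice
  }
  vol <- voxelVolume(vals, spacing_mm, c(xs[1], ys[1], zs[1]))

  # idealized midsagittal landmarks at a common height, so the induced
  # anatomical frame is a pure translation of the construction frame
  lm <- make_landmarks(
    ans = c(0, 45, 20), pns = c(0, 11, 20),
    molar_r = c(22, 20, 10), molar_l = c(-22, 20, 10),
    occlusal = rbind(c(-12, 15, 6), c(12, 15, 6), c(0, 40, 6)),
    anchors = c(canine_p1 = 8, p1_mid = 5, p1_p2 = 2),
    bands = list(p1 = c(2, 8), p2 = c(-2, 2), m1 = c(-10, -4)))

  truth <- new("PhantomTruth",
    thicknessField = local({
      ta <- t_ant; tp <- t_post; Rl <- R; tm <- theta_max
      co <- canal_on
      function(p) {
        p <- matrix(p, ncol = 3L)
        y <- p[, 2]
        theta <- atan2(abs(p[, 1]), p[, 3])
        tt <- vault_thickness_profile(y, ta, tp)
        tt[y < 10 | y > 46 | theta > tm] <- NA_real_
        if (co) tt[(p[, 1] - 6.5)^2 + (y - 21)^2 <= 1.2^2] <- NA_real_
        tt
      }
    }),
    landmarks = lm,
    rootsPresent = c(r = unname(roots_on[["r"]]), l = unname(roots_on[["l"]])),
    canalPresent = canal_on, huLevels = hu_levels)
  list(volume = vol, truth = truth)
}

# unit icosphere: subdivided icosahedron, vertices projected to the sphere
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(subdiv)) {
    nf <- nrow(F)
    edge_id <- new.env(hash = TRUE)
    nv <- nrow(V)
    newV <- list()
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_id[[key]]
      if (!is.null(id)) return(id)
      m <- V[a, ] + V[b, ]
      m <- m / sqrt(sum(m^2))
      newV[[length(newV) + 1L]] <<- m
      id <- nv + length(newV)
      edge_id[[key]] <- id
      id
    }
    F2 <- matrix(0L, 4L * nf, 3L)
    for (f in seq_len(nf)) {
      a <- F[f, 1]; b <- F[f, 2]; cc <- F[f, 3]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      F2[4 * f - 3, ] <- c(a, ab, ca)
      F2[4 * f - 2, ] <- c(b, bc, ab)
      F2[4 * f - 1, ] <- c(cc, ca, bc)
      F2[4 * f, ] <- c(ab, bc, ca)
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- F2
  }
  list(vertices = V, faces = F)
}

# triangulated rectangle grid at height z(x, y); winding chosen so the
# face normal points along +z or -z
grid_surface <- function(xr, yr, step, zfun, normal_up = TRUE) {
  xs <- seq(xr[1], xr[2], length.out = max(2L, ceiling(diff(xr) / step) + 1L))
  ys <- seq(yr[1], yr[2], length.out = max(2L, ceiling(diff(yr) / step) + 1L))
  nxp <- length(xs); nyp <- length(ys)
  V <- cbind(rep(xs, times = nyp), rep(ys, each = nxp), 0)
  V[, 3] <- zfun(V[, 1], V[, 2])
  idx <- function(i, j) (j - 1L) * nxp + i
  i <- rep(seq_len(nxp - 1L), times = nyp - 1L)
  j <- rep(seq_len(nyp - 1L), each = nxp - 1L)
  a <- idx(i, j); b <- idx(i + 1L, j); cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
  F <- if (normal_up) rbind(cbind(a, b, cc), cbind(a, cc, d))
       else rbind(cbind(a, cc, b), cbind(a, d, cc))
  triMesh(V, F)
}

#' Exact oral/nasal mesh pairs with analytic separation
#'
#' Bypasses segmentation to unit-test the geometric core on meshes whose
#' thickness is known in closed form:
#' * `slab`: two parallel rectangles separated by `thickness`; AA is the
#'   exact rectangle area, MD the constant thickness.
#' * `spherical_shell`: concentric spheres with radial separation exactly
#'   `thickness` at every vertex.
#' * `gradient_wedge`: flat oral plane under a tilted nasal plane; the
#'   vertical separation ramps linearly from `t_from` to `t_to`, so the
#'   area-weighted mean distance is exactly `(t_from + t_to) / 2`.
#'
#' The nasal surface is padded laterally so angled rays from the oral patch
#' still land on it.
#'
#' @param type one of `"slab"`, `"spherical_shell"`, `"gradient_wedge"`
#' @param thickness separation in mm (slab, spherical_shell)
#' @param extent numeric(2), slab extent in x and y (mm)
#' @param inner_r inner sphere radius (spherical_shell)
#' @param t_from,t_to wedge thickness at y = 0 and y = `length` (gradient_wedge)
#' @param length,width wedge patch dimensions (mm)
#' @param step surface triangulation pitch (mm)
#' @param subdiv icosphere subdivision level
#' @return list with `oral` and `nasal` [TriMesh-class] objects and `truth`
#'   ([PhantomTruth-class])
#' @export
makeMeshPair <- function(type = c("slab", "spherical_shell", "gradient_wedge"),
                         thickness = 5, extent = c(20, 10), inner_r = 10,
                         t_from = 10, t_to = 3.5, length = 30, width = 20,
                         step = 0.5, subdiv = 3) {
  type <- match.arg(type)
  pad <- 8
  if (type == "slab") {
    ex <- extent[1] / 2; ey <- extent[2] / 2
    oral <- grid_surface(c(-ex, ex), c(-ey, ey), step,
                         function(x, y) rep(0, base::length(x)),
                         normal_up = FALSE)
    nasal <- grid_surface(c(-ex - pad, ex + pad), c(-ey - pad, ey + pad),
                          2 * step,
                          function(x, y) rep(thickness, base::length(x)),
                          normal_up = TRUE)
    eyb <- extent[2]
    lm <- make_landmarks(
      ans = c(0, 0.45 * eyb, thickness + 2),
      pns = c(0, -0.45 * eyb, thickness + 2),
      molar_r = c(ex, 0, -3), molar_l = c(-ex, 0, -3),
      occlusal = rbind(c(-5, -2, -3), c(5, -2, -3), c(0, 2, -3)),
      anchors = c(canine_p1 = 0.30 * eyb, p1_mid = 0.15 * eyb, p1_p2 = 0),
      bands = list(p1 = c(eyb / 6, eyb / 2 + 1),
                   p2 = c(-eyb / 6, eyb / 6),
                   m1 = c(-eyb / 2 - 1, -eyb / 6)))
    tf <- function(p) rep(thickness, nrow(matrix(p, ncol = 3L)))
  } else if (type == "spherical_shell") {
    ico <- icosphere(subdiv)
    # oral = inner sphere, normals toward the centre (the "oral cavity")
    oral <- triMesh(ico$vertices * inner_r, ico$faces[, c(1, 3, 2)])
    nasal <- triMesh(ico$vertices * (inner_r + thickness), ico$faces)
    lm <- make_landmarks(
      ans = c(0, inner_r / 2, 0), pns = c(0, -inner_r / 2, 0),
      molar_r = c(inner_r, 0, -2), molar_l = c(-inner_r, 0, -2),
      occlusal = rbind(c(-5, -2, -inner_r - 3), c(5, -2, -inner_r - 3),
                       c(0, 2, -inner_r - 3)),
      anchors = c(canine_p1 = 2, p1_mid = 1, p1_p2 = 0),
      bands = list(p1 = c(0, 2), p2 = c(-1, 0), m1 = c(-3, -1)))
    tf <- function(p) rep(thickness, nrow(matrix(p, ncol = 3L)))
  } else {
    ex <- width / 2
    oral <- grid_surface(c(-ex, ex), c(0, length), step,
                         function(x, y) rep(0, base::length(x)),
                         normal_up = FALSE)
    L <- length; tfr <- t_from; tto <- t_to
    nasal <- grid_surface(c(-ex - pad, ex + pad), c(-pad, L + pad), step,
                          function(x, y)
                            tfr + (tto - tfr) * pmin(1, pmax(0, y / L)),
                          normal_up = TRUE)
    lm <- make_landmarks(
      ans = c(0, L, t_from + 2), pns = c(0, 0, t_from + 2),
      molar_r = c(ex, L / 2, -3), molar_l = c(-ex, L / 2, -3),
      occlusal = rbind(c(-5, 2, -3), c(5, 2, -3), c(0, L - 2, -3)),
      anchors = c(canine_p1 = 0.4 * L - L / 2, p1_mid = 0.25 * L - L / 2,
                  p1_p2 = 0.1 * L - L / 2),
      bands = list(p1 = c(L / 6, L / 2 + 1) - 0,
                   p2 = c(-L / 6, L / 6),
                   m1 = c(-L / 2 - 1, -L / 6)))
    tf <- function(p) {
      p <- matrix(p, ncol = 3L)
      tfr + (tto - tfr) * pmin(1, pmax(0, p[, 2] / L))
    }
  }
  truth <- new("PhantomTruth", thicknessField = tf, landmarks = lm,
               rootsPresent = c(r = FALSE, l = FALSE), canalPresent = FALSE,
               huLevels = defaultHuLevels())
  list(oral = oral, nasal = nasal, truth = truth)
}

#' Specify a simulated patient cohort
#'
#' Defaults mirror the structure of a paediatric/adolescent CBCT cohort:
#' 184 patients, 33.7% female, age groups 4-12 / 13-16 / 17-20 with
#' probabilities 33:42:109, incisor roots reaching into the anterior ROI in
#' 57% of patients, and fixed effects on the mm scale for a mean-distance
#' response over two sides x three ROIs. Responses are generated from the
#' same model the analysis fits: `y = X beta + b_patient + eps` with
#' `b ~ N(0, sigma_b^2)` per patient and `eps ~ N(0, sigma_e^2)`.
#'
#' @param n_patients cohort size
#' @param sex_ratio fraction female
#' @param age_group_probs probabilities of the 4-12, 13-16, 17-20 groups
#'   (must sum to 1)
#' @param teeth_prob probability that incisor roots extend into the ROI
#' @param fixed_effects named coefficients matched against the columns of
#'   `model.matrix(~ sex + age_group + teeth + side + roi)` (design
#'   `"roi"`) or `~ sex + age_group + teeth + side + angle + point`
#'   (design `"angle"`)
#' @param sigma_b random-intercept SD (mm)
#' @param sigma_e residual SD (mm)
#' @param design `"roi"` (2 sides x 3 ROIs per patient) or `"angle"`
#'   (2 sides x 3 points x 4 angles per patient)
#' @param seed integer seed driving all randomness
#' @return a validated `CohortSpec` list
#' @export
cohortSpec <- function(n_patients = 184, sex_ratio = 62 / 184,
                       age_group_probs = c(33, 42, 109) / 184,
                       teeth_prob = 105 / 184,
                       fixed_effects = c(
                         `(Intercept)` = 9.94, sexfemale = -1.12,
                         `age_group13-16` = 0.52, `age_group17-20` = 0.51,
                         teethyes = 0.73, sider = 0.04,
                         roi2 = -4.75, roi3 = -6.94),
                       sigma_b = 1.5, sigma_e = 1.0,
                       design = c("roi", "angle"), seed = 1L) {
  design <- match.arg(design)
  if (abs(sum(age_group_probs) - 1) > 1e-8)
    stop("age_group_probs must sum to 1")
  if (sigma_b < 0 || sigma_e < 0) stop("sigma_b and sigma_e must be >= 0")
  if (n_patients < 1) stop("n_patients must be >= 1")
  structure(list(n_patients = as.integer(n_patients), sex_ratio = sex_ratio,
                 age_group_probs = age_group_probs, teeth_prob = teeth_prob,
                 fixed_effects = fixed_effects, sigma_b = sigma_b,
                 sigma_e = sigma_e, design = design,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Simulate a cohort measurement table
#'
#' Forward simulation of the random-intercept model on a long-format table;
#' identical seeds give identical tables.
#'
#' @param spec a [cohortSpec()]
#' @return data.frame with columns `patient_id`, `sex`, `age_years`,
#'   `age_group`, `side`, `roi`, `point`, `angle_deg`, `teeth`, `response`,
#'   `unit`
#' @export
sampleCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    sex <- factor(ifelse(runif(n) < spec$sex_ratio, "female", "male"),
                  levels = c("male", "female"))
    grp <- sample(c("4-12", "13-16", "17-20"), n, replace = TRUE,
                  prob = spec$age_group_probs)
    age_group <- factor(grp, levels = c("4-12", "13-16", "17-20"))
    lo <- c(`4-12` = 4, `13-16` = 13, `17-20` = 17)
    hi <- c(`4-12` = 12, `13-16` = 16, `17-20` = 20)
    age <- vapply(grp, function(g)
      sample(seq(lo[[g]], hi[[g]]), 1L), numeric(1))
    teeth <- factor(ifelse(runif(n) < spec$teeth_prob, "yes", "no"),
                    levels = c("no", "yes"))
    pat <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                      sex = sex, age_years = age, age_group = age_group,
                      teeth = teeth)
    if (spec$design == "roi") {
      tab <- merge(pat, expand.grid(side = factor(c("l", "r")),
                                    roi = factor(c("1", "2", "3")),
                                    KEEP.OUT.ATTRS = FALSE))
      tab$point <- NA_character_
      tab$angle_deg <- NA_real_
      form <- ~ sex + age_group + teeth + side + roi
    } else {
      tab <- merge(pat, expand.grid(side = factor(c("l", "r")),
                                    point = factor(c("2", "1", "3"),
                                                   levels = c("2", "1", "3")),
                                    angle = factor(c("0", "10", "20", "30")),
                                    KEEP.OUT.ATTRS = FALSE))
      tab$angle_deg <- as.numeric(as.character(tab$angle))
      tab$roi <- NA_character_
      form <- ~ sex + age_group + teeth + side + angle + point
    }
    tab <- tab[order(tab$patient_id), ]
    rownames(tab) <- NULL
    X <- stats::model.matrix(form, tab)
    beta <- spec$fixed_effects
    unknown <- setdiff(names(beta), colnames(X))
    if (length(unknown))
      stop("fixed_effects name(s) not in the design: ",
           paste(unknown, collapse = ", "))
    bvec <- setNames(numeric(ncol(X)), colnames(X))
    bvec[names(beta)] <- beta
    b_pat <- stats::rnorm(n, 0, spec$sigma_b)
    names(b_pat) <- pat$patient_id
    tab$response <- as.vector(X %*% bvec) +
      b_pat[tab$patient_id] +
      stats::rnorm(nrow(tab), 0, spec$sigma_e)
    tab$unit <- "mm"
    keep <- c("patient_id", "sex", "age_years", "age_group", "side",
              if (spec$design == "roi") "roi" else c("point", "angle"),
              "angle_deg"[spec$design == "angle"], "teeth", "response",
              "unit")
    tab[, intersect(keep, names(tab))]
  })
}
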