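# Ground-truthed synthetic micro-CT phantoms. Bones are capsules (cylinder
# + hemispherical caps) so "end-to-end length" is analytic: axis length +
# 2 * radius. Material HU is sampled at voxel centres BEFORE Gaussian blur,
# so partial-volume voxels fall between tissue and bone HU and measured
# length becomes threshold dependent, as in real scans.

.gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# separable 3D Gaussian blur; constant (air) padding outside the grid.
# Each axis is one banded-matrix multiply (BLAS) on the axis-first reshape;
# the padding contribution is the kernel mass falling outside the grid.
.blur_axis <- function(arr, ax, k, pad_value) {
  d <- dim(arr)
  n <- d[ax]
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    i <- seq(max(1, 1 - j), min(n, n - j))
    K[cbind(i, i + j)] <- k[j + r + 1L]
  }
  deficit <- 1 - rowSums(K)   # kernel mass outside the grid
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  x <- if (ax == 1) arr else aperm(arr, perm)
  dims <- dim(x)
  dim(x) <- c(n, prod(dims[-1]))
  y <- K %*% x + pad_value * deficit
  dim(y) <- dims
  if (ax != 1) y <- aperm(y, order(perm))
  y
}

.blur3d <- function(arr, sigma_um, spacing, pad_value) {
  for (ax in 1:3) {
    k <- .gauss_kernel(sigma_um / spacing[ax])
    if (length(k) == 1) next
    arr <- .blur_axis(arr, ax, k, pad_value)
  }
  arr
}

.shift3_num <- function(m, axis, by, fill) {
  d <- dim(m)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (by > 0) { idx_dst[[axis]] <- (1 + by):n; idx_src[[axis]] <- 1:(n - by) }
  else if (by < 0) { idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Describe a synthetic bone capsule
#'
#' @param name canonical bone name (free for phantoms).
#' @param side `"LEFT"`, `"RIGHT"` or `NA`.
#' @param center_um capsule centre, physical um (slice, row, col).
#' @param axis direction of the long axis (normalised internally).
#' @param length_um end-to-end length including both caps (> 2 * radius).
#' @param radius_um capsule radius (> 0).
#' @param lumen_radius_um optional hollow-lumen radius (< radius) emulating
#'   the marrow cavity; 0 for solid.
#' @return A list describing one capsule.
#' @export
capsule <- function(name, side = NA_character_, center_um, axis, length_um,
                    radius_um, lumen_radius_um = 0) {
  if (radius_um <= 0) stop("capsule radius must be > 0")
  if (length_um <= 2 * radius_um)
    stop("capsule length must exceed its diameter (", 2 * radius_um, " um)")
  if (lumen_radius_um >= radius_um) stop("lumen must be thinner than the capsule")
  list(name = toupper(name), side = toupper(side),
       center_um = as.numeric(center_um), axis = .unit(as.numeric(axis)),
       length_um = as.numeric(length_um), radius_um = as.numeric(radius_um),
       lumen_radius_um = as.numeric(lumen_radius_um))
}

#' Specify a synthetic micro-CT phantom
#'
#' Materials default to bone 800 HU, soft tissue 50 HU, air -1000 HU —
#' mid-range values of the density bands the segmentation targets. Blur
#' sigma defaults to one 20-um voxel of partial-volume spread; noise is
#' additive Gaussian in HU. The seed is mandatory so every phantom is
#' reproducible bit for bit.
#'
#' @param shape grid dimension (slice, row, col), voxels.
#' @param spacing_um voxel spacing, um (scalar or length 3).
#' @param bones list of [capsule()] specs.
#' @param hu_bone,hu_tissue,hu_air material HU values.
#' @param blur_sigma_um Gaussian partial-volume blur sigma, um.
#' @param noise_sd_hu additive Gaussian noise SD, HU.
#' @param tissue_margin_voxels inset of the soft-tissue block from the grid
#'   boundary (air outside).
#' @param seed RNG seed (integer).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing_um = 20, bones = list(),
                         hu_bone = 800, hu_tissue = 50, hu_air = -1000,
                         blur_sigma_um = 20, noise_sd_hu = 0,
                         tissue_margin_voxels = 3, seed = 1L) {
  spacing <- as.numeric(spacing_um)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), all(spacing > 0))
  structure(list(shape = shape, spacing = spacing, bones = bones,
                 hu_bone = hu_bone, hu_tissue = hu_tissue, hu_air = hu_air,
                 blur_sigma_um = blur_sigma_um, noise_sd_hu = noise_sd_hu,
                 tissue_margin_voxels = tissue_margin_voxels,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared distance from every voxel centre in a bounding box to a segment
.paint_capsule <- function(arr, spec, cap, value, radius_um) {
  spacing <- spec$spacing
  h <- cap$length_um / 2 - cap$radius_um       # axis half-length
  u <- cap$axis
  margin <- radius_um + 2 * max(spacing)
  lo_um <- cap$center_um - abs(u) * h - margin
  hi_um <- cap$center_um + abs(u) * h + margin
  lo <- pmax(1L, floor(lo_um / spacing) + 1L)
  hi <- pmin(dim(arr), ceiling(hi_um / spacing) + 1L)
  if (any(lo > hi)) stop("capsule lies outside the grid")
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  # voxel centre physical coordinates, relative to segment end A
  A <- cap$center_um - h * u
  xs <- (ii - 1) * spacing[1] - A[1]
  ys <- (jj - 1) * spacing[2] - A[2]
  zs <- (kk - 1) * spacing[3] - A[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  vx <- array(xs, c(nx, ny, nz))
  vy <- array(rep(ys, each = nx), c(nx, ny, nz))
  vz <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  t <- vx * u[1] + vy * u[2] + vz * u[3]
  t <- pmin(pmax(t, 0), 2 * h)
  d2 <- (vx - t * u[1])^2 + (vy - t * u[2])^2 + (vz - t * u[3])^2
  sel <- d2 <= radius_um^2
  sub <- arr[ii, jj, kk]
  sub[sel] <- value
  arr[ii, jj, kk] <- sub
  arr
}

.capsule_fits <- function(spec, cap) {
  h <- cap$length_um / 2 - cap$radius_um
  margin <- 3 * spec$blur_sigma_um
  ends <- rbind(cap$center_um - h * cap$axis, cap$center_um + h * cap$axis)
  lo <- apply(ends, 2, min) - cap$radius_um - margin
  hi <- apply(ends, 2, max) + cap$radius_um + margin
  all(lo >= 0) && all(hi <= (spec$shape - 1) * spec$spacing)
}

#' Render a phantom specification into a calibrated volume
#'
#' Paints air / soft-tissue block / bone capsules (innermost material
#' wins), applies Gaussian partial-volume blur, then adds voxel-wise
#' Gaussian noise under the spec's seed. Also derives the analytic ground
#' truth and a landmark set seeded at each capsule's centre voxel.
#'
#' @param spec a [phantom_spec()].
#' @return List: `volume` ([ct_volume()], HU), `truth` (data.frame `bone`,
#'   `side`, `length_um`, axis components), `landmarks`
#'   (a `landmark_set`).
#' @export
make_capsule_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  arr <- array(spec$hu_air, d)
  m <- spec$tissue_margin_voxels
  if (all(d > 2 * m)) {
    arr[(m + 1):(d[1] - m), (m + 1):(d[2] - m), (m + 1):(d[3] - m)] <-
      spec$hu_tissue
  }
  for (cap in spec$bones) {
    if (!.capsule_fits(spec, cap))
      stop("capsule ", cap$name, " does not fit the grid with a 3-sigma margin")
    arr <- .paint_capsule(arr, spec, cap, spec$hu_bone, cap$radius_um)
    if (cap$lumen_radius_um > 0)
      arr <- .paint_capsule(arr, spec, cap, spec$hu_tissue,
                            cap$lumen_radius_um)
  }
  arr <- .blur3d(arr, spec$blur_sigma_um, spec$spacing, spec$hu_air)
  if (spec$noise_sd_hu > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sd_hu)
  }
  vol <- ct_volume(arr, spec$spacing, source_id = "phantom")
  truth <- do.call(rbind, lapply(spec$bones, function(cap)
    data.frame(bone = cap$name, side = cap$side, length_um = cap$length_um,
               radius_um = cap$radius_um,
               axis_s = cap$axis[1], axis_r = cap$axis[2],
               axis_c = cap$axis[3], stringsAsFactors = FALSE)))
  seeds <- do.call(rbind, lapply(spec$bones, function(cap)
    round(cap$center_um / spec$spacing)))
  lms <- if (length(spec$bones))
    landmarks(bone = truth$bone, side = truth$side,
              slice = seeds[, 1], row = seeds[, 2], col = seeds[, 3])
  else NULL
  list(volume = vol, truth = truth, landmarks = lms)
}

#' Single capsule at arbitrary orientation in a tight grid
#'
#' Builds a one-bone phantom whose grid is sized to the oriented capsule's
#' bounding box plus the blur margin — the workhorse for length-recovery
#' validation across random orientations.
#'
#' @param length_um end-to-end capsule length, um.
#' @param axis long-axis direction (normalised internally).
#' @param radius_um capsule radius, um.
#' @param bone,side names for the record.
#' @param spacing_um,blur_sigma_um,noise_sd_hu,seed see [phantom_spec()].
#' @return As [make_capsule_volume()].
#' @export
make_oblique_capsule <- function(length_um, axis = c(1, 0, 0),
                                 radius_um = 250, bone = "FEMUR",
                                 side = "RIGHT", spacing_um = 20,
                                 blur_sigma_um = 20, noise_sd_hu = 0,
                                 seed = 1L) {
  u <- .unit(as.numeric(axis))
  sp <- spacing_um
  h <- length_um / 2 - radius_um
  margin_um <- 3 * blur_sigma_um + 4 * sp
  ext_um <- 2 * abs(u) * h + 2 * radius_um + 2 * margin_um
  shape <- ceiling(ext_um / sp) + 4L
  ctr <- (shape - 1) / 2 * sp
  spec <- phantom_spec(shape, sp,
                       list(capsule(bone, side, ctr, u, length_um,
                                    radius_um)),
                       blur_sigma_um = blur_sigma_um,
                       noise_sd_hu = noise_sd_hu, seed = seed)
  make_capsule_volume(spec)
}

#' Mirrored left/right limb-pair phantom with programmable asymmetry
#'
#' Places one right capsule at nominal length and one left capsule at
#' `nominal * (1 - asymmetry_percent / 100)` at exactly mirrored positions
#' about the mid-sagittal (column) plane, so the ground-truth L/R ratio is
#' `1 - asymmetry_percent / 100` exactly, the injected-asymmetry scale of
#' chondrocyte-ablation phenotype models (~5-20%).
#'
#' @param nominal_length_um right-side capsule length, um.
#' @param asymmetry_percent 0 <= a < 100.
#' @param radius_um capsule radius, um.
#' @param bone bone name for both sides.
#' @param spacing_um,blur_sigma_um,noise_sd_hu,seed see [phantom_spec()].
#' @return As [make_capsule_volume()]; `truth` carries attribute
#'   `lr_ratio_truth`.
#' @export
make_limb_pair <- function(nominal_length_um = 5000, asymmetry_percent = 0,
                           radius_um = 250, bone = "FEMUR",
                           spacing_um = 20, blur_sigma_um = 20,
                           noise_sd_hu = 0, seed = 1L) {
  if (asymmetry_percent < 0 || asymmetry_percent >= 100)
    stop("asymmetry must be in [0, 100)")
  sp <- spacing_um
  margin <- ceiling((3 * blur_sigma_um + 4 * sp) / sp) + 4L
  nz <- ceiling(nominal_length_um / sp) + 2L * margin
  r_vox <- ceiling(radius_um / sp)
  ny <- 2L * (r_vox + margin) + 1L
  half_w <- r_vox + margin
  nc <- 2L * (2L * half_w + 1L)               # two mirrored half grids
  ctr_col_right <- (nc - 1) - half_w          # voxel index
  ctr_col_left <- half_w
  zc <- (nz - 1) / 2 * sp
  yc <- (ny - 1) / 2 * sp
  left_len <- nominal_length_um * (1 - asymmetry_percent / 100)
  bones <- list(
    capsule(bone, "RIGHT", c(zc, yc, ctr_col_right * sp), c(1, 0, 0),
            nominal_length_um, radius_um),
    capsule(bone, "LEFT", c(zc, yc, ctr_col_left * sp), c(1, 0, 0),
            left_len, radius_um))
  spec <- phantom_spec(c(nz, ny, nc), sp, bones,
                       blur_sigma_um = blur_sigma_um,
                       noise_sd_hu = noise_sd_hu, seed = seed)
  out <- make_capsule_volume(spec)
  attr(out$truth, "lr_ratio_truth") <- 1 - asymmetry_percent / 100
  out
}

#' Near-touching parallel capsule pair (radius/ulna, tibia/fibula style)
#'
#' Two parallel capsules whose surfaces are `gap_um` apart. With blur on
#' the order of the gap the thresholded mask fuses into one component —
#' the geometry that forces composite segmentation of radius+ulna and
#' tibia+fibula; with blur much smaller than the gap they stay separate.
#' `protrusion_um` shifts the second capsule distally so it protrudes past
#' the first, as the fibula does past the tibia.
#'
#' @param length_um first capsule length, um.
#' @param length2_um second capsule length, um (default 0.85 * length).
#' @param radius_um capsule radius, um (both).
#' @param gap_um surface-to-surface gap, >= 0.
#' @param protrusion_um distal shift of the second capsule, um.
#' @param names,sides names/sides for the two capsules.
#' @param spacing_um,blur_sigma_um,noise_sd_hu,seed see [phantom_spec()].
#' @return As [make_capsule_volume()].
#' @export
make_fused_pair <- function(length_um = 4000, length2_um = 0.85 * length_um,
                            radius_um = 200, gap_um = 40, protrusion_um = 0,
                            names = c("TIBIA", "FIBULA"),
                            sides = c("RIGHT", "RIGHT"),
                            spacing_um = 20, blur_sigma_um = 40,
                            noise_sd_hu = 0, seed = 1L) {
  if (gap_um < 0) stop("gap must be >= 0")
  sp <- spacing_um
  margin <- ceiling((3 * blur_sigma_um + 4 * sp) / sp) + 4L
  maxlen <- max(length_um, length2_um + abs(protrusion_um))
  nz <- ceiling((maxlen + abs(protrusion_um)) / sp) + 2L * margin
  r_vox <- ceiling(radius_um / sp)
  ny <- 2L * (r_vox + margin) + 1L
  sep <- 2 * radius_um + gap_um               # centre-to-centre, um
  nc <- ceiling(sep / sp) + 2L * (r_vox + margin) + 1L
  yc <- (ny - 1) / 2 * sp
  zc <- (nz - 1) / 2 * sp
  c1 <- (r_vox + margin) * sp
  c2 <- c1 + sep
  bones <- list(
    capsule(names[1], sides[1], c(zc, yc, c1), c(1, 0, 0), length_um,
            radius_um),
    capsule(names[2], sides[2],
            c(zc + (length_um - length2_um) / 2 + protrusion_um, yc, c2),
            c(1, 0, 0), length2_um, radius_um))
  spec <- phantom_spec(c(nz, ny, nc), sp, bones,
                       blur_sigma_um = blur_sigma_um,
                       noise_sd_hu = noise_sd_hu, seed = seed)
  make_capsule_volume(spec)
}

# fixed body-plan slots: per bone, length (um), radius (um), slot offsets
# (row band voxels, col offset voxels from the side centre) and a small
# deterministic tilt of the long axis. Lengths are late-embryonic mouse
# scale so a whole body fits a desk-scale grid.
.body_plan <- function() {
  data.frame(
    bone   = c("CLAVICLE", "HUMERUS", "RADIUS", "ULNA", "FEMUR", "TIBIA"),
    length = c(1600, 3200, 2500, 2900, 3100, 3400),
    radius = c(140, 240, 170, 190, 250, 220),
    row_band = c(0, 1, 1, 1, 2, 2),
    col_off  = c(0, -30, 0, 28, -18, 18),
    tilt_r = c(0.10, 0.06, 0.03, 0.05, -0.04, -0.07),
    tilt_c = c(0.12, -0.03, 0.02, 0.04, -0.03, 0.03),
    stringsAsFactors = FALSE)
}

#' Whole-body phantom: paired long bones plus debris
#'
#' A stand-in for a whole-body scan: left/right clavicle, humerus, radius,
#' ulna, femur and tibia (12 capsules at fixed body-plan slots with small
#' per-bone axis tilts, mirrored across the mid-sagittal plane) embedded in
#' a soft-tissue block, plus small random high-HU debris specks for the
#' outlier/volume filters to remove. Landmark seeds are auto-generated at
#' capsule centres.
#'
#' @param spacing_um voxel spacing, um.
#' @param blur_sigma_um,noise_sd_hu,seed see [phantom_spec()].
#' @param n_debris number of 1-2 voxel debris specks.
#' @param scale multiplies all body-plan lengths/radii.
#' @return As [make_capsule_volume()], plus `spec`.
#' @export
make_body_phantom <- function(spacing_um = 20, blur_sigma_um = 20,
                              noise_sd_hu = 0, seed = 1L, n_debris = 8,
                              scale = 1) {
  sp <- spacing_um
  plan <- .body_plan()
  plan$length <- plan$length * scale
  plan$radius <- plan$radius * scale
  margin <- ceiling((3 * blur_sigma_um) / sp) + 6L
  maxlen_vox <- ceiling(max(plan$length) / sp)
  nz <- maxlen_vox + 2L * margin + 10L
  band_pitch <- ceiling(max(plan$radius) * 2 / sp) + 26L
  ny <- 3L * band_pitch + 2L * margin
  half_w <- 100L
  nc <- 2L * half_w + 2L * margin
  # left/right centres exactly mirrored about the mid-sagittal voxel plane
  side_ctr <- c(LEFT = margin + half_w %/% 2,
                RIGHT = (nc - 1L) - (margin + half_w %/% 2))
  zc <- (nz - 1) / 2 * sp
  bones <- list()
  for (side in c("LEFT", "RIGHT")) {
    sgn <- if (side == "LEFT") -1 else 1
    for (i in seq_len(nrow(plan))) {
      p <- plan[i, ]
      rowc <- (margin + p$row_band * band_pitch + band_pitch %/% 2) * sp
      colc <- (side_ctr[[side]] + sgn * p$col_off) * sp
      ax <- .unit(c(1, p$tilt_r, sgn * p$tilt_c))
      bones[[length(bones) + 1L]] <-
        capsule(p$bone, side, c(zc, rowc, colc), ax, p$length, p$radius)
    }
  }
  spec <- phantom_spec(c(nz, ny, nc), sp, bones,
                       blur_sigma_um = blur_sigma_um,
                       noise_sd_hu = noise_sd_hu, seed = seed)
  out <- make_capsule_volume(spec)
  # debris specks: painted after blur so they stay compact and sharp
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed + 7L)
  d <- spec$shape
  placed <- 0L; tries <- 0L
  arr <- out$volume$data
  while (placed < n_debris && tries < 200L) {
    tries <- tries + 1L
    pos <- c(sample(seq(margin, nz - margin), 1),
             sample(seq(margin, ny - margin), 1),
             sample(seq(margin, nc - margin), 1))
    block <- arr[pos[1] + (-2:2), pos[2] + (-2:2), pos[3] + (-2:2)]
    if (max(block) > spec$hu_tissue + 50) next  # too close to a bone
    arr[pos[1] + (0:1), pos[2] + (0:1), pos[3]] <- spec$hu_bone
    placed <- placed + 1L
  }
  out$volume$data <- arr
  out$spec <- spec
  out
}
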