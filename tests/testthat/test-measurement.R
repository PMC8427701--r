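# build a bone_component directly from a logical array
component_from <- function(arr, spacing = 20) {
  labs <- label_components_3d(bone_mask(arr, spacing))
  bone_component(labs, 1, bone = "FEMUR", side = "RIGHT")
}

test_that("inertia tensor matches hand-summed moments for collinear voxels", {
  m <- array(FALSE, c(5, 3, 3))
  m[1:5, 2, 2] <- TRUE               # 1x1x5 rod along the slice axis
  comp <- component_from(m, spacing = 1)
  ine <- inertia_tensor(comp)
  S <- sum(((1:5) - 3)^2)            # centred squared offsets = 10
  expect_equal(ine$eigenvalues, c(0, S, S))
  expect_false(ine$degenerate)
  expect_equal(abs(ine$axes[, 1]), c(1, 0, 0))  # long axis = rod axis
})

test_that("single voxel gives a zero tensor, degenerate, box falls back", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  comp <- component_from(m, spacing = 20)
  ine <- inertia_tensor(comp)
  expect_true(ine$degenerate)
  expect_equal(ine$tensor, matrix(0, 3, 3))
  box <- aligned_box(comp, ine)
  expect_true(box$degenerate)
  expect_equal(sort(box$dims), c(20, 20, 20))   # exact voxel edges
  expect_equal(feret_diameter(comp), 20 * sqrt(3))  # body diagonal
})

test_that("long axis of a voxelised capsule is within 2 degrees of truth", {
  u <- c(1, 0.35, -0.2) / sqrt(sum(c(1, 0.35, -0.2)^2))
  p <- make_oblique_capsule(2600, u, radius_um = 180, blur_sigma_um = 0)
  labs <- label_components_3d(apply_threshold(p$volume, 398))
  comp <- bone_component(labs, 1)
  ine <- inertia_tensor(comp)
  ang <- acos(min(1, abs(sum(ine$axes[, 1] * u)))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("aligned box recovers exact dims of an axis-aligned cuboid", {
  m <- array(FALSE, c(44, 14, 14))
  m[3:42, 3:12, 3:12] <- TRUE        # 40 x 10 x 10 voxels
  box <- aligned_box(component_from(m, spacing = 20))
  expect_equal(box$length_um, 800)
  expect_equal(sort(box$dims), c(200, 200, 800))
  expect_equal(box$width_um, c(200, 200))
})

test_that("every voxel corner projects inside the reported extents", {
  set.seed(14)
  for (trial in 1:5) {
    arr <- array(FALSE, c(12, 12, 12))
    seedv <- c(6, 6, 6); arr[6, 6, 6] <- TRUE
    for (k in 1:200) {    # random connected blob growth
      at <- which(arr)
      pick <- arrayInd(sample(at, 1), dim(arr))
      nb <- pick + sample(c(-1, 0, 1), 3, replace = TRUE)
      if (all(nb >= 1 & nb <= 12)) arr[nb[1], nb[2], nb[3]] <- TRUE
    }
    comp <- component_from(arr, spacing = 20)
    box <- aligned_box(comp)
    corners <- as.matrix(expand.grid(c(-.5, .5), c(-.5, .5), c(-.5, .5)))
    pts <- do.call(rbind, lapply(1:8, function(i)
      sweep(comp$voxels, 2, -corners[i, ]) %*% diag(comp$spacing)))
    proj <- pts %*% box$axes
    expect_true(all(proj >= rep(box$extents[1, ], each = nrow(proj)) - 1e-6))
    expect_true(all(proj <= rep(box$extents[2, ], each = nrow(proj)) + 1e-6))
  }
})

test_that("capsule length is recovered within the discretisation bound", {
  u <- c(0.8, 0.5, 0.33)
  p <- make_oblique_capsule(5000, u, radius_um = 250, blur_sigma_um = 20)
  tab <- measure_bones(p$volume, p$landmarks, threshold_hu = 398,
                       cleanup = FALSE)
  expect_gte(tab$length_mm * 1000, 5000 - 20)
  expect_lte(tab$length_mm * 1000, 5000 + 2 * 20)
})

test_that("feret equals closed form on cuboids and brute force on blobs", {
  m <- array(FALSE, c(44, 14, 14))
  m[3:42, 3:12, 3:12] <- TRUE
  comp <- component_from(m, spacing = 1)
  expect_equal(feret_diameter(comp), sqrt(40^2 + 10^2 + 10^2))

  set.seed(25)
  for (trial in 1:4) {
    arr <- array(FALSE, c(10, 10, 10))
    arr[sample(1000, 400)] <- TRUE
    labs <- label_components_3d(bone_mask(arr, 20))
    sizes <- tabulate(labs$data[labs$data > 0], labs$n_labels)
    comp <- bone_component(labs, which.max(sizes))
    expect_equal(feret_diameter(comp),
                 feret_bruteforce(comp$voxels, comp$spacing))
  }
})

test_that("box length never exceeds feret; bent rod strictly below", {
  set.seed(31)
  for (trial in 1:3) {
    u <- rnorm(3)
    p <- make_oblique_capsule(2200, u, radius_um = 180, blur_sigma_um = 10,
                              noise_sd_hu = 10, seed = trial)
    tab <- measure_bones(p$volume, p$landmarks, threshold_hu = 398,
                         cleanup = FALSE)
    expect_lte(tab$length_mm, tab$feret_mm + 1e-12)
  }

  # bent rod: two capsules joined at an elbow; the feret diagonal spans
  # tip to tip while the box aligns with the overall principal axis
  sp <- 20
  elbow <- phantom_spec(c(140, 105, 40), sp, list(
    capsule("TIBIA", "RIGHT", c(900, 515, 400), c(1, 0.05, 0), 1700, 150),
    capsule("FIBULA", "RIGHT", c(2019, 1110, 400), c(0.6, 0.8, 0), 1700, 150)),
    blur_sigma_um = 10)
  out <- make_capsule_volume(elbow)
  labs <- label_components_3d(apply_threshold(out$volume, 398))
  expect_equal(labs$n_labels, 1)     # joined at the elbow
  rec <- measure_component(bone_component(labs, 1))
  expect_gt(rec$feret_mm, rec$length_mm)
})

test_that("length is invariant to translation, mirroring and 90-degree turns", {
  arr <- array(FALSE, c(30, 16, 16))
  set.seed(8)
  arr[4:26, 5:11, 6:12] <- array(runif(23 * 7 * 7) < 0.8, c(23, 7, 7))
  arr[4:26, 8, 8] <- TRUE            # keep it connected
  labs <- label_components_3d(bone_mask(arr, 20))
  sizes <- tabulate(labs$data[labs$data > 0], labs$n_labels)
  base <- measure_component(bone_component(labs, which.max(sizes)))

  shifted <- array(FALSE, c(34, 20, 20))
  shifted[2:31, 3:18, 3:18] <- arr[1:30, 1:16, 1:16]
  labs2 <- label_components_3d(bone_mask(shifted, 20))
  sizes2 <- tabulate(labs2$data[labs2$data > 0], labs2$n_labels)
  tr <- measure_component(bone_component(labs2, which.max(sizes2)))
  expect_equal(tr$length_mm, base$length_mm, tolerance = 1e-9)
  expect_equal(tr$feret_mm, base$feret_mm, tolerance = 1e-9)

  mirrored <- arr[, , 16:1]
  labs3 <- label_components_3d(bone_mask(mirrored, 20))
  sizes3 <- tabulate(labs3$data[labs3$data > 0], labs3$n_labels)
  mi <- measure_component(bone_component(labs3, which.max(sizes3)))
  expect_equal(mi$length_mm, base$length_mm, tolerance = 1e-9)

  turned <- aperm(arr, c(1, 3, 2))   # 90-degree rotation about slice axis
  labs4 <- label_components_3d(bone_mask(turned, 20))
  sizes4 <- tabulate(labs4$data[labs4$data > 0], labs4$n_labels)
  ro <- measure_component(bone_component(labs4, which.max(sizes4)))
  expect_equal(ro$length_mm, base$length_mm, tolerance = 1e-9)
})

test_that("fused pair with protruding member measures longer than the lone bone", {
  fused <- make_fused_pair(length_um = 2400, length2_um = 2200,
                           radius_um = 180, gap_um = 20,
                           protrusion_um = 300, blur_sigma_um = 40)
  mask <- apply_threshold(fused$volume, 398)
  labs <- label_components_3d(mask)
  expect_equal(labs$n_labels, 1)
  comp_len <- measure_component(bone_component(labs, 1))$length_mm * 1000

  lone <- make_oblique_capsule(2400, c(1, 0, 0), radius_um = 180,
                               blur_sigma_um = 40)
  lone_tab <- measure_bones(lone$volume, lone$landmarks, threshold_hu = 398,
                            cleanup = FALSE)
  lone_len <- lone_tab$length_mm * 1000
  expect_gt(comp_len, lone_len)
  expect_lte(comp_len, 2400 + 300 + 2 * 20)
})
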