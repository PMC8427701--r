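test_that("histogram bins span the data and count every voxel", {
  v <- ct_volume(array(0:255, c(4, 8, 8)), 20)
  h <- compute_histogram(v)
  expect_length(h$bin_edges, 257)
  expect_true(all(diff(h$bin_edges) > 0))
  expect_true(all(h$counts == 1))

  const <- compute_histogram(ct_volume(array(7, c(2, 2, 2)), 20))
  expect_equal(sum(const$counts > 0), 1)
  expect_equal(sum(const$counts), 8)

  set.seed(5)
  rv <- ct_volume(array(rnorm(1000), c(10, 10, 10)), 20)
  expect_equal(sum(compute_histogram(rv)$counts), 1000)
})

test_that("maximum-entropy threshold matches closed form and brute force", {
  # uniform histogram: criterion reduces to ln((t+1)(255-t)), max at t = 127
  v <- ct_volume(array(rep(0:255, 2), c(8, 8, 8)), 20)
  h <- compute_histogram(v)
  expect_equal(max_entropy_threshold(h), h$bin_edges[129])  # bin 127 0-based

  # two equal spikes: criterion constant on the tie range, lowest t wins
  spikes <- structure(list(bin_edges = 0:256,
                           counts = as.integer(
                             tabulate(c(rep(11, 50), rep(201, 50)), 256))),
                      class = "hu_histogram")
  expect_equal(max_entropy_threshold(spikes), 11)  # lower edge of bin 11 (0-based)

  expect_error(
    max_entropy_threshold(compute_histogram(ct_volume(array(1, c(2, 2, 2)), 20))),
    "degenerate")
})

test_that("maximum-entropy threshold equals the exhaustive scan on random histograms", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(c(16, 64, 256), 1)
    counts <- rpois(n, lambda = sample(c(0.5, 2, 20), 1))
    if (sum(counts > 0) < 2) next
    h <- structure(list(bin_edges = seq(-1000, 2000, length.out = n + 1),
                        counts = as.integer(counts)),
                   class = "hu_histogram")
    expect_equal(max_entropy_threshold(h),
                 kapur_bruteforce(counts, h$bin_edges))
  }
})

test_that("preset thresholds reproduce the benchmarked stage values", {
  expect_equal(preset_threshold("P7", "high", "mimics-style"), 650)
  expect_equal(preset_threshold("P7", "low", "mimics-style"), 398)
  expect_equal(preset_threshold("E17.5", "high", "mimics-style"), 398)
  expect_equal(preset_threshold("E17.5", "low", "mimics-style"), 226)
  expect_equal(preset_threshold("P7", "high", "bonej-style"), 500)
  expect_equal(preset_threshold("P7", "low", "bonej-style"), 385)
  expect_equal(preset_threshold("E17.5", "high", "bonej-style"), 400)
  expect_equal(preset_threshold("E17.5", "low", "bonej-style"), 280)
  expect_error(preset_threshold("P30", "low"), "available")

  tab <- threshold_presets()
  for (p in unique(tab$profile)) for (s in unique(tab$stage)) {
    hu <- function(l) tab$hu[tab$stage == s & tab$level == l & tab$profile == p]
    expect_true(hu("low") < hu("medium") && hu("medium") < hu("high"))
  }
})

test_that("apply_threshold is inclusive at the bound and monotone", {
  v <- ct_volume(array(c(-1000, 50, 800, 398), c(1, 2, 2)), 20)
  m <- apply_threshold(v, 398)
  expect_equal(sum(m$data), 2)  # 800 and the exactly-398 voxel
  expect_true(all(apply_threshold(v, min(v$data))$data))
  expect_error(apply_threshold(v, 500, 400), "lower")

  p <- make_oblique_capsule(1800, c(1, .4, .1), radius_um = 220,
                            blur_sigma_um = 30)
  vols <- vapply(seq(280, 650, by = 30), function(th)
    sum(apply_threshold(p$volume, th)$data), 0)
  expect_true(all(diff(vols) <= 0))
  expect_true(any(diff(vols) < 0))
})

test_that("fill_holes_2d closes lumens and is idempotent", {
  # annulus slice -> solid disk
  m <- array(FALSE, c(1, 21, 21))
  for (i in 1:21) for (j in 1:21) {
    r <- sqrt((i - 11)^2 + (j - 11)^2)
    m[1, i, j] <- r <= 8 && r >= 4
  }
  solid <- array(FALSE, c(1, 21, 21))
  for (i in 1:21) for (j in 1:21)
    solid[1, i, j] <- sqrt((i - 11)^2 + (j - 11)^2) <= 8
  filled <- fill_holes_2d(bone_mask(m, 20))
  expect_identical(filled$data, solid)
  expect_identical(fill_holes_2d(filled)$data, filled$data)  # idempotent
  expect_identical(fill_holes_2d(bone_mask(solid, 20))$data, solid)

  # hollow capsule phantom: filled volume equals the solid capsule's mask
  hollow <- phantom_spec(c(60, 31, 31), 20,
    list(capsule("FEMUR", "RIGHT", c(590, 300, 300), c(1, 0, 0), 1000, 200,
                 lumen_radius_um = 100)), blur_sigma_um = 0)
  solid_spec <- phantom_spec(c(60, 31, 31), 20,
    list(capsule("FEMUR", "RIGHT", c(590, 300, 300), c(1, 0, 0), 1000, 200)),
    blur_sigma_um = 0)
  mh <- fill_holes_2d(apply_threshold(make_capsule_volume(hollow)$volume, 398))
  ms <- apply_threshold(make_capsule_volume(solid_spec)$volume, 398)
  expect_identical(mh$data, ms$data)
})

test_that("remove_outliers_2d deletes specks below the retention floor", {
  m <- array(FALSE, c(1, 30, 30))
  m[1, 5, 5] <- TRUE                 # isolated pixel
  m[1, 10:19, 10:19] <- TRUE         # 100-px blob
  out <- remove_outliers_2d(bone_mask(m, 20), min_retained = 5)
  expect_false(out$data[1, 5, 5])
  expect_true(all(out$data[1, 10:19, 10:19]))

  # boundary rule: exactly min_retained survives (strict < removal)
  m2 <- array(FALSE, c(1, 10, 10))
  m2[1, 2:6, 3] <- TRUE              # 5 px
  expect_equal(sum(remove_outliers_2d(bone_mask(m2, 20),
                                      min_retained = 5)$data), 5)
  expect_equal(sum(remove_outliers_2d(bone_mask(m2, 20),
                                      min_retained = 6)$data), 0)
})

test_that("erode_2d shrinks per slice and composes additively", {
  m <- array(FALSE, c(2, 9, 9))
  m[1, 4:6, 4:6] <- TRUE             # 3x3 -> centre pixel
  m[2, 5, 5] <- TRUE                 # single pixel -> empty
  e <- erode_2d(bone_mask(m, 20))
  expect_equal(which(e$data[1, , ]), which(matrix(seq_len(81), 9, 9) == 41))
  expect_equal(sum(e$data[2, , ]), 0)

  disk <- array(FALSE, c(1, 41, 41))
  for (i in 1:41) for (j in 1:41)
    disk[1, i, j] <- sqrt((i - 21)^2 + (j - 21)^2) <= 15
  dm <- bone_mask(disk, 20)
  e2 <- erode_2d(dm, 2)
  expect_identical(e2$data, erode_2d(erode_2d(dm, 1), 1)$data)
  # disk radius r -> about r-2 after two erosions (+-1 px on the boundary)
  radii <- sqrt(rowSums((which(e2$data[1, , ], arr.ind = TRUE) - 21)^2))
  expect_lt(max(radii), 15 - 2 + 1.5)
  expect_identical(erode_2d(dm, 0)$data, dm$data)
})

test_that("watershed_separate_2d splits necked blobs, leaves convex ones", {
  two <- array(FALSE, c(1, 40, 80))
  for (i in 1:40) for (j in 1:80)
    two[1, i, j] <- sqrt((i - 20)^2 + (j - 25)^2) <= 12 ||
      sqrt((i - 20)^2 + (j - 55)^2) <= 12
  two[1, 19:21, 25:55] <- TRUE       # thin neck
  ws <- watershed_separate_2d(bone_mask(two, 20))
  expect_gte(max(EBImage::bwlabel(ws$data[1, , ] * 1)), 2)

  disk <- array(FALSE, c(1, 30, 30))
  for (i in 1:30) for (j in 1:30)
    disk[1, i, j] <- sqrt((i - 15)^2 + (j - 15)^2) <= 10
  out <- watershed_separate_2d(bone_mask(disk, 20))
  expect_identical(out$data, disk)

  empty <- bone_mask(array(FALSE, c(2, 10, 10)), 20)
  expect_identical(watershed_separate_2d(empty)$data, empty$data)
})

test_that("label_components_3d matches connectivity semantics and BFS", {
  m <- array(FALSE, c(6, 6, 6))
  m[1:2, 1:2, 1:2] <- TRUE
  m[5:6, 5:6, 5:6] <- TRUE
  expect_equal(label_components_3d(bone_mask(m, 20))$n_labels, 2)

  corner <- array(FALSE, c(2, 2, 2))
  corner[1, 1, 1] <- TRUE; corner[2, 2, 2] <- TRUE
  expect_equal(label_components_3d(bone_mask(corner, 20), 26)$n_labels, 1)
  expect_equal(label_components_3d(bone_mask(corner, 20), 6)$n_labels, 2)

  set.seed(33)
  for (conn in c(6, 26)) {
    noise <- array(runif(30^3) < 0.25, c(30, 30, 30))
    got <- label_components_3d(bone_mask(noise, 20), conn)
    expect_identical(got$data, bfs_partition(noise, conn))
  }
})

test_that("filter_by_volume drops small components and renumbers", {
  m <- array(FALSE, c(30, 30, 30))
  m[2:21, 2:17, 2:17] <- TRUE        # 5120 voxels
  m[25:27, 25:29, 25:24 + 4] <- TRUE # 3x5x4 = 60 voxels
  labs <- label_components_3d(bone_mask(m, 20))
  expect_equal(labs$n_labels, 2)
  f <- filter_by_volume(labs, 1000)
  expect_equal(f$n_labels, 1)
  expect_equal(sort(unique(as.integer(f$data))), c(0L, 1L))
  expect_identical(filter_by_volume(labs, 0)$data, labs$data)

  # survivor count equals brute force over the component size table
  set.seed(7)
  noise <- array(runif(20^3) < 0.2, c(20, 20, 20))
  labs2 <- label_components_3d(bone_mask(noise, 20))
  sizes <- tabulate(labs2$data[labs2$data > 0], labs2$n_labels)
  for (mv in c(1, 3, 10, 50))
    expect_equal(filter_by_volume(labs2, mv)$n_labels, sum(sizes >= mv))
})
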