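test_that("centerline interpolates landmarks exactly at zero smoothing", {
  # collinear equally spaced points: the curve is the straight segment
  pts <- cbind(10, 20, seq(5, 45, length.out = 5))
  cl <- fit_centerline(landmark_set(pts), smoothing = 0)
  expect_lt(max(abs(cl$points_dense[, 1] - 10)), 1e-9)
  expect_lt(max(abs(cl$points_dense[, 2] - 20)), 1e-9)
  expect_equal(cl$length, 40, tolerance = 1e-6)

  set.seed(51)
  pts2 <- cbind(sort(runif(5, 0, 60)), runif(5, 10, 50), runif(5, 10, 50))
  cl2 <- fit_centerline(landmark_set(pts2), smoothing = 0)
  tt <- c(0, cumsum(sqrt(rowSums(diff(pts2)^2))))
  tt <- tt / max(tt)
  fitted <- sapply(cl2$coords, function(cc) cc$f(tt))
  expect_lt(max(abs(fitted - pts2)), 1e-6)
})

test_that("default smoothing keeps landmark deviation within 2 mm", {
  set.seed(52)
  pts <- cbind(30 + rnorm(5, 0, 2), 30 + rnorm(5, 0, 2), seq(10, 60, length.out = 5))
  cl <- fit_centerline(landmark_set(pts))
  expect_lte(cl$landmark_deviation, 2)
})

test_that("degenerate landmark sets are rejected", {
  pts <- cbind(10, 20, c(5, 5, 15, 25, 35))
  expect_error(landmark_set(pts), "distinct")
  expect_error(landmark_set(cbind(1:4, 1:4, 1:4)), "5x3")
})

test_that("centerline recovers a circular arc", {
  th <- seq(0, pi / 2, length.out = 5)
  pts <- cbind(40 + 30 * cos(th), 40 + 30 * sin(th), 20)
  cl <- fit_centerline(landmark_set(pts), smoothing = 0)
  # sampled curve stays within tolerance of the analytic radius-30 arc
  r <- sqrt((cl$points_dense[, 1] - 40)^2 + (cl$points_dense[, 2] - 40)^2)
  expect_lt(max(abs(r - 30)), 0.5)
  expect_equal(cl$length, 30 * pi / 2, tolerance = 0.01)
})

test_that("centerline samples are evenly spaced in arc length with unit tangents", {
  # straight segment of length 63: spacing exactly 1 mm, identical tangents
  pts <- cbind(5, 5, seq(0, 63, length.out = 5))
  samp <- sample_centerline(fit_centerline(landmark_set(pts), 0), 64)
  expect_equal(samp$spacing, 1, tolerance = 1e-9)
  d <- sqrt(rowSums(diff(samp$centers)^2))
  expect_lt(max(abs(d - 1)), 1e-6)
  expect_lt(max(abs(sweep(samp$tangents, 2, c(0, 0, 1)))), 1e-9)

  # helix: spacing uniform to 0.1% against dense-polyline arc length
  t5 <- seq(0, 1, length.out = 5)
  helix <- function(t) cbind(30 + 10 * cos(2 * pi * t), 30 + 10 * sin(2 * pi * t), 60 * t)
  cl <- fit_centerline(landmark_set(helix(t5)), smoothing = 0, n_dense = 8001)
  samp <- sample_centerline(cl, 64)
  d <- sqrt(rowSums(diff(samp$centers)^2))
  expect_lt((max(d) - min(d)) / mean(d), 0.001 + 0.002) # chord-vs-arc slack
  expect_lt(max(abs(sqrt(rowSums(samp$tangents^2)) - 1)), 1e-9)
  expect_error(sample_centerline(cl, 1), "at least 2")
})

test_that("slice frames are right-handed, orthonormal and sagittal-locked", {
  s <- c(1, 0, 0)
  # tangent orthogonal to sagittal axis: u is exactly the sagittal axis
  fr <- slice_frame(c(0, 0, 1), s)
  expect_equal(fr$u, c(1, 0, 0))
  expect_equal(fr$v, c(0, 1, 0)) # t x u

  # 45-degree tangent: hand-computed Gram-Schmidt
  t45 <- c(1, 0, 1) / sqrt(2)
  fr <- slice_frame(t45, s)
  u_hand <- (s - sum(s * t45) * t45)
  u_hand <- u_hand / sqrt(sum(u_hand^2))
  expect_equal(fr$u, u_hand, tolerance = 1e-12)

  set.seed(53)
  for (i in 1:20) {
    t_ <- rnorm(3)
    t_ <- t_ / sqrt(sum(t_^2))
    fr <- slice_frame(t_, s)
    expect_lt(abs(sum(fr$u * t_)), 1e-10)
    expect_lt(abs(sum(fr$v * t_)), 1e-10)
    expect_lt(abs(sum(fr$u * fr$v)), 1e-10)
    expect_equal(sum(tavrisk:::cross3(fr$u, fr$v) * t_), 1, tolerance = 1e-10)
  }
  # tangent parallel to sagittal: axial fallback with a message
  expect_message(slice_frame(c(1, 0, 0), s), "axial")
})

test_that("slice resampling reproduces constant, on-grid and ramp volumes", {
  vol_c <- volume_grid(array(7, c(20, 20, 20)))
  fr <- list(u = c(1, 0, 0), v = c(0, 1, 0))
  sl <- resample_slice(vol_c, c(9.5, 9.5, 9.5), fr, size = 16, in_plane_spacing = 1)
  expect_true(all(sl == 7))

  # axial frame, unit spacing, center on-grid: the exact voxel plane
  set.seed(54)
  arr <- array(rnorm(20^3), c(20, 20, 20))
  vol <- volume_grid(arr)
  sl <- resample_slice(vol, c(7.5, 7.5, 10), fr, size = 16, in_plane_spacing = 1)
  expect_equal(sl, arr[1:16, 1:16, 11], tolerance = 1e-12, ignore_attr = TRUE)

  # linear ramp I(x,y,z) = x is reproduced exactly by trilinear sampling
  xs <- array(rep(0:19, times = 400), c(20, 20, 20))
  volr <- volume_grid(xs)
  fr2 <- list(u = c(0.6, 0.8, 0), v = c(0, 0, 1))
  ctr <- c(9.2, 9.7, 9.4)
  sl <- resample_slice(volr, ctr, fr2, size = 8, in_plane_spacing = 0.7)
  off <- (seq_len(8) - 4.5) * 0.7
  expected <- outer(off * fr2$u[1], rep(0, 8), "+") + ctr[1]
  expect_equal(sl, matrix(expected[, 1], 8, 8), tolerance = 1e-6, ignore_attr = TRUE)

  # out-of-volume positions are filled and counted
  sl3 <- resample_slice(vol, c(0, 0, 0), fr, size = 16, in_plane_spacing = 2)
  expect_gt(attr(sl3, "n_outside"), 0)
  expect_true(any(sl3 == -1000))
})

test_that("extract_roi straightens a vertical cylinder into centered disks", {
  ph <- render_phantom_volume("straight", dims = c(64, 64, 80), radius = 8)
  roi <- extract_roi(ph$volume, ph$landmarks)
  expect_equal(dim(roi$intensities), c(64, 64, 64))
  core <- ph$volume$intensities[33, 33, 40]
  for (k in c(1, 16, 32, 48, 64)) {
    sl <- roi$intensities[, , k]
    # center bright, corners background
    expect_equal(sl[32, 32], core)
    expect_lt(sl[2, 2], core - 100)
    # the disk is centred: centroid of bright pixels at the slice center
    bright <- which(sl > 100, arr.ind = TRUE)
    expect_lt(max(abs(colMeans(bright) - 32.5)), 1)
  }
  expect_error(
    extract_roi(ph$volume, landmark_set(cbind(100, 100, seq(1, 50, length.out = 5)))),
    "bounding box"
  )
})

test_that("curved-tube phantom keeps its core on the straightened axis", {
  ph <- render_phantom_volume("arc", dims = c(72, 48, 72), radius = 7)
  roi <- extract_roi(ph$volume, ph$landmarks)
  centers <- roi$intensities[32:33, 32:33, ]
  core_hits <- apply(centers > 100, 3, all)
  expect_gte(mean(core_hits), 0.95)
})

test_that("slice frames stay orthogonal to the local tangent across the ROI", {
  t5 <- seq(0, 1, length.out = 5)
  helix <- function(t) cbind(32 + 8 * cos(2 * pi * t), 32 + 8 * sin(2 * pi * t), 8 + 48 * t)
  lms <- landmark_set(helix(t5))
  cl <- fit_centerline(lms, smoothing = 0)
  samp <- sample_centerline(cl, 64)
  for (i in seq(1, 64, by = 7)) {
    fr <- slice_frame(samp$tangents[i, ], c(1, 0, 0))
    expect_lt(abs(sum(fr$u * samp$tangents[i, ])), 1e-8)
    expect_lt(abs(sum(fr$v * samp$tangents[i, ])), 1e-8)
  }
  d <- sqrt(rowSums(diff(samp$centers)^2))
  expect_lt(max(abs(d - samp$spacing)) / samp$spacing, 0.005)
})

test_that("ROI extraction is equivariant under a common rigid motion", {
  ph <- render_phantom_volume("helix", dims = c(64, 64, 80), radius = 7)
  roi1 <- extract_roi(ph$volume, ph$landmarks)

  # rotate the volume and landmarks 90 degrees about z: (x,y,z)->(-y,x,z)
  arr <- ph$volume$intensities
  d <- dim(arr)
  arr_rot <- aperm(arr, c(2, 1, 3))[d[2]:1, , ] # new[x',y',z] = old[y, x', z] mirrored
  pts <- ph$landmarks$points
  pts_rot <- cbind((d[2] - 1) - pts[, 2], pts[, 1], pts[, 3])
  vol_rot <- volume_grid(arr_rot, sagittal_axis = 2)
  roi2 <- extract_roi(vol_rot, landmark_set(pts_rot))

  rng <- diff(range(roi1$intensities))
  expect_lt(mean(abs(roi1$intensities - roi2$intensities)) / rng, 0.01)
})

test_that("volumes and landmarks round-trip through NIfTI and JSON", {
  dir <- withr::local_tempdir()
  set.seed(55)
  vol <- volume_grid(array(rnorm(8 * 8 * 8), c(8, 8, 8)),
    spacing = c(1, 1, 2), origin = c(5, -3, 10)
  )
  pv <- file.path(dir, "v.nii.gz")
  write_volume(vol, pv)
  back <- read_volume(pv)
  expect_equal(back$intensities, vol$intensities, tolerance = 1e-6)
  expect_equal(back$spacing, vol$spacing)
  expect_equal(as.numeric(back$origin), vol$origin, tolerance = 1e-6)

  lm <- landmark_set(cbind(1:5, 2:6, seq(3, 30, length.out = 5)))
  pl <- file.path(dir, "lm.json")
  write_landmarks(lm, pl)
  expect_equal(read_landmarks(pl)$points, lm$points)
})
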