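test_that("phantom labels partition the brain with the expected contrast", {
  ph <- small_phantom()
  labs <- sort(unique(as.vector(ph$seg$data)))
  expect_true(all(labs %in% c(0, 2, 3, 4, 41, 1001:1004)))
  expect_true(all(c(2, 41, 3, 4) %in% labs))

  # WM / ventricle mean uptake ratio is exact without smoothing
  ph0 <- make_phantom(phantom_config(n = 32L, pet_fwhm_mm = 0,
                                     pet_uptake = c(wm = 1, gm = 0.6,
                                                    ventricle = 0.1,
                                                    background = 0)))
  wm <- mean(ph0$pet$data[ph0$seg$data %in% c(2, 41)])
  vent <- mean(ph0$pet$data[ph0$seg$data == 4])
  expect_equal(wm / vent, 10)

  expect_error(make_phantom(phantom_config(n = 16L)), "too small")
})

test_that("the WM compartment is non-convex (midpoint witness)", {
  ph <- small_phantom()
  wm <- array(ph$seg$data %in% c(2, 41), dim(ph$seg$data))
  idx <- which(wm, arr.ind = TRUE)
  set.seed(3)
  witness <- FALSE
  for (i in 1:5000) {
    a <- idx[sample.int(nrow(idx), 1), ]
    b <- idx[sample.int(nrow(idx), 1), ]
    mid <- round((a + b) / 2)
    if (!wm[mid[1], mid[2], mid[3]]) { witness <- TRUE; break }
  }
  expect_true(witness)
})

test_that("slice-wise projection conserves mass and is exact for a point source", {
  ph <- small_phantom()
  s <- project_to_sinograms(ph$pet)
  slice_sums <- apply(ph$pet$data, 3, sum)
  proj_sums <- apply(s$data, c(1, 3), sum)       # per angle x slice
  active <- slice_sums > max(slice_sums) * 0.01
  rel <- abs(sweep(proj_sums[, active], 2, slice_sums[active], "/") - 1)
  expect_lt(max(rel), 0.01)

  zero <- image_volume(array(0, c(16, 16, 4)), affine = diag(4))
  expect_equal(sum(project_to_sinograms(zero)$data), 0)
  expect_error(project_to_sinograms(zero, numeric(0)), "empty")

  # centred point source: flat unit trace at the central detector bin
  pt <- image_volume(array(0, c(33, 33, 3)), affine = diag(4))
  pt$data[17, 17, 2] <- 1
  sp <- project_to_sinograms(pt)
  ctr_bin <- (dim(sp$data)[2] + 1) / 2
  # a delta at the isocentre traces no sinusoid: at every angle its mass
  # stays at the central detector bin (within the interpolated delta's
  # one-pixel support)
  for (a in seq_len(dim(sp$data)[1])) {
    prof <- sp$data[a, , 2]
    expect_equal(which.max(prof), ctr_bin)
    near <- sum(prof[(ctr_bin - 1):(ctr_bin + 1)])
    expect_gt(near / sum(prof), 0.95)
  }
})

test_that("count scaling reproduces the dose x uptake x sensitivity x time product", {
  ph <- small_phantom()
  s <- project_to_sinograms(ph$pet)
  s20 <- scale_counts(s, count_model(duration_s = 1200))
  expect_equal(s20$total, 370 * 0.05 * 15000 * 1200, tolerance = 1 / 3.33e8)
  s5 <- scale_counts(s, count_model(duration_s = 300))
  expect_equal(s5$total, s20$total / 4, tolerance = 1e-12)

  # global scaling preserves bin ratios
  nz <- which(s$data > 0)[c(10, 5000)]
  expect_equal(s20$data[nz[1]] / s20$data[nz[2]],
               s$data[nz[1]] / s$data[nz[2]], tolerance = 1e-12)

  zero <- project_to_sinograms(
    image_volume(array(0, c(16, 16, 4)), affine = diag(4)))
  expect_error(scale_counts(zero, count_model()), "zero-total")
})

test_that("Poisson noise has the right moments and is seed-reproducible", {
  flat <- image_volume(array(1, c(16, 16, 2)), affine = diag(4))
  s <- project_to_sinograms(flat)
  s$data[] <- 100                                 # bins of mean 100
  n1 <- add_poisson_noise(s, seed = 42)
  n2 <- add_poisson_noise(s, seed = 42)
  expect_identical(n1$data, n2$data)

  big <- s; big$data <- array(100, c(100, 100, 10))  # 1e5 draws
  nb <- add_poisson_noise(big, seed = 7)
  expect_lt(abs(mean(nb$data) - 100), 1)
  expect_lt(abs(stats::var(as.vector(nb$data)) - 100), 3)

  zs <- s; zs$data[] <- 0
  expect_equal(sum(add_poisson_noise(zs, 1)$data), 0)
  neg <- s; neg$data[1] <- -1
  expect_error(add_poisson_noise(neg, 1), "negative")
})

test_that("FBP round-trips a noise-free phantom and validates coverage", {
  ph <- small_phantom()
  s <- project_to_sinograms(ph$pet)
  rec <- fbp_reconstruct(s, "ramp")
  interior <- ph$seg$data != 0
  nrmse <- sqrt(mean((rec$data[interior] - ph$pet$data[interior])^2)) /
    diff(range(ph$pet$data))
  expect_lt(nrmse, 0.10)

  zs <- s; zs$data[] <- 0; zs$total <- 0
  expect_equal(sum(fbp_reconstruct(zs)$data), 0)

  short <- project_to_sinograms(ph$pet, angles = seq(0, 90, by = 1))
  expect_error(fbp_reconstruct(short), "180")
})

test_that("the Hamming window reduces noise variance relative to the ramp", {
  ph <- small_phantom()
  s <- scale_counts(project_to_sinograms(ph$pet),
                    count_model(duration_s = 300))
  wm_core <- erode_mask(image_volume(
    array(as.double(ph$seg$data %in% c(2, 41)), dim(ph$seg$data)),
    spacing = ph$seg$spacing, affine = ph$seg$affine), 2)$data != 0
  vh <- vr <- numeric(4)
  for (i in 1:4) {
    noisy <- add_poisson_noise(s, seed = 100 + i)
    vh[i] <- stats::var(fbp_reconstruct(noisy, "hamming")$data[wm_core])
    vr[i] <- stats::var(fbp_reconstruct(noisy, "ramp")$data[wm_core])
  }
  expect_lt(mean(vh), mean(vr))
})

test_that("5-min noise variance is about 4x the 20-min variance", {
  ph <- cached("ph32", make_phantom(phantom_config(n = 32L)))
  s <- project_to_sinograms(ph$pet)
  wm_core <- erode_mask(image_volume(
    array(as.double(ph$seg$data %in% c(2, 41)), dim(ph$seg$data)),
    spacing = ph$seg$spacing, affine = ph$seg$affine), 1)$data != 0
  recs <- function(duration, seeds) {
    sc <- scale_counts(s, count_model(duration_s = duration))
    vapply(seeds, function(sd)
      fbp_reconstruct(add_poisson_noise(sc, sd))$data[wm_core],
      numeric(sum(wm_core)))
  }
  r20 <- recs(1200, 1:20)
  r5 <- recs(300, 21:40)
  v20 <- mean(apply(r20, 1, stats::var))
  v5 <- mean(apply(r5, 1, stats::var))
  expect_gt(v5 / v20, 3)
  expect_lt(v5 / v20, 5)
})

test_that("random_motion respects bounds, seeding, and the CLT", {
  ms <- random_motion(500, seed = 5)
  mat <- t(vapply(ms, unclass, numeric(6)))
  expect_true(all(mat >= -10 & mat <= 10))
  expect_identical(random_motion(500, seed = 5), ms)
  # uniform(-10,10): sd = 20/sqrt(12); mean within 3*sd/sqrt(n)
  expect_true(all(abs(colMeans(mat)) < 3 * (20 / sqrt(12)) / sqrt(500)))
})

test_that("noise-free end-to-end linearity holds", {
  ph <- cached("ph32", make_phantom(phantom_config(n = 32L)))
  s1 <- project_to_sinograms(ph$pet)
  pet2 <- ph$pet; pet2$data <- 2 * pet2$data
  s2 <- project_to_sinograms(pet2)
  expect_equal(s2$total, 2 * s1$total, tolerance = 1e-12)
  r1 <- fbp_reconstruct(s1, "ramp"); r2 <- fbp_reconstruct(s2, "ramp")
  core <- ph$seg$data != 0
  expect_equal(mean(r2$data[core]), 2 * mean(r1$data[core]), tolerance = 0.01)
})

test_that("run_benchmark emits a complete tidy table", {
  res <- run_benchmark(trials = 2, noise_durations = 0, methods = "tcbc",
                       phantom = phantom_config(n = 48L),
                       config = tcbc_config(n_starts = 3L,
                                            max_roi_voxels = 8000),
                       seed = 7)
  expect_equal(nrow(res), 2L)
  need <- c("trial", "method", "duration_s", "objective", "converged",
            "seconds",
            paste0("true_", c("tx", "ty", "tz", "rx", "ry", "rz")),
            paste0("est_", c("tx", "ty", "tz", "rx", "ry", "rz")),
            paste0("err_", c("tx", "ty", "tz", "rx", "ry", "rz")))
  expect_true(all(need %in% names(res)))
  expect_false(anyNA(res[, need]))
  # ground-truth self-consistency: applied o truth = identity
  ctr <- volume_center(make_phantom(phantom_config(n = 48L))$pet)
  motions <- random_motion(2, seed = 7)
  for (t in 1:2) {
    M <- build_transform(motions[[t]], ctr)
    tp <- as.numeric(res[res$trial == t, paste0("true_",
                                                c("tx", "ty", "tz", "rx", "ry", "rz"))])
    expect_equal(build_transform(tp, ctr) %*% M, diag(4), tolerance = 1e-9)
  }
})
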