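mask_vol <- function(arr) image_volume(arr * 1, affine = diag(4))

test_that("erode_mask matches the definitional cases and a brute-force scan", {
  cube <- array(0, c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- 1
  m <- mask_vol(cube)
  e1 <- erode_mask(m, 1, 6)
  expect_equal(sum(e1$data), 1)
  expect_equal(e1$data[3, 3, 3], 1)

  expect_identical(erode_mask(m, 0)$data, m$data)

  # brute-force neighbour-check oracle on the lobed WM phantom mask
  ph <- small_phantom()
  wm <- mask_vol(array(as.double(ph$seg$data %in% c(2, 41)),
                       dim(ph$seg$data)))
  er <- erode_mask(wm, 1, 6)$data != 0
  w <- wm$data != 0
  d <- dim(w)
  oracle <- array(FALSE, d)
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1)) {
    oracle[i, j, k] <- w[i, j, k] && w[i - 1, j, k] && w[i + 1, j, k] &&
      w[i, j - 1, k] && w[i, j + 1, k] && w[i, j, k - 1] && w[i, j, k + 1]
  }
  expect_identical(er, oracle)

  # monotone: eroded set shrinks with iterations and stays inside
  e2 <- erode_mask(wm, 2, 6)$data != 0
  expect_true(all(!e2 | er))
  expect_lt(sum(e2), sum(er))

  single <- array(0, c(4, 4, 4)); single[2, 2, 2] <- 1
  expect_error(erode_mask(mask_vol(single), 1), "emptied")
})

test_that("sum_frames applies strict window containment", {
  fr <- function(v, a, b) image_volume(array(v, c(4, 4, 4)),
                                       frame_start = a, frame_end = b)
  frames <- list(fr(1, 3000, 3300), fr(1, 3300, 3600),
                 fr(1, 3600, 3900), fr(1, 3900, 4200))
  s <- sum_frames(frames, c(3000, 4200))
  expect_equal(unique(as.vector(s$data)), 4)
  expect_equal(s$frame_start, 3000)
  expect_equal(s$frame_end, 4200)

  # a partially overlapping frame is excluded
  frames5 <- c(frames, list(fr(100, 4100, 4500)))
  s <- sum_frames(frames5, c(3000, 4200))
  expect_equal(unique(as.vector(s$data)), 4)

  expect_error(sum_frames(frames, c(10000, 20000)), "no frame")
  expect_error(sum_frames(list(image_volume(array(1, c(4, 4, 4)))),
                          c(0, 1)), "metadata")
})

test_that("compute_suvr reproduces constructed ratios and invariances", {
  ph <- make_phantom(phantom_config(n = 40L, pet_fwhm_mm = 0,
                                    mr_noise_sd = 0))
  cfg <- suvr_config()

  # uniform PET: every SUVR is exactly 1
  uni <- ph$pet; uni$data[] <- 2.5
  res <- compute_suvr(uni, ph$seg, diag(4), cfg)
  expect_equal(unname(res$suvr), rep(1, 5))

  # constructed contrast: targets at 1.4, WM reference at 1.0
  pet <- ph$pet
  pet$data[] <- 0.6
  pet$data[ph$seg$data %in% c(2, 41)] <- 1.0
  pet$data[ph$seg$data %in% 1001:1004] <- 1.4
  res <- compute_suvr(pet, ph$seg, diag(4), cfg)
  expect_equal(unname(res$suvr), rep(1.4, 5), tolerance = 1e-12)

  # scale invariance under global PET rescaling
  pet$data[ph$seg$data == 1001] <- 2.0   # heterogeneous targets
  r1 <- compute_suvr(pet, ph$seg, diag(4), cfg)
  pet2 <- pet; pet2$data <- pet2$data * 37.5
  r2 <- compute_suvr(pet2, ph$seg, diag(4), cfg)
  expect_equal(r1$suvr, r2$suvr, tolerance = 1e-12)

  # composite equals the direct masked mean over the union (oracle)
  union <- ph$seg$data %in% 1001:1004
  expect_equal(unname(r1$suvr["early_composite"]),
               mean(pet$data[union]) / r1$reference_mean, tolerance = 1e-12)

  expect_error(suvr_config(targets = list(a = 2L)), "disjoint")
  bad <- suvr_config(targets = list(precuneus = 9999L))
  expect_error(compute_suvr(pet, ph$seg, diag(4), bad), "precuneus")
})

test_that("misalignment biases SUVR and re-registration restores it", {
  ph <- make_phantom(phantom_config(n = 48L))
  center <- volume_center(ph$pet)
  cfg <- suvr_config()
  aligned <- compute_suvr(ph$pet, ph$seg, diag(4), cfg)

  M <- build_transform(rigid_params(5, -4, 3, 4, -3, 5), center)
  seg_m <- resample_volume(ph$seg, M, "nearest")
  misaligned <- compute_suvr(ph$pet, seg_m, diag(4), cfg)
  expect_gt(max(abs(misaligned$suvr - aligned$suvr)), 0.02)

  roi <- select_target_roi(seg_m, c(2, 41))
  fit <- tcbc_register(ph$pet, roi,
                       tcbc_config(n_starts = 6L, seed = 4L,
                                   max_roi_voxels = 10000),
                       center = center)
  corrected <- compute_suvr(ph$pet, seg_m, fit$matrix, cfg)
  expect_equal(unname(corrected$suvr), unname(aligned$suvr),
               tolerance = 0.02)
})
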