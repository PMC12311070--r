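# Shared fixtures built once per test run (all generated in code; no files).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# small default-contrast phantom (48^3, 2 mm)
small_phantom <- function() cached("ph48", make_phantom(phantom_config(n = 48L)))

# medium phantom for registration tests
med_phantom <- function() cached("ph64", make_phantom(phantom_config(n = 64L)))

# acceptance-scale phantom
big_phantom <- function() cached("ph96", make_phantom(phantom_config(n = 96L)))

# unsmoothed, noise-free-contrast phantom: WM is the strict intensity
# maximum, so the TCBC objective's optimum is exactly at alignment
sharp_phantom <- function()
  cached("ph48s", make_phantom(phantom_config(n = 48L, pet_fwhm_mm = 0,
                                              mr_noise_sd = 0)))

# smooth Gaussian blob for interpolation-error checks (sigma well above the
# voxel size so trilinear error stays small)
blob_volume <- function(n = 32L, spacing = c(1, 1, 1.5), sigma = 9) {
  cached(paste0("blob", n), {
    ax <- function(nn, sp) (seq_len(nn) - (nn + 1) / 2) * sp
    x <- ax(n, spacing[1]); y <- ax(n, spacing[2]); z <- ax(n, spacing[3])
    r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
    image_volume(exp(-r2 / (2 * sigma^2)), spacing = spacing)
  })
}

expect_params_close <- function(est, ref, tol_t, tol_r) {
  d <- unclass(as_rigid_params_test(est)) - unclass(as_rigid_params_test(ref))
  expect_lt(max(abs(d[1:3])), tol_t)
  expect_lt(max(abs(d[4:6])), tol_r)
}

as_rigid_params_test <- function(x) {
  if (inherits(x, "rigid_params")) return(x)
  rigid_params(x[1], x[2], x[3], x[4], x[5], x[6])
}
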