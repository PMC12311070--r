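#' Digital brain phantom configuration
#'
#' Parameters of the synthetic PET/MR pair used throughout the simulation
#' benchmark. Tissue geometry is defined relative to the field of view, so
#' any grid large enough to resolve the shells can be used. Default contrast
#' emulates an amyloid tracer in a cognitively normal subject: high uniform
#' white-matter (WM) uptake, lower gray-matter (GM) uptake, near-zero
#' ventricle uptake.
#'
#' @param n grid size per axis (voxels, default 96; minimum 24).
#' @param spacing voxel size, mm (default 2).
#' @param pet_uptake named uptake values (arbitrary activity units) for
#'   `wm`, `gm`, `ventricle`, `background`; must satisfy
#'   wm > gm > ventricle >= 0.
#' @param mr_intensity named T1w-like intensities for the same tissues.
#' @param pet_fwhm_mm Gaussian smoothing FWHM emulating PET resolution
#'   (default 4 mm; 0 disables).
#' @param mr_noise_sd within-tissue Gaussian noise SD on the MR intensities
#'   (default 5, about SNR 22 against the WM intensity, emulating T1w
#'   acquisition noise; 0 disables). Deterministic for a given config.
#' @param jitter_seed optional integer; when given, tissue semi-axes are
#'   jittered by up to +/-3% for shape variability (also reseeds the MR
#'   noise).
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n = 96L, spacing = 2,
                           pet_uptake = c(wm = 1.0, gm = 0.6,
                                          ventricle = 0.05, background = 0),
                           mr_intensity = c(wm = 110, gm = 80,
                                            ventricle = 30, background = 0),
                           pet_fwhm_mm = 4, mr_noise_sd = 5,
                           jitter_seed = NULL) {
  stopifnot(length(n) %in% c(1L, 3L), spacing > 0, pet_fwhm_mm >= 0,
            mr_noise_sd >= 0)
  n <- as.integer(if (length(n) == 1L) rep(n, 3L) else n)
  u <- pet_uptake
  if (!(u[["wm"]] > u[["gm"]] && u[["gm"]] > u[["ventricle"]] &&
        u[["ventricle"]] >= 0))
    stop("uptake must satisfy wm > gm > ventricle >= 0", call. = FALSE)
  structure(list(n = n, spacing = spacing, pet_uptake = u,
                 mr_intensity = mr_intensity, pet_fwhm_mm = pet_fwhm_mm,
                 mr_noise_sd = mr_noise_sd, jitter_seed = jitter_seed),
            class = "phantom_config")
}

# FreeSurfer-style stand-in label IDs used by the phantom segmentation
PHANTOM_LABELS <- c(gm = 3L, wm_left = 2L, wm_right = 41L, ventricle = 4L,
                    precuneus = 1001L, anterior_cingulate = 1002L,
                    posterior_cingulate = 1003L, medial_orbitofrontal = 1004L)

# Separable 3-D Gaussian smoothing by dense banded matrix products.
gaussian_smooth3 <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  smooth_axis <- function(a, axis) {
    s <- sigma / spacing[axis]
    if (s < 1e-6) return(a)
    n <- dim(a)[axis]
    r <- ceiling(4 * s)
    i <- seq_len(n)
    ksum <- sum(exp(-((-r):r)^2 / (2 * s^2)))
    K <- outer(i, i, function(p, q) {
      d <- p - q
      ifelse(abs(d) <= r, exp(-d^2 / (2 * s^2)), 0)
    }) / ksum
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- K %*% matrix(ap, nrow = n)
    aperm(array(m, dim(ap)), order(perm))
  }
  smooth_axis(smooth_axis(smooth_axis(arr, 1L), 2L), 3L)
}

#' Build the digital brain phantom
#'
#' Nested-ellipsoid brain: an outer GM shell, an interior WM compartment with
#' a lobed (non-convex) boundary split into left/right hemispheres (labels 2
#' and 41), a central ventricle pair (label 4), and four cortical target
#' patches with stand-in IDs 1001-1004 (precuneus-, anterior-cingulate-,
#' posterior-cingulate-, and medial-orbitofrontal-like) used by the SUVR
#' machinery. Target patches carry GM uptake in the PET volume.
#'
#' @param cfg a [phantom_config].
#' @return list with elements `pet`, `mr` ([image_volume]s) and `seg`
#'   (label [image_volume]).
#' @export
make_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (any(cfg$n < 24L))
    stop("grid too small to contain the phantom shells (need >= 24 voxels per axis)",
         call. = FALSE)
  n <- cfg$n
  spacing <- rep(cfg$spacing, 3L)
  tmpl <- image_volume(array(0, n), spacing = spacing)
  half <- spacing * (n - 1) / 2
  jit <- c(1, 1, 1)
  if (!is.null(cfg$jitter_seed)) {
    set.seed(cfg$jitter_seed)
    jit <- stats::runif(3, 0.97, 1.03)
  }
  # normalized coordinates, -1..1 across the field of view
  x <- (seq_len(n[1]) - (n[1] + 1) / 2) * spacing[1] / half[1]
  y <- (seq_len(n[2]) - (n[2] + 1) / 2) * spacing[2] / half[2]
  z <- (seq_len(n[3]) - (n[3] + 1) / 2) * spacing[3] / half[3]
  X <- array(rep(x, times = n[2] * n[3]), n)
  Y <- array(rep(rep(y, each = n[1]), times = n[3]), n)
  Z <- array(rep(z, each = n[1] * n[2]), n)

  inside_ellipsoid <- function(cx, cy, cz, a, b, c)
    ((X - cx) / a)^2 + ((Y - cy) / b)^2 + ((Z - cz) / c)^2 <= 1

  brain <- inside_ellipsoid(0, 0, 0, 0.73 * jit[1], 0.89 * jit[2],
                            0.68 * jit[3])
  # lobed WM: radial threshold modulated by angle for a non-convex boundary
  a_wm <- 0.54 * jit[1]; b_wm <- 0.69 * jit[2]; c_wm <- 0.50 * jit[3]
  ux <- X / a_wm; uy <- Y / b_wm; uz <- Z / c_wm
  r <- sqrt(ux^2 + uy^2 + uz^2)
  theta <- atan2(uy, ux)
  phi <- asin(pmin(1, pmax(-1, uz / pmax(r, 1e-9))))
  # azimuthal and polar lobes: WM must be structurally complex in all three
  # directions or tilts are only weakly constrained (pivot error)
  lobes <- 1 + 0.12 * sin(3 * theta) * cos(2 * phi) + 0.08 * cos(5 * theta) +
    0.10 * sin(2 * phi) * cos(2 * theta + 1) + 0.07 * sin(3 * phi + 2 * theta)
  wm <- r <= lobes & brain
  vent <- inside_ellipsoid(-0.125, 0.05, 0.02, 0.083, 0.23, 0.104) |
          inside_ellipsoid( 0.125, 0.05, 0.02, 0.083, 0.23, 0.104)
  vent <- vent & brain
  wm <- wm & !vent
  gm <- brain & !wm & !vent

  seg <- array(0L, n)
  seg[gm] <- PHANTOM_LABELS[["gm"]]
  seg[wm & X < 0] <- PHANTOM_LABELS[["wm_left"]]
  seg[wm & X >= 0] <- PHANTOM_LABELS[["wm_right"]]
  seg[vent] <- PHANTOM_LABELS[["ventricle"]]
  patches <- list(precuneus = c(0, -0.68, 0.36),
                  anterior_cingulate = c(0, 0.57, 0.26),
                  posterior_cingulate = c(0, -0.62, 0.05),
                  medial_orbitofrontal = c(0, 0.62, -0.26))
  for (nm in names(patches)) {
    p <- patches[[nm]]
    sph <- inside_ellipsoid(p[1], p[2], p[3], 0.16, 0.16, 0.16)
    seg[gm & sph] <- PHANTOM_LABELS[[nm]]
  }

  u <- cfg$pet_uptake
  pet_arr <- array(u[["background"]], n)
  pet_arr[gm] <- u[["gm"]]
  pet_arr[wm] <- u[["wm"]]
  pet_arr[vent] <- u[["ventricle"]]
  pet_arr <- gaussian_smooth3(pet_arr, cfg$pet_fwhm_mm, spacing)
  i <- cfg$mr_intensity
  mr_arr <- array(i[["background"]], n)
  mr_arr[gm] <- i[["gm"]]
  mr_arr[wm] <- i[["wm"]]
  mr_arr[vent] <- i[["ventricle"]]
  if (cfg$mr_noise_sd > 0) {
    set.seed(if (is.null(cfg$jitter_seed)) 715L else cfg$jitter_seed + 1L)
    mr_arr[brain] <- pmax(0, mr_arr[brain] +
                            stats::rnorm(sum(brain), 0, cfg$mr_noise_sd))
  }

  list(pet = image_volume(pet_arr, spacing = spacing, affine = tmpl$affine),
       mr = image_volume(mr_arr, spacing = spacing, affine = tmpl$affine),
       seg = image_volume(array(as.double(seg), n), spacing = spacing,
                          affine = tmpl$affine))
}

#' Sinogram stack constructor (internal representation)
#'
#' Per-slice 2-D projection data, `n_angles x n_detector_bins x n_slices`,
#' with the source-grid geometry retained so reconstruction can return a
#' matching volume. `count_scale` records the factor applied by
#' [scale_counts()] so reconstructions can be mapped back to activity units.
#' @keywords internal
sinogram_stack <- function(data, angles, src_dim, spacing, affine,
                           count_scale = 1) {
  structure(list(data = data, angles = angles, src_dim = src_dim,
                 spacing = spacing, affine = affine,
                 count_scale = count_scale, total = sum(data)),
            class = "sinogram_stack")
}

#' @export
print.sinogram_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sinogram_stack> %d angles x %d bins x %d slices, total %.6g\n",
              d[1], d[2], d[3], x$total))
  invisible(x)
}

#' Forward-project a volume to slice-wise sinograms
#'
#' Discrete Radon transform of each axial slice: line integrals (unit pixel
#' step, bilinear sampling) at each projection angle, detector bins spanning
#' the slice diagonal.
#'
#' @param vol non-negative [image_volume].
#' @param angles projection angles in degrees (default 180 angles uniform
#'   over \[0, 180)).
#' @return a `sinogram_stack`.
#' @export
project_to_sinograms <- function(vol, angles = seq(0, 179, length.out = 180)) {
  stopifnot(is_image_volume(vol))
  if (length(angles) == 0L) stop("empty angle list", call. = FALSE)
  if (min(vol$data) < 0)
    stop("volume must be non-negative", call. = FALSE)
  d <- dim(vol$data)
  nbins <- 2L * ceiling(sqrt(d[1]^2 + d[2]^2) / 2) + 3L  # odd, > diagonal
  out <- .radon_cpp(as.double(vol$data), d, angles * pi / 180, nbins)
  sinogram_stack(array(out, c(length(angles), nbins, d[3])),
                 angles = as.numeric(angles), src_dim = d,
                 spacing = vol$spacing, affine = vol$affine)
}

#' Count model for sinogram scaling
#'
#' Expected total prompt counts of a scan: injected dose x brain uptake
#' fraction x system sensitivity x acquisition duration.
#'
#' @param dose_mbq injected dose, MBq (default 370).
#' @param uptake_fraction brain uptake as a fraction of injected dose
#'   (default 0.05).
#' @param sensitivity_kcps_per_mbq system counting sensitivity, kcps/MBq
#'   (default 15).
#' @param duration_s acquisition duration, seconds.
#' @return an object of class `count_model`.
#' @export
count_model <- function(dose_mbq = 370, uptake_fraction = 0.05,
                        sensitivity_kcps_per_mbq = 15, duration_s = 1200) {
  stopifnot(dose_mbq > 0, uptake_fraction > 0,
            sensitivity_kcps_per_mbq > 0, duration_s > 0)
  structure(list(dose_mbq = dose_mbq, uptake_fraction = uptake_fraction,
                 sensitivity_kcps_per_mbq = sensitivity_kcps_per_mbq,
                 duration_s = duration_s),
            class = "count_model")
}

expected_total_counts <- function(cm) {
  cm$dose_mbq * cm$uptake_fraction * cm$sensitivity_kcps_per_mbq * 1000 *
    cm$duration_s
}

#' Scale a sinogram stack to expected scan counts
#'
#' Multiplies all bins by one global factor so the stack total equals the
#' count model's expected total (dose x uptake fraction x sensitivity x
#' duration).
#'
#' @param s a `sinogram_stack` with positive total.
#' @param cm a [count_model].
#' @return the scaled `sinogram_stack` (with `count_scale` recorded).
#' @export
scale_counts <- function(s, cm) {
  stopifnot(inherits(s, "sinogram_stack"), inherits(cm, "count_model"))
  if (s$total <= 0) stop("zero-total sinogram cannot be scaled", call. = FALSE)
  f <- expected_total_counts(cm) / s$total
  sinogram_stack(s$data * f, s$angles, s$src_dim, s$spacing, s$affine,
                 count_scale = s$count_scale * f)
}

#' Add Poisson noise to a sinogram stack
#'
#' Each bin is independently replaced by a Poisson draw with that bin's mean.
#'
#' @param s a `sinogram_stack` (all bins >= 0, in counts).
#' @param seed integer seed for reproducibility.
#' @return a noisy `sinogram_stack`.
#' @export
add_poisson_noise <- function(s, seed = 1L) {
  stopifnot(inherits(s, "sinogram_stack"))
  if (min(s$data) < 0) stop("negative sinogram bin", call. = FALSE)
  set.seed(seed)
  noisy <- stats::rpois(length(s$data), as.double(s$data))
  sinogram_stack(array(as.double(noisy), dim(s$data)), s$angles, s$src_dim,
                 s$spacing, s$affine, count_scale = s$count_scale)
}

# ramp / Hamming-windowed ramp frequency filter (cycles per sample)
fbp_filter <- function(pad, filter) {
  f <- c(seq(0, pad / 2), seq(-pad / 2 + 1, -1)) / pad
  ramp <- 2 * abs(f)
  if (filter == "hamming")
    ramp <- ramp * (0.54 + 0.46 * cos(pi * f / 0.5))
  ramp
}

#' Filtered back-projection reconstruction
#'
#' Per-slice FBP: each angle's projection is frequency-filtered (ramp or
#' Hamming-windowed ramp) and back-projected. Requires the stack's angles to
#' be uniform over \[0, 180). Negative reconstructed values are clipped to 0,
#' and when the stack was count-scaled the image is returned in the original
#' activity units (divided by `count_scale`).
#'
#' @param s a `sinogram_stack`.
#' @param filter `"hamming"` or `"ramp"`.
#' @return an [image_volume] on the source grid.
#' @export
fbp_reconstruct <- function(s, filter = c("hamming", "ramp")) {
  stopifnot(inherits(s, "sinogram_stack"))
  filter <- match.arg(filter)
  na <- dim(s$data)[1]; nb <- dim(s$data)[2]; nz <- dim(s$data)[3]
  expect <- seq(0, 180, length.out = na + 1)[seq_len(na)]
  if (max(abs(s$angles - expect)) > 1e-6 || (max(s$angles) - min(s$angles)) <
      180 * (1 - 1 / na) - 1e-6)
    stop("FBP requires angles uniform over [0, 180) with >= 180 degree span",
         call. = FALSE)
  pad <- 2^ceiling(log2(2 * nb))
  filt <- fbp_filter(pad, filter)
  # filter along the detector-bin axis: reshape to bins x (angles*slices)
  m <- matrix(aperm(s$data, c(2, 1, 3)), nrow = nb)
  mp <- rbind(m, matrix(0, pad - nb, ncol(m)))
  mf <- Re(stats::mvfft(stats::mvfft(mp) * filt, inverse = TRUE)) / pad
  filtered <- aperm(array(mf[seq_len(nb), ], c(nb, na, nz)), c(2, 1, 3))
  rec <- .backproject_cpp(as.double(filtered), dim(filtered),
                          s$src_dim[1], s$src_dim[2])
  rec <- rec / 2  # ramp defined as 2|f| with pi/na backprojection weight
  rec[rec < 0] <- 0
  image_volume(array(rec / s$count_scale, s$src_dim), spacing = s$spacing,
               affine = s$affine)
}

#' Draw random rigid motions
#'
#' Independent uniform draws of each parameter within the given ranges.
#'
#' @param n number of motions (>= 1).
#' @param t_range translation range, mm (default c(-10, 10)).
#' @param r_range rotation range, degrees (default c(-10, 10)).
#' @param seed integer seed.
#' @return list of [rigid_params].
#' @export
random_motion <- function(n, t_range = c(-10, 10), r_range = c(-10, 10),
                          seed = 1L) {
  stopifnot(n >= 1, t_range[1] < t_range[2], r_range[1] < r_range[2])
  set.seed(seed)
  lapply(seq_len(n), function(i)
    as_rigid_params(c(stats::runif(3, t_range[1], t_range[2]),
                      stats::runif(3, r_range[1], r_range[2]))))
}

#' Simulate a noisy PET volume
#'
#' Project -> scale to expected counts -> Poisson noise -> Hamming-filtered
#' FBP, returning the reconstruction in the source activity units.
#'
#' @param pet noise-free PET [image_volume].
#' @param cm a [count_model] (its duration sets the noise level).
#' @param seed noise seed.
#' @param filter FBP filter.
#' @param angles projection angles, degrees.
#' @return an [image_volume].
#' @export
simulate_noisy_pet <- function(pet, cm = count_model(), seed = 1L,
                               filter = "hamming",
                               angles = seq(0, 179, length.out = 180)) {
  s <- scale_counts(project_to_sinograms(pet, angles), cm)
  fbp_reconstruct(add_poisson_noise(s, seed), filter)
}

#' Run the motion-correction simulation benchmark
#'
#' For each trial a random rigid motion is applied (pull-back resampling) to
#' the phantom MR and segmentation; for each noise level one noisy PET is
#' reconstructed (shared by all methods); each registration method then
#' estimates the correcting transform. Ground truth is the decomposition of
#' the *inverse* applied matrix, since registration recovers the mask-to-PET
#' alignment.
#'
#' @param trials number of motion trials.
#' @param noise_durations acquisition durations in seconds defining the
#'   noise levels; `0` means noise-free (the phantom PET itself). Default
#'   `c(1200, 300)` (20-min and 5-min scans).
#' @param methods subset of `c("tcbc", "nmi")`.
#' @param phantom a [phantom_config].
#' @param config a [tcbc_config] shared by both methods (its seed is
#'   re-derived per trial so that both methods see identical starts).
#' @param hist a [histogram_config] for the NMI baseline.
#' @param wm_labels label IDs forming the TCBC target ROI (default c(2, 41)).
#' @param seed master seed for motions, noise, and per-trial start seeds.
#' @param verbose print per-trial progress.
#' @return a `data.frame`, one row per trial x method x duration, with true,
#'   estimated and error (estimated - true) parameters, the objective, and
#'   diagnostics.
#' @export
run_benchmark <- function(trials = 10L, noise_durations = c(1200, 300),
                          methods = c("tcbc", "nmi"),
                          phantom = phantom_config(),
                          config = tcbc_config(n_starts = 10L,
                                               max_roi_voxels = 20000),
                          hist = histogram_config(sample_stride = 4L),
                          wm_labels = c(2, 41), seed = 1L, verbose = FALSE) {
  methods <- match.arg(methods, c("tcbc", "nmi"), several.ok = TRUE)
  ph <- make_phantom(phantom)
  center <- volume_center(ph$pet)
  nd <- length(noise_durations)
  motions <- random_motion(trials, seed = seed)
  set.seed(seed + 1L)
  noise_seeds <- matrix(sample.int(.Machine$integer.max - 1L, trials * nd),
                        trials, nd)
  start_seeds <- matrix(sample.int(.Machine$integer.max - 1L, trials * nd),
                        trials, nd)
  scaled <- lapply(noise_durations, function(d) {
    if (d <= 0) return(NULL)
    scale_counts(project_to_sinograms(ph$pet),
                 count_model(duration_s = d))
  })
  pnames <- c("tx", "ty", "tz", "rx", "ry", "rz")
  rows <- list()
  for (t in seq_len(trials)) {
    M <- build_transform(motions[[t]], center)
    truth <- decompose_transform(solve(M), center)
    moved_mr <- resample_volume(ph$mr, M, "trilinear")
    moved_seg <- resample_volume(ph$seg, M, "nearest")
    roi <- tryCatch(select_target_roi(moved_seg, wm_labels),
                    error = function(e) NULL)
    for (d in seq_len(nd)) {
      pet_d <- if (noise_durations[d] <= 0) ph$pet else
        fbp_reconstruct(add_poisson_noise(scaled[[d]], noise_seeds[t, d]))
      for (method in methods) {
        cfg <- config
        cfg$seed <- start_seeds[t, d]
        t0 <- proc.time()[["elapsed"]]
        fit <- tryCatch({
          if (method == "tcbc") {
            if (is.null(roi)) stop("target ROI empty after motion")
            tcbc_register(pet_d, roi, cfg, center = center)
          } else {
            mi_register(pet_d, moved_mr, cfg, hist, center = center)
          }
        }, error = function(e) e)
        secs <- proc.time()[["elapsed"]] - t0
        row <- data.frame(trial = t, method = method,
                          duration_s = noise_durations[d],
                          stringsAsFactors = FALSE)
        for (i in seq_along(pnames))
          row[[paste0("true_", pnames[i])]] <- unclass(truth)[i]
        if (inherits(fit, "error")) {
          for (i in seq_along(pnames)) {
            row[[paste0("est_", pnames[i])]] <- NA_real_
            row[[paste0("err_", pnames[i])]] <- NA_real_
          }
          row$objective <- NA_real_
          row$converged <- FALSE
          row$error <- conditionMessage(fit)
        } else {
          est <- unclass(fit$params)
          for (i in seq_along(pnames)) {
            row[[paste0("est_", pnames[i])]] <- est[i]
            row[[paste0("err_", pnames[i])]] <- est[i] - unclass(truth)[i]
          }
          row$objective <- fit$objective
          row$converged <- fit$converged[fit$best_start]
          row$error <- NA_character_
        }
        row$seconds <- secs
        rows[[length(rows) + 1L]] <- row
        if (verbose)
          message(sprintf("trial %d/%d %s %ss: %.1fs", t, trials, method,
                          noise_durations[d], secs))
      }
    }
  }
  do.call(rbind, rows)
}
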