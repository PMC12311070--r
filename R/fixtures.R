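#' Fixture scenario specification
#'
#' Named, seeded scenarios tying the phantom, motion, and noise pieces into
#' small reproducible test assets. Identical specs produce byte-identical
#' volumes.
#'
#' @param scenario one of `"noise-free-aligned"`, `"noise-free-moved"`,
#'   `"20min-moved"`, `"5min-moved"`, `"suvr-phantom"`.
#' @param seed integer seed driving the motion draw and Poisson noise.
#' @param n grid size per axis (default 64).
#' @param motion a [rigid_params], or `"random"` to draw one from
#'   +/-10 mm / +/-10 deg with the spec seed (ignored by the aligned and
#'   SUVR scenarios).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(scenario = c("noise-free-aligned",
                                      "noise-free-moved", "20min-moved",
                                      "5min-moved", "suvr-phantom"),
                         seed = 1L, n = 64L, motion = "random") {
  scenario <- match.arg(scenario)
  structure(list(scenario = scenario, seed = as.integer(seed),
                 n = as.integer(n), motion = motion),
            class = "fixture_spec")
}

#' Build a fixture file set
#'
#' Writes PET, MR and segmentation NIfTI volumes plus a `truth.json` record
#' (applied matrix, ground-truth parameters of its inverse, count model and
#' phantom configuration) into `dir`.
#'
#' @param spec a [fixture_spec].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory volumes, the truth record,
#'   and the written paths.
#' @export
build_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- phantom_config(n = spec$n)
  ph <- make_phantom(cfg)
  center <- volume_center(ph$pet)
  moved <- !(spec$scenario %in% c("noise-free-aligned", "suvr-phantom"))
  motion <- rigid_params()
  if (moved) {
    motion <- if (identical(spec$motion, "random"))
      random_motion(1, seed = spec$seed)[[1]] else as_rigid_params(spec$motion)
  }
  M <- build_transform(motion, center)
  truth_params <- decompose_transform(solve(M), center)
  mr <- if (moved) resample_volume(ph$mr, M, "trilinear") else ph$mr
  seg <- if (moved) resample_volume(ph$seg, M, "nearest") else ph$seg
  duration <- switch(spec$scenario, `20min-moved` = 1200,
                     `5min-moved` = 300, 0)
  cm <- NULL
  pet <- ph$pet
  noisy_total <- NULL
  if (duration > 0) {
    cm <- count_model(duration_s = duration)
    s <- scale_counts(project_to_sinograms(ph$pet), cm)
    ns <- add_poisson_noise(s, seed = spec$seed + 1L)
    noisy_total <- ns$total
    pet <- fbp_reconstruct(ns, "hamming")
  }
  paths <- c(pet = file.path(dir, "pet.nii.gz"),
             mr = file.path(dir, "mr.nii.gz"),
             seg = file.path(dir, "seg.nii.gz"),
             truth = file.path(dir, "truth.json"))
  write_nifti(pet, paths[["pet"]])
  write_nifti(mr, paths[["mr"]])
  write_nifti(seg, paths[["seg"]])
  truth <- list(scenario = spec$scenario, seed = spec$seed,
                applied_matrix = M,
                applied_params = as.list(unclass(motion)),
                truth_params = as.list(unclass(truth_params)),
                rotation_center = center,
                count_model = if (is.null(cm)) NULL else unclass(cm),
                noisy_total_counts = noisy_total,
                phantom = list(n = cfg$n, spacing = cfg$spacing,
                               pet_uptake = as.list(cfg$pet_uptake),
                               mr_intensity = as.list(cfg$mr_intensity),
                               pet_fwhm_mm = cfg$pet_fwhm_mm))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(list(pet = pet, mr = mr, seg = seg, truth = truth,
                 paths = paths))
}
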