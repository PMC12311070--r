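#' Configuration for multi-start registration
#'
#' Shared search settings for [tcbc_register()] and [mi_register()]: the
#' number of random initial guesses, the ranges they are drawn from, the
#' optimization sense for the tracer-characteristic objective, simplex
#' termination tolerances, and the random seed.
#'
#' Registration is unconstrained; only the *initial guesses* are bounded by
#' the stated ranges.
#'
#' @param n_starts number of random initial guesses (default 100).
#' @param init_translation_range length-2, mm (default c(-10, 10)).
#' @param init_rotation_range length-2, degrees (default c(-10, 10)).
#' @param sense `"maximize"` (high-uptake target ROI, e.g. amyloid WM) or
#'   `"minimize"` (low-uptake target ROI, e.g. FDG WM).
#' @param tol_x,tol_f absolute simplex termination tolerances on parameters
#'   and objective (defaults 1e-4).
#' @param max_eval maximum objective evaluations per start (default 200 x 6).
#' @param max_roi_voxels cap on ROI voxels entering the objective; when the
#'   ROI is larger, a deterministic random subset of voxel centres is used
#'   (speed knob for benchmarks; default `Inf` = all voxels).
#' @param seed integer seed for the initial guesses (and ROI subset).
#' @return an object of class `tcbc_config`.
#' @export
tcbc_config <- function(n_starts = 100L,
                        init_translation_range = c(-10, 10),
                        init_rotation_range = c(-10, 10),
                        sense = c("maximize", "minimize"),
                        tol_x = 1e-4, tol_f = 1e-4,
                        max_eval = 1200L,
                        max_roi_voxels = Inf,
                        seed = 1L) {
  sense <- match.arg(sense)
  stopifnot(n_starts >= 1L,
            length(init_translation_range) == 2L,
            init_translation_range[1] < init_translation_range[2],
            length(init_rotation_range) == 2L,
            init_rotation_range[1] < init_rotation_range[2],
            tol_x > 0, tol_f > 0, max_eval >= 1, max_roi_voxels >= 1)
  structure(list(n_starts = as.integer(n_starts),
                 init_translation_range = as.numeric(init_translation_range),
                 init_rotation_range = as.numeric(init_rotation_range),
                 sense = sense, tol_x = tol_x, tol_f = tol_f,
                 max_eval = as.integer(max_eval),
                 max_roi_voxels = max_roi_voxels,
                 seed = as.integer(seed)),
            class = "tcbc_config")
}

# 0-based voxel indices (N x 3) of the nonzero voxels of a mask volume
mask_voxel_indices <- function(roi) {
  idx <- which(roi$data != 0)
  if (length(idx) == 0L) stop("empty ROI", call. = FALSE)
  d <- dim(roi$data)
  idx0 <- idx - 1L
  cbind(idx0 %% d[1],
        (idx0 %/% d[1]) %% d[2],
        idx0 %/% (d[1] * d[2]))
}

# ROI-voxel -> PET-voxel 3x4 matrix for given world transform m
roi_to_pet_matrix <- function(pet, roi, m) {
  A <- solve(pet$affine) %*% m %*% roi$affine
  A[1:3, , drop = FALSE]
}

#' Mean PET intensity inside a transformed target ROI
#'
#' The tracer-characteristic objective: PET is sampled trilinearly at the
#' world positions of the ROI voxel centres after applying the rigid
#' transform, and averaged. Samples falling outside the PET field contribute
#' 0 but still count in the denominator (the fixed ROI voxel count), so
#' transforms that push the ROI out of the field are penalized.
#'
#' @param pet PET [image_volume].
#' @param roi binary ROI mask, an [image_volume] on its own grid (nonzero =
#'   in ROI); typically from [select_target_roi()].
#' @param params a [rigid_params] applied to the ROI (world space).
#' @param center rotation centre, world mm; defaults to the PET volume
#'   centre.
#' @return scalar mean intensity.
#' @export
masked_mean_intensity <- function(pet, roi, params = rigid_params(),
                                  center = volume_center(pet)) {
  stopifnot(is_image_volume(pet), is_image_volume(roi))
  idx <- mask_voxel_indices(roi)
  m <- build_transform(params, center)
  .masked_mean_cpp(as.double(pet$data), dim(pet$data), idx,
                   roi_to_pet_matrix(pet, roi, m))
}

#' Extract a target ROI from a label segmentation
#'
#' Binary union of the requested integer label IDs (e.g. FreeSurfer cerebral
#' white matter = labels 2 and 41).
#'
#' @param segmentation label [image_volume] (integer anatomical labels).
#' @param label_ids integer vector of label IDs to include.
#' @return a binary [image_volume] with attribute `n_voxels`.
#' @export
select_target_roi <- function(segmentation, label_ids) {
  stopifnot(is_image_volume(segmentation))
  if (length(label_ids) == 0L)
    stop("`label_ids` must name at least one label", call. = FALSE)
  mask <- array(as.double(segmentation$data %in% label_ids),
                dim(segmentation$data))
  n <- sum(mask)
  if (n == 0L)
    stop("no voxels carry the requested labels: ",
         paste(label_ids, collapse = ", "), call. = FALSE)
  out <- image_volume(mask, spacing = segmentation$spacing,
                      affine = segmentation$affine)
  attr(out, "n_voxels") <- as.integer(n)
  out
}

# Draw n_starts parameter vectors uniformly from the configured ranges.
draw_starts <- function(config) {
  tr <- config$init_translation_range
  rr <- config$init_rotation_range
  t(vapply(seq_len(config$n_starts), function(i)
    c(stats::runif(3, tr[1], tr[2]), stats::runif(3, rr[1], rr[2])),
    numeric(6)))
}

# Shared multi-start Nelder-Mead harness. `objective(p)` is minimized.
multistart_optimize <- function(objective, config, center) {
  starts <- draw_starts(config)
  per_start <- vector("list", config$n_starts)
  for (s in seq_len(config$n_starts)) {
    fit <- nelder_mead(objective, starts[s, ],
                       tol_x = config$tol_x, tol_f = config$tol_f,
                       max_eval = config$max_eval)
    per_start[[s]] <- fit
  }
  values <- vapply(per_start, `[[`, numeric(1), "value")
  ok <- is.finite(values)
  if (!any(ok))
    stop("registration failure: no start produced a finite objective",
         call. = FALSE)
  best <- which(ok)[which.min(values[ok])]  # ties -> lowest start index
  p <- as_rigid_params(per_start[[best]]$par)
  structure(list(
    params = p,
    matrix = build_transform(p, center),
    objective = values[best],
    start_objectives = values,
    converged = vapply(per_start, `[[`, logical(1), "converged"),
    evaluations = vapply(per_start, `[[`, integer(1), "evaluations"),
    best_start = best,
    center = center),
    class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n  ")
  print(x$params)
  cat(sprintf("  objective %.6g (start %d of %d, %d converged)\n",
              x$objective, x$best_start, length(x$start_objectives),
              sum(x$converged)))
  invisible(x)
}

#' Tracer characteristic-based co-registration
#'
#' Finds the rigid transform aligning an MR-derived target ROI with a PET
#' volume by optimizing the mean PET intensity within the transformed ROI
#' ([masked_mean_intensity()]). `n_starts` independent unconstrained
#' Nelder-Mead searches are run from random initial guesses; the start with
#' the lowest objective (`-I_mean` when `sense = "maximize"`) wins. The
#' returned matrix is the one to apply to the MR image and all MR-derived
#' masks to align them with PET.
#'
#' @param pet PET [image_volume] (the fixed image).
#' @param roi binary target ROI mask in MR space (e.g. cerebral WM for
#'   amyloid tracers), from [select_target_roi()].
#' @param config a [tcbc_config].
#' @param center rotation centre, world mm; defaults to the PET volume
#'   centre.
#' @return a `registration_result`: best [rigid_params], 4x4 matrix,
#'   objective value, per-start objectives, convergence flags, centre.
#' @export
tcbc_register <- function(pet, roi, config = tcbc_config(),
                          center = volume_center(pet)) {
  stopifnot(is_image_volume(pet), is_image_volume(roi),
            inherits(config, "tcbc_config"))
  set.seed(config$seed)
  idx <- mask_voxel_indices(roi)
  if (nrow(idx) > config$max_roi_voxels) {
    keep <- sort(sample.int(nrow(idx), config$max_roi_voxels))
    idx <- idx[keep, , drop = FALSE]
  }
  sgn <- if (config$sense == "maximize") -1 else 1
  # single-precision evaluator: volume copy + transform algebra live in C++
  ptr <- .tcbc_obj_new(as.double(pet$data), dim(pet$data), idx,
                       solve(pet$affine), roi$affine, center, sgn)
  objective <- function(p) .tcbc_obj_eval(ptr, p)
  multistart_optimize(objective, config, center)
}
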