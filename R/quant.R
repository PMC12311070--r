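#' SUVR configuration
#'
#' Named target ROI label sets, the reference (cerebral WM) label set, and
#' the erosion applied to the reference before computing the ratio. With the
#' phantom's stand-in IDs the defaults give the four cortical targets plus
#' the early amyloid composite (union of the four).
#'
#' @param targets named list of integer label vectors, one per target ROI.
#' @param reference integer labels of the reference region (default
#'   cerebral WM, c(2, 41)).
#' @param erode_iterations erosion passes applied to the reference
#'   (default 1).
#' @param connectivity structuring-element connectivity, 6 (faces) or 26
#'   (default 6).
#' @param composite name of the composite ROI formed from the union of all
#'   targets (`NULL` to disable; default `"early_composite"`).
#' @return an object of class `suvr_config`.
#' @export
suvr_config <- function(targets = list(precuneus = 1001L,
                                       anterior_cingulate = 1002L,
                                       posterior_cingulate = 1003L,
                                       medial_orbitofrontal = 1004L),
                        reference = c(2L, 41L),
                        erode_iterations = 1L,
                        connectivity = 6L,
                        composite = "early_composite") {
  stopifnot(is.list(targets), length(targets) >= 1L,
            !is.null(names(targets)), erode_iterations >= 0L,
            connectivity %in% c(6L, 26L))
  if (length(intersect(unlist(targets), reference)) > 0L)
    stop("target and reference label sets must be disjoint", call. = FALSE)
  structure(list(targets = targets, reference = as.integer(reference),
                 erode_iterations = as.integer(erode_iterations),
                 connectivity = as.integer(connectivity),
                 composite = composite),
            class = "suvr_config")
}

shift_mask <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
  out
}

#' Morphologically erode a binary mask
#'
#' A voxel survives an iteration iff all of its structuring-element
#' neighbours (6 face neighbours, or 26 for full connectivity) are inside the
#' mask; voxels on the array border are treated as having outside neighbours.
#'
#' @param mask binary [image_volume] (nonzero = inside).
#' @param iterations number of erosion passes (0 returns the mask unchanged).
#' @param connectivity 6 or 26.
#' @return eroded binary [image_volume].
#' @export
erode_mask <- function(mask, iterations = 1L, connectivity = 6L) {
  stopifnot(is_image_volume(mask), iterations >= 0L,
            connectivity %in% c(6L, 26L))
  m <- mask$data != 0
  if (!any(m)) stop("empty mask", call. = FALSE)
  offsets <- if (connectivity == 6L) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
         c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  }
  for (it in seq_len(iterations)) {
    keep <- m
    for (o in offsets) keep <- keep & shift_mask(m, o[1], o[2], o[3])
    m <- keep
    if (!any(m))
      stop("erosion emptied the reference mask", call. = FALSE)
  }
  image_volume(array(as.double(m), dim(m)), spacing = mask$spacing,
               affine = mask$affine)
}

#' Sum dynamic PET frames within a time window
#'
#' Voxelwise sum of the frames whose `[frame_start, frame_end)` interval lies
#' strictly within the window (partially overlapping frames are excluded).
#'
#' @param frames list of [image_volume]s with frame timing metadata, on a
#'   common grid.
#' @param window length-2 window in seconds (e.g. `c(3000, 4200)` for the
#'   50-70 min post-injection window).
#' @return an [image_volume] carrying the combined frame window.
#' @export
sum_frames <- function(frames, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  keep <- vapply(frames, function(f) {
    if (is.null(f$frame_start) || is.null(f$frame_end))
      stop("frame timing metadata missing", call. = FALSE)
    f$frame_start >= window[1] && f$frame_end <= window[2]
  }, logical(1))
  if (!any(keep))
    stop("no frame lies within the requested window", call. = FALSE)
  sel <- frames[keep]
  d <- dim(sel[[1]]$data)
  acc <- array(0, d)
  for (f in sel) {
    if (!all(dim(f$data) == d)) stop("frames must share a grid", call. = FALSE)
    acc <- acc + f$data
  }
  image_volume(acc, spacing = sel[[1]]$spacing, affine = sel[[1]]$affine,
               frame_start = min(vapply(sel, `[[`, numeric(1), "frame_start")),
               frame_end = max(vapply(sel, `[[`, numeric(1), "frame_end")))
}

#' Compute SUVR over target ROIs with an eroded-WM reference
#'
#' Applies the registration transform to the segmentation (nearest-neighbour
#' resampling), erodes the reference region, and returns the mean PET uptake
#' in each target ROI divided by the mean uptake in the eroded reference,
#' plus the composite (computed over the union's voxels).
#'
#' @param pet PET [image_volume] (e.g. a 50-70 min frame sum).
#' @param seg label [image_volume] in MR space.
#' @param transform 4x4 rigid matrix mapping the segmentation onto the PET
#'   (identity by default).
#' @param cfg a [suvr_config].
#' @return named list: per-ROI SUVR values plus attributes-like fields
#'   `reference_mean` and `voxels` (per-ROI voxel counts after transform).
#' @export
compute_suvr <- function(pet, seg, transform = diag(4), cfg = suvr_config()) {
  stopifnot(is_image_volume(pet), is_image_volume(seg),
            inherits(cfg, "suvr_config"))
  seg_t <- if (all(transform == diag(4))) seg else
    resample_volume(seg, transform, "nearest")
  if (!all(dim(seg_t$data) == dim(pet$data)))
    stop("segmentation and PET must share a grid after transformation",
         call. = FALSE)
  ref_mask <- seg_t$data %in% cfg$reference
  if (!any(ref_mask))
    stop("quantification error: empty reference region after transform",
         call. = FALSE)
  ref_vol <- image_volume(array(as.double(ref_mask), dim(seg_t$data)),
                          spacing = seg_t$spacing, affine = seg_t$affine)
  ref_er <- erode_mask(ref_vol, cfg$erode_iterations, cfg$connectivity)
  ref_mean <- mean(pet$data[ref_er$data != 0])
  if (!is.finite(ref_mean) || ref_mean == 0)
    stop("quantification error: degenerate reference mean", call. = FALSE)
  rois <- cfg$targets
  if (!is.null(cfg$composite))
    rois[[cfg$composite]] <- unique(unlist(cfg$targets))
  suvr <- list(); voxels <- list()
  for (nm in names(rois)) {
    tmask <- seg_t$data %in% rois[[nm]]
    if (!any(tmask))
      stop("quantification error: empty target ROI '", nm,
           "' after transform", call. = FALSE)
    suvr[[nm]] <- mean(pet$data[tmask]) / ref_mean
    voxels[[nm]] <- sum(tmask)
  }
  list(suvr = unlist(suvr), reference_mean = ref_mean,
       reference_voxels = sum(ref_er$data != 0), voxels = unlist(voxels))
}
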