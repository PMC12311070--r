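#' Joint-histogram configuration for NMI
#'
#' @param bins histogram bins per modality (default 32).
#' @param clip intensity clipping percentiles, length 2 in (0, 100)
#'   (default c(0.5, 99.5)); intensities outside are clamped to the edge bin.
#' @param smooth logical; smooth the joint histogram with a 1-bin Gaussian
#'   before computing entropies (default FALSE).
#' @param sample_stride voxel stride of the sampling grid used inside
#'   [mi_register()] (default 1 = every voxel); a speed knob for benchmarks.
#' @return an object of class `histogram_config`.
#' @export
histogram_config <- function(bins = 32L, clip = c(0.5, 99.5),
                             smooth = FALSE, sample_stride = 1L) {
  stopifnot(bins >= 2L, length(clip) == 2L, clip[1] < clip[2],
            sample_stride >= 1L)
  structure(list(bins = as.integer(bins), clip = as.numeric(clip),
                 smooth = isTRUE(smooth),
                 sample_stride = as.integer(sample_stride)),
            class = "histogram_config")
}

clip_bounds <- function(x, clip) {
  q <- stats::quantile(x, clip / 100, names = FALSE, type = 7)
  if (q[2] <= q[1]) q <- range(x)
  q
}

bin_index <- function(x, lo, hi, bins) {
  if (hi <= lo) return(rep.int(1L, length(x)))
  b <- floor((x - lo) / (hi - lo) * bins) + 1L
  pmin.int(pmax.int(b, 1L), bins)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information of two volumes on a common grid
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` from the joint intensity histogram, with
#' percentile clipping; values range over (1, 2] with `NMI(A, A) = 2` for any
#' non-constant image.
#'
#' @param a,b [image_volume]s on the same grid (`b` typically already
#'   resampled under a candidate transform).
#' @param cfg a [histogram_config].
#' @return scalar NMI.
#' @export
normalized_mutual_information <- function(a, b, cfg = histogram_config()) {
  stopifnot(is_image_volume(a), is_image_volume(b),
            inherits(cfg, "histogram_config"))
  if (!all(dim(a$data) == dim(b$data)))
    stop("`a` and `b` must share a grid", call. = FALSE)
  av <- as.double(a$data); bv <- as.double(b$data)
  if (length(unique(av)) == 1L && length(unique(bv)) == 1L)
    stop("undefined entropy: both images are constant", call. = FALSE)
  qa <- clip_bounds(av, cfg$clip); qb <- clip_bounds(bv, cfg$clip)
  ia <- bin_index(av, qa[1], qa[2], cfg$bins)
  ib <- bin_index(bv, qb[1], qb[2], cfg$bins)
  joint <- matrix(tabulate(ia + (ib - 1L) * cfg$bins, cfg$bins^2),
                  cfg$bins, cfg$bins)
  if (cfg$smooth) joint <- smooth_hist_gauss(joint)
  joint <- joint / sum(joint)
  ha <- entropy_nats(rowSums(joint))
  hb <- entropy_nats(colSums(joint))
  hab <- entropy_nats(joint)
  if (hab <= 0)
    stop("undefined entropy: degenerate joint histogram", call. = FALSE)
  (ha + hb) / hab
}

# separable Gaussian smoothing of a 2-D histogram, sigma = 1 bin
smooth_hist_gauss <- function(h, sigma = 1) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m) {   # along rows, replicated edges
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      src <- pmin.int(pmax.int(seq_len(n) + o, 1L), n)
      out <- out + k[o + r + 1] * m[src, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(h))))
}

#' Rigid registration by normalized mutual information
#'
#' The in-package stand-in for MI-family co-registration tools (such as
#' FreeSurfer's `mri_coreg`): NMI between the fixed image and the moving
#' image under a candidate rigid transform is maximized with the same
#' multi-start Nelder-Mead harness as [tcbc_register()]. This reproduces the
#' comparator's algorithmic family, not any specific implementation.
#'
#' Sample points are the fixed-image voxels (optionally strided); at each
#' candidate transform the moving image is sampled trilinearly at the
#' transformed point positions and only in-field pairs enter the joint
#' histogram. Clip bounds are computed once per registration.
#'
#' @param fixed fixed [image_volume] (e.g. PET).
#' @param moving moving [image_volume] (e.g. the MR to be aligned); the
#'   returned matrix is the transform to apply to `moving` to align it with
#'   `fixed`.
#' @param config a [tcbc_config] (the `sense` field is ignored; NMI is
#'   always maximized).
#' @param hist a [histogram_config].
#' @param center rotation centre, world mm; defaults to the fixed volume
#'   centre.
#' @return a `registration_result` (see [tcbc_register()]).
#' @export
mi_register <- function(fixed, moving, config = tcbc_config(),
                        hist = histogram_config(),
                        center = volume_center(fixed)) {
  stopifnot(is_image_volume(fixed), is_image_volume(moving),
            inherits(config, "tcbc_config"),
            inherits(hist, "histogram_config"))
  set.seed(config$seed)
  d <- dim(fixed$data)
  st <- hist$sample_stride
  gi <- seq.int(0L, d[1] - 1L, by = st)
  gj <- seq.int(0L, d[2] - 1L, by = st)
  gk <- seq.int(0L, d[3] - 1L, by = st)
  pts <- as.matrix(expand.grid(i = gi, j = gj, k = gk))
  storage.mode(pts) <- "double"
  fvals <- as.double(fixed$data[cbind(pts[, 1] + 1, pts[, 2] + 1,
                                      pts[, 3] + 1)])
  qf <- clip_bounds(fvals, hist$clip)
  qm <- clip_bounds(as.double(moving$data), hist$clip)
  fixed_bin <- bin_index(fvals, qf[1], qf[2], hist$bins) - 1L
  # the candidate transform moves `moving`; sampling pulls back through its
  # inverse. Single-precision evaluator, constructed once per registration.
  ptr <- .nmi_obj_new(as.double(moving$data), dim(moving$data), pts,
                      fixed_bin, solve(moving$affine), fixed$affine,
                      center, qm[1], qm[2], hist$bins)
  objective <- function(p) {
    v <- .nmi_obj_eval(ptr, p)
    if (is.na(v)) Inf else -v
  }
  multistart_optimize(objective, config, center)
}
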