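#' 4D BOLD volume series
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param voxel_size voxel dimensions in mm (length 3).
#' @param mask logical 3D array matching the spatial shape of `data`.
#' @param tr repetition time in seconds.
#' @return a `volume_series` object.
#' @export
volume_series <- function(data, voxel_size = c(2, 2, 2), mask, tr = 2) {
  if (length(dim(data)) != 4) stop_arg("`data` must be a 4D array")
  if (!identical(dim(mask), dim(data)[1:3])) {
    stop_arg("mask shape must equal the spatial shape of `data`")
  }
  if (!any(mask)) stop_arg("mask must contain at least one voxel")
  if (tr <= 0) stop_arg("`tr` must be positive")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 mask = array(as.logical(mask), dim(mask)), tr = tr),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d grid, %d volumes, TR %g s, %d mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' Simulate event-related BOLD data with a planted pattern geometry
#'
#' In-ROI voxel time courses are the HRF-convolved event regressors of
#' each condition, scaled by that voxel's entry in the condition's
#' planted pattern, plus stationary AR(1) Gaussian noise; voxels inside
#' the mask but outside the ROI contain noise only; voxels outside the
#' mask are zero.  Conditions without a planted pattern (e.g.
#' pseudoword trials) contribute no signal.
#'
#' @param design an [event_design()].
#' @param patterns a `pattern_set` from [embed_geometry()], or `NULL`
#'   for pure noise.
#' @param shape 3D grid dimensions.
#' @param noise_sd marginal SD of the AR(1) noise (0 for noise-free).
#' @param ar1_phi lag-1 autocorrelation of the noise, in (-1, 1).
#' @param motion if `TRUE`, adds slow sinusoidal motion-like nuisance
#'   drifts with voxel-specific gains.
#' @param seed integer seed.
#' @param tr repetition time in seconds (default: the design's TR;
#'   2 s as in the study acquisition).
#' @param mask logical 3D array; defaults to [ellipsoid_mask()] of `shape`.
#' @param voxel_size voxel dimensions in mm.
#' @param oversample HRF convolution oversampling (bins per TR).
#' @return a [volume_series()].
#' @export
simulate_bold <- function(design, patterns = NULL, shape = c(20, 20, 20),
                          noise_sd = 1, ar1_phi = 0.3, motion = FALSE,
                          seed = 1, tr = NULL, mask = NULL,
                          voxel_size = c(2, 2, 2), oversample = 16) {
  tr <- tr %||% attr(design, "tr") %||% 2
  if (abs(ar1_phi) >= 1) stop_arg("`ar1_phi` must be in (-1, 1)")
  if (noise_sd < 0) stop_arg("`noise_sd` must be non-negative")
  if (is.null(mask)) mask <- ellipsoid_mask(shape)
  if (!identical(dim(mask), as.integer(shape)) && !identical(dim(mask), shape)) {
    stop_arg("mask dimensions must equal `shape`")
  }
  run_length <- attr(design, "run_length")
  n_vols <- as.integer(ceiling(run_length / tr))
  if (max(design$onset + design$duration) > n_vols * tr + 1e-9) {
    stop_arg("design does not fit within the series length")
  }
  nv <- prod(shape)
  mask_lin <- which(mask)
  n_mask <- length(mask_lin)

  arr <- array(0, dim = c(shape, n_vols))

  ## noise (and optional drifts) at mask voxels
  if (noise_sd > 0 || motion) {
    with_seed(seed, {
      block <- matrix(0, n_vols, n_mask)
      if (noise_sd > 0) {
        z <- matrix(stats::rnorm(n_vols * n_mask), n_vols, n_mask)
        if (ar1_phi != 0) {
          innov_sd <- noise_sd * sqrt(1 - ar1_phi^2)
          block <- apply_ar1(z * innov_sd, ar1_phi)
        } else {
          block <- z * noise_sd
        }
      }
      if (motion) {
        tt <- seq_len(n_vols) * tr
        d1 <- sin(2 * pi * tt / (n_vols * tr) * 1.5)
        d2 <- tt / (n_vols * tr) - 0.5
        g1 <- stats::rnorm(n_mask, sd = 0.5)
        g2 <- stats::rnorm(n_mask, sd = 0.5)
        block <- block + d1 %o% g1 + d2 %o% g2
      }
      idx <- rep(mask_lin, times = n_vols) +
        rep((seq_len(n_vols) - 1L) * nv, each = n_mask)
      arr[idx] <- as.vector(t(block))
    })
  }

  ## task signal at ROI voxels
  if (!is.null(patterns)) {
    roi <- patterns$roi_indices
    if (!all(mask[roi])) stop_arg("`roi_indices` must lie inside the mask")
    conds <- intersect(unique(design$condition), patterns$concepts)
    if (length(conds)) {
      X <- vapply(conds, function(cc) {
        ev <- design$condition == cc
        convolve_events(design$onset[ev], design$duration[ev], n_vols, tr,
                        oversample = oversample)
      }, numeric(n_vols))
      sig <- X %*% patterns$patterns[match(conds, patterns$concepts), , drop = FALSE]
      idx <- rep(roi, times = n_vols) +
        rep((seq_len(n_vols) - 1L) * nv, each = length(roi))
      arr[idx] <- arr[idx] + as.vector(t(sig))
    }
  }

  volume_series(arr, voxel_size, mask, tr)
}

## recursive AR(1) filter applied column-wise (stationary marginal
## variance assumed handled by the caller via the innovation SD)
apply_ar1 <- function(z, phi) {
  out <- stats::filter(z, filter = phi, method = "recursive")
  matrix(as.numeric(out), nrow(z), ncol(z))
}
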