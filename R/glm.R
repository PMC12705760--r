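#' Discrete-cosine high-pass drift basis
#'
#' The standard DCT drift set: `K = floor(2 * T / cutoff)` cosine
#' regressors covering all periods longer than the cutoff, where `T` is
#' the run duration in seconds.  Columns are mutually orthogonal.
#'
#' @param n_vols number of volumes.
#' @param tr repetition time in seconds.
#' @param cutoff_s high-pass cutoff in seconds (`Inf` disables drifts).
#' @return `n_vols x K` matrix (zero columns when `K = 0`).
#' @export
dct_drift_basis <- function(n_vols, tr, cutoff_s = 128) {
  if (!is.finite(cutoff_s)) {
    return(matrix(numeric(0), n_vols, 0))
  }
  K <- floor(2 * n_vols * tr / cutoff_s)
  K <- min(K, n_vols - 1)
  if (K < 1) return(matrix(numeric(0), n_vols, 0))
  v <- seq_len(n_vols)
  out <- vapply(seq_len(K), function(k) {
    cos(pi * (2 * v - 1) * k / (2 * n_vols))
  }, numeric(n_vols))
  colnames(out) <- sprintf("drift_%02d", seq_len(K))
  out
}

#' Build a first-level GLM design matrix
#'
#' One HRF-convolved column per task condition (boxcars over event
#' durations, convolved on a 16-bins-per-TR oversampled grid and
#' sampled at volume midpoints), followed by DCT drift columns for all
#' periods longer than `hpf_cutoff_s`, optional nuisance columns, and a
#' constant column last.
#'
#' @param design an [event_design()].
#' @param n_vols number of retained volumes.
#' @param tr repetition time (default: the design's TR).
#' @param hrf named list of [canonical_hrf()] parameter overrides.
#' @param hpf_cutoff_s high-pass cutoff in seconds (default 128).
#' @param nuisance optional time x k numeric matrix (e.g. realignment
#'   parameters).
#' @param oversample convolution oversampling (bins per TR).
#' @return a `design_matrix`: list with `x` (time x regressors),
#'   `names`, `n_task` (number of task columns) and `tr`.  A warning is
#'   issued if the final matrix is rank deficient (estimation then uses
#'   the pseudoinverse solution of the least-squares problem).
#' @export
build_design_matrix <- function(design, n_vols, tr = NULL, hrf = list(),
                                hpf_cutoff_s = 128, nuisance = NULL,
                                oversample = 16) {
  tr <- tr %||% attr(design, "tr")
  if (is.null(tr)) stop_arg("`tr` must be given or carried by the design")
  if (nrow(design) > 0 && max(design$onset + design$duration) > n_vols * tr + 1e-9) {
    stop_arg("events fall outside the `n_vols` x `tr` acquisition window")
  }
  conds <- unique(design$condition)
  task <- if (length(conds)) {
    vapply(conds, function(cc) {
      ev <- design$condition == cc
      convolve_events(design$onset[ev], design$duration[ev], n_vols, tr,
                      oversample = oversample, hrf = hrf)
    }, numeric(n_vols))
  } else {
    matrix(numeric(0), n_vols, 0)
  }
  drifts <- dct_drift_basis(n_vols, tr, hpf_cutoff_s)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_vols) stop_arg("`nuisance` must have `n_vols` rows")
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- sprintf("nuis_%02d", seq_len(ncol(nuisance)))
    }
  } else {
    nuisance <- matrix(numeric(0), n_vols, 0)
  }
  x <- cbind(task, drifts, nuisance, constant = 1)
  colnames(x)[seq_along(conds)] <- conds
  if (qr(x)$rank < ncol(x)) {
    warning("design matrix is rank deficient; estimation will use the pseudoinverse",
            call. = FALSE)
  }
  structure(list(x = x, names = colnames(x), n_task = length(conds), tr = tr),
            class = "design_matrix")
}

## least-squares fit Y ~ X returning the coefficient matrix; falls back
## to the pseudoinverse for rank-deficient designs
ls_coef <- function(X, Y) {
  qx <- qr(X)
  if (qx$rank == ncol(X)) {
    qr.coef(qx, Y)
  } else {
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
  }
}

## pooled lag-1 autocorrelation of OLS residuals across mask voxels
pooled_ar1_phi <- function(R) {
  num <- sum(R[-1, , drop = FALSE] * R[-nrow(R), , drop = FALSE])
  den <- sum(R^2)
  if (den < 1e-24) return(0)
  num / den
}

## Cochrane-Orcutt style whitening of a matrix (columns are series)
ar1_whiten <- function(M, phi) {
  out <- M
  out[1, ] <- M[1, ] * sqrt(1 - phi^2)
  out[-1, ] <- M[-1, , drop = FALSE] - phi * M[-nrow(M), , drop = FALSE]
  out
}

## extract the mask-voxel time series of a volume_series: n_vols x n_mask
mask_timeseries <- function(vol) {
  d <- dim(vol$data)
  mat <- matrix(vol$data, prod(d[1:3]), d[4])
  t(mat[which(vol$mask), , drop = FALSE])
}

#' Least-Squares-Single trial beta estimation
#'
#' Fits one GLM per trial of interest, with three task regressors: the
#' single trial at hand, all other trials of interest combined, and all
#' baseline (pseudoword) trials combined; plus DCT drifts, optional
#' nuisance columns and a constant.  The coefficient of the
#' trial-of-interest regressor at every mask voxel is that trial's
#' activation estimate.  Optional single-pass AR(1) prewhitening: a
#' pooled lag-1 residual autocorrelation is estimated from a reference
#' model (all trials of interest as one regressor) and applied to data
#' and design before the per-trial fits.
#'
#' @param vol a [volume_series()].
#' @param design an [event_design()]; trials of interest are all events
#'   whose condition differs from `baseline_condition`, and their
#'   condition labels must be unique (one trial per concept).
#' @param ar1 estimate and apply AR(1) prewhitening (default `TRUE`).
#' @param hpf_cutoff_s high-pass cutoff in seconds (`Inf` disables).
#' @param nuisance optional time x k nuisance matrix.
#' @param baseline_condition label of the baseline trials (default
#'   `"pseudoword"`); may be absent from the design.
#' @param oversample convolution oversampling.
#' @return a `trial_beta_set`: list with `concepts` (alphabetically
#'   ordered trial labels), `betas` (concepts x mask-voxel matrix, rows
#'   in concept order, columns in `which(mask)` order), `mask`, `dim`,
#'   `voxel_size` and the estimated `ar1_phi`.
#' @export
lss_betas <- function(vol, design, ar1 = TRUE, hpf_cutoff_s = 128,
                      nuisance = NULL, baseline_condition = "pseudoword",
                      oversample = 16) {
  if (!inherits(vol, "volume_series")) stop_arg("`vol` must be a volume_series")
  tr <- vol$tr
  n_vols <- dim(vol$data)[4]
  interest <- which(design$condition != baseline_condition)
  base_ev <- which(design$condition == baseline_condition)
  if (length(interest) < 1) stop_arg("design contains no trials of interest")
  labs <- design$condition[interest]
  if (anyDuplicated(labs)) {
    stop_arg("trial-of-interest labels must be unique (one trial per concept)")
  }

  ## per-trial and baseline regressors
  Xtr <- vapply(interest, function(e) {
    convolve_events(design$onset[e], design$duration[e], n_vols, tr,
                    oversample = oversample)
  }, numeric(n_vols))
  Xbase <- if (length(base_ev)) {
    convolve_events(design$onset[base_ev], design$duration[base_ev], n_vols, tr,
                    oversample = oversample)
  } else {
    NULL
  }
  drifts <- dct_drift_basis(n_vols, tr, hpf_cutoff_s)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_vols) stop_arg("`nuisance` must have `n_vols` rows")
  }
  extra <- cbind(drifts, nuisance, constant = rep(1, n_vols))
  n_reg <- 2 + (!is.null(Xbase)) + ncol(extra)
  if (n_vols <= n_reg) {
    stop_arg("fewer volumes (", n_vols, ") than regressors (", n_reg, ")")
  }

  Y <- mask_timeseries(vol)

  phi <- 0
  if (ar1) {
    Xref <- cbind(rowSums(Xtr), Xbase, extra)
    phi <- pooled_ar1_phi(Y - Xref %*% ls_coef(Xref, Y))
    if (abs(phi) >= 1) phi <- sign(phi) * 0.99
    if (phi != 0) {
      Y <- ar1_whiten(Y, phi)
      Xtr <- ar1_whiten(Xtr, phi)
      if (!is.null(Xbase)) Xbase <- ar1_whiten(matrix(Xbase), phi)
      extra <- ar1_whiten(extra, phi)
    }
  }

  all_tr <- rowSums(Xtr)
  betas <- matrix(NA_real_, length(interest), ncol(Y))
  for (i in seq_along(interest)) {
    Xi <- cbind(Xtr[, i], all_tr - Xtr[, i], Xbase, extra)
    betas[i, ] <- ls_coef(Xi, Y)[1, ]
  }
  ord <- order(labs)
  structure(list(concepts = labs[ord], betas = betas[ord, , drop = FALSE],
                 mask = vol$mask, dim = dim(vol$mask),
                 voxel_size = vol$voxel_size, ar1_phi = phi),
            class = "trial_beta_set")
}

#' Statistic map
#'
#' @param values 3D array of statistic values (NaN outside the mask).
#' @param df degrees of freedom.
#' @param kind `"t"` or `"z"`.
#' @return a `stat_map` object.
#' @export
stat_map <- function(values, df, kind = c("t", "z")) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3) stop_arg("`values` must be a 3D array")
  structure(list(values = values, df = df, kind = kind), class = "stat_map")
}

#' Block-design GLM contrast
#'
#' Fits a boxcar-convolved block GLM (one regressor per task condition,
#' plus drifts and a constant) and returns the per-voxel contrast
#' estimate and t statistic, as used for the localizer activation maps.
#'
#' @param vol a [volume_series()].
#' @param design an [event_design()] with block events.
#' @param contrast numeric weight vector over the task conditions (in
#'   `unique(design$condition)` order); must not be all zero.
#' @param ar1 apply pooled AR(1) prewhitening (default `TRUE`).
#' @param hpf_cutoff_s high-pass cutoff in seconds.
#' @param nuisance optional nuisance matrix.
#' @return list with `stat` (a [stat_map()] of t values), `contrast`
#'   (3D contrast-estimate image, NaN outside the mask) and `df`.
#' @export
block_glm_contrast <- function(vol, design, contrast, ar1 = TRUE,
                               hpf_cutoff_s = 128, nuisance = NULL) {
  n_vols <- dim(vol$data)[4]
  conds <- unique(design$condition)
  if (length(contrast) != length(conds)) {
    stop_arg("`contrast` length must equal the number of task conditions (",
             length(conds), ")")
  }
  if (all(contrast == 0)) stop_arg("contrast of all zeros")
  dm <- build_design_matrix(design, n_vols, tr = vol$tr,
                            hpf_cutoff_s = hpf_cutoff_s, nuisance = nuisance)
  X <- dm$x
  Y <- mask_timeseries(vol)
  if (ar1) {
    phi <- pooled_ar1_phi(Y - X %*% ls_coef(X, Y))
    if (phi != 0) {
      Y <- ar1_whiten(Y, phi)
      X <- ar1_whiten(X, phi)
    }
  }
  cvec <- c(contrast, rep(0, ncol(X) - length(contrast)))
  qx <- qr(X)
  B <- ls_coef(X, Y)
  R <- Y - X %*% B
  df <- n_vols - qx$rank
  sigma2 <- colSums(R^2) / df
  XtXinv_c <- solve(crossprod(X), cvec)
  c_var <- sum(cvec * XtXinv_c)
  est <- as.vector(crossprod(cvec, B))
  tval <- est / sqrt(sigma2 * c_var)
  dims <- dim(vol$mask)
  timg <- array(NaN, dims)
  cimg <- array(NaN, dims)
  timg[which(vol$mask)] <- tval
  cimg[which(vol$mask)] <- est
  list(stat = stat_map(timg, df, "t"), contrast = cimg, df = df)
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis, in voxel units.  Kernels
#' are renormalized at the grid boundary (truncated tails), so a
#' constant image is unchanged everywhere.
#'
#' @param img 3D numeric array.
#' @param fwhm_mm full width at half maximum in mm (scalar or length 3).
#' @param voxel_size voxel dimensions in mm.
#' @return smoothed 3D array.
#' @export
smooth_volume <- function(img, fwhm_mm, voxel_size = c(2, 2, 2)) {
  if (any(fwhm_mm <= 0)) stop_arg("`fwhm_mm` must be positive")
  fwhm_mm <- rep_len(fwhm_mm, 3)
  voxel_size <- rep_len(voxel_size, 3)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  dims <- dim(img)
  out <- img
  for (ax in 1:3) {
    n <- dims[ax]
    s <- sigma_vox[ax]
    r <- max(1L, ceiling(4 * s))
    w <- exp(-(0:r)^2 / (2 * s^2))
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      M[i, j] <- w[abs(j - i) + 1]
      M[i, ] <- M[i, ] / sum(M[i, ])
    }
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(out, perm)
    a <- array(M %*% matrix(a, n), dim(a))
    out <- aperm(a, order(perm))
  }
  out
}
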