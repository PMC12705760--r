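## Planting a known representational geometry into voxel patterns.

## integer offsets of a sphere of the given radius (inclusive boundary,
## voxel units); shared by the searchlight and the harmonic basis.
sphere_offsets <- function(radius_vox) {
  r <- floor(radius_vox)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[rowSums(g^2) <= radius_vox^2, , drop = FALSE]
}

## Frequency at which the sphere window transform vanishes at both w
## and 2w: sums of cos(w.v) and sin(w.v) over every fully-interior
## sphere of this radius are then exactly zero, and the quadrature pair
## has equal power and zero cross-moment over every such sphere.
## Found by grid scan + Newton; cached per radius.
harmonic_env <- new.env(parent = emptyenv())

harmonic_frequency <- function(radius_vox) {
  key <- format(radius_vox)
  if (!is.null(harmonic_env[[key]])) return(harmonic_env[[key]])
  O <- sphere_offsets(radius_vox)
  khat2 <- function(p) {
    w <- c(p, 0)
    c(sum(cos(O %*% w)), sum(cos(O %*% (2 * w))))
  }
  grid <- seq(0.05, pi - 0.05, length.out = 120)
  W <- as.matrix(expand.grid(w1 = grid, w2 = grid))
  f1 <- colSums(cos(O %*% t(cbind(W, 0))))
  f2 <- colSums(cos(O %*% t(2 * cbind(W, 0))))
  p <- W[which.min(f1^2 + f2^2), ]
  for (it in 1:80) {
    Fv <- khat2(p)
    if (max(abs(Fv)) < 1e-12) break
    h <- 1e-7
    J <- cbind((khat2(p + c(h, 0)) - Fv) / h, (khat2(p + c(0, h)) - Fv) / h)
    step <- tryCatch(solve(J, Fv), error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 0.5) step <- step * 0.5 / max(abs(step))
    p <- p - step
  }
  if (max(abs(khat2(p))) > 1e-9) {
    stop_arg("no sphere-window-nulling frequency found for radius ", radius_vox)
  }
  w <- c(unlist(p), 0)
  harmonic_env[[key]] <- w
  w
}

#' Plant an exact representational geometry into voxel patterns
#'
#' Constructs per-condition multi-voxel patterns over a region of
#' interest (ROI) whose correlation-distance RDM reproduces a given
#' target RDM exactly, providing ground truth for pipeline validation.
#'
#' Two constructions are available:
#' \describe{
#'   \item{`basis = "random"` (default)}{factorizes the target
#'     similarity matrix `S = 1 - d` against random centered
#'     orthonormal voxel basis vectors.  The sample correlation matrix
#'     of the returned patterns, computed over \emph{all} ROI voxels,
#'     equals `S` exactly.  Works for any positive semidefinite target;
#'     requires `length(roi_indices) >= rank(S) + 1`.}
#'   \item{`basis = "harmonic"`}{for rank-2 targets only: patterns are
#'     laid on a spatial quadrature sinusoid pair whose frequency nulls
#'     the searchlight sphere's window transform, so \emph{every}
#'     sphere of radius `radius_vox` lying fully inside the ROI sees
#'     the exact target correlations.  This is the construction that
#'     lets a noise-free searchlight analysis return Spearman rho = 1
#'     at every ROI-interior center; the full-ROI correlation matrix is
#'     then only approximately `S` (the guarantee moves from the ROI to
#'     its interior spheres).}
#' }
#'
#' @param target an [rdm()]; `1 - target$d` must be positive
#'   semidefinite (correlation-realizable), otherwise an error.
#' @param roi_indices linear voxel indices (into the 3D grid) receiving
#'   the patterns.
#' @param amplitude positive scale applied to the patterns.
#' @param seed integer seed (random basis only).
#' @param basis `"random"` or `"harmonic"` (see Details).
#' @param dim 3D grid dimensions; required for the harmonic basis.
#' @param radius_vox searchlight radius the harmonic basis is tuned to.
#' @param n_voxels number of ROI voxels; must equal
#'   `length(roi_indices)` (redundant, kept for explicitness).
#' @return a `pattern_set`: list with `concepts`, `patterns`
#'   (conditions x voxels), `roi_indices` and `basis`.
#' @export
embed_geometry <- function(target, roi_indices, amplitude = 1, seed = 1,
                           basis = c("random", "harmonic"), dim = NULL,
                           radius_vox = 3, n_voxels = length(roi_indices)) {
  basis <- match.arg(basis)
  validate_rdm(target)
  if (n_voxels != length(roi_indices)) {
    stop_arg("`n_voxels` must equal `length(roi_indices)`")
  }
  if (amplitude <= 0) stop_arg("`amplitude` must be positive")
  k <- length(target$labels)
  S <- 1 - target$d
  diag(S) <- 1
  eg <- eigen(S, symmetric = TRUE)
  tol <- 1e-10 * max(abs(eg$values), 1)
  if (min(eg$values) < -tol) {
    stop_arg("target RDM is not correlation-realizable (1 - d is not positive semidefinite)")
  }
  r <- sum(eg$values > tol)
  A <- eg$vectors[, seq_len(r), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(r)], 0)), r)

  if (basis == "random") {
    if (n_voxels < r + 1) {
      stop_arg("need at least rank(S) + 1 = ", r + 1, " voxels, got ", n_voxels)
    }
    B <- with_seed(seed, {
      M <- matrix(stats::rnorm(r * n_voxels), r, n_voxels)
      M <- M - rowMeans(M)
      t(qr.Q(qr(t(M)))[, seq_len(r), drop = FALSE])  # orthonormal, centered rows
    })
    patterns <- amplitude * (A %*% B)
  } else {
    if (is.null(dim)) stop_arg("`dim` (grid dimensions) is required for the harmonic basis")
    if (r > 2) {
      stop_arg("harmonic planting requires a rank-2 (or rank-1) correlation ",
               "structure; this target has rank ", r)
    }
    w <- harmonic_frequency(radius_vox)
    coords <- lin_to_ijk(roi_indices, dim)
    phase <- as.vector(coords %*% w)
    if (r == 1) A <- cbind(A, 0)
    patterns <- amplitude * (A[, 1] %o% cos(phase) + A[, 2] %o% sin(phase))
  }
  rownames(patterns) <- target$labels
  structure(list(concepts = target$labels, patterns = patterns,
                 roi_indices = as.integer(roi_indices), basis = basis),
            class = "pattern_set")
}

#' Ellipsoidal brain-like mask
#'
#' Binary mask of an axis-aligned ellipsoid centered in the grid with
#' semi-axes `0.45 * dim` (the desk-scale default leaving room for
#' radius-3 searchlights).
#'
#' @param dim integer vector of 3 grid dimensions.
#' @param semi_axes optional semi-axes in voxels.
#' @return logical 3D array.
#' @export
ellipsoid_mask <- function(dim, semi_axes = 0.45 * dim) {
  ctr <- (dim + 1) / 2
  i <- (seq_len(dim[1]) - ctr[1]) / semi_axes[1]
  j <- (seq_len(dim[2]) - ctr[2]) / semi_axes[2]
  k <- (seq_len(dim[3]) - ctr[3]) / semi_axes[3]
  d2 <- outer(outer(i^2, j^2, "+"), k^2, "+")
  d2 <= 1
}

#' Compact spherical ROI of a requested size
#'
#' The `n` mask voxels closest to `center` (Euclidean distance in voxel
#' units, deterministic tie-break by linear index), as linear indices.
#' Convenience for planting geometries in a ball-shaped region.
#'
#' @param mask logical 3D array.
#' @param center voxel coordinates of the ROI centre.
#' @param n number of voxels.
#' @return integer vector of linear voxel indices.
#' @export
roi_ball <- function(mask, center, n) {
  dims <- dim(mask)
  lin <- which(mask)
  if (length(lin) < n) stop_arg("mask has fewer than ", n, " voxels")
  ijk <- lin_to_ijk(lin, dims)
  d2 <- colSums((t(ijk) - center)^2)
  lin[order(d2, lin)[seq_len(n)]]
}
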