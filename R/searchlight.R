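#' Define searchlight centers and neighborhoods
#'
#' Sphere neighborhoods in voxel units (integer offsets with squared
#' Euclidean norm `<= radius_vox^2`, inclusive boundary).  A mask voxel
#' is retained as a center iff at least `min_fraction` of the full
#' geometric sphere (123 voxels at radius 3) lies inside the mask —
#' the masking threshold relevant at brain boundaries.
#'
#' @param mask logical 3D array.
#' @param radius_vox sphere radius in voxels (default 3).
#' @param min_fraction minimal in-mask fraction of the sphere, with the
#'   full geometric sphere size as denominator (default 0.5).
#' @return a `searchlight_set`: list with `centers` (linear indices),
#'   `neighbors` (per center, in-mask linear indices within the sphere,
#'   always containing the center), `radius_vox`, `min_fraction`,
#'   `sphere_size` and `dim`.
#' @export
searchlight_centers <- function(mask, radius_vox = 3, min_fraction = 0.5) {
  if (!any(mask)) stop_arg("mask is empty")
  dims <- dim(mask)
  off <- sphere_offsets(radius_vox)
  m <- nrow(off)
  lin <- which(mask)
  ijk <- lin_to_ijk(lin, dims)
  n <- length(lin)
  neigh <- matrix(NA_integer_, n, m)
  for (o in seq_len(m)) {
    ci <- ijk[, 1] + off[o, 1]
    cj <- ijk[, 2] + off[o, 2]
    ck <- ijk[, 3] + off[o, 3]
    ok <- ci >= 1L & ci <= dims[1] & cj >= 1L & cj <= dims[2] &
      ck >= 1L & ck <= dims[3]
    cand <- rep(NA_integer_, n)
    cand[ok] <- ci[ok] + (cj[ok] - 1L) * dims[1] + (ck[ok] - 1L) * dims[1] * dims[2]
    cand[ok][!mask[cand[ok]]] <- NA_integer_
    neigh[, o] <- cand
  }
  counts <- rowSums(!is.na(neigh))
  keep <- counts >= min_fraction * m
  neighbors <- lapply(which(keep), function(i) {
    sort(neigh[i, !is.na(neigh[i, ])])
  })
  structure(list(centers = lin[keep], neighbors = neighbors,
                 radius_vox = radius_vox, min_fraction = min_fraction,
                 sphere_size = m, dim = dims),
            class = "searchlight_set")
}

#' @export
print.searchlight_set <- function(x, ...) {
  cat(sprintf("<searchlight_set> %d centers, radius %g vox (sphere size %d), min fraction %g\n",
              length(x$centers), x$radius_vox, x$sphere_size, x$min_fraction))
  invisible(x)
}

#' Neural RDM of a voxel neighborhood
#'
#' Restricts each concept's activation pattern to the given voxels,
#' normalizes it (centering and unit variance across voxels — a no-op
#' for the subsequent Pearson correlation) and computes the pairwise
#' correlation-distance RDM.
#'
#' @param betas a `trial_beta_set` from [lss_betas()].
#' @param voxel_idx column indices into `betas$betas` (positions within
#'   the mask-voxel ordering), at least 2.
#' @return an [rdm()].  A constant (zero-variance) restricted pattern
#'   raises a condition of class `slrsa_constant_pattern`.
#' @export
neural_rdm <- function(betas, voxel_idx) {
  if (length(voxel_idx) < 2) stop_arg("need at least 2 voxels")
  P <- betas$betas[, voxel_idx, drop = FALSE]
  cs <- P - rowMeans(P)
  ss <- rowSums(cs^2)
  if (any(ss == 0)) {
    stop(structure(class = c("slrsa_constant_pattern", "error", "condition"),
                   list(message = paste0(
                     "constant pattern for concept(s): ",
                     paste(betas$concepts[ss == 0], collapse = ", ")),
                     call = NULL)))
  }
  cs <- cs / sqrt(ss)
  d <- 1 - tcrossprod(cs)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[d < 0] <- 0
  d[d > 2] <- 2
  rdm(d, betas$concepts)
}

## map grid linear indices -> beta column positions
mask_column_map <- function(mask) {
  cm <- integer(length(mask))
  cm[which(mask)] <- seq_len(sum(mask))
  cm
}

#' Searchlight map of model-brain representational similarity
#'
#' At every searchlight center, the Spearman rank correlation between
#' the neighborhood's neural RDM and the model RDM (off-diagonal
#' upper-triangle cells, average ranks) is computed and written to the
#' center voxel; all other voxels are NaN.  Searchlights containing a
#' constant pattern are skipped and logged (NaN at the center).
#'
#' @param betas a `trial_beta_set`; concept labels must equal the model
#'   labels in identical order.
#' @param model an [rdm()].
#' @param sls a [searchlight_centers()] result on the same grid.
#' @return an `rsa_map`: list with `values` (3D array of rho, NaN off
#'   center), `model_label`, `dim`, `voxel_size` and `skipped` (linear
#'   indices of skipped centers).
#' @export
rsa_map <- function(betas, model, sls) {
  validate_rdm(model)
  if (!identical(betas$concepts, model$labels)) {
    stop_arg("beta concept labels must equal the model RDM labels (same order)")
  }
  if (!all(sls$dim == betas$dim)) stop_arg("searchlight grid does not match betas")
  cm <- mask_column_map(betas$mask)
  mr <- rank(upper_tri_vec(model$d), ties.method = "average")
  vals <- array(NaN, betas$dim)
  skipped <- integer(0)
  B <- betas$betas
  for (i in seq_along(sls$centers)) {
    cols <- cm[sls$neighbors[[i]]]
    P <- B[, cols, drop = FALSE]
    cs <- P - rowMeans(P)
    ss <- rowSums(cs^2)
    if (any(ss == 0)) {
      skipped <- c(skipped, sls$centers[i])
      next
    }
    cs <- cs / sqrt(ss)
    dvec <- 1 - upper_tri_vec(tcrossprod(cs))
    dvec[dvec < 0] <- 0
    dvec[dvec > 2] <- 2
    if (stats::var(dvec) == 0) {
      skipped <- c(skipped, sls$centers[i])
      next
    }
    vals[sls$centers[i]] <- stats::cor(mr, rank(dvec, ties.method = "average"))
  }
  if (length(skipped)) {
    message(length(skipped), " searchlight(s) skipped (constant pattern or degenerate neural RDM)")
  }
  structure(list(values = vals, model_label = attr(model, "label") %||% "model",
                 dim = betas$dim, voxel_size = betas$voxel_size,
                 skipped = skipped),
            class = "rsa_map")
}

#' Searchlight partial Spearman RSA controlling for nuisance RDMs
#'
#' Ranks are taken first (neural, model and nuisance upper-triangle
#' cells), then the nuisance ranks are partialled out linearly from
#' both the neural and the model ranks; the map value is the Pearson
#' correlation of the two residual vectors.  With an empty nuisance
#' list this reduces exactly to [rsa_map()].
#'
#' @param betas a `trial_beta_set`.
#' @param model an [rdm()].
#' @param nuisance list of [rdm()] objects sharing the model's labels.
#' @param sls a [searchlight_centers()] result.
#' @return an `rsa_map`.
#' @export
partial_rsa_map <- function(betas, model, nuisance, sls) {
  if (length(nuisance) == 0) return(rsa_map(betas, model, sls))
  validate_rdm(model)
  for (nu in nuisance) {
    validate_rdm(nu)
    if (!identical(nu$labels, model$labels)) {
      stop_arg("nuisance RDM labels must equal the model labels")
    }
  }
  if (!identical(betas$concepts, model$labels)) {
    stop_arg("beta concept labels must equal the model RDM labels (same order)")
  }
  mr <- rank(upper_tri_vec(model$d), ties.method = "average")
  Z <- cbind(1, vapply(nuisance, function(nu) {
    rank(upper_tri_vec(nu$d), ties.method = "average")
  }, numeric(length(mr))))
  if (qr(cbind(Z, mr))$rank < ncol(Z) + 1) {
    stop_arg("nuisance RDMs are collinear with the model RDM (rank deficient)")
  }
  qz <- qr(Z)
  mres <- qr.resid(qz, mr)
  cm <- mask_column_map(betas$mask)
  vals <- array(NaN, betas$dim)
  skipped <- integer(0)
  B <- betas$betas
  for (i in seq_along(sls$centers)) {
    cols <- cm[sls$neighbors[[i]]]
    P <- B[, cols, drop = FALSE]
    cs <- P - rowMeans(P)
    ss <- rowSums(cs^2)
    if (any(ss == 0)) {
      skipped <- c(skipped, sls$centers[i])
      next
    }
    cs <- cs / sqrt(ss)
    dvec <- 1 - upper_tri_vec(tcrossprod(cs))
    dvec[dvec < 0] <- 0
    dvec[dvec > 2] <- 2
    if (stats::var(dvec) == 0) {
      skipped <- c(skipped, sls$centers[i])
      next
    }
    nr <- rank(dvec, ties.method = "average")
    vals[sls$centers[i]] <- stats::cor(qr.resid(qz, nr), mres)
  }
  if (length(skipped)) {
    message(length(skipped), " searchlight(s) skipped (constant pattern or degenerate neural RDM)")
  }
  structure(list(values = vals, model_label = attr(model, "label") %||% "model",
                 dim = betas$dim, voxel_size = betas$voxel_size,
                 skipped = skipped),
            class = "rsa_map")
}
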