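#' @keywords internal
"_PACKAGE"

## Small shared helpers. Conventions used throughout the package:
##  - voxel indices are 1-based (i, j, k) array indices; "linear" indices
##    index into the flattened 3D grid in R's column-major order;
##  - world coordinates (mm) place the origin at the volume centre:
##    world = (ijk - (dim + 1) / 2) * voxel_size.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Vectorize the off-diagonal upper triangle of a square matrix
#'
#' Cells are taken row-major, excluding the diagonal: (1,2), (1,3), ...,
#' (2,3), ... The same helper is used for neural and model RDMs so the
#' two vectorizations always align.
#'
#' @param m square numeric matrix.
#' @return numeric vector of length `n (n - 1) / 2`.
#' @keywords internal
upper_tri_vec <- function(m) {
  t(m)[lower.tri(m)]
}

## Spearman rho via average ranks (correlation distances can tie).
spearman_rho <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

## linear index <-> (i, j, k) for a 3D grid
lin_to_ijk <- function(lin, dim) arrayInd(lin, .dim = dim)

ijk_to_lin <- function(ijk, dim) {
  ijk <- matrix(ijk, ncol = 3)
  ijk[, 1] + (ijk[, 2] - 1L) * dim[1] + (ijk[, 3] - 1L) * dim[1] * dim[2]
}

## world mm coordinates, origin at the volume centre
ijk_to_world <- function(ijk, dim, voxel_size) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(sweep(ijk, 2, (dim + 1) / 2, "-"), 2, voxel_size, "*")
}

## local RNG scope: leaves the caller's .Random.seed untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_arg <- function(...) stop(..., call. = FALSE)
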