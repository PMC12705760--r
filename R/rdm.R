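#' Representational dissimilarity matrix
#'
#' Central currency of the pipeline: a symmetric condition-by-condition
#' matrix of correlation distances (1 - Pearson r), zero diagonal,
#' entries in `[0, 2]`.  Invariants are asserted on construction.
#'
#' @param d square numeric dissimilarity matrix.
#' @param labels ordered condition names (default: row names of `d`).
#' @return an `rdm`: list with `labels` and `d`.
#' @export
rdm <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  if (is.null(labels)) stop_arg("an RDM needs condition labels")
  x <- structure(list(labels = as.character(labels), d = d), class = "rdm")
  validate_rdm(x)
  dimnames(x$d) <- list(x$labels, x$labels)
  x
}

validate_rdm <- function(x, tol = 1e-8) {
  if (!inherits(x, "rdm")) stop_arg("not an `rdm` object")
  d <- x$d
  if (nrow(d) != ncol(d)) stop_arg("RDM matrix must be square")
  if (length(x$labels) != nrow(d)) stop_arg("label count must equal matrix order")
  if (max(abs(d - t(d))) > tol) stop_arg("RDM matrix must be symmetric")
  if (max(abs(diag(d))) > tol) stop_arg("RDM diagonal must be zero")
  if (min(d) < -tol || max(d) > 2 + tol) {
    stop_arg("RDM entries must lie in [0, 2] (correlation distance)")
  }
  invisible(TRUE)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d conditions, mean off-diagonal distance %.3f\n",
              length(x$labels), mean(upper_tri_vec(x$d))))
  invisible(x)
}

#' Correlation-distance RDM from a feature matrix
#'
#' `d[i, j] = 1 - Pearson(row_i, row_j)` across the feature dimensions,
#' the conversion used for both the language (concepts x embedding
#' dimensions) and the experience (concepts x feature categories)
#' model matrices.
#'
#' @param m numeric matrix, one row per condition; every row must have
#'   nonzero variance.
#' @param labels condition labels (default: row names).
#' @return an [rdm()].
#' @export
correlation_distance_rdm <- function(m, labels = rownames(m)) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop_arg("need at least 2 rows")
  if (is.null(labels)) labels <- sprintf("cond_%02d", seq_len(nrow(m)))
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    stop_arg("zero-variance row(s): ", paste(labels[v == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(t(m))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[d < 0] <- 0          # clip numerical overshoot at the boundaries
  d[d > 2] <- 2
  rdm(d, labels)
}

#' Language RDM from a semantic space, dropping absent concepts
#'
#' Builds the correlation-distance RDM over the requested concepts,
#' silently-never: concepts absent from the space are dropped \emph{and
#' reported} via the `dropped_concepts` attribute and a message (the
#' study dropped 6 of 64 words not found in the embedding vocabulary).
#'
#' @param sm a [semantic_matrix()].
#' @param concepts concepts to include (default: all in the space).
#' @return an [rdm()] with attribute `dropped_concepts`.
#' @export
semantic_rdm <- function(sm, concepts = NULL) {
  if (!inherits(sm, "semantic_matrix")) stop_arg("`sm` must be a semantic_matrix")
  concepts <- concepts %||% sm$concepts
  dropped <- setdiff(concepts, sm$concepts)
  kept <- intersect(concepts, sm$concepts)
  if (length(kept) < 2) stop_arg("fewer than 2 requested concepts are in the space")
  if (length(dropped)) {
    message("dropping ", length(dropped), " concept(s) absent from the semantic space: ",
            paste(dropped, collapse = ", "))
  }
  out <- correlation_distance_rdm(sm$vectors[kept, , drop = FALSE], kept)
  attr(out, "dropped_concepts") <- dropped
  out
}

#' Experience feature matrix from property listings
#'
#' For each participant and non-missing concept, category counts are
#' converted to proportions of that cell's total listed properties;
#' proportions are then averaged across the participants for whom the
#' concept is available (missing cells are excluded, never imputed).
#' Cells with zero listed properties are treated as unavailable.
#'
#' @param pl a `property_listings` object.
#' @param concepts concept subset and row order (default: all).
#' @return numeric matrix, `length(concepts)` x 11, with dimnames.
#' @export
build_experience_matrix <- function(pl, concepts = NULL) {
  if (!inherits(pl, "property_listings")) stop_arg("`pl` must be property_listings")
  concepts <- concepts %||% pl$concepts
  if (!all(concepts %in% pl$concepts)) {
    stop_arg("unknown concept(s): ",
             paste(setdiff(concepts, pl$concepts), collapse = ", "))
  }
  k <- length(pl$categories)
  out <- matrix(NA_real_, length(concepts), k,
                dimnames = list(concepts, pl$categories))
  for (cc in concepts) {
    ci <- match(cc, pl$concepts)
    cellm <- matrix(pl$counts[, ci, ], ncol = k)   # participants x categories
    tots <- rowSums(cellm)
    avail <- !pl$missing[, ci] & tots > 0
    if (!any(avail)) {
      stop_arg("concept '", cc, "' is missing for all participants")
    }
    prop <- cellm[avail, , drop = FALSE] / tots[avail]
    out[cc, ] <- colMeans(prop)
  }
  out
}

#' Compare two RDMs by Spearman rank correlation
#'
#' Spearman's rho over the `k (k - 1) / 2` off-diagonal upper-triangle
#' cells (average ranks for ties).  With `n_perm > 0` the p value comes
#' from jointly relabeling the conditions of `b` (rows and columns
#' permuted together) `n_perm` times; with `n_perm = 0` an asymptotic
#' t-approximation p value is returned.
#'
#' @param a,b [rdm()] objects with identical labels in identical order
#'   (no silent reordering).
#' @param n_perm number of condition-relabeling permutations (>= 0).
#' @param seed integer seed for the permutations.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return an `rdm_comparison`: list with `rho`, `p`, `n_pairs`,
#'   `n_perm`, `alternative`.
#' @export
compare_rdms <- function(a, b, n_perm = 0, seed = 1,
                         alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  validate_rdm(a)
  validate_rdm(b)
  if (!identical(a$labels, b$labels)) {
    stop_arg("RDM labels differ (or are ordered differently); align them explicitly")
  }
  if (n_perm < 0) stop_arg("`n_perm` must be >= 0")
  va <- upper_tri_vec(a$d)
  vb <- upper_tri_vec(b$d)
  n_pairs <- length(va)
  rho <- spearman_rho(va, vb)
  k <- length(a$labels)
  if (n_perm == 0) {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n_pairs - 2) / (1 - rho^2))
      p <- if (alternative == "greater") {
        stats::pt(tval, n_pairs - 2, lower.tail = FALSE)
      } else {
        2 * stats::pt(-abs(tval), n_pairs - 2)
      }
    }
  } else {
    ra <- rank(va, ties.method = "average")
    perm_rho <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        pp <- sample.int(k)
        stats::cor(ra, rank(upper_tri_vec(b$d[pp, pp]), ties.method = "average"))
      }, numeric(1))
    })
    p <- if (alternative == "greater") {
      (1 + sum(perm_rho >= rho)) / (1 + n_perm)
    } else {
      (1 + sum(abs(perm_rho) >= abs(rho))) / (1 + n_perm)
    }
  }
  structure(list(rho = rho, p = p, n_pairs = n_pairs, n_perm = n_perm,
                 alternative = alternative),
            class = "rdm_comparison")
}

#' @export
print.rdm_comparison <- function(x, ...) {
  cat(sprintf("<rdm_comparison> Spearman rho = %.4f, p = %.4g (%s, %d pairs%s)\n",
              x$rho, x$p, x$alternative, x$n_pairs,
              if (x$n_perm > 0) sprintf(", %d permutations", x$n_perm) else ", asymptotic"))
  invisible(x)
}
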