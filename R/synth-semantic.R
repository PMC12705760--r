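#' Synthetic distributional semantic space
#'
#' Generates a concepts-by-dimensions embedding matrix as linear
#' mixtures of a small number of latent semantic factors plus isotropic
#' Gaussian noise, a stand-in for word2vec-style vectors.  Latent
#' mixing weights are positive, so with a single factor and no noise
#' all rows are perfectly (positively) correlated and the resulting
#' correlation-distance RDM is identically zero.
#'
#' @param n_concepts number of concepts (rows), at least 2.
#' @param n_dims embedding dimensionality (default 400).
#' @param n_latent number of latent factors, `1 <= n_latent <= n_dims`.
#' @param noise_sd SD of the isotropic noise added to each entry.
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @param concepts optional concept labels (default `concept_01`, ...).
#' @return a `semantic_matrix`: list with `concepts` (labels) and
#'   `vectors` (`n_concepts x n_dims` matrix with row names).
#' @export
make_semantic_space <- function(n_concepts, n_dims = 400, n_latent = 4,
                                noise_sd = 0.1, seed = 1, concepts = NULL) {
  if (n_concepts < 2) stop_arg("`n_concepts` must be at least 2")
  if (n_dims < 1 || n_latent < 1 || n_latent > n_dims) {
    stop_arg("need 1 <= n_latent <= n_dims and n_dims >= 1")
  }
  if (noise_sd < 0) stop_arg("`noise_sd` must be non-negative")
  if (is.null(concepts)) {
    concepts <- sprintf("concept_%03d", seq_len(n_concepts))
  }
  if (length(concepts) != n_concepts) stop_arg("label count must equal `n_concepts`")
  with_seed(seed, {
    scores <- matrix(abs(stats::rnorm(n_concepts * n_latent)), n_concepts, n_latent)
    loadings <- matrix(stats::rnorm(n_latent * n_dims), n_latent, n_dims)
    vectors <- scores %*% loadings
    if (noise_sd > 0) {
      vectors <- vectors + matrix(stats::rnorm(n_concepts * n_dims, sd = noise_sd),
                                  n_concepts, n_dims)
    }
    rownames(vectors) <- concepts
    semantic_matrix(concepts, vectors)
  })
}

#' @rdname make_semantic_space
#' @param vectors dense numeric matrix, one row per concept.
#' @export
semantic_matrix <- function(concepts, vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(concepts)) {
    stop_arg("row count of `vectors` must equal the number of labels")
  }
  if (any(rowSums(abs(vectors)) == 0)) {
    stop_arg("all-zero rows are not allowed (undefined correlation)")
  }
  rownames(vectors) <- concepts
  structure(list(concepts = as.character(concepts), vectors = vectors),
            class = "semantic_matrix")
}

#' Synthetic property-listing tables
#'
#' Emulates the post-scan property listing task: for each participant
#' and concept, a Poisson total of listed properties (mean
#' `mean_props`, the instructed "three to four") distributed over the
#' eleven feature categories according to a concept-specific category
#' profile shared across participants (so concepts carry a stable
#' experiential signature).  Each (participant, concept) cell is
#' independently flagged missing with probability `missing_rate`;
#' missing cells are flagged, never silently zero.
#'
#' @param n_participants,n_concepts table dimensions.
#' @param mean_props expected number of properties per listed cell.
#' @param missing_rate probability in `[0, 1)` that a cell is missing.
#' @param seed integer seed.
#' @param concentration Dirichlet-type concentration of the per-concept
#'   category profiles; smaller values give more distinct concepts.
#' @return a `property_listings`: list with `participants`, `concepts`,
#'   `categories` (the fixed 11 labels), `counts`
#'   (participants x concepts x 11 integer array) and `missing`
#'   (participants x concepts logical matrix).
#' @export
make_property_listings <- function(n_participants = 51, n_concepts = 58,
                                   mean_props = 3.5, missing_rate = 0.02,
                                   seed = 1, concentration = 0.8) {
  if (missing_rate < 0 || missing_rate >= 1) stop_arg("`missing_rate` must be in [0, 1)")
  if (mean_props <= 0) stop_arg("`mean_props` must be positive")
  if (n_participants < 1 || n_concepts < 1) stop_arg("dimensions must be positive")
  k <- length(PROPERTY_CATEGORIES)
  participants <- sprintf("sub_%02d", seq_len(n_participants))
  concepts <- sprintf("concept_%03d", seq_len(n_concepts))
  with_seed(seed, {
    ## per-concept category profile (normalized gamma draws)
    prof <- matrix(stats::rgamma(n_concepts * k, shape = concentration), n_concepts, k)
    prof <- prof / rowSums(prof)
    counts <- array(0L, dim = c(n_participants, n_concepts, k),
                    dimnames = list(participants, concepts, PROPERTY_CATEGORIES))
    missing <- matrix(stats::runif(n_participants * n_concepts) < missing_rate,
                      n_participants, n_concepts,
                      dimnames = list(participants, concepts))
    for (cc in seq_len(n_concepts)) {
      tot <- stats::rpois(n_participants, mean_props)
      draws <- vapply(tot, function(tt) {
        as.integer(stats::rmultinom(1, tt, prof[cc, ]))
      }, integer(k))
      counts[, cc, ] <- t(draws)
    }
    structure(list(participants = participants, concepts = concepts,
                   categories = PROPERTY_CATEGORIES, counts = counts,
                   missing = missing),
              class = "property_listings")
  })
}
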