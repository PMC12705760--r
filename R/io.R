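## External interfaces: NIfTI-1 for volumes and maps, TSV for tables
## and RDMs (plain text, full double precision, bit-exact round trips).

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a 3D or 4D volume as NIfTI-1
#'
#' @param x numeric array (3D or 4D) or a [volume_series()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_size voxel dimensions in mm.
#' @param tr repetition time for 4D data, seconds.
#' @return `read_volume` returns the array with attributes
#'   `voxel_size` (and `tr` for 4D data); `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(x, path, voxel_size = c(2, 2, 2), tr = 2) {
  if (inherits(x, "volume_series")) {
    voxel_size <- x$voxel_size
    tr <- x$tr
    x <- x$data
  }
  x <- x * 1  # logical -> numeric
  pd <- if (length(dim(x)) == 4) c(voxel_size, tr) else voxel_size
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  pd <- RNifti::pixdim(img)
  attr(out, "voxel_size") <- pd[1:3]
  if (length(dim(out)) == 4) attr(out, "tr") <- pd[4]
  out
}

#' Write / read an event design as a 3-column TSV
#'
#' Columns `onset`, `duration`, `condition` (seconds), one header line.
#'
#' @param design an [event_design()].
#' @param path file path.
#' @param run_length,tr run metadata (not stored in the TSV; must be
#'   supplied on read).
#' @return `read_event_design` returns an [event_design()].
#' @export
write_event_design <- function(design, path) {
  df <- data.frame(onset = fmt_num(design$onset),
                   duration = fmt_num(design$duration),
                   condition = design$condition)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_design
#' @export
read_event_design <- function(path, run_length, tr = 2) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "condition")
  if (!all(need %in% names(df))) {
    stop_arg("event TSV must have columns onset, duration, condition")
  }
  event_design(as.numeric(df$onset), as.numeric(df$duration), df$condition,
               run_length = run_length, tr = tr)
}

#' Write / read an RDM as labelled TSV
#'
#' First column `label`, then one column per condition; values are
#' written at full precision so a write-then-read round trip is
#' bit-exact.  On read all RDM invariants (symmetry, zero diagonal,
#' range, label presence) are enforced.
#'
#' @param x an [rdm()].
#' @param path file path.
#' @return `read_rdm` returns an [rdm()].
#' @export
write_rdm <- function(x, path) {
  validate_rdm(x)
  m <- matrix(fmt_num(x$d), nrow(x$d))
  df <- data.frame(label = x$labels, m, stringsAsFactors = FALSE)
  names(df) <- c("label", x$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "label") {
    stop_arg("malformed RDM file: missing `label` column")
  }
  labels <- as.character(df$label)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(m) != nrow(m)) stop_arg("malformed RDM file: matrix is not square")
  if (!identical(colnames(m), labels)) {
    stop_arg("malformed RDM file: column labels do not match the label column")
  }
  storage.mode(m) <- "double"
  rdm(m, labels)
}

#' Write / read a semantic matrix as whitespace-delimited text
#'
#' One row per concept, a leading label column, then the embedding
#' coordinates at full precision.
#'
#' @param sm a [semantic_matrix()].
#' @param path file path.
#' @return `read_semantic_matrix` returns a [semantic_matrix()].
#' @export
write_semantic_matrix <- function(sm, path) {
  m <- matrix(fmt_num(sm$vectors), nrow(sm$vectors))
  utils::write.table(cbind(sm$concepts, m), path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_semantic_matrix
#' @export
read_semantic_matrix <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_arg("malformed semantic matrix file")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  semantic_matrix(as.character(df[[1]]), m)
}

#' Write / read property listings as long-format TSV
#'
#' Columns `participant`, `concept`, `category`, `count`; missing
#' (participant, concept) cells have no rows and are reconstructed as
#' flagged-missing on read.
#'
#' @param pl a `property_listings` object.
#' @param path file path.
#' @return `read_property_listings` returns a `property_listings`.
#' @export
write_property_listings <- function(pl, path) {
  rows <- list()
  for (p in seq_along(pl$participants)) {
    for (cc in seq_along(pl$concepts)) {
      if (pl$missing[p, cc]) next
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pl$participants[p], concept = pl$concepts[cc],
        category = pl$categories, count = pl$counts[p, cc, ],
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_property_listings
#' @export
read_property_listings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("participant", "concept", "category", "count")
  if (!all(need %in% names(df))) {
    stop_arg("property TSV must have columns participant, concept, category, count")
  }
  if (!all(df$category %in% PROPERTY_CATEGORIES)) {
    stop_arg("unknown feature categories in file")
  }
  participants <- unique(df$participant)
  concepts <- unique(df$concept)
  k <- length(PROPERTY_CATEGORIES)
  counts <- array(0L, c(length(participants), length(concepts), k),
                  dimnames = list(participants, concepts, PROPERTY_CATEGORIES))
  missing <- matrix(TRUE, length(participants), length(concepts),
                    dimnames = list(participants, concepts))
  pi_ <- match(df$participant, participants)
  ci_ <- match(df$concept, concepts)
  ki_ <- match(df$category, PROPERTY_CATEGORIES)
  counts[cbind(pi_, ci_, ki_)] <- as.integer(df$count)
  missing[cbind(pi_, ci_)] <- FALSE
  structure(list(participants = participants, concepts = concepts,
                 categories = PROPERTY_CATEGORIES, counts = counts,
                 missing = missing),
            class = "property_listings")
}

#' Write an RSA map or statistic map as NIfTI-1 (NaN background)
#'
#' @param map an `rsa_map` or [stat_map()].
#' @param path file path.
#' @export
write_map <- function(map, path) {
  vals <- if (inherits(map, "rsa_map")) map$values else map$values
  vs <- if (inherits(map, "rsa_map")) map$voxel_size else c(2, 2, 2)
  write_volume(vals, path, voxel_size = vs)
}

#' Write a cluster/overlap table as TSV
#'
#' @param report an `overlap_report` from [cluster_table()] or a
#'   `cluster_result`'s `clusters` data frame.
#' @param path file path.
#' @export
write_cluster_table <- function(report, path) {
  tab <- if (inherits(report, "overlap_report")) report$table else report
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
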