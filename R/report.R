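#' Percentage overlap between two binary masks
#'
#' `100 * |a AND b| / |a|`: the percentage of voxels of `a` that also
#' belong to `b` (e.g. significant RSA voxels falling inside a
#' localizer activation mask).  Undefined (NA, with a warning) when `a`
#' is empty.
#'
#' @param a,b logical (or 0/1) arrays on the same grid.
#' @return percentage in `[0, 100]`, or `NA` for empty `a`.
#' @export
overlap_percent <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_arg("masks must share the same grid")
  a <- a != 0
  b <- b != 0
  na <- sum(a)
  if (na == 0) {
    warning("overlap undefined: first mask is empty", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(a & b) / na
}

#' Cluster table with localizer overlaps and local maxima
#'
#' One row per reported peak: cluster id, cluster size, per-localizer
#' overlap percentage (percentage of the cluster's voxels inside each
#' localizer mask, 1 decimal), peak world coordinates (mm) and peak
#' statistic.  Local maxima within a cluster are reported greedily in
#' decreasing statistic order subject to a minimal separation of
#' `peak_sep_mm`, at most `max_peaks` per cluster.  Whole-map overlaps
#' (percentage of all significant voxels inside each localizer) are
#' returned alongside.
#'
#' @param result a `cluster_result` from [cluster_inference()].
#' @param localizers named list of binary masks on the same grid.
#' @param stat optional [stat_map()] used for peak values (default: the
#'   result's own map).
#' @param significant_only restrict the table to FWE-significant
#'   clusters (default `TRUE`).
#' @param peak_sep_mm minimal separation between reported peaks.
#' @param max_peaks maximal number of local maxima per cluster.
#' @return an `overlap_report`: list with `table` (data frame) and
#'   `map_overlap` (named percentages over the whole significance
#'   mask; `NA` when it is empty).
#' @export
cluster_table <- function(result, localizers = list(), stat = NULL,
                          significant_only = TRUE, peak_sep_mm = 8,
                          max_peaks = 16) {
  stat <- stat %||% result$stat
  dims <- dim(result$labels)
  if (!identical(dim(stat$values), dims)) stop_arg("statistic grid mismatch")
  for (nm in names(localizers)) {
    if (!identical(dim(localizers[[nm]]), dims)) {
      stop_arg("localizer '", nm, "' grid mismatch")
    }
  }
  voxel_size <- result$voxel_size
  tab <- result$clusters
  if (significant_only) tab <- tab[tab$significant, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    id <- tab$cluster[i]
    vox <- which(result$labels == id)
    sv <- stat$values[vox]
    ord <- order(sv, decreasing = TRUE)
    world <- ijk_to_world(lin_to_ijk(vox, dims), dims, voxel_size)
    sel <- integer(0)
    for (cand in ord) {
      if (length(sel) >= max_peaks) break
      if (length(sel) == 0 ||
          all(sqrt(colSums((t(world[sel, , drop = FALSE]) - world[cand, ])^2)) >=
              peak_sep_mm)) {
        sel <- c(sel, cand)
      }
    }
    ov <- vapply(localizers, function(loc) {
      cl_mask <- array(FALSE, dims)
      cl_mask[vox] <- TRUE
      round(overlap_percent(cl_mask, loc), 1)
    }, numeric(1))
    for (s in seq_along(sel)) {
      row <- data.frame(cluster = id, size = tab$size[i],
                        peak_x = world[sel[s], 1], peak_y = world[sel[s], 2],
                        peak_z = world[sel[s], 3], peak_stat = sv[sel[s]],
                        p_fwe = tab$p_fwe[i], is_cluster_peak = s == 1L)
      for (nm in names(ov)) row[[paste0("overlap_", nm)]] <- ov[[nm]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  table_out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(cluster = integer(0), size = integer(0), peak_x = numeric(0),
               peak_y = numeric(0), peak_z = numeric(0), peak_stat = numeric(0),
               p_fwe = numeric(0), is_cluster_peak = logical(0))
  }
  map_overlap <- if (length(localizers)) {
    if (sum(result$sig_mask) == 0) {
      stats::setNames(rep(NA_real_, length(localizers)), names(localizers))
    } else {
      vapply(localizers, function(loc) {
        round(overlap_percent(result$sig_mask, loc), 1)
      }, numeric(1))
    }
  } else {
    numeric(0)
  }
  structure(list(table = table_out, map_overlap = map_overlap),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n")
  if (length(x$map_overlap)) {
    cat("whole-map overlap (%):",
        paste(sprintf("%s %.1f", names(x$map_overlap), x$map_overlap), collapse = ", "),
        "\n")
  }
  print(x$table, digits = 3)
  invisible(x)
}
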