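#' Filter localization points by photon count
#'
#' Localizations exceeding a photon-count threshold are retained as
#' specific super-resolution localization points (SLPs); dimmer points
#' are discarded as background. Row order is preserved. The threshold is
#' an explicit parameter: it is an acquisition-dependent setting with no
#' universal value, and the applied value is recorded in the result.
#'
#' @param locs data frame with at least a `photons` column
#'   (localization list: `x_nm`, `y_nm`, `z_nm`, `photons`, `channel`,
#'   `frame`, ...).
#' @param photon_threshold nonnegative count; rows with
#'   `photons > photon_threshold` are kept.
#' @return the filtered data frame, with attribute `photon_threshold`.
#' @export
filter_slp <- function(locs, photon_threshold) {
  if (photon_threshold < 0) {
    stop_cm("photon threshold must be nonnegative",
            "cristamorph_argument_error")
  }
  stopifnot("photons" %in% names(locs))
  out <- locs[locs$photons > photon_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "photon_threshold") <- photon_threshold
  out
}

# shoelace area of a polygon given in order (nm^2)
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(seq_len(nrow(xy))[-1], 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Convex hull and hull area of a 2D point cluster
#'
#' Constructs the 2D convex hull around an SLP cluster (x, y only; the
#' hull is always computed in the lateral plane) and returns its area by
#' the shoelace formula, converted to um^2. Clusters with fewer than
#' three distinct, non-collinear points cannot be delineated and raise a
#' `cristamorph_degenerate_cluster_error`.
#'
#' @param xy_nm n x 2 matrix of point coordinates in nm.
#' @return list with `hull` (indices into the input rows, counter-
#'   clockwise cycle) and `area_um2`.
#' @export
convex_hull_area <- function(xy_nm) {
  xy <- as.matrix(xy_nm)[, 1:2, drop = FALSE]
  if (nrow(unique(xy)) < 3) {
    stop_cm("fewer than three distinct points: degenerate cluster",
            "cristamorph_degenerate_cluster_error")
  }
  hull <- rev(chull(xy)) # chull returns clockwise; store counterclockwise
  if (length(hull) < 3) {
    stop_cm("collinear points: degenerate cluster",
            "cristamorph_degenerate_cluster_error")
  }
  area_nm2 <- shoelace_area(xy[hull, , drop = FALSE])
  if (area_nm2 == 0) {
    stop_cm("collinear points: degenerate cluster",
            "cristamorph_degenerate_cluster_error")
  }
  list(hull = hull, area_um2 = area_nm2 / NM2_PER_UM2)
}

#' SLP density of a delineated mitochondrion
#'
#' Number of specific localization points divided by the convex-hull
#' area, SLP/um^2.
#'
#' @param n_slp SLP count (>= 0).
#' @param area_um2 hull area, um^2 (> 0).
#' @return density in SLP/um^2.
#' @export
slp_density <- function(n_slp, area_um2) {
  if (any(n_slp < 0)) stop_cm("n_slp must be nonnegative",
                              "cristamorph_argument_error")
  check_positive(area_um2, "area_um2")
  n_slp / area_um2
}

#' Hull-delineate every cluster of a localization list
#'
#' Cluster membership is an input assignment (`cluster_id` column):
#' clusters correspond to individual mitochondria identified in the
#' correlated confocal channel, not to an automatic spatial clustering.
#' Degenerate clusters (< 3 non-collinear points) are excluded and
#' reported in the `excluded` element.
#'
#' @param locs localization data frame with `x_nm`, `y_nm`, and
#'   `cluster_id` columns (already photon-filtered).
#' @return list with `clusters` (data frame: `cluster_id`, `n_slp`,
#'   `area_um2`, `slp_density`) and `excluded` (cluster ids).
#' @export
delineate_clusters <- function(locs) {
  stopifnot(all(c("x_nm", "y_nm", "cluster_id") %in% names(locs)))
  locs <- locs[!is.na(locs$cluster_id), , drop = FALSE]
  ids <- unique(locs$cluster_id)
  rows <- list()
  excluded <- character(0)
  for (id in ids) {
    sub <- locs[locs$cluster_id == id, c("x_nm", "y_nm"), drop = FALSE]
    hull <- tryCatch(convex_hull_area(as.matrix(sub)), error = function(e) e)
    if (inherits(hull, "cristamorph_degenerate_cluster_error")) {
      excluded <- c(excluded, as.character(id))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = id, n_slp = nrow(sub), area_um2 = hull$area_um2,
      slp_density = slp_density(nrow(sub), hull$area_um2),
      stringsAsFactors = FALSE)
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), n_slp = integer(0),
               area_um2 = numeric(0), slp_density = numeric(0))
  list(clusters = clusters, excluded = excluded)
}

#' Correlation of paired per-mitochondrion areas across two channels
#'
#' Used to validate that an inner-compartment label (e.g. cytochrome-c)
#' delineates the same organelle outline as an outer-membrane label
#' (e.g. TOM20): the hull areas of the same mitochondria measured in the
#' two channels should correlate near-perfectly. Pearson's R on the
#' paired areas.
#'
#' @param areas_a,areas_b equal-length area vectors (>= 3 pairs).
#' @return list with `r`, `p_value`, `n`.
#' @export
paired_area_correlation <- function(areas_a, areas_b) {
  if (length(areas_a) != length(areas_b) || length(areas_a) < 3) {
    stop_cm("need equal-length vectors with at least 3 pairs",
            "cristamorph_argument_error")
  }
  if (sd(areas_a) == 0 || sd(areas_b) == 0) {
    stop_cm("zero variance: correlation undefined",
            "cristamorph_degenerate_error")
  }
  ct <- cor.test(areas_a, areas_b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(areas_a))
}

#' Labeled volume of a postsynaptic-density (Homer) segmentation
#'
#' Measures the reconstructed volume of the postsynaptic labeling
#' associated with a bouton on a voxelized 3D segmentation: voxels are
#' grouped into 6-connected components and the largest component's
#' voxel count times the voxel volume is reported (satellite specks are
#' ignored).
#'
#' @param mask 3D logical array.
#' @param voxel_size_um voxel edge lengths in um (length 3).
#' @return list with `volume_um3` (largest component), `total_um3` (all
#'   true voxels) and `n_components`. Empty masks give zero with a
#'   warning.
#' @export
homer_volume <- function(mask, voxel_size_um) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  voxel_size_um <- rep_len(as.numeric(voxel_size_um), 3L)
  check_positive(voxel_size_um, "voxel_size_um")
  vox_vol <- prod(voxel_size_um)
  if (!any(mask)) {
    warn_cm("empty mask: volume is 0", "cristamorph_empty_mask_warning")
    return(list(volume_um3 = 0, total_um3 = 0, n_components = 0L))
  }
  lab <- cpp_label_components3d(as.logical(mask), dim(mask))
  counts <- tabulate(lab[lab > 0])
  list(volume_um3 = max(counts) * vox_vol,
       total_um3 = sum(counts) * vox_vol,
       n_components = length(counts))
}

#' Split a bouton population at the median postsynaptic volume
#'
#' Boutons with a postsynaptic (Homer) volume below the population
#' median form the low-performance (LP) group, boutons above it the
#' high-performance (HP) group. Records exactly at the median go to LP
#' (explicit tie rule). The median is the standard mid-order statistic.
#'
#' @param records data frame with a `homer_volume_um3` column.
#' @return the data frame with a `split_class` column and attribute
#'   `median_um3`.
#' @examples
#' median_split(data.frame(homer_volume_um3 = c(1, 2, 3, 4)))$split_class
#' @export
median_split <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop_cm("empty record set", "cristamorph_argument_error")
  }
  v <- records$homer_volume_um3
  if (is.null(v) || any(is.na(v))) {
    stop_cm("homer_volume_um3 must be present on every record",
            "cristamorph_validation_error")
  }
  med <- median(v)
  records$split_class <- ifelse(v <= med, "LP", "HP")
  attr(records, "median_um3") <- med
  records
}

#' Read / write localization lists as CSV
#'
#' Plain-CSV molecule lists with the column convention `x_nm`, `y_nm`,
#' `z_nm`, `photons`, `channel`, `frame`, and optionally `cluster_id`
#' and `truth_label`.
#'
#' @param locs localization data frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); data frame (reader).
#' @export
write_localizations <- function(locs, path) {
  write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
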