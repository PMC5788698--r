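#' Labeled voxel volume
#'
#' Container for a segmented tomographic (sub)volume: a 3D integer grid of
#' compartment labels with anisotropic voxel sizes and section-thickness
#' metadata. The thickness pair records beam-induced section thinning: the
#' reconstructed volume is thinner than the cut section, and measurements
#' must be rescaled in z accordingly (see [z_scale_factor()]).
#'
#' @param labels 3D integer array of compartment labels (0 = background).
#' @param voxel_size numeric length-3, voxel edge lengths in nm (x, y, z).
#' @param legend named integer vector mapping compartment name to label.
#'   Must cover every nonzero label present in `labels`.
#' @param original_thickness physical section thickness at cutting, nm.
#' @param reconstructed_thickness thickness of the reconstructed volume,
#'   nm; at most `original_thickness`.
#' @param interior_sets optional named list: for each membrane compartment,
#'   the compartment names whose voxels lie strictly inside it. Used by
#'   [mesh_from_labels()] to build mid-surface meshes of membrane shells.
#' @return an object of class `labeled_volume`.
#' @seealso [generate_mito_phantom()], [mesh_from_labels()]
#' @export
labeled_volume <- function(labels, voxel_size,
                           legend = mito_label_legend(),
                           original_thickness = voxel_size[3] * dim(labels)[3],
                           reconstructed_thickness = original_thickness,
                           interior_sets = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  check_positive(voxel_size, "voxel_size")
  check_positive(original_thickness, "original_thickness")
  check_positive(reconstructed_thickness, "reconstructed_thickness")
  if (reconstructed_thickness > original_thickness) {
    stop_cm("reconstructed thickness exceeds the original section thickness",
            "cristamorph_argument_error")
  }
  present <- setdiff(unique(as.integer(labels)), 0L)
  if (!all(present %in% legend)) {
    stop_cm("label legend does not cover every nonzero label",
            "cristamorph_argument_error")
  }
  structure(
    list(labels = labels, voxel_size = voxel_size, legend = legend,
         original_thickness = original_thickness,
         reconstructed_thickness = reconstructed_thickness,
         interior_sets = interior_sets %||% mito_interior_sets()),
    class = "labeled_volume")
}

#' Standard label legend for mitochondrial phantom volumes
#'
#' Compartments: outer mitochondrial membrane (omm), inner boundary
#' membrane (ibm), crista membrane (cm), matrix, crista lumen, and the
#' intermembrane space (ims) between OMM and IBM.
#'
#' @return named integer vector.
#' @export
mito_label_legend <- function() {
  c(background = 0L, omm = 1L, ibm = 2L, cm = 3L,
    matrix = 4L, crista_lumen = 5L, ims = 6L)
}

#' @rdname mito_label_legend
#' @export
mito_interior_sets <- function() {
  list(omm = c("ibm", "cm", "matrix", "crista_lumen", "ims"),
       ibm = c("cm", "matrix", "crista_lumen"),
       cm = "crista_lumen")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g nm\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  section thickness %g nm (reconstructed %g nm)\n",
              x$original_thickness, x$reconstructed_thickness))
  tab <- table(factor(as.integer(x$labels), levels = unname(x$legend),
                      labels = names(x$legend)))
  cat("  voxels per label:\n")
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat(sprintf("    %-13s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Write / read a labeled volume as multi-page TIFF plus JSON sidecar
#'
#' One 8-bit grayscale TIFF page per z-slice holds the integer labels;
#' voxel sizes, thickness metadata, the label legend and (optionally) the
#' phantom ground truth travel in a JSON sidecar next to it.
#'
#' @param vol a [labeled_volume()].
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @param ground_truth optional list (e.g. a `phantom_ground_truth`)
#'   stored verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
write_labeled_volume <- function(vol, path, ground_truth = NULL) {
  stopifnot(inherits(vol, "labeled_volume"))
  d <- dim(vol$labels)
  if (max(vol$labels) > 255L) {
    stop_cm("8-bit TIFF export supports at most 255 labels",
            "cristamorph_argument_error")
  }
  pages <- lapply(seq_len(d[3]), function(k) {
    # tiff stores samples in [0, 1]; keep labels exact at 8 bits
    t(vol$labels[, , k]) / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(
    voxel_size_nm = vol$voxel_size,
    original_thickness_nm = vol$original_thickness,
    reconstructed_thickness_nm = vol$reconstructed_thickness,
    legend = as.list(vol$legend),
    interior_sets = vol$interior_sets,
    ground_truth = if (!is.null(ground_truth)) unclass(ground_truth))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_labeled_volume
#' @export
read_labeled_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    t(round(p * 255))
  })
  d <- c(dim(slices[[1]]), length(slices))
  labels <- array(0L, dim = d)
  for (k in seq_along(slices)) labels[, , k] <- as.integer(slices[[k]])
  legend <- unlist(meta$legend)
  storage.mode(legend) <- "integer"
  vol <- labeled_volume(
    labels, voxel_size = meta$voxel_size_nm, legend = legend,
    original_thickness = meta$original_thickness_nm,
    reconstructed_thickness = meta$reconstructed_thickness_nm,
    interior_sets = meta$interior_sets)
  attr(vol, "ground_truth") <- meta$ground_truth
  vol
}
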