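#' Crista-membrane density
#'
#' CM density is the surface area of crista membrane per unit
#' mitochondrial volume (1/nm). It correlates with respiratory capacity:
#' more membrane in the same organelle volume accommodates more
#' electron-transport-chain complexes.
#'
#' @param a_cm crista membrane surface area, nm^2.
#' @param v_mito mitochondrial (OMM-enclosed) volume, nm^3; must be > 0.
#' @return CM density in 1/nm.
#' @examples
#' cm_density(100, 100) # 1
#' @export
cm_density <- function(a_cm, v_mito) {
  if (any(a_cm < 0)) stop_cm("a_cm must be nonnegative",
                             "cristamorph_argument_error")
  check_positive(v_mito, "v_mito")
  a_cm / v_mito
}

#' Crista shape factor (lamellarity)
#'
#' CM surface area divided by crista lumen volume (1/nm). Thin,
#' sheet-like (lamellar) cristae enclose little lumen per membrane area,
#' so higher values mean more lamellar cristae: a slab of lumen
#' thickness t approaches 2/t, a tubular crista of lumen radius rho
#' approaches 2/rho. Undefined when the lumen volume is zero, in which
#' case `NA` is returned with attribute `undefined = TRUE` (never 0).
#'
#' @param a_cm crista membrane surface area, nm^2.
#' @param v_lumen total crista lumen volume, nm^3.
#' @return CSF in 1/nm, or flagged `NA` when `v_lumen <= 0`.
#' @export
crista_shape_factor <- function(a_cm, v_lumen) {
  if (any(a_cm < 0)) stop_cm("a_cm must be nonnegative",
                             "cristamorph_argument_error")
  out <- ifelse(v_lumen > 0, a_cm / v_lumen, NA_real_)
  if (any(v_lumen <= 0)) attr(out, "undefined") <- TRUE
  out
}

#' Ratio of total CM surface between two groups
#'
#' Multiplies each group's CM density by its median mitochondrial volume
#' to obtain the CM surface carried by a typical organelle, and returns
#' the ratio `(density_a * volume_a) / (density_b * volume_b)`.
#'
#' @param density_a,density_b CM densities, 1/nm.
#' @param volume_a,volume_b median mitochondrial volumes, nm^3.
#' @return dimensionless ratio (group a over group b).
#' @examples
#' # how much more CM surface a typical high-activity bouton carries
#' group_cm_surface_ratio(0.0408, 119e6, 0.0227, 73.4e6) # about 2.9
#' @export
group_cm_surface_ratio <- function(density_a, volume_a, density_b, volume_b) {
  check_positive(c(density_a, volume_a, density_b, volume_b),
                 "densities and volumes")
  (density_a * volume_a) / (density_b * volume_b)
}

#' Measure the full set of ultrastructural parameters of one mitochondrion
#'
#' Runs the meshing pipeline on a labeled volume: builds mid-surface
#' meshes of the OMM, IBM and CM, stretches z-coordinates by the
#' volume's [z_scale_factor()] (coordinates are always scaled before any
#' measurement), closes open crista meshes with minimal planar caps, and
#' integrates areas and volumes. Mitochondrial volume is the volume
#' enclosed by the outer-membrane mesh; crista lumen volume is enclosed
#' by the CM mesh.
#'
#' @param vol a [labeled_volume()].
#' @param sigma_envelope smoothing bandwidth (voxels) for the large,
#'   smooth OMM/IBM envelopes, where staircase suppression dominates.
#' @param sigma_cm smoothing bandwidth for the crista membrane. Cristae
#'   carry the smallest curvature radii in the organelle and iso-surface
#'   smoothing shrinks a surface by about `sigma^2/2` times its total
#'   curvature, so a smaller bandwidth is used here.
#' @param id identifier copied to the output row.
#' @return one-row data frame of class `ultrastructure_measure` with
#'   columns `id`, `a_omm`, `a_ibm`, `a_cm` (nm^2), `v_mito`, `v_lumen`
#'   (nm^3), `cm_density`, `csf` (1/nm), and `n_cm_components`.
#' @export
measure_mitochondrion <- function(vol, sigma_envelope = 0.9,
                                  sigma_cm = 0.55, id = "mito_1") {
  stopifnot(inherits(vol, "labeled_volume"))
  f <- z_scale_factor(vol$original_thickness, vol$reconstructed_thickness)

  get_mesh <- function(comp, sigma) {
    m <- mesh_from_labels(vol, comp, method = "isosurface", sigma = sigma)
    m <- apply_z_scale(m, f)
    if (!is_watertight(m)) m <- cap_mesh_holes(m)
    m
  }

  omm <- get_mesh("omm", sigma_envelope)
  ibm <- get_mesh("ibm", sigma_envelope)
  a_omm <- surface_area(omm)
  v_mito <- enclosed_volume(omm)
  a_ibm <- surface_area(ibm)

  has_cm <- any(vol$labels == vol$legend[["cm"]])
  if (has_cm) {
    cm <- get_mesh("cm", sigma_cm)
    a_cm <- surface_area(cm)
    v_lumen <- enclosed_volume(cm)
    n_cm_comp <- cm$n_components
  } else {
    a_cm <- 0
    v_lumen <- 0
    n_cm_comp <- 0L
  }

  out <- data.frame(
    id = id, a_omm = a_omm, a_ibm = a_ibm, a_cm = a_cm,
    v_mito = v_mito, v_lumen = v_lumen,
    cm_density = cm_density(a_cm, v_mito),
    csf = as.numeric(crista_shape_factor(a_cm, v_lumen)),
    n_cm_components = n_cm_comp,
    stringsAsFactors = FALSE)
  class(out) <- c("ultrastructure_measure", "data.frame")
  out
}
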