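#' Serial-section synapse profile series
#'
#' Per-section measurements of synaptic appositions: on each serial
#' section the synapse appears as a chord whose length is recorded,
#' together with the active-zone id and a perforation flag.
#'
#' @param profiles data frame with columns `section` (integer), `az_id`,
#'   `chord_nm` (>= 0) and `perforated` (logical).
#' @param section_thickness section thickness in nm.
#' @return object of class `synapse_profile_series`.
#' @export
synapse_profile_series <- function(profiles, section_thickness) {
  check_positive(section_thickness, "section_thickness")
  if (nrow(profiles) > 0) {
    stopifnot(all(c("section", "az_id", "chord_nm", "perforated") %in%
                  names(profiles)))
    if (any(profiles$chord_nm < 0)) {
      stop_cm("chord lengths must be nonnegative", "cristamorph_argument_error")
    }
  }
  structure(list(profiles = profiles, section_thickness = section_thickness),
            class = "synapse_profile_series")
}

#' Active-zone area from serial sections
#'
#' The area of each active zone is the sum of its measured chord lengths
#' across consecutive sections multiplied by the section thickness
#' (chord-sum estimator), converted from nm^2 to um^2. Per-active-zone
#' subtotals are retained.
#'
#' @param series a [synapse_profile_series()].
#' @return list with `total_um2` and a data frame `per_az` (`az_id`,
#'   `area_um2`, `perforated`). An empty series yields zero with a
#'   warning.
#' @examples
#' s <- synapse_profile_series(
#'   data.frame(section = 1:3, az_id = "az1", chord_nm = c(300, 400, 300),
#'              perforated = FALSE), section_thickness = 60)
#' synapse_area(s)$total_um2 # 0.06
#' @export
synapse_area <- function(series) {
  stopifnot(inherits(series, "synapse_profile_series"))
  p <- series$profiles
  if (is.null(p) || nrow(p) == 0) {
    warn_cm("empty profile series: synapse area is 0",
            "cristamorph_empty_series_warning")
    return(list(total_um2 = 0,
                per_az = data.frame(az_id = character(0),
                                    area_um2 = numeric(0),
                                    perforated = logical(0))))
  }
  sums <- tapply(p$chord_nm, p$az_id, sum)
  perf <- tapply(p$perforated, p$az_id, any)
  per_az <- data.frame(az_id = names(sums),
                       area_um2 = as.numeric(sums) *
                         series$section_thickness / NM2_PER_UM2,
                       perforated = as.logical(perf),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(total_um2 = sum(per_az$area_um2), per_az = per_az)
}

#' Cavalieri volume from serial cross-section areas
#'
#' Classical Cavalieri estimator: the sum of cross-sectional areas
#' multiplied by section thickness.
#'
#' @param areas_nm2 per-section cross-section areas, nm^2.
#' @param section_thickness section thickness, nm.
#' @return volume in nm^3; an empty series yields zero with a warning.
#' @export
cavalieri_volume <- function(areas_nm2, section_thickness) {
  check_positive(section_thickness, "section_thickness")
  if (length(areas_nm2) == 0) {
    warn_cm("empty area series: volume is 0",
            "cristamorph_empty_series_warning")
    return(0)
  }
  if (any(areas_nm2 < 0)) {
    stop_cm("cross-section areas must be nonnegative",
            "cristamorph_argument_error")
  }
  sum(areas_nm2) * section_thickness
}

#' Classify a bouton as low- or high-performance
#'
#' Synaptic strength scales with active-zone geometry, so boutons are
#' classified by morphology alone: low-performance (LP) boutons have a
#' single, nonperforated active zone with total area strictly below the
#' threshold; high-performance (HP) boutons have multiple and/or
#' perforated active zone(s) with total area strictly above it. Records
#' matching neither rule (including an area exactly at the threshold)
#' remain `"unclassified"` - the rule uses strict inequalities on both
#' sides and the boundary is deliberately left unassigned.
#'
#' @param n_active_zones number of active zones.
#' @param any_perforated logical, any perforated active zone.
#' @param az_total_area_um2 total active-zone area, um^2.
#' @param threshold_um2 classification threshold, default 0.09 um^2.
#' @return `"LP"`, `"HP"` or `"unclassified"`.
#' @examples
#' classify_bouton(1, FALSE, 0.05) # LP
#' classify_bouton(2, FALSE, 0.15) # HP
#' classify_bouton(1, FALSE, 0.09) # unclassified (boundary)
#' @export
classify_bouton <- function(n_active_zones, any_perforated,
                            az_total_area_um2, threshold_um2 = 0.09) {
  if (any(is.na(c(n_active_zones, any_perforated, az_total_area_um2)))) {
    stop_cm("classification fields must not be missing",
            "cristamorph_validation_error")
  }
  if (az_total_area_um2 < 0 || n_active_zones < 1) {
    stop_cm("invalid bouton geometry", "cristamorph_validation_error")
  }
  if (n_active_zones == 1 && !any_perforated &&
      az_total_area_um2 < threshold_um2) {
    "LP"
  } else if ((n_active_zones > 1 || any_perforated) &&
             az_total_area_um2 > threshold_um2) {
    "HP"
  } else {
    "unclassified"
  }
}

#' Assemble a bouton record from serial-section measurements
#'
#' @param series a [synapse_profile_series()] for one bouton.
#' @param mito_areas_nm2 mitochondrial cross-section areas per section.
#' @param id bouton identifier.
#' @param group optional group label.
#' @param threshold_um2 LP/HP area threshold.
#' @return one-row data frame (`bouton_record`) with geometry, volume
#'   and class.
#' @export
bouton_record <- function(series, mito_areas_nm2 = numeric(0), id = "b1",
                          group = NA_character_, threshold_um2 = 0.09) {
  sa <- synapse_area(series)
  vol <- if (length(mito_areas_nm2)) {
    cavalieri_volume(mito_areas_nm2, series$section_thickness)
  } else {
    NA_real_
  }
  n_az <- nrow(sa$per_az)
  any_perf <- any(sa$per_az$perforated)
  out <- data.frame(
    id = id, group = group, n_active_zones = n_az,
    any_perforated = any_perf, az_total_area_um2 = sa$total_um2,
    mito_volume_nm3 = vol,
    class = classify_bouton(max(n_az, 1L), isTRUE(any_perf), sa$total_um2,
                            threshold_um2),
    stringsAsFactors = FALSE)
  class(out) <- c("bouton_record", "data.frame")
  out
}

# arc length of a 2-column polyline, nm
polyline_length <- function(polyline) {
  d <- diff(polyline)
  sum(sqrt(rowSums(d^2)))
}

#' Shortest distances from particles to a membrane polyline
#'
#' Segment-wise point-to-segment Euclidean distance in the section
#' plane.
#'
#' @param points n x 2 matrix of particle coordinates, nm.
#' @param polyline m x 2 matrix (m >= 2) of membrane vertices, nm.
#' @return numeric vector of distances, nm.
#' @export
particle_membrane_distance <- function(points, polyline) {
  points <- as.matrix(points)
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) {
    stop_cm("membrane polyline needs at least two points",
            "cristamorph_argument_error")
  }
  n <- nrow(points)
  best <- rep(Inf, n)
  for (s in seq_len(nrow(polyline) - 1)) {
    a <- polyline[s, ]
    b <- polyline[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (points[, 1] - a[1])^2 + (points[, 2] - a[2])^2
    } else {
      t <- ((points[, 1] - a[1]) * ab[1] + (points[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (points[, 1] - (a[1] + t * ab[1]))^2 +
            (points[, 2] - (a[2] + t * ab[2]))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Membrane association rule for immunogold particles
#'
#' A gold particle is counted as membrane-associated if it lies no
#' further from the membrane than the cutoff (inclusive at exactly the
#' cutoff). The 40-nm default accommodates the intracellular epitope
#' position plus the span of the primary and secondary antibodies
#' (about 15 nm each).
#'
#' @param distance_nm particle-to-membrane distance(s), nm; must be >= 0.
#' @param cutoff_nm association cutoff, nm (default 40).
#' @return logical vector.
#' @examples
#' gold_is_membrane_associated(c(39, 40, 41)) # TRUE TRUE FALSE
#' @export
gold_is_membrane_associated <- function(distance_nm, cutoff_nm = 40) {
  if (any(distance_nm < 0)) {
    stop_cm("distances must be nonnegative", "cristamorph_argument_error")
  }
  distance_nm <= cutoff_nm
}

#' Linear density of membrane-associated gold particles
#'
#' Number of membrane-associated particles per micrometre of membrane.
#'
#' @param points n x 2 particle coordinates, nm.
#' @param polyline membrane polyline, nm.
#' @param cutoff_nm association cutoff, nm.
#' @return list with `density_per_um`, `n_associated`, and
#'   `membrane_length_um`.
#' @export
gold_linear_density <- function(points, polyline, cutoff_nm = 40) {
  len_um <- polyline_length(as.matrix(polyline)) / NM_PER_UM
  if (!is.finite(len_um) || len_um <= 0) {
    stop_cm("membrane polyline has zero length", "cristamorph_argument_error")
  }
  points <- as.matrix(points)
  n_assoc <- if (nrow(points) == 0) 0L else {
    sum(gold_is_membrane_associated(
      particle_membrane_distance(points, polyline), cutoff_nm))
  }
  list(density_per_um = n_assoc / len_um, n_associated = as.integer(n_assoc),
       membrane_length_um = len_um)
}
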