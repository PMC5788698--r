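#' Simulate serial-section profiles of a synthetic bouton
#'
#' Slices analytically defined shapes at parallel z-planes spaced by the
#' section thickness, emulating a serial-section EM series: each active
#' zone is a planar disc (seen edge-on, it contributes a chord per
#' section), the mitochondrion is a solid of revolution contributing a
#' cross-section area per section. True areas and volumes are returned
#' alongside so stereological estimators can be validated against them.
#'
#' Sections are placed at `z = zmin + (k - 1/2) * thickness` (midpoint
#' convention) unless a random offset is requested.
#'
#' @param az_shapes list of active zones, each a list with `radius_nm`,
#'   optional `center_z_nm` (default 0) and `perforated` flag.
#' @param mito_shape `NULL` or a list: `kind` (`"sphere"` or
#'   `"capsule"`), `r_nm`, for capsules `L_nm` (axis in the section
#'   plane), optional `center_z_nm`.
#' @param section_thickness nm.
#' @param random_offset randomize the slicing offset within one
#'   thickness (uses `seed`); default `FALSE` (deterministic midpoint).
#' @param seed integer seed (used only when `random_offset`).
#' @return object of class `section_series_bundle`: list with `synapse`
#'   (a [synapse_profile_series()]), `mito_areas_nm2`,
#'   `section_thickness`, `true_az_area_um2`, `true_mito_volume_nm3`.
#' @export
generate_serial_bouton <- function(az_shapes, mito_shape = NULL,
                                   section_thickness = 60,
                                   random_offset = FALSE, seed = 1L) {
  check_positive(section_thickness, "section_thickness")
  t <- section_thickness
  offset <- if (random_offset) with_seed(seed, runif(1, 0, t)) else 0

  slice_chords <- function(radius, cz) {
    zmin <- cz - radius
    zmax <- cz + radius
    if (zmax - zmin < t) {
      warn_cm("shape thinner than one section: single-section series",
              "cristamorph_thin_shape_warning")
    }
    k0 <- floor((zmin - offset) / t)
    zk <- (k0:ceiling((zmax - offset) / t)) * t + offset + t / 2
    zk <- zk[zk > zmin & zk < zmax]
    list(z = zk, chord = 2 * sqrt(pmax(radius^2 - (zk - cz)^2, 0)))
  }

  profiles <- list()
  true_az <- 0
  for (i in seq_along(az_shapes)) {
    az <- az_shapes[[i]]
    cz <- az$center_z_nm %||% 0
    sl <- slice_chords(az$radius_nm, cz)
    true_az <- true_az + pi * az$radius_nm^2
    if (length(sl$z)) {
      profiles[[i]] <- data.frame(
        section = as.integer(round((sl$z - offset - t / 2) / t)),
        az_id = sprintf("az%d", i), chord_nm = sl$chord,
        perforated = isTRUE(az$perforated))
    }
  }
  prof <- if (length(profiles)) do.call(rbind, profiles) else
    data.frame(section = integer(0), az_id = character(0),
               chord_nm = numeric(0), perforated = logical(0))

  mito_areas <- numeric(0)
  true_v <- NA_real_
  if (!is.null(mito_shape)) {
    cz <- mito_shape$center_z_nm %||% 0
    r <- mito_shape$r_nm
    if (identical(mito_shape$kind, "capsule")) {
      L <- mito_shape$L_nm
      half <- r
      area_at <- function(dz) {
        # cross-section of a capsule whose axis lies in the section plane:
        # rectangle 2*sqrt(r^2-dz^2) x L plus a full disc of the same chord
        half_w <- sqrt(pmax(r^2 - dz^2, 0))
        2 * half_w * L + pi * half_w^2
      }
      true_v <- pi * r^2 * L + 4 / 3 * pi * r^3
    } else {
      half <- r
      area_at <- function(dz) pi * pmax(r^2 - dz^2, 0)
      true_v <- 4 / 3 * pi * r^3
    }
    zmin <- cz - half
    zmax <- cz + half
    if (zmax - zmin < t) {
      warn_cm("mitochondrion thinner than one section: single-section series",
              "cristamorph_thin_shape_warning")
    }
    k0 <- floor((zmin - offset) / t)
    zk <- (k0:ceiling((zmax - offset) / t)) * t + offset + t / 2
    zk <- zk[zk > zmin & zk < zmax]
    mito_areas <- area_at(zk - cz)
  }

  structure(
    list(synapse = synapse_profile_series(prof, t),
         mito_areas_nm2 = mito_areas, section_thickness = t,
         true_az_area_um2 = true_az / NM2_PER_UM2,
         true_mito_volume_nm3 = true_v),
    class = "section_series_bundle")
}

#' Specification of a synthetic STORM localization field
#'
#' @param footprints data frame of elliptical organelle footprints:
#'   `cx_um`, `cy_um`, `ax_um`, `ay_um` (semi-axes), `density_per_um2`
#'   (true specific-SLP surface density per footprint).
#' @param sigma_xy_nm lateral localization precision (Gaussian jitter
#'   applied to specific points), nm. Realistic dSTORM values are
#'   20-30 nm.
#' @param background_density_per_um2 uniform nonspecific localization
#'   density over the field.
#' @param photon_model list with `specific` and `background`, each
#'   `c(meanlog, sdlog)` of a lognormal photon-count distribution.
#'   Acquisition-dependent; defaults give well-separated distributions
#'   (specific ~ 5000, background ~ 500 photons).
#' @param field_size_um field width and height, um.
#' @param seed integer seed.
#' @return object of class `storm_field_spec`.
#' @export
storm_field_spec <- function(footprints,
                             sigma_xy_nm = 25,
                             background_density_per_um2 = 0,
                             photon_model = list(specific = c(8.5, 0.35),
                                                 background = c(6.2, 0.35)),
                             field_size_um = c(10, 10),
                             seed = 1L) {
  stopifnot(is.data.frame(footprints),
            all(c("cx_um", "cy_um", "ax_um", "ay_um", "density_per_um2") %in%
                names(footprints)))
  if (sigma_xy_nm < 0 || background_density_per_um2 < 0 ||
      any(footprints$density_per_um2 < 0)) {
    stop_cm("densities and sigma_xy must be nonnegative",
            "cristamorph_argument_error")
  }
  within_x <- footprints$cx_um - footprints$ax_um >= 0 &
    footprints$cx_um + footprints$ax_um <= field_size_um[1]
  within_y <- footprints$cy_um - footprints$ay_um >= 0 &
    footprints$cy_um + footprints$ay_um <= field_size_um[2]
  if (!all(within_x & within_y)) {
    stop_cm("footprints must lie within the field",
            "cristamorph_argument_error")
  }
  structure(list(footprints = footprints, sigma_xy_nm = sigma_xy_nm,
                 background_density_per_um2 = background_density_per_um2,
                 photon_model = photon_model,
                 field_size_um = rep_len(field_size_um, 2L),
                 seed = as.integer(seed)),
            class = "storm_field_spec")
}

#' Generate a synthetic STORM localization field
#'
#' Specific points are sampled uniformly inside each elliptical
#' footprint with Poisson counts at the footprint's density, then
#' jittered with isotropic Gaussian localization noise; background
#' points are uniform over the field. Photon counts are drawn from the
#' corresponding lognormal model and every point keeps its ground-truth
#' label and (for specific points) footprint id.
#'
#' @param spec a [storm_field_spec()].
#' @return localization data frame: `x_nm`, `y_nm`, `z_nm`, `photons`,
#'   `channel`, `frame`, `cluster_id`, `truth_label`.
#' @export
generate_storm_field <- function(spec) {
  stopifnot(inherits(spec, "storm_field_spec"))
  with_seed(spec$seed, {
    fp <- spec$footprints
    parts <- list()
    for (i in seq_len(nrow(fp))) {
      area <- pi * fp$ax_um[i] * fp$ay_um[i]
      n <- rpois(1, fp$density_per_um2[i] * area)
      if (n == 0) next
      r <- sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      x <- (fp$cx_um[i] + fp$ax_um[i] * r * cos(th)) * NM_PER_UM
      y <- (fp$cy_um[i] + fp$ay_um[i] * r * sin(th)) * NM_PER_UM
      parts[[length(parts) + 1L]] <- data.frame(
        x_nm = x + rnorm(n, 0, spec$sigma_xy_nm),
        y_nm = y + rnorm(n, 0, spec$sigma_xy_nm),
        z_nm = 0,
        photons = rlnorm(n, spec$photon_model$specific[1],
                         spec$photon_model$specific[2]),
        channel = 1L, frame = 0L,
        cluster_id = sprintf("fp%d", i), truth_label = "specific",
        stringsAsFactors = FALSE)
    }
    nbg <- rpois(1, spec$background_density_per_um2 *
                   prod(spec$field_size_um))
    if (nbg > 0) {
      parts[[length(parts) + 1L]] <- data.frame(
        x_nm = runif(nbg, 0, spec$field_size_um[1]) * NM_PER_UM,
        y_nm = runif(nbg, 0, spec$field_size_um[2]) * NM_PER_UM,
        z_nm = 0,
        photons = rlnorm(nbg, spec$photon_model$background[1],
                         spec$photon_model$background[2]),
        channel = 1L, frame = 0L,
        cluster_id = NA_character_, truth_label = "background",
        stringsAsFactors = FALSE)
    }
    out <- if (length(parts)) do.call(rbind, parts) else
      data.frame(x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
                 photons = numeric(0), channel = integer(0),
                 frame = integer(0), cluster_id = character(0),
                 truth_label = character(0))
    if (nrow(out)) out$frame <- seq_len(nrow(out))
    rownames(out) <- NULL
    attr(out, "rng") <- RNGkind()[1]
    out
  })
}

#' Specification of a synthetic immunogold particle field
#'
#' @param membrane_polyline m x 2 matrix of membrane vertices, nm.
#' @param specific_linear_density specific particles per um of membrane.
#' @param distance_sigma_nm Gaussian spread of specific particles
#'   perpendicular to the membrane, nm.
#' @param background_areal_density nonspecific particles per um^2.
#' @param field_size_nm field width/height for background placement, nm.
#' @param seed integer seed.
#' @return object of class `gold_field_spec`.
#' @export
gold_field_spec <- function(membrane_polyline,
                            specific_linear_density = 4.87,
                            distance_sigma_nm = 12,
                            background_areal_density = 0,
                            field_size_nm = c(5000, 5000),
                            seed = 1L) {
  membrane_polyline <- as.matrix(membrane_polyline)
  if (nrow(membrane_polyline) < 2) {
    stop_cm("membrane polyline needs at least two points",
            "cristamorph_argument_error")
  }
  if (specific_linear_density < 0 || background_areal_density < 0 ||
      distance_sigma_nm < 0) {
    stop_cm("densities and sigma must be nonnegative",
            "cristamorph_argument_error")
  }
  structure(list(membrane_polyline = membrane_polyline,
                 specific_linear_density = specific_linear_density,
                 distance_sigma_nm = distance_sigma_nm,
                 background_areal_density = background_areal_density,
                 field_size_nm = rep_len(field_size_nm, 2L),
                 seed = as.integer(seed)),
            class = "gold_field_spec")
}

#' Generate a synthetic immunogold particle field
#'
#' Specific particles are placed along the membrane polyline with
#' Poisson counts at the stated linear density, positions uniform in
#' arc length, and signed Gaussian offsets perpendicular to the local
#' segment; background particles are uniform over the field. Ground
#' truth labels are retained.
#'
#' @param spec a [gold_field_spec()].
#' @return data frame: `x_nm`, `y_nm`, `truth_label`.
#' @export
generate_gold_field <- function(spec) {
  stopifnot(inherits(spec, "gold_field_spec"))
  with_seed(spec$seed, {
    poly <- spec$membrane_polyline
    seg <- diff(poly)
    seg_len <- sqrt(rowSums(seg^2))
    total <- sum(seg_len)
    n_spec <- rpois(1, spec$specific_linear_density * total / NM_PER_UM)
    parts <- list()
    if (n_spec > 0) {
      s <- runif(n_spec, 0, total)
      cum <- c(0, cumsum(seg_len))
      idx <- findInterval(s, cum, rightmost.closed = TRUE)
      idx[idx > nrow(seg)] <- nrow(seg)
      frac <- (s - cum[idx]) / seg_len[idx]
      base <- poly[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
      normal <- cbind(-seg[idx, 2], seg[idx, 1]) / seg_len[idx]
      off <- rnorm(n_spec, 0, spec$distance_sigma_nm)
      parts[[1]] <- data.frame(x_nm = base[, 1] + off * normal[, 1],
                               y_nm = base[, 2] + off * normal[, 2],
                               truth_label = "specific",
                               stringsAsFactors = FALSE)
    }
    area_um2 <- prod(spec$field_size_nm) / NM2_PER_UM2
    n_bg <- rpois(1, spec$background_areal_density * area_um2)
    if (n_bg > 0) {
      parts[[length(parts) + 1L]] <- data.frame(
        x_nm = runif(n_bg, 0, spec$field_size_nm[1]),
        y_nm = runif(n_bg, 0, spec$field_size_nm[2]),
        truth_label = "background", stringsAsFactors = FALSE)
    }
    out <- if (length(parts)) do.call(rbind, parts) else
      data.frame(x_nm = numeric(0), y_nm = numeric(0),
                 truth_label = character(0))
    rownames(out) <- NULL
    attr(out, "rng") <- RNGkind()[1]
    out
  })
}

# lognormal parameters matching a target median and quartile ratio
lognormal_from_median_iqr <- function(median, q1, q3) {
  if (median <= 0 || q1 <= 0) {
    stop_cm("medians and quartiles must be positive",
            "cristamorph_spec_error")
  }
  if (q1 > q3) {
    stop_cm("infeasible IQR: lower quartile above upper",
            "cristamorph_spec_error")
  }
  if (!(q1 <= median && median <= q3)) {
    stop_cm("IQR bounds must bracket the median", "cristamorph_spec_error")
  }
  # two-parameter lognormal: median fixes meanlog; the quartile ratio
  # fixes sdlog (quartiles of the fit are symmetric in log space)
  list(meanlog = log(median),
       sdlog = log(q3 / q1) / (2 * qnorm(0.75)))
}

#' Specification of a synthetic two-group bouton cohort
#'
#' Generative parameters per group: for every metric a target median
#' and interquartile range, realized with a lognormal distribution
#' whose median matches the target exactly and whose quartile ratio
#' matches the target IQR as closely as a two-parameter lognormal
#' allows (median + quartile-ratio matching). Lognormal is the natural
#' family here: morphometric quantities are positive and right-skewed.
#'
#' @param groups named list; each element is a list with `n` (>= 2) and
#'   `metrics`, a named list of `c(median, q1, q3)` targets.
#' @param seed integer seed.
#' @return object of class `population_spec`.
#' @examples
#' ps <- population_spec(list(
#'   PV = list(n = 10, metrics = list(cm_density = c(0.0408, 0.0389, 0.0519))),
#'   CB1R = list(n = 10, metrics = list(cm_density = c(0.0227, 0.0218, 0.0256)))))
#' head(generate_population(ps))
#' @export
population_spec <- function(groups, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  for (g in names(groups)) {
    if ((groups[[g]]$n %||% 0) < 2) {
      stop_cm("group sizes must be at least 2", "cristamorph_spec_error")
    }
    for (m in names(groups[[g]]$metrics)) {
      tgt <- groups[[g]]$metrics[[m]]
      lognormal_from_median_iqr(tgt[1], tgt[2], tgt[3]) # validates
    }
  }
  structure(list(groups = groups, seed = as.integer(seed),
                 family = "lognormal"),
            class = "population_spec")
}

#' Generate a synthetic bouton cohort
#'
#' Draws per-group, per-metric lognormal samples from a
#' [population_spec()]. Metrics are drawn independently within a group;
#' between-metric correlation is not modeled (group membership itself
#' carries the joint structure of interest).
#'
#' @param spec a [population_spec()].
#' @return data frame with `group`, `bouton_id`, and one column per
#'   metric; attribute `rng` records the generator algorithm.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, {
    parts <- lapply(names(spec$groups), function(g) {
      gs <- spec$groups[[g]]
      df <- data.frame(group = g,
                       bouton_id = sprintf("%s_%d", g, seq_len(gs$n)),
                       stringsAsFactors = FALSE)
      for (m in names(gs$metrics)) {
        tgt <- gs$metrics[[m]]
        par <- lognormal_from_median_iqr(tgt[1], tgt[2], tgt[3])
        df[[m]] <- if (par$sdlog == 0) rep(tgt[1], gs$n) else
          rlnorm(gs$n, par$meanlog, par$sdlog)
      }
      df
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    attr(out, "rng") <- RNGkind()[1]
    out
  })
}

#' Reference cohort targets for hippocampal presynaptic mitochondria
#'
#' Default generative targets (`c(median, q1, q3)` per metric) for the
#' two study systems the synthetic cohort emulates: perisomatic
#' GABAergic boutons of hippocampal CA1, where fast-spiking PV+ basket
#' cells are the high-activity population and CB1R+ basket cells the
#' low-activity one, and glutamatergic perforant-path boutons of the
#' dentate gyrus (DG) split into high-performance (HP) and
#' low-performance (LP) classes by active-zone geometry. Values are
#' published group medians/IQRs of CM density (1/nm), crista shape
#' factor (1/nm), convex-hull area (um^2), cytochrome-c SLP density
#' (SLP/um^2), mitochondrial volume (nm^3) and postsynaptic (Homer)
#' volume (um^3). Where a dispersion was not reported (CA1
#' mitochondrial volumes are literature medians), the relative IQR of
#' the corresponding DG metric is reused; this affects only cohort
#' dispersion, never the medians.
#'
#' @return named list of group target lists, suitable for
#'   [population_spec()].
#' @export
ca1_reference_targets <- function() {
  list(
    PV = list(n = 10, metrics = list(
      cm_density = c(0.0408, 0.0389, 0.0519),
      csf = c(0.233, 0.218, 0.251),
      hull_area_um2 = c(0.287, 0.158, 0.368),
      slp_density = c(565.7, 434.8, 725.7),
      mito_volume_nm3 = c(119e6, 119e6 * 0.60, 119e6 * 1.11))),
    CB1R = list(n = 10, metrics = list(
      cm_density = c(0.0227, 0.0218, 0.0256),
      csf = c(0.191, 0.147, 0.220),
      hull_area_um2 = c(0.164, 0.098, 0.203),
      slp_density = c(461.1, 378.8, 612.0),
      mito_volume_nm3 = c(73.4e6, 73.4e6 * 0.69, 73.4e6 * 1.46))))
}

#' @rdname ca1_reference_targets
#' @export
dg_reference_targets <- function() {
  list(
    HP = list(n = 10, metrics = list(
      cm_density = c(0.0552, 0.0509, 0.0587),
      csf = c(0.268, 0.237, 0.301),
      slp_density = c(598.5, 455.6, 822.0),
      mito_volume_nm3 = c(41.8e6, 25e6, 46.5e6),
      homer_volume_um3 = c(0.0365, 0.0282, 0.0578))),
    LP = list(n = 9, metrics = list(
      cm_density = c(0.0262, 0.0258, 0.0290),
      csf = c(0.195, 0.190, 0.219),
      slp_density = c(370.8, 296.3, 440.7),
      mito_volume_nm3 = c(18.9e6, 13e6, 27.6e6),
      homer_volume_um3 = c(0.0162, 0.0150, 0.0265))))
}
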