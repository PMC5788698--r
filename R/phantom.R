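#' Specification of a mitochondrial voxel phantom
#'
#' Describes an idealized mitochondrion used to generate labeled volumes
#' with exactly known geometry: an envelope (outer membrane mid-surface)
#' that is either a capsule (cylinder with hemispherical caps) or an
#' ellipsoid, an inner boundary membrane (IBM) offset inward by the
#' membrane separation, and a stack of cristae modeled as parallel
#' rounded lamellar slabs or parallel capsule tubes inside the IBM, both
#' with smoothly curved rims as in real cristae. All closed-form
#' areas/volumes of these shapes are available analytically, which makes
#' the phantom a ground-truth oracle for the meshing pipeline.
#'
#' @param envelope_kind `"capsule"` or `"ellipsoid"`.
#' @param envelope_dims named numeric, nm. Capsule: `L` (cylinder length)
#'   and `r` (radius). Ellipsoid: semi-axes `a`, `b`, `c` (x, y, z).
#' @param membrane_separation OMM-to-IBM gap in nm.
#' @param crista_model `"lamellar"`, `"tubular"` or `"none"`.
#' @param n_cristae number of cristae (>= 0).
#' @param crista_dims named numeric, nm. Lamellar: width `w`, height `h`,
#'   lumen thickness `t`, center spacing `s` (requires `t < s`). Tubular:
#'   radius `rho`, length `len`, spacing `s`.
#' @param voxel_size voxel edge length in nm (scalar or per-axis). For
#'   the stated recovery tolerances the voxel should be at most a third
#'   of the smallest feature size, defined as the smallest surface
#'   curvature radius in the phantom (`t/2` for lamellar cristae, `rho`
#'   for tubular ones; see [phantom_feature_size()]).
#' @param seed integer seed recorded with the phantom.
#' @return an object of class `mito_phantom_spec`.
#' @examples
#' spec <- mito_phantom_spec()
#' phantom_ground_truth(spec)
#' @export
mito_phantom_spec <- function(envelope_kind = c("capsule", "ellipsoid"),
                              envelope_dims = c(L = 600, r = 200),
                              membrane_separation = 20,
                              crista_model = c("lamellar", "tubular", "none"),
                              n_cristae = 5,
                              crista_dims = c(w = 220, h = 160, t = 24, s = 90),
                              voxel_size = 4,
                              seed = 1L) {
  envelope_kind <- match.arg(envelope_kind)
  crista_model <- match.arg(crista_model)
  envelope_dims <- unlist(envelope_dims)
  crista_dims <- unlist(crista_dims)
  check_positive(envelope_dims, "envelope_dims")
  check_positive(membrane_separation, "membrane_separation")
  check_positive(voxel_size, "voxel_size")
  if (n_cristae < 0 || n_cristae != round(n_cristae)) {
    stop_cm("n_cristae must be a nonnegative integer",
            "cristamorph_argument_error")
  }
  need <- if (envelope_kind == "capsule") c("L", "r") else c("a", "b", "c")
  if (!all(need %in% names(envelope_dims))) {
    stop_cm(sprintf("envelope_dims must name %s", paste(need, collapse = ", ")),
            "cristamorph_argument_error")
  }
  if (crista_model != "none" && n_cristae > 0) {
    need_c <- if (crista_model == "lamellar") c("w", "h", "t", "s")
              else c("rho", "len", "s")
    if (!all(need_c %in% names(crista_dims))) {
      stop_cm(sprintf("crista_dims must name %s",
                      paste(need_c, collapse = ", ")),
              "cristamorph_argument_error")
    }
    check_positive(crista_dims[need_c], "crista_dims")
    if (crista_model == "lamellar" && crista_dims["t"] >= crista_dims["s"]) {
      stop_cm("lamellar lumen thickness t must be smaller than spacing s",
              "cristamorph_argument_error")
    }
  }
  structure(
    list(envelope_kind = envelope_kind, envelope_dims = envelope_dims,
         membrane_separation = membrane_separation,
         crista_model = crista_model, n_cristae = as.integer(n_cristae),
         crista_dims = crista_dims,
         voxel_size = rep_len(as.numeric(voxel_size), 3L),
         seed = as.integer(seed)),
    class = "mito_phantom_spec")
}

# surface area of an ellipsoid with semi-axes a, b, c by midpoint
# quadrature of the parametric area element (absolute accuracy far below
# the sub-percent tolerances asserted on phantoms)
ellipsoid_area <- function(a, b, c, n = 600L) {
  th <- (seq_len(n) - 0.5) * pi / n
  ph <- (seq_len(n) - 0.5) * 2 * pi / n
  st <- sin(th); ct <- cos(th)
  cp2 <- cos(ph)^2; sp2 <- sin(ph)^2
  integrand <- outer(seq_len(n), seq_len(n), function(i, j) {
    s <- st[i]; cth <- ct[i]
    s * sqrt(b^2 * c^2 * s^2 * cp2[j] + a^2 * c^2 * s^2 * sp2[j] +
             a^2 * b^2 * cth^2)
  })
  sum(integrand) * (pi / n) * (2 * pi / n)
}

#' Smallest resolvable feature size of a phantom
#'
#' The smallest surface curvature radius in the phantom: `t/2` for
#' rounded lamellar cristae (rim radius), `rho` for tubular cristae,
#' and the smallest envelope radius when there are no cristae. Recovery
#' tolerances are claimed for `voxel_size <= phantom_feature_size / 3`
#' on singly-curved surfaces; doubly-curved tube caps need about twice
#' that linear resolution (see [seeded_phantom_grid()]).
#'
#' @param spec a [mito_phantom_spec()].
#' @return feature size in nm.
#' @export
phantom_feature_size <- function(spec) {
  stopifnot(inherits(spec, "mito_phantom_spec"))
  env_min <- if (spec$envelope_kind == "capsule") {
    unname(spec$envelope_dims["r"])
  } else {
    min(spec$envelope_dims[c("a", "b", "c")])
  }
  if (spec$n_cristae == 0 || spec$crista_model == "none") return(env_min)
  crista <- if (spec$crista_model == "lamellar") {
    unname(spec$crista_dims["t"]) / 2
  } else {
    unname(spec$crista_dims["rho"])
  }
  min(env_min, crista)
}

# does every crista sit strictly inside the IBM with meshing clearance?
# (same corner test generate_mito_phantom applies before voxelizing)
phantom_fits <- function(spec) {
  sdf_ibm_f <- envelope_sdf_fun(spec, offset = spec$membrane_separation)
  clearance <- 2 * max(spec$voxel_size)
  for (xc in crista_centers(spec)) {
    bb <- crista_bbox(spec, xc)
    corners <- as.matrix(expand.grid(bb[1, ], bb[2, ], bb[3, ]))
    if (any(sdf_ibm_f(corners[, 1], corners[, 2], corners[, 3]) >
            -clearance)) {
      return(FALSE)
    }
  }
  TRUE
}

# crista center positions along the envelope long axis (x), nm
crista_centers <- function(spec) {
  n <- spec$n_cristae
  if (n == 0 || spec$crista_model == "none") return(numeric(0))
  s <- unname(spec$crista_dims["s"])
  (seq_len(n) - (n + 1) / 2) * s
}

#' Closed-form ground truth for a phantom specification
#'
#' Computes membrane areas, volumes, CM density and crista shape factor
#' (CSF) of the phantom directly from its geometry: capsule OMM area
#' `2*pi*r*L + 4*pi*r^2`; lamellar cristae are rounded slabs (a core
#' rectangle `w x h` dilated by a ball of radius `t/2`, matching the
#' curved rims of real cristae) with exact Steiner closed forms, CM area
#' `2*w*h + pi*t*(w+h) + pi*t^2` and lumen volume
#' `w*h*t + pi*t^2*(w+h)/4 + pi*t^3/6` per crista; tubular cristae are
#' capsules with CM area `2*pi*rho*len + 4*pi*rho^2` and lumen
#' `pi*rho^2*len + 4/3*pi*rho^3`. The ellipsoid area uses
#' high-resolution quadrature of the exact area element. CM density is
#' CM area over mitochondrial (OMM-enclosed) volume; CSF is CM area over
#' crista lumen volume and is undefined (NA, flagged) when there are no
#' cristae.
#'
#' @param spec a [mito_phantom_spec()].
#' @return object of class `phantom_ground_truth`: list with elements
#'   `a_omm`, `a_ibm`, `a_cm` (nm^2), `v_mito`, `v_lumen` (nm^3),
#'   `cm_density`, `csf` (1/nm), and `csf_defined`.
#' @export
phantom_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "mito_phantom_spec"))
  g <- spec$membrane_separation
  if (spec$envelope_kind == "capsule") {
    L <- unname(spec$envelope_dims["L"]); r <- unname(spec$envelope_dims["r"])
    if (g >= r) stop_cm("membrane separation exceeds capsule radius",
                        "cristamorph_geometry_error")
    a_omm <- 2 * pi * r * L + 4 * pi * r^2
    v_mito <- pi * r^2 * L + 4 / 3 * pi * r^3
    r2 <- r - g
    a_ibm <- 2 * pi * r2 * L + 4 * pi * r2^2
  } else {
    ax <- unname(spec$envelope_dims[c("a", "b", "c")])
    if (g >= min(ax)) stop_cm("membrane separation exceeds smallest semi-axis",
                              "cristamorph_geometry_error")
    a_omm <- ellipsoid_area(ax[1], ax[2], ax[3])
    v_mito <- 4 / 3 * pi * prod(ax)
    a_ibm <- ellipsoid_area(ax[1] - g, ax[2] - g, ax[3] - g)
  }
  n <- spec$n_cristae
  if (spec$crista_model == "lamellar" && n > 0) {
    w <- unname(spec$crista_dims["w"]); h <- unname(spec$crista_dims["h"])
    t <- unname(spec$crista_dims["t"])
    # rounded slab (core rectangle w x h dilated by a ball of radius t/2):
    # two flat faces, half-cylinder rim along the perimeter, sphere at the
    # corners (Steiner formula for a dilated convex polygon)
    a_cm <- n * (2 * w * h + pi * t * (w + h) + pi * t^2)
    v_lumen <- n * (w * h * t + pi * t^2 * (w + h) / 4 + pi * t^3 / 6)
  } else if (spec$crista_model == "tubular" && n > 0) {
    rho <- unname(spec$crista_dims["rho"])
    len <- unname(spec$crista_dims["len"])
    # capsule tube: cylinder with hemispherical caps
    a_cm <- n * (2 * pi * rho * len + 4 * pi * rho^2)
    v_lumen <- n * (pi * rho^2 * len + 4 / 3 * pi * rho^3)
  } else {
    a_cm <- 0
    v_lumen <- 0
  }
  csf_defined <- v_lumen > 0
  structure(
    list(a_omm = a_omm, a_ibm = a_ibm, a_cm = a_cm,
         v_mito = v_mito, v_lumen = v_lumen,
         cm_density = a_cm / v_mito,
         csf = if (csf_defined) a_cm / v_lumen else NA_real_,
         csf_defined = csf_defined),
    class = "phantom_ground_truth")
}

# signed distance helpers (vectorized over voxel coordinate arrays)

sdf_capsule_x <- function(X, Y, Z, r, L) {
  q <- pmax(abs(X) - L / 2, 0)
  sqrt(q * q + Y * Y + Z * Z) - r
}

sdf_ellipsoid <- function(X, Y, Z, a, b, c) {
  f <- sqrt((X / a)^2 + (Y / b)^2 + (Z / c)^2)
  g <- sqrt((X / a^2)^2 + (Y / b^2)^2 + (Z / c^2)^2)
  d <- f * (f - 1) / pmax(g, 1e-300)
  d[f < 1e-9] <- -min(a, b, c)
  d
}

# rounded slab: all points within t/2 of the core rectangle w x h lying
# in the y-z plane at x = xc (smooth surface, exact Steiner closed forms)
sdf_rounded_slab_x <- function(X, Y, Z, xc, w, h, t) {
  qy <- pmax(abs(Y) - w / 2, 0)
  qz <- pmax(abs(Z) - h / 2, 0)
  sqrt((X - xc)^2 + qy^2 + qz^2) - t / 2
}

# capsule tube with axis along y, centered at (xc, 0, 0)
sdf_tube_y <- function(X, Y, Z, xc, rho, len) {
  qy <- pmax(abs(Y) - len / 2, 0)
  sqrt((X - xc)^2 + qy^2 + Z^2) - rho
}

envelope_sdf_fun <- function(spec, offset = 0) {
  if (spec$envelope_kind == "capsule") {
    L <- unname(spec$envelope_dims["L"])
    r <- unname(spec$envelope_dims["r"]) - offset
    function(X, Y, Z) sdf_capsule_x(X, Y, Z, r, L)
  } else {
    ax <- unname(spec$envelope_dims[c("a", "b", "c")]) - offset
    function(X, Y, Z) sdf_ellipsoid(X, Y, Z, ax[1], ax[2], ax[3])
  }
}

crista_sdf_fun <- function(spec, xc) {
  if (spec$crista_model == "lamellar") {
    w <- unname(spec$crista_dims["w"]); h <- unname(spec$crista_dims["h"])
    t <- unname(spec$crista_dims["t"])
    function(X, Y, Z) sdf_rounded_slab_x(X, Y, Z, xc, w, h, t)
  } else {
    rho <- unname(spec$crista_dims["rho"])
    len <- unname(spec$crista_dims["len"])
    function(X, Y, Z) sdf_tube_y(X, Y, Z, xc, rho, len)
  }
}

# axis-aligned bounding half-extents of one crista centered at xc
crista_bbox <- function(spec, xc) {
  d <- spec$crista_dims
  if (spec$crista_model == "lamellar") {
    rbind(xc + c(-1, 1) * d[["t"]] / 2,
          c(-1, 1) * (d[["w"]] + d[["t"]]) / 2,
          c(-1, 1) * (d[["h"]] + d[["t"]]) / 2)
  } else {
    rbind(xc + c(-1, 1) * d[["rho"]],
          c(-1, 1) * (d[["len"]] / 2 + d[["rho"]]),
          c(-1, 1) * d[["rho"]])
  }
}

#' Seeded grid of phantom specifications for recovery validation
#'
#' Draws `n` random phantom specifications spanning the supported
#' geometry space (capsule and ellipsoid envelopes, lamellar and tubular
#' cristae) with dimensions in realistic presynaptic ranges, each at the
#' validated resolution for its geometry: one third of the rim curvature
#' radius (`t/6`) for lamellae and one eighth of the tube radius for
#' tubular cristae, whose doubly-curved caps shift twice as fast under
#' iso-surface smoothing. Used to validate that the meshing pipeline
#' recovers the analytic ground truth across geometries.
#'
#' @param n number of specifications.
#' @param seed integer seed.
#' @return list of [mito_phantom_spec()] objects.
#' @export
seeded_phantom_grid <- function(n = 10, seed = 1L) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    tubular <- i %% 2 == 0
    ellipsoid <- i %% 4 %in% c(2, 3)
    if (ellipsoid) {
      kind <- "ellipsoid"
      dims <- c(a = runif(1, 330, 390), b = runif(1, 260, 300),
                c = runif(1, 230, 260))
    } else {
      kind <- "capsule"
      dims <- c(L = runif(1, 500, 620), r = runif(1, 200, 230))
    }
    # resolution per convergence scans: >= 3 voxels per curvature radius
    # for singly-curved lamella rims, >= 8 per tube radius for the
    # doubly-curved tube caps (level-set shift grows with kappa1 + kappa2)
    if (tubular) {
      rho <- runif(1, 28, 38)
      cd <- c(rho = rho, len = runif(1, 170, 230),
              s = 2 * rho + runif(1, 25, 45))
      nc <- sample(3:5, 1)
      vox <- rho / 8
    } else {
      t <- runif(1, 24, 34)
      cd <- c(w = runif(1, 160, 210), h = runif(1, 120, 150), t = t,
              s = t + runif(1, 45, 65))
      nc <- sample(3:5, 1)
      vox <- t / 6
    }
    repeat {
      sp <- mito_phantom_spec(envelope_kind = kind, envelope_dims = dims,
                              membrane_separation = 20, crista_model =
                                if (tubular) "tubular" else "lamellar",
                              n_cristae = nc, crista_dims = cd,
                              voxel_size = vox, seed = seed + i)
      if (phantom_fits(sp) || nc <= 2) break
      nc <- nc - 1L # drop outermost cristae until the stack fits
    }
    sp
  }))
}

#' Generate a labeled mitochondrial phantom volume
#'
#' Voxelizes a [mito_phantom_spec()] into a [labeled_volume()] whose
#' compartments are the OMM, IBM and CM membrane shells (each about two
#' voxels thick, centered on the analytic mid-surface), the matrix, the
#' crista lumina and the intermembrane space, and returns it together
#' with the closed-form [phantom_ground_truth()]. Membrane shells are
#' centered on the true surfaces so that mid-surface meshing recovers
#' the analytic areas.
#'
#' @param spec a [mito_phantom_spec()].
#' @param max_voxels refuse to build grids larger than this (memory
#'   guard); exceeded size raises a `cristamorph_size_error`.
#' @param pad_voxels background padding on every side, in voxels.
#' @return list with elements `volume` ([labeled_volume()]) and
#'   `ground_truth` ([phantom_ground_truth()]).
#' @examples
#' p <- generate_mito_phantom(mito_phantom_spec(voxel_size = 16))
#' p$ground_truth$cm_density
#' @export
generate_mito_phantom <- function(spec, max_voxels = 4e7, pad_voxels = 6L) {
  stopifnot(inherits(spec, "mito_phantom_spec"))
  truth <- phantom_ground_truth(spec)
  vs <- spec$voxel_size
  vmax <- max(vs)
  # membrane shells are ~1 voxel thick: wide enough that the shell
  # registers on the voxel-center lattice (window equals the voxel
  # pitch), thin enough that a thin crista lumen keeps an interior
  # voxel layer between its two walls. A thinner shell also means less
  # rounding of sharp crista rims during mid-surface extraction.
  shell_half <- 0.5 * vmax

  if (spec$envelope_kind == "capsule") {
    L <- unname(spec$envelope_dims["L"]); r <- unname(spec$envelope_dims["r"])
    half <- c(L / 2 + r, r, r)
  } else {
    half <- unname(spec$envelope_dims[c("a", "b", "c")])
  }
  half <- half + shell_half + pad_voxels * vs
  n_dim <- pmax(4L, ceiling(2 * half / vs))
  if (prod(n_dim) > max_voxels) {
    stop_cm(sprintf(
      "phantom grid of %d x %d x %d voxels exceeds max_voxels = %g",
      n_dim[1], n_dim[2], n_dim[3], max_voxels), "cristamorph_size_error")
  }

  sdf_omm_f <- envelope_sdf_fun(spec, offset = 0)
  sdf_ibm_f <- envelope_sdf_fun(spec, offset = spec$membrane_separation)
  centers <- crista_centers(spec)

  # cristae must sit strictly inside the IBM (convex), with clearance for
  # the membrane shells and one voxel of matrix
  clearance <- 2 * shell_half + vmax
  for (xc in centers) {
    bb <- crista_bbox(spec, xc)
    corners <- as.matrix(expand.grid(bb[1, ], bb[2, ], bb[3, ]))
    d <- sdf_ibm_f(corners[, 1], corners[, 2], corners[, 3])
    if (any(d > -clearance)) {
      stop_cm("cristae overlap or come too close to the IBM envelope",
              "cristamorph_geometry_error")
    }
  }
  if (length(centers) > 1 && spec$crista_model == "lamellar") {
    gap <- unname(spec$crista_dims["s"] - spec$crista_dims["t"])
    if (gap <= clearance) {
      stop_cm("adjacent crista membranes merge at this voxel size",
              "cristamorph_geometry_error")
    }
  }

  xs <- (seq_len(n_dim[1]) - 0.5) * vs[1] - n_dim[1] * vs[1] / 2
  ys <- (seq_len(n_dim[2]) - 0.5) * vs[2] - n_dim[2] * vs[2] / 2
  zs <- (seq_len(n_dim[3]) - 0.5) * vs[3] - n_dim[3] * vs[3] / 2
  X <- array(rep(xs, times = n_dim[2] * n_dim[3]), dim = n_dim)
  Y <- array(rep(rep(ys, each = n_dim[1]), times = n_dim[3]), dim = n_dim)
  Z <- array(rep(zs, each = n_dim[1] * n_dim[2]), dim = n_dim)

  d_omm <- sdf_omm_f(X, Y, Z)
  d_ibm <- sdf_ibm_f(X, Y, Z)
  d_cri <- if (length(centers) > 0) {
    dmin <- crista_sdf_fun(spec, centers[1])(X, Y, Z)
    for (xc in centers[-1]) {
      dmin <- pmin(dmin, crista_sdf_fun(spec, xc)(X, Y, Z))
    }
    dmin
  } else {
    array(Inf, dim = n_dim)
  }

  leg <- mito_label_legend()
  lab <- array(leg[["background"]], dim = n_dim)
  lab[abs(d_omm) <= shell_half] <- leg[["omm"]]
  ims <- d_omm < -shell_half & d_ibm > shell_half
  lab[ims] <- leg[["ims"]]
  lab[abs(d_ibm) <= shell_half & d_omm < -shell_half] <- leg[["ibm"]]
  inside_ibm <- d_ibm < -shell_half
  lab[inside_ibm] <- leg[["matrix"]]
  lab[inside_ibm & abs(d_cri) <= shell_half] <- leg[["cm"]]
  lab[inside_ibm & d_cri < -shell_half] <- leg[["crista_lumen"]]

  vol <- labeled_volume(lab, voxel_size = vs,
                        original_thickness = n_dim[3] * vs[3],
                        reconstructed_thickness = n_dim[3] * vs[3])
  attr(vol, "seed") <- spec$seed
  list(volume = vol, ground_truth = truth)
}
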