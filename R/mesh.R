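#' Triangle mesh of a compartment surface
#'
#' Lightweight S3 container: `vertices` is an n x 3 matrix of nm
#' coordinates, `triangles` an m x 3 matrix of 1-based vertex indices
#' wound so that normals point out of the enclosed compartment.
#'
#' @param vertices n x 3 numeric matrix, nm.
#' @param triangles m x 3 integer matrix of vertex indices.
#' @param compartment compartment name.
#' @param closed logical; `TRUE` if the mesh is watertight.
#' @param n_components number of connected components.
#' @param oriented logical; `TRUE` when construction guarantees outward
#'   winding on every component (set by the package's meshers).
#' @return object of class `compartment_mesh`.
#' @export
compartment_mesh <- function(vertices, triangles, compartment = "",
                             closed = NA, n_components = NA_integer_,
                             oriented = FALSE) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || (nrow(triangles) > 0 && ncol(triangles) != 3L)) {
    stop_cm("vertices and triangles must have three columns",
            "cristamorph_argument_error")
  }
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices))) {
    stop_cm("triangle indices out of range", "cristamorph_argument_error")
  }
  structure(list(vertices = vertices, triangles = triangles,
                 compartment = compartment, closed = closed,
                 n_components = n_components, oriented = oriented),
            class = "compartment_mesh")
}

#' @export
print.compartment_mesh <- function(x, ...) {
  cat(sprintf(
    "<compartment_mesh> '%s': %d vertices, %d triangles, %s, %s component(s)\n",
    x$compartment, nrow(x$vertices), nrow(x$triangles),
    if (isTRUE(x$closed)) "watertight" else "open/unknown",
    x$n_components))
  invisible(x)
}

# undirected edge keys of all triangle edges (3 per face); numeric keys
# are exact below 2^53 (vertex counts far smaller than 2^26)
mesh_edge_keys <- function(tri, nv) {
  a <- c(tri[, 1], tri[, 2], tri[, 3])
  b <- c(tri[, 2], tri[, 3], tri[, 1])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  list(lo = lo, hi = hi, key = lo * (nv + 1) + hi)
}

mesh_open_edge_count <- function(mesh) {
  if (nrow(mesh$triangles) == 0) return(0L)
  key <- mesh_edge_keys(mesh$triangles, nrow(mesh$vertices))$key
  cnt <- tabulate(match(key, unique(key)))
  sum(cnt != 2L)
}

#' Is a mesh watertight?
#'
#' A mesh is watertight when every undirected edge is shared by exactly
#' two triangles.
#'
#' @param mesh a [compartment_mesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  nrow(mesh$triangles) > 0 && mesh_open_edge_count(mesh) == 0L
}

# connected components of the triangle graph (union-find over vertices)
mesh_component_count <- function(mesh) {
  nv <- nrow(mesh$vertices)
  if (nv == 0 || nrow(mesh$triangles) == 0) return(0L)
  cpp_mesh_component_count(mesh$triangles, nv)
}

#' Iso-surface or voxel-exact mesh of a labeled compartment
#'
#' Two meshing modes:
#'
#' * `"isosurface"` (default): builds a scalar field that is 1 inside
#'   the compartment, 0 outside, and 0.5 on the membrane shell itself,
#'   smooths it with a small Gaussian, and extracts the 0.5 level set by
#'   marching tetrahedra. Because the shell is assigned the iso-value,
#'   the extracted surface passes through the shell mid-surface, so
#'   membrane thickness does not contribute to area. Accurate for
#'   curved, smooth organelle surfaces.
#' * `"block"`: the voxel-exact boundary of the binary mask (every
#'   exposed voxel face, two triangles each). Areas and volumes are then
#'   exact for axis-aligned shapes (a single voxel of edge a gives area
#'   6a^2 and volume a^3), which makes this mode the oracle for the
#'   divergence-theorem volume integrator.
#'
#' For membrane compartments the labels strictly inside the membrane are
#' taken from `vol$interior_sets`; volumetric compartments (no interior
#' set) are meshed as solids.
#'
#' @param vol a [labeled_volume()].
#' @param compartment name present in the volume legend.
#' @param method `"isosurface"` or `"block"`.
#' @param sigma Gaussian smoothing bandwidth in voxels (isosurface mode).
#' @param interior optional character vector overriding the interior
#'   label set for this compartment.
#' @return a [compartment_mesh()]; its `n_components` field flags
#'   multi-blob labels.
#' @export
mesh_from_labels <- function(vol, compartment,
                             method = c("isosurface", "block"),
                             sigma = 0.9, interior = NULL) {
  stopifnot(inherits(vol, "labeled_volume"))
  method <- match.arg(method)
  if (!compartment %in% names(vol$legend)) {
    stop_cm(sprintf("compartment '%s' is not in the volume legend",
                    compartment), "cristamorph_argument_error")
  }
  id <- vol$legend[[compartment]]
  interior <- interior %||% vol$interior_sets[[compartment]]
  lab <- vol$labels
  d <- dim(lab)
  field <- array(0, dim = d)
  if (is.null(interior)) {
    field[lab == id] <- 1
  } else {
    in_ids <- vol$legend[intersect(interior, names(vol$legend))]
    field[lab == id] <- 0.5
    if (length(in_ids)) field[array(lab %in% in_ids, dim = d)] <- 1
  }
  if (!any(field > 0)) {
    stop_cm(sprintf("compartment '%s' has no voxels", compartment),
            "cristamorph_empty_mesh_error")
  }

  if (method == "isosurface") {
    if (sigma > 0) field <- cpp_gauss_smooth3(field, d, sigma)
    res <- cpp_marching_tets(field, d, vol$voxel_size, 0.5)
    mesh <- compartment_mesh(res$vertices, res$triangles, compartment,
                             oriented = TRUE)
  } else {
    mesh <- block_mesh(field >= 0.5, vol$voxel_size, compartment)
  }
  mesh$closed <- is_watertight(mesh)
  mesh$n_components <- mesh_component_count(mesh)
  mesh
}

# voxel-exact boundary mesh: two triangles per exposed voxel face,
# vertices on the voxel-corner lattice, outward winding
block_mesh <- function(mask, voxel_size, compartment = "") {
  d <- dim(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  node_id <- function(i, j, k) i + (nx + 1L) * (j + (ny + 1L) * k) # 0-based
  shift <- function(m, dx, dy, dz) {
    out <- array(FALSE, dim = d)
    xs <- seq_len(nx) + dx; ys <- seq_len(ny) + dy; zs <- seq_len(nz) + dz
    okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
    okz <- zs >= 1 & zs <= nz
    out[which(okx), which(oky), which(okz)] <-
      m[xs[okx], ys[oky], zs[okz], drop = FALSE]
    out
  }
  tris <- vector("list", 6)
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (q in seq_along(dirs)) {
    dv <- dirs[[q]]
    exposed <- mask & !shift(mask, dv[1], dv[2], dv[3])
    idx <- which(exposed, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    i0 <- idx[, 1] - 1L; j0 <- idx[, 2] - 1L; k0 <- idx[, 3] - 1L
    # face corner nodes for each direction, wound so normals point along dv
    face <- switch(q,
      cbind(node_id(i0 + 1, j0, k0), node_id(i0 + 1, j0 + 1, k0),
            node_id(i0 + 1, j0 + 1, k0 + 1), node_id(i0 + 1, j0, k0 + 1)),
      cbind(node_id(i0, j0, k0), node_id(i0, j0, k0 + 1),
            node_id(i0, j0 + 1, k0 + 1), node_id(i0, j0 + 1, k0)),
      cbind(node_id(i0, j0 + 1, k0), node_id(i0, j0 + 1, k0 + 1),
            node_id(i0 + 1, j0 + 1, k0 + 1), node_id(i0 + 1, j0 + 1, k0)),
      cbind(node_id(i0, j0, k0), node_id(i0 + 1, j0, k0),
            node_id(i0 + 1, j0, k0 + 1), node_id(i0, j0, k0 + 1)),
      cbind(node_id(i0, j0, k0 + 1), node_id(i0 + 1, j0, k0 + 1),
            node_id(i0 + 1, j0 + 1, k0 + 1), node_id(i0, j0 + 1, k0 + 1)),
      cbind(node_id(i0, j0, k0), node_id(i0, j0 + 1, k0),
            node_id(i0 + 1, j0 + 1, k0), node_id(i0 + 1, j0, k0)))
    tris[[q]] <- rbind(face[, c(1, 2, 3), drop = FALSE],
                       face[, c(1, 3, 4), drop = FALSE])
  }
  allt <- do.call(rbind, tris)
  if (is.null(allt) || nrow(allt) == 0) {
    return(compartment_mesh(matrix(numeric(0), 0, 3),
                            matrix(integer(0), 0, 3), compartment))
  }
  nodes <- sort(unique(as.vector(allt)))
  remap <- integer(max(nodes) + 1L)
  remap[nodes + 1L] <- seq_along(nodes)
  tri <- matrix(remap[allt + 1L], ncol = 3)
  i <- nodes %% (nx + 1L)
  j <- (nodes %/% (nx + 1L)) %% (ny + 1L)
  k <- nodes %/% ((nx + 1L) * (ny + 1L))
  verts <- cbind(i * voxel_size[1], j * voxel_size[2], k * voxel_size[3])
  compartment_mesh(verts, tri, compartment, oriented = TRUE)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas in nm^2. Degenerate triangles contribute zero;
#' if every triangle is degenerate a warning is raised.
#'
#' @param mesh a [compartment_mesh()].
#' @return area in nm^2.
#' @export
surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "compartment_mesh"))
  tri <- mesh$triangles
  if (nrow(tri) == 0) {
    stop_cm("mesh has no triangles", "cristamorph_empty_mesh_error")
  }
  v <- mesh$vertices
  u <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  w <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  areas <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  if (all(areas == 0)) {
    warn_cm("all triangles are degenerate", "cristamorph_degenerate_warning")
  }
  sum(areas)
}

#' Volume enclosed by a watertight mesh
#'
#' Divergence-theorem signed volume (sum of signed tetrahedra against
#' the origin), returned as an absolute value after verifying that the
#' triangle orientation is globally consistent. Non-watertight meshes
#' raise an error naming the number of open edges; [cap_mesh_holes()]
#' can close planar openings first.
#'
#' @param mesh a [compartment_mesh()].
#' @return volume in nm^3.
#' @export
enclosed_volume <- function(mesh) {
  stopifnot(inherits(mesh, "compartment_mesh"))
  tri <- mesh$triangles
  if (nrow(tri) == 0) {
    stop_cm("mesh has no triangles", "cristamorph_empty_mesh_error")
  }
  open_edges <- mesh_open_edge_count(mesh)
  if (open_edges > 0) {
    stop_cm(sprintf("mesh is not watertight: %d open edge(s)", open_edges),
            "cristamorph_open_mesh_error")
  }
  v <- mesh$vertices
  signed_sum <- function(tri) {
    p0 <- v[tri[, 1], , drop = FALSE]
    p1 <- v[tri[, 2], , drop = FALSE]
    p2 <- v[tri[, 3], , drop = FALSE]
    p0[, 1] * (p1[, 2] * p2[, 3] - p1[, 3] * p2[, 2]) -
      p0[, 2] * (p1[, 1] * p2[, 3] - p1[, 3] * p2[, 1]) +
      p0[, 3] * (p1[, 1] * p2[, 2] - p1[, 2] * p2[, 1])
  }
  if (isTRUE(mesh$oriented)) {
    # construction guarantees outward winding on every component
    return(abs(sum(signed_sum(mesh$triangles))) / 6)
  }
  # unknown provenance: make winding consistent per connected component
  # and accumulate absolute component volumes
  fixed <- cpp_orient_faces(mesh$triangles, mesh$vertices)
  det <- signed_sum(fixed$faces)
  sum(abs(tapply(det, fixed$component, sum))) / 6
}

#' Close planar openings of a mesh with centroid fans
#'
#' Finds boundary loops (edges used by a single triangle) and caps each
#' with a triangle fan around the loop centroid, oriented to match the
#' surrounding surface. Used to close crista membranes that open at a
#' crista junction before integrating the lumen volume.
#'
#' @param mesh a [compartment_mesh()].
#' @return a watertight [compartment_mesh()] (if all openings were
#'   simple loops).
#' @export
cap_mesh_holes <- function(mesh) {
  tri <- mesh$triangles
  a <- c(tri[, 1], tri[, 2], tri[, 3])
  b <- c(tri[, 2], tri[, 3], tri[, 1])
  key <- paste(pmin(a, b), pmax(a, b))
  cnt <- table(key)
  boundary <- cnt[key] == 1L
  if (!any(boundary)) return(mesh)
  ba <- a[boundary]
  bb <- b[boundary]
  nxt <- stats::setNames(bb, ba) # each boundary vertex has one outgoing edge
  verts <- mesh$vertices
  new_tri <- list()
  remaining <- stats::setNames(rep(TRUE, length(ba)), ba)
  for (s in ba) {
    if (!isTRUE(remaining[[as.character(s)]])) next
    loop <- s
    cur <- nxt[[as.character(s)]]
    remaining[[as.character(s)]] <- FALSE
    while (!is.null(cur) && cur != s) {
      loop <- c(loop, cur)
      remaining[[as.character(cur)]] <- FALSE
      cur <- nxt[[as.character(cur)]]
    }
    centroid <- colMeans(verts[loop, , drop = FALSE])
    verts <- rbind(verts, centroid)
    cid <- nrow(verts)
    to <- c(loop[-1], loop[1])
    # interior face traverses (a, b); cap must traverse (b, a)
    new_tri[[length(new_tri) + 1L]] <- cbind(to, loop, cid)
  }
  mesh$vertices <- verts
  mesh$triangles <- rbind(tri, do.call(rbind, new_tri))
  mesh$closed <- is_watertight(mesh)
  mesh
}

#' z-scaling factor for beam-induced section thinning
#'
#' Reconstructed tomographic volumes are thinner than the cut section
#' because of shrinkage under the electron beam. Measurements are made on
#' models whose z-coordinates are stretched back by
#' `original / reconstructed`.
#'
#' @param original_thickness section thickness at cutting, nm.
#' @param reconstructed_thickness thickness of the reconstructed volume, nm.
#' @return multiplicative z scale factor.
#' @examples
#' z_scale_factor(200, 120) # 1.667
#' @export
z_scale_factor <- function(original_thickness, reconstructed_thickness) {
  check_positive(original_thickness, "original_thickness")
  check_positive(reconstructed_thickness, "reconstructed_thickness")
  original_thickness / reconstructed_thickness
}

#' Apply a z scale factor to mesh coordinates
#'
#' @param mesh a [compartment_mesh()].
#' @param factor scale factor from [z_scale_factor()].
#' @return the rescaled mesh.
#' @export
apply_z_scale <- function(mesh, factor) {
  stopifnot(inherits(mesh, "compartment_mesh"))
  check_positive(factor, "factor")
  mesh$vertices[, 3] <- mesh$vertices[, 3] * factor
  mesh
}

#' Write / read a compartment mesh as PLY
#'
#' Binary little-endian PLY by default (float vertex coordinates, int32
#' face indices); `ascii = TRUE` writes a plain-text variant readable by
#' the same reader.
#'
#' @param mesh a [compartment_mesh()].
#' @param path file path.
#' @param ascii write ASCII PLY instead of binary.
#' @return `path` invisibly (writer); a [compartment_mesh()] (reader).
#' @export
write_ply <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "compartment_mesh"))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$triangles)
  fmt <- if (ascii) "ascii" else "binary_little_endian"
  header <- c("ply", sprintf("format %s 1.0", fmt),
              sprintf("comment compartment %s", mesh$compartment),
              sprintf("element vertex %d", nv),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices", "end_header")
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
    writeLines(paste(3, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                     mesh$triangles[, 3] - 1L), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.numeric(t(mesh$vertices)), con, size = 4L,
             endian = "little")
    for (r in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$triangles[r, ] - 1L), con, size = 4L,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 100) {
      stop_cm("malformed PLY header", "cristamorph_io_error")
    }
  }
  fmt <- sub("^format (\\S+).*$", "\\1", grep("^format", header, value = TRUE))
  nv <- as.integer(sub("^element vertex (\\d+).*$", "\\1",
                       grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("^element face (\\d+).*$", "\\1",
                       grep("^element face", header, value = TRUE)))
  comp <- sub("^comment compartment ", "",
              grep("^comment compartment", header, value = TRUE))
  if (length(comp) == 0) comp <- ""
  if (fmt == "ascii") {
    vl <- readLines(con, n = nv)
    verts <- do.call(rbind, lapply(strsplit(vl, " +"),
                                   function(x) as.numeric(x[1:3])))
    fl <- readLines(con, n = nf)
    tris <- do.call(rbind, lapply(strsplit(fl, " +"),
                                  function(x) as.integer(x[2:4]) + 1L))
  } else {
    verts <- matrix(readBin(con, "numeric", n = 3L * nv, size = 4L,
                            endian = "little"),
                    ncol = 3L, byrow = TRUE)
    tris <- matrix(0L, nf, 3L)
    for (r in seq_len(nf)) {
      readBin(con, "raw", n = 1L)
      tris[r, ] <- readBin(con, "integer", n = 3L, size = 4L,
                           endian = "little") + 1L
    }
  }
  if (nv == 0) verts <- matrix(numeric(0), 0, 3)
  if (nf == 0) tris <- matrix(integer(0), 0, 3)
  mesh <- compartment_mesh(verts, tris, comp)
  mesh$closed <- is_watertight(mesh)
  mesh$n_components <- mesh_component_count(mesh)
  mesh
}
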