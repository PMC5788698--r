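test_that("block mesh of a single voxel is the exact cube", {
  vol <- single_voxel_volume(edge_nm = 10)
  m <- mesh_from_labels(vol, "matrix", method = "block")
  expect_true(is_watertight(m))
  expect_equal(surface_area(m), 6 * 10^2)
  expect_equal(enclosed_volume(m), 10^3)
  expect_identical(m$n_components, 1L)
})

test_that("block-mesh volume equals voxel count times voxel volume", {
  lab <- array(0L, dim = c(8, 8, 8))
  lab[2:5, 3:6, 2:4] <- 4L          # axis-aligned block
  lab[7, 7, 6:7] <- 4L              # second detached blob
  vol <- labeled_volume(lab, voxel_size = c(5, 4, 6))
  m <- mesh_from_labels(vol, "matrix", method = "block")
  expect_equal(enclosed_volume(m), (4 * 4 * 3 + 2) * 5 * 4 * 6)
  expect_identical(m$n_components, 2L) # disjoint blobs are flagged
})

test_that("iso-surface mesh recovers a voxelized sphere within tolerance", {
  r <- 500
  vox <- 5
  n <- ceiling(2 * (r + 8 * vox) / vox)
  ax <- (seq_len(n) - 0.5) * vox - n * vox / 2
  X <- array(rep(ax, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(ax, each = n * n), dim = c(n, n, n))
  lab <- array(0L, dim = c(n, n, n))
  lab[X^2 + Y^2 + Z^2 <= r^2] <- 4L
  vol <- labeled_volume(lab, voxel_size = vox)
  m <- mesh_from_labels(vol, "matrix", method = "isosurface", sigma = 0.9)
  expect_true(is_watertight(m))
  expect_lt(abs(surface_area(m) - 4 * pi * r^2) / (4 * pi * r^2), 0.02)
  expect_lt(abs(enclosed_volume(m) - 4 / 3 * pi * r^3) /
              (4 / 3 * pi * r^3), 0.01)
})

test_that("surface area matches closed forms and scaling laws", {
  # unit-edge regular tetrahedron: area sqrt(3)
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  tris <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  m <- compartment_mesh(verts, tris, "tetra")
  expect_equal(surface_area(m), sqrt(3), tolerance = 1e-12)
  s <- 2.5
  ms <- m
  ms$vertices <- ms$vertices * s
  expect_equal(surface_area(ms), sqrt(3) * s^2, tolerance = 1e-12)
  expect_equal(enclosed_volume(ms), enclosed_volume(m) * s^3,
               tolerance = 1e-12)
})

test_that("degenerate-only meshes warn; empty masks error", {
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  m <- compartment_mesh(verts, rbind(c(1, 2, 3)), "line")
  expect_warning(surface_area(m), class = "cristamorph_degenerate_warning")
  vol <- single_voxel_volume()
  expect_error(mesh_from_labels(vol, "cm"),
               class = "cristamorph_empty_mesh_error")
})

test_that("enclosed_volume rejects open meshes, naming open edges", {
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  open_mesh <- compartment_mesh(verts, rbind(c(1, 2, 3), c(1, 2, 4)), "open")
  err <- tryCatch(enclosed_volume(open_mesh), error = identity)
  expect_s3_class(err, "cristamorph_open_mesh_error")
  expect_match(conditionMessage(err), "open edge")
})

test_that("hole capping closes an open surface for volume integration", {
  vol <- single_voxel_volume(edge_nm = 10)
  m <- mesh_from_labels(vol, "matrix", method = "block")
  # remove the two triangles of the +z face: one square opening
  zmax <- max(m$vertices[, 3])
  face_z <- apply(m$triangles, 1, function(tr)
    all(m$vertices[tr, 3] == zmax))
  open_mesh <- m
  open_mesh$triangles <- m$triangles[!face_z, , drop = FALSE]
  expect_false(is_watertight(open_mesh))
  capped <- cap_mesh_holes(open_mesh)
  expect_true(is_watertight(capped))
  expect_equal(enclosed_volume(capped), 1000)
})

test_that("orientation is normalized before volume integration", {
  vol <- single_voxel_volume(edge_nm = 10)
  m <- mesh_from_labels(vol, "matrix", method = "block")
  scrambled <- m
  scrambled$oriented <- FALSE
  flip <- c(1, 4, 7)
  scrambled$triangles[flip, ] <- scrambled$triangles[flip, c(1, 3, 2)]
  expect_equal(enclosed_volume(scrambled), 1000)
})

test_that("z-scaling follows thickness ratio and the affine volume law", {
  expect_equal(z_scale_factor(200, 200), 1.0)
  expect_equal(z_scale_factor(200, 120), 1.6667, tolerance = 1e-4)
  expect_error(z_scale_factor(0, 100), class = "cristamorph_argument_error")
  vol <- single_voxel_volume(edge_nm = 10)
  m <- mesh_from_labels(vol, "matrix", method = "block")
  f <- 1.37
  expect_equal(enclosed_volume(apply_z_scale(m, f)),
               f * enclosed_volume(m), tolerance = 1e-12)
  # z-scaling is applied to coordinates before measurement in the
  # measurement pipeline (order fixed): a thinner reconstruction scales
  # the measured volume up by exactly f
  lab <- array(0L, dim = c(6, 6, 6)); lab[2:5, 2:5, 2:5] <- 4L
  v1 <- labeled_volume(lab, voxel_size = 10)
  v2 <- labeled_volume(lab, voxel_size = 10, original_thickness = 60,
                       reconstructed_thickness = 40)
  m1 <- measure_block <- function(v) {
    mm <- mesh_from_labels(v, "matrix", method = "block")
    mm <- apply_z_scale(mm, z_scale_factor(v$original_thickness,
                                           v$reconstructed_thickness))
    enclosed_volume(mm)
  }
  expect_equal(measure_block(v2), measure_block(v1) * 1.5)
})

test_that("PLY round-trips binary and ascii meshes", {
  vol <- single_voxel_volume(edge_nm = 10)
  m <- mesh_from_labels(vol, "matrix", method = "block")
  for (ascii in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".ply")
    write_ply(m, path, ascii = ascii)
    m2 <- read_ply(path)
    expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-6)
    expect_identical(dim(m2$triangles), dim(m$triangles))
    expect_equal(enclosed_volume(m2), 1000, tolerance = 1e-4)
    expect_identical(m2$compartment, "matrix")
    unlink(path)
  }
})

test_that("isotropic scaling transforms densities by 1/s", {
  p <- generate_mito_phantom(mito_phantom_spec(voxel_size = 8))
  vol <- p$volume
  m <- mesh_from_labels(vol, "cm", sigma = 0.55)
  a1 <- surface_area(m); v1 <- enclosed_volume(m)
  s <- 2
  ms <- m
  ms$vertices <- ms$vertices * s
  expect_equal(surface_area(ms) / a1, s^2, tolerance = 1e-10)
  expect_equal(enclosed_volume(ms) / v1, s^3, tolerance = 1e-10)
  # hence cm_density and csf scale by 1/s
  expect_equal((surface_area(ms) / enclosed_volume(ms)) / (a1 / v1),
               1 / s, tolerance = 1e-10)
})
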