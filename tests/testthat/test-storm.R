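test_that("photon filtering keeps bright points and preserves order", {
  locs <- data.frame(x_nm = 1:5, y_nm = 1:5, z_nm = 0,
                     photons = c(100, 900, 1500, 2000, 50),
                     channel = 1, frame = 1:5)
  expect_identical(filter_slp(locs, 0)$photons, locs$photons)
  f <- filter_slp(locs, 1000)
  expect_identical(f$photons, c(1500, 2000))
  expect_identical(nrow(filter_slp(locs, 1e6)), 0L)
  expect_error(filter_slp(locs, -1), class = "cristamorph_argument_error")
})

test_that("convex hull area is exact on a unit square and ignores interior
          points", {
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  h <- convex_hull_area(sq)
  expect_equal(h$area_um2, 1.0)
  with_interior <- rbind(sq, c(500, 500), c(250, 750))
  h2 <- convex_hull_area(with_interior)
  expect_equal(h2$area_um2, h$area_um2)
  expect_setequal(with_interior[h2$hull, 1], sq[, 1])
})

test_that("hull area is invariant to order and rigid motion, monotone
          under addition", {
  set.seed(42)
  pts <- cbind(runif(60, 0, 800), runif(60, 0, 500))
  a0 <- convex_hull_area(pts)$area_um2
  expect_equal(convex_hull_area(pts[sample(60), ])$area_um2, a0)
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- sweep(pts %*% rot, 2, c(2000, -350), "+")
  expect_equal(convex_hull_area(moved)$area_um2, a0, tolerance = 1e-12)
  a_prev <- 0
  for (k in c(10, 25, 60)) {
    a_k <- convex_hull_area(pts[1:k, ])$area_um2
    expect_gte(a_k, a_prev)
    a_prev <- a_k
  }
})

test_that("degenerate clusters raise and are excluded from delineation", {
  expect_error(convex_hull_area(rbind(c(0, 0), c(1, 1))),
               class = "cristamorph_degenerate_cluster_error")
  expect_error(convex_hull_area(cbind(1:5, 2 * (1:5))),
               class = "cristamorph_degenerate_cluster_error")
  locs <- data.frame(
    x_nm = c(0, 800, 800, 0, 0, 100, 200),
    y_nm = c(0, 0, 600, 600, 0, 100, 200),
    cluster_id = c("good", "good", "good", "good", "bad", "bad", "bad"))
  locs$y_nm[5:7] <- locs$x_nm[5:7] # collinear cluster
  d <- delineate_clusters(locs)
  expect_identical(d$excluded, "bad")
  expect_identical(d$clusters$cluster_id, "good")
})

test_that("slp_density divides count by hull area", {
  expect_equal(slp_density(100, 0.25), 400)
  expect_equal(slp_density(0, 0.5), 0)
  expect_error(slp_density(10, 0), class = "cristamorph_argument_error")
  # unit-convention invariance: nm coordinates to um^2 area
  pts_nm <- rbind(c(0, 0), c(500, 0), c(500, 500), c(0, 500))
  area_um2 <- convex_hull_area(pts_nm)$area_um2
  area_direct <- (500 / 1000)^2
  expect_equal(slp_density(50, area_um2), 50 / area_direct)
})

test_that("storm fields honor Poisson counts, jitter and truth labels", {
  fp <- data.frame(cx_um = 5, cy_um = 5, ax_um = sqrt(0.3 / pi),
                   ay_um = sqrt(0.3 / pi), density_per_um2 = 600)
  counts <- vapply(1:40, function(s) {
    f <- generate_storm_field(storm_field_spec(fp, seed = s))
    sum(f$truth_label == "specific")
  }, numeric(1))
  # lambda x A = 600 x 0.3 = 180 specific points expected per field
  expect_equal(mean(counts), 180, tolerance = 0.05)
  # sigma = 0: all specific points exactly inside the footprint
  f0 <- generate_storm_field(storm_field_spec(fp, sigma_xy_nm = 0,
                                              seed = 2))
  r2 <- ((f0$x_nm / 1000 - 5) / fp$ax_um)^2 +
        ((f0$y_nm / 1000 - 5) / fp$ay_um)^2
  expect_lte(max(r2), 1 + 1e-9)
  # background-only field
  fb <- generate_storm_field(storm_field_spec(
    fp[0, ], background_density_per_um2 = 10, seed = 3))
  expect_true(all(fb$truth_label == "background"))
  expect_error(storm_field_spec(
    data.frame(cx_um = 0.1, cy_um = 5, ax_um = 0.5, ay_um = 0.2,
               density_per_um2 = 10)), class = "cristamorph_argument_error")
})

test_that("photon filtering separates well-separated photon models", {
  fp <- data.frame(cx_um = 5, cy_um = 5, ax_um = 0.4, ay_um = 0.3,
                   density_per_um2 = 600)
  f <- generate_storm_field(storm_field_spec(
    fp, background_density_per_um2 = 30, seed = 9))
  kept <- filter_slp(f, photon_threshold = 1500)
  recall <- sum(kept$truth_label == "specific") /
    sum(f$truth_label == "specific")
  precision <- mean(kept$truth_label == "specific")
  expect_gt(recall, 0.95)
  expect_gt(precision, 0.95)
})

test_that("hull density estimates the generative SLP density", {
  fp <- data.frame(cx_um = 5, cy_um = 5, ax_um = 0.45, ay_um = 0.35,
                   density_per_um2 = 600)
  dens <- vapply(1:20, function(s) {
    f <- generate_storm_field(storm_field_spec(fp, seed = 20 + s))
    cl <- delineate_clusters(f)$clusters
    cl$slp_density[1]
  }, numeric(1))
  # hulls sit inside the true ellipse, so the estimate is mildly biased
  # upward relative to the footprint density; it must land near truth
  expect_equal(mean(dens), 600, tolerance = 0.10)
})

test_that("paired areas across channels correlate strongly", {
  expect_equal(paired_area_correlation(1:10, 1:10)$r, 1.0)
  expect_equal(paired_area_correlation(1:10, -(1:10))$r, -1.0)
  expect_error(paired_area_correlation(rep(1, 5), 1:5),
               class = "cristamorph_degenerate_error")
  # same footprints sampled independently in two channels
  set.seed(5)
  sizes <- runif(48, 0.2, 0.6)
  fps <- data.frame(cx_um = rep(seq(1, 12, length.out = 8), 6),
                    cy_um = rep(seq(1, 12, length.out = 6), each = 8),
                    ax_um = sizes, ay_um = sizes * 0.8,
                    density_per_um2 = 500)
  a <- generate_storm_field(storm_field_spec(fps, field_size_um = c(13, 13),
                                             seed = 101))
  b <- generate_storm_field(storm_field_spec(fps, field_size_um = c(13, 13),
                                             seed = 202))
  ca <- delineate_clusters(a)$clusters
  cb <- delineate_clusters(b)$clusters
  shared <- intersect(ca$cluster_id, cb$cluster_id)
  r <- paired_area_correlation(ca$area_um2[match(shared, ca$cluster_id)],
                               cb$area_um2[match(shared, cb$cluster_id)])$r
  expect_gt(r, 0.9)
})

test_that("homer volume counts connected voxels times voxel volume", {
  mask <- array(FALSE, dim = c(10, 10, 10))
  mask[2:6, 2:5, 2:6] <- TRUE # 100 voxels
  hv <- homer_volume(mask, c(0.08, 0.08, 0.15))
  expect_equal(hv$volume_um3, 100 * 0.08 * 0.08 * 0.15)
  expect_equal(hv$volume_um3, 0.096)
  expect_identical(hv$n_components, 1L)
  mask[9, 9, 9] <- TRUE # satellite speck
  hv2 <- homer_volume(mask, c(0.08, 0.08, 0.15))
  expect_identical(hv2$n_components, 2L)
  expect_equal(hv2$volume_um3, 0.096) # largest component only
  expect_warning(h0 <- homer_volume(array(FALSE, dim = c(3, 3, 3)),
                                    c(0.1, 0.1, 0.1)),
                 class = "cristamorph_empty_mask_warning")
  expect_equal(h0$volume_um3, 0)
})

test_that("voxelized ball volume is recovered within tolerance", {
  n <- 41
  ax <- seq_len(n) - (n + 1) / 2
  X <- array(rep(ax, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(ax, each = n * n), dim = c(n, n, n))
  mask <- X^2 + Y^2 + Z^2 <= 18^2
  hv <- homer_volume(mask, c(0.01, 0.01, 0.01))
  truth <- 4 / 3 * pi * 0.18^3
  expect_lt(abs(hv$volume_um3 - truth) / truth, 0.05)
})

test_that("median split assigns every bouton, ties going to LP", {
  r <- median_split(data.frame(homer_volume_um3 = c(1, 2, 3, 4)))
  expect_identical(r$split_class, c("LP", "LP", "HP", "HP"))
  # odd length: the median record itself goes to LP
  r2 <- median_split(data.frame(homer_volume_um3 = c(5, 1, 3)))
  expect_identical(r2$split_class[r2$homer_volume_um3 == 3], "LP")
  # published DG example: population median 0.0265 um^3
  r3 <- median_split(data.frame(homer_volume_um3 = c(0.011, 0.020, 0.0265,
                                                     0.040, 0.0518)))
  expect_equal(attr(r3, "median_um3"), 0.0265)
  expect_identical(r3$split_class[r3$homer_volume_um3 == 0.011], "LP")
  expect_identical(r3$split_class[r3$homer_volume_um3 == 0.0518], "HP")
  expect_true(all(r3$split_class %in% c("LP", "HP")))
  expect_lte(abs(sum(r3$split_class == "LP") - sum(r3$split_class == "HP")),
             sum(r3$homer_volume_um3 == 0.0265) + 1)
  expect_error(median_split(data.frame()),
               class = "cristamorph_argument_error")
})

test_that("localization CSV round-trips", {
  f <- generate_storm_field(storm_field_spec(
    data.frame(cx_um = 2, cy_um = 2, ax_um = 0.3, ay_um = 0.2,
               density_per_um2 = 300), field_size_um = c(4, 4), seed = 1))
  path <- tempfile(fileext = ".csv")
  write_localizations(f, path)
  f2 <- read_localizations(path)
  expect_equal(f2$x_nm, f$x_nm, tolerance = 1e-9)
  expect_identical(f2$truth_label, f$truth_label)
  unlink(path)
})
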